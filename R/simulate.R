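#' Configuration for the synthetic FFQ-study generator
#'
#' Bundles every knob of the generator.  Defaults emulate the marginal
#' structure of a Spanish population-based case-control study: total
#' energy lognormal with mean 1805 kcal/day (SD 535), per-1000 kcal
#' nutrient densities lognormal with the reference table's global
#' moments, a latent Gaussian factor pair inducing a negative
#' correlation of -0.32 between the computed E-DII and NEAC scores, a
#' ~35\% case fraction, and a planted per-unit log-odds effect of the
#' exposure on case status.
#'
#' @param n number of subjects to generate.
#' @param seed master integer seed; every stage derives its own
#'   deterministic sub-stream from it.
#' @param reference a \code{parameter_reference}
#'   (default \code{\link{default_parameter_reference}()}).
#' @param teac_table a \code{teac_table}
#'   (default \code{\link{default_teac_table}()}).
#' @param energy_mean,energy_sd lognormal moments of total daily energy
#'   (kcal/day).
#' @param edii_neac_correlation target Pearson correlation between the
#'   computed E-DII and NEAC scores, in (-1, 1).
#' @param param_loading,item_loading loadings (0-1) of nutrient densities
#'   and food-item grams on the latent inflammatory and antioxidant
#'   factors; they bound the attainable |correlation|.
#' @param nondrinker_p probability a subject reports zero alcohol intake.
#' @param exposure_type which planted exposure drives case status:
#'   \code{"edii"} (continuous E-DII) or \code{"profile"} (the 0-6
#'   combined score).
#' @param beta_exposure planted per-unit log-odds for the exposure.
#' @param case_fraction target marginal case probability.
#' @param covariate_effects named log-odds of covariate effects on case
#'   status (see defaults in the function body).
#' @param quartile_logor optional length-3 vector of extra planted
#'   log-ORs for E-DII quartiles 2-4 versus 1.
#' @param interaction optional list \code{(modifier, level, logor)}
#'   planting an exposure-by-modifier interaction.
#' @param sex_male_p probability of male sex (set 0 for a single-sex
#'   breast-cancer-style study).
#' @return list of class \code{generator_config}.
#' @export
generator_config <- function(n = 2000, seed = 1,
                             reference = default_parameter_reference(),
                             teac_table = default_teac_table(),
                             energy_mean = 1805, energy_sd = 535,
                             edii_neac_correlation = -0.32,
                             param_loading = 0.65, item_loading = 0.65,
                             nondrinker_p = 0.3,
                             exposure_type = c("edii", "profile"),
                             beta_exposure = log(1.14),
                             case_fraction = 0.35,
                             covariate_effects = NULL,
                             quartile_logor = NULL,
                             interaction = NULL,
                             sex_male_p = 0.517) {
  exposure_type <- match.arg(exposure_type)
  stopifnot(n >= 1, energy_mean > 0, energy_sd > 0,
            abs(edii_neac_correlation) < 1,
            param_loading > 0, param_loading < 1,
            item_loading > 0, item_loading < 1,
            nondrinker_p >= 0, nondrinker_p <= 1,
            case_fraction > 0, case_fraction < 1)
  if (is.null(covariate_effects)) {
    covariate_effects <- c(sex_male = 0.3, age_per10 = 0.25,
                           smoking_current = 0.2, smoking_former = 0.1,
                           bmi_per5 = 0.15, inactive = 0.2,
                           family_history_yes = 0.6)
  }
  structure(list(n = n, seed = as.integer(seed), reference = reference,
                 teac_table = teac_table, energy_mean = energy_mean,
                 energy_sd = energy_sd,
                 edii_neac_correlation = edii_neac_correlation,
                 param_loading = param_loading, item_loading = item_loading,
                 nondrinker_p = nondrinker_p, exposure_type = exposure_type,
                 beta_exposure = beta_exposure, case_fraction = case_fraction,
                 covariate_effects = covariate_effects,
                 quartile_logor = quartile_logor, interaction = interaction,
                 sex_male_p = sex_male_p),
            class = "generator_config")
}

# lognormal meanlog/sdlog from arithmetic mean and sd
lnorm_pars <- function(m, s) {
  sdlog <- sqrt(log(1 + (s / m)^2))
  list(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

# synthetic food-item gram-intake means/SDs paired with the TEAC fixture;
# items absent here get a generic small intake
item_gram_moments <- function(item_names) {
  means <- c(leafy_vegetables = 60, other_vegetables = 90, citrus_fruit = 45,
             other_fruit = 80, berries = 8, legumes = 30, nuts = 8,
             whole_grains = 60, olive_oil = 25, red_wine = 50, tea = 40,
             dark_chocolate = 5, fruit_juice = 50, coffee = 100)
  m <- ifelse(item_names %in% names(means), means[item_names], 20)
  data.frame(item_name = item_names, gram_mean = as.numeric(m),
             gram_sd = 0.8 * as.numeric(m), stringsAsFactors = FALSE)
}

# core sampler: draws n subjects' intake + item tables given the latent
# factor correlation; consumes the current RNG stream.
sample_intake_core <- function(n, rho_latent, config) {
  ref <- config$reference
  teac <- config$teac_table
  p <- nrow(ref)

  u_infl <- stats::rnorm(n)
  u_anti <- rho_latent * u_infl + sqrt(1 - rho_latent^2) * stats::rnorm(n)

  energy <- do.call(stats::rlnorm, c(list(n = n),
                                     lnorm_pars(config$energy_mean,
                                                config$energy_sd)))

  lam <- config$param_loading
  sgn <- ifelse(ref$effect_score >= 0, 1, -1)
  z <- outer(u_infl, sgn * lam) +
    matrix(stats::rnorm(n * p), n, p) * sqrt(1 - lam^2)
  dens <- matrix(0, n, p)
  for (j in seq_len(p)) {
    lp <- lnorm_pars(ref$global_mean[j], ref$global_sd[j])
    dens[, j] <- stats::qlnorm(stats::pnorm(z[, j]), lp$meanlog, lp$sdlog)
  }
  colnames(dens) <- ref$parameter_name
  if ("alcohol" %in% ref$parameter_name && config$nondrinker_p > 0) {
    nondrinker <- stats::runif(n) < config$nondrinker_p
    dens[nondrinker, "alcohol"] <- 0
  }
  raw <- dens * energy / 1000

  intakes <- data.frame(subject_id = sprintf("S%05d", seq_len(n)),
                        energy_kcal = energy,
                        stringsAsFactors = FALSE)
  intakes$alcohol_g <- if ("alcohol" %in% colnames(raw)) raw[, "alcohol"] else 0
  intakes <- cbind(intakes, as.data.frame(raw))

  lam_f <- config$item_loading
  k <- nrow(teac)
  gm <- item_gram_moments(teac$item_name)
  zi <- outer(u_anti, rep(lam_f, k)) +
    matrix(stats::rnorm(n * k), n, k) * sqrt(1 - lam_f^2)
  grams <- matrix(0, n, k)
  for (j in seq_len(k)) {
    lp <- lnorm_pars(gm$gram_mean[j], gm$gram_sd[j])
    grams[, j] <- stats::qlnorm(stats::pnorm(zi[, j]), lp$meanlog, lp$sdlog)
  }
  colnames(grams) <- teac$item_name
  items <- cbind(data.frame(subject_id = intakes$subject_id,
                            stringsAsFactors = FALSE),
                 as.data.frame(grams))
  list(intakes = intakes, items = items)
}

# measure the attainable |cor(E-DII, NEAC)| at perfectly correlated
# latent factors, on a deterministic pilot sample (fixed internal seed so
# the calibration is a pure function of the configured marginal structure)
attainable_correlation <- function(config, n_pilot = 4000) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(1830477L)
  pilot <- sample_intake_core(n_pilot, 1, config)
  edii <- batch_edii(pilot$intakes, config$reference)$edii_total
  neac <- batch_neac(pilot$items, config$teac_table)$teac_total_no_coffee
  stats::cor(edii, neac)
}

#' Generate synthetic FFQ intake and food-item tables
#'
#' Draws subject-level daily energy, raw intakes of every reference food
#' parameter, and food-item gram intakes.  Nutrient densities and item
#' grams have lognormal marginals (guaranteeing non-negativity) coupled
#' through a Gaussian copula: each density loads on a latent inflammatory
#' factor (sign-aligned with its effect score) and each item's grams on
#' a latent antioxidant factor.  The generator first measures, on a
#' deterministic internal pilot, the maximum correlation between the
#' computed E-DII and NEAC scores attainable under the configured
#' marginals, then scales the latent factor correlation so the computed
#' scores hit the configured target; an unattainable target raises an
#' error before any sampling.
#'
#' @param config a \code{\link{generator_config}}.
#' @return list: \code{intakes} (wide intake table), \code{items} (wide
#'   gram table), \code{rho_latent} (the calibrated latent correlation).
#' @export
generate_intakes <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  target <- config$edii_neac_correlation
  rho_latent <- 0
  if (target != 0) {
    cmax <- attainable_correlation(config)
    rho_latent <- target / cmax
    if (!is.finite(rho_latent) || abs(rho_latent) > 1) {
      abort(paste0("target E-DII/NEAC correlation %.3f is infeasible under the",
                   " configured marginals (attainable maximum |r| = %.3f);",
                   " raise the factor loadings"), target, abs(cmax))
    }
  }
  set.seed(derive_seed(config$seed, "intakes"))
  out <- sample_intake_core(config$n, rho_latent, config)
  out$rho_latent <- rho_latent
  out
}

# draw study covariates, marginals loosely mirroring a Spanish
# case-control baseline table (calibration conveniences, not estimates)
sample_covariates <- function(n, config) {
  sex <- ifelse(stats::runif(n) < config$sex_male_p, "male", "female")
  data.frame(
    sex = sex,
    age = pmin(pmax(stats::rnorm(n, 63, 12), 30), 90),
    study_area = sample(paste0("area", 1:5), n, replace = TRUE),
    education = sample(c("less_than_primary", "primary", "high_school",
                         "university"), n, replace = TRUE,
                       prob = c(0.175, 0.325, 0.288, 0.212)),
    smoking = sample(c("never", "former", "current"), n, replace = TRUE,
                     prob = c(0.44, 0.35, 0.21)),
    bmi = pmin(pmax(stats::rnorm(n, 26.6, 4.4), 16), 50),
    physical_activity = sample(c("inactive", "moderately_active", "active",
                                 "very_active"), n, replace = TRUE,
                               prob = c(0.386, 0.147, 0.122, 0.345)),
    family_history = sample(c("no", "yes", "unknown"), n, replace = TRUE,
                            prob = c(0.859, 0.086, 0.055)),
    nsaids = sample(c("no", "yes", "unknown"), n, replace = TRUE,
                    prob = c(0.58, 0.387, 0.033)),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic case-control study with planted effects
#'
#' Builds a full study table: intakes are generated and scored through
#' the package's own E-DII and NEAC engines, covariates are drawn
#' independently of diet, the combined 0-6 profile is computed from
#' sex-specific quartiles of the pre-outcome population, and case status
#' is drawn from the logistic model
#' \deqn{P(case) = logit^{-1}(\alpha + \beta \cdot exposure + \gamma' covariates)}
#' with \eqn{\alpha} solved numerically to hit the requested marginal
#' case fraction.  The planted coefficients are embedded in the result's
#' \code{truth} attribute so downstream fits can be checked for
#' parameter recovery.
#'
#' @param config a \code{\link{generator_config}}.
#' @return study data frame (one row per subject: case status,
#'   covariates, \code{edii}, \code{neac}, quartiles, \code{profile},
#'   \code{combined_category} inputs, sensitivity columns) with
#'   attributes \code{truth} (planted coefficients and seed),
#'   \code{intakes}, \code{items}.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  gen <- generate_intakes(config)
  edii <- batch_edii(gen$intakes, config$reference)
  neac <- batch_neac(gen$items, config$teac_table)
  n <- nrow(gen$intakes)

  set.seed(derive_seed(config$seed, "covariates"))
  cov <- sample_covariates(n, config)

  study <- data.frame(subject_id = gen$intakes$subject_id,
                      stringsAsFactors = FALSE)
  study <- cbind(study, cov)
  study$edii <- edii$edii_total
  study$neac <- neac$teac_total_no_coffee
  study$neac_with_coffee <- neac$teac_total
  study$alcohol_g <- gen$intakes$alcohol_g
  study$energy_kcal <- gen$intakes$energy_kcal
  study$energy_nonalcohol <- gen$intakes$energy_kcal - 7 * gen$intakes$alcohol_g

  # profile from sex-specific quartiles of the pre-outcome population
  grp <- if (config$sex_male_p %in% c(0, 1)) rep("all", n) else study$sex
  es <- lapply(split(study$edii, grp), quartile_cutpoints)
  ns <- lapply(split(study$neac, grp), quartile_cutpoints)
  study$edii_quartile <- assign_quartile_grouped(study$edii, grp, es)
  study$neac_quartile <- assign_quartile_grouped(study$neac, grp, ns)
  study$profile <- edii_neac_profile(study$edii_quartile, study$neac_quartile)

  exposure <- switch(config$exposure_type, edii = study$edii,
                     profile = study$profile)
  eff <- config$covariate_effects
  lp <- config$beta_exposure * exposure +
    eff[["sex_male"]] * (study$sex == "male") +
    eff[["age_per10"]] * (study$age - 63) / 10 +
    eff[["smoking_current"]] * (study$smoking == "current") +
    eff[["smoking_former"]] * (study$smoking == "former") +
    eff[["bmi_per5"]] * (study$bmi - 26.6) / 5 +
    eff[["inactive"]] * (study$physical_activity == "inactive") +
    eff[["family_history_yes"]] * (study$family_history == "yes")
  if (!is.null(config$quartile_logor)) {
    stopifnot(length(config$quartile_logor) == 3)
    lp <- lp + c(0, config$quartile_logor)[study$edii_quartile]
  }
  if (!is.null(config$interaction)) {
    ia <- config$interaction
    lp <- lp + ia$logor * exposure *
      (as.character(study[[ia$modifier]]) == ia$level)
  }

  alpha <- stats::uniroot(
    function(a) mean(stats::plogis(a + lp)) - config$case_fraction,
    lower = -30, upper = 30, tol = 1e-10)$root

  set.seed(derive_seed(config$seed, "outcome"))
  study$case_status <- stats::rbinom(n, 1, stats::plogis(alpha + lp))
  if (all(study$case_status == 1) || all(study$case_status == 0)) {
    abort("requested case fraction %.3f produced a single-outcome study",
          config$case_fraction)
  }

  study$months_diagnosis_to_interview <- NA_real_
  cases <- study$case_status == 1
  study$months_diagnosis_to_interview[cases] <-
    stats::rgamma(sum(cases), shape = 2, scale = 1.8)

  attr(study, "truth") <- list(
    exposure_type = config$exposure_type,
    beta_exposure = config$beta_exposure,
    or_exposure = exp(config$beta_exposure),
    alpha = alpha,
    covariate_effects = as.list(eff),
    quartile_logor = config$quartile_logor,
    interaction = config$interaction,
    rho_latent = gen$rho_latent,
    edii_neac_correlation_target = config$edii_neac_correlation,
    seed = config$seed)
  attr(study, "intakes") <- gen$intakes
  attr(study, "items") <- gen$items
  study
}

#' Covariate set of the generator's final CRC-style model
#'
#' The adjustment set matching the generator's planted covariate model:
#' sex, age, study area, education, family history, smoking, BMI,
#' physical activity and NSAID use.
#'
#' @param include_sex drop sex for single-sex studies or sex-stratified
#'   fits.
#' @return character vector of covariate names.
#' @export
final_model_covariates <- function(include_sex = TRUE) {
  c(if (include_sex) "sex", "age", "study_area", "education",
    "family_history", "smoking", "bmi", "physical_activity", "nsaids")
}
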