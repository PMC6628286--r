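#' Specify a case-control logistic model
#'
#' Bundles the design of one unconditional logistic regression:
#' which exposure column, how the exposure enters (continuous per-unit,
#' quartile indicators with Q1 reference, ordinal 1-4 trend coding, or a
#' categorical variable with a declared reference), and the covariate
#' set.  Character covariates are dummy-coded with their first sorted
#' level as reference; an explicit \code{"unknown"} level is retained as
#' its own dummy, never dropped.
#'
#' @param exposure name of the exposure column.
#' @param exposure_type one of \code{"continuous"}, \code{"quartile"},
#'   \code{"ordinal"}, \code{"categorical"}.
#' @param covariates character vector of covariate column names.
#' @param exposure_ref reference level for categorical exposures.
#' @param label optional model label carried into reports.
#' @return list of class \code{model_spec}.
#' @export
model_spec <- function(exposure, exposure_type = c("continuous", "quartile",
                                                   "ordinal", "categorical"),
                       covariates = character(), exposure_ref = NULL,
                       label = NULL) {
  exposure_type <- match.arg(exposure_type)
  structure(list(exposure = exposure, exposure_type = exposure_type,
                 covariates = covariates, exposure_ref = exposure_ref,
                 label = if (is.null(label)) exposure else label),
            class = "model_spec")
}

#' Fit an unconditional logistic regression model
#'
#' Maximum-likelihood fit of the binomial logit model for case status on
#' an exposure plus covariates, with Wald 95\% confidence intervals and
#' p-values per term.  Subjects with missing values in any used column
#' are excluded and counted (an explicit \code{"unknown"} category is a
#' level, not a missing value).  Rank deficiency and separation raise
#' errors naming the offending terms.  Convergence uses IRLS with
#' relative log-likelihood tolerance 1e-10 and at most 100 iterations.
#'
#' @param study study data frame with \code{case_status} in 0/1.
#' @param spec a \code{\link{model_spec}}.
#' @return data frame of class \code{model_result}: one row per
#'   coefficient with \code{term}, \code{estimate} (log-odds), \code{se},
#'   \code{or}, \code{ci_lo}, \code{ci_hi}, \code{p}.  Attributes:
#'   \code{loglik}, \code{df}, \code{n_cases}, \code{n_controls},
#'   \code{n_excluded}, \code{exposure_terms}, \code{label}, \code{fit}
#'   (the underlying glm object).
#' @export
fit_logistic <- function(study, spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (!all(study$case_status %in% c(0, 1))) abort("case_status must be 0/1")
  if (length(unique(study$case_status)) < 2) {
    abort("case_status must contain both cases and controls")
  }
  cols <- c("case_status", spec$exposure, spec$covariates)
  missing_cols <- setdiff(cols, names(study))
  if (length(missing_cols) > 0) {
    abort("study table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  d <- study[cols]
  d$.exposure <- encode_exposure(d[[spec$exposure]], spec)
  for (cv in spec$covariates) {
    if (is.character(d[[cv]]) || is.logical(d[[cv]])) d[[cv]] <- factor(d[[cv]])
  }
  complete <- stats::complete.cases(d)
  n_excluded <- sum(!complete)
  d <- d[complete, , drop = FALSE]

  rhs <- c(".exposure", spec$covariates)
  fml <- stats::reformulate(rhs, response = "case_status")
  withCallingHandlers(
    fit <- stats::glm(fml, data = d, family = stats::binomial(),
                      control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        abort("separation detected while fitting exposure '%s'", spec$exposure)
      }
      invokeRestart("muffleWarning")
    }
  )
  if (!fit$converged) {
    abort("IRLS did not converge in 100 iterations for exposure '%s'",
          spec$exposure)
  }
  cf <- stats::coef(fit)
  if (any(is.na(cf))) {
    abort("rank-deficient design; aliased term(s): %s",
          paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  res <- data.frame(term = rownames(sm),
                    estimate = sm[, "Estimate"],
                    se = sm[, "Std. Error"],
                    or = exp(sm[, "Estimate"]),
                    ci_lo = exp(sm[, "Estimate"] - 1.96 * sm[, "Std. Error"]),
                    ci_hi = exp(sm[, "Estimate"] + 1.96 * sm[, "Std. Error"]),
                    p = sm[, "Pr(>|z|)"],
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "loglik") <- as.numeric(stats::logLik(fit))
  attr(res, "df") <- length(cf)
  attr(res, "n_cases") <- sum(d$case_status == 1)
  attr(res, "n_controls") <- sum(d$case_status == 0)
  attr(res, "n_excluded") <- n_excluded
  attr(res, "exposure_terms") <- grep("^\\.exposure", res$term, value = TRUE)
  attr(res, "label") <- spec$label
  attr(res, "fit") <- fit
  class(res) <- c("model_result", "data.frame")
  res
}

# internal: code the exposure column per the spec
encode_exposure <- function(x, spec) {
  switch(spec$exposure_type,
    continuous = as.numeric(x),
    ordinal = {
      if (any(!x %in% 1:4)) abort("ordinal exposure must hold quartiles 1..4")
      as.numeric(x)
    },
    quartile = {
      if (any(!x %in% 1:4)) abort("quartile exposure must hold values 1..4")
      factor(paste0("Q", x), levels = paste0("Q", 1:4))
    },
    categorical = {
      f <- factor(x)
      if (!is.null(spec$exposure_ref)) f <- stats::relevel(f, spec$exposure_ref)
      f
    })
}

#' Exposure odds ratios from a fitted model
#'
#' Convenience accessor: the exposure rows of a \code{model_result}
#' (dropping intercept and covariate terms).
#'
#' @param result a \code{model_result}.
#' @return data frame of the exposure coefficient rows.
#' @export
exposure_or <- function(result) {
  result[result$term %in% attr(result, "exposure_terms"), , drop = FALSE]
}

#' Crude odds ratio from a 2x2 table
#'
#' Cross-product odds ratio with the Woolf (log-scale Wald) confidence
#' interval; serves as an independent arithmetic oracle for
#' \code{\link{fit_logistic}} on single binary exposures.  Cell layout:
#' \code{a} = exposed cases, \code{b} = exposed controls, \code{c} =
#' unexposed cases, \code{d} = unexposed controls.
#'
#' @param a,b,c,d non-negative cell counts; all must be positive (no
#'   continuity correction is applied).
#' @return list with \code{or}, \code{ci_lo}, \code{ci_hi}.
#' @examples
#' crude_or_2x2(499, 790, 642, 1404)$or  # 1.3814
#' @export
crude_or_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0)) abort("cell counts must be >= 0")
  if (any(cells == 0)) {
    abort("zero cell in 2x2 table (%s); no continuity correction is applied",
          paste(names(cells)[cells == 0], collapse = ", "))
  }
  or <- a * d / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = or, ci_lo = exp(log(or) - 1.96 * se), ci_hi = exp(log(or) + 1.96 * se))
}

#' Test for linear trend across quartiles
#'
#' Dose-response trend test: the quartile index itself (1-4) enters the
#' covariate-adjusted model as a continuous ordinal term; the Wald
#' p-value of its coefficient is the trend p.
#'
#' @param study study data frame.
#' @param quartile name of the quartile column (values 1..4).
#' @param covariates covariate names.
#' @return list: \code{trend_p}, \code{or_per_quartile}, \code{result}
#'   (the full \code{model_result}).
#' @export
trend_test <- function(study, quartile, covariates = character()) {
  res <- fit_logistic(study, model_spec(quartile, "ordinal", covariates,
                                        label = paste0("trend:", quartile)))
  row <- exposure_or(res)
  list(trend_p = row$p, or_per_quartile = row$or, result = res)
}

#' Likelihood-ratio test for effect-measure modification
#'
#' Compares the covariate-adjusted model with and without
#' exposure-by-modifier interaction terms: statistic =
#' 2(logLik_with - logLik_without) >= 0, chi-square reference with df =
#' number of interaction terms.
#'
#' @param study study data frame.
#' @param spec a \code{\link{model_spec}}; the modifier is added to the
#'   covariates of both nested models if not already present.
#' @param modifier name of the (binary, after any collapsing) modifier
#'   column.
#' @return list: \code{statistic}, \code{df}, \code{p},
#'   \code{result_with}, \code{result_without}.
#' @export
lrt_interaction <- function(study, spec, modifier) {
  stopifnot(inherits(spec, "model_spec"))
  covs <- union(spec$covariates, modifier)
  spec0 <- model_spec(spec$exposure, spec$exposure_type, covs,
                      spec$exposure_ref, paste0(spec$label, ":base"))
  res0 <- fit_logistic(study, spec0)

  d <- study
  d$.exposure <- encode_exposure(d[[spec$exposure]], spec)
  for (cv in covs) {
    if (is.character(d[[cv]]) || is.logical(d[[cv]])) d[[cv]] <- factor(d[[cv]])
  }
  use <- c("case_status", ".exposure", covs)
  d <- d[stats::complete.cases(d[use]), use]
  fml1 <- stats::as.formula(paste(
    "case_status ~ .exposure +", paste(covs, collapse = " + "),
    "+ .exposure:", modifier))
  fit1 <- stats::glm(fml1, data = d, family = stats::binomial(),
                     control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  ll1 <- as.numeric(stats::logLik(fit1))
  cf1 <- stats::coef(fit1)
  df <- sum(!is.na(cf1)) - attr(res0, "df")
  if (df < 0) abort("interaction model is not an extension of the base model")
  statistic <- max(0, 2 * (ll1 - attr(res0, "loglik")))
  p <- if (df == 0) 1 else stats::pchisq(statistic, df, lower.tail = FALSE)
  list(statistic = statistic, df = df, p = p,
       loglik_with = ll1, loglik_without = attr(res0, "loglik"),
       result_without = res0)
}

#' Stratified analysis
#'
#' Refits a model within each level of a stratifier, dropping the
#' stratifier itself from the covariate set (the convention of stratified
#' report rows).  Strata that are empty or lack both outcome levels are
#' skipped with a warning.
#'
#' @param study study data frame.
#' @param spec a \code{\link{model_spec}}.
#' @param stratifier name of the stratifying column.
#' @return named list of \code{model_result}s, one per retained stratum.
#' @export
stratified_analysis <- function(study, spec, stratifier) {
  stopifnot(inherits(spec, "model_spec"), stratifier %in% names(study))
  covs <- setdiff(spec$covariates, stratifier)
  levels_ <- sort(unique(as.character(study[[stratifier]])))
  out <- list()
  for (lv in levels_) {
    sub <- study[as.character(study[[stratifier]]) == lv, , drop = FALSE]
    if (nrow(sub) == 0 || length(unique(sub$case_status)) < 2) {
      warning(sprintf("stratum %s=%s skipped (empty or single outcome level)",
                      stratifier, lv))
      next
    }
    sp <- model_spec(spec$exposure, spec$exposure_type, covs,
                     spec$exposure_ref, paste0(spec$label, " | ", stratifier,
                                               "=", lv))
    out[[lv]] <- fit_logistic(sub, sp)
  }
  out
}

#' Sensitivity analysis suite
#'
#' The three standard re-fits of a final model: (1) excluding cases with
#' more than \code{max_delay_months} between diagnosis and interview;
#' (2) additionally adjusting for energy intake from non-alcohol sources
#' and alcohol consumption; (3) restricting to non-drinkers.  A
#' sensitivity whose required column is absent is skipped with a warning.
#'
#' @param study study data frame; sensitivities use columns
#'   \code{months_diagnosis_to_interview}, \code{energy_nonalcohol},
#'   \code{alcohol_g} where available.
#' @param spec a \code{\link{model_spec}} for the main (final) model.
#' @param max_delay_months exclusion threshold for sensitivity 1.
#' @return named list of \code{model_result}s
#'   (\code{exclude_late_interview}, \code{adjust_energy_alcohol},
#'   \code{nondrinkers_only}) with per-element attribute
#'   \code{n_excluded_rule} where applicable.
#' @export
sensitivity_suite <- function(study, spec, max_delay_months = 6) {
  stopifnot(inherits(spec, "model_spec"))
  out <- list()

  if ("months_diagnosis_to_interview" %in% names(study)) {
    late <- study$case_status == 1 &
      !is.na(study$months_diagnosis_to_interview) &
      study$months_diagnosis_to_interview > max_delay_months
    r <- fit_logistic(study[!late, , drop = FALSE], spec)
    attr(r, "n_excluded_rule") <- sum(late)
    out$exclude_late_interview <- r
  } else {
    warning("months_diagnosis_to_interview absent; sensitivity 1 skipped")
  }

  extra <- c("energy_nonalcohol", "alcohol_g")
  if (all(extra %in% names(study))) {
    sp <- model_spec(spec$exposure, spec$exposure_type,
                     union(spec$covariates, extra), spec$exposure_ref,
                     paste0(spec$label, " + energy/alcohol"))
    out$adjust_energy_alcohol <- fit_logistic(study, sp)
  } else {
    warning("energy_nonalcohol/alcohol_g absent; sensitivity 2 skipped")
  }

  if ("alcohol_g" %in% names(study)) {
    nd <- !is.na(study$alcohol_g) & study$alcohol_g == 0
    r <- fit_logistic(study[nd, , drop = FALSE], spec)
    attr(r, "n_excluded_rule") <- sum(!nd)
    out$nondrinkers_only <- r
  } else {
    warning("alcohol_g absent; sensitivity 3 skipped")
  }
  out
}

#' Render a quartile-model report row
#'
#' Shapes one exposure's results the way case-control association tables
#' are printed: per-unit OR, Q2-Q4 ORs versus Q1, and the trend p-value.
#'
#' @param study study data frame.
#' @param exposure continuous exposure column name.
#' @param quartile quartile column name (1..4).
#' @param covariates covariate names.
#' @param label row label.
#' @return one-row data frame with OR (95\% CI) strings per column.
#' @export
report_row <- function(study, exposure, quartile, covariates = character(),
                       label = exposure) {
  cont <- exposure_or(fit_logistic(
    study, model_spec(exposure, "continuous", covariates)))
  qres <- exposure_or(fit_logistic(
    study, model_spec(quartile, "quartile", covariates)))
  tr <- trend_test(study, quartile, covariates)
  fmt <- function(r) sprintf("%.2f (%.2f-%.2f)", r$or, r$ci_lo, r$ci_hi)
  data.frame(label = label,
             per_unit = fmt(cont[1, ]),
             Q1 = "1.00 (ref)",
             Q2 = fmt(qres[1, ]), Q3 = fmt(qres[2, ]), Q4 = fmt(qres[3, ]),
             p_trend = signif(tr$trend_p, 2),
             stringsAsFactors = FALSE)
}
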