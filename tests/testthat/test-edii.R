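test_that("energy density is intake per 1000 kcal", {
  expect_equal(energy_density(20, 2000), 10)
  expect_equal(energy_density(0, 1234), 0)
  expect_equal(energy_density(14, 1000), 14)
  expect_error(energy_density(10, 0), "energy_kcal")
  expect_error(energy_density(-1, 1000), "raw_intake")
})

test_that("parameter score is the centered-CDF transform times the effect weight", {
  # oracle: 2*pnorm(2) - 1 = 0.954499736, times -0.5
  expect_equal(parameter_score(14, 10, 2, -0.5), -0.477249868,
               tolerance = 1e-9)
  expect_equal(parameter_score(10, 10, 2, 0.7), 0)
  # CDF limit: approaches but never reaches the effect score
  far <- parameter_score(26, 10, 2, 1)  # z = 8
  expect_lt(far, 1)
  expect_gt(far, 1 - 1e-12)
  expect_error(parameter_score(Inf, 10, 2, 1), "finite")
  expect_error(parameter_score(1, 10, 0, 1), "global_sd")
})

test_that("compute_edii sums resolvable contributions and reports coverage", {
  ref <- tiny_reference()
  s <- list(subject_id = "s1", energy_kcal = 1000,
            parameter_intakes = c(A = 14, B = 1))
  r <- compute_edii(s, ref)
  expect_equal(r$edii_total, -0.477249868, tolerance = 1e-9)
  expect_equal(r$n_parameters_used, 2)
  expect_equal(sum(r$contributions), r$edii_total, tolerance = 1e-12)

  # subject at the global-mean diet scores exactly zero
  s0 <- list(subject_id = "s0", energy_kcal = 1000,
             parameter_intakes = c(A = 10, B = 1))
  expect_equal(compute_edii(s0, ref)$edii_total, 0)

  # parameter missing from the subject is skipped, not imputed as zero
  s1 <- list(subject_id = "s2", energy_kcal = 1000,
             parameter_intakes = c(A = 14))
  r1 <- compute_edii(s1, ref)
  expect_equal(r1$n_parameters_used, 1)
  expect_equal(r1$missing_parameters, "B")

  expect_error(compute_edii(list(subject_id = "sx", energy_kcal = 1000,
                                 parameter_intakes = c(zz = 1)), ref),
               "no parameter resolves")
})

test_that("null effect scores give a zero E-DII for any diet", {
  ref <- load_parameter_reference(write_fixture(data.frame(
    parameter_name = c("A", "B"), global_mean = c(10, 1),
    global_sd = c(2, 1), effect_score = c(0, 0))))
  s <- list(subject_id = "s", energy_kcal = 1700,
            parameter_intakes = c(A = 99, B = 42))
  expect_equal(compute_edii(s, ref)$edii_total, 0)
})

test_that("E-DII is isocaloric-invariant, bounded, monotone, decomposable", {
  ref <- default_parameter_reference()
  set.seed(11)
  for (i in 1:10) {
    energy <- runif(1, 1200, 3000)
    intakes <- ref$global_mean * exp(rnorm(30, 0, 0.4)) * energy / 1000
    names(intakes) <- ref$parameter_name
    s <- list(subject_id = "s", energy_kcal = energy,
              parameter_intakes = intakes)
    r <- compute_edii(s, ref)

    # isocaloric invariance: scaling everything by c > 0 changes nothing
    cc <- runif(1, 0.3, 3)
    s2 <- list(subject_id = "s", energy_kcal = energy * cc,
               parameter_intakes = intakes * cc)
    expect_equal(compute_edii(s2, ref)$edii_total, r$edii_total,
                 tolerance = 1e-9)

    # strict bound by the total absolute effect weight
    expect_lt(abs(r$edii_total), sum(abs(ref$effect_score)))

    # decomposition into independently computed parameter scores
    manual <- sum(parameter_score(intakes[ref$parameter_name] * 1000 / energy,
                                  ref$global_mean, ref$global_sd,
                                  ref$effect_score))
    expect_equal(r$edii_total, manual, tolerance = 1e-12)
  }

  # monotonicity: raising a pro-inflammatory intake never lowers the score
  base <- ref$global_mean * 1.8  # at 1800 kcal, density == global mean
  names(base) <- ref$parameter_name
  s <- list(subject_id = "s", energy_kcal = 1800, parameter_intakes = base)
  r0 <- compute_edii(s, ref)$edii_total
  for (step in c(1, 5, 20)) {
    up <- base
    up["saturated_fat"] <- up["saturated_fat"] + step  # effect +0.373
    r1 <- compute_edii(list(subject_id = "s", energy_kcal = 1800,
                            parameter_intakes = up), ref)$edii_total
    expect_gte(r1, r0)
    r0 <- r1
  }
})

test_that("batch_edii matches compute_edii row-wise and manifests exclusions", {
  ref <- default_parameter_reference()
  set.seed(21)
  n <- 20
  intakes <- data.frame(subject_id = sprintf("s%02d", 1:n),
                        energy_kcal = runif(n, 1200, 2800))
  for (p in ref$parameter_name) {
    intakes[[p]] <- ref$global_mean[ref$parameter_name == p] *
      exp(rnorm(n, 0, 0.3)) * intakes$energy_kcal / 1000
  }
  batch <- batch_edii(intakes, ref)
  single <- vapply(1:n, function(i) {
    compute_edii(list(subject_id = intakes$subject_id[i],
                      energy_kcal = intakes$energy_kcal[i],
                      parameter_intakes = unlist(intakes[i, ref$parameter_name])),
                 ref)$edii_total
  }, numeric(1))
  expect_equal(batch$edii_total, single, tolerance = 1e-12)

  # identical subjects -> identical scores; empty input -> empty output
  three <- intakes[c(1, 1, 1), ]
  expect_equal(length(unique(batch_edii(three, ref)$edii_total)), 1)
  expect_equal(nrow(batch_edii(intakes[0, ], ref)), 0)

  # zero-energy subject goes to the exclusion manifest
  intakes$energy_kcal[3] <- 0
  b2 <- batch_edii(intakes, ref)
  expect_equal(nrow(b2), n - 1)
  expect_equal(attr(b2, "exclusions")$subject_id, "s03")
})

test_that("simulated mean E-DII matches a numeric-integration oracle", {
  # oracle: E[contribution_i] under the generator's lognormal-copula
  # marginal, by quadrature over the latent normal; alcohol mixes in the
  # zero-inflated point mass
  cfg <- generator_config(n = 1000, seed = 5)
  ref <- cfg$reference
  expected <- vapply(seq_len(nrow(ref)), function(j) {
    m <- ref$global_mean[j]; s <- ref$global_sd[j]; e <- ref$effect_score[j]
    sdlog <- sqrt(log(1 + (s / m)^2)); mlog <- log(m) - sdlog^2 / 2
    f <- function(z) (2 * pnorm((qlnorm(pnorm(z), mlog, sdlog) - m) / s) - 1) *
      dnorm(z) * e
    v <- integrate(f, -8, 8, rel.tol = 1e-8)$value
    if (ref$parameter_name[j] == "alcohol") {
      v <- (1 - cfg$nondrinker_p) * v +
        cfg$nondrinker_p * (2 * pnorm((0 - m) / s) - 1) * e
    }
    v
  }, numeric(1))
  gen <- generate_intakes(cfg)
  scored <- batch_edii(gen$intakes, ref)
  expect_equal(mean(scored$edii_total), sum(expected), tolerance = 0.2)
})
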