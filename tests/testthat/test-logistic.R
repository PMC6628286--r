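test_that("crude 2x2 odds ratio matches direct arithmetic", {
  # counts of the top vs bottom combined-score categories in the
  # motivating CRC analysis
  r <- crude_or_2x2(499, 790, 642, 1404)
  expect_equal(r$or, 499 * 1404 / (790 * 642), tolerance = 1e-12)
  expect_equal(r$or, 1.3814, tolerance = 1e-4)
  expect_lt(r$ci_lo, r$or)
  expect_gt(r$ci_hi, r$or)

  expect_equal(crude_or_2x2(10, 10, 10, 10)$or, 1.0)
  expect_error(crude_or_2x2(1, 1, 1, 0), "zero cell")
  expect_error(crude_or_2x2(1, -1, 1, 1), ">= 0")
})

test_that("logistic MLE equals the 2x2 cross-product oracle", {
  tables <- list(c(499, 790, 642, 1404), c(30, 40, 25, 55), c(12, 9, 7, 20))
  for (tb in tables) {
    study <- expand_2x2(tb[1], tb[2], tb[3], tb[4])
    res <- fit_logistic(study, model_spec("exposed", "continuous"))
    oracle <- crude_or_2x2(tb[1], tb[2], tb[3], tb[4])
    row <- exposure_or(res)
    expect_equal(row$or, oracle$or, tolerance = 1e-6)
    # Wald CI agrees with the Woolf interval on a saturated 2x2
    expect_equal(row$ci_lo, oracle$ci_lo, tolerance = 1e-4)
    expect_equal(row$ci_hi, oracle$ci_hi, tolerance = 1e-4)
  }
})

test_that("model bookkeeping: counts, exclusions, degenerate designs", {
  study <- expand_2x2(20, 30, 25, 40)
  res <- fit_logistic(study, model_spec("exposed", "continuous"))
  expect_equal(attr(res, "n_cases"), 45)
  expect_equal(attr(res, "n_controls"), 70)

  # constant exposure -> rank deficiency error naming the term
  study$flat <- 1
  expect_error(fit_logistic(study, model_spec("flat", "continuous")),
               "rank-deficient")

  # missing covariate values are excluded and counted
  study$age <- rnorm(nrow(study), 60, 5)
  study$age[1:7] <- NA
  res2 <- fit_logistic(study, model_spec("exposed", "continuous", "age"))
  expect_equal(attr(res2, "n_excluded"), 7)

  # 'unknown' is a retained dummy level, not a missing value
  study$fh <- sample(c("no", "yes", "unknown"), nrow(study), TRUE)
  study$age <- rnorm(nrow(study), 60, 5)
  res3 <- fit_logistic(study, model_spec("exposed", "continuous", "fh"))
  expect_true(any(grepl("unknown", res3$term)))
  expect_equal(attr(res3, "n_excluded"), 0)
})

test_that("trend coefficient is Wald-tested on the ordinal quartile index", {
  set.seed(51)
  n <- 4000
  q <- sample(1:4, n, replace = TRUE)
  y <- rbinom(n, 1, plogis(-1 + 0.3 * q))
  tr <- trend_test(data.frame(case_status = y, q = q), "q")
  expect_lt(tr$trend_p, 0.001)
  expect_gt(tr$or_per_quartile, 1)

  # no-effect toy: coefficient ~0, p near 1 on a balanced saturated design
  toy <- expand_2x2(25, 25, 25, 25)
  toy$q <- toy$exposed + 1
  tr0 <- trend_test(toy, "q")
  expect_equal(tr0$or_per_quartile, 1, tolerance = 1e-6)
  expect_gt(tr0$trend_p, 0.99)
})

test_that("trend test holds its type-I error under the null", {
  set.seed(52)
  reps <- 1000
  p <- numeric(reps)
  for (i in seq_len(reps)) {
    st <- data.frame(case_status = rbinom(300, 1, 0.4),
                     q = sample(1:4, 300, replace = TRUE))
    p[i] <- trend_test(st, "q")$trend_p
  }
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("LRT for interaction is non-negative and calibrated under the null", {
  set.seed(53)
  stats <- numeric(100)
  for (i in 1:100) {
    st <- null_study(150, seed = 5300 + i)
    lr <- lrt_interaction(st, model_spec("x", "continuous", "age"), "modifier")
    stats[i] <- lr$statistic
    expect_gte(lr$statistic, 0)
    expect_equal(lr$df, 1)
  }

  # null rejection rate at alpha = 0.05 across 1000 replicates
  set.seed(54)
  reps <- 1000
  p <- numeric(reps)
  for (i in seq_len(reps)) {
    st <- data.frame(case_status = rbinom(300, 1, 0.4),
                     x = rnorm(300),
                     modifier = sample(c("a", "b"), 300, TRUE))
    lr <- lrt_interaction(st, model_spec("x", "continuous"), "modifier")
    p[i] <- lr$p
  }
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("LRT detects a planted interaction and ignores a degenerate one", {
  set.seed(55)
  n <- 8000
  x <- rnorm(n)
  mod <- sample(c("lo", "hi"), n, TRUE)
  y <- rbinom(n, 1, plogis(-0.5 + 0.2 * x + log(2) * x * (mod == "hi")))
  st <- data.frame(case_status = y, x = x, modifier = mod)
  lr <- lrt_interaction(st, model_spec("x", "continuous"), "modifier")
  expect_lt(lr$p, 0.01)

  # constant modifier spans nothing: statistic 0, p 1
  st$flatmod <- "same"
  lr0 <- tryCatch(
    lrt_interaction(st, model_spec("x", "continuous"), "flatmod"),
    error = function(e) e)
  # a constant factor is aliased; either a clean 0-df result or a
  # rank-deficiency error is acceptable, never a spurious signal
  if (!inherits(lr0, "error")) {
    expect_equal(lr0$statistic, 0, tolerance = 1e-8)
    expect_equal(lr0$p, 1)
  }
})

test_that("stratified analysis drops the stratifier and preserves structure", {
  set.seed(56)
  n <- 3000
  st <- data.frame(case_status = rbinom(n, 1, 0.4),
                   x = rnorm(n),
                   sex = sample(c("male", "female"), n, TRUE),
                   age = rnorm(n, 60, 10))
  spec <- model_spec("x", "continuous", c("sex", "age"))
  out <- stratified_analysis(st, spec, "sex")
  expect_setequal(names(out), c("male", "female"))
  expect_false(any(grepl("sex", out$male$term)))

  # stratifier independent of everything: stratum ORs within 3 SE of pooled
  pooled <- exposure_or(fit_logistic(st, spec))
  for (g in names(out)) {
    row <- exposure_or(out[[g]])
    expect_lt(abs(row$estimate - pooled$estimate), 3 * row$se)
  }

  # duplicated stratum data give identical ORs
  st2 <- rbind(transform(st, g = "s1"), transform(st, g = "s2"))
  out2 <- stratified_analysis(st2, model_spec("x", "continuous", "age"), "g")
  expect_equal(exposure_or(out2$s1)$or, exposure_or(out2$s2)$or,
               tolerance = 1e-10)
})

test_that("sensitivity suite refits and accounts for exclusions", {
  set.seed(57)
  n <- 2000
  st <- data.frame(case_status = rbinom(n, 1, 0.4),
                   x = rnorm(n), age = rnorm(n, 60, 10))
  st$months_diagnosis_to_interview <- ifelse(st$case_status == 1,
                                             rgamma(n, 2, 0.5), NA)
  st$alcohol_g <- ifelse(runif(n) < 0.3, 0, rlnorm(n, 2, 0.8))
  st$energy_nonalcohol <- rnorm(n, 1800, 500)
  spec <- model_spec("x", "continuous", "age")
  out <- sensitivity_suite(st, spec)
  expect_setequal(names(out), c("exclude_late_interview",
                                "adjust_energy_alcohol", "nondrinkers_only"))
  late <- sum(st$case_status == 1 & st$months_diagnosis_to_interview > 6)
  expect_equal(attr(out$exclude_late_interview, "n_excluded_rule"), late)
  expect_equal(attr(out$exclude_late_interview, "n_cases"),
               sum(st$case_status == 1) - late)
  expect_equal(attr(out$nondrinkers_only, "n_cases") +
                 attr(out$nondrinkers_only, "n_controls"),
               sum(st$alcohol_g == 0))
  expect_true(all(c("energy_nonalcohol", "alcohol_g") %in%
                    out$adjust_energy_alcohol$term))

  # no case beyond the delay threshold: sensitivity 1 equals the main fit
  st$months_diagnosis_to_interview[st$case_status == 1] <- 2
  out2 <- sensitivity_suite(st, spec)
  main <- fit_logistic(st, spec)
  expect_equal(exposure_or(out2$exclude_late_interview)$estimate,
               exposure_or(main)$estimate, tolerance = 1e-12)

  # missing column: that sensitivity is skipped with a warning
  st$alcohol_g <- NULL
  st$energy_nonalcohol <- NULL
  w <- capture_warnings(out3 <- sensitivity_suite(st, spec))
  expect_true(any(grepl("alcohol", w)))
  expect_false("nondrinkers_only" %in% names(out3))
  expect_false("adjust_energy_alcohol" %in% names(out3))
})

test_that("adding outcome-irrelevant noise covariates leaves the OR stable", {
  set.seed(58)
  n <- 5000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.5 + 0.4 * x))
  st <- data.frame(case_status = y, x = x, noise = rnorm(n))
  r1 <- exposure_or(fit_logistic(st, model_spec("x", "continuous")))
  r2 <- exposure_or(fit_logistic(st, model_spec("x", "continuous", "noise")))
  expect_lt(abs(r1$estimate - r2$estimate), 0.02)
})
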