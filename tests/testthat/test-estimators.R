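test_that("wald ratios follow the first-order delta method", {
  d <- hd(bx = c(1.0, 0.071, -0.5), by = c(0.5, 0.018, 0.1),
          sy = c(0.1, 0.0151, 0.1))
  wr <- mr_wald_ratio(d)
  expect_equal(wr$beta, c(0.5, 0.018 / 0.071, -0.2))
  expect_equal(wr$se, c(0.1, 0.0151 / 0.071, 0.2))
  expect_equal(wr$beta[2], 0.2535, tolerance = 1e-3)
  expect_equal(wr$se[2], 0.2127, tolerance = 1e-3)
  # second-order SE adds the exposure-variance term
  d2 <- hd(bx = 1, by = 0.5, sy = 0.1, sx = 0.2)
  expect_equal(mr_wald_ratio(d2, second_order = TRUE)$se,
               sqrt(0.1^2 + 0.5^2 * 0.2^2))
  expect_error(mr_wald_ratio(hd(bx = 0, by = 0.1, sy = 0.1)), "zero exposure")
})

test_that("fixed-effect IVW matches closed form and a regression oracle", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(3:30, 1)
    bx <- rnorm(n, 0.05, 0.02)
    by <- rnorm(n, 0.01, 0.01)
    sy <- runif(n, 0.005, 0.03)
    est <- mr_ivw(hd(bx, by, sy), model = "fixed")
    # closed form
    expect_equal(est$beta, sum(bx * by / sy^2) / sum(bx^2 / sy^2),
                 tolerance = 1e-10)
    # independent oracle: weighted least squares through the origin
    fit <- summary(lm(by ~ bx - 1, weights = 1 / sy^2))
    expect_equal(est$beta, unname(coef(fit)[1, 1]), tolerance = 1e-10)
    expect_equal(est$se, unname(coef(fit)[1, 2]) / fit$sigma, tolerance = 1e-10)
    # random-effects SE is the fixed one inflated by dispersion, floored at 1
    er <- mr_ivw(hd(bx, by, sy), model = "random")
    expect_equal(er$se, est$se * max(1, fit$sigma), tolerance = 1e-10)
  }
})

test_that("single-variant and equal-weight IVW degenerate correctly", {
  d1 <- hd(bx = 0.07, by = 0.02, sy = 0.015)
  expect_equal(mr_ivw(d1)$beta, mr_wald_ratio(d1)$beta)
  expect_equal(mr_ivw(d1)$se, mr_wald_ratio(d1)$se)
  expect_warning(est <- mr_ivw(d1, robust = TRUE), "falls back")
  expect_equal(est$beta, mr_wald_ratio(d1)$beta)
  # two variants, unit exposure effects, equal outcome SEs: mean of ratios
  d2 <- hd(bx = c(1, 1), by = c(0.2, 0.6), sy = c(0.1, 0.1))
  expect_equal(mr_ivw(d2)$beta, 0.4)
})

test_that("egger recovers an exact linear relation to machine precision", {
  set.seed(21)
  bx <- runif(8, 0.01, 0.08)
  by <- 0.012 + 0.3 * bx          # exact: intercept 0.012, slope 0.3
  sy <- runif(8, 0.005, 0.02)
  est <- mr_egger(hd(bx, by, sy))
  expect_equal(est$beta, 0.3, tolerance = 1e-12)
  expect_equal(est$intercept, 0.012, tolerance = 1e-12)
  # orientation: negating some exposure effects must not change the fit
  flip <- c(1, -1, 1, -1, 1, 1, -1, 1)
  est2 <- mr_egger(hd(bx * flip, by * flip, sy))
  expect_equal(est2$beta, est$beta, tolerance = 1e-12)
  expect_equal(est2$intercept, est$intercept, tolerance = 1e-12)
  expect_error(mr_egger(hd(bx = c(1, 2), by = c(1, 2), sy = c(1, 1))),
               "at least 3")
  expect_error(mr_egger(hd(bx = c(1, 1, 1), by = c(1, 2, 3), sy = c(1, 1, 1))),
               "not identifiable")
})

test_that("weighted median reduces to the sample median with equal weights", {
  set.seed(31)
  for (n in c(5, 9, 13)) {
    r <- rnorm(n)
    d <- hd(bx = rep(1, n), by = r, sy = rep(0.1, n))
    est <- suppressWarnings(mr_median(d, "simple", n_boot = 100, seed = 1))
    expect_equal(est$beta, median(r))
  }
})

test_that("weight penalization spares consistent variants and bites outliers", {
  pen <- penalize_weights(ratios = c(0.5, 0.5, 0.5), weights = c(1, 2, 3),
                          reference = 0.5)
  expect_equal(pen$weights, c(1, 2, 3))
  expect_equal(pen$factor, c(1, 1, 1))
  # q giving chi-square(1) upper-tail p = 0.001 shrinks the weight to 2% of raw
  q <- qchisq(0.001, df = 1, lower.tail = FALSE)
  pen2 <- penalize_weights(ratios = sqrt(q), weights = 1, reference = 0)
  expect_equal(pen2$factor, 0.02, tolerance = 1e-12)
  expect_error(penalize_weights(1:3, 1:2, 0), "length")
})

test_that("penalized estimates equal plain ones without heterogeneity and differ with it", {
  # homogeneous dataset: every ratio equals the causal effect
  set.seed(41)
  bx <- runif(6, 0.02, 0.08)
  d <- hd(bx, by = 0.25 * bx, sy = runif(6, 0.005, 0.02))
  expect_identical(mr_ivw(d)$beta, mr_ivw(d, penalized = TRUE)$beta)
  # one gross outlier attracts a penalty and moves the estimate
  d2 <- hd(bx = c(0.05, 0.06, 0.07, 0.04), by = c(0.0125, 0.015, 0.0175, 0.08),
           sy = rep(0.005, 4))
  expect_lt(abs(mr_ivw(d2, penalized = TRUE)$beta - 0.25),
            abs(mr_ivw(d2)$beta - 0.25))
})

test_that("estimates are invariant to allele relabelling of the inputs", {
  sim <- simulate_pair(simulation_config(n_snps = 15, theta = 0.2, seed = 99))
  d <- harmonize(sim$exposure, sim$outcome)
  oc <- sim$outcome
  i <- seq(2, nrow(oc), by = 2)
  tmp <- oc$effect_allele[i]
  oc$effect_allele[i] <- oc$other_allele[i]
  oc$other_allele[i] <- tmp
  oc$beta[i] <- -oc$beta[i]
  oc$eaf[i] <- 1 - oc$eaf[i]
  d2 <- harmonize(sim$exposure, oc)
  for (fit in list(mr_ivw, function(x) mr_ivw(x, robust = TRUE), mr_egger)) {
    expect_equal(fit(d2)$beta, fit(d)$beta, tolerance = 1e-12)
  }
  m1 <- mr_median(d, "weighted", n_boot = 200, seed = 5)
  m2 <- mr_median(d2, "weighted", n_boot = 200, seed = 5)
  expect_identical(m1$beta, m2$beta)
  expect_identical(m1$se, m2$se)
})

test_that("the estimator battery runs all methods deterministically in order", {
  d <- paper_harmonized()
  a <- mr_all_methods(d, n_boot = 300, seed = 7)
  b <- mr_all_methods(d, n_boot = 300, seed = 7)
  expect_identical(a, b)
  expect_equal(a$method,
               c("simple_median", "weighted_median", "penalized_weighted_median",
                 "ivw", "penalized_ivw", "robust_ivw", "penalized_robust_ivw",
                 "mr_egger", "penalized_mr_egger", "robust_mr_egger",
                 "penalized_robust_mr_egger"))
  expect_true(all(a$n_variants == 14))
  expect_equal(a$or, exp(a$beta))
  expect_equal(a$ci_lower, a$beta - qnorm(0.975) * a$se)
  # intercept columns populated only for the Egger family
  expect_true(all(is.na(a$intercept[!grepl("egger", a$method)])))
  expect_true(all(!is.na(a$intercept[grepl("egger", a$method)])))
})

test_that("median bootstrap responds to seed but the point estimate does not", {
  d <- paper_harmonized()
  m1 <- mr_median(d, "weighted", n_boot = 500, seed = 1)
  m2 <- mr_median(d, "weighted", n_boot = 500, seed = 2)
  expect_identical(m1$beta, m2$beta)
  expect_false(identical(m1$se, m2$se))
  expect_warning(mr_median(d, "simple", n_boot = 50, seed = 1), "unstable")
})
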