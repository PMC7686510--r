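# The eleven causal-effect estimators plus the per-variant Wald ratio.
#
# All estimators regress the outcome effects betaY on the exposure effects
# betaX with inverse outcome-variance weights 1/seY^2, the summary-data
# formulation in which the slope is the causal effect of the exposure on the
# outcome (log-odds per exposure unit here). The IVW family constrains the
# intercept to zero; the Egger family frees it, and a non-zero intercept
# estimates directional pleiotropy.

METHOD_ORDER <- c("simple_median", "weighted_median", "penalized_weighted_median",
                  "ivw", "penalized_ivw", "robust_ivw", "penalized_robust_ivw",
                  "mr_egger", "penalized_mr_egger", "robust_mr_egger",
                  "penalized_robust_mr_egger")

# Internal seed for the S-estimate initialization of the MM fits; fixed so
# the robust estimators are deterministic functions of the data.
ROBUST_INIT_SEED <- 714025L

mr_estimate <- function(method, beta, se, n_variants, intercept = NA_real_,
                        intercept_se = NA_real_, intercept_pvalue = NA_real_) {
  beta <- unname(beta); se <- unname(se)
  intercept <- unname(intercept); intercept_se <- unname(intercept_se)
  intercept_pvalue <- unname(intercept_pvalue)
  est <- data.frame(
    method = method, n_variants = n_variants, beta = beta, se = se,
    ci_lower = beta - Z975 * se, ci_upper = beta + Z975 * se,
    pvalue = normal_pvalue(beta, se),
    or = exp(beta), or_ci_lower = exp(beta - Z975 * se),
    or_ci_upper = exp(beta + Z975 * se),
    intercept = intercept, intercept_se = intercept_se,
    intercept_pvalue = intercept_pvalue,
    stringsAsFactors = FALSE
  )
  class(est) <- c("mr_estimate", "data.frame")
  est
}

#' @export
print.mr_estimate <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  if (all(is.na(df$intercept)))
    df <- df[setdiff(names(df), c("intercept", "intercept_se", "intercept_pvalue"))]
  print(df, row.names = FALSE, ...)
  invisible(x)
}

unpack <- function(d) {
  stopifnot(inherits(d, "harmonized_data"))
  v <- d$variants
  list(snp = v$snp, bx = v$beta_exposure, sx = v$se_exposure,
       by = v$beta_outcome, sy = v$se_outcome, n = nrow(v))
}

#' Per-variant Wald ratio estimates
#'
#' The Wald ratio for one variant is the outcome effect divided by the
#' exposure effect; its first-order delta-method standard error is
#' `se_outcome / |beta_exposure|` (the exposure-side uncertainty is ignored;
#' set `second_order = TRUE` to add it).
#'
#' @param d A `harmonized_data` object.
#' @param second_order Add the exposure-variance term
#'   `beta_outcome^2 * se_exposure^2 / beta_exposure^4` to the variance.
#' @return A data frame with one row per variant: `snp`, `beta`, `se`,
#'   `ci_lower`, `ci_upper`, `pvalue` (normal). Suitable as scatter data for
#'   per-variant forest/scatter displays.
#' @export
mr_wald_ratio <- function(d, second_order = FALSE) {
  u <- unpack(d)
  zero <- u$bx == 0
  if (any(zero))
    stopf("wald ratio undefined for variant(s) with zero exposure effect: %s",
          paste(u$snp[zero], collapse = ", "))
  beta <- u$by / u$bx
  se <- u$sy / abs(u$bx)
  if (second_order) se <- sqrt(se^2 + u$by^2 * u$sx^2 / u$bx^4)
  data.frame(snp = u$snp, beta = beta, se = se,
             ci_lower = beta - Z975 * se, ci_upper = beta + Z975 * se,
             pvalue = normal_pvalue(beta, se), stringsAsFactors = FALSE)
}

#' Heterogeneity-penalized weights
#'
#' Down-weights variants whose Wald ratio is inconsistent with a candidate
#' causal effect. For variant j with ratio `r_j` and inverse-variance weight
#' `w_j`, the squared standardized deviation `q_j = w_j (r_j - theta_ref)^2`
#' is referred to a chi-square(1) upper tail `p_j`, and the weight becomes
#' `w_j * min(1, 20 p_j)`: variants with heterogeneity p >= 0.05 keep their
#' full weight, outlying variants are smoothly penalized.
#'
#' @param ratios Per-variant Wald ratios.
#' @param weights Raw inverse-variance weights of the ratios
#'   (`beta_exposure^2 / se_outcome^2`).
#' @param reference Candidate causal effect the deviations are measured from.
#' @return A list: `weights` (penalized), `factor` (per-variant multiplier in
#'   \[0, 1\]), `pvalues` (heterogeneity p-values).
#' @export
penalize_weights <- function(ratios, weights, reference) {
  if (length(ratios) != length(weights))
    stopf("penalize_weights: ratios and weights differ in length")
  q <- weights * (ratios - reference)^2
  p <- pchisq(q, df = 1, lower.tail = FALSE)
  fac <- pmin(1, 20 * p)
  list(weights = weights * fac, factor = fac, pvalues = p)
}

# Weighted least squares through the origin (closed form).
wls_origin <- function(bx, by, w) {
  beta <- sum(w * bx * by) / sum(w * bx^2)
  se_fixed <- sqrt(1 / sum(w * bx^2))
  n <- length(bx)
  sigma <- if (n > 1) sqrt(sum(w * (by - beta * bx)^2) / (n - 1)) else NA_real_
  list(beta = beta, se_fixed = se_fixed, sigma = sigma)
}

# Weighted least squares with intercept (closed form).
wls_intercept <- function(bx, by, w) {
  X <- cbind(1, bx)
  XtWX <- crossprod(X, w * X)
  cov_fixed <- solve(XtWX)
  beta <- drop(cov_fixed %*% crossprod(X, w * by))
  n <- length(bx)
  res <- by - drop(X %*% beta)
  sigma <- sqrt(sum(w * res^2) / (n - 2))
  list(intercept = beta[1], slope = beta[2],
       se_fixed = sqrt(diag(cov_fixed)), sigma = sigma)
}

# Tukey bisquare psi and its derivative at 95% efficiency.
BISQUARE_C <- 4.685
bisq_psi <- function(u) ifelse(abs(u) <= BISQUARE_C, u * (1 - (u / BISQUARE_C)^2)^2, 0)
bisq_dpsi <- function(u) {
  t2 <- (u / BISQUARE_C)^2
  ifelse(abs(u) <= BISQUARE_C, (1 - t2) * (1 - 5 * t2), 0)
}

# MM-estimation (bisquare, S-initialized) of a weighted regression, with a
# psi-based sandwich covariance. `X` and `y` arrive already multiplied by
# sqrt(weight), so the fit is in standardized coordinates and the robust
# scale `s` plays the role of the residual dispersion sigma. The sandwich
# variance s^2 A^{-1} B A^{-1} (A = sum psi' x x', B = sum psi^2 x x') is
# inflated by the Huber small-sample correction
# 1 + (p/n) var(psi') / mean(psi')^2.
robust_fit <- function(X, y) {
  n <- nrow(X)
  p <- ncol(X)
  fit <- with_preserved_seed(ROBUST_INIT_SEED,
    MASS::rlm(X, y, method = "MM", psi = MASS::psi.bisquare, maxit = 200))
  if (!fit$converged) warnf("robust regression did not converge in 200 iterations")
  u <- (y - drop(X %*% coef(fit))) / fit$s
  A <- crossprod(X, bisq_dpsi(u) * X)
  B <- crossprod(X, bisq_psi(u)^2 * X)
  Ainv <- solve(A)
  V <- fit$s^2 * (Ainv %*% B %*% Ainv)
  K <- 1 + p / n * var(bisq_dpsi(u)) / mean(bisq_dpsi(u))^2
  list(coef = coef(fit), se = sqrt(diag(V)) * K, sigma = fit$s)
}

resolve_model <- function(model, n) {
  model <- match.arg(model, c("default", "random", "fixed"))
  if (model == "default") model <- if (n >= 4) "random" else "fixed"
  model
}

# Dispersion handling shared by the estimator families: random-effects
# multiplies the fixed-effect SE by the residual dispersion floored at 1
# (multiplicative random effects, underdispersion floored); fixed ignores it.
inflate_se <- function(se_fixed, sigma, model) {
  if (model == "random") se_fixed * max(1, sigma) else se_fixed
}

# Regression weights for the IVW/Egger families, optionally
# heterogeneity-penalized. The penalty weighs each ratio by the inverse of
# its full delta-method variance (outcome term plus exposure term), the
# ratio-precision definition the robust/penalized estimator family uses, and
# measures deviations from the plain fixed-effect IVW estimate.
ivw_weights <- function(u, penalized) {
  w <- 1 / u$sy^2
  if (!penalized) return(w)
  ref <- wls_origin(u$bx, u$by, w)$beta
  ratio_var <- u$sy^2 / u$bx^2 + u$by^2 * u$sx^2 / u$bx^4
  pen <- penalize_weights(u$by / u$bx, 1 / ratio_var, ref)
  w * pen$factor
}

#' Inverse-variance weighted (IVW) estimator
#'
#' Weighted regression of outcome effects on exposure effects through the
#' origin with weights `1/se_outcome^2`. The `"random"` model multiplies the
#' fixed-effect standard error by the residual dispersion, floored at 1, so
#' overdispersion (heterogeneity) widens the interval but underdispersion
#' never narrows it; `"default"` uses the random-effects model from 4
#' variants upwards. `penalized = TRUE` replaces the weights by
#' heterogeneity-penalized weights (see [penalize_weights()]): each variant's
#' Wald ratio is weighted by the inverse of its full delta-method variance
#' (outcome and exposure terms) and deviations are measured from the plain
#' fixed-effect IVW estimate. `robust = TRUE` replaces least squares by
#' MM-estimation with bisquare loss (95% efficiency, S-initialization) on the
#' weighted regression, with a psi-based sandwich standard error under the
#' same dispersion floor.
#'
#' @param d A `harmonized_data` object.
#' @param model `"default"`, `"random"` or `"fixed"`.
#' @param penalized Use heterogeneity-penalized weights.
#' @param robust Use MM-estimation instead of least squares.
#' @return A one-row `mr_estimate` data frame: `method`, `n_variants`,
#'   `beta`, `se`, normal-quantile 95% CI, `pvalue`, odds-ratio scale
#'   columns, and (NA here) intercept columns.
#' @examples
#' fx <- paper_fixture()
#' d <- harmonize(fx$exposure, fx$outcome)
#' mr_ivw(d)
#' mr_ivw(d, robust = TRUE)
#' @export
mr_ivw <- function(d, model = "default", penalized = FALSE, robust = FALSE) {
  u <- unpack(d)
  if (u$n == 0) stopf("mr_ivw: no variants")
  method <- paste0(if (penalized) "penalized_" else "", if (robust) "robust_" else "", "ivw")
  if (u$n == 1) {
    if (robust) warnf("single variant: robust IVW falls back to the Wald ratio")
    wr <- mr_wald_ratio(d)
    return(mr_estimate(method, wr$beta, wr$se, 1L))
  }
  model <- resolve_model(model, u$n)
  w <- ivw_weights(u, penalized)
  if (robust) {
    sw <- sqrt(w)
    fit <- robust_fit(cbind(x = sw * u$bx), sw * u$by)
    se <- if (model == "random") fit$se / min(1, fit$sigma) else fit$se / fit$sigma
    return(mr_estimate(method, unname(fit$coef[1]), unname(se[1]), u$n))
  }
  fit <- wls_origin(u$bx, u$by, w)
  mr_estimate(method, fit$beta, inflate_se(fit$se_fixed, fit$sigma, model), u$n)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome effects on exposure effects with a free
#' intercept. Variants are first oriented so every exposure effect is
#' positive (negating both effects where needed), which makes the intercept
#' interpretable as the average directional pleiotropic effect; the slope is
#' the pleiotropy-adjusted causal estimate. Dispersion, penalization and
#' robust fitting behave exactly as in [mr_ivw()].
#'
#' @inheritParams mr_ivw
#' @return A one-row `mr_estimate` data frame with the intercept estimate,
#'   its standard error and normal p-value in the `intercept*` columns.
#' @examples
#' fx <- paper_fixture()
#' d <- harmonize(fx$exposure, fx$outcome)
#' mr_egger(d)
#' @export
mr_egger <- function(d, model = "default", penalized = FALSE, robust = FALSE) {
  u <- unpack(d)
  if (u$n < 3) stopf("mr_egger: at least 3 variants required, got %d", u$n)
  flip <- u$bx < 0
  bx <- ifelse(flip, -u$bx, u$bx)
  by <- ifelse(flip, -u$by, u$by)
  if (var(bx) == 0)
    stopf("mr_egger: exposure effects are all equal; slope not identifiable")
  model <- resolve_model(model, u$n)
  w <- ivw_weights(list(bx = bx, by = by, sy = u$sy, sx = u$sx), penalized)
  method <- paste0(if (penalized) "penalized_" else "",
                   if (robust) "robust_" else "", "mr_egger")
  if (robust) {
    sw <- sqrt(w)
    fit <- robust_fit(cbind(intercept = sw, x = sw * bx), sw * by)
    denom <- if (model == "random") min(1, fit$sigma) else fit$sigma
    se <- fit$se / denom
    return(mr_estimate(method, unname(fit$coef[2]), unname(se[2]), u$n,
                       intercept = unname(fit$coef[1]),
                       intercept_se = unname(se[1]),
                       intercept_pvalue = normal_pvalue(fit$coef[1], se[1])))
  }
  fit <- wls_intercept(bx, by, w)
  se <- inflate_se(fit$se_fixed, fit$sigma, model)
  mr_estimate(method, fit$slope, se[2], u$n,
              intercept = fit$intercept, intercept_se = se[1],
              intercept_pvalue = normal_pvalue(fit$intercept, se[1]))
}

# Interpolated 50th weight percentile of ordered ratios: cumulative weight
# midpoints s_j = (cumsum(w) - w/2) / sum(w), linear interpolation between
# the ratios straddling 0.5.
weighted_median <- function(r, w) {
  o <- order(r)
  r <- r[o]
  w <- w[o]
  s <- (cumsum(w) - 0.5 * w) / sum(w)
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] <= 0.5) return(r[length(r)])
  k <- max(which(s < 0.5))
  r[k] + (r[k + 1] - r[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
}

#' Median-based estimators
#'
#' The median of the per-variant Wald ratios, in three weightings: `"simple"`
#' (equal weights: consistent if a majority of instruments are valid),
#' `"weighted"` (inverse-variance weights `beta_exposure^2 / se_outcome^2`:
#' consistent if valid instruments carry half the weight), and `"penalized"`
#' (weighted, after heterogeneity-penalizing the weights against the
#' weighted-median estimate). The point estimate interpolates the 50th
#' percentile of the cumulative weight distribution over ordered ratios. The
#' standard error is a parametric bootstrap: exposure and outcome effects are
#' resampled from their normal sampling distributions and the median
#' re-estimated (weights held at their observed values); the SE is the SD
#' over replicates and the p-value a normal test.
#'
#' @param d A `harmonized_data` object.
#' @param weighting `"simple"`, `"weighted"` or `"penalized"`.
#' @param n_boot Bootstrap replicates (default 10000; fewer than 100 warns).
#' @param seed Seed for the bootstrap stream (the caller's RNG state is left
#'   untouched).
#' @return A one-row `mr_estimate` data frame.
#' @examples
#' fx <- paper_fixture()
#' d <- harmonize(fx$exposure, fx$outcome)
#' mr_median(d, "weighted", n_boot = 500)
#' @export
mr_median <- function(d, weighting = c("simple", "weighted", "penalized"),
                      n_boot = 10000, seed = 20201111) {
  weighting <- match.arg(weighting)
  u <- unpack(d)
  if (u$n < 3) stopf("mr_median: at least 3 variants required, got %d", u$n)
  if (n_boot < 100) warnf("n_boot = %d gives an unstable bootstrap SE", n_boot)
  r <- u$by / u$bx
  w <- switch(weighting,
    simple = rep(1 / u$n, u$n),
    weighted = u$bx^2 / u$sy^2,
    penalized = {
      wr <- u$bx^2 / u$sy^2
      ref <- weighted_median(r, wr)
      penalize_weights(r, wr, ref)$weights
    })
  if (sum(w) <= 0) stopf("mr_median: total weight is zero")
  beta <- weighted_median(r, w)
  boots <- with_preserved_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bxb <- rnorm(u$n, u$bx, u$sx)
      byb <- rnorm(u$n, u$by, u$sy)
      weighted_median(byb / bxb, w)
    }, numeric(1))
  })
  label <- c(simple = "simple_median", weighted = "weighted_median",
             penalized = "penalized_weighted_median")[[weighting]]
  mr_estimate(label, beta, sd(boots), u$n)
}

#' Run all eleven estimators
#'
#' Applies the full estimator battery — simple, weighted and penalized
#' weighted median; IVW, penalized, robust and penalized robust IVW;
#' MR-Egger, penalized, robust and penalized robust MR-Egger — and stacks the
#' results in that order. Deterministic given `seed` (the three median
#' bootstraps share the same resampling stream).
#'
#' @param d A `harmonized_data` object.
#' @param n_boot Bootstrap replicates for the median-family standard errors.
#' @param seed Seed for the bootstrap stream.
#' @return An `mr_estimate` data frame with eleven rows.
#' @examples
#' fx <- paper_fixture()
#' d <- harmonize(fx$exposure, fx$outcome)
#' mr_all_methods(d, n_boot = 500)
#' @export
mr_all_methods <- function(d, n_boot = 10000, seed = 20201111) {
  res <- rbind(
    mr_median(d, "simple", n_boot, seed),
    mr_median(d, "weighted", n_boot, seed),
    mr_median(d, "penalized", n_boot, seed),
    mr_ivw(d),
    mr_ivw(d, penalized = TRUE),
    mr_ivw(d, robust = TRUE),
    mr_ivw(d, penalized = TRUE, robust = TRUE),
    mr_egger(d),
    mr_egger(d, penalized = TRUE),
    mr_egger(d, robust = TRUE),
    mr_egger(d, penalized = TRUE, robust = TRUE)
  )
  stopifnot(identical(res$method, METHOD_ORDER))
  class(res) <- c("mr_estimate", "data.frame")
  res
}
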