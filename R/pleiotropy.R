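# Instrument-validity tests: MR-Egger intercept and MR-PRESSO global/outlier.

#' MR-Egger intercept test for directional pleiotropy
#'
#' Fits the plain (non-robust, unpenalized) MR-Egger regression and returns
#' its intercept: the estimated average directional pleiotropic effect of the
#' instruments on the outcome. Under valid instruments the intercept is zero;
#' intercept p < 0.05 is the conventional evidence threshold for directional
#' pleiotropy.
#'
#' @param d A `harmonized_data` object with at least 3 variants.
#' @return A list: `intercept`, `se`, `pvalue`.
#' @examples
#' fx <- paper_fixture()
#' d <- harmonize(fx$exposure, fx$outcome)
#' egger_intercept_test(d)
#' @export
egger_intercept_test <- function(d) {
  fit <- mr_egger(d)
  list(intercept = fit$intercept, se = fit$intercept_se,
       pvalue = fit$intercept_pvalue)
}

#' MR-PRESSO global and outlier test
#'
#' Residual-sum-and-outlier test for horizontal pleiotropy. For each variant
#' j the leave-one-out IVW estimate theta(-j) is computed from the remaining
#' variants; the observed statistic is the weighted residual sum of squares
#' `RSS = sum_j (betaY_j - theta(-j) betaX_j)^2 / seY_j^2`. Its null
#' distribution is simulated parametrically: both coordinates are resampled
#' from their sampling distributions (`betaX* ~ N(betaX_j, seX_j)`,
#' `betaY* ~ N(theta(-j) betaX_j, seY_j)`) and the RSS recomputed with the
#' same leave-one-out scheme. The global p-value is the empirical tail
#' probability `(1 + #\{RSS* >= RSS\}) / (n_sim + 1)`, so it is floored at
#' `1/(n_sim + 1)`. The outlier test compares each variant's observed
#' residual contribution with its simulated distribution and
#' Bonferroni-adjusts across variants.
#'
#' Simulation draws come from a single seeded stream consumed in sorted
#' variant-ID order, so datasets differing only in row order give identical
#' results; the caller's RNG state is untouched. The distortion test is not
#' implemented (`distortion_test = TRUE` errors).
#'
#' @param d A `harmonized_data` object with at least 4 variants.
#' @param n_sim Number of null simulations (default 10000; below 1000 warns,
#'   as the p-value resolution becomes coarse).
#' @param seed Seed for the simulation streams.
#' @param outlier_test Also compute per-variant outlier p-values.
#' @param distortion_test Not implemented; must stay `FALSE`.
#' @return An object of class `mr_presso`: `rss_observed`,
#'   `global_pvalue`, `outlier_pvalues` (named, Bonferroni-adjusted, `NULL`
#'   if not requested), `n_sim`, `seed`.
#' @examples
#' fx <- paper_fixture()
#' d <- harmonize(fx$exposure, fx$outcome)
#' mr_presso(d, n_sim = 1000)
#' @export
mr_presso <- function(d, n_sim = 10000, seed = 42, outlier_test = TRUE,
                      distortion_test = FALSE) {
  if (isTRUE(distortion_test))
    stopf("the MR-PRESSO distortion test is not implemented")
  u <- unpack(d)
  if (u$n < 4) stopf("mr_presso: at least 4 variants required, got %d", u$n)
  if (n_sim < 1000) warnf("n_sim = %d gives coarse p-value resolution", n_sim)

  w <- 1 / u$sy^2
  loo_theta <- function(BX, BY, W) {
    # rows = datasets, cols = variants; leave-one-out IVW per column
    sxy <- rowSums(W * BX * BY)
    sxx <- rowSums(W * BX^2)
    (sxy - W * BX * BY) / (sxx - W * BX^2)
  }
  W1 <- matrix(w, 1, u$n)
  th <- loo_theta(matrix(u$bx, 1), matrix(u$by, 1), W1)
  obs <- drop((matrix(u$by, 1) - th * matrix(u$bx, 1))^2 * W1)
  rss_obs <- sum(obs)

  BX <- BY <- matrix(NA_real_, n_sim, u$n)
  with_preserved_seed(seed, {
    for (j in canonical_order(u$snp)) {
      BX[, j] <- rnorm(n_sim, u$bx[j], u$sx[j])
      BY[, j] <- rnorm(n_sim, th[j] * u$bx[j], u$sy[j])
    }
  })
  W <- matrix(w, n_sim, u$n, byrow = TRUE)
  THS <- loo_theta(BX, BY, W)
  SIM <- (BY - THS * BX)^2 * W
  rss_sim <- rowSums(SIM)
  global_p <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)

  outlier <- NULL
  if (outlier_test) {
    praw <- (1 + colSums(SIM >= matrix(obs, n_sim, u$n, byrow = TRUE))) / (n_sim + 1)
    outlier <- setNames(pmin(1, praw * u$n), u$snp)
  }
  structure(list(rss_observed = rss_obs, global_pvalue = global_p,
                 outlier_pvalues = outlier, n_sim = n_sim, seed = seed),
            class = "mr_presso")
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("MR-PRESSO global test: RSS = %.3f, p = %.4g (%d simulations)\n",
              x$rss_observed, x$global_pvalue, x$n_sim))
  if (!is.null(x$outlier_pvalues)) {
    sig <- x$outlier_pvalues[x$outlier_pvalues < 0.05]
    if (length(sig) > 0) {
      cat("Outlier variants (Bonferroni-adjusted p < 0.05):\n")
      print(signif(sig, 3))
    } else {
      cat("No outlier variants at adjusted p < 0.05\n")
    }
  }
  invisible(x)
}
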