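# Instrument strength (variance explained) and binary-outcome power.

#' Variance in the exposure explained by the instruments
#'
#' Per-variant contribution `beta^2 * 2 * MAF * (1 - MAF) / sd^2` with
#' `MAF = min(eaf, 1 - eaf)`, summed over variants. `sd` is the phenotypic
#' standard deviation of the exposure in its own units (0.5 mg/dl for serum
#' calcium).
#'
#' @param exposure Variant-association data frame (needs `snp`, `beta`,
#'   `eaf`).
#' @param sd Exposure standard deviation, same units as `beta`.
#' @return An object of class `instrument_strength`: `per_variant_r2` (named
#'   proportions), `total_r2`, `sd_exposure`.
#' @examples
#' fx <- paper_fixture()
#' variance_explained(fx$exposure)
#' @export
variance_explained <- function(exposure, sd = 0.5) {
  if (!is.numeric(sd) || length(sd) != 1 || sd <= 0)
    stopf("variance_explained: sd must be a positive scalar")
  x <- as.data.frame(exposure)
  need <- c("snp", "beta", "eaf")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0)
    stopf("variance_explained: missing column(s) %s", paste(miss, collapse = ", "))
  bad <- which(!is.finite(x$eaf))
  if (length(bad) > 0)
    stopf("variance_explained: missing eaf for variant(s) %s",
          paste(x$snp[bad], collapse = ", "))
  maf <- pmin(x$eaf, 1 - x$eaf)
  r2 <- x$beta^2 * 2 * maf * (1 - maf) / sd^2
  structure(list(per_variant_r2 = setNames(r2, x$snp),
                 total_r2 = sum(r2), sd_exposure = sd),
            class = "instrument_strength")
}

#' @export
print.instrument_strength <- function(x, ...) {
  cat(sprintf("Instrument strength: %d variants explain %.2f%% of exposure variance (SD = %g)\n",
              length(x$per_variant_r2), 100 * x$total_r2, x$sd_exposure))
  print(round(100 * x$per_variant_r2, 2))
  invisible(x)
}

check_power_args <- function(n_total, case_fraction, r2, alpha) {
  if (n_total <= 0) stopf("n_total must be positive")
  if (case_fraction <= 0 || case_fraction >= 1) stopf("case_fraction must be in (0,1)")
  if (r2 <= 0 || r2 >= 1) stopf("r2 must be in (0,1)")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0,1)")
}

#' Statistical power of a two-sample MR study with a binary outcome
#'
#' Non-centrality approximation for a case-control outcome: with case
#' fraction `K` and odds ratio `OR` per SD of the exposure, the per-SD
#' mean shift is `b = K (OR / (1 + K (OR - 1)) - 1)`, the outcome variance
#' `v = K (1 - K) - b^2`, and the 1-df chi-square non-centrality is
#' `NCP = N R2 b^2 / v`. Power is the upper tail of the noncentral
#' chi-square(1, NCP) at the central 1 - alpha quantile. At `OR = 1` the
#' power equals `alpha` by construction.
#'
#' @param n_total Total sample size of the outcome study.
#' @param case_fraction Proportion of cases.
#' @param r2 Proportion of exposure variance explained by the instruments.
#' @param odds_ratio True odds ratio per SD of exposure (vectorized).
#' @param alpha Type-I error rate.
#' @return Power as a proportion (same length as `odds_ratio`).
#' @examples
#' mr_power(440328, 34217 / 440328, 0.011, 1.28)
#' @export
mr_power <- function(n_total, case_fraction, r2, odds_ratio, alpha = 0.05) {
  check_power_args(n_total, case_fraction, r2, alpha)
  if (any(odds_ratio <= 0)) stopf("odds_ratio must be positive")
  K <- case_fraction
  b <- K * (odds_ratio / (1 + K * (odds_ratio - 1)) - 1)
  v <- K * (1 - K) - b^2
  ncp <- n_total * r2 * b^2 / v
  pchisq(qchisq(1 - alpha, df = 1), df = 1, ncp = ncp, lower.tail = FALSE)
}

#' Smallest detectable odds ratio at a target power
#'
#' Inverts [mr_power()] over the odds ratio by bisection, on the requested
#' side of the null (`"above"`: OR > 1; `"below"`: OR < 1), to a tolerance
#' of 1e-6 in OR.
#'
#' @inheritParams mr_power
#' @param target_power Desired power, in `(alpha, 1)`.
#' @param direction `"above"` or `"below"` 1.
#' @return The odds ratio at which power equals `target_power`.
#' @examples
#' min_detectable_or(440328, 34217 / 440328, 0.011, target_power = 0.8)
#' @export
min_detectable_or <- function(n_total, case_fraction, r2, target_power = 0.8,
                              alpha = 0.05, direction = c("above", "below")) {
  direction <- match.arg(direction)
  check_power_args(n_total, case_fraction, r2, alpha)
  if (target_power <= alpha || target_power >= 1)
    stopf("target_power must be in (alpha, 1)")
  f <- function(or) mr_power(n_total, case_fraction, r2, or, alpha) - target_power
  if (direction == "above") {
    hi <- 1.01
    while (f(hi) < 0 && hi < 1e6) hi <- hi * 2
    if (f(hi) < 0)
      stopf("min_detectable_or: power never reaches %.3f for OR up to %g (power at bound: %.4f)",
            target_power, hi, f(hi) + target_power)
    lo <- 1 + 1e-12
  } else {
    lo <- 0.99
    while (f(lo) < 0 && lo > 1e-6) lo <- lo / 2
    if (f(lo) < 0)
      stopf("min_detectable_or: power never reaches %.3f for OR down to %g (power at bound: %.4f)",
            target_power, lo, f(lo) + target_power)
    hi <- 1 - 1e-12
  }
  uniroot(f, lower = min(lo, hi), upper = max(lo, hi), tol = 1e-8)$root
}
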