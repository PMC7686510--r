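# Synthetic two-sample MR summary statistics with known ground truth.

#' Configuration for the synthetic summary-statistic generator
#'
#' Describes the data-generating model behind [simulate_pair()]: independent
#' variants with per-variant true exposure effects gamma_j, optional
#' horizontal pleiotropy alpha_j, true outcome effects
#' `Gamma_j = theta * gamma_j + alpha_j`, and observed effects drawn from
#' normal sampling distributions whose standard errors scale as
#' `scale / sqrt(2 MAF_j (1 - MAF_j))` — the usual GWAS relation in which
#' `scale` plays the role of an effective sample size.
#'
#' Defaults emulate the serum-calcium instrument set: exposure effects of a
#' few hundredths of a unit with standard errors around 0.003, outcome
#' (log-odds) standard errors around 0.01, and a quarter of the outcome rows
#' emitted with swapped allele labels so harmonization is always exercised.
#'
#' @param n_snps Number of variants.
#' @param theta True causal effect (log-odds per exposure unit).
#' @param gamma_mean,gamma_sd Normal distribution of the true exposure
#'   effects; `gamma_positive = TRUE` folds it to positive values.
#' @param gamma_positive Force all true exposure effects positive.
#' @param pleiotropy `"none"`, `"balanced"` (alpha centred at 0) or
#'   `"directional"` (alpha centred at `alpha_mean`).
#' @param alpha_mean,alpha_sd Pleiotropy distribution (log-odds scale);
#'   `alpha_mean` is forced to 0 under `"balanced"` and ignored under
#'   `"none"`.
#' @param maf_range Interval in (0, 0.5] the minor allele frequencies are
#'   drawn from.
#' @param se_exposure_scale,se_outcome_scale Sampling-error scales (see
#'   description).
#' @param swap_fraction Fraction of outcome rows emitted with swapped allele
#'   labels (beta negated, frequency complemented).
#' @param n_outliers Number of planted outlier variants (the first
#'   `n_outliers` variants).
#' @param outlier_shift Outlier displacement in units of the variant's
#'   outcome standard error.
#' @param seed Integer seed for the generator stream.
#' @return A validated list of class `simulation_config`.
#' @examples
#' simulation_config(n_snps = 20, theta = 0.25)
#' @export
simulation_config <- function(n_snps = 50, theta = 0, gamma_mean = 0.02,
                              gamma_sd = 0.008, gamma_positive = TRUE,
                              pleiotropy = c("none", "balanced", "directional"),
                              alpha_mean = 0.05, alpha_sd = 0.01,
                              maf_range = c(0.05, 0.5),
                              se_exposure_scale = 0.002,
                              se_outcome_scale = 0.0075,
                              swap_fraction = 0.25, n_outliers = 0,
                              outlier_shift = 0, seed = 1) {
  pleiotropy <- match.arg(pleiotropy)
  if (n_snps < 1) stopf("n_snps must be at least 1")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stopf("maf_range must be an interval within (0, 0.5]")
  if (se_exposure_scale <= 0 || se_outcome_scale <= 0)
    stopf("se scales must be positive")
  if (swap_fraction < 0 || swap_fraction > 1)
    stopf("swap_fraction must be in [0, 1]")
  if (n_outliers < 0 || n_outliers > n_snps)
    stopf("n_outliers must be in [0, n_snps]")
  if (pleiotropy == "balanced") alpha_mean <- 0
  if (pleiotropy == "none") { alpha_mean <- 0; alpha_sd <- 0 }
  structure(list(n_snps = as.integer(n_snps), theta = theta,
                 gamma_mean = gamma_mean, gamma_sd = gamma_sd,
                 gamma_positive = gamma_positive, pleiotropy = pleiotropy,
                 alpha_mean = alpha_mean, alpha_sd = alpha_sd,
                 maf_range = maf_range,
                 se_exposure_scale = se_exposure_scale,
                 se_outcome_scale = se_outcome_scale,
                 swap_fraction = swap_fraction,
                 n_outliers = as.integer(n_outliers),
                 outlier_shift = outlier_shift, seed = seed),
            class = "simulation_config")
}

#' Simulate an exposure/outcome summary-statistic pair
#'
#' Generates the two association tables a two-sample MR analysis consumes,
#' plus the ground truth they were generated from. Per variant: a MAF and a
#' true exposure effect gamma are drawn; pleiotropy alpha is added per the
#' configured mode; the true outcome effect is `theta * gamma + alpha`
#' (planted outliers are further shifted by `outlier_shift` outcome standard
#' errors); observed effects are normal draws around the truth; alleles are
#' assigned randomly with random letter case, and a `swap_fraction` of
#' outcome rows are emitted with swapped allele labels so that harmonization
#' must flip them back. All draws come from one stream seeded by
#' `config$seed`, consumed variant by variant in ID order, so the same
#' configuration always yields the same tables.
#'
#' @param config A [simulation_config()] object.
#' @return A list: `exposure` and `outcome` (variant-association data
#'   frames) and `truth` (list with `theta` and per-variant `gamma`, `alpha`,
#'   `maf`, `se_exposure`, `se_outcome`, `outlier`, `swapped`).
#' @examples
#' sim <- simulate_pair(simulation_config(n_snps = 10, theta = 0.25, seed = 7))
#' d <- harmonize(sim$exposure, sim$outcome)
#' mr_ivw(d)
#' @export
simulate_pair <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cf <- config
  n <- cf$n_snps
  ids <- sprintf("snp%05d", seq_len(n))
  pairs <- list(c("A", "C"), c("A", "G"), c("A", "T"), c("C", "G"),
                c("C", "T"), c("G", "T"))
  exposure <- vector("list", n)
  outcome <- vector("list", n)
  truth <- data.frame(snp = ids, gamma = NA_real_, alpha = NA_real_,
                      maf = NA_real_, se_exposure = NA_real_,
                      se_outcome = NA_real_, outlier = seq_len(n) <= cf$n_outliers,
                      swapped = NA, stringsAsFactors = FALSE)
  with_preserved_seed(cf$seed, {
    for (j in canonical_order(ids)) {
      maf <- runif(1, cf$maf_range[1], cf$maf_range[2])
      gamma <- rnorm(1, cf$gamma_mean, cf$gamma_sd)
      if (cf$gamma_positive) gamma <- abs(gamma)
      alpha <- if (cf$pleiotropy == "none") 0 else
        rnorm(1, cf$alpha_mean, cf$alpha_sd)
      se_x <- cf$se_exposure_scale / sqrt(2 * maf * (1 - maf))
      se_y <- cf$se_outcome_scale / sqrt(2 * maf * (1 - maf))
      Gamma <- cf$theta * gamma + alpha
      if (truth$outlier[j]) Gamma <- Gamma + cf$outlier_shift * se_y
      beta_x <- rnorm(1, gamma, se_x)
      beta_y <- rnorm(1, Gamma, se_y)
      al <- pairs[[sample.int(6, 1)]]
      if (runif(1) < 0.5) al <- rev(al)        # which allele is the effect allele
      eaf <- if (runif(1) < 0.5) maf else 1 - maf
      eaf_out <- min(max(eaf + rnorm(1, 0, 0.005), 0.001), 0.999)
      case_e <- runif(1) < 0.5                 # mixed-case labels, as real files have
      case_o <- runif(1) < 0.5
      swap <- runif(1) < cf$swap_fraction
      e_al <- if (case_e) tolower(al) else al
      o_al <- if (case_o) tolower(al) else al
      if (swap) o_al <- rev(o_al)
      exposure[[j]] <- data.frame(
        snp = ids[j], effect_allele = e_al[1], other_allele = e_al[2],
        eaf = eaf, beta = beta_x, se = se_x,
        pvalue = max(normal_pvalue(beta_x, se_x), 1e-300),
        stringsAsFactors = FALSE)
      outcome[[j]] <- data.frame(
        snp = ids[j], effect_allele = o_al[1], other_allele = o_al[2],
        eaf = if (swap) 1 - eaf_out else eaf_out,
        beta = if (swap) -beta_y else beta_y, se = se_y,
        pvalue = max(normal_pvalue(beta_y, se_y), 1e-300),
        stringsAsFactors = FALSE)
      truth$gamma[j] <- gamma
      truth$alpha[j] <- alpha
      truth$maf[j] <- maf
      truth$se_exposure[j] <- se_x
      truth$se_outcome[j] <- se_y
      truth$swapped[j] <- swap
    }
  })
  list(exposure = do.call(rbind, exposure), outcome = do.call(rbind, outcome),
       truth = list(theta = cf$theta, variants = truth, config = cf))
}

#' The packaged serum-calcium / ischemic-stroke tables
#'
#' Returns the 14-variant exposure (serum calcium, mg/dl) and outcome
#' (ischemic stroke, log-odds) summary-statistic tables shipped with the
#' package, read from the packaged fixture files.
#'
#' @return A list with `exposure` and `outcome` variant-association data
#'   frames (14 rows each).
#' @examples
#' fx <- paper_fixture()
#' nrow(fx$exposure)
#' @export
paper_fixture <- function() {
  list(
    exposure = read_summary_table(
      system.file("extdata", "calcium_exposure.tsv", package = "camr")),
    outcome = read_summary_table(
      system.file("extdata", "stroke_outcome.tsv", package = "camr"))
  )
}
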