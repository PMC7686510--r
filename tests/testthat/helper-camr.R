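# Shared test fixtures, all built in code.

make_assoc <- function(snp, ea, oa, eaf, beta, se, p = 0.5) {
  data.frame(snp = snp, effect_allele = ea, other_allele = oa, eaf = eaf,
             beta = beta, se = se, pvalue = p, stringsAsFactors = FALSE)
}

# Build a harmonized_data object directly from effect vectors, for estimator
# math tests that do not involve allele handling.
hd <- function(bx, by, sy, sx = rep(1e-8, length(bx)),
               snp = sprintf("rs%03d", seq_along(bx))) {
  v <- data.frame(snp = snp, beta_exposure = bx, se_exposure = sx,
                  eaf_exposure = 0.3, beta_outcome = by, se_outcome = sy,
                  eaf_outcome = 0.3, flipped = FALSE, palindromic = FALSE,
                  stringsAsFactors = FALSE)
  structure(list(variants = v,
                 dropped = data.frame(snp = character(), reason = character(),
                                      stringsAsFactors = FALSE),
                 provenance = "test fixture"),
            class = "harmonized_data")
}

paper_harmonized <- function() {
  fx <- paper_fixture()
  harmonize(fx$exposure, fx$outcome)
}

# Turn a harmonized dataset back into exposure/outcome association tables
# (already aligned), for idempotence checks.
as_tables <- function(d) {
  v <- d$variants
  list(
    exposure = make_assoc(v$snp, "A", "G", v$eaf_exposure, v$beta_exposure,
                          v$se_exposure),
    outcome = make_assoc(v$snp, "A", "G", v$eaf_outcome, v$beta_outcome,
                         v$se_outcome)
  )
}
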