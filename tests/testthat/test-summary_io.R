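test_that("the packaged summary tables read and validate", {
  fx <- paper_fixture()
  expect_equal(nrow(fx$exposure), 14)
  expect_equal(nrow(fx$outcome), 14)
  expect_equal(fx$exposure$snp[1], "rs10491003")
  expect_equal(fx$exposure$beta[1], 0.027)
  expect_equal(fx$exposure$se[1], 0.005)
  r <- fx$outcome[fx$outcome$snp == "rs1550532", ]
  expect_equal(r$beta, 0.0022)
  # allele labels are upper-cased regardless of file case
  expect_true(all(fx$exposure$effect_allele %in% c("A", "C", "G", "T")))
  expect_true(all(fx$outcome$effect_allele %in% c("A", "C", "G", "T")))
})

test_that("a header-only file yields an empty record list", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("snp\teffect_allele\tother_allele\teaf\tbeta\tse\tpval", f)
  out <- read_summary_table(f)
  expect_equal(nrow(out), 0)
})

test_that("missing columns and malformed rows are reported precisely", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("snp\tea\toa\teaf\tbeta\tse\tpval",
               "rs1\tA\tG\t0.2\t0.1\t0.05\t0.01"), f)
  expect_error(read_summary_table(f), "configuration")
  expect_silent(read_summary_table(
    f, summary_dialect(effect_allele = "ea", other_allele = "oa")))

  g <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("snp\teffect_allele\tother_allele\teaf\tbeta\tse\tpval",
               "rs1\tA\tG\t0.2\t0.1\t0.05\t0.01",
               "rs2\tA\tG\t0.2\tnot_a_number\t0.05\t0.01"), g)
  expect_error(read_summary_table(g), "row\\(s\\) 2")

  h <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("snp\teffect_allele\tother_allele\teaf\tbeta\tse\tpval",
               "rs1\tA\tA\t0.2\t0.1\t0.05\t0.01"), h)
  expect_error(read_summary_table(h), "invalid record")
})

test_that("harmonization aligns the packaged tables with the documented flips", {
  d <- paper_harmonized()
  v <- d$variants
  expect_equal(nrow(v), 14)
  expect_equal(nrow(d$dropped), 0)
  expect_setequal(v$snp[v$flipped],
                  c("rs11967485", "rs1570669", "rs7336933", "rs7481584"))
  # identical alleles, case-insensitive: copied as-is
  expect_equal(v$beta_outcome[v$snp == "rs1801725"], 0.018)
  expect_false(v$flipped[v$snp == "rs1801725"])
  # swapped alleles: negated beta, complemented frequency
  expect_equal(v$beta_outcome[v$snp == "rs1570669"], -0.0191)
  expect_equal(v$eaf_outcome[v$snp == "rs1570669"], 1 - 0.6604)
  expect_equal(v$beta_outcome[v$snp == "rs7481584"], 0.0105)
  # the C/G variant is palindromic but frequency-concordant, so retained
  expect_true(v$palindromic[v$snp == "rs1550532"])
  # exposure input order is preserved
  expect_equal(v$snp, paper_fixture()$exposure$snp)
})

test_that("strand-complemented records align with and without swaps", {
  ex <- make_assoc("rs9", "G", "T", 0.2, 0.05, 0.01)
  # complement of G/T is C/A: same orientation after complementing
  out_same <- make_assoc("rs9", "C", "A", 0.21, 0.03, 0.02)
  v <- harmonize(ex, out_same)$variants
  expect_false(v$flipped)
  expect_equal(v$beta_outcome, 0.03)
  # complement then swap: A/C relative to G/T
  out_swap <- make_assoc("rs9", "A", "C", 0.79, 0.03, 0.02)
  v <- harmonize(ex, out_swap)$variants
  expect_true(v$flipped)
  expect_equal(v$beta_outcome, -0.03)
  expect_equal(v$eaf_outcome, 0.21)
})

test_that("palindromic variants are resolved by frequency concordance", {
  ex <- c_assoc <- make_assoc(c("rs1", "rs2"), c("A", "C"), c("T", "G"),
                              c(0.30, 0.30), c(0.05, 0.05), c(0.01, 0.01))
  # concordant, both below the limit: retained
  out <- make_assoc(c("rs1", "rs2"), c("A", "C"), c("T", "G"),
                    c(0.32, 0.31), c(0.03, 0.03), c(0.02, 0.02))
  d <- harmonize(ex, out)
  expect_equal(nrow(d$variants), 2)
  expect_true(all(d$variants$palindromic))
  # discordant sides of 0.5: dropped
  out$eaf[1] <- 0.65
  d <- harmonize(ex, out)
  expect_equal(d$dropped$snp, "rs1")
  expect_equal(d$dropped$reason, "palindromic_eaf_discordant")
  # inside the ambiguity band around 0.5: dropped even if concordant
  ex2 <- make_assoc("rs3", "A", "T", 0.45, 0.05, 0.01)
  out2 <- make_assoc("rs3", "A", "T", 0.46, 0.03, 0.02)
  expect_error(harmonize(ex2, out2), "no variants survived")
  d2 <- harmonize(rbind(ex, ex2), rbind(out[2, ], out2))
  expect_equal(d2$dropped$snp, "rs3")
  # a higher limit admits it
  d3 <- harmonize(ex2, out2, palindromic_eaf_limit = 0.49)
  expect_equal(nrow(d3$variants), 1)
})

test_that("the variant count invariant holds over the ID intersection", {
  ex <- make_assoc(c("rs1", "rs2", "rs3"), c("A", "A", "A"), c("G", "G", "G"),
                   0.3, 0.05, 0.01)
  out <- make_assoc(c("rs2", "rs3", "rs4"), c("A", "A", "A"), c("G", "C", "G"),
                    0.3, 0.03, 0.02)
  d <- harmonize(ex, out)
  # rs1/rs4 are outside the intersection; rs3 has irreconcilable alleles
  expect_equal(nrow(d$variants) + nrow(d$dropped), 2)
  expect_equal(d$dropped$snp, "rs3")
  expect_equal(d$dropped$reason, "incompatible_alleles")
  expect_error(harmonize(make_assoc("rs1", "A", "G", 0.3, 0.05, 0.01),
                         make_assoc("rs9", "A", "G", 0.3, 0.03, 0.02)),
               "no variants")
})

test_that("harmonization is idempotent and invariant to allele relabelling", {
  for (seed in 1:5) {
    sim <- simulate_pair(simulation_config(n_snps = 12, theta = 0.2, seed = seed))
    d <- harmonize(sim$exposure, sim$outcome)
    # idempotence: harmonizing the aligned tables changes nothing
    tabs <- as_tables(d)
    d2 <- harmonize(tabs$exposure, tabs$outcome)
    expect_equal(d2$variants$beta_outcome, d$variants$beta_outcome)
    expect_false(any(d2$variants$flipped))
    # relabelling invariance: swap alleles + negate beta + complement eaf
    oc <- sim$outcome
    i <- seq(1, nrow(oc), by = 2)
    tmp <- oc$effect_allele[i]
    oc$effect_allele[i] <- oc$other_allele[i]
    oc$other_allele[i] <- tmp
    oc$beta[i] <- -oc$beta[i]
    oc$eaf[i] <- 1 - oc$eaf[i]
    d3 <- harmonize(sim$exposure, oc)
    expect_equal(d3$variants$beta_outcome, d$variants$beta_outcome)
    expect_equal(d3$variants$eaf_outcome, d$variants$eaf_outcome)
    expect_equal(d3$dropped, d$dropped)
  }
})

test_that("harmonized datasets round-trip through disk", {
  d <- paper_harmonized()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_harmonized(d, f)
  d2 <- read_harmonized(f)
  expect_equal(d2$variants, d$variants)
  expect_equal(nrow(d2$dropped), 0)
  expect_true(any(grepl("harmonized: 14", d2$provenance)))

  # with a dropped variant, a sidecar report appears and round-trips
  ex <- rbind(paper_fixture()$exposure,
              make_assoc("rs_bad", "A", "T", 0.45, 0.01, 0.01))
  out <- rbind(paper_fixture()$outcome,
               make_assoc("rs_bad", "A", "T", 0.46, 0.01, 0.01))
  d3 <- harmonize(ex, out)
  g <- withr::local_tempfile(fileext = ".tsv")
  write_harmonized(d3, g)
  expect_true(file.exists(paste0(g, ".dropped.tsv")))
  d4 <- read_harmonized(g)
  expect_equal(d4$dropped, d3$dropped)
  expect_equal(nrow(d4$variants), 14)
})
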