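# Reading, validating and harmonizing GWAS summary-statistic tables.

VALID_ALLELES <- c("A", "C", "G", "T")

#' Column-name mapping for summary-statistic tables
#'
#' GWAS summary files rarely agree on column names. A dialect maps the seven
#' fields the package needs onto the names used in a particular file.
#'
#' @param snp,effect_allele,other_allele,eaf,beta,se,pvalue Column names in
#'   the file for, respectively: variant identifier (rsID), effect allele,
#'   other (non-effect) allele, effect-allele frequency, per-allele effect
#'   estimate, its standard error, and the association p-value.
#' @return A named character vector usable as the `dialect` argument of
#'   [read_summary_table()].
#' @examples
#' summary_dialect(snp = "rsid", pvalue = "p")
#' @export
summary_dialect <- function(snp = "snp", effect_allele = "effect_allele",
                            other_allele = "other_allele", eaf = "eaf",
                            beta = "beta", se = "se", pvalue = "pval") {
  c(snp = snp, effect_allele = effect_allele, other_allele = other_allele,
    eaf = eaf, beta = beta, se = se, pvalue = pvalue)
}

# Validate a variant-association data frame. Checks the row-level invariants
# (valid distinct alleles, eaf in (0,1), se > 0, p in (0,1]) and fails with
# the offending row numbers.
validate_variants <- function(x, what = "summary table") {
  need <- c("snp", "effect_allele", "other_allele", "eaf", "beta", "se", "pvalue")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0)
    stopf("%s is missing required columns: %s", what, paste(miss, collapse = ", "))
  x$snp <- as.character(x$snp)
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))
  for (col in c("eaf", "beta", "se", "pvalue")) {
    v <- x[[col]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad) > 0)
        stopf("%s: non-numeric '%s' in row(s) %s", what, col,
              paste(bad, collapse = ", "))
      x[[col]] <- num
    }
  }
  bad_rows <- which(
    !(x$effect_allele %in% VALID_ALLELES) |
      !(x$other_allele %in% VALID_ALLELES) |
      x$effect_allele == x$other_allele |
      !is.finite(x$eaf) | x$eaf <= 0 | x$eaf >= 1 |
      !is.finite(x$beta) |
      !is.finite(x$se) | x$se <= 0 |
      !is.finite(x$pvalue) | x$pvalue <= 0 | x$pvalue > 1
  )
  if (length(bad_rows) > 0)
    stopf("%s: invalid record(s) in row(s) %s (check alleles, eaf in (0,1), se > 0, p in (0,1])",
          what, paste(bad_rows, collapse = ", "))
  if (anyDuplicated(x$snp))
    stopf("%s: duplicated variant IDs: %s", what,
          paste(unique(x$snp[duplicated(x$snp)]), collapse = ", "))
  rownames(x) <- NULL
  x[need]
}

#' Read a GWAS summary-statistic table
#'
#' Reads a TSV (or CSV, by file extension) of per-variant association records
#' and validates every row. Allele strings are upper-cased; columns beyond
#' those in the dialect are ignored.
#'
#' @param path Path to the file.
#' @param dialect Named character vector from [summary_dialect()] mapping the
#'   required fields to column names in the file.
#' @return A data frame with columns `snp`, `effect_allele`, `other_allele`,
#'   `eaf`, `beta`, `se`, `pvalue`, one row per variant.
#' @examples
#' path <- system.file("extdata", "calcium_exposure.tsv", package = "camr")
#' head(read_summary_table(path))
#' @export
read_summary_table <- function(path, dialect = summary_dialect()) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "#",
                    colClasses = "character")
  miss <- setdiff(unname(dialect), names(raw))
  if (length(miss) > 0)
    stopf("configuration error: column(s) %s not present in %s",
          paste(miss, collapse = ", "), path)
  out <- raw[unname(dialect)]
  names(out) <- names(dialect)
  if (nrow(out) == 0) {
    out <- data.frame(snp = character(), effect_allele = character(),
                      other_allele = character(), eaf = numeric(),
                      beta = numeric(), se = numeric(), pvalue = numeric(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  validate_variants(out, what = path)
}

complement_allele <- function(a) {
  chartr("ACGT", "TGCA", a)
}

is_palindromic_pair <- function(ea, oa) {
  ea == complement_allele(oa)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Joins the two tables on variant ID and expresses each outcome effect on
#' the exposure's effect allele. Allele comparison is case-insensitive. Per
#' shared variant: if the outcome alleles match the exposure alleles the
#' record is copied; if effect and other allele are swapped the outcome beta
#' is negated and the frequency replaced by its complement (`flipped`); if
#' neither matches, both comparisons are retried after strand complementation
#' (A<->T, C<->G). Palindromic variants (A/T or C/G) are strand-ambiguous, so
#' they are retained only when the exposure and aligned outcome frequencies
#' agree: both on the same side of 0.5 and both at most
#' `palindromic_eaf_limit` (or at least its complement). Everything else in
#' the ID intersection is dropped with a reason.
#'
#' @param exposure,outcome Variant-association data frames as returned by
#'   [read_summary_table()] (validated again here).
#' @param palindromic_eaf_limit Frequency cut-off for keeping palindromic
#'   variants; default 0.42 leaves a guard band around 0.5 where strand
#'   cannot be inferred from frequency.
#' @return An object of class `harmonized_data`: a list with `variants` (data
#'   frame: `snp`, `beta_exposure`, `se_exposure`, `eaf_exposure`,
#'   `beta_outcome`, `se_outcome`, `eaf_outcome`, `flipped`, `palindromic`,
#'   ordered as in the exposure input), `dropped` (data frame `snp`,
#'   `reason` for intersection members that could not be harmonized) and
#'   `provenance` (character log).
#' @examples
#' fx <- paper_fixture()
#' d <- harmonize(fx$exposure, fx$outcome)
#' d
#' @export
harmonize <- function(exposure, outcome, palindromic_eaf_limit = 0.42) {
  exposure <- validate_variants(as.data.frame(exposure), "exposure")
  outcome <- validate_variants(as.data.frame(outcome), "outcome")
  if (nrow(exposure) == 0 || nrow(outcome) == 0)
    stopf("harmonize: exposure and outcome must both be non-empty")
  shared <- exposure$snp[exposure$snp %in% outcome$snp]
  prov <- c(
    sprintf("exposure variants: %d", nrow(exposure)),
    sprintf("outcome variants: %d", nrow(outcome)),
    sprintf("shared variant IDs: %d", length(shared)),
    sprintf("absent from outcome: %d; absent from exposure: %d",
            sum(!exposure$snp %in% outcome$snp),
            sum(!outcome$snp %in% exposure$snp)),
    sprintf("palindromic eaf limit: %g", palindromic_eaf_limit)
  )

  rows <- list()
  dropped <- list()
  for (id in shared) {
    e <- exposure[exposure$snp == id, ]
    o <- outcome[outcome$snp == id, ]
    align <- align_alleles(e$effect_allele, e$other_allele,
                           o$effect_allele, o$other_allele)
    if (is.na(align$flip)) {
      dropped[[id]] <- "incompatible_alleles"
      next
    }
    beta_o <- if (align$flip) -o$beta else o$beta
    eaf_o <- if (align$flip) 1 - o$eaf else o$eaf
    pal <- is_palindromic_pair(e$effect_allele, e$other_allele)
    if (pal) {
      ok <- (e$eaf <= palindromic_eaf_limit && eaf_o <= palindromic_eaf_limit) ||
        (e$eaf >= 1 - palindromic_eaf_limit && eaf_o >= 1 - palindromic_eaf_limit)
      if (!ok) {
        dropped[[id]] <- "palindromic_eaf_discordant"
        next
      }
    }
    rows[[id]] <- data.frame(
      snp = id, beta_exposure = e$beta, se_exposure = e$se,
      eaf_exposure = e$eaf, beta_outcome = beta_o, se_outcome = o$se,
      eaf_outcome = eaf_o, flipped = align$flip, palindromic = pal,
      stringsAsFactors = FALSE
    )
  }
  variants <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(snp = character(), beta_exposure = numeric(),
               se_exposure = numeric(), eaf_exposure = numeric(),
               beta_outcome = numeric(), se_outcome = numeric(),
               eaf_outcome = numeric(), flipped = logical(),
               palindromic = logical(), stringsAsFactors = FALSE)
  rownames(variants) <- NULL
  dropped_df <- data.frame(snp = names(dropped),
                           reason = unlist(unname(dropped), use.names = FALSE),
                           stringsAsFactors = FALSE)
  if (nrow(dropped_df) == 0)
    dropped_df <- data.frame(snp = character(), reason = character(),
                             stringsAsFactors = FALSE)
  if (nrow(variants) == 0)
    stopf("harmonize: no variants survived harmonization (%d shared, all dropped)",
          length(shared))
  prov <- c(prov, sprintf("harmonized: %d; dropped: %d; flipped: %d; palindromic kept: %d",
                          nrow(variants), nrow(dropped_df),
                          sum(variants$flipped), sum(variants$palindromic)))
  structure(list(variants = variants, dropped = dropped_df, provenance = prov),
            class = "harmonized_data")
}

# Decide the orientation of an outcome allele pair relative to the exposure
# pair. Returns flip = FALSE (same orientation), TRUE (effect/other swapped,
# beta must be negated) or NA (irreconcilable). Strand complementation is
# tried only when direct comparison fails.
align_alleles <- function(e_ea, e_oa, o_ea, o_oa) {
  if (o_ea == e_ea && o_oa == e_oa) return(list(flip = FALSE))
  if (o_ea == e_oa && o_oa == e_ea) return(list(flip = TRUE))
  c_ea <- complement_allele(o_ea)
  c_oa <- complement_allele(o_oa)
  if (c_ea == e_ea && c_oa == e_oa) return(list(flip = FALSE))
  if (c_ea == e_oa && c_oa == e_ea) return(list(flip = TRUE))
  list(flip = NA)
}

#' @export
print.harmonized_data <- function(x, ...) {
  cat(sprintf("Harmonized two-sample MR dataset: %d variants (%d flipped, %d palindromic), %d dropped\n",
              nrow(x$variants), sum(x$variants$flipped),
              sum(x$variants$palindromic), nrow(x$dropped)))
  print(x$variants, ...)
  if (nrow(x$dropped) > 0) {
    cat("Dropped variants:\n")
    print(x$dropped, ...)
  }
  invisible(x)
}

#' Write / read a harmonized dataset
#'
#' `write_harmonized()` writes the variant table as TSV (with the flip and
#' palindromic audit columns); if any variants were dropped during
#' harmonization a `<path>.dropped.tsv` sidecar records them. Provenance
#' lines are embedded as `#`-prefixed header comments. `read_harmonized()`
#' restores the object, so the pair round-trips without loss.
#'
#' @param dataset A `harmonized_data` object.
#' @param path Output path (TSV).
#' @return `write_harmonized()` returns `path` invisibly; `read_harmonized()`
#'   returns a `harmonized_data` object.
#' @export
write_harmonized <- function(dataset, path) {
  stopifnot(inherits(dataset, "harmonized_data"))
  if (nrow(dataset$variants) == 0) stopf("write_harmonized: empty dataset")
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stopf("cannot write to %s", path)
  on.exit(close(con))
  writeLines(paste0("# ", dataset$provenance), con)
  write.table(dataset$variants, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (nrow(dataset$dropped) > 0)
    write.table(dataset$dropped, paste0(path, ".dropped.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_harmonized
#' @export
read_harmonized <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  prov <- sub("^# ", "", lines[startsWith(lines, "#")])
  variants <- read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, comment.char = "#")
  side <- paste0(path, ".dropped.tsv")
  dropped <- if (file.exists(side))
    read.table(side, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
               colClasses = "character")
  else data.frame(snp = character(), reason = character(),
                  stringsAsFactors = FALSE)
  structure(list(variants = variants, dropped = dropped, provenance = prov),
            class = "harmonized_data")
}
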