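#' Default column map for summary-statistic files
#'
#' Maps the internal field names to the column headers expected in a
#' tab-delimited summary-statistics file. Override entries to read
#' other dialects; [plink_assoc_colmap()] provides a ready-made map for
#' PLINK `.assoc.logistic`-style output.
#'
#' @return Named character vector: internal field -> file column.
#' @export
default_colmap <- function() {
  c(snp_id = "snp_id", chrom = "chrom", pos = "pos",
    effect_allele = "effect_allele", other_allele = "other_allele",
    effect = "effect", eaf = "eaf", pvalue = "pvalue",
    n_cases = "n_cases", n_controls = "n_controls", n_total = "n_total")
}

#' @rdname default_colmap
#' @export
plink_assoc_colmap <- function() {
  c(snp_id = "SNP", chrom = "CHR", pos = "BP",
    effect_allele = "A1", other_allele = "A2",
    effect = "OR", eaf = "MAF", pvalue = "P",
    n_cases = "NCA", n_controls = "NCO", n_total = "NMISS")
}

#' Read a GWAS summary-statistics table
#'
#' Reads a tab-delimited file of per-SNP association records, validates
#' each row against the field invariants (allele frequency strictly in
#' (0,1), P-value in (0,1], positive odds ratio for binary traits,
#' consistent sample sizes) and drops rows that fail, reporting the
#' number dropped via a message and a `"n_dropped"` attribute.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param trait_kind `"binary"` (effect column holds an odds ratio) or
#'   `"quantitative"` (effect is a beta in trait units).
#' @param colmap Named character vector mapping internal field names to
#'   file column names; see [default_colmap()].
#' @return Data frame with the standardized columns `snp_id`, `chrom`,
#'   `pos`, `effect_allele`, `other_allele`, `effect`, `eaf`, `pvalue`,
#'   `n_cases`, `n_controls`, `n_total`.
#' @export
read_summary <- function(path, trait_kind = c("binary", "quantitative"),
                         colmap = default_colmap()) {
  trait_kind <- match.arg(trait_kind)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                "effect", "eaf", "pvalue")
  for (f in required) {
    if (!colmap[[f]] %in% names(raw))
      stop("mandatory column '", colmap[[f]], "' (field ", f,
           ") missing from ", path)
  }
  get <- function(f, default = NA) {
    col <- colmap[[f]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else default
  }
  out <- data.frame(
    snp_id = as.character(get("snp_id")),
    chrom = as.character(get("chrom")),
    pos = suppressWarnings(as.integer(get("pos"))),
    effect_allele = toupper(as.character(get("effect_allele"))),
    other_allele = toupper(as.character(get("other_allele"))),
    effect = suppressWarnings(as.numeric(get("effect"))),
    eaf = suppressWarnings(as.numeric(get("eaf"))),
    pvalue = suppressWarnings(as.numeric(get("pvalue"))),
    n_cases = suppressWarnings(as.integer(get("n_cases", 0L))),
    n_controls = suppressWarnings(as.integer(get("n_controls", 0L))),
    n_total = suppressWarnings(as.integer(get("n_total", NA))),
    stringsAsFactors = FALSE
  )
  if (all(is.na(out$n_total)))
    out$n_total <- out$n_cases + out$n_controls
  ok <- !is.na(out$snp_id) & !is.na(out$pos) &
    out$effect_allele %in% c("A", "C", "G", "T") &
    out$other_allele %in% c("A", "C", "G", "T") &
    !is.na(out$eaf) & out$eaf > 0 & out$eaf < 1 &
    !is.na(out$pvalue) & out$pvalue > 0 & out$pvalue <= 1 &
    !is.na(out$effect) & !is.na(out$n_total) & out$n_total > 0
  if (trait_kind == "binary") {
    ok <- ok & out$effect > 0 &
      out$n_total >= out$n_cases + out$n_controls
  }
  ok[is.na(ok)] <- FALSE
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    message("read_summary: dropped ", n_dropped,
            " row(s) failing field invariants")
  out <- out[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write a summary-statistics table
#'
#' Inverse of [read_summary()] under the default column map: writes a
#' tab-delimited file that reads back with all fields preserved.
#'
#' @param x Summary data frame as returned by [read_summary()].
#' @param path Output path.
#' @export
write_summary <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

allele_pair_status <- function(ea1, oa1, ea2, oa2) {
  ifelse(ea1 == ea2 & oa1 == oa2, "same",
         ifelse(ea1 == oa2 & oa1 == ea2, "swapped", "mismatch"))
}

is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

#' Align discovery and test summary statistics on a common effect allele
#'
#' Intersects two summary tables on SNP identifier and expresses the
#' test-study effect on the discovery study's effect allele. If the two
#' studies report swapped allele labels the test effect is inverted
#' (odds ratio to its reciprocal, beta negated) and the test allele
#' frequency complemented. SNPs whose allele pairs are neither
#' identical nor swapped are excluded. Strand-ambiguous (A/T, C/G)
#' SNPs are kept and aligned by allele label by default; set
#' `palindromic = "drop"` to exclude them.
#'
#' The direction flag `same_direction` records whether the aligned
#' effects agree in sign (log odds ratio for binary traits, beta for
#' quantitative); SNPs with an exactly null effect in either study get
#' `NA` and are excluded from direction-of-effect models.
#'
#' @param disc,test Summary data frames from [read_summary()].
#' @param trait_kind `"binary"` or `"quantitative"`.
#' @param palindromic `"keep"` (default) or `"drop"`.
#' @return Data frame with one row per shared, alignable SNP:
#'   `snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#'   `effect_disc`, `eaf_disc`, `pvalue_disc`, `n_cases_disc`,
#'   `n_controls_disc`, `n_total_disc`, the same six `_test` columns,
#'   and `same_direction`.
#' @export
harmonize <- function(disc, test,
                      trait_kind = c("binary", "quantitative"),
                      palindromic = c("keep", "drop")) {
  trait_kind <- match.arg(trait_kind)
  palindromic <- match.arg(palindromic)
  stopifnot(nrow(disc) > 0, nrow(test) > 0)
  shared <- intersect(disc$snp_id, test$snp_id)
  if (length(shared) == 0) {
    warning("no SNP identifiers shared between the two studies")
    return(empty_pairs())
  }
  d <- disc[match(shared, disc$snp_id), , drop = FALSE]
  t <- test[match(shared, test$snp_id), , drop = FALSE]
  status <- allele_pair_status(d$effect_allele, d$other_allele,
                               t$effect_allele, t$other_allele)
  n_mismatch <- sum(status == "mismatch")
  if (n_mismatch > 0)
    message("harmonize: excluded ", n_mismatch,
            " SNP(s) with incompatible allele pairs")
  keep <- status != "mismatch"
  if (palindromic == "drop") {
    pal <- is_palindromic(d$effect_allele, d$other_allele)
    keep <- keep & !pal
  }
  d <- d[keep, , drop = FALSE]
  t <- t[keep, , drop = FALSE]
  status <- status[keep]
  swap <- status == "swapped"
  eff_test <- t$effect
  eaf_test <- t$eaf
  if (trait_kind == "binary") {
    eff_test[swap] <- 1 / eff_test[swap]
  } else {
    eff_test[swap] <- -eff_test[swap]
  }
  eaf_test[swap] <- 1 - eaf_test[swap]
  if (trait_kind == "binary") {
    s_d <- sign(log(d$effect))
    s_t <- sign(log(eff_test))
  } else {
    s_d <- sign(d$effect)
    s_t <- sign(eff_test)
  }
  same_direction <- ifelse(s_d == 0 | s_t == 0, NA, s_d == s_t)
  out <- data.frame(
    snp_id = d$snp_id, chrom = d$chrom, pos = d$pos,
    effect_allele = d$effect_allele, other_allele = d$other_allele,
    effect_disc = d$effect, eaf_disc = d$eaf, pvalue_disc = d$pvalue,
    n_cases_disc = d$n_cases, n_controls_disc = d$n_controls,
    n_total_disc = d$n_total,
    effect_test = eff_test, eaf_test = eaf_test, pvalue_test = t$pvalue,
    n_cases_test = t$n_cases, n_controls_test = t$n_controls,
    n_total_test = t$n_total,
    same_direction = same_direction,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

empty_pairs <- function() {
  data.frame(snp_id = character(), chrom = character(), pos = integer(),
             effect_allele = character(), other_allele = character(),
             effect_disc = numeric(), eaf_disc = numeric(),
             pvalue_disc = numeric(), n_cases_disc = integer(),
             n_controls_disc = integer(), n_total_disc = integer(),
             effect_test = numeric(), eaf_test = numeric(),
             pvalue_test = numeric(), n_cases_test = integer(),
             n_controls_test = integer(), n_total_test = integer(),
             same_direction = logical(), stringsAsFactors = FALSE)
}

#' Filter harmonized pairs on discovery minor-allele frequency
#'
#' Retains pairs whose discovery minor-allele frequency
#' `min(eaf, 1 - eaf)` strictly exceeds `min_maf` (default 1%).
#'
#' @param pairs Harmonized pair table from [harmonize()].
#' @param min_maf MAF threshold in `[0, 0.5)`.
#' @return Filtered pair table.
#' @export
apply_maf_filter <- function(pairs, min_maf = 0.01) {
  stopifnot(min_maf >= 0, min_maf < 0.5)
  maf <- pmin(pairs$eaf_disc, 1 - pairs$eaf_disc)
  pairs[maf > min_maf, , drop = FALSE]
}
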