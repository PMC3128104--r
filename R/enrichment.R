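#' Fit a replication-versus-power logistic model
#'
#' Fits, by maximum likelihood, one of the six logistic regressions of
#' the per-SNP replication indicator used to test for an underlying
#' shared genetic signal between two studies:
#'
#' * `"I"`  — `replicated ~ power`, all SNPs;
#' * `"II"` — `replicated ~ power * near_exon`, all SNPs;
#' * `"III"` — Model I restricted to SNPs whose effects agree in
#'   direction across the two studies;
#' * `"IV"` — Model II on the same-direction subset;
#' * `"M1"` — `replicated ~ same_direction`, all SNPs with a defined
#'   direction flag;
#' * `"M2"` — `replicated ~ power * same_direction`.
#'
#' Each fit tests a single genome-wide hypothesis (is replication a
#' function of power / proximity / direction), so the reported
#' P-values need no multiple-testing correction across SNPs.
#'
#' @param records Power-record table from [power_records()].
#' @param model_tag One of `"I"`, `"II"`, `"III"`, `"IV"`, `"M1"`,
#'   `"M2"`.
#' @param near_exon_threshold_bp Distance cutoff in bp selecting the
#'   `near_<d>` column (required for Models II and IV).
#' @param p_type `"wald"` (default, the `glm` summary P-value) or
#'   `"lrt"` (likelihood-ratio drop-in-deviance test per term).
#' @return Object of class `enrichment_fit`: list with `model_tag`,
#'   `coefficients` (data frame, rows named by term: `estimate`, `se`,
#'   `p_value`), `n_snps`, `snp_subset`, `near_exon_threshold_bp`,
#'   `converged`, `separation`, and the underlying `glm` fit. When the
#'   fit fails to converge or separates, P-values are withheld (`NA`)
#'   and the flags are set.
#' @export
fit_model <- function(records,
                      model_tag = c("I", "II", "III", "IV", "M1", "M2"),
                      near_exon_threshold_bp = NULL,
                      p_type = c("wald", "lrt")) {
  model_tag <- match.arg(model_tag)
  p_type <- match.arg(p_type)
  stopifnot(is.data.frame(records), nrow(records) > 0)
  d <- records
  subset_tag <- "all"
  if (model_tag %in% c("III", "IV")) {
    if (!"same_direction" %in% names(d) || all(is.na(d$same_direction)))
      stop("same_direction flag required for Model ", model_tag)
    d <- d[!is.na(d$same_direction) & d$same_direction, , drop = FALSE]
    subset_tag <- "same_direction"
  }
  if (model_tag %in% c("M1", "M2")) {
    if (!"same_direction" %in% names(d) || all(is.na(d$same_direction)))
      stop("same_direction flag required for Model ", model_tag)
    d <- d[!is.na(d$same_direction), , drop = FALSE]
  }
  if (model_tag %in% c("II", "IV")) {
    if (is.null(near_exon_threshold_bp))
      stop("near_exon_threshold_bp required for Model ", model_tag)
    col <- paste0("near_", near_exon_threshold_bp)
    if (!col %in% names(d))
      stop("column '", col, "' not found; annotate with that threshold")
    d$near_exon <- d[[col]]
  }
  y <- d$replicated
  if (all(y) || !any(y))
    stop("replication indicator is constant; model cannot be fit")
  form <- switch(model_tag,
    I = replicated ~ power,
    II = replicated ~ power * near_exon,
    III = replicated ~ power,
    IV = replicated ~ power * near_exon,
    M1 = replicated ~ same_direction,
    M2 = replicated ~ power * same_direction)
  fit <- suppressWarnings(
    stats::glm(form, data = d, family = stats::binomial("logit")))
  sm <- summary(fit)$coefficients
  # fitted probabilities pinned at 0/1 indicate (quasi-)separation
  eps <- 1e-8
  separation <- any(fit$fitted.values > 1 - eps) ||
    any(fit$fitted.values < eps)
  converged <- fit$converged
  co <- data.frame(estimate = sm[, 1], se = sm[, 2],
                   p_value = sm[, 4], row.names = rownames(sm))
  if (p_type == "lrt") {
    dr <- stats::drop1(fit, test = "LRT")
    labels <- attr(fit$terms, "term.labels")
    assign <- attr(stats::model.matrix(fit), "assign")
    for (tm in intersect(rownames(dr), labels)) {
      idx <- which(assign == match(tm, labels))
      co$p_value[idx] <- dr[tm, "Pr(>Chi)"]
    }
  }
  if (!converged || separation) co$p_value <- NA_real_
  # report logical/indicator terms under their bare names
  rownames(co) <- sub("TRUE$", "", rownames(co))
  rownames(co) <- gsub("TRUE:", ":", rownames(co), fixed = TRUE)
  structure(list(model_tag = model_tag, coefficients = co,
                 n_snps = nrow(d), snp_subset = subset_tag,
                 near_exon_threshold_bp =
                   if (model_tag %in% c("II", "IV"))
                     near_exon_threshold_bp else NULL,
                 converged = converged, separation = separation,
                 p_type = p_type, fit = fit),
            class = "enrichment_fit")
}

#' @export
print.enrichment_fit <- function(x, ...) {
  cat("Replication-enrichment logistic model ", x$model_tag,
      " (", x$snp_subset, " SNPs, n = ", x$n_snps, ")\n", sep = "")
  if (!is.null(x$near_exon_threshold_bp))
    cat("Near-exon threshold:", x$near_exon_threshold_bp, "bp\n")
  if (!x$converged) cat("WARNING: fit did not converge\n")
  if (x$separation) cat("WARNING: separation detected; P-values withheld\n")
  printCoefmat(as.matrix(x$coefficients), P.values = TRUE,
               has.Pvalue = TRUE)
  invisible(x)
}

#' Serialize an enrichment fit to JSON
#'
#' @param x An `enrichment_fit`.
#' @param path Optional output path; if omitted the JSON string is
#'   returned.
#' @export
write_fit_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "enrichment_fit"))
  obj <- list(model_tag = x$model_tag,
              n_snps = x$n_snps,
              snp_subset = x$snp_subset,
              near_exon_threshold_bp = x$near_exon_threshold_bp,
              converged = x$converged,
              separation = x$separation,
              coefficients = cbind(term = rownames(x$coefficients),
                                   x$coefficients))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Excess replication above a power threshold
#'
#' Counts SNPs at or above a power threshold, how many of them
#' replicate, and how many replications would be expected if the
#' genome-wide average replication rate applied to that stratum; the
#' excess is observed minus expected. Also tabulates replication by
#' power decile.
#'
#' @param records Power-record table from [power_records()].
#' @param power_threshold Power cutoff in (0, 1); SNPs with
#'   `power >= power_threshold` form the high-power stratum.
#' @return Object of class `excess_report`; see [excess_from_counts()]
#'   for the fields, plus `per_decile` (data frame: `decile`, `n`,
#'   `n_replicated`, `rate`).
#' @export
excess_by_power <- function(records, power_threshold = 0.6) {
  stopifnot(power_threshold > 0, power_threshold < 1,
            all(c("power", "replicated") %in% names(records)))
  n_total <- nrow(records)
  overall_rate <- mean(records$replicated)
  high <- records$power >= power_threshold
  rep <- excess_from_counts(n_total = n_total,
                            n_high = sum(high),
                            n_replicated_high = sum(records$replicated[high]),
                            overall_rate = overall_rate)
  rep$power_threshold <- power_threshold
  dec <- if ("power_decile" %in% names(records)) records$power_decile
         else power_decile(records$power)
  tab <- stats::aggregate(cbind(n = rep(1L, n_total),
                                n_replicated = as.integer(records$replicated)),
                          by = list(decile = dec), FUN = sum)
  tab$rate <- tab$n_replicated / tab$n
  rep$per_decile <- tab
  rep
}

#' Excess-replication arithmetic from stratum counts
#'
#' The count-level arithmetic behind [excess_by_power()], usable
#' directly when only published counts are available: with `n_high`
#' SNPs in the high-power stratum and a genome-wide replication rate
#' `overall_rate`, the expected number of replications in the stratum
#' is `n_high * overall_rate` and the excess is the observed count
#' minus that expectation. The fraction `expected / observed` estimates
#' the share of high-power replications that are still false.
#'
#' @param n_total Total number of SNPs.
#' @param n_high SNPs in the high-power stratum.
#' @param n_replicated_high Replicated SNPs within the stratum.
#' @param overall_rate Genome-wide replication rate (fraction).
#' @return Object of class `excess_report`: list with `n_total`,
#'   `n_high`, `n_replicated_high`, `overall_rate`, `expected`,
#'   `excess`, `excess_int` (nearest integer), `high_rate`,
#'   `high_fraction`, `false_fraction`.
#' @export
excess_from_counts <- function(n_total, n_high, n_replicated_high,
                               overall_rate) {
  stopifnot(n_high >= 0, n_high <= n_total,
            n_replicated_high <= n_high,
            overall_rate >= 0, overall_rate <= 1)
  expected <- n_high * overall_rate
  excess <- n_replicated_high - expected
  structure(list(
    n_total = n_total,
    n_high = n_high,
    n_replicated_high = n_replicated_high,
    overall_rate = overall_rate,
    expected = expected,
    excess = excess,
    excess_int = round(excess),
    high_rate = if (n_high > 0) n_replicated_high / n_high else NA_real_,
    high_fraction = n_high / n_total,
    false_fraction = if (n_replicated_high > 0)
      expected / n_replicated_high else NA_real_
  ), class = "excess_report")
}

#' @export
print.excess_report <- function(x, ...) {
  cat(sprintf(
    "High-power stratum: %d of %d SNPs (%.1f%%); %d replicated (%.1f%%)\n",
    x$n_high, x$n_total, 100 * x$high_fraction, x$n_replicated_high,
    100 * x$high_rate))
  cat(sprintf(
    "Expected at the overall rate of %.2f%%: %.1f; excess: %.1f (~%d)\n",
    100 * x$overall_rate, x$expected, x$excess, x$excess_int))
  if (!is.na(x$false_fraction))
    cat(sprintf("Estimated false fraction among stratum hits: %.0f%%\n",
                100 * x$false_fraction))
  invisible(x)
}

#' Permutation control for the power-replication association
#'
#' Permutes the replication labels across SNPs, refits Model I each
#' time, and returns the permuted power-term P-values. Under the
#' permutation null, power carries no information about replication,
#' so the observed Model-I P-value can be compared against this
#' distribution. (When individual-level data are available the
#' analogous control permutes case/control status; at summary level the
#' label permutation preserves the same null.)
#'
#' @param records Power-record table.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed.
#' @return Numeric vector of `n_perm` permuted power-term P-values.
#' @export
permutation_control <- function(records, n_perm = 200, seed = 1) {
  stopifnot(n_perm >= 1)
  set.seed(seed)
  vapply(seq_len(n_perm), function(i) {
    r <- records
    r$replicated <- sample(r$replicated)
    fit <- fit_model(r, "I")
    fit$coefficients["power", "p_value"]
  }, numeric(1))
}

#' Greedy sliding-window LD pruning
#'
#' Thins SNPs to approximate linkage equilibrium: within a sliding
#' window of `window` SNPs, advanced by `step` SNPs, any pair of
#' retained SNPs with squared genotype correlation at or above
#' `r2_max` loses its later member. Deterministic given the column
#' order (SNPs must be ordered by chromosome and position).
#'
#' @param genotypes Numeric matrix, individuals x SNPs, dosages in
#'   `[0, 2]`; columns named by SNP id and position-ordered.
#' @param window Window size in SNPs (>= 2; default 50).
#' @param step Window step in SNPs (default 5).
#' @param r2_max Pruning threshold on r-squared (default 0.5).
#' @return Character vector of retained SNP ids (column names), or
#'   retained column indices if the matrix is unnamed.
#' @export
ld_prune <- function(genotypes, window = 50, step = 5, r2_max = 0.5) {
  stopifnot(is.matrix(genotypes), window >= 2, step >= 1,
            r2_max > 0, r2_max <= 1)
  p <- ncol(genotypes)
  keep <- rep(TRUE, p)
  start <- 1L
  repeat {
    end <- min(start + window - 1L, p)
    idx <- which(keep[start:end]) + start - 1L
    if (length(idx) >= 2) {
      r2 <- suppressWarnings(stats::cor(genotypes[, idx, drop = FALSE]))^2
      r2[is.na(r2)] <- 0
      for (a in seq_len(length(idx) - 1)) {
        if (!keep[idx[a]]) next
        for (b in (a + 1):length(idx)) {
          if (keep[idx[b]] && r2[a, b] >= r2_max) keep[idx[b]] <- FALSE
        }
      }
    }
    if (end == p) break
    start <- start + step
  }
  if (!is.null(colnames(genotypes))) colnames(genotypes)[keep]
  else which(keep)
}

#' Smoothed replication proportion across power
#'
#' Fits a cubic smoothing spline to the 0/1 replication indicator as a
#' function of power and evaluates it on a uniform grid over `[0, 1]`.
#' Descriptive only (the display used alongside the logistic fits);
#' no inference is attached.
#'
#' @param records Power-record table with >= 50 rows.
#' @param grid_n Number of grid points (default 101).
#' @return Data frame with columns `power` (uniform, increasing over
#'   `[0, 1]`) and `proportion` (smoothed replication proportion).
#' @export
spline_summary <- function(records, grid_n = 101) {
  stopifnot(nrow(records) >= 50)
  y <- as.numeric(records$replicated)
  grid <- seq(0, 1, length.out = grid_n)
  if (stats::var(y) == 0) {
    return(data.frame(power = grid, proportion = rep(mean(y), grid_n)))
  }
  sp <- stats::smooth.spline(records$power, y)
  data.frame(power = grid,
             proportion = stats::predict(sp, grid)$y)
}
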