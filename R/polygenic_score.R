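#' Polygenic scores from discovery log odds ratios
#'
#' Scores each individual as the mean, over SNPs whose discovery
#' P-value falls below `threshold`, of `ln(OR) * dosage` (the averaging
#' convention of PLINK's scoring routine; set `method = "sum"` for the
#' unaveraged total). Missing dosages are skipped per individual;
#' individuals with no usable SNPs get `NA`.
#'
#' @param dosages Numeric matrix, individuals x SNPs, entries in
#'   `[0, 2]` or `NA`; columns named by SNP id.
#' @param disc Discovery summary table (needs `snp_id`, `effect` as
#'   odds ratio, `pvalue`).
#' @param threshold Discovery P-value cutoff selecting the SNP subset.
#' @param method `"mean"` (default) or `"sum"`.
#' @return Data frame: `individual_id`, `score`, `n_snps_used`,
#'   `threshold`.
#' @export
compute_scores <- function(dosages, disc, threshold = 1,
                           method = c("mean", "sum")) {
  method <- match.arg(method)
  stopifnot(is.matrix(dosages), !is.null(colnames(dosages)))
  use <- disc$snp_id[disc$pvalue < threshold]
  use <- intersect(use, colnames(dosages))
  if (length(use) == 0)
    stop("no SNPs pass the discovery P-value threshold ", threshold)
  lnor <- log(disc$effect[match(use, disc$snp_id)])
  d <- dosages[, use, drop = FALSE]
  contrib <- sweep(d, 2, lnor, `*`)
  n_used <- rowSums(!is.na(d))
  total <- rowSums(contrib, na.rm = TRUE)
  score <- if (method == "mean") ifelse(n_used > 0, total / n_used, NA)
           else ifelse(n_used > 0, total, NA)
  ids <- rownames(dosages)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(dosages)))
  data.frame(individual_id = ids, score = score,
             n_snps_used = as.integer(n_used), threshold = threshold,
             stringsAsFactors = FALSE)
}

#' Association between polygenic score and case status
#'
#' Logistic regression of case/control status on the score, returning
#' the Wald P-value for the score term and Nagelkerke's pseudo-R2
#' (with Cox-Snell available via `r2_type`).
#'
#' @param scores Data frame from [compute_scores()] (uses `score`).
#' @param phenotype Logical or 0/1 vector of case status, one entry per
#'   row of `scores`.
#' @param r2_type `"nagelkerke"` (default) or `"coxsnell"`.
#' @return List: `p_value`, `pseudo_r2`, `estimate`, `n`, `separation`.
#' @export
score_association <- function(scores, phenotype,
                              r2_type = c("nagelkerke", "coxsnell")) {
  r2_type <- match.arg(r2_type)
  y <- as.integer(phenotype)
  s <- scores$score
  ok <- !is.na(s) & !is.na(y)
  y <- y[ok]; s <- s[ok]
  if (sum(y == 1) < 2 || sum(y == 0) < 2)
    stop("need at least two individuals in each phenotype class")
  if (stats::var(s) == 0) stop("score is constant; association undefined")
  fit <- suppressWarnings(
    stats::glm(y ~ s, family = stats::binomial("logit")))
  n <- length(y)
  # Cox-Snell from the null/fitted deviances; Nagelkerke rescales by
  # the maximum attainable Cox-Snell value
  cs <- 1 - exp((fit$deviance - fit$null.deviance) / n)
  r2 <- if (r2_type == "coxsnell") cs
        else cs / (1 - exp(-fit$null.deviance / n))
  eps <- 1e-8
  separation <- any(fit$fitted.values > 1 - eps) ||
    any(fit$fitted.values < eps) || !fit$converged
  sm <- summary(fit)$coefficients
  list(p_value = if (separation) NA_real_ else sm["s", 4],
       pseudo_r2 = r2,
       estimate = sm["s", 1],
       n = n, separation = separation)
}

#' Pseudo-R2 across a ladder of discovery P-value thresholds
#'
#' Recomputes the score and its association with phenotype at each
#' threshold, progressively admitting more weakly associated SNPs.
#'
#' @inheritParams compute_scores
#' @param phenotype Case status vector.
#' @param thresholds Ascending P-value ladder (default
#'   `c(1e-4, 1e-3, 0.01, 0.1, 0.5, 1)`).
#' @return Data frame: `threshold`, `n_snps`, `p_value`, `pseudo_r2`.
#' @export
score_profile <- function(dosages, disc, phenotype,
                          thresholds = c(1e-4, 1e-3, 0.01, 0.1, 0.5, 1),
                          method = c("mean", "sum")) {
  method <- match.arg(method)
  res <- lapply(thresholds, function(th) {
    sc <- tryCatch(compute_scores(dosages, disc, th, method),
                   error = function(e) NULL)
    if (is.null(sc))
      return(data.frame(threshold = th, n_snps = 0L,
                        p_value = NA_real_, pseudo_r2 = NA_real_))
    a <- score_association(sc, phenotype)
    data.frame(threshold = th, n_snps = max(sc$n_snps_used),
               p_value = a$p_value, pseudo_r2 = a$pseudo_r2)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
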