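#' Power of the case-control allelic test for a given odds ratio
#'
#' Computes the probability that a 1-df allelic (2x2 allele-count)
#' chi-square test at significance level `alpha` rejects the null in a
#' test sample of `n_cases` cases and `n_controls` controls, when the
#' true effect equals a discovery odds ratio at a discovery control
#' minor-allele frequency.
#'
#' The odds ratio and MAF are first rounded to two decimal places; an
#' odds ratio that rounds to 1.00 is treated as a null effect and
#' returns exactly `alpha`. The case allele frequency implied by the
#' odds ratio is
#' \deqn{p_1 = OR \cdot p_0 / (1 + p_0 (OR - 1))}
#' and the noncentrality parameter of the allelic test on 2N alleles is
#' \deqn{\lambda = (p_1 - p_0)^2 / [\bar p (1-\bar p)
#'       (1/(2 n_{cases}) + 1/(2 n_{controls}))]}
#' with \eqn{\bar p} the allele-count-weighted mean frequency. Power is
#' the upper tail of the noncentral chi-square(1, \eqn{\lambda}) beyond
#' the central chi-square critical value.
#'
#' @param or_disc Discovery odds ratio (> 0), per effect-allele copy.
#' @param maf_disc Discovery control frequency of that allele, in
#'   (0, 1); conventionally the minor allele, but the calculation is
#'   invariant to relabelling (`maf -> 1 - maf`, `OR -> 1/OR`).
#' @param n_cases,n_controls Test-sample case and control counts.
#' @param alpha Significance level used to declare replication.
#' @param round_inputs Round OR and MAF to 2 decimals first (default TRUE).
#' @return Power, a value in `[alpha, 1]`. Vectorized over `or_disc` and
#'   `maf_disc`.
#' @examples
#' power_binary(1.30, 0.30, n_cases = 2191, n_controls = 1434)
#' power_binary(1.00, 0.25, n_cases = 2191, n_controls = 1434)  # = alpha
#' @export
power_binary <- function(or_disc, maf_disc, n_cases, n_controls,
                         alpha = 0.05, round_inputs = TRUE) {
  stopifnot(all(or_disc > 0), all(maf_disc > 0), all(maf_disc < 1),
            n_cases >= 1, n_controls >= 1, alpha > 0, alpha < 1)
  if (round_inputs) {
    or_disc <- round(or_disc, 2)
    maf_disc <- round(maf_disc, 2)
  }
  if (any(maf_disc <= 0 | maf_disc >= 1))
    stop("MAF rounds to 0 or 1; inputs must satisfy the MAF > 1% filter")
  p0 <- maf_disc
  p1 <- or_disc * p0 / (1 + p0 * (or_disc - 1))
  m1 <- 2 * n_cases
  m2 <- 2 * n_controls
  pbar <- (m1 * p1 + m2 * p0) / (m1 + m2)
  ncp <- (p1 - p0)^2 / (pbar * (1 - pbar) * (1 / m1 + 1 / m2))
  crit <- stats::qchisq(1 - alpha, df = 1)
  pow <- stats::pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE)
  # exact size at the null: rounding can leave OR == 1 with ncp == 0
  pow[or_disc == 1] <- alpha
  pow
}

#' Power of the single-SNP test for a quantitative trait
#'
#' Power of the 1-df F test of a SNP in a linear regression of a
#' quantitative trait on allele dosage, given a discovery effect size in
#' trait units per effect allele. The SNP variance is taken as
#' \eqn{2p(1-p)} under Hardy-Weinberg equilibrium, the variance
#' explained is \eqn{R^2 = \beta^2 \cdot 2p(1-p) / s^2}, and Cohen's
#' effect size \eqn{f^2 = R^2/(1-R^2)} drives a noncentral
#' F(1, N-2) distribution with noncentrality \eqn{f^2 (u + v + 1)}
#' where u = 1 and v = N - 2.
#'
#' @param beta_disc Discovery effect in trait units per effect allele.
#' @param eaf_disc Effect-allele frequency, in (0, 1).
#' @param n_test Number of individuals in the test sample (> 2).
#' @param sd_trait Trait standard deviation in the same units as
#'   `beta_disc` (default 9.2, the sample-size-weighted SD of height in
#'   centimetres across the discovery cohorts).
#' @param alpha Significance level.
#' @return Power in `[alpha, 1]`. Vectorized over `beta_disc` and
#'   `eaf_disc`.
#' @examples
#' power_quantitative(0.4, 0.25, n_test = 37052)
#' power_quantitative(0, 0.25, n_test = 1000)  # = alpha
#' @export
power_quantitative <- function(beta_disc, eaf_disc, n_test,
                               sd_trait = 9.2, alpha = 0.05) {
  stopifnot(all(eaf_disc > 0), all(eaf_disc < 1), sd_trait > 0,
            alpha > 0, alpha < 1)
  if (n_test <= 2) stop("n_test must exceed 2 (denominator df is N - 2)")
  var_snp <- 2 * eaf_disc * (1 - eaf_disc)
  r2 <- beta_disc^2 * var_snp / sd_trait^2
  if (any(r2 >= 1))
    stop("implied R^2 >= 1: beta_disc inconsistent with sd_trait")
  f2 <- r2 / (1 - r2)
  u <- 1
  v <- n_test - 2
  ncp <- f2 * (u + v + 1)
  crit <- stats::qf(1 - alpha, df1 = u, df2 = v)
  pow <- stats::pf(crit, df1 = u, df2 = v, ncp = ncp, lower.tail = FALSE)
  pow[beta_disc == 0] <- alpha
  pow
}

#' Invert the quantitative power function for the effect size
#'
#' Finds the non-negative effect (trait units per allele) whose
#' analytic power equals `target` at the given design. Used to lay out
#' simulation grids spanning a prescribed power range.
#'
#' @inheritParams power_quantitative
#' @param target Desired power, in (alpha, 1).
#' @return Effect size (>= 0).
#' @export
beta_for_power <- function(target, eaf_disc, n_test, sd_trait = 9.2,
                           alpha = 0.05) {
  stopifnot(target > alpha, target < 1)
  f <- function(b)
    power_quantitative(b, eaf_disc, n_test, sd_trait, alpha) - target
  upper <- sd_trait / sqrt(2 * eaf_disc * (1 - eaf_disc))
  stats::uniroot(f, lower = 0, upper = upper * 0.99, tol = 1e-10)$root
}

#' Drop the SNPs with the lowest sample sizes
#'
#' Removes the fraction of rows with the smallest per-SNP sample size;
#' rows tied with the value at the cut are kept. Used when per-SNP
#' sample sizes vary across a meta-analysis and poorly-covered SNPs
#' would otherwise contribute unstable effect estimates.
#'
#' @param x Data frame with a sample-size column.
#' @param fraction Fraction to drop, in `[0, 1)`; default 0.20.
#' @param n_col Name of the sample-size column (default `"n_total"`).
#' @return The filtered data frame.
#' @export
filter_low_n <- function(x, fraction = 0.20, n_col = "n_total") {
  stopifnot(is.data.frame(x), fraction >= 0, fraction < 1,
            n_col %in% names(x))
  if (fraction == 0 || nrow(x) == 0) return(x)
  n <- x[[n_col]]
  k <- floor(fraction * length(n))
  if (k == 0) return(x)
  # the (k+1)-th smallest survives; ties with it survive too
  v <- sort(n)[k + 1]
  x[n >= v, , drop = FALSE]
}

#' Assign power deciles
#'
#' Bins power values into deciles 0-9 with breaks at 0.1, 0.2, ...;
#' a power of exactly 1 falls in the top bin.
#'
#' @param power Numeric vector in `[0, 1]`.
#' @return Integer vector in 0:9.
#' @export
power_decile <- function(power) {
  stopifnot(all(power >= 0 & power <= 1))
  pmin(floor(power * 10), 9L)
}

#' Build per-SNP power records from a harmonized study pair
#'
#' Computes, for each harmonized SNP, the power to replicate the
#' discovery effect in the test sample, the replication indicator
#' (test P below `alpha_replication`), the direction-agreement flag,
#' and the power decile. This is the table that the enrichment models
#' consume.
#'
#' @param pairs Harmonized pair table from [harmonize()].
#' @param trait_kind `"binary"` or `"quantitative"`.
#' @param alpha_power Alpha used inside the power calculation.
#' @param alpha_replication Alpha used to declare replication.
#' @param sd_trait Trait SD for the quantitative calculator.
#' @param annotation Optional exon annotation from
#'   [nearest_exon_distance()]; its `near_*` indicator columns are
#'   merged in by `snp_id`.
#' @return Data frame with columns `snp_id`, `power`, `replicated`,
#'   `same_direction`, `power_decile`, plus any `near_*` columns.
#' @export
power_records <- function(pairs, trait_kind = c("binary", "quantitative"),
                          alpha_power = 0.05, alpha_replication = 0.05,
                          sd_trait = 9.2, annotation = NULL) {
  trait_kind <- match.arg(trait_kind)
  stopifnot(is.data.frame(pairs), nrow(pairs) > 0)
  if (trait_kind == "binary") {
    # express effect on the minor-allele scale before rounding
    flip <- pairs$eaf_disc > 0.5
    maf <- pmin(pairs$eaf_disc, 1 - pairs$eaf_disc)
    or_minor <- ifelse(flip, 1 / pairs$effect_disc, pairs$effect_disc)
    pow <- power_binary(or_minor, maf,
                        n_cases = pairs$n_cases_test[1],
                        n_controls = pairs$n_controls_test[1],
                        alpha = alpha_power)
  } else {
    pow <- power_quantitative(pairs$effect_disc, pairs$eaf_disc,
                              n_test = pairs$n_total_test[1],
                              sd_trait = sd_trait, alpha = alpha_power)
  }
  out <- data.frame(
    snp_id = pairs$snp_id,
    power = pow,
    replicated = pairs$pvalue_test < alpha_replication,
    same_direction = pairs$same_direction,
    power_decile = power_decile(pow),
    stringsAsFactors = FALSE
  )
  if (!is.null(annotation)) {
    keep <- c("snp_id", grep("^near_", names(annotation), value = TRUE),
              "exon_distance")
    keep <- intersect(keep, names(annotation))
    out <- merge(out, annotation[, keep, drop = FALSE],
                 by = "snp_id", all.x = TRUE, sort = FALSE)
  }
  out
}
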