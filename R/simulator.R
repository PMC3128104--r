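#' Forward simulation of case-control replication for one SNP
#'
#' Simulates a population of `pop_size` individuals with genotypes
#' drawn under Hardy-Weinberg equilibrium at the given minor-allele
#' frequency. An individual's disease risk is
#' `prevalence * or^g` for `g` risk alleles; the individual is affected
#' if that risk exceeds a uniform random draw. The population is fixed,
#' and for each of `n_reps` replicates a fresh case-control sample of
#' the requested size is drawn and a single-SNP logistic regression is
#' fit. The empirical replication rate is the fraction of replicates
#' with P below `alpha`.
#'
#' @param or True per-allele odds ratio (risk-scale multiplier).
#' @param maf Risk-allele frequency in (0, 0.5].
#' @param n_cases,n_controls Sample sizes per replicate.
#' @param prevalence Baseline disease risk (default 0.01). Requires
#'   `prevalence * or^2 < 1` so risk stays a probability.
#' @param pop_size Population size (default 1e5).
#' @param n_reps Number of case-control resamples (default 100).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed.
#' @return Fraction of replicates reaching P < `alpha`.
#' @export
simulate_binary_replication_rate <- function(or, maf, n_cases, n_controls,
                                             prevalence = 0.01,
                                             pop_size = 1e5,
                                             n_reps = 100, alpha = 0.05,
                                             seed = 1) {
  stopifnot(or > 0, maf > 0, maf <= 0.5, prevalence > 0)
  if (prevalence * or^2 >= 1)
    stop("prevalence * or^2 must stay below 1 (risk is a probability)")
  set.seed(seed)
  g <- stats::rbinom(pop_size, 2, maf)
  risk <- prevalence * or^g
  affected <- stats::runif(pop_size) < risk
  idx_case <- which(affected)
  idx_ctrl <- which(!affected)
  if (length(idx_case) < n_cases || length(idx_ctrl) < n_controls)
    stop("population supplied only ", length(idx_case), " affected / ",
         length(idx_ctrl), " unaffected individuals; increase pop_size")
  hits <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    gc_case <- tabulate(g[sample(idx_case, n_cases)] + 1L, nbins = 3)
    gc_ctrl <- tabulate(g[sample(idx_ctrl, n_controls)] + 1L, nbins = 3)
    hits[i] <- logistic_dose_p(gc_case, gc_ctrl) < alpha
  }
  mean(hits)
}

# Wald P for the dosage term of a logistic regression of case status on
# genotype, fit on counts aggregated by genotype class (identical
# likelihood to the individual-level fit).
logistic_dose_p <- function(gc_case, gc_ctrl) {
  present <- (gc_case + gc_ctrl) > 0
  if (sum(present) < 2) return(1)
  d <- data.frame(g = (0:2)[present], case = gc_case[present],
                  ctrl = gc_ctrl[present])
  fit <- suppressWarnings(
    stats::glm(cbind(case, ctrl) ~ g, data = d,
               family = stats::binomial()))
  sm <- summary(fit)$coefficients
  if (!"g" %in% rownames(sm)) return(1)
  sm["g", 4]
}

#' Forward simulation of quantitative-trait replication for one SNP
#'
#' Per replicate, draws `n_test` individuals with HWE genotypes at the
#' given allele frequency; each individual's trait is a standard-normal
#' baseline plus `beta_sd` per copy of the effect allele (effect in
#' trait-SD units). A simple linear regression of trait on dosage is
#' fit and the rejection at level `alpha` recorded.
#'
#' @param beta_sd True effect per allele in units of the baseline SD.
#' @param maf Effect-allele frequency in (0, 1).
#' @param n_test Individuals per replicate (> 10).
#' @param n_reps Number of replicates (default 100).
#' @param alpha Significance level.
#' @param seed Integer seed.
#' @return Fraction of replicates reaching P < `alpha`.
#' @export
simulate_quantitative_replication_rate <- function(beta_sd, maf, n_test,
                                                   n_reps = 100,
                                                   alpha = 0.05,
                                                   seed = 1) {
  stopifnot(maf > 0, maf < 1, n_reps >= 1)
  if (n_test <= 10) stop("n_test must exceed 10")
  set.seed(seed)
  hits <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    g <- stats::rbinom(n_test, 2, maf)
    y <- stats::rnorm(n_test) + beta_sd * g
    if (stats::var(g) == 0) { hits[i] <- FALSE; next }
    # t test of the slope in y ~ g via the sample correlation
    r <- stats::cor(g, y)
    tval <- r * sqrt((n_test - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tval), df = n_test - 2)
    hits[i] <- p < alpha
  }
  mean(hits)
}

#' Generate a synthetic discovery/test summary-statistic study pair
#'
#' Emulates two independent GWAS of the same trait over a shared SNP
#' panel with known ground truth. A fraction of SNPs carry a true
#' effect (log odds ratio, or beta, drawn from a zero-centred normal);
#' each study's observed effect is the truth plus noise from the
#' asymptotic sampling distribution of the single-SNP estimator at
#' that study's sample size, with Wald P-values. SNPs are placed on a
#' single synthetic chromosome carrying randomly located exons;
#' optionally, causal SNPs are preferentially planted near exons.
#'
#' @param n_snps Number of SNPs.
#' @param frac_causal Fraction with a true effect (default 0.3).
#' @param effect_scale SD of the true log odds ratio (binary) or of the
#'   true beta in trait units (quantitative); default 0.08.
#' @param maf_range Range of the uniform MAF spectrum
#'   (default `c(0.05, 0.5)`).
#' @param n_disc,n_test Sample sizes: `c(cases, controls)` for binary,
#'   a single N for quantitative. Defaults `c(1868, 2938)` and
#'   `c(2191, 1434)`, the sizes of a typical discovery and test
#'   case-control pair.
#' @param trait_kind `"binary"` or `"quantitative"`.
#' @param sd_trait Trait SD (quantitative only; default 1).
#' @param exon_frac_near If non-`NULL`, the probability that a causal
#'   SNP is placed within `exon_near_bp` of an exon.
#' @param exon_near_bp Planting distance for near-exon causal SNPs
#'   (default 10000).
#' @param genome_length Synthetic chromosome length (default 1e8).
#' @param n_exons Number of exons (default 2000).
#' @param exon_width Exon width in bp (default 200).
#' @param seed Integer seed; regeneration with the same seed is
#'   byte-identical.
#' @return List of class `sim_study_pair`: `discovery` and `test`
#'   (summary tables in the [read_summary()] schema), `truth`
#'   (`snp_id`, `maf`, `causal`, `true_effect`, `planted_near_exon`),
#'   `exons` (`chrom`, `start`, `end`), `seed`.
#' @export
generate_study_pair <- function(n_snps, frac_causal = 0.3,
                                effect_scale = 0.08,
                                maf_range = c(0.05, 0.5),
                                n_disc = c(1868, 2938),
                                n_test = c(2191, 1434),
                                trait_kind = c("binary", "quantitative"),
                                sd_trait = 1,
                                exon_frac_near = NULL,
                                exon_near_bp = 10000,
                                genome_length = 1e8,
                                n_exons = 2000, exon_width = 200,
                                seed = 1) {
  trait_kind <- match.arg(trait_kind)
  stopifnot(frac_causal >= 0, frac_causal <= 1, n_snps >= 1)
  set.seed(seed)
  snp_id <- sprintf("rs%06d", seq_len(n_snps))
  maf <- stats::runif(n_snps, maf_range[1], maf_range[2])
  causal <- stats::runif(n_snps) < frac_causal
  true_eff <- ifelse(causal, stats::rnorm(n_snps, 0, effect_scale), 0)

  exon_start <- sort(sample.int(genome_length - exon_width, n_exons))
  exons <- data.frame(chrom = "1", start = exon_start,
                      end = exon_start + exon_width - 1L,
                      stringsAsFactors = FALSE)
  pos <- sample.int(genome_length, n_snps, replace = TRUE)
  planted <- rep(FALSE, n_snps)
  if (!is.null(exon_frac_near)) {
    plant <- causal & stats::runif(n_snps) < exon_frac_near
    k <- sum(plant)
    if (k > 0) {
      anchor <- sample.int(n_exons, k, replace = TRUE)
      offset <- sample(-exon_near_bp:exon_near_bp, k, replace = TRUE)
      pos[plant] <- pmin(pmax(exons$start[anchor] + offset, 1L),
                         genome_length)
      planted <- plant
    }
  }

  if (trait_kind == "binary") {
    stopifnot(length(n_disc) == 2, length(n_test) == 2)
    disc <- sample_binary_summary(snp_id, pos, maf, true_eff,
                                  n_disc[1], n_disc[2])
    test <- sample_binary_summary(snp_id, pos, maf, true_eff,
                                  n_test[1], n_test[2])
  } else {
    stopifnot(length(n_disc) == 1, length(n_test) == 1)
    disc <- sample_quant_summary(snp_id, pos, maf, true_eff,
                                 n_disc, sd_trait)
    test <- sample_quant_summary(snp_id, pos, maf, true_eff,
                                 n_test, sd_trait)
  }
  truth <- data.frame(snp_id = snp_id, maf = maf, causal = causal,
                      true_effect = if (trait_kind == "binary")
                        exp(true_eff) else true_eff,
                      planted_near_exon = planted,
                      stringsAsFactors = FALSE)
  structure(list(discovery = disc, test = test, truth = truth,
                 exons = exons, trait_kind = trait_kind, seed = seed),
            class = "sim_study_pair")
}

# observed summary stats for one case-control study from the asymptotic
# sampling distribution of the allelic log-OR estimator
sample_binary_summary <- function(snp_id, pos, p0, lnor_true,
                                  n_cases, n_controls) {
  p1 <- exp(lnor_true) * p0 / (1 + p0 * (exp(lnor_true) - 1))
  se <- sqrt(1 / (2 * n_cases * p1 * (1 - p1)) +
               1 / (2 * n_controls * p0 * (1 - p0)))
  lnor_obs <- lnor_true + stats::rnorm(length(p0), 0, se)
  z <- lnor_obs / se
  eaf_obs <- stats::rbinom(length(p0), 2 * n_controls, p0) /
    (2 * n_controls)
  eaf_obs <- pmin(pmax(eaf_obs, 1 / (4 * n_controls)),
                  1 - 1 / (4 * n_controls))
  data.frame(
    snp_id = snp_id, chrom = "1", pos = pos,
    effect_allele = "A", other_allele = "G",
    effect = exp(lnor_obs), eaf = eaf_obs,
    pvalue = pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin),
    n_cases = n_cases, n_controls = n_controls,
    n_total = n_cases + n_controls,
    stringsAsFactors = FALSE
  )
}

sample_quant_summary <- function(snp_id, pos, eaf, beta_true, n,
                                 sd_trait) {
  var_snp <- 2 * eaf * (1 - eaf)
  se <- sd_trait / sqrt(n * var_snp)
  beta_obs <- beta_true + stats::rnorm(length(eaf), 0, se)
  z <- beta_obs / se
  eaf_obs <- stats::rbinom(length(eaf), 2 * n, eaf) / (2 * n)
  eaf_obs <- pmin(pmax(eaf_obs, 1 / (4 * n)), 1 - 1 / (4 * n))
  data.frame(
    snp_id = snp_id, chrom = "1", pos = pos,
    effect_allele = "A", other_allele = "G",
    effect = beta_obs, eaf = eaf_obs,
    pvalue = pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin),
    n_cases = 0L, n_controls = 0L, n_total = n,
    stringsAsFactors = FALSE
  )
}

#' Write a simulated study pair to disk
#'
#' Emits `discovery.tsv`, `test.tsv` and `truth.tsv` (tab-delimited,
#' readable by [read_summary()]) and `exons.bed` (0-based half-open,
#' readable by [read_exons_bed()]) into a directory.
#'
#' @param pair A `sim_study_pair` from [generate_study_pair()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_study_pair <- function(pair, dir) {
  stopifnot(inherits(pair, "sim_study_pair"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_summary(pair$discovery, file.path(dir, "discovery.tsv"))
  write_summary(pair$test, file.path(dir, "test.tsv"))
  utils::write.table(pair$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  bed <- data.frame(chrom = pair$exons$chrom,
                    start = pair$exons$start - 1L,
                    end = pair$exons$end)
  utils::write.table(bed, file.path(dir, "exons.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(dir)
}

#' Simulate HWE genotype dosages
#'
#' Individuals x SNPs matrix of 0/1/2 dosages, each SNP binomial(2,
#' maf) under Hardy-Weinberg equilibrium, SNPs independent.
#'
#' @param n Number of individuals.
#' @param mafs Vector of allele frequencies, one per SNP.
#' @param seed Integer seed.
#' @return Integer matrix with SNP ids `snp1..snpP` as column names.
#' @export
simulate_genotypes <- function(n, mafs, seed = 1) {
  set.seed(seed)
  g <- vapply(mafs, function(p) stats::rbinom(n, 2, p), integer(n))
  colnames(g) <- paste0("snp", seq_along(mafs))
  g
}

#' Simulate genotypes with block LD structure
#'
#' Generates SNPs in consecutive blocks; within a block, each SNP is a
#' copy of the block's founder SNP with each individual's genotype
#' independently redrawn with probability `1 - rho`, giving pairwise
#' genotype correlation of roughly `rho` within the block and zero
#' between blocks. Exists to exercise LD-aware steps (pruning,
#' clumping); it is not a population-genetic LD model.
#'
#' @param n Individuals.
#' @param n_snps Total SNPs.
#' @param block_size SNPs per block.
#' @param rho Within-block copy fidelity in `[0, 1]`.
#' @param maf Founder allele frequency (default 0.3).
#' @param seed Integer seed.
#' @return Integer matrix, individuals x SNPs.
#' @export
simulate_ld_genotypes <- function(n, n_snps, block_size = 10, rho = 0.9,
                                  maf = 0.3, seed = 1) {
  set.seed(seed)
  g <- matrix(0L, n, n_snps)
  for (b in seq_len(ceiling(n_snps / block_size))) {
    cols <- ((b - 1) * block_size + 1):min(b * block_size, n_snps)
    founder <- stats::rbinom(n, 2, maf)
    for (j in cols) {
      redraw <- stats::runif(n) >= rho
      col <- founder
      col[redraw] <- stats::rbinom(sum(redraw), 2, maf)
      g[, j] <- col
    }
  }
  colnames(g) <- paste0("snp", seq_len(n_snps))
  g
}
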