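# Independent Monte-Carlo oracle for the allelic-test power: draws case
# and control allele counts from binomials and applies the Pearson
# chi-square test to the 2x2 allele table (vectorized). Shares no code
# with power_binary's noncentral-chi-square path.
mc_power_allelic <- function(or, maf, n_cases, n_controls,
                             alpha = 0.05, B = 4000, seed = 1) {
  set.seed(seed)
  p0 <- maf
  p1 <- or * p0 / (1 + p0 * (or - 1))
  m1 <- 2 * n_cases
  m2 <- 2 * n_controls
  a <- rbinom(B, m1, p1)   # effect alleles in cases
  c_ <- rbinom(B, m2, p0)  # effect alleles in controls
  b <- m1 - a
  d <- m2 - c_
  n <- m1 + m2
  chi2 <- n * (a * d - b * c_)^2 /
    ((a + b) * (c_ + d) * (a + c_) * (b + d))
  mean(chi2 > qchisq(1 - alpha, df = 1))
}

# Brute-force nearest-exon distance: all-pairs scan.
brute_nearest_distance <- function(snps, exons, window_bp = 1e6) {
  vapply(seq_len(nrow(snps)), function(i) {
    e <- exons[exons$chrom == snps$chrom[i], , drop = FALSE]
    if (nrow(e) == 0) return(NA_real_)
    p <- snps$pos[i]
    d <- ifelse(p < e$start, e$start - p,
                ifelse(p > e$end, p - e$end, 0))
    dm <- min(d)
    if (dm > window_bp) NA_real_ else dm
  }, numeric(1))
}

# Small harmonizable summary-table builder for reader/harmonizer tests.
make_summary <- function(snp_id, effect, eaf, pvalue = 0.5,
                         ea = "A", oa = "G", pos = seq_along(snp_id),
                         n_cases = 100L, n_controls = 100L) {
  data.frame(snp_id = snp_id, chrom = "1", pos = as.integer(pos),
             effect_allele = rep_len(ea, length(snp_id)),
             other_allele = rep_len(oa, length(snp_id)),
             effect = effect, eaf = eaf,
             pvalue = rep_len(pvalue, length(snp_id)),
             n_cases = n_cases, n_controls = n_controls,
             n_total = n_cases + n_controls,
             stringsAsFactors = FALSE)
}

# Records table for enrichment tests without the simulator: power drawn
# uniformly, replication Bernoulli with logistic link on power.
make_records <- function(n, b0 = -3, b1 = 0, seed = 1) {
  set.seed(seed)
  pow <- runif(n)
  pr <- plogis(b0 + b1 * pow)
  data.frame(snp_id = paste0("rs", seq_len(n)),
             power = pow,
             replicated = runif(n) < pr,
             same_direction = runif(n) < 0.5,
             power_decile = powerrep::power_decile(pow),
             stringsAsFactors = FALSE)
}

# End-to-end records from a simulated pair (harmonize -> annotate ->
# power), used by enrichment and acceptance tests.
sim_records <- function(n_snps = 20000, frac_causal = 0.3,
                        exon_frac_near = NULL, seed = 1,
                        thresholds = c(2000, 10000, 25000)) {
  pair <- generate_study_pair(n_snps, frac_causal = frac_causal,
                              exon_frac_near = exon_frac_near,
                              seed = seed)
  pairs <- harmonize(pair$discovery, pair$test)
  pairs <- apply_maf_filter(pairs, 0.01)
  ann <- nearest_exon_distance(pairs, pair$exons,
                               thresholds = thresholds)
  power_records(pairs, "binary", annotation = ann)
}
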