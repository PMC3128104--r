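test_that("forward simulators are deterministic given the seed", {
  r1 <- simulate_binary_replication_rate(1.3, 0.3, 300, 300,
                                         pop_size = 2e5, n_reps = 20,
                                         seed = 5)
  r2 <- simulate_binary_replication_rate(1.3, 0.3, 300, 300,
                                         pop_size = 2e5, n_reps = 20,
                                         seed = 5)
  expect_identical(r1, r2)
  q1 <- simulate_quantitative_replication_rate(0.1, 0.3, 500,
                                               n_reps = 20, seed = 5)
  q2 <- simulate_quantitative_replication_rate(0.1, 0.3, 500,
                                               n_reps = 20, seed = 5)
  expect_identical(q1, q2)
})

test_that("null effects reject at about the test size", {
  r <- simulate_binary_replication_rate(1, 0.3, 500, 500,
                                        pop_size = 2e5, n_reps = 200,
                                        seed = 17)
  expect_lt(abs(r - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
  q <- simulate_quantitative_replication_rate(0, 0.3, 1000,
                                              n_reps = 200, seed = 18)
  expect_lt(abs(q - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("an undersized population is refused with advice", {
  expect_error(
    simulate_binary_replication_rate(1.3, 0.3, 2191, 1434,
                                     pop_size = 1e5, seed = 1),
    "pop_size")
  expect_error(
    simulate_binary_replication_rate(15, 0.3, 10, 10,
                                     prevalence = 0.01),
    "probability")
})

test_that("binary forward simulation agrees with the analytic power", {
  # case/control draws kept small relative to the affected pool so the
  # fixed-population replicates are close to independent
  pts <- data.frame(or = c(1.25, 1.15), maf = c(0.3, 0.4))
  for (i in seq_len(nrow(pts))) {
    analytic <- power_binary(pts$or[i], pts$maf[i], 500, 500)
    reps <- 150
    emp <- simulate_binary_replication_rate(
      pts$or[i], pts$maf[i], 500, 500, pop_size = 1e6,
      n_reps = reps, seed = 600 + i)
    se <- sqrt(analytic * (1 - analytic) / reps)
    expect_lt(abs(emp - analytic), 3.5 * se,
              label = sprintf("point %d (|%.3f - %.3f|)", i, emp,
                              analytic))
  }
})

test_that("genotype frequencies satisfy Hardy-Weinberg expectations", {
  g <- simulate_genotypes(50000, c(0.1, 0.3, 0.5), seed = 9)
  for (j in 1:3) {
    p <- c(0.1, 0.3, 0.5)[j]
    expected <- 50000 * c((1 - p)^2, 2 * p * (1 - p), p^2)
    observed <- tabulate(g[, j] + 1L, nbins = 3)
    chi2 <- sum((observed - expected)^2 / expected)
    expect_gt(pchisq(chi2, df = 2, lower.tail = FALSE), 0.001)
  }
})

test_that("a null study pair has uniform test P-values", {
  ks <- sapply(1:5, function(s) {
    pair <- generate_study_pair(3000, frac_causal = 0, seed = 700 + s)
    suppressWarnings(ks.test(pair$test$pvalue, "punif"))$p.value
  })
  expect_gt(min(p.adjust(ks, "bonferroni")), 0.01)
})

test_that("same seed regenerates a byte-identical study pair", {
  p1 <- generate_study_pair(500, seed = 123)
  p2 <- generate_study_pair(500, seed = 123)
  expect_identical(serialize(p1, NULL), serialize(p2, NULL))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_study_pair(p1, d1)
  write_study_pair(p2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("generated tables round-trip through the package readers", {
  pair <- generate_study_pair(300, seed = 44)
  d <- withr::local_tempdir()
  write_study_pair(pair, d)
  disc <- read_summary(file.path(d, "discovery.tsv"), "binary")
  attr(disc, "n_dropped") <- NULL
  expect_equal(disc, pair$discovery, tolerance = 1e-12)
  ex <- read_exons_bed(file.path(d, "exons.bed"))
  expect_equal(ex$start, pair$exons$start)
  expect_equal(ex$end, pair$exons$end)
})

test_that("the asymptotic sampler is calibrated against analytic power", {
  # condition on the truth: among SNPs whose true effect gives high
  # analytic power, the test study replicates at about the mean power
  pair <- generate_study_pair(30000, seed = 55)
  pow <- power_binary(pair$truth$true_effect, pair$truth$maf,
                      2191, 1434, round_inputs = FALSE)
  rep_ <- pair$test$pvalue < 0.05
  for (cut in c(0.5, 0.8)) {
    sel <- pow > cut
    expect_gt(sum(sel), 50)
    se <- sqrt(sum(pow[sel] * (1 - pow[sel]))) / sum(sel)
    expect_lt(abs(mean(rep_[sel]) - mean(pow[sel])), 3 * se + 0.01,
              label = sprintf("bin > %.1f", cut))
  }
})

test_that("causal SNPs are planted near exons when requested", {
  pair <- generate_study_pair(5000, exon_frac_near = 1, seed = 66)
  ann <- nearest_exon_distance(
    data.frame(snp_id = pair$truth$snp_id, chrom = "1",
               pos = pair$discovery$pos),
    pair$exons, thresholds = 10000)
  near <- ann$near_10000
  expect_true(all(near[pair$truth$planted_near_exon]))
  frac_causal_near <- mean(near[pair$truth$causal])
  frac_null_near <- mean(near[!pair$truth$causal])
  expect_gt(frac_causal_near, frac_null_near + 0.3)
})
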