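test_that("null effects give power exactly equal to the test size", {
  expect_identical(power_binary(1.00, 0.30, 2191, 1434), 0.05)
  # OR that rounds to 1.00 is a null effect under the rounding rule
  expect_identical(power_binary(1.004, 0.30, 2191, 1434), 0.05)
  expect_identical(power_quantitative(0, 0.25, 1000), 0.05)
  expect_identical(power_binary(1.00, 0.2, 500, 500, alpha = 0.01), 0.01)
})

test_that("binary power matches the binomial allele-count Monte-Carlo oracle", {
  grid <- data.frame(or = c(1.30, 1.15, 1.10, 1.45, 1.20, 1.08),
                     maf = c(0.30, 0.20, 0.45, 0.10, 0.35, 0.25))
  B <- 4000
  for (i in seq_len(nrow(grid))) {
    analytic <- power_binary(grid$or[i], grid$maf[i], 2191, 1434)
    emp <- mc_power_allelic(grid$or[i], grid$maf[i], 2191, 1434,
                            B = B, seed = 100 + i)
    se <- sqrt(analytic * (1 - analytic) / B)
    expect_lt(abs(emp - analytic), 3 * se + 1e-12,
              label = sprintf("point %d (|%.4f - %.4f|)", i, emp,
                              analytic))
  }
})

test_that("quantitative power matches the forward-simulation oracle", {
  n <- 2000
  grid <- data.frame(beta = c(0.045, 0.06, 0.08),
                     maf = c(0.30, 0.20, 0.40))
  reps <- 400
  for (i in seq_len(nrow(grid))) {
    analytic <- power_quantitative(grid$beta[i], grid$maf[i], n,
                                   sd_trait = 1)
    emp <- simulate_quantitative_replication_rate(
      grid$beta[i], grid$maf[i], n, n_reps = reps, seed = 200 + i)
    se <- sqrt(analytic * (1 - analytic) / reps)
    expect_lt(abs(emp - analytic), 3 * se,
              label = sprintf("point %d (|%.3f - %.3f|)", i, emp,
                              analytic))
  }
})

test_that("power is monotone in sample size and effect magnitude", {
  ns <- seq(500, 5000, length.out = 10)
  pb <- sapply(ns, function(n) power_binary(1.2, 0.3, n, n))
  expect_true(all(diff(pb) > 0))
  ors <- seq(1.05, 1.6, length.out = 10)
  pb2 <- sapply(ors, function(o) power_binary(o, 0.3, 1000, 1000))
  expect_true(all(diff(pb2) > 0))
  betas <- seq(0.01, 0.2, length.out = 10)
  pq <- power_quantitative(betas, 0.3, 2000, sd_trait = 1)
  expect_true(all(diff(pq) > 0))
  pq2 <- sapply(c(500, 1000, 4000), function(n)
    power_quantitative(0.05, 0.3, n, sd_trait = 1))
  expect_true(all(diff(pq2) > 0))
})

test_that("binary power is invariant to relabelling the minor allele", {
  # p -> 1 - p with OR -> 1/OR describes the same SNP
  p <- power_binary(1.23, 0.37, 1500, 1200, round_inputs = FALSE)
  q <- power_binary(1 / 1.23, 1 - 0.37, 1500, 1200,
                    round_inputs = FALSE)
  expect_equal(p, q, tolerance = 1e-12)
})

test_that("degenerate power inputs are rejected", {
  expect_error(power_binary(1.2, 0.001, 100, 100), "MAF")
  expect_error(power_quantitative(0.1, 0.3, n_test = 2), "n_test")
  expect_error(power_quantitative(50, 0.5, 100, sd_trait = 1), "R\\^2")
})

test_that("beta_for_power inverts the quantitative power function", {
  for (target in c(0.2, 0.5, 0.9)) {
    b <- beta_for_power(target, 0.3, 2000, sd_trait = 1)
    expect_equal(power_quantitative(b, 0.3, 2000, sd_trait = 1),
                 target, tolerance = 1e-6)
  }
})

test_that("filter_low_n drops the lowest-n fraction and keeps ties", {
  x <- data.frame(snp_id = letters[1:10], n_total = 1:10)
  out <- filter_low_n(x, 0.2)
  expect_setequal(out$n_total, 3:10)
  expect_identical(filter_low_n(x, 0), x)
  tied <- data.frame(snp_id = letters[1:5], n_total = rep(7L, 5))
  expect_identical(nrow(filter_low_n(tied, 0.2)), 5L)
})

test_that("power deciles bin [0,0.1),... with 1.0 in the top bin", {
  expect_identical(power_decile(c(0, 0.05, 0.1, 0.55, 0.9, 0.999, 1)),
                   c(0, 0, 1, 5, 9, 9, 9))
})

test_that("power_records assembles power, replication and direction", {
  pair <- generate_study_pair(500, seed = 42)
  pairs <- harmonize(pair$discovery, pair$test)
  rec <- power_records(pairs, "binary")
  expect_identical(nrow(rec), nrow(pairs))
  expect_true(all(rec$power >= 0.05 - 1e-9 & rec$power <= 1))
  expect_identical(rec$replicated, pairs$pvalue_test < 0.05)
  # effect-allele frequency above 0.5 must flip to the minor scale
  pairs2 <- pairs[1:10, ]
  pairs2$eaf_disc <- 1 - pairs2$eaf_disc
  pairs2$effect_disc <- 1 / pairs2$effect_disc
  rec2 <- power_records(pairs2, "binary")
  expect_equal(rec2$power, rec$power[1:10], tolerance = 1e-9)
})
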