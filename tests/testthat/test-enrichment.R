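test_that("fit_model terms match each model definition", {
  rec <- make_records(2000, b0 = -2.5, b1 = 2, seed = 5)
  rec$near_2000 <- runif(2000) < 0.15
  terms <- function(f) rownames(f$coefficients)
  expect_setequal(terms(fit_model(rec, "I")),
                  c("(Intercept)", "power"))
  f2 <- fit_model(rec, "II", near_exon_threshold_bp = 2000)
  expect_setequal(terms(f2),
                  c("(Intercept)", "power", "near_exon",
                    "power:near_exon"))
  f3 <- fit_model(rec, "III")
  expect_identical(f3$snp_subset, "same_direction")
  expect_lt(f3$n_snps, nrow(rec))
  expect_setequal(terms(fit_model(rec, "M1")),
                  c("(Intercept)", "same_direction"))
  expect_setequal(terms(fit_model(rec, "M2")),
                  c("(Intercept)", "power", "same_direction",
                    "power:same_direction"))
})

test_that("degenerate inputs to fit_model error or flag", {
  rec <- make_records(100, seed = 1)
  rec$replicated <- TRUE
  expect_error(fit_model(rec, "I"), "constant")
  rec2 <- make_records(100, seed = 1)
  expect_error(fit_model(rec2, "II"), "near_exon_threshold_bp")
  rec2$same_direction <- NA
  expect_error(fit_model(rec2, "III"), "same_direction")
})

test_that("Wald and LRT P-values broadly agree on a strong signal", {
  rec <- make_records(5000, b0 = -3, b1 = 3, seed = 8)
  pw <- fit_model(rec, "I")$coefficients["power", "p_value"]
  pl <- fit_model(rec, "I", p_type = "lrt")$coefficients["power",
                                                         "p_value"]
  expect_lt(pw, 0.01)
  expect_lt(pl, 0.01)
  expect_equal(log10(pw), log10(pl), tolerance = 0.5)
})

test_that("excess counting matches brute force on random records", {
  for (seed in 1:5) {
    rec <- make_records(3000, b0 = -2.5, b1 = 1.5, seed = seed)
    rep_ <- excess_by_power(rec, 0.6)
    high <- rec$power >= 0.6
    expect_identical(rep_$n_high, sum(high))
    expect_identical(rep_$n_replicated_high, sum(rec$replicated[high]))
    expect_equal(rep_$expected, sum(high) * mean(rec$replicated))
    expect_equal(rep_$excess,
                 sum(rec$replicated[high]) -
                   sum(high) * mean(rec$replicated))
    expect_identical(sum(rep_$per_decile$n), nrow(rec))
    expect_identical(sum(rep_$per_decile$n_replicated),
                     sum(rec$replicated))
  }
})

test_that("excess is zero when the stratum rate equals the overall rate", {
  # every record above threshold: expected = observed exactly
  rec <- make_records(500, b0 = 0, b1 = 0, seed = 2)
  rec$power <- runif(500, 0.7, 1)
  rep_ <- excess_by_power(rec, 0.05)
  expect_identical(rep_$n_high, 500L)
  expect_equal(rep_$excess, 0)
})

test_that("enriched synthetic data yield a positive, significant power term", {
  rec <- sim_records(20000, seed = 77)
  f <- fit_model(rec, "I")
  expect_gt(f$coefficients["power", "estimate"], 0)
  expect_lt(f$coefficients["power", "p_value"], 0.01)
})

test_that("the same-direction subset sharpens the power association", {
  # mirrors the ordering of the Model III vs Model I P-values in the
  # weak-to-moderate signal regime; the direction filter removes half
  # the null SNPs while keeping nearly all true signal
  wins <- 0
  for (s in 1:10) {
    pair <- generate_study_pair(30000, effect_scale = 0.04,
                                seed = 500 + s)
    rec <- power_records(harmonize(pair$discovery, pair$test),
                         "binary")
    p1 <- fit_model(rec, "I")$coefficients["power", "p_value"]
    p3 <- fit_model(rec, "III")$coefficients["power", "p_value"]
    wins <- wins + (p3 <= p1)
  }
  expect_gt(wins, 5)
})

test_that("permutation is reproducible and destroys the association", {
  rec <- sim_records(10000, seed = 31)
  p1 <- permutation_control(rec, n_perm = 1, seed = 9)
  p2 <- permutation_control(rec, n_perm = 1, seed = 9)
  expect_identical(p1, p2)
  perm <- permutation_control(rec, n_perm = 40, seed = 10)
  observed <- fit_model(rec, "I")$coefficients["power", "p_value"]
  expect_lt(observed, min(perm))
})

test_that("ld_prune keeps the earlier SNP of a correlated pair", {
  set.seed(4)
  g1 <- rbinom(200, 2, 0.3)
  geno <- cbind(snpA = g1, snpB = g1, snpC = rbinom(200, 2, 0.3))
  kept <- ld_prune(geno, window = 3, step = 1, r2_max = 0.5)
  expect_identical(kept, c("snpA", "snpC"))
  expect_error(ld_prune(geno, window = 1), "window")
})

test_that("independent SNPs survive pruning; retained pairs are below r2", {
  geno <- simulate_genotypes(500, rep(0.3, 30), seed = 6)
  expect_identical(ld_prune(geno), colnames(geno))
  blocky <- simulate_ld_genotypes(400, 200, block_size = 10,
                                  rho = 0.95, seed = 8)
  kept <- ld_prune(blocky, window = 50, step = 5, r2_max = 0.5)
  expect_lt(length(kept), 200)
  # brute-force: every retained within-window pair is below threshold
  ki <- match(kept, colnames(blocky))
  for (a in seq_along(ki)) {
    for (b in seq_along(ki)) {
      if (b <= a || ki[b] - ki[a] >= 50) next
      r2 <- suppressWarnings(
        cor(blocky[, ki[a]], blocky[, ki[b]]))^2
      expect_lt(r2, 0.5)
    }
  }
})

test_that("spline summary is flat for constant input and spans [0,1]", {
  rec <- make_records(200, seed = 3)
  rec$replicated <- rep(c(TRUE, FALSE), 100)[order(runif(200))] & FALSE
  rec$replicated <- FALSE
  s <- spline_summary(rec)
  expect_true(all(s$proportion == 0))
  expect_identical(range(s$power), c(0, 1))
  expect_true(all(diff(s$power) > 0))
})

test_that("fits serialize to JSON and print without error", {
  rec <- make_records(1000, b0 = -2, b1 = 1, seed = 12)
  f <- fit_model(rec, "I")
  js <- write_fit_json(f)
  parsed <- jsonlite::fromJSON(js)
  expect_identical(parsed$model_tag, "I")
  expect_identical(parsed$n_snps, f$n_snps)
  expect_output(print(f), "Model I|model I|logistic model I")
})
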