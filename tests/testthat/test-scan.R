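flat_profile <- function(mean = 0.2) {
  tibble::tibble(
    chrom = "1", population = "p", bin = 1:20,
    bin_start = (0:19) * 5000L, bin_end = (1:20) * 5000L,
    mean_r2_adj = mean, n_pairs = 100L
  )
}

pairs_for <- function(i, distances, r2_adj) {
  tibble::tibble(
    chrom = "1", idx_a = i, idx_b = i + seq_along(distances),
    pos_a = 0L, pos_b = as.integer(distances), distance = as.integer(distances),
    r2 = r2_adj, r2_adj = r2_adj
  )
}

test_that("SNP deviation test handles direction, thresholds and degeneracy", {
  prof <- flat_profile(0.2)
  d15 <- seq(2000, 90000, length.out = 15)

  # all deviations exactly +0.2 with zero variance -> above, p = 0
  t1 <- snp_test(1L, pairs_for(1L, d15, rep(0.4, 15)), prof)
  expect_equal(t1$direction, "above")
  expect_equal(t1$p_value, 0)
  expect_equal(t1$n_neighbors, 15L)

  # 14 neighbours -> untestable regardless of signal
  t2 <- snp_test(1L, pairs_for(1L, d15[-1], rep(0.4, 14)), prof)
  expect_equal(t2$direction, "untestable")
  expect_equal(t2$reason, "too_few_neighbors")

  # all-zero deviations -> mixed (zero is on neither side), p = 1
  t3 <- snp_test(1L, pairs_for(1L, d15, rep(0.2, 15)), prof)
  expect_equal(t3$direction, "mixed")
  expect_equal(t3$p_value, 1)

  # empty expected bin -> untestable with reason
  gappy <- flat_profile(0.2)
  gappy$mean_r2_adj[1] <- NA
  gappy$n_pairs[1] <- 0L
  t4 <- snp_test(1L, pairs_for(1L, c(3000, d15[-1]), rep(0.1, 15)), gappy)
  expect_equal(t4$reason, "empty_expected_bin")

  # below direction with strictly negative deviations
  t5 <- snp_test(1L, pairs_for(1L, d15, rep(0.1, 15) - seq(0, 0.05, length.out = 15)), prof)
  expect_equal(t5$direction, "below")
  expect_lt(t5$p_value, 1e-6)
})

test_that("t statistic and p-value match the textbook one-sample computation", {
  set.seed(71)
  prof <- flat_profile(0.2)
  d <- stats::rnorm(20, mean = 0.1, sd = 0.05)
  dist20 <- seq(2000, 95000, length.out = 20)
  res <- snp_test(1L, pairs_for(1L, dist20, 0.2 + d), prof)
  t_ref <- mean(d) / (stats::sd(d) / sqrt(20))
  expect_equal(res$t_stat, t_ref, tolerance = 1e-10)
  expect_equal(res$p_value, 2 * stats::pt(-abs(t_ref), 19), tolerance = 1e-10)
  expect_equal(res$p_value, stats::t.test(d)$p.value, tolerance = 1e-10)
})

test_that("BH mask reproduces the step-up rule and its hand-worked case", {
  # thresholds 0.0125, 0.025, 0.0375, 0.05 -> k = 2
  mask <- bh_adjust(c(0.01, 0.02, 0.04, 0.2), alpha = 0.05)
  expect_equal(mask, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(bh_adjust(rep(1, 5)), rep(FALSE, 5))
  expect_equal(bh_adjust(0.04, alpha = 0.05), TRUE)

  # oracle equivalence on 1000 random vectors, and monotonicity
  set.seed(81)
  for (k in 1:1000) {
    m <- sample(1:500, 1)
    p <- switch(sample(3, 1),
      stats::runif(m),
      stats::rbeta(m, 0.3, 4), # enriched small p
      round(stats::runif(m), 2) # heavy ties
    )
    mask <- bh_adjust(p, alpha = 0.05)
    expect_identical(mask, oracle_bh(p, alpha = 0.05))
    if (any(mask)) {
      expect_true(all(mask[p <= max(p[mask])]))
    }
  }
})

test_that("SV calling collects maximal uniform-direction runs with span rule", {
  mk_tests <- function(pos, dir, sig) {
    tibble::tibble(
      snp_index = seq_along(pos), chrom = "1", pos = as.integer(pos),
      direction = dir, bh_significant = sig,
      n_neighbors = 20L
    )
  }
  # 5 consecutive significant "above" SNPs
  t1 <- mk_tests(seq(1000, 2600, by = 400), rep("above", 5), rep(TRUE, 5))
  sv <- call_svs(t1, "popA")
  expect_equal(nrow(sv), 1L)
  expect_equal(sv$start, 1000L)
  expect_equal(sv$end, 2600L)
  expect_equal(sv$size_bp, 1600L)
  expect_equal(sv$n_snps, 5L)
  expect_equal(sv$direction, "above")
  expect_equal(sv$snp_pos[[1]], seq(1000L, 2600L, by = 400L))

  # 3 significant SNPs spanning only 800 bp -> span rule rejects
  t2 <- mk_tests(c(1000, 1400, 1800), rep("above", 3), rep(TRUE, 3))
  expect_equal(nrow(call_svs(t2)), 0L)

  # A-A-B-B-B: direction flip terminates the run; only the below run called
  t3 <- mk_tests(seq(1000, 5800, by = 1200),
    c("above", "above", "below", "below", "below"), rep(TRUE, 5)
  )
  sv3 <- call_svs(t3)
  expect_equal(nrow(sv3), 1L)
  expect_equal(sv3$direction, "below")
  expect_equal(sv3$n_snps, 3L)

  # a non-significant SNP in the middle splits a run
  t4 <- mk_tests(seq(1000, 8200, by = 1200), rep("above", 7),
    c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  )
  sv4 <- call_svs(t4)
  expect_equal(nrow(sv4), 2L)
  expect_equal(sv4$n_snps, c(3L, 3L))
})

test_that("scan output equals the naive transcription of the definition", {
  # random dense panels of <= 100 SNPs; min_neighbors left at 15, which
  # at 2 kb spacing leaves room for real calls
  for (k in 1:12) {
    planted <- if (k %% 3 == 0) {
      list(planted_segment("1", 20001L, 140000L,
        kind = if (k %% 2) "high_ld" else "low_ld", strength = 0.95
      ))
    } else {
      list()
    }
    sim <- simulate_panel(sim_config(
      n_animals = 40, n_snps = sample(60:100, 1), mean_spacing_bp = 2000,
      n_founders = 4, recomb_rate_per_bp = 7.5e-6, maf_floor = 0.15,
      seed = 7000 + k, planted = planted
    ))
    panel <- apply_qc(sim$panel)$filtered
    scan <- scan_population(panel)
    naive <- oracle_naive_scan(panel)
    got <- as.data.frame(tidy(scan)[c("chrom", "start", "end", "n_snps", "direction")])
    expect_equal(got, naive, ignore_attr = TRUE, info = paste("panel", k))
    if (nrow(scan$svs) > 0) {
      expect_true(validate_svs(scan$svs, scan$tests))
    }
  }
})

test_that("scan is deterministic and skips undersized chromosomes with a warning", {
  sim <- simulate_panel(small_scan_config(seed = 91, n_snps = 300))
  panel <- apply_qc(sim$panel)$filtered
  s1 <- scan_population(panel)
  s2 <- scan_population(panel)
  expect_identical(tidy(s1), tidy(s2))
  expect_identical(s1$tests, s2$tests)

  tiny <- make_panel(c("0101", "1010", "1100", "0011"), pos = c(1e3, 2e3, 3e3, 4e3))
  expect_warning(scan_population(tiny), "skipped")
})

test_that("the post-hoc validator rejects rule violations", {
  tests <- tibble::tibble(
    snp_index = 1:5, chrom = "1", pos = seq(1000L, 5000L, by = 1000L),
    direction = rep("above", 5), bh_significant = rep(TRUE, 5),
    n_neighbors = rep(20L, 5)
  )
  sv <- call_svs(tests, "p")
  expect_true(validate_svs(sv, tests))

  bad <- sv
  bad$direction <- "below"
  expect_error(validate_svs(bad, tests), "direction")

  tests2 <- tests
  tests2$n_neighbors[2] <- 10L
  expect_error(validate_svs(sv, tests2), "neighbors")

  tests3 <- tests
  tests3$bh_significant[3] <- FALSE
  expect_error(validate_svs(sv, tests3), "significant")
})
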