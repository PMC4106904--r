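test_that("population summary statistics follow Table-style arithmetic", {
  svs <- tibble::tibble(
    population = "A", chrom = "1",
    start = c(1000L, 5000L), end = c(2000L, 8000L),
    size_bp = c(1000L, 3000L), n_snps = c(3L, 5L)
  )
  st <- population_stats(svs)
  expect_equal(st$n_svs, 2L)
  expect_equal(st$total_size_mb, 0.004)
  expect_equal(st$mean_size_kb, 2.0)
  expect_equal(st$mean_snps_per_sv, 4.0)
  expect_equal(st$max_snps_per_sv, 5L)
  expect_equal(st$n_snps_in_svs, 8L)

  one <- population_stats(svs[1, ])
  expect_equal(one$min_size_kb, one$max_size_kb)
  expect_equal(one$min_size_kb, one$mean_size_kb)

  shuffled <- population_stats(svs[2:1, ])
  expect_equal(shuffled, st)

  expect_equal(nrow(population_stats(svs[0, ])), 0L)
  expect_equal(empty_population_stats("Z")$n_svs, 0L)
})

test_that("per-chromosome SV density is count over Mb", {
  svs <- tibble::tibble(
    population = "A",
    chrom = c("1", "1", "1", "1", "2"),
    start = 1:5 * 1000L, end = 1:5 * 1000L + 500L,
    size_bp = 500L, n_snps = 3L
  )
  sizes <- tibble::tibble(chrom = c("1", "2", "3"), length_bp = c(1e7, 2e7, 5e6))
  dens <- sv_per_mb(svs, sizes)
  expect_equal(dens$svs_per_mb[dens$chrom == "1"], 0.4)
  expect_equal(dens$svs_per_mb[dens$chrom == "2"], 0.05)
  expect_equal(dens$svs_per_mb[dens$chrom == "3"], 0)
  expect_error(sv_per_mb(dplyr::mutate(svs, chrom = "9"), sizes), "absent")
})

test_that("MAF spectrum is a proper histogram over [0, 0.5]", {
  mono <- tibble::tibble(n_AA = rep(50L, 10), n_Aa = 0L, n_aa = 0L)
  sp <- maf_spectrum(mono)
  expect_equal(sp$proportion[1], 1)
  expect_equal(sum(sp$proportion), 1)
  expect_equal(maf_spectrum(mono, include_monomorphic = FALSE)$n_snps, rep(0L, 10))

  # uniform MAFs fill bins roughly evenly
  set.seed(131)
  n <- 500L
  maf <- stats::runif(1e4, 0, 0.5)
  counts <- tibble::tibble(
    n_AA = round(n * maf^2), n_Aa = round(n * 2 * maf * (1 - maf))
  )
  counts$n_aa <- n - counts$n_AA - counts$n_Aa
  sp2 <- maf_spectrum(counts)
  expect_equal(sum(sp2$proportion), 1)
  gof <- stats::chisq.test(sp2$n_snps)
  expect_gt(gof$p.value, 0.01)
})

test_that("PCA satisfies trace, orthonormality and reconstruction identities", {
  set.seed(141)
  for (k in 1:5) {
    x <- matrix(stats::rpois(19 * 29, 30), nrow = 19)
    rownames(x) <- paste0("pop", 1:19)
    pca <- sv_pca(x)
    xc <- sweep(x, 2, colMeans(x))
    # trace conservation: eigenvalues sum to total variance
    expect_equal(sum(pca$eigenvalues), sum(diag(stats::cov(xc))), tolerance = 1e-10)
    expect_true(all(diff(pca$eigenvalues) <= 1e-10))
    # loadings orthonormal
    gram <- crossprod(pca$loadings)
    expect_equal(gram, diag(ncol(pca$loadings)), tolerance = 1e-10, ignore_attr = TRUE)
    # full reconstruction of the centred matrix
    expect_equal(pca$scores %*% t(pca$loadings), xc, tolerance = 1e-10, ignore_attr = TRUE)
    # score covariance diagonal with eigenvalues
    expect_equal(diag(stats::cov(pca$scores)), pca$eigenvalues[seq_len(ncol(pca$scores))],
      tolerance = 1e-10, ignore_attr = TRUE
    )
    # cross-check variances against prcomp
    pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    expect_equal(pca$eigenvalues, (pr$sdev^2)[seq_along(pca$eigenvalues)], tolerance = 1e-10)
  }
})

test_that("PCA separates duplicated clusters on PC1 and is sign-stable", {
  base <- matrix(stats::rpois(29, 20), nrow = 1)
  x <- rbind(
    base[rep(1, 5), ] + 0L,
    base[rep(1, 5), ] + 40L
  )
  rownames(x) <- paste0("p", 1:10)
  pca <- sv_pca(x)
  s1 <- pca$scores[, 1]
  expect_true(all(s1[1:5] * s1[6:10] < 0)) # two sides of PC1
  expect_lt(pca$eigenvalues[2], 1e-8)

  # sign convention: identical results across repeated runs
  expect_identical(sv_pca(x), sv_pca(x))
  # largest-|loading| element positive in every component
  for (j in seq_len(ncol(pca$loadings))) {
    expect_gt(pca$loadings[which.max(abs(pca$loadings[, j])), j], 0)
  }

  # constant matrix: all-zero eigenvalues, defined result
  cst <- matrix(5, nrow = 4, ncol = 6)
  p0 <- sv_pca(cst)
  expect_equal(p0$eigenvalues, rep(0, length(p0$eigenvalues)))
})

test_that("SV count matrix rows sum to population SV counts", {
  svs <- tibble::tibble(
    population = c("A", "A", "B", "A"),
    chrom = c("1", "2", "1", "1")
  )
  m <- sv_count_matrix(svs)
  expect_equal(rownames(m), c("A", "B"))
  expect_equal(m["A", "1"], 2L)
  expect_equal(rowSums(m), c(A = 3, B = 1))
  m2 <- sv_count_matrix(svs, chromosomes = c("1", "2", "3"))
  expect_equal(m2[, "3"], c(A = 0, B = 0))
})

test_that("tidiers return tibbles keyed by population and component", {
  set.seed(151)
  x <- matrix(stats::rpois(5 * 8, 10), nrow = 5, dimnames = list(paste0("p", 1:5), NULL))
  pca <- sv_pca(x)
  td <- tidy(pca)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$population, paste0("p", 1:5))
  gl <- glance(pca)
  expect_equal(sum(gl$prop_variance), 1, tolerance = 1e-12)
  expect_equal(gl$cum_variance[nrow(gl)], 1, tolerance = 1e-12)
})
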