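test_that("overlapping SVs merge across populations, boundary rule inclusive", {
  svs <- tibble::tibble(
    population = c("A", "B"), chrom = "1",
    start = c(100L, 150L), end = c(200L, 300L),
    snp_pos = list(c(100L, 150L, 200L), c(150L, 250L, 300L))
  )
  reg <- merge_regions(svs)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$start, 100L)
  expect_equal(reg$end, 300L)
  expect_equal(reg$populations[[1]], c("A", "B"))
  expect_equal(reg$n_populations, 2L)
  expect_equal(reg$n_snps, 5L) # union: 150 shared

  # adjacent but not sharing a base -> two regions
  svs2 <- tibble::tibble(
    population = "A", chrom = "1",
    start = c(100L, 201L), end = c(200L, 300L),
    snp_pos = list(100L, 300L)
  )
  expect_equal(nrow(merge_regions(svs2)), 2L)

  # transitive single linkage: A-B overlap, B-C overlap, A-C do not
  svs3 <- tibble::tibble(
    population = c("A", "B", "C"), chrom = "1",
    start = c(100L, 180L, 260L), end = c(200L, 280L, 350L),
    snp_pos = list(100L, 200L, 300L)
  )
  reg3 <- merge_regions(svs3)
  expect_equal(nrow(reg3), 1L)
  expect_equal(reg3$n_populations, 3L)
})

test_that("merging matches a union-find oracle on random fixtures", {
  set.seed(101)
  for (k in 1:200) {
    iv <- random_intervals(sample(2:50, 1))
    got <- merge_regions(iv)
    want <- oracle_merge(as.data.frame(iv))
    expect_equal(as.data.frame(got[c("chrom", "start", "end")]),
      want[c("chrom", "start", "end")],
      ignore_attr = TRUE
    )
    # disjoint, sorted, and no more regions than inputs
    expect_lte(nrow(got), nrow(iv))
    by_chr <- split(got, got$chrom)
    for (g in by_chr) {
      if (nrow(g) > 1) expect_true(all(g$start[-1] > g$end[-nrow(g)]))
    }
    # covered bases conserved: union of SV bases == union of region bases
    cover <- function(df) {
      sum(vapply(split(df, df$chrom), function(d) {
        length(unique(unlist(Map(seq, d$start, d$end))))
      }, numeric(1)))
    }
    expect_equal(cover(as.data.frame(got)), cover(as.data.frame(iv)))
  }
})

test_that("merging cross-checks against IRanges reduce", {
  skip_if_not_installed("IRanges")
  set.seed(102)
  for (k in 1:20) {
    iv <- random_intervals(sample(2:60, 1), chroms = "1")
    got <- merge_regions(iv)
    # min.gapwidth = 0: merge only intervals sharing >= 1 bp, not abutting ones
    red <- IRanges::reduce(
      IRanges::IRanges(start = iv$start, end = iv$end),
      min.gapwidth = 0L
    )
    expect_equal(got$start, IRanges::start(red))
    expect_equal(got$end, IRanges::end(red))
  }
})

test_that("external-interval overlap counting matches the quadratic oracle", {
  regions <- tibble::tibble(chrom = "1", start = 100L, end = 300L)
  external <- tibble::tibble(
    chrom = "1", start = c(250L, 500L), end = c(400L, 600L),
    label = c("x", "y")
  )
  st <- overlap_count(regions, external)
  expect_equal(st$n_overlapping, 1L)
  expect_equal(st$fraction, 0.5)

  st0 <- overlap_count(regions, external[0, ])
  expect_equal(st0, tibble::tibble(n_query = 0L, n_overlapping = 0L, fraction = 0))

  set.seed(111)
  for (k in 1:200) {
    reg <- random_intervals(sample(1:30, 1))[c("chrom", "start", "end")]
    ext <- random_intervals(sample(1:30, 1))[c("chrom", "start", "end")]
    ext$label <- paste0("e", seq_len(nrow(ext)))
    got <- overlap_count(reg, ext)
    expect_equal(got$n_overlapping, oracle_overlap(reg, ext))
    expect_equal(got$fraction, got$n_overlapping / nrow(ext))
  }
})

test_that("gene annotation assigns by >= 1 bp overlap, genes reusable", {
  regions <- tibble::tibble(chrom = "1", start = c(100L, 600L), end = c(300L, 800L))
  genes <- tibble::tibble(
    chrom = "1", start = c(249L, 300L, 650L), end = c(500L, 400L, 5000L),
    label = c("G1", "G2", "G3")
  )
  ann <- annotate_genes(regions, genes)
  expect_equal(ann$genes[[1]], c("G1")) # G2 starts at base 301 (half-open), misses 100-300
  expect_equal(ann$genes[[2]], c("G3"))

  # quadratic-oracle equivalence on random fixtures
  set.seed(121)
  for (k in 1:30) {
    reg <- random_intervals(10)[c("chrom", "start", "end")]
    gn <- random_intervals(30)[c("chrom", "start", "end")]
    gn$label <- paste0("g", seq_len(nrow(gn)))
    ann <- annotate_genes(reg, gn)
    for (r in seq_len(nrow(reg))) {
      hits <- gn$label[
        gn$chrom == reg$chrom[r] & gn$start + 1L <= reg$end[r] & gn$end >= reg$start[r]
      ]
      expect_equal(ann$genes[[r]], sort(hits))
    }
  }
})

test_that("population-consistency histogram tallies regions", {
  regions <- tibble::tibble(n_populations = c(1L, 1L, 3L, 2L, 1L))
  tab <- region_consistency_table(regions)
  expect_equal(tab$n_regions[tab$n_populations == 1], 3L)
  expect_equal(tab$n_regions[tab$n_populations == 3], 1L)
  set.seed(122)
  np <- sample(1:5, 40, replace = TRUE)
  tab2 <- region_consistency_table(tibble::tibble(n_populations = np))
  expect_equal(sum(tab2$n_regions), 40L)
  for (v in unique(np)) {
    expect_equal(tab2$n_regions[tab2$n_populations == v], sum(np == v))
  }
})
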