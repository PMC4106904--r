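#' Minor allele frequency from genotype counts
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (vectorized); `AA` and `aa` are
#'   the two homozygote classes — the result is invariant under swapping
#'   them.
#' @return MAF in `[0, 0.5]`: `min(p, 1 - p)` with
#'   `p = (2 n_AA + n_Aa) / (2 (n_AA + n_Aa + n_aa))`.
#' @examples
#' compute_maf(90, 9, 1) # (2*1 + 9) / 200 counted from the rare side
#' @export
compute_maf <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (any(n < 1L)) abort("MAF undefined: all genotypes missing for some marker")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  pmin(p, 1 - p)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact conditional test: given the observed allele counts, the
#' p-value is the total probability of all heterozygote counts whose
#' conditional probability (under random union of gametes) is less than or
#' equal to that of the observed configuration.
#'
#' @inheritParams compute_maf
#' @return P-values in `(0, 1]`, vectorized over markers. Monomorphic
#'   markers have a single attainable configuration and return 1.
#' @details The exact test is preferred over the chi-square approximation
#'   because array data routinely contain markers with rare genotype
#'   classes where the asymptotic test misbehaves. A relative tolerance of
#'   1e-9 guards the `<=` comparison against floating-point ties between
#'   configurations of equal probability.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0L)) abort("negative genotype counts")
  mapply(hwe_exact_one, n_AA, n_Aa, n_aa)
}

hwe_exact_one <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (n < 1L) abort("HWE test undefined: no called genotypes")
  n_minor <- min(2L * n_AA + n_Aa, 2L * n_aa + n_Aa)
  if (n_minor == 0L) return(1.0)
  # attainable heterozygote counts share the parity of the minor-allele count
  h <- seq.int(n_minor %% 2L, n_minor, by = 2L)
  hom_minor <- (n_minor - h) %/% 2L
  hom_major <- n - hom_minor - h
  keep <- hom_major >= 0L
  h <- h[keep]; hom_minor <- hom_minor[keep]; hom_major <- hom_major[keep]
  lp <- lfactorial(n) - lfactorial(hom_minor) - lfactorial(h) - lfactorial(hom_major) +
    h * log(2) + lfactorial(n_minor) + lfactorial(2L * n - n_minor) - lfactorial(2L * n)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  p_obs <- pr[h == n_Aa]
  min(1.0, sum(pr[pr <= p_obs * (1 + 1e-9)]))
}

genotype_counts_from_panel <- function(panel) {
  al <- panel$alleles
  odd <- seq(1L, nrow(al), by = 2L)
  g <- al[odd, , drop = FALSE] + al[odd + 1L, , drop = FALSE]
  tibble::tibble(
    id = panel$map$id, chrom = panel$map$chrom, pos = panel$map$pos,
    n_AA = colSums(g == 2L), n_Aa = colSums(g == 1L), n_aa = colSums(g == 0L),
    n_missing = 0L
  )
}

#' Marker quality control: missing rate, HWE, MAF
#'
#' Applies the three marker filters in fixed order — call rate, exact
#' Hardy-Weinberg test, minor allele frequency — removing a marker at the
#' first filter it fails (so each removal is attributed to exactly one
#' filter). Retained markers keep their original order. Filtering is per
#' population: never pool populations before testing HWE.
#'
#' @param x A [haplotype_panel()], or a per-marker tibble with columns
#'   `n_AA`, `n_Aa`, `n_aa`, `n_missing` (and any identifier columns,
#'   which are carried through).
#' @param max_missing Maximum tolerated missing-call proportion
#'   (default 0.10). Phased panels have no missing calls, so this filter
#'   only acts on genotype-count input.
#' @param hwe_alpha Significance level below which a marker is removed as
#'   violating HWE (default 1e-3).
#' @param maf_min Minimum minor allele frequency (default 0.05, a
#'   proportion, so monomorphic markers are always removed when
#'   `maf_min > 0`).
#' @return A list with elements:
#'   * `filtered` — the retained markers: a `haplotype_panel` when `x` was
#'     a panel, otherwise the retained rows of the input tibble;
#'   * `markers` — per-input-marker tibble with `maf`, `missing_rate`,
#'     `hwe_p` and `status` (`"retained"` or the removing filter);
#'   * `report` — one-row tibble: `n_input`, `n_removed_missing`,
#'     `n_removed_hwe`, `n_removed_maf`, `n_retained`,
#'     `retained_fraction`.
#' @examples
#' sim <- simulate_panel(sim_config(n_animals = 30, n_snps = 50, seed = 1))
#' qc <- apply_qc(sim$panel)
#' qc$report
#' @export
apply_qc <- function(x, max_missing = 0.10, hwe_alpha = 1e-3, maf_min = 0.05) {
  stopifnot(
    max_missing >= 0, max_missing <= 1,
    hwe_alpha >= 0, hwe_alpha <= 1,
    maf_min >= 0, maf_min <= 1
  )
  is_panel <- inherits(x, "haplotype_panel")
  counts <- if (is_panel) genotype_counts_from_panel(x) else tibble::as_tibble(x)
  stopifnot(all(c("n_AA", "n_Aa", "n_aa") %in% names(counts)))
  if (!"n_missing" %in% names(counts)) counts$n_missing <- 0L

  n_called <- counts$n_AA + counts$n_Aa + counts$n_aa
  missing_rate <- counts$n_missing / pmax(1L, n_called + counts$n_missing)
  fail_missing <- missing_rate > max_missing | n_called == 0L

  hwe_p <- rep(NA_real_, nrow(counts))
  testable <- !fail_missing
  hwe_p[testable] <- hwe_exact_test(
    counts$n_AA[testable], counts$n_Aa[testable], counts$n_aa[testable]
  )
  fail_hwe <- !fail_missing & hwe_p < hwe_alpha

  maf <- rep(NA_real_, nrow(counts))
  maf[n_called > 0L] <- compute_maf(
    counts$n_AA[n_called > 0L], counts$n_Aa[n_called > 0L], counts$n_aa[n_called > 0L]
  )
  fail_maf <- !fail_missing & !fail_hwe & maf < maf_min

  status <- dplyr::case_when(
    fail_missing ~ "removed_missing",
    fail_hwe ~ "removed_hwe",
    fail_maf ~ "removed_maf",
    .default = "retained"
  )
  keep <- status == "retained"
  if (!any(keep)) warn("QC removed every marker")

  markers <- dplyr::bind_cols(
    counts,
    tibble::tibble(missing_rate = missing_rate, hwe_p = hwe_p, maf = maf, status = status)
  )
  report <- tibble::tibble(
    n_input = nrow(counts),
    n_removed_missing = sum(fail_missing),
    n_removed_hwe = sum(fail_hwe),
    n_removed_maf = sum(fail_maf),
    n_retained = sum(keep),
    retained_fraction = sum(keep) / max(1L, nrow(counts))
  )
  filtered <- if (is_panel) subset_snps(x, keep) else counts[keep, , drop = FALSE]
  list(filtered = filtered, markers = markers, report = report)
}
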