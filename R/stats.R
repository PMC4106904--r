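#' Per-population summary statistics of SV calls
#'
#' The standard summary row per population: number of SVs, total size in
#' Mb, mean/max/min size in kb, SNPs involved, and SNPs per SV.
#'
#' @param svs SV tibble (one or more populations; the output has one row
#'   per population present).
#' @return Tibble with columns `population`, `n_svs`, `total_size_mb`,
#'   `mean_size_kb`, `max_size_kb`, `min_size_kb`, `n_snps_in_svs`,
#'   `mean_snps_per_sv`, `max_snps_per_sv`. An empty input gives a
#'   zero-row tibble; use [empty_population_stats()] for an explicit
#'   all-zero row.
#' @export
population_stats <- function(svs) {
  if (nrow(svs) == 0L) {
    return(empty_population_stats()[0L, ])
  }
  svs |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(
      n_svs = dplyr::n(),
      total_size_mb = sum(.data$size_bp) / 1e6,
      mean_size_kb = mean(.data$size_bp) / 1e3,
      max_size_kb = max(.data$size_bp) / 1e3,
      min_size_kb = min(.data$size_bp) / 1e3,
      n_snps_in_svs = sum(.data$n_snps),
      mean_snps_per_sv = mean(.data$n_snps),
      max_snps_per_sv = max(.data$n_snps),
      .groups = "drop"
    )
}

#' @param population Label for the zero row.
#' @rdname population_stats
#' @export
empty_population_stats <- function(population = "pop") {
  tibble::tibble(
    population = population, n_svs = 0L, total_size_mb = 0,
    mean_size_kb = 0, max_size_kb = 0, min_size_kb = 0,
    n_snps_in_svs = 0L, mean_snps_per_sv = 0, max_snps_per_sv = 0L
  )
}

#' Structural-variant density per chromosome
#'
#' @param svs SV tibble.
#' @param chrom_sizes Tibble from [read_chrom_sizes()]; must cover every
#'   chromosome carrying an SV.
#' @return Tibble per chromosome in `chrom_sizes`: `chrom`, `n_svs`,
#'   `length_mb`, `svs_per_mb` (0 for chromosomes without SVs).
#' @export
sv_per_mb <- function(svs, chrom_sizes) {
  missing_ch <- setdiff(unique(svs$chrom), chrom_sizes$chrom)
  if (length(missing_ch) > 0L) {
    abort(sprintf(
      "SVs on chromosome(s) absent from sizes file: %s",
      paste(missing_ch, collapse = ", ")
    ))
  }
  chrom_sizes |>
    dplyr::left_join(dplyr::count(svs, .data$chrom, name = "n_svs"), by = "chrom") |>
    dplyr::mutate(
      n_svs = dplyr::coalesce(.data$n_svs, 0L),
      length_mb = .data$length_bp / 1e6,
      svs_per_mb = .data$n_svs / .data$length_mb
    ) |>
    dplyr::select("chrom", "n_svs", "length_mb", "svs_per_mb")
}

#' Minor-allele-frequency spectrum
#'
#' Histogram of per-marker MAF over `[0, 0.5]`, as proportions of
#' markers. Monomorphic markers (MAF 0) sit in the first bin and can be
#' excluded.
#'
#' @param x A [haplotype_panel()] or a genotype-count tibble with
#'   `n_AA`, `n_Aa`, `n_aa` columns.
#' @param bin_width MAF bin width (default 0.05).
#' @param include_monomorphic Keep MAF-0 markers (default TRUE)?
#' @return Tibble `bin_start`, `bin_end`, `n_snps`, `proportion`
#'   (proportions sum to 1 over the included markers). Bins are
#'   `[bin_start, bin_end)` except the last, which is closed at 0.5.
#' @export
maf_spectrum <- function(x, bin_width = 0.05, include_monomorphic = TRUE) {
  counts <- if (inherits(x, "haplotype_panel")) genotype_counts_from_panel(x) else tibble::as_tibble(x)
  maf <- compute_maf(counts$n_AA, counts$n_Aa, counts$n_aa)
  if (!include_monomorphic) maf <- maf[maf > 0]
  n_bins <- ceiling(0.5 / bin_width)
  bin <- pmin(floor(maf / bin_width) + 1L, n_bins)
  tb <- tabulate(bin, nbins = n_bins)
  tibble::tibble(
    bin_start = (seq_len(n_bins) - 1) * bin_width,
    bin_end = pmin(seq_len(n_bins) * bin_width, 0.5),
    n_snps = tb,
    proportion = if (sum(tb) > 0L) tb / sum(tb) else rep(0, n_bins)
  )
}

#' Plot a MAF spectrum
#'
#' @param spectrum Tibble from [maf_spectrum()].
#' @return A ggplot bar chart of the proportion of SNPs per MAF bin.
#' @export
plot_maf_spectrum <- function(spectrum) {
  spectrum |>
    ggplot2::ggplot(ggplot2::aes(
      x = (.data$bin_start + .data$bin_end) / 2, y = .data$proportion
    )) +
    ggplot2::geom_col(width = 0.9 * (spectrum$bin_end - spectrum$bin_start)) +
    ggplot2::labs(x = "minor allele frequency", y = "proportion of SNPs") +
    ggplot2::theme_minimal()
}

#' Per-chromosome SV count matrix
#'
#' One row per population, one column per chromosome, entries the number
#' of SVs — the input for the PCA of population relatedness.
#'
#' @param svs SV tibble across populations.
#' @param chromosomes Optional chromosome order (default: sorted unique
#'   chromosomes present).
#' @return Integer matrix with population row names and chromosome column
#'   names.
#' @export
sv_count_matrix <- function(svs, chromosomes = NULL) {
  if (is.null(chromosomes)) chromosomes <- sort(unique(svs$chrom))
  pops <- sort(unique(svs$population))
  m <- matrix(0L, nrow = length(pops), ncol = length(chromosomes),
    dimnames = list(pops, chromosomes)
  )
  tb <- dplyr::count(svs, .data$population, .data$chrom)
  m[cbind(tb$population, tb$chrom)] <- tb$n
  m
}
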