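#' Distance bin of a SNP pair
#'
#' Bins are half-open on the left and closed on the right:
#' bin b covers `((b-1) * bin_width, b * bin_width]`, so every distance in
#' `1..window` maps to exactly one of `window / bin_width` bins and the
#' window bound itself is included.
#'
#' @param distance Pair distance(s) in bp, `0 < distance <= window`.
#' @param bin_width Bin width in bp (default 5000).
#' @param window Window size in bp (default 100000).
#' @return Integer bin index in `1..(window / bin_width)`.
#' @export
bin_index <- function(distance, bin_width = 5000L, window = 100000L) {
  if (any(distance <= 0L | distance > window)) {
    abort(sprintf("distance out of range (0, %d]", as.integer(window)))
  }
  as.integer(ceiling(distance / bin_width))
}

#' Expected-LD profile of one chromosome
#'
#' The scan's baseline: mean corrected r-squared per distance bin,
#' computed from all window pairs of one chromosome in one population.
#' Deviations of individual SNPs are later judged against these "expected
#' means". Empty bins are explicit (`mean_r2_adj = NA`, `n_pairs = 0`),
#' never a silent zero: a SNP whose neighbour pair falls in an empty bin
#' is untestable.
#'
#' @param pairs LD-pair tibble from [pairwise_ld_window()], restricted to
#'   a single chromosome.
#' @param population Population label carried into the output.
#' @inheritParams bin_index
#' @return Tibble with one row per bin: `chrom`, `population`, `bin`,
#'   `bin_start`, `bin_end` (bp, half-open left), `mean_r2_adj`,
#'   `n_pairs`. `sum(n_pairs)` equals `nrow(pairs)`.
#' @export
expected_profile <- function(pairs, population = "pop", bin_width = 5000L, window = 100000L) {
  if (nrow(pairs) == 0L) abort("cannot build an expected-LD profile from zero pairs")
  chroms <- unique(pairs$chrom)
  if (length(chroms) != 1L) {
    abort("expected_profile takes pairs from a single chromosome; split first")
  }
  n_bins <- as.integer(window / bin_width)
  b <- bin_index(pairs$distance, bin_width, window)
  means <- tapply(pairs$r2_adj, factor(b, levels = seq_len(n_bins)), mean)
  counts <- tabulate(b, nbins = n_bins)
  tibble::tibble(
    chrom = chroms, population = population,
    bin = seq_len(n_bins),
    bin_start = (seq_len(n_bins) - 1L) * as.integer(bin_width),
    bin_end = seq_len(n_bins) * as.integer(bin_width),
    mean_r2_adj = as.numeric(means),
    n_pairs = counts
  )
}

#' Genome-wide LD-decay table
#'
#' Pools per-chromosome expected-LD profiles into one decay curve per
#' population. Two weightings are available because genome-wide averaging
#' can either pool all pairs (each pair counts once) or average
#' chromosome means (each chromosome counts once).
#'
#' @param profiles One or more [expected_profile()] tibbles row-bound
#'   together (may span chromosomes and populations).
#' @param weighting `"pair"` (pool pairs, i.e. count-weighted mean of bin
#'   means) or `"chromosome"` (unweighted mean over chromosomes with data
#'   in that bin).
#' @return Tibble: `population`, `bin`, `bin_start`, `bin_end`,
#'   `mean_r2_adj`, `n_pairs` (total pairs in the bin).
#' @export
ld_decay_table <- function(profiles, weighting = c("pair", "chromosome")) {
  weighting <- match.arg(weighting)
  stopifnot(nrow(profiles) >= 1L)
  profiles |>
    dplyr::group_by(.data$population, .data$bin, .data$bin_start, .data$bin_end) |>
    dplyr::summarise(
      mean_r2_adj = if (sum(.data$n_pairs) == 0L) {
        NA_real_
      } else if (weighting == "pair") {
        sum(.data$mean_r2_adj * .data$n_pairs, na.rm = TRUE) / sum(.data$n_pairs)
      } else {
        mean(.data$mean_r2_adj[.data$n_pairs > 0L])
      },
      n_pairs = sum(.data$n_pairs),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$population, .data$bin)
}

#' Plot LD decay curves
#'
#' @param decay A tibble from [ld_decay_table()] (or a single-chromosome
#'   [expected_profile()]).
#' @return A ggplot: mean corrected r-squared against bin midpoint in kb,
#'   one line per population.
#' @export
plot_ld_decay <- function(decay) {
  decay |>
    dplyr::filter(.data$n_pairs > 0L) |>
    ggplot2::ggplot(ggplot2::aes(
      x = (.data$bin_start + .data$bin_end) / 2000,
      y = .data$mean_r2_adj, colour = .data$population
    )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "pair distance (kb)", y = expression(mean ~ adjusted ~ r^2),
      colour = "population"
    ) +
    ggplot2::theme_minimal()
}
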