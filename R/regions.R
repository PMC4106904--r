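#' Merge structural variants into cross-population regions
#'
#' Single-linkage merge of SV intervals (1-based inclusive coordinates)
#' that share at least one base pair: overlap is transitive, so chains of
#' pairwise-overlapping SVs collapse into one region — the unique minimal
#' disjoint cover of the calls. Regions record the union of member
#' populations and of member SNP positions.
#'
#' @param svs SV tibble across one or more populations (see
#'   [scan_population()]); needs columns `population`, `chrom`, `start`,
#'   `end` and list-column `snp_pos`.
#' @return Tibble of disjoint regions sorted by chromosome and start:
#'   `chrom`, `start`, `end`, `size_bp`, `n_snps` (distinct member SNP
#'   positions), `n_populations`, plus list-columns `populations` and
#'   `directions` (distinct member directions, when present in the
#'   input).
#' @examples
#' svs <- tibble::tibble(
#'   population = c("A", "B"), chrom = "1",
#'   start = c(100L, 150L), end = c(200L, 300L),
#'   snp_pos = list(c(100L, 160L, 200L), c(150L, 220L, 300L))
#' )
#' merge_regions(svs) # one region 100-300 shared by A and B
#' @export
merge_regions <- function(svs) {
  if (nrow(svs) == 0L) {
    return(tibble::tibble(
      chrom = character(), start = integer(), end = integer(),
      size_bp = integer(), n_snps = integer(), n_populations = integer(),
      populations = list(), directions = list()
    ))
  }
  if (!"snp_pos" %in% names(svs)) svs$snp_pos <- list(integer())
  svs |>
    dplyr::arrange(.data$chrom, .data$start, .data$end) |>
    dplyr::group_by(.data$chrom) |>
    # a new cluster opens when an SV starts beyond every base seen so far
    dplyr::mutate(cluster = cumsum(
      .data$start > dplyr::lag(cummax(as.numeric(.data$end)), default = -Inf)
    )) |>
    dplyr::group_by(.data$chrom, .data$cluster) |>
    dplyr::summarise(
      start = min(.data$start),
      end = max(.data$end),
      size_bp = max(.data$end) - min(.data$start),
      n_snps = length(unique(unlist(.data$snp_pos))),
      populations = list(sort(unique(.data$population))),
      directions = list(
        if ("direction" %in% names(svs)) sort(unique(.data$direction)) else character()
      ),
      .groups = "drop"
    ) |>
    dplyr::mutate(n_populations = lengths(.data$populations)) |>
    dplyr::select(
      "chrom", "start", "end", "size_bp", "n_snps",
      "n_populations", "populations", "directions"
    ) |>
    dplyr::arrange(.data$chrom, .data$start)
}

# regions use 1-based inclusive [start, end]; interval sets are BED-style
# 0-based half-open, i.e. their bases are start+1 .. end
overlaps_any_region <- function(regions, chrom, start0, end0) {
  r <- regions[regions$chrom == chrom, , drop = FALSE]
  if (nrow(r) == 0L) return(FALSE)
  any(start0 + 1L <= r$end & end0 >= r$start)
}

#' Count external intervals overlapping the called regions
#'
#' For comparisons against externally reported variant sets (for example
#' CNV region lists): an external interval counts as overlapping when it
#' shares at least one base pair with any region. Both inputs must be on
#' the same assembly; no liftover is attempted.
#'
#' @param regions Region tibble from [merge_regions()] (1-based
#'   inclusive).
#' @param external Interval tibble from [read_intervals_bed()] (0-based
#'   half-open).
#' @return One-row tibble: `n_query` (external intervals),
#'   `n_overlapping`, `fraction` (0 when the external set is empty).
#' @export
overlap_count <- function(regions, external) {
  n_query <- nrow(external)
  if (n_query == 0L) {
    return(tibble::tibble(n_query = 0L, n_overlapping = 0L, fraction = 0))
  }
  hit <- purrr::pmap_lgl(
    external[c("chrom", "start", "end")],
    function(chrom, start, end) overlaps_any_region(regions, chrom, start, end)
  )
  tibble::tibble(
    n_query = n_query, n_overlapping = sum(hit), fraction = sum(hit) / n_query
  )
}

#' Annotate regions with overlapping gene intervals
#'
#' @param regions Region tibble from [merge_regions()].
#' @param genes Labelled interval tibble (0-based half-open, see
#'   [read_intervals_bed()]).
#' @return `regions` with list-column `genes` (labels of genes sharing at
#'   least one bp; a gene may annotate several regions) and `n_genes`.
#' @export
annotate_genes <- function(regions, genes) {
  regions$genes <- purrr::pmap(
    regions[c("chrom", "start", "end")],
    function(chrom, start, end) {
      g <- genes[genes$chrom == chrom, , drop = FALSE]
      sort(g$label[g$start + 1L <= end & g$end >= start])
    }
  )
  regions$n_genes <- lengths(regions$genes)
  regions
}

#' Cross-population consistency of regions
#'
#' @param regions Region tibble from [merge_regions()].
#' @return Tibble `n_populations` / `n_regions`: how many regions are
#'   shared by exactly that many populations.
#' @export
region_consistency_table <- function(regions) {
  regions |>
    dplyr::count(.data$n_populations, name = "n_regions") |>
    dplyr::arrange(dplyr::desc(.data$n_populations))
}

#' Write merged regions as TSV
#'
#' Columns: chromosome, start, end, size in bp, number of SNPs, number of
#' populations, comma-separated population labels.
#'
#' @param regions Region tibble from [merge_regions()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_regions_tsv <- function(regions, path) {
  regions |>
    dplyr::mutate(
      populations = purrr::map_chr(.data$populations, paste, collapse = ","),
      directions = NULL,
      genes = NULL
    ) |>
    readr::write_tsv(path)
  invisible(path)
}
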