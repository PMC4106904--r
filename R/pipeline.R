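#' Run the full LD structural-variation pipeline
#'
#' Orchestrates QC, windowed LD, expected-LD profiles, the deviation scan,
#' cross-population region merging, summary statistics and (with two or
#' more populations) PCA of per-chromosome SV counts, writing each stage's
#' table to a run directory. Reruns with identical inputs and settings
#' are byte-identical: every stage is deterministic.
#'
#' @param panels A [haplotype_panel()] or list of panels (one per
#'   population; population labels must be distinct).
#' @param out_dir Run directory, created if needed.
#' @param chrom_sizes Optional tibble from [read_chrom_sizes()]; when
#'   given, per-chromosome SV densities are written too.
#' @param maf_min,hwe_alpha,max_missing QC thresholds, see [apply_qc()].
#' @inheritParams scan_population
#' @return Invisibly, a list with the per-population `scans`, the merged
#'   `regions`, `stats`, optional `pca`, and `files` (paths written:
#'   qc_report.tsv, decay.tsv, svs.bed, svs.tsv, regions.tsv, stats.tsv,
#'   pca_scores.tsv when applicable, manifest.tsv).
#' @export
run_pipeline <- function(panels, out_dir, chrom_sizes = NULL,
                         maf_min = 0.05, hwe_alpha = 1e-3, max_missing = 0.10,
                         window = 100000L, bin_width = 5000L,
                         min_neighbors = 15L, min_snps = 3L, min_span = 1000L,
                         alpha = 0.05, bh_scope = "chromosome",
                         correction = "subtract_inv_n") {
  if (inherits(panels, "haplotype_panel")) panels <- list(panels)
  stopifnot(length(panels) >= 1L, all(purrr::map_lgl(panels, inherits, "haplotype_panel")))
  if (min_snps < 1L || min_neighbors < 1L || window < 1L || bin_width < 1L ||
    alpha <= 0 || alpha >= 1 || min_span < 0L) {
    abort("invalid pipeline configuration", class = "ldsv_config_error")
  }
  pops <- purrr::map_chr(panels, "population")
  if (anyDuplicated(pops) > 0L) abort("duplicate population labels", class = "ldsv_config_error")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(out_dir, f)

  qc <- purrr::map(panels, apply_qc,
    max_missing = max_missing, hwe_alpha = hwe_alpha, maf_min = maf_min
  )
  qc_report <- purrr::map2(qc, pops, ~ dplyr::bind_cols(tibble::tibble(population = .y), .x$report)) |>
    dplyr::bind_rows()
  readr::write_tsv(qc_report, path("qc_report.tsv"))

  scans <- purrr::map(qc, ~ scan_population(.x$filtered,
    window = window, bin_width = bin_width, min_neighbors = min_neighbors,
    min_snps = min_snps, min_span = min_span, alpha = alpha,
    bh_scope = bh_scope, correction = correction
  ))
  names(scans) <- pops

  decay <- ld_decay_table(dplyr::bind_rows(purrr::map(scans, "profiles")), weighting = "pair")
  readr::write_tsv(decay, path("decay.tsv"))

  svs <- dplyr::bind_rows(purrr::map(scans, tidy))
  write_sv_bed(svs, path("svs.bed"))
  svs |>
    dplyr::select(-"snp_index", -"snp_pos") |>
    readr::write_tsv(path("svs.tsv"))

  regions <- merge_regions(svs)
  write_regions_tsv(regions, path("regions.tsv"))

  stats <- population_stats(svs)
  readr::write_tsv(stats, path("stats.tsv"))
  if (!is.null(chrom_sizes)) {
    readr::write_tsv(sv_per_mb(svs, chrom_sizes), path("sv_density.tsv"))
  }

  pca <- NULL
  if (length(panels) >= 2L && nrow(svs) > 0L) {
    pca <- sv_pca(sv_count_matrix(svs))
    readr::write_tsv(tidy(pca), path("pca_scores.tsv"))
  }

  cfg <- c(
    maf_min = maf_min, hwe_alpha = hwe_alpha, max_missing = max_missing,
    window = window, bin_width = bin_width, min_neighbors = min_neighbors,
    min_snps = min_snps, min_span = min_span, alpha = alpha
  )
  outputs <- list.files(out_dir, pattern = "\\.(tsv|bed)$")
  manifest <- c(
    paste0("ldsv_version\t", as.character(utils::packageVersion("ldsv"))),
    paste0("bh_scope\t", bh_scope),
    paste0("correction\t", correction),
    paste(names(cfg), cfg, sep = "\t"),
    paste(paste0("population\t", pops)),
    paste0("md5_", outputs, "\t", tools::md5sum(file.path(out_dir, outputs)))
  )
  readr::write_lines(manifest, path("manifest.tsv"))

  invisible(list(
    scans = scans, regions = regions, stats = stats, pca = pca,
    files = file.path(out_dir, c(outputs, "manifest.tsv"))
  ))
}
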