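#' Read a phased VCF into a haplotype panel
#'
#' Loads a VCF of phased genotypes and returns the corresponding
#' [haplotype_panel()], with two haplotype rows per sample. Only biallelic
#' SNP sites whose genotypes are all fully phased (`|` separator, no
#' missing alleles) are retained; everything else is dropped and tallied in
#' the load report attached to the result.
#'
#' @param path Path to a VCF (plain or bgzipped) with GT fields.
#' @param samples Optional character vector of sample names to keep;
#'   default keeps all samples.
#' @param population Population label for the panel; defaults to the file
#'   name without extension.
#'
#' @return A `haplotype_panel` whose attribute `"load_report"` is a named
#'   list: `n_sites`, `dropped_multiallelic`, `dropped_nonsnp`,
#'   `dropped_unphased` (unphased or missing genotypes), `n_retained`.
#'
#' @details Unphased or missing genotypes cause the whole site to be
#'   dropped rather than imputed: phasing is an upstream responsibility
#'   (typically BEAGLE or similar), and the LD computation requires
#'   complete phased columns. Allele 1 in the matrix is ALT.
#' @export
read_phased_vcf <- function(path, samples = NULL, population = NULL) {
  if (!file.exists(path)) abort(sprintf("cannot read VCF '%s'", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, ncol = 1L, dimnames = list(NULL, colnames(v@gt)[-1L]))
  if (!is.null(samples)) {
    missing_s <- setdiff(samples, colnames(gt))
    if (length(missing_s) > 0L) {
      abort(sprintf("samples not in VCF: %s", paste(missing_s, collapse = ", ")))
    }
    gt <- gt[, samples, drop = FALSE]
  }

  n_sites <- nrow(fix)
  is_snv <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L & !is.na(fix$ALT)
  is_biallelic <- !grepl(",", fix$ALT %||% "")
  phased <- apply(gt, 1L, function(g) all(grepl("^[01]\\|[01]$", g)))

  keep <- is_snv & is_biallelic & phased
  report <- list(
    n_sites = n_sites,
    dropped_multiallelic = sum(!is_biallelic),
    dropped_nonsnp = sum(is_biallelic & !is_snv),
    dropped_unphased = sum(is_biallelic & is_snv & !phased),
    n_retained = sum(keep)
  )
  if (report$n_retained == 0L) abort("no phased biallelic SNP sites retained from VCF")

  gt <- gt[keep, , drop = FALSE]
  hap1 <- substr(gt, 1L, 1L)
  hap2 <- substr(gt, 3L, 3L)
  # interleave so rows 2k-1, 2k are the two haplotypes of sample k
  al <- matrix(0L, nrow = 2L * ncol(gt), ncol = nrow(gt))
  al[seq(1L, nrow(al), by = 2L), ] <- t(matrix(as.integer(hap1), nrow = nrow(gt)))
  al[seq(2L, nrow(al), by = 2L), ] <- t(matrix(as.integer(hap2), nrow = nrow(gt)))

  map <- tibble::tibble(
    id = ifelse(is.na(fix$ID[keep]) | fix$ID[keep] == ".",
      paste0(fix$CHROM[keep], ":", fix$POS[keep]), fix$ID[keep]
    ),
    chrom = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]),
    ref = fix$REF[keep],
    alt = fix$ALT[keep]
  )
  if (anyDuplicated(map[c("chrom", "pos")]) > 0L) {
    abort("duplicate positions on a chromosome in VCF")
  }
  if (is.null(population)) {
    population <- sub("\\.vcf(\\.gz)?$", "", basename(path))
  }
  panel <- haplotype_panel(al, map, population = population)
  attr(panel, "load_report") <- report
  panel
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write the haplotype matrix TSV dialect
#'
#' A plain-text exchange format for phased panels: header lines starting
#' with `#population` and `#map` (tab-separated: id, chrom, pos, ref, alt —
#' one `#map` line per SNP in order), followed by one line per haplotype
#' written as a contiguous 0/1 string.
#'
#' @param path File path.
#' @return `read_haplotype_tsv` returns a [haplotype_panel()];
#'   `write_haplotype_tsv` invisibly returns `path`.
#' @examples
#' p <- simulate_panel(sim_config(n_animals = 4, n_snps = 6, seed = 1))$panel
#' f <- tempfile(fileext = ".tsv")
#' write_haplotype_tsv(p, f)
#' identical(read_haplotype_tsv(f)$alleles, p$alleles)
#' @export
read_haplotype_tsv <- function(path) {
  lines <- readr::read_lines(path)
  if (length(lines) == 0L) abort(sprintf("empty haplotype file '%s'", path))
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  pop_line <- hdr[startsWith(hdr, "#population")]
  population <- if (length(pop_line) > 0L) strsplit(pop_line[[1L]], "\t")[[1L]][2L] else "pop"
  map_lines <- hdr[startsWith(hdr, "#map")]
  if (length(map_lines) == 0L) abort("no #map header lines found")
  parts <- stringr::str_split(map_lines, "\t", simplify = TRUE)
  if (ncol(parts) < 4L) abort("#map lines need at least id, chrom, pos fields")
  map <- tibble::tibble(
    id = parts[, 2L], chrom = parts[, 3L],
    pos = suppressWarnings(as.integer(parts[, 4L]))
  )
  if (anyNA(map$pos)) abort("non-integer position in #map header")
  if (ncol(parts) >= 6L) {
    map$ref <- parts[, 5L]
    map$alt <- parts[, 6L]
  }
  widths <- nchar(body)
  if (length(unique(widths)) != 1L) {
    abort(sprintf("ragged haplotype rows: widths %s", paste(unique(widths), collapse = ",")))
  }
  if (widths[[1L]] != nrow(map)) {
    abort(sprintf("haplotype rows have %d symbols but map has %d SNPs", widths[[1L]], nrow(map)))
  }
  chars <- stringr::str_split(body, "", simplify = TRUE)
  bad <- which(
    array(!(chars %in% c("0", "1")), dim = dim(chars)),
    arr.ind = TRUE
  )
  if (nrow(bad) > 0L) {
    abort(sprintf(
      "non-binary allele symbol '%s' at haplotype row %d, SNP column %d",
      chars[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L], bad[1L, 2L]
    ))
  }
  al <- matrix(as.integer(chars), nrow = nrow(chars))
  haplotype_panel(al, map, population = population)
}

#' @param panel A [haplotype_panel()] to serialize.
#' @rdname read_haplotype_tsv
#' @export
write_haplotype_tsv <- function(panel, path) {
  stopifnot(inherits(panel, "haplotype_panel"))
  m <- panel$map
  ref <- if ("ref" %in% names(m)) m$ref else rep("A", nrow(m))
  alt <- if ("alt" %in% names(m)) m$alt else rep("G", nrow(m))
  hdr <- c(
    paste0("#population\t", panel$population),
    paste("#map", m$id, m$chrom, m$pos, ref, alt, sep = "\t")
  )
  rows <- apply(panel$alleles, 1L, paste0, collapse = "")
  readr::write_lines(c(hdr, rows), path)
  invisible(path)
}

#' Write called structural variants to BED
#'
#' Serializes an SV table (as returned by [scan_population()] or
#' [call_svs()]) as BED6: internal 1-based inclusive SNP-position spans are
#' converted to 0-based half-open intervals, the name field is
#' `population:direction`, the score is the member-SNP count.
#'
#' @param svs Tibble of SVs with columns `chrom`, `start`, `end`,
#'   `population`, `direction`, `n_snps`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_sv_bed <- function(svs, path) {
  header <- "# ldsv structural variants (BED6: chrom, start, end, population:direction, n_snps, strand)"
  if (is.null(svs) || nrow(svs) == 0L) {
    readr::write_lines(header, path)
    return(invisible(path))
  }
  bed <- svs |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::transmute(
      chrom = .data$chrom,
      start0 = .data$start - 1L,
      end = .data$end,
      name = paste0(.data$population, ":", .data$direction),
      score = .data$n_snps,
      strand = "."
    )
  readr::write_lines(
    c(header, do.call(paste, c(unname(as.list(bed)), sep = "\t"))),
    path
  )
  invisible(path)
}

#' Read a BED file of intervals
#'
#' Reads 3+ column BED into an interval tibble kept in the file's native
#' 0-based half-open coordinates. Labels come from column 4 when present,
#' otherwise intervals are auto-numbered `iv_1`, `iv_2`, ...
#'
#' @param path BED file path; `#`-comment and `track` lines are skipped.
#' @return Tibble with columns `chrom`, `start`, `end` (0-based half-open)
#'   and `label`.
#' @export
read_intervals_bed <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")]
  if (length(lines) == 0L) {
    return(tibble::tibble(
      chrom = character(), start = integer(), end = integer(), label = character()
    ))
  }
  parts <- stringr::str_split(lines, "\t")
  ncols <- lengths(parts)
  if (any(ncols < 3L)) abort("BED lines need at least 3 columns")
  chrom <- purrr::map_chr(parts, 1L)
  start <- suppressWarnings(as.integer(purrr::map_chr(parts, 2L)))
  end <- suppressWarnings(as.integer(purrr::map_chr(parts, 3L)))
  if (anyNA(start) || anyNA(end)) abort("non-integer BED coordinates")
  if (any(start >= end)) {
    i <- which(start >= end)[[1L]]
    abort(sprintf("BED interval with start >= end at line %d (%s:%d-%d)", i, chrom[i], start[i], end[i]))
  }
  label <- purrr::imap_chr(parts, function(p, i) if (length(p) >= 4L) p[[4L]] else paste0("iv_", i))
  tibble::tibble(chrom = chrom, start = start, end = end, label = label)
}

#' Read a chromosome-sizes file
#'
#' @param path Two-column TSV: chromosome name, length in bp.
#' @return Tibble with columns `chrom` and `length_bp`.
#' @export
read_chrom_sizes <- function(path) {
  tb <- readr::read_tsv(path,
    col_names = c("chrom", "length_bp"),
    col_types = readr::cols(chrom = "c", length_bp = "d"), comment = "#"
  )
  if (anyNA(tb$length_bp) || any(tb$length_bp <= 0)) abort("non-positive or missing chromosome length")
  if (anyDuplicated(tb$chrom) > 0L) {
    abort(sprintf("duplicate chromosome '%s' in sizes file", tb$chrom[duplicated(tb$chrom)][[1L]]))
  }
  tb
}
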