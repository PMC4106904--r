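#' Construct a phased haplotype panel
#'
#' A haplotype panel bundles a phased 0/1 allele matrix (one row per
#' haplotype, two per diploid animal; one column per SNP) with its SNP map
#' for a single population. It is the central input object of the LD scan:
#' all pairwise r-squared computation, expected-LD profiling and structural
#' variant calling operate on panels.
#'
#' @param alleles Integer or numeric matrix of 0/1 alleles; rows are
#'   haplotypes, columns are SNPs in map order. No missing values are
#'   allowed: phasing is an upstream responsibility and phased input is
#'   complete.
#' @param map Data frame with one row per SNP and columns `id`, `chrom`,
#'   `pos` (1-based bp). Optional columns `ref` and `alt` carry the allele
#'   labels (allele 1 in the matrix is ALT). Must be sorted by chromosome
#'   then strictly increasing position.
#' @param population Single string labelling the population (breed).
#'
#' @return An object of class `haplotype_panel`: a list with elements
#'   `alleles`, `map` (a tibble) and `population`.
#'
#' @details Allele orientation does not matter downstream: minor-allele
#'   frequencies and r-squared are invariant under swapping the 0/1 labels
#'   at any locus.
#'
#' @examples
#' al <- matrix(c(0, 1, 0, 1, 1, 0, 1, 0), nrow = 4)
#' map <- data.frame(id = c("s1", "s2"), chrom = "1", pos = c(100L, 900L))
#' haplotype_panel(al, map, population = "demo")
#' @export
haplotype_panel <- function(alleles, map, population = "pop") {
  alleles <- as.matrix(alleles)
  ok <- array(alleles %in% c(0L, 1L), dim = dim(alleles))
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1L, ]
    abort(sprintf(
      "alleles must be strictly 0/1 with no missing values (offending entry at haplotype %d, SNP column %d)",
      bad[[1L]], bad[[2L]]
    ))
  }
  storage.mode(alleles) <- "integer"
  map <- tibble::as_tibble(map)
  stopifnot(all(c("id", "chrom", "pos") %in% names(map)))
  map$chrom <- as.character(map$chrom)
  map$pos <- as.integer(map$pos)
  if (ncol(alleles) != nrow(map)) {
    abort("number of allele columns must equal number of map rows")
  }
  if (any(map$pos < 1L)) abort("positions must be >= 1")
  check_sorted_map(map)
  if (nrow(alleles) < 4L || nrow(alleles) %% 2L != 0L) {
    abort("a panel needs an even number of haplotypes, at least 4")
  }
  structure(
    list(
      alleles = alleles,
      map = map,
      population = as.character(population)[[1L]]
    ),
    class = "haplotype_panel"
  )
}

check_sorted_map <- function(map) {
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (any(diff(p) <= 0L)) {
      abort(sprintf(
        "unsorted positions: chromosome %s positions must be strictly increasing (duplicate or out-of-order near %d)",
        ch, p[which(diff(p) <= 0L)[1L] + 1L]
      ))
    }
  }
  invisible(map)
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf(
    "<haplotype_panel> population '%s': %d haplotypes (%d animals) x %d SNPs on %d chromosome(s)\n",
    x$population, nrow(x$alleles), nrow(x$alleles) %/% 2L,
    ncol(x$alleles), length(unique(x$map$chrom))
  ))
  invisible(x)
}

#' @export
dim.haplotype_panel <- function(x) dim(x$alleles)

n_haplotypes <- function(panel) nrow(panel$alleles)

#' Subset a haplotype panel by SNP
#'
#' @param panel A [haplotype_panel()].
#' @param keep Logical or integer index over SNP columns.
#' @return A `haplotype_panel` restricted to the kept SNPs.
#' @export
subset_snps <- function(panel, keep) {
  haplotype_panel(
    panel$alleles[, keep, drop = FALSE],
    panel$map[keep, , drop = FALSE],
    population = panel$population
  )
}
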