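#' Two-locus haplotype frequencies
#'
#' Counts minor-allele and joint minor–minor haplotype frequencies for a
#' pair of phased loci. The minor allele is determined per locus; a tie at
#' frequency 0.5 is broken toward allele 1.
#'
#' @param col_a,col_b 0/1 allele vectors of equal length (one entry per
#'   haplotype), both polymorphic.
#' @return Named list: `p1` (minor-allele frequency at locus A), `q1`
#'   (minor at locus B), `p11` (joint minor–minor haplotype frequency).
#' @examples
#' two_locus_freqs(c(1, 1, 0, 0), c(1, 1, 0, 0)) # perfect coupling
#' @export
two_locus_freqs <- function(col_a, col_b) {
  stopifnot(length(col_a) == length(col_b))
  fa <- mean(col_a)
  fb <- mean(col_b)
  if (fa %in% c(0, 1) || fb %in% c(0, 1)) abort("monomorphic column in LD computation")
  ya <- if (fa <= 0.5) col_a else 1L - col_a
  yb <- if (fb <= 0.5) col_b else 1L - col_b
  list(p1 = mean(ya), q1 = mean(yb), p11 = mean(ya * yb))
}

#' Squared-correlation linkage disequilibrium
#'
#' \eqn{r^2 = (p_{11} - p_1 q_1)^2 / (p_1 p_2 q_1 q_2)} where \eqn{p_1,
#' p_2} are the minor and major allele frequencies at the first SNP,
#' \eqn{q_1, q_2} at the second, and \eqn{p_{11}} the joint minor–minor
#' haplotype frequency. Equals the squared Pearson correlation of the two
#' 0/1 indicator vectors and is invariant to allele labelling and locus
#' order.
#'
#' @param f A list as returned by [two_locus_freqs()] (vectorized: `p1`,
#'   `q1`, `p11` may be equal-length vectors).
#' @return r-squared in `[0, 1]`.
#' @export
r_squared <- function(f) {
  num <- (f$p11 - f$p1 * f$q1)^2
  den <- f$p1 * (1 - f$p1) * f$q1 * (1 - f$q1)
  num / den
}

#' Sample-size correction of r-squared
#'
#' Finite samples inflate r-squared: even unlinked loci have expected
#' r-squared of about 1/n for n haplotypes. The default correction
#' subtracts that baseline. Corrected values are deliberately not floored
#' at zero so that "all below expectation" comparisons remain meaningful
#' near linkage equilibrium.
#'
#' @param r2 Raw r-squared value(s).
#' @param n_haplotypes Number of haplotypes in the sample (>= 4).
#' @param method `"subtract_inv_n"` (default): `r2 - 1/n`;
#'   `"hill_weir"`: `(r2 - 1/n) / (1 - 1/n)`; `"none"`: identity.
#' @return Adjusted r-squared (may be slightly negative).
#' @export
adjust_r2 <- function(r2, n_haplotypes, method = c("subtract_inv_n", "hill_weir", "none")) {
  method <- match.arg(method)
  if (method != "none" && n_haplotypes < 4L) abort("need at least 4 haplotypes for correction")
  switch(method,
    subtract_inv_n = r2 - 1 / n_haplotypes,
    hill_weir = (r2 - 1 / n_haplotypes) / (1 - 1 / n_haplotypes),
    none = r2
  )
}

#' All pairwise LD within a distance window
#'
#' Enumerates every ordered SNP pair (a before b, same chromosome,
#' `0 < pos_b - pos_a <= window`) and computes raw and sample-size
#' corrected r-squared for each. Pairs are formed left-to-right only, so
#' distance is always positive; this matches the scan's definition of a
#' SNP's neighbours as the polymorphic SNPs within the window to its
#' right.
#'
#' @param panel A [haplotype_panel()] with polymorphic SNPs (run
#'   [apply_qc()] first).
#' @param window Window size in bp (default 100000).
#' @param correction Correction method passed to [adjust_r2()].
#' @return Tibble with one row per pair: `chrom`, `idx_a`, `idx_b`
#'   (column indices in the panel), `pos_a`, `pos_b`, `distance`, `r2`,
#'   `r2_adj`.
#' @examples
#' sim <- simulate_panel(sim_config(n_animals = 20, n_snps = 30, seed = 2))
#' pairs <- pairwise_ld_window(sim$panel, window = 1e5)
#' head(pairs)
#' @export
pairwise_ld_window <- function(panel, window = 100000L, correction = "subtract_inv_n") {
  stopifnot(inherits(panel, "haplotype_panel"), window > 0)
  map <- panel$map
  n <- n_haplotypes(panel)
  freq1 <- colMeans(panel$alleles)
  if (any(freq1 %in% c(0, 1))) {
    abort("monomorphic SNP column; apply QC before computing LD")
  }
  # orient every column to its minor allele (ties at 0.5 keep allele 1)
  y <- panel$alleles
  flip <- freq1 > 0.5
  y[, flip] <- 1L - y[, flip]
  pminor <- colMeans(y)

  out <- vector("list", 0L)
  m <- nrow(map)
  # pairs by column offset: vectorized joint-frequency computation per lag
  for (d in seq_len(max(0L, m - 1L))) {
    ia <- seq_len(m - d)
    ib <- ia + d
    ok <- map$chrom[ia] == map$chrom[ib] & (map$pos[ib] - map$pos[ia]) <= window
    if (!any(ok)) {
      # offsets only grow in genomic distance within a chromosome; once no
      # pair at this lag fits the window on any chromosome, larger lags
      # cannot either
      break
    }
    ia <- ia[ok]
    ib <- ib[ok]
    p11 <- colMeans(y[, ia, drop = FALSE] * y[, ib, drop = FALSE])
    r2 <- r_squared(list(p1 = pminor[ia], q1 = pminor[ib], p11 = p11))
    out[[d]] <- tibble::tibble(
      chrom = map$chrom[ia], idx_a = ia, idx_b = ib,
      pos_a = map$pos[ia], pos_b = map$pos[ib],
      distance = map$pos[ib] - map$pos[ia],
      r2 = r2, r2_adj = adjust_r2(r2, n, correction)
    )
  }
  if (length(out) == 0L) {
    return(tibble::tibble(
      chrom = character(), idx_a = integer(), idx_b = integer(),
      pos_a = integer(), pos_b = integer(), distance = integer(),
      r2 = double(), r2_adj = double()
    ))
  }
  dplyr::bind_rows(out) |> dplyr::arrange(.data$idx_a, .data$idx_b)
}
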