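#' Simulation configuration
#'
#' Parameters of the founder-copy haplotype simulator. Each sample
#' haplotype copies one of a small set of founder haplotypes and switches
#' founders between adjacent SNPs with probability
#' `1 - exp(-recomb_rate_per_bp * gap)`, which produces linkage
#' disequilibrium that decays with physical distance — the background the
#' scan's expected means are estimated from.
#'
#' @param n_animals Diploid sample size (haplotypes = 2x this). Default
#'   200.
#' @param n_snps Number of SNPs. Default 2000.
#' @param mean_spacing_bp Mean inter-SNP gap; gaps are geometric around
#'   this mean, so positions are irregular like an array map. Default
#'   4000 (about 25 right-neighbours per SNP within 100 kb).
#' @param n_founders Number of founder haplotypes (>= 2). Default 4.
#' @param recomb_rate_per_bp Per-bp founder-switch rate in (0, 1).
#'   Default 7.5e-6.
#' @param maf_floor Founder allele frequencies are drawn uniformly on
#'   `[maf_floor, 1 - maf_floor]`. Default 0.1.
#' @param seed RNG seed; the whole simulation is deterministic given it.
#' @param chrom Chromosome label. Default "1".
#' @param planted List of [planted_segment()] descriptors (non-overlapping).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_animals = 200L, n_snps = 2000L, mean_spacing_bp = 4000L,
                       n_founders = 4L, recomb_rate_per_bp = 7.5e-6,
                       maf_floor = 0.1, seed = 1L, chrom = "1",
                       planted = list()) {
  stopifnot(
    n_animals >= 2L, n_snps >= 2L, mean_spacing_bp > 0L,
    n_founders >= 2L, recomb_rate_per_bp > 0, recomb_rate_per_bp < 1,
    maf_floor >= 0, maf_floor < 0.5
  )
  if (length(planted) > 1L) {
    iv <- dplyr::bind_rows(planted)
    iv <- iv[order(iv$chrom, iv$start_bp), ]
    same <- iv$chrom[-1L] == iv$chrom[-nrow(iv)]
    if (any(same & iv$start_bp[-1L] <= iv$end_bp[-nrow(iv)])) {
      abort("planted segments must not overlap")
    }
  }
  structure(
    list(
      n_animals = as.integer(n_animals), n_snps = as.integer(n_snps),
      mean_spacing_bp = as.integer(mean_spacing_bp),
      n_founders = as.integer(n_founders),
      recomb_rate_per_bp = recomb_rate_per_bp, maf_floor = maf_floor,
      seed = as.integer(seed), chrom = as.character(chrom), planted = planted
    ),
    class = "sim_config"
  )
}

#' @param chrom,start_bp,end_bp Segment location (1-based inclusive bp).
#' @param kind `"high_ld"` (coupled template haplotypes raise r-squared)
#'   or `"low_ld"` (column permutation destroys r-squared).
#' @param strength Proportion in `[0, 1]` controlling how completely the
#'   segment is overwritten.
#' @rdname sim_config
#' @export
planted_segment <- function(chrom, start_bp, end_bp, kind = c("high_ld", "low_ld"),
                            strength = 0.9) {
  kind <- match.arg(kind)
  stopifnot(start_bp < end_bp, strength >= 0, strength <= 1)
  tibble::tibble(
    chrom = as.character(chrom), start_bp = as.integer(start_bp),
    end_bp = as.integer(end_bp), kind = kind, strength = strength
  )
}

#' Simulate a phased haplotype panel with decaying LD
#'
#' Founder-copy model: founder haplotypes are drawn SNP-wise at uniform
#' allele frequencies, then each sample haplotype mosaics over the
#' founders with distance-dependent switch probability. Planted segments
#' from the configuration are applied afterwards (in the same seeded RNG
#' stream, so the full result is reproducible).
#'
#' @param config A [sim_config()].
#' @param population Population label for the panel.
#' @return List with `panel` (a [haplotype_panel()]) and `truth` (tibble
#'   of planted segments, zero rows when none).
#' @examples
#' sim <- simulate_panel(sim_config(n_animals = 20, n_snps = 50, seed = 42))
#' sim$panel
#' @export
simulate_panel <- function(config, population = "sim") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$n_snps
  n_hap <- 2L * config$n_animals

  gaps <- stats::rgeom(m - 1L, 1 / config$mean_spacing_bp) + 1L
  pos <- cumsum(c(1L, gaps))
  freqs <- stats::runif(m, config$maf_floor, 1 - config$maf_floor)
  founders <- matrix(
    stats::rbinom(config$n_founders * m, 1L, rep(freqs, each = config$n_founders)),
    nrow = config$n_founders
  )
  # enforce the frequency floor on the realized founder panel, so no
  # simulated marker is (near-)monomorphic by construction
  repeat {
    ff <- colMeans(founders)
    bad <- which(ff < config$maf_floor | ff > 1 - config$maf_floor)
    if (length(bad) == 0L) break
    founders[, bad] <- stats::rbinom(
      config$n_founders * length(bad), 1L,
      rep(freqs[bad], each = config$n_founders)
    )
  }

  fid <- sample.int(config$n_founders, n_hap, replace = TRUE)
  al <- matrix(0L, nrow = n_hap, ncol = m)
  al[, 1L] <- founders[fid, 1L]
  for (j in 2L:m) {
    p_switch <- 1 - exp(-config$recomb_rate_per_bp * gaps[j - 1L])
    sw <- stats::runif(n_hap) < p_switch
    if (any(sw)) fid[sw] <- sample.int(config$n_founders, sum(sw), replace = TRUE)
    al[, j] <- founders[fid, j]
  }

  map <- tibble::tibble(
    id = paste0("snp_", seq_len(m)), chrom = config$chrom, pos = as.integer(pos)
  )
  panel <- haplotype_panel(al, map, population = population)
  for (k in seq_along(config$planted)) {
    panel <- plant_segment(panel, config$planted[[k]])
  }
  truth <- if (length(config$planted) > 0L) {
    dplyr::bind_rows(config$planted)
  } else {
    planted_segment("0", 1L, 2L)[0L, ]
  }
  list(panel = panel, truth = truth)
}

#' Plant a high- or low-LD segment into a panel
#'
#' `high_ld`: two complementary template haplotypes are built from the
#' segment (the first haplotype's alleles and their complement, which
#' differ at every SNP); each haplotype's segment is, with probability
#' `strength`, overwritten by the template that matches its own allele at
#' the segment's last SNP. Anchoring the choice to an existing allele
#' couples every in-segment SNP to that anchor column, so within-segment
#' r-squared rises toward 1 while the natural decaying LD between the
#' anchor and the right flank is preserved — as around a real
#' recombination-suppressed rearrangement, the elevated LD fades into the
#' background instead of collapsing at the boundary. At strength 1 every
#' within-segment pair is perfectly coupled (r-squared 1) and every SNP
#' stays polymorphic. `low_ld`: each SNP column in the segment is, with
#' probability `strength`, independently permuted across haplotypes,
#' destroying association while preserving allele frequencies.
#'
#' Uses the current RNG stream; seed externally (or via
#' [simulate_panel()]) for reproducibility.
#'
#' @param panel A [haplotype_panel()].
#' @param seg A [planted_segment()] row within the panel's coordinates.
#' @return The modified panel.
#' @export
plant_segment <- function(panel, seg) {
  stopifnot(inherits(panel, "haplotype_panel"))
  cols <- which(
    panel$map$chrom == seg$chrom &
      panel$map$pos >= seg$start_bp & panel$map$pos <= seg$end_bp
  )
  if (length(cols) == 0L) {
    warn(sprintf("planted segment %s:%d-%d contains no SNPs", seg$chrom, seg$start_bp, seg$end_bp))
    return(panel)
  }
  if (seg$strength == 0) return(panel)
  n_hap <- nrow(panel$alleles)
  if (seg$kind == "high_ld") {
    template_a <- panel$alleles[1L, cols]
    template_b <- 1L - template_a
    # anchor on the most informative column in the right half of the
    # segment: coupling to a common allele keeps every planted column
    # polymorphic, and a right-side anchor preserves decaying LD into the
    # right flank (the side the scan's neighbour windows look at)
    right_half <- cols[cols >= cols[ceiling(length(cols) / 2)]]
    freq <- colMeans(panel$alleles[, right_half, drop = FALSE])
    anchor <- right_half[which.min(abs(freq - 0.5))]
    match_a <- panel$alleles[, anchor] == template_a[match(anchor, cols)]
    overwrite <- stats::runif(n_hap) < seg$strength
    for (h in which(overwrite)) {
      panel$alleles[h, cols] <- if (match_a[h]) template_a else template_b
    }
  } else {
    for (j in cols) {
      if (stats::runif(1L) < seg$strength) {
        panel$alleles[, j] <- panel$alleles[sample.int(n_hap), j]
      }
    }
  }
  panel
}

#' Write planted-segment truth as BED
#'
#' @param truth Truth tibble from [simulate_panel()].
#' @param path Output path. 1-based inclusive segment coordinates are
#'   converted to BED 0-based half-open; the name field is the segment
#'   kind.
#' @return Invisibly, `path`.
#' @export
write_truth_bed <- function(truth, path) {
  header <- "# ldsv planted-segment truth (BED4: chrom, start, end, kind)"
  if (nrow(truth) == 0L) {
    readr::write_lines(header, path)
    return(invisible(path))
  }
  truth <- truth[order(truth$chrom, truth$start_bp), ]
  readr::write_lines(
    c(header, paste(truth$chrom, truth$start_bp - 1L, truth$end_bp, truth$kind, sep = "\t")),
    path
  )
  invisible(path)
}

#' The default validation scenario
#'
#' The package's reference simulation for validating the scan: 200
#' animals, 2000 SNPs at 4 kb mean spacing on one chromosome (about 8 Mb),
#' with one planted high-LD and one planted low-LD segment at strength
#' 0.9. Segments span 130 kb (roughly 30 SNPs): the deviation unit is a
#' SNP together with its full 100-kb right window, so a deviating region
#' must exceed the window for any member SNP's whole neighbourhood to lie
#' inside it.
#'
#' @param seed RNG seed.
#' @param planted Include the two planted segments (default TRUE; FALSE
#'   gives the matching null panel).
#' @return A [sim_config()].
#' @export
default_scenario <- function(seed = 1L, planted = TRUE) {
  segs <- if (planted) {
    list(
      planted_segment("1", 2000001L, 2130000L, "high_ld", strength = 0.9),
      planted_segment("1", 5000001L, 5130000L, "low_ld", strength = 0.9)
    )
  } else {
    list()
  }
  sim_config(
    n_animals = 200L, n_snps = 2000L, mean_spacing_bp = 4000L,
    n_founders = 4L, recomb_rate_per_bp = 7.5e-6, maf_floor = 0.1,
    seed = seed, planted = segs
  )
}
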