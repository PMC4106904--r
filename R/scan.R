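#' Deviation test of one SNP against the expected-LD profile
#'
#' For a focal SNP, each of its right-window neighbour pairs carries a
#' deviation `d_j = r2_adj - expected mean of the pair's distance bin`.
#' The SNP qualifies directionally when every deviation is strictly on one
#' side of zero, and its p-value comes from the paired t-test of the
#' observed values against their expected means — algebraically the
#' two-sided one-sample t-test of the deviations against zero with
#' `n_neighbors - 1` degrees of freedom.
#'
#' @param i Column index of the focal SNP in its panel (left member of
#'   every pair).
#' @param pairs_from_i LD-pair tibble (see [pairwise_ld_window()])
#'   containing exactly the window pairs whose `idx_a == i`.
#' @param profile The chromosome's [expected_profile()].
#' @param min_neighbors Minimum number of right-window neighbours for the
#'   SNP to be testable (default 15); sparser SNPs are recorded as
#'   untestable.
#' @return One-row tibble: `snp_index`, `n_neighbors`, `direction`
#'   (`"above"`, `"below"`, `"mixed"` or `"untestable"`),
#'   `mean_deviation`, `t_stat`, `p_value`, `reason` (why untestable, else
#'   `NA`).
#' @details Degenerate cases follow the limit behaviour of the t
#'   statistic: zero-variance deviations with nonzero mean give
#'   `p_value = 0` (maximally significant); all-exactly-zero deviations
#'   give direction `"mixed"` (a zero deviation is on neither side) and
#'   `p_value = 1`.
#' @export
snp_test <- function(i, pairs_from_i, profile, min_neighbors = 15L) {
  stopifnot(all(pairs_from_i$idx_a == i))
  k <- nrow(pairs_from_i)
  base <- tibble::tibble(
    snp_index = as.integer(i), n_neighbors = k,
    direction = "untestable", mean_deviation = NA_real_,
    t_stat = NA_real_, p_value = NA_real_, reason = NA_character_
  )
  if (k < min_neighbors) {
    base$reason <- "too_few_neighbors"
    return(base)
  }
  bw <- profile$bin_end[2L] - profile$bin_start[2L]
  win <- max(profile$bin_end)
  expected <- profile$mean_r2_adj[bin_index(pairs_from_i$distance, bw, win)]
  if (anyNA(expected)) {
    base$reason <- "empty_expected_bin"
    return(base)
  }
  d <- pairs_from_i$r2_adj - expected
  base$mean_deviation <- mean(d)
  base$direction <- if (all(d > 0)) "above" else if (all(d < 0)) "below" else "mixed"
  s <- sd(d)
  if (s == 0) {
    if (base$mean_deviation == 0) {
      base$t_stat <- 0
      base$p_value <- 1
    } else {
      base$t_stat <- sign(base$mean_deviation) * Inf
      base$p_value <- 0
    }
  } else {
    base$t_stat <- base$mean_deviation / (s / sqrt(k))
    base$p_value <- 2 * pt(-abs(base$t_stat), df = k - 1L)
  }
  base
}

#' Benjamini-Hochberg step-up significance mask
#'
#' Sorts the m p-values, finds the largest k such that
#' `p_(k) <= alpha * k / m`, and declares the k smallest p-values
#' significant. Tied p-values share a fate, and the procedure is monotone:
#' if p_i is declared significant, so is every p_j <= p_i.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return Logical mask, same length and order as the input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04, 0.2)) # k = 2: smallest two significant
#' @export
bh_adjust <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0L) return(logical(0L))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must be in [0, 1] with no NA")
  }
  m <- length(p_values)
  ps <- sort(p_values)
  ok <- ps <= alpha * seq_len(m) / m
  if (!any(ok)) return(rep(FALSE, m))
  p_values <= ps[max(which(ok))]
}

#' Call structural variants from ordered SNP tests
#'
#' A structural variant is a maximal run of consecutive post-QC SNPs that
#' are all BH-significant with the same strict deviation direction, with
#' at least `min_snps` members and spanning at least `min_span` bp between
#' the first and last member positions. A direction flip or any
#' non-qualifying SNP terminates a run.
#'
#' @param tests Tibble of per-SNP tests in map order with columns
#'   `snp_index`, `chrom`, `pos`, `direction`, `bh_significant`.
#' @param population Population label stamped onto the calls.
#' @param min_snps Minimum member SNPs per SV (default 3).
#' @param min_span Minimum span `end - start` in bp (default 1000).
#' @return Tibble of SVs: `population`, `chrom`, `start`, `end`,
#'   `size_bp`, `n_snps`, `direction`, plus list-columns `snp_index` and
#'   `snp_pos` with the members.
#' @export
call_svs <- function(tests, population = "pop", min_snps = 3L, min_span = 1000L) {
  empty <- tibble::tibble(
    population = character(), chrom = character(),
    start = integer(), end = integer(), size_bp = integer(),
    n_snps = integer(), direction = character(),
    snp_index = list(), snp_pos = list()
  )
  if (nrow(tests) == 0L) return(empty)
  split_pos <- split(tests$pos, tests$chrom)
  if (!all(vapply(split_pos, function(p) !is.unsorted(p, strictly = TRUE), logical(1L)))) {
    abort("tests must be ordered by map position within each chromosome")
  }
  state <- ifelse(
    tests$bh_significant %in% TRUE & tests$direction %in% c("above", "below"),
    paste0(tests$chrom, ":", tests$direction), "none"
  )
  r <- rle(state)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  keep <- r$values != "none" & r$lengths >= min_snps
  if (!any(keep)) return(empty)
  svs <- purrr::map2(run_start[keep], run_end[keep], function(a, b) {
    rows <- tests[a:b, ]
    tibble::tibble(
      population = population,
      chrom = rows$chrom[[1L]],
      start = rows$pos[[1L]],
      end = rows$pos[[nrow(rows)]],
      size_bp = rows$pos[[nrow(rows)]] - rows$pos[[1L]],
      n_snps = nrow(rows),
      direction = rows$direction[[1L]],
      snp_index = list(rows$snp_index),
      snp_pos = list(rows$pos)
    )
  }) |> dplyr::bind_rows()
  svs |>
    dplyr::filter(.data$size_bp >= min_span) |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Scan a population for LD-based structural variants
#'
#' The full per-population pipeline, run chromosome by chromosome:
#' window-restricted pairwise LD, distance-binned expected-LD profile,
#' per-SNP deviation tests, Benjamini-Hochberg correction over the
#' testable SNPs, and run-based variant calling. Deterministic given the
#' panel and settings.
#'
#' @param panel A QC-filtered [haplotype_panel()] (every SNP polymorphic).
#' @param window Neighbourhood size in bp (default 100000).
#' @param bin_width Distance-bin width in bp (default 5000).
#' @param min_neighbors Minimum right-window neighbours per testable SNP
#'   (default 15).
#' @param min_snps Minimum SNPs per called SV (default 3).
#' @param min_span Minimum SV span in bp (default 1000).
#' @param alpha FDR level for the BH correction (default 0.05).
#' @param bh_scope `"chromosome"` applies BH per chromosome (each
#'   chromosome's testable SNPs form one family); `"genome"` pools all
#'   chromosomes of the population into one family.
#' @param correction r-squared sample-size correction (see [adjust_r2()]).
#' @return An object of class `ldsv_scan`: list with `svs` (the calls,
#'   see [call_svs()]), `tests` (all per-SNP tests with `chrom`, `pos`,
#'   `bh_significant`), `profiles` (per-chromosome expected-LD profiles),
#'   `population` and `params`. Use [tidy()] for the SV table and
#'   [glance()] for a one-row summary.
#' @examples
#' sim <- simulate_panel(sim_config(n_animals = 50, n_snps = 300, seed = 3))
#' scan <- scan_population(apply_qc(sim$panel)$filtered)
#' glance(scan)
#' @export
scan_population <- function(panel, window = 100000L, bin_width = 5000L,
                            min_neighbors = 15L, min_snps = 3L,
                            min_span = 1000L, alpha = 0.05,
                            bh_scope = c("chromosome", "genome"),
                            correction = "subtract_inv_n") {
  bh_scope <- match.arg(bh_scope)
  stopifnot(
    inherits(panel, "haplotype_panel"),
    window > 0, bin_width > 0, window %% bin_width == 0,
    min_neighbors >= 1, min_snps >= 1, min_span >= 0,
    alpha > 0, alpha < 1
  )
  pairs <- pairwise_ld_window(panel, window = window, correction = correction)
  map <- panel$map

  tests_by_chrom <- list()
  profiles <- list()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    if (length(idx) < min_neighbors + 1L) {
      warn(sprintf(
        "chromosome %s skipped: %d SNPs cannot give any SNP %d neighbours",
        ch, length(idx), min_neighbors
      ))
      next
    }
    pc <- pairs[pairs$chrom == ch, , drop = FALSE]
    if (nrow(pc) == 0L) {
      warn(sprintf("chromosome %s skipped: no pairs within %d bp", ch, as.integer(window)))
      next
    }
    prof <- expected_profile(pc, panel$population, bin_width, window)
    profiles[[ch]] <- prof
    by_a <- split(pc, factor(pc$idx_a, levels = idx))
    tests <- purrr::map2(
      idx, by_a,
      ~ snp_test(.x, .y, prof, min_neighbors = min_neighbors)
    ) |> dplyr::bind_rows()
    tests$chrom <- ch
    tests$pos <- map$pos[idx]
    tests_by_chrom[[ch]] <- tests
  }
  tests <- dplyr::bind_rows(tests_by_chrom)
  if (nrow(tests) == 0L) {
    tests <- tibble::tibble(
      snp_index = integer(), n_neighbors = integer(), direction = character(),
      mean_deviation = double(), t_stat = double(), p_value = double(),
      reason = character(), chrom = character(), pos = integer(),
      bh_significant = logical()
    )
  } else {
    tests$bh_significant <- FALSE
    testable <- !is.na(tests$p_value)
    if (bh_scope == "chromosome") {
      for (ch in unique(tests$chrom)) {
        sel <- testable & tests$chrom == ch
        if (any(sel)) tests$bh_significant[sel] <- bh_adjust(tests$p_value[sel], alpha)
      }
    } else if (any(testable)) {
      tests$bh_significant[testable] <- bh_adjust(tests$p_value[testable], alpha)
    }
    tests <- dplyr::arrange(tests, match(.data$chrom, unique(map$chrom)), .data$pos)
  }

  svs <- call_svs(tests, panel$population, min_snps = min_snps, min_span = min_span)
  structure(
    list(
      svs = svs, tests = tests,
      profiles = dplyr::bind_rows(profiles),
      population = panel$population,
      params = list(
        window = window, bin_width = bin_width, min_neighbors = min_neighbors,
        min_snps = min_snps, min_span = min_span, alpha = alpha,
        bh_scope = bh_scope, correction = correction
      )
    ),
    class = "ldsv_scan"
  )
}

#' @export
print.ldsv_scan <- function(x, ...) {
  cat(sprintf(
    "<ldsv_scan> population '%s': %d SV(s) from %d tested SNP(s) on %d chromosome(s)\n",
    x$population, nrow(x$svs), sum(!is.na(x$tests$p_value)),
    length(unique(x$tests$chrom))
  ))
  invisible(x)
}

#' Tidy a structural-variant scan
#'
#' @param x An `ldsv_scan` object.
#' @param ... Unused.
#' @return `tidy()` returns the SV call table (one row per SV);
#'   `glance()` returns a one-row summary: populations, SNPs tested,
#'   BH-significant count, SV count, total/mean SV size.
#' @exportS3Method generics::tidy
#' @export
tidy.ldsv_scan <- function(x, ...) x$svs

#' @rdname tidy.ldsv_scan
#' @exportS3Method generics::glance
#' @export
glance.ldsv_scan <- function(x, ...) {
  tibble::tibble(
    population = x$population,
    n_snps_tested = sum(!is.na(x$tests$p_value)),
    n_bh_significant = sum(x$tests$bh_significant),
    n_svs = nrow(x$svs),
    total_size_bp = sum(x$svs$size_bp),
    mean_size_bp = if (nrow(x$svs) > 0L) mean(x$svs$size_bp) else NA_real_
  )
}

#' Independent post-hoc validator of SV calls
#'
#' Re-checks every emitted SV directly against the definition, using only
#' the call table and the per-SNP test table (not the caller's internal
#' state): at least `min_snps` members, span at least `min_span`,
#' consecutive member indices, every member BH-significant with the SV's
#' uniform direction, and every member with at least `min_neighbors`
#' neighbours.
#'
#' @param svs SV tibble from [call_svs()] / [scan_population()].
#' @param tests Matching per-SNP test tibble.
#' @inheritParams call_svs
#' @inheritParams snp_test
#' @return `TRUE` invisibly; aborts with a description of the first
#'   violated requirement otherwise.
#' @export
validate_svs <- function(svs, tests, min_snps = 3L, min_span = 1000L, min_neighbors = 15L) {
  for (i in seq_len(nrow(svs))) {
    sv <- svs[i, ]
    idx <- sv$snp_index[[1L]]
    rows <- tests[match(idx, tests$snp_index), ]
    ok <- c(
      n_snps = sv$n_snps >= min_snps && length(idx) == sv$n_snps,
      span = sv$size_bp >= min_span && sv$size_bp == sv$end - sv$start,
      consecutive = all(diff(idx) == 1L),
      one_chrom = all(rows$chrom == sv$chrom),
      neighbors = all(rows$n_neighbors >= min_neighbors),
      direction = all(rows$direction == sv$direction) &&
        sv$direction %in% c("above", "below"),
      significant = all(rows$bh_significant)
    )
    if (!all(ok)) {
      abort(sprintf(
        "SV %s:%d-%d (%s) violates: %s",
        sv$chrom, sv$start, sv$end, sv$population,
        paste(names(ok)[!ok], collapse = ", ")
      ))
    }
  }
  invisible(TRUE)
}
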