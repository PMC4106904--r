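# Independent reference implementations used as oracles. Deliberately
# naive (enumeration, double loops, union-find) and kept free of any code
# path they are checking.

# exact HWE p-value by direct enumeration with choose(); probabilities of
# all heterozygote configurations given the allele counts
oracle_hwe_enum <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_minor <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)
  if (n_minor == 0) return(1.0)
  hs <- seq(n_minor %% 2, n_minor, by = 2)
  probs <- vapply(hs, function(h) {
    hom_minor <- (n_minor - h) / 2
    hom_major <- n - hom_minor - h
    if (hom_major < 0) return(0)
    # multinomial genotype count / multinomial gamete count
    exp(
      lchoose(n, hom_minor) + lchoose(n - hom_minor, h) + h * log(2) -
        lchoose(2 * n, n_minor)
    )
  }, numeric(1))
  probs <- probs / sum(probs)
  p_obs <- probs[hs == n_Aa]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-9)]))
}

# literal transcription of the BH step-up rule: compare the sorted
# p-values from the largest down with alpha*i/m, stop at the first i
# where p_(i) <= alpha*i/m, declare the smallest i significant
oracle_bh <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  k <- 0
  for (i in m:1) {
    if (sorted[i] <= alpha * i / m) {
      k <- i
      break
    }
  }
  mask <- rep(FALSE, m)
  if (k > 0) mask[ord[seq_len(k)]] <- TRUE
  mask
}

# brute-force window pair enumeration by double loop
oracle_window_pairs <- function(map, window) {
  out <- list()
  m <- nrow(map)
  for (a in seq_len(m)) {
    for (b in seq_len(m)) {
      if (b > a && map$chrom[a] == map$chrom[b] &&
        map$pos[b] - map$pos[a] <= window && map$pos[b] > map$pos[a]) {
        out[[length(out) + 1L]] <- c(a, b)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(idx_a = integer(), idx_b = integer()))
  }
  df <- as.data.frame(do.call(rbind, out))
  names(df) <- c("idx_a", "idx_b")
  df
}

# naive transcription of the scan definition: double-loop LD, sorted-pair
# binning, per-SNP all-above/all-below check with t.test(), p.adjust BH,
# run collection — no shared code with scan_population internals
oracle_naive_scan <- function(panel, window = 100000, bin_width = 5000,
                              min_neighbors = 15, min_snps = 3,
                              min_span = 1000, alpha = 0.05) {
  map <- panel$map
  n <- nrow(panel$alleles)
  svs <- list()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    # all window pairs, double loop
    pr <- list()
    for (a in idx) {
      for (b in idx) {
        d <- map$pos[b] - map$pos[a]
        if (b > a && d > 0 && d <= window) {
          r2 <- stats::cor(panel$alleles[, a], panel$alleles[, b])^2
          pr[[length(pr) + 1L]] <- data.frame(a = a, b = b, d = d, adj = r2 - 1 / n)
        }
      }
    }
    if (length(pr) == 0L) next
    pr <- do.call(rbind, pr)
    bin_of <- ceiling(pr$d / bin_width)
    bin_mean <- tapply(pr$adj, bin_of, mean)

    res <- data.frame(i = idx, dir = "none", p = NA_real_)
    for (r in seq_along(idx)) {
      i <- idx[r]
      mine <- pr[pr$a == i, ]
      if (nrow(mine) < min_neighbors) next
      dev <- mine$adj - bin_mean[as.character(ceiling(mine$d / bin_width))]
      if (all(dev > 0)) res$dir[r] <- "above"
      if (all(dev < 0)) res$dir[r] <- "below"
      res$p[r] <- if (stats::sd(dev) == 0) {
        if (mean(dev) == 0) 1 else 0
      } else {
        stats::t.test(dev)$p.value
      }
    }
    testable <- !is.na(res$p)
    res$sig <- FALSE
    if (any(testable)) {
      res$sig[testable] <- stats::p.adjust(res$p[testable], method = "BH") <= alpha
    }
    # collect maximal qualifying runs
    run_dir <- ifelse(res$sig & res$dir %in% c("above", "below"), res$dir, "none")
    r <- rle(run_dir)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (q in which(r$values != "none" & r$lengths >= min_snps)) {
      first <- map$pos[res$i[starts[q]]]
      last <- map$pos[res$i[ends[q]]]
      if (last - first >= min_span) {
        svs[[length(svs) + 1L]] <- data.frame(
          chrom = ch, start = first, end = last,
          n_snps = r$lengths[q], direction = r$values[q]
        )
      }
    }
  }
  if (length(svs) == 0L) {
    return(data.frame(
      chrom = character(), start = integer(), end = integer(),
      n_snps = integer(), direction = character()
    ))
  }
  out <- do.call(rbind, svs)
  out[order(out$chrom, out$start), , drop = FALSE]
}

# union-find single-linkage merge of intervals (>=1 bp shared, inclusive)
oracle_merge <- function(iv) {
  n <- nrow(iv)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a < b && iv$chrom[a] == iv$chrom[b] &&
        iv$start[a] <= iv$end[b] && iv$start[b] <= iv$end[a]) {
        parent[find(a)] <- find(b)
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  out <- lapply(unique(root), function(r) {
    members <- iv[root == r, , drop = FALSE]
    data.frame(
      chrom = members$chrom[1], start = min(members$start), end = max(members$end),
      n_members = nrow(members)
    )
  })
  out <- do.call(rbind, out)
  out[order(out$chrom, out$start), , drop = FALSE]
}

# quadratic any-overlap counting (regions 1-based inclusive, external
# 0-based half-open)
oracle_overlap <- function(regions, external) {
  hits <- 0L
  for (e in seq_len(nrow(external))) {
    found <- FALSE
    for (r in seq_len(nrow(regions))) {
      if (external$chrom[e] == regions$chrom[r] &&
        external$start[e] + 1L <= regions$end[r] &&
        external$end[e] >= regions$start[r]) {
        found <- TRUE
      }
    }
    hits <- hits + found
  }
  hits
}

# random SV-like interval fixture
random_intervals <- function(n, chroms = c("1", "2"), max_pos = 10000L, population = NULL) {
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample.int(500L, n, replace = TRUE)
  tibble::tibble(
    population = if (is.null(population)) sample(c("A", "B", "C"), n, replace = TRUE) else population,
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + len,
    snp_pos = purrr::map2(start, start + len, ~ seq(.x, .y, length.out = 3) |> round() |> as.integer())
  )
}
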