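#' Principal component analysis of per-chromosome SV counts
#'
#' Covariance-based PCA of a populations-by-chromosomes count matrix:
#' columns are mean-centred (no variance scaling by default, matching the
#' covariance formulation) and the covariance matrix is
#' eigendecomposed. Eigenvector sign is fixed by making each loading
#' vector's largest-magnitude element positive, so results are bitwise
#' reproducible.
#'
#' @param counts Numeric matrix (rows = populations, columns = variables,
#'   e.g. from [sv_count_matrix()]) with at least 2 rows.
#' @param n_components Number of components to retain (default: all,
#'   `min(nrow - 1, ncol)`).
#' @param scale. Also divide each column by its standard deviation
#'   (correlation-matrix PCA); default FALSE. Zero-variance columns are
#'   left unscaled.
#' @return An object of class `ldsv_pca`: list with `eigenvalues`
#'   (non-increasing, all `min(nrow - 1, ncol)` of them), `loadings`
#'   (orthonormal columns, one per retained component), `scores`
#'   (populations x retained components), `center`, `scale`,
#'   `n_components`. Use [tidy()] for scores and [glance()] for variance
#'   explained.
#' @export
sv_pca <- function(counts, n_components = NULL, scale. = FALSE) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L) abort("PCA needs at least 2 rows")
  max_comp <- min(nrow(counts) - 1L, ncol(counts))
  if (is.null(n_components)) n_components <- max_comp
  stopifnot(n_components >= 1L, n_components <= max_comp)

  center <- colMeans(counts)
  x <- sweep(counts, 2L, center)
  scl <- rep(1, ncol(counts))
  if (isTRUE(scale.)) {
    s <- apply(counts, 2L, sd)
    scl <- ifelse(s > 0, s, 1)
    x <- sweep(x, 2L, scl, "/")
  }
  cv <- stats::cov(x)
  eig <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eig$values, 0)[seq_len(max_comp)]
  load <- eig$vectors[, seq_len(n_components), drop = FALSE]
  # sign convention: largest-|loading| element of each component positive
  for (j in seq_len(ncol(load))) {
    k <- which.max(abs(load[, j]))
    if (load[k, j] < 0) load[, j] <- -load[, j]
  }
  rownames(load) <- colnames(counts)
  colnames(load) <- paste0("PC", seq_len(ncol(load)))
  scores <- x %*% load
  rownames(scores) <- rownames(counts)
  structure(
    list(
      eigenvalues = ev, loadings = load, scores = scores,
      center = center, scale = scl, n_components = n_components
    ),
    class = "ldsv_pca"
  )
}

#' @export
print.ldsv_pca <- function(x, ...) {
  tot <- sum(x$eigenvalues)
  pct <- if (tot > 0) 100 * x$eigenvalues[seq_len(min(2L, length(x$eigenvalues)))] / tot else c(0, 0)
  cat(sprintf(
    "<ldsv_pca> %d row(s), %d component(s); PC1 %.1f%%, PC2 %.1f%% of variance\n",
    nrow(x$scores), x$n_components, pct[1L], if (length(pct) > 1L) pct[2L] else 0
  ))
  invisible(x)
}

#' Tidy an SV-count PCA
#'
#' @param x An `ldsv_pca` object.
#' @param ... Unused.
#' @return `tidy()` returns one row per population with its component
#'   scores; `glance()` one row per component with eigenvalue and
#'   variance proportions.
#' @exportS3Method generics::tidy
#' @export
tidy.ldsv_pca <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(population = rownames(x$scores) %||% as.character(seq_len(nrow(x$scores)))),
    tibble::as_tibble(x$scores)
  )
}

#' @rdname tidy.ldsv_pca
#' @exportS3Method generics::glance
#' @export
glance.ldsv_pca <- function(x, ...) {
  tot <- sum(x$eigenvalues)
  tibble::tibble(
    component = paste0("PC", seq_along(x$eigenvalues)),
    eigenvalue = x$eigenvalues,
    prop_variance = if (tot > 0) x$eigenvalues / tot else rep(0, length(x$eigenvalues)),
    cum_variance = if (tot > 0) cumsum(x$eigenvalues) / tot else rep(0, length(x$eigenvalues))
  )
}

#' Plot PCA scores of populations
#'
#' @param pca An `ldsv_pca` object.
#' @param components Two component names to plot (default PC1, PC2).
#' @return A ggplot scatter of population scores with text labels.
#' @export
plot_pca_scores <- function(pca, components = c("PC1", "PC2")) {
  sc <- tidy(pca)
  stopifnot(all(components %in% names(sc)))
  ggplot2::ggplot(sc, ggplot2::aes(
    x = .data[[components[[1L]]]], y = .data[[components[[2L]]]],
    label = .data$population
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::labs(x = components[[1L]], y = components[[2L]]) +
    ggplot2::theme_minimal()
}
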