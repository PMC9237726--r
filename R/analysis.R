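#' Select a spectral region of interest
#'
#' Restricts a map to the axis points inside the closed interval
#' `[lo, hi]` cm^-1, e.g. the fingerprint region or a single band, for
#' region-restricted clustering or inspection.
#'
#' @param map A [spectral_map].
#' @param lo,hi Window bounds in cm^-1, `lo < hi`.
#' @return A [spectral_map] restricted to the selected columns.
#' @export
select_region <- function(map, lo, hi) {
  stopifnot(inherits(map, "spectral_map"))
  if (lo >= hi) abort_sm("region bounds must satisfy lo < hi", "parameter")
  idx <- axis_in_window(map$axis, lo, hi)
  if (!length(idx)) {
    below <- map$axis[map$axis < lo]
    above <- map$axis[map$axis > hi]
    abort_sm(sprintf(
      "window [%g, %g] contains no axis points; nearest available: %s",
      lo, hi,
      paste(c(if (length(below)) sprintf("%.6g", max(below)),
              if (length(above)) sprintf("%.6g", min(above))),
            collapse = " and ")), "window")
  }
  out <- map
  out$axis <- map$axis[idx]
  out$absorbance <- map$absorbance[, idx, drop = FALSE]
  sm_log(out, sprintf("region [%g, %g] cm^-1 selected (%d columns)",
                      lo, hi, length(idx)))
}

#' Principal component analysis of spectra
#'
#' Mean-centers the spectra (no variance scaling — absorbance channels
#' share units, and scaling would inflate noise-only wavenumbers) and
#' eigendecomposes the sample covariance via singular value decomposition.
#' The loadings are *eigen-spectra*: unit-norm spectral modes of variation
#' over the wavenumber axis. The sign of each eigen-spectrum is fixed so
#' that its entry of largest magnitude is positive, making results
#' reproducible across eigensolvers.
#'
#' @param map A [spectral_map] with at least 2 pixels.
#' @param n_components Number of components,
#'   `<= min(n_pixels, n_wavenumbers)`. Default 15.
#' @return An object of class `pca_result`: `mean_spectrum`,
#'   `eigen_spectra` (`n_components x n_wavenumbers`, orthonormal rows),
#'   `scores` (`n_pixels x n_components`),
#'   `explained_variance_ratio` (fractions of total centered variance),
#'   and the training `axis`.
#' @export
fit_pca <- function(map, n_components = 15L) {
  stopifnot(inherits(map, "spectral_map"))
  X <- map$absorbance
  n <- nrow(X)
  if (n < 2) abort_sm("PCA requires at least 2 pixels", "data")
  n_components <- as.integer(n_components)
  if (n_components < 1 || n_components > min(dim(X)))
    abort_sm(sprintf("n_components must be in [1, %d]", min(dim(X))),
             "parameter")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0, nv = min(dim(X)))
  eigvals <- sv$d^2 / (n - 1)                 # covariance eigenvalues
  total_var <- sum(eigvals)
  V <- t(sv$v[, seq_len(n_components), drop = FALSE])  # rows = eigen-spectra
  # sign convention: largest-magnitude entry of each eigen-spectrum positive
  for (i in seq_len(n_components)) {
    j <- which.max(abs(V[i, ]))
    if (V[i, j] < 0) V[i, ] <- -V[i, ]
  }
  scores <- Xc %*% t(V)
  structure(list(
    mean_spectrum = mu,
    eigen_spectra = V,
    scores = scores,
    explained_variance_ratio =
      if (total_var > 0) eigvals[seq_len(n_components)] / total_var
      else rep(0, n_components),
    axis = map$axis), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d components over %d wavenumbers, %d pixels\n",
              nrow(x$eigen_spectra), ncol(x$eigen_spectra), nrow(x$scores)))
  cat("  explained variance:",
      paste(sprintf("%.3f", utils::head(x$explained_variance_ratio, 5)),
            collapse = " "),
      if (length(x$explained_variance_ratio) > 5) "...", "\n")
  invisible(x)
}

#' Cumulative explained variance
#'
#' Running sum of the explained-variance ratios, the curve used to choose
#' how many components to carry into clustering.
#'
#' @param pca A `pca_result` from [fit_pca].
#' @return Numeric vector of non-decreasing fractions.
#' @export
cumulative_variance <- function(pca) {
  stopifnot(inherits(pca, "pca_result"))
  cumsum(pca$explained_variance_ratio)
}

#' Project spectra onto fitted principal components
#'
#' Projects (new) spectra onto a fitted PCA basis:
#' `(x - mean_spectrum) %*% t(eigen_spectra)`. The map's axis must be
#' identical to the axis the PCA was fitted on.
#'
#' @param map A [spectral_map].
#' @param pca A `pca_result` from [fit_pca].
#' @return Scores matrix `n_pixels x n_components`.
#' @export
project <- function(map, pca) {
  stopifnot(inherits(map, "spectral_map"), inherits(pca, "pca_result"))
  if (length(map$axis) != length(pca$axis) ||
      any(map$axis != pca$axis))
    abort_sm("map axis differs from the axis the PCA was fitted on",
             "incompatible_axes")
  sweep(map$absorbance, 2, pca$mean_spectrum) %*% t(pca$eigen_spectra)
}

#' Graph-based clustering of pixels (Leiden)
#'
#' Builds a k-nearest-neighbour graph (Euclidean distances, directed edges
#' symmetrized by union, unweighted) on the supplied score matrix and
#' partitions it with the Leiden community-detection algorithm under the
#' modularity objective at the given resolution. Labels are relabelled so
#' cluster 0 is the largest, descending by size, ties broken by
#' first-occurrence pixel index. An optional seeded 2-D force-directed
#' layout of the same graph can be attached for visualization; it never
#' feeds the clustering.
#'
#' @param scores Numeric matrix, pixels in rows (typically PCA scores).
#' @param n_neighbors Neighbours per pixel for the kNN graph
#'   (`2 <= n_neighbors < n_pixels`). Default 15.
#' @param resolution Leiden resolution parameter (> 0). Default 1.
#' @param seed Integer seed controlling the Leiden refinement (and the
#'   layout, when requested). Default 0.
#' @param embedding Compute the decorative 2-D graph layout? Default FALSE.
#' @return An object of class `cluster_assignment`: integer `labels`
#'   (0-based, size-ordered), optional `embedding`
#'   (`n_pixels x 2`), and `params`.
#' @export
cluster_pixels <- function(scores, n_neighbors = 15L, resolution = 1,
                           seed = 0L, embedding = FALSE) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  n_neighbors <- as.integer(n_neighbors)
  if (n_neighbors < 2L || n_neighbors >= n)
    abort_sm(sprintf("n_neighbors must satisfy 2 <= k < n_pixels (%d)", n),
             "parameter")
  if (resolution <= 0) abort_sm("resolution must be > 0", "parameter")
  D <- as.matrix(stats::dist(scores))
  nb <- t(apply(D, 1, function(d) order(d)[2:(n_neighbors + 1L)]))
  edges <- cbind(rep(seq_len(n), each = n_neighbors), as.vector(t(nb)))
  g <- igraph::simplify(igraph::graph_from_edgelist(edges, directed = FALSE))
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 5)
  labels <- relabel_by_size(as.integer(igraph::membership(comm)))
  emb <- NULL
  if (isTRUE(embedding)) {
    set.seed(as.integer(seed))
    emb <- igraph::layout_with_fr(g)
  }
  structure(list(labels = labels, embedding = emb,
                 params = list(n_neighbors = n_neighbors,
                               resolution = resolution,
                               seed = as.integer(seed))),
            class = "cluster_assignment")
}

# Relabel integer communities so label 0 is the largest cluster, descending
# by size; ties broken by the cluster whose first member pixel comes first.
relabel_by_size <- function(labels) {
  u <- unique(labels)
  sizes <- vapply(u, function(l) sum(labels == l), integer(1))
  first <- vapply(u, function(l) which(labels == l)[1], integer(1))
  ord <- u[order(-sizes, first)]
  match(labels, ord) - 1L
}

#' @export
print.cluster_assignment <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("<cluster_assignment> %d pixels, %d clusters (sizes: %s)\n",
              length(x$labels), length(tab),
              paste(as.integer(tab), collapse = ", ")))
  cat(sprintf("  n_neighbors = %d, resolution = %g, seed = %d\n",
              x$params$n_neighbors, x$params$resolution, x$params$seed))
  invisible(x)
}

#' Best-matching label agreement
#'
#' Fraction of pixels on which a cluster labelling agrees with a reference
#' labelling under the best one-to-one matching of labels (all label
#' permutations are scored when the label sets are small; a greedy
#' confusion-matrix matching is used beyond 8 labels).
#'
#' @param labels Candidate integer labels.
#' @param reference Reference integer labels of the same length.
#' @return Agreement fraction in `[0, 1]`.
#' @export
label_agreement <- function(labels, reference) {
  if (length(labels) != length(reference))
    abort_sm("label vectors differ in length", "label")
  ul <- unique(labels); ur <- unique(reference)
  conf <- table(factor(labels, ul), factor(reference, ur))
  k <- max(length(ul), length(ur))
  if (length(ul) <= 8 && length(ur) <= 8) {
    perms <- function(v) if (length(v) <= 1) list(v) else
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perms(v[-i]), function(p) c(v[i], p))))
    short <- if (length(ul) <= length(ur)) "row" else "col"
    best <- 0
    if (short == "row") {
      for (p in perms(seq_along(ur))) {
        hit <- sum(vapply(seq_along(ul), function(i)
          conf[i, p[i]], numeric(1)))
        best <- max(best, hit)
      }
    } else {
      for (p in perms(seq_along(ul))) {
        hit <- sum(vapply(seq_along(ur), function(j)
          conf[p[j], j], numeric(1)))
        best <- max(best, hit)
      }
    }
  } else {
    # greedy: repeatedly take the largest remaining confusion cell
    best <- 0
    m <- as.matrix(conf)
    while (nrow(m) && ncol(m) && max(m) > 0) {
      ij <- which(m == max(m), arr.ind = TRUE)[1, ]
      best <- best + m[ij[1], ij[2]]
      m <- m[-ij[1], -ij[2], drop = FALSE]
    }
  }
  best / length(labels)
}
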