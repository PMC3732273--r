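# Deterministic sign convention: each coordinate column is flipped so that
# its largest-magnitude entry is positive (first such entry on ties).
sign_fix_columns <- function(M) {
  for (k in seq_len(ncol(M))) {
    i <- which.max(abs(M[, k]))
    if (M[i, k] < 0) M[, k] <- -M[, k]
  }
  M
}

new_embedding <- function(technique, coords, eigenvalues, extension_cache,
                          graph, ids) {
  rownames(coords) <- ids
  structure(list(technique = technique, coords = coords, d = ncol(coords),
                 eigenvalues = eigenvalues, extension_cache = extension_cache,
                 graph = graph, ids = ids),
            class = "manifold_embedding")
}

#' @export
print.manifold_embedding <- function(x, ...) {
  cat(sprintf("<manifold_embedding> %s: %d atlases -> %d dimensions (k_D = %d)\n",
              x$technique, nrow(x$coords), x$d, x$graph$k_D))
  invisible(x)
}

#' Isomap embedding of an atlas library
#'
#' Geodesic distances are taken as exact shortest paths on the weighted
#' neighbour graph, then classical multidimensional scaling is applied: the
#' squared-geodesic matrix is double-centred (\eqn{B = -\tfrac12 J G^2 J}),
#' and coordinate column \eqn{k} is \eqn{\sqrt{\lambda_k}\,v_k} for the top
#' positive eigenpairs of \eqn{B}. Global geodesic geometry is therefore
#' preserved as well as the metric allows.
#'
#' @param g A connected [build_knn_graph()] graph.
#' @param d Embedding dimension, `1 <= d <= n-1`. If `d` exceeds the number
#'   of positive eigenvalues the embedding is truncated with a warning.
#' @return A `manifold_embedding`; the extension cache stores the geodesic
#'   matrix, squared-geodesic column means and grand mean, and the eigenpairs
#'   used by the Nystrom out-of-sample formula.
#' @export
embed_isomap <- function(g, d) {
  n <- g$n
  d <- check_dim(d, n)
  G <- graph_geodesics(g)
  G2 <- G^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% G2 %*% J
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  pos <- which(eig$values > max(eig$values) * 1e-12 & eig$values > 0)
  if (length(pos) < d) {
    warning(sprintf("only %d positive eigenvalues; truncating d from %d",
                    length(pos), d), call. = FALSE)
    d <- length(pos)
  }
  lambda <- eig$values[seq_len(d)]
  V <- eig$vectors[, seq_len(d), drop = FALSE]
  coords <- sign_fix_columns(sweep(V, 2, sqrt(lambda), `*`))
  V <- sign_fix_columns(V)  # same sign convention as the coordinates
  cache <- list(geodesics = G, col_means_sq = colMeans(G2),
                grand_mean_sq = mean(G2), eigenvectors = V,
                eigenvalues = lambda)
  new_embedding("isomap", coords, lambda, cache, g, g$ids)
}

#' Locally Linear Embedding of an atlas library
#'
#' Each atlas is expressed as an affine combination of its `k_D` nearest
#' neighbours; the reconstruction weights are found from a local Gram matrix
#' assembled purely from metric distances,
#' \eqn{C_{jk} = \tfrac12 (D_{ij}^2 + D_{ik}^2 - D_{jk}^2)}, which equals the
#' centred inner-product Gram exactly because the rms field metric is
#' Euclidean on flattened displacement fields. The embedding coordinates are
#' the eigenvectors of \eqn{M = (I-W)^\top (I-W)} for the `d` smallest
#' non-trivial eigenvalues (the constant null vector is discarded).
#'
#' @param D A `distance_matrix`.
#' @param k_D Neighbours per point (at least `d` recommended).
#' @param d Embedding dimension.
#' @param reg Local Gram regularization: `reg * trace(C)` is added to the
#'   diagonal before solving, conditioning the system when `k_D` exceeds the
#'   local intrinsic dimension.
#' @param symmetrization Passed to [build_knn_graph()] (connectivity check).
#' @return A `manifold_embedding`; the extension cache stores the training
#'   distances, neighbour sets and regularization used for out-of-sample
#'   reconstruction.
#' @export
embed_lle <- function(D, k_D, d, reg = 1e-3,
                      symmetrization = c("union", "mutual")) {
  symmetrization <- match.arg(symmetrization)
  n <- nrow(D)
  d <- check_dim(d, n)
  g <- build_knn_graph(D, k_D, symmetrization)
  assert_connected(g)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nbrs <- g$knn[i, ]
    W[i, nbrs] <- lle_weights(D[i, nbrs], D[nbrs, nbrs, drop = FALSE], reg)
  }
  M <- crossprod(diag(n) - W)
  eig <- eigen((M + t(M)) / 2, symmetric = TRUE)
  vals <- rev(eig$values)                       # ascending
  vecs <- eig$vectors[, rev(seq_len(n)), drop = FALSE]
  # the constant eigenvector at eigenvalue 0 is discarded
  coords <- sign_fix_columns(vecs[, 1L + seq_len(d), drop = FALSE])
  cache <- list(train_D = as.matrix(D), k_D = as.integer(k_D), reg = reg)
  new_embedding("lle", coords, vals[1L + seq_len(d)], cache, g, g$ids)
}

# Affine reconstruction weights from distances: d_i = distances from the
# point to its neighbours, Dnn = neighbour-neighbour distances.
lle_weights <- function(d_i, Dnn, reg) {
  k <- length(d_i)
  C <- 0.5 * (outer(d_i^2, rep(1, k)) + outer(rep(1, k), d_i^2) - Dnn^2)
  C <- (C + t(C)) / 2
  tr <- sum(diag(C))
  C <- C + diag(reg * (if (tr > 0) tr else 1), k)
  w <- tryCatch(solve(C, rep(1, k)),
                error = function(e) stop("singular local Gram system in LLE even after regularization",
                                         call. = FALSE))
  w / sum(w)
}

#' Laplacian Eigenmaps embedding of an atlas library
#'
#' Graph edges are weighted with the heat kernel
#' \eqn{W_{ij} = \exp(-D_{ij}^2 / t)} (or 1 under `weights = "binary"`), and
#' the generalized eigenproblem \eqn{L f = \lambda\,\mathrm{Deg}\, f} with
#' \eqn{L = \mathrm{Deg} - W} is solved. The constant eigenvector at
#' \eqn{\lambda \approx 0} (unique on a connected graph) is discarded and the
#' next `d` eigenvectors, Deg-orthonormal and in ascending eigenvalue order,
#' form the coordinates.
#'
#' @param g A connected [build_knn_graph()] graph.
#' @param d Embedding dimension.
#' @param t Heat-kernel bandwidth (default 1, the value used throughout the
#'   optimization experiments); must be > 0.
#' @param weights `"heat"` or `"binary"`.
#' @return A `manifold_embedding`; `eigenvalues` excludes the trivial value,
#'   and the cache stores bandwidth, node degrees and the kernel-form
#'   eigenvalues \eqn{1 - \lambda_k} used for out-of-sample extension.
#' @export
embed_lem <- function(g, d, t = 1, weights = c("heat", "binary")) {
  weights <- match.arg(weights)
  if (t <= 0) stop("heat-kernel bandwidth t must be > 0", call. = FALSE)
  assert_connected(g)
  n <- g$n
  d <- check_dim(d, n)
  A <- g$adjacency
  W <- matrix(0, n, n)
  on_edge <- g$edges
  W[on_edge] <- if (weights == "heat") exp(-A[on_edge]^2 / t) else 1
  deg <- rowSums(W)
  s <- 1 / sqrt(deg)
  Lsym <- diag(n) - W * outer(s, s)  # Deg^{-1/2} (Deg - W) Deg^{-1/2}
  eig <- eigen((Lsym + t(Lsym)) / 2, symmetric = TRUE)
  vals <- rev(eig$values)
  vecs <- eig$vectors[, rev(seq_len(n)), drop = FALSE]
  if (vals[1] > 1e-9)
    warning("smallest Laplacian eigenvalue is not numerically zero", call. = FALSE)
  f <- vecs * s                       # back-transform to generalized eigenvectors
  keep <- 1L + seq_len(d)
  coords <- sign_fix_columns(f[, keep, drop = FALSE])
  lambda <- vals[keep]
  cache <- list(t = t, weights = weights, degrees = deg,
                kernel_eigenvalues = 1 - lambda,
                trivial_eigenvalue = vals[1])
  new_embedding("lem", coords, lambda, cache, g, g$ids)
}

check_dim <- function(d, n) {
  d <- as.integer(d)
  if (d < 1L || d > n - 1L)
    stop(sprintf("embedding dimension d must be in [1, %d]", n - 1L),
         call. = FALSE)
  d
}

#' Serialize embedding coordinates as TSV with a metadata sidecar
#'
#' Writes the coordinates as a TSV (id column plus one column per
#' dimension) and the embedding metadata (technique, d, k_D, symmetrization,
#' eigenvalues and, for lem, the kernel bandwidth) as a JSON sidecar named
#' `<path>.meta.json`. The serialized form documents an embedding; the live
#' R object additionally carries the caches needed by [extend()].
#'
#' @param e A `manifold_embedding`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(e, path) {
  tab <- data.frame(id = e$ids, e$coords, check.names = FALSE)
  names(tab)[-1] <- paste0("dim", seq_len(e$d))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(technique = e$technique, d = e$d, k_D = e$graph$k_D,
               symmetrization = e$graph$symmetrization,
               eigenvalues = as.numeric(e$eigenvalues))
  if (e$technique == "lem") meta$t <- e$extension_cache$t
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Compute an embedding by technique name
#'
#' Convenience dispatcher used by the pipeline and the leave-one-out driver.
#'
#' @param D A `distance_matrix`.
#' @param technique `"isomap"`, `"lle"` or `"lem"`.
#' @param d Embedding dimension.
#' @param k_D Graph neighbourhood size.
#' @param t Heat-kernel bandwidth (lem only).
#' @param reg Local Gram regularization (lle only).
#' @param symmetrization Graph symmetrization rule.
#' @return A `manifold_embedding`.
#' @export
compute_embedding <- function(D, technique = c("lle", "isomap", "lem"),
                              d, k_D, t = 1, reg = 1e-3,
                              symmetrization = "union") {
  technique <- match.arg(technique)
  switch(technique,
    isomap = {
      g <- build_knn_graph(D, k_D, symmetrization)
      embed_isomap(g, d)
    },
    lle = embed_lle(D, k_D, d, reg = reg, symmetrization = symmetrization),
    lem = {
      g <- build_knn_graph(D, k_D, symmetrization)
      embed_lem(g, d, t = t)
    })
}
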