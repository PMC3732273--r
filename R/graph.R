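#' k-nearest-neighbour graph on a distance matrix
#'
#' All three embedding techniques operate on a connected graph built with the
#' k-nearest-neighbour rule in the high-dimensional metric space. Under
#' `"union"` symmetrization an edge (i,j) exists if either node lists the
#' other among its `k_D` nearest; under `"mutual"`, only if both do. Edge
#' weights are the metric distances; ties in the neighbour ranking are broken
#' by the smaller index.
#'
#' @param D A `distance_matrix` (see [distance_matrix()]) or plain symmetric
#'   matrix.
#' @param k_D Neighbours per node, `1 <= k_D <= n-1`.
#' @param symmetrization `"union"` (default) or `"mutual"`.
#' @return An object of class `nn_graph` with fields `n`, `k_D`, `adjacency`
#'   (weighted, 0 = absent), `knn` (each node's own `k_D` nearest, a matrix),
#'   `symmetrization` and `ids`.
#' @export
build_knn_graph <- function(D, k_D, symmetrization = c("union", "mutual")) {
  symmetrization <- match.arg(symmetrization)
  n <- nrow(D)
  k_D <- as.integer(k_D)
  if (k_D < 1L || k_D > n - 1L)
    stop(sprintf("k_D must be in [1, %d]", n - 1L), call. = FALSE)
  ids <- attr(D, "ids")
  if (is.null(ids)) ids <- rownames(D)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  knn <- matrix(0L, n, k_D)
  for (i in seq_len(n)) {
    ord <- order(D[i, ], seq_len(n))        # stable: ties to smaller index
    ord <- ord[ord != i]
    knn[i, ] <- ord[seq_len(k_D)]
  }
  listed <- matrix(FALSE, n, n)
  for (i in seq_len(n)) listed[i, knn[i, ]] <- TRUE
  sym <- if (symmetrization == "union") listed | t(listed) else listed & t(listed)
  diag(sym) <- FALSE
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  A[sym] <- D[sym]
  # edge presence is kept separately from the weights: two coincident
  # atlases are joined by a legitimate zero-weight edge
  structure(list(n = n, k_D = k_D, adjacency = A, edges = sym, knn = knn,
                 symmetrization = symmetrization, ids = ids),
            class = "nn_graph")
}

#' @export
print.nn_graph <- function(x, ...) {
  cat(sprintf("<nn_graph> %d nodes, k_D = %d (%s), %d edges\n",
              x$n, x$k_D, x$symmetrization, sum(x$edges) / 2))
  invisible(x)
}

as_igraph <- function(g) {
  idx <- which(g$edges & upper.tri(g$edges), arr.ind = TRUE)
  ig <- igraph::make_empty_graph(n = g$n, directed = FALSE)
  ig <- igraph::add_edges(ig, as.vector(t(idx)))
  igraph::E(ig)$weight <- g$adjacency[idx]
  ig
}

#' Assert that a neighbour graph is connected
#'
#' The spectral embeddings are only well defined on a connected graph (and a
#' connected graph guarantees the Laplacian has exactly one trivial
#' eigenvalue). A disconnected graph signals that `k_D` is too small for the
#' library and raises an error of class `disconnected_graph` listing the
#' components.
#'
#' @param g An [build_knn_graph()] result.
#' @return Integer component labels (all 1 when connected), invisibly.
#' @export
assert_connected <- function(g) {
  comp <- igraph::components(as_igraph(g))$membership
  if (max(comp) > 1L) {
    sizes <- table(comp)
    stop(errorCondition(
      sprintf("neighbour graph is disconnected (k_D = %d too small): %d components of sizes %s",
              g$k_D, max(comp), paste(sizes, collapse = ", ")),
      class = c("disconnected_graph", "error"),
      components = as.integer(comp)))
  }
  invisible(as.integer(comp))
}

#' All-pairs geodesic distances on the neighbour graph
#'
#' Exact Dijkstra shortest paths on the weighted edges (no landmark
#' approximation; libraries here have order 10^2 nodes).
#'
#' @param g An [build_knn_graph()] result; must be connected.
#' @return n x n matrix of geodesic distances (mm).
#' @export
graph_geodesics <- function(g) {
  assert_connected(g)
  G <- igraph::distances(as_igraph(g), algorithm = "dijkstra")
  dimnames(G) <- list(g$ids, g$ids)
  G
}
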