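#' Nystrom out-of-sample extension of a target onto a learned manifold
#'
#' Positions a new image on a previously computed embedding from nothing but
#' its metric distances to the training atlases: no eigendecomposition is
#' redone and no displacement field is touched beyond the precomputed
#' distance vector, so an unseen target costs one registration to the average
#' atlas. The formula dispatches on the technique:
#'
#' * `isomap` — target geodesics are routed through the target's `k_D`
#'   nearest training points ("gateways"), then the kernel form of classical
#'   MDS gives coordinate \eqn{k} as
#'   \eqn{(2\sqrt{\lambda_k})^{-1} \sum_j v_{jk}\,(\bar g^2_j - g^2_{tj})}
#'   with \eqn{\bar g^2_j} the stored squared-geodesic column means.
#' * `lle` — affine reconstruction weights of the target from its `k_D`
#'   nearest training points (same local Gram and regularization as
#'   training), applied to the training coordinates. Exact for on-manifold
#'   points, no kernel eigen-inversion needed.
#' * `lem` — heat-kernel row over the target's `k_D` nearest training
#'   points, normalized by the target's kernel degree and divided by the
#'   kernel-form eigenvalues \eqn{1-\lambda_k}, which is the exactly
#'   self-consistent Nystrom rule for the generalized eigenproblem.
#'
#' A target at zero metric distance from a training atlas is
#' indistinguishable from it under the deformation metric and is returned at
#' that atlas's stored coordinates for every technique.
#'
#' @param e A `manifold_embedding`.
#' @param dists Length-n vector of target-to-atlas distances from
#'   [target_distances()], computed with the same metric variant as the
#'   embedding's distance matrix.
#' @param target_id Optional identifier carried into the result.
#' @param gateways `"knn"` (default): route isomap target geodesics through
#'   the target's `k_D` nearest training points only; `"all"`: through every
#'   training point.
#' @return A `target_embedding` with fields `coords` (length `e$d`),
#'   `technique` and `target_id`.
#' @export
extend <- function(e, dists, target_id = "target",
                   gateways = c("knn", "all")) {
  gateways <- match.arg(gateways)
  n <- length(e$ids)
  if (length(dists) != n)
    stop(sprintf("`dists` must have length %d (one per training atlas)", n),
         call. = FALSE)
  if (any(!is.finite(dists)) || any(dists < 0))
    stop("`dists` must be finite and non-negative", call. = FALSE)
  dists <- as.numeric(dists)

  hit <- which(dists <= max(dists) * 1e-15)
  if (length(hit) > 0L) {
    coords <- as.numeric(e$coords[hit[1], ])
  } else {
    k_D <- e$graph$k_D
    nbrs <- order(dists, seq_len(n))[seq_len(min(k_D, n))]
    coords <- switch(e$technique,
      isomap = {
        gw <- if (gateways == "knn") nbrs else seq_len(n)
        geo_t <- apply(e$extension_cache$geodesics[gw, , drop = FALSE] +
                         dists[gw], 2, min)
        x <- e$extension_cache$col_means_sq - geo_t^2
        as.numeric(crossprod(e$extension_cache$eigenvectors, x)) /
          (2 * sqrt(e$extension_cache$eigenvalues))
      },
      lle = {
        cache <- e$extension_cache
        w <- lle_weights(dists[nbrs],
                         cache$train_D[nbrs, nbrs, drop = FALSE], cache$reg)
        as.numeric(w %*% e$coords[nbrs, , drop = FALSE])
      },
      lem = {
        cache <- e$extension_cache
        K <- if (cache$weights == "heat") exp(-dists[nbrs]^2 / cache$t)
             else rep(1, length(nbrs))
        if (all(K == 0))
          stop("target kernel row is numerically zero: target too far from the manifold",
               call. = FALSE)
        as.numeric(crossprod(e$coords[nbrs, , drop = FALSE], K / sum(K))) /
          cache$kernel_eigenvalues
      },
      stop("unknown embedding technique", call. = FALSE))
  }
  structure(list(coords = coords, technique = e$technique,
                 target_id = target_id),
            class = "target_embedding")
}

#' @export
print.target_embedding <- function(x, ...) {
  cat(sprintf("<target_embedding> '%s' on %s manifold: (%s)\n",
              x$target_id, x$technique,
              paste(signif(x$coords, 4), collapse = ", ")))
  invisible(x)
}

#' Nearest atlases to a target on the manifold
#'
#' The embedded manifold lives in a Euclidean space, so atlas similarity to
#' the target is plain L2 distance between embedding coordinates. These
#' nearest atlases are the ones propagated to label fusion.
#'
#' @param e A `manifold_embedding`.
#' @param t A `target_embedding` from [extend()] with matching technique and
#'   dimension.
#' @param k_d Number of atlases to return, `1 <= k_d <= n`.
#' @return Character vector of `k_d` atlas ids, closest first, ties broken
#'   by smaller row index; the integer row indices are attached as attribute
#'   `"indices"`.
#' @export
nearest_on_manifold <- function(e, t, k_d) {
  if (!identical(e$technique, t$technique))
    stop("embedding and target embedding use different techniques", call. = FALSE)
  if (length(t$coords) != e$d)
    stop("target embedding dimension does not match the manifold", call. = FALSE)
  n <- nrow(e$coords)
  k_d <- as.integer(k_d)
  if (k_d < 1L || k_d > n)
    stop(sprintf("k_d must be in [1, %d]", n), call. = FALSE)
  d2 <- colSums((t(e$coords) - t$coords)^2)
  idx <- order(d2, seq_len(n))[seq_len(k_d)]
  structure(e$ids[idx], indices = idx)
}
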