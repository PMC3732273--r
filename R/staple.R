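#' Stack of rater decisions
#'
#' Bundles R binary segmentations of one volume (the "raters": here the
#' propagated label maps of the selected atlases) for fusion.
#'
#' @param maps List of [label_map()]s on one grid.
#' @param rater_ids Optional character ids (default `r1..rR`).
#' @return An object of class `rater_stack` with the decisions as an
#'   n-voxel x R 0/1 matrix plus the shared grid.
#' @export
rater_stack <- function(maps, rater_ids = NULL) {
  R <- length(maps)
  if (R < 1L) stop("need >= 1 rater", call. = FALSE)
  grid <- maps[[1]]$grid
  for (m in maps) check_same_grid(m, maps[[1]], "rater decisions")
  if (is.null(rater_ids)) rater_ids <- paste0("r", seq_len(R))
  D <- vapply(maps, function(m) as.integer(m$values), integer(n_voxels(grid)))
  colnames(D) <- rater_ids
  structure(list(decisions = D, grid = grid, rater_ids = rater_ids),
            class = "rater_stack")
}

#' @export
print.rater_stack <- function(x, ...) {
  cat(sprintf("<rater_stack> %d raters on %d voxels, vote range [%d, %d]\n",
              ncol(x$decisions), nrow(x$decisions),
              min(rowSums(x$decisions)), max(rowSums(x$decisions))))
  invisible(x)
}

# consensus codes
CONSENSUS_BG <- 0L
NON_CONSENSUS <- 1L
CONSENSUS_FG <- 2L

#' Split a volume into consensus and non-consensus regions
#'
#' Voxels where every rater agrees are consensus foreground/background; EM is
#' solved only on the remainder, which reduces the bias that large agreed
#' regions (mostly background) would otherwise exert on the performance
#' estimates.
#'
#' @param s A [rater_stack()].
#' @return 3-D integer array over the grid with codes 0 (consensus
#'   background), 1 (non-consensus), 2 (consensus foreground).
#' @export
consensus_split <- function(s) {
  votes <- rowSums(s$decisions)
  R <- ncol(s$decisions)
  code <- rep(NON_CONSENSUS, length(votes))
  code[votes == 0L] <- CONSENSUS_BG
  code[votes == R] <- CONSENSUS_FG
  array(code, dim = s$grid$dims)
}

# Linear indices of the 6-connected neighbours of the given voxels
# (nv x 6 matrix, NA where the neighbour falls outside the grid).
neighbour_indices_6 <- function(lin_idx, dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  i0 <- lin_idx - 1L
  x <- i0 %% nx
  y <- (i0 %/% nx) %% ny
  z <- i0 %/% (nx * ny)
  out <- matrix(NA_integer_, length(lin_idx), 6L)
  shift <- function(xx, yy, zz, ok) {
    r <- rep(NA_integer_, length(lin_idx))
    r[ok] <- xx[ok] + nx * (yy[ok] + ny * zz[ok]) + 1L
    r
  }
  out[, 1] <- shift(x - 1L, y, z, x > 0L)
  out[, 2] <- shift(x + 1L, y, z, x < nx - 1L)
  out[, 3] <- shift(x, y - 1L, z, y > 0L)
  out[, 4] <- shift(x, y + 1L, z, y < ny - 1L)
  out[, 5] <- shift(x, y, z - 1L, z > 0L)
  out[, 6] <- shift(x, y, z + 1L, z < nz - 1L)
  out
}

#' STAPLE fusion with mean-field MRF, solved on non-consensus voxels
#'
#' Simultaneous truth and performance level estimation: an EM loop that
#' alternates a per-voxel posterior for the true label (E-step) with
#' per-rater sensitivity/specificity estimates (M-step). The E-step updates
#' only the non-consensus voxels; consensus voxels keep their agreed label
#' with probability fixed at 0 or 1 and contribute those fixed values to the
#' M-step sums and, as neighbours, to the spatial term. Spatial consistency
#' is a Markov random field under the mean-field approximation: one sweep per
#' EM iteration adds \eqn{\beta \sum_{y \in N_6(x)} (2 W_y - 1)} to each
#' voxel's log-odds before normalization.
#'
#' @param s A [rater_stack()].
#' @param beta MRF strength, >= 0 (default 0.2; 0 disables the spatial term
#'   and yields classical STAPLE).
#' @param prior Prior probability that a voxel is foreground; default is the
#'   mean rater vote over the non-consensus region (prevalence is unknown).
#' @param init_p,init_q Initial sensitivity/specificity per rater.
#' @param tol Convergence threshold on the change of the mean of all
#'   performance parameters.
#' @param max_iter Iteration cap.
#' @param seed Accepted for call-signature stability across the pipeline;
#'   the algorithm is deterministic and draws no random numbers.
#' @return A `staple_result`: `probability` (3-D array in `[0,1]`), `fused`
#'   ([label_map()], threshold 0.5 with ties to foreground), `sensitivity`
#'   and `specificity` per rater, `iterations`, `converged`, `consensus`
#'   (the [consensus_split()] codes) and `loglik_trace` (observed-data
#'   log-likelihood over the non-consensus region per iteration).
#' @export
staple <- function(s, beta = 0.2, prior = NULL,
                   init_p = 0.99999, init_q = 0.99999,
                   tol = 1e-7, max_iter = 100L, seed = NULL) {
  if (beta < 0) stop("MRF strength beta must be >= 0", call. = FALSE)
  D <- s$decisions
  R <- ncol(D)
  cons <- consensus_split(s)
  code <- as.integer(cons)
  nc <- which(code == NON_CONSENSUS)
  W <- as.numeric(code == CONSENSUS_FG)  # fixed 0/1 on consensus voxels

  cons_fg <- code == CONSENSUS_FG
  cons_bg <- code == CONSENSUS_BG
  # fixed consensus contributions to the M-step sums
  fg_D <- colSums(D[cons_fg, , drop = FALSE])
  bg_notD <- colSums(1L - D[cons_bg, , drop = FALSE])
  n_fg_cons <- sum(cons_fg)
  n_bg_cons <- sum(cons_bg)

  if (length(nc) == 0L) {
    p <- pmin(pmax(fg_D / max(n_fg_cons, 1L), 1e-6), 1)
    q <- pmin(pmax(bg_notD / max(n_bg_cons, 1L), 1e-6), 1)
    if (n_fg_cons == 0L) p <- rep(1, R)
    if (n_bg_cons == 0L) q <- rep(1, R)
    return(new_staple_result(W, s, p, q, cons, 0L, TRUE, numeric(0)))
  }

  Dnc <- D[nc, , drop = FALSE]
  storage.mode(Dnc) <- "double"
  if (is.null(prior)) prior <- mean(Dnc)
  prior <- min(max(prior, 1e-6), 1 - 1e-6)

  degen <- apply(Dnc, 2, function(col) all(col == col[1]))
  if (any(degen))
    warning(sprintf("%d rater(s) are constant over the non-consensus region; their performance estimates are clamped",
                    sum(degen)), call. = FALSE)

  nbr <- if (beta > 0) neighbour_indices_6(nc, s$grid$dims) else NULL
  clamp <- function(v) pmin(pmax(v, 1e-6), 1 - 1e-6)
  p <- clamp(rep(init_p, R))
  q <- clamp(rep(init_q, R))
  loglik <- numeric(0)
  converged <- FALSE
  iter <- 0L

  # consensus voxels carry observed labels: their (fixed) complete-data terms
  # belong in the log-likelihood so the EM ascent property is visible
  cons_ll <- function(p, q) {
    n_fg_cons * log(prior) + sum(fg_D * log(p) + (n_fg_cons - fg_D) * log(1 - p)) +
      n_bg_cons * log(1 - prior) + sum(bg_notD * log(q) + (n_bg_cons - bg_notD) * log(1 - q))
  }

  while (iter < max_iter) {
    iter <- iter + 1L
    la <- log(prior) + Dnc %*% log(p) + (1 - Dnc) %*% log(1 - p)
    lb <- log(1 - prior) + Dnc %*% log(1 - q) + (1 - Dnc) %*% log(q)
    la <- as.numeric(la); lb <- as.numeric(lb)
    loglik <- c(loglik,
                sum(pmax(la, lb) + log1p(exp(-abs(la - lb)))) + cons_ll(p, q))
    logodds <- la - lb
    if (beta > 0) {
      Wn <- matrix(W[nbr], nrow = length(nc))      # NA where outside the grid
      logodds <- logodds + beta * rowSums(2 * Wn - 1, na.rm = TRUE)
    }
    W[nc] <- stats::plogis(logodds)

    Wnc <- W[nc]
    sum_w <- sum(Wnc) + n_fg_cons
    sum_nw <- (length(nc) - sum(Wnc)) + n_bg_cons
    p_new <- clamp((as.numeric(crossprod(Dnc, Wnc)) + fg_D) / sum_w)
    q_new <- clamp((as.numeric(crossprod(1 - Dnc, 1 - Wnc)) + bg_notD) / sum_nw)

    delta <- abs(mean(c(p_new, q_new)) - mean(c(p, q)))
    p <- p_new; q <- q_new
    if (delta < tol) { converged <- TRUE; break }
  }
  new_staple_result(W, s, p, q, cons, iter, converged, loglik)
}

new_staple_result <- function(W, s, p, q, cons, iterations, converged,
                              loglik) {
  prob <- array(W, dim = s$grid$dims)
  fused <- label_map(array(as.integer(W >= 0.5), dim = s$grid$dims), s$grid)
  names(p) <- names(q) <- s$rater_ids
  structure(list(probability = prob, fused = fused,
                 sensitivity = p, specificity = q,
                 iterations = iterations, converged = converged,
                 consensus = cons, loglik_trace = loglik,
                 rater_ids = s$rater_ids, grid = s$grid),
            class = "staple_result")
}

#' @export
print.staple_result <- function(x, ...) {
  cat(sprintf("<staple_result> %d raters, %d EM iterations (%s), fused volume %.1f mm^3\n",
              length(x$sensitivity), x$iterations,
              if (x$converged) "converged" else "not converged",
              volume_mm3(x$fused)))
  cat(sprintf("  sensitivity %.4f-%.4f, specificity %.4f-%.4f, %d non-consensus voxels\n",
              min(x$sensitivity), max(x$sensitivity),
              min(x$specificity), max(x$specificity),
              sum(x$consensus == NON_CONSENSUS)))
  invisible(x)
}

#' Segment a target by manifold selection and STAPLE fusion
#'
#' Selects the target's `k_d` nearest atlases on the manifold, stacks their
#' label maps as raters and fuses them with [staple()].
#'
#' @param e A `manifold_embedding` of the library.
#' @param t The target's `target_embedding` from [extend()].
#' @param library The [atlas_library()] the embedding was learned from.
#' @param k_d Number of atlases to fuse.
#' @param beta MRF strength passed to [staple()].
#' @param ... Further arguments passed to [staple()].
#' @return A `staple_result` with the selected atlas ids in field
#'   `selected_ids`.
#' @export
fuse_target <- function(e, t, library, k_d, beta = 0.2, ...) {
  if (!identical(e$ids, library$ids))
    stop("embedding and library atlas ids do not match", call. = FALSE)
  sel <- nearest_on_manifold(e, t, k_d)
  idx <- attr(sel, "indices")
  stack <- rater_stack(library_labels(library)[idx], rater_ids = as.character(sel))
  res <- staple(stack, beta = beta, ...)
  res$selected_ids <- as.character(sel)
  res
}
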