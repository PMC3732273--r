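#' Parameter grid for the leave-one-out search
#'
#' Axes of the 4-D mean-Dice matrix: manifold technique, embedding dimension
#' `d`, graph neighbourhood `k_D` and number of fused atlases `k_d`. The
#' default ranges mirror the neighbourhoods in which the published optima
#' were found (the exact swept ranges are configurable).
#'
#' @param techniques Subset of `c("lle", "isomap", "lem")`, in tie-break
#'   preference order.
#' @param d_values,k_D_values,k_d_values Positive integer axes.
#' @return An object of class `param_grid`.
#' @export
param_grid <- function(techniques = c("lle", "isomap", "lem"),
                       d_values = seq(1, 25, by = 2),
                       k_D_values = seq(5, 25, by = 2),
                       k_d_values = seq(1, 19, by = 2)) {
  techniques <- match.arg(techniques, several.ok = TRUE)
  stopifnot(length(d_values) > 0, length(k_D_values) > 0,
            length(k_d_values) > 0,
            all(d_values >= 1), all(k_D_values >= 1), all(k_d_values >= 1))
  structure(list(techniques = techniques,
                 d_values = as.integer(sort(unique(d_values))),
                 k_D_values = as.integer(sort(unique(k_D_values))),
                 k_d_values = as.integer(sort(unique(k_d_values)))),
            class = "param_grid")
}

#' Plain nearest-neighbour atlas selection in the high-dimensional space
#'
#' The no-manifold comparator ("BASE"): the `k_d` atlases with the smallest
#' metric distances to the target, no embedding involved. Downstream fusion
#' is identical to the manifold route, so any accuracy difference is
#' attributable to the selection step alone.
#'
#' @param D A `distance_matrix` (supplies the atlas ids).
#' @param target_dists Length-n vector of target-to-atlas metric distances.
#' @param k_d Number of atlases to select.
#' @return Character vector of `k_d` atlas ids, closest first, ties broken
#'   by smaller index; integer indices in attribute `"indices"`.
#' @export
base_selection <- function(D, target_dists, k_d) {
  n <- length(target_dists)
  k_d <- as.integer(k_d)
  if (k_d < 1L || k_d > n)
    stop(sprintf("k_d must be in [1, %d]", n), call. = FALSE)
  ids <- attr(D, "ids")
  if (is.null(ids)) ids <- rownames(D)
  idx <- order(target_dists, seq_len(n))[seq_len(k_d)]
  structure(ids[idx], indices = idx)
}

# Shared fold bookkeeping: which entries remain when entry f and its
# same-subject sibling (the flipped copy) are held out.
fold_keep <- function(library, f) {
  subjects <- library_subjects(library)
  which(subjects != subjects[f])
}

# Fuse the given library entries (by index) and score against truth.
fuse_and_score <- function(library, idx, truth, beta, ...) {
  stack <- rater_stack(library_labels(library)[idx],
                       rater_ids = library$ids[idx])
  res <- staple(stack, beta = beta, ...)
  dice(res$fused, truth)
}

new_loocv_cache <- function(library, variant) {
  cache <- new.env(parent = emptyenv())
  cache$D <- distance_matrix(library, variant = variant)
  cache$variant <- variant
  cache$embeddings <- new.env(parent = emptyenv())
  cache$fusions <- new.env(parent = emptyenv())
  cache
}

# Embedding for one fold at >= d dimensions, from the cache when present.
fold_embedding <- function(cache, library, keep, f, technique, d, k_D,
                           t, reg) {
  key <- paste(f, technique, k_D, sep = "|")
  e <- cache$embeddings[[key]]
  if (is.null(e) || attr(e, "requested_d") < d) {
    want <- min(max(d, cache$d_max %||% d), length(keep) - 1L)
    D_sub <- new_distance_matrix(cache$D[keep, keep, drop = FALSE],
                                 attr(cache$D, "ids")[keep], cache$variant)
    e <- compute_embedding(D_sub, technique, d = want, k_D = k_D,
                           t = t, reg = reg)
    attr(e, "requested_d") <- want
    cache$embeddings[[key]] <- e
  }
  slice_embedding(e, d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Restrict an embedding to its first d coordinate columns. Valid because all
# three techniques order columns by their canonical eigenvalue ordering and
# each column's value, sign rule and extension formula are independent of d.
slice_embedding <- function(e, d) {
  # e$d can fall short of d when isomap truncated to the positive spectrum
  if (e$d <= d) return(e)
  e$coords <- e$coords[, seq_len(d), drop = FALSE]
  e$eigenvalues <- e$eigenvalues[seq_len(d)]
  if (e$technique == "isomap") {
    e$extension_cache$eigenvectors <-
      e$extension_cache$eigenvectors[, seq_len(d), drop = FALSE]
    e$extension_cache$eigenvalues <- e$extension_cache$eigenvalues[seq_len(d)]
  } else if (e$technique == "lem") {
    e$extension_cache$kernel_eigenvalues <-
      e$extension_cache$kernel_eigenvalues[seq_len(d)]
  }
  e$d <- d
  e
}

#' Leave-one-out accuracy of one parameter combination
#'
#' For each library entry: hold out the entry and every entry of the same
#' subject (its mid-sagittally flipped sibling), compute the distance matrix
#' on the remainder, learn the manifold, extend it with the held-out target's
#' distances, select its `k_d` nearest atlases on the manifold, fuse them
#' with STAPLE, and score Dice against the held-out manual labels. The cell
#' value is the mean over all folds.
#'
#' A disconnected neighbour graph in any fold marks the whole cell missing
#' (`mean = NA`) with the count of failed folds, rather than silently
#' embedding a sub-population.
#'
#' @param library An [atlas_library()] whose entries carry `subject_id` and
#'   `laterality`.
#' @param technique `"lle"`, `"isomap"` or `"lem"`.
#' @param d,k_D,k_d Embedding dimension, graph neighbourhood, fused-atlas
#'   count.
#' @param beta STAPLE MRF strength.
#' @param variant Metric variant for [distance_matrix()].
#' @param t,reg Technique hyperparameters (see [compute_embedding()]).
#' @param cache Internal: a shared cache created by [grid_search()]; the
#'   result is identical with or without it.
#' @return List with `mean`, `sd`, `per_target` (named Dice vector) and
#'   `n_failed` folds.
#' @export
loocv_cell <- function(library, technique, d, k_D, k_d, beta = 0.2,
                       variant = "rms", t = 1, reg = 1e-3, cache = NULL) {
  n <- length(library)
  if (is.null(cache)) cache <- new_loocv_cache(library, variant)
  per <- rep(NA_real_, n)
  names(per) <- library$ids
  failed <- 0L
  for (f in seq_len(n)) {
    keep <- fold_keep(library, f)
    if (length(keep) - 1L < k_D)
      stop(sprintf("fold %d leaves %d atlases; k_D = %d needs more", f,
                   length(keep), k_D), call. = FALSE)
    if (length(keep) - 1L < d)
      stop(sprintf("fold %d leaves %d atlases; d = %d needs more", f,
                   length(keep), d), call. = FALSE)
    res <- tryCatch({
      e <- fold_embedding(cache, library, keep, f, technique, d, k_D, t, reg)
      dists <- as.numeric(cache$D[f, keep])
      te <- extend(e, dists, target_id = library$ids[f])
      sel <- nearest_on_manifold(e, te, k_d)
      idx_sub <- attr(sel, "indices")
      fkey <- paste(f, paste(sort(keep[idx_sub]), collapse = ","), sep = "|")
      dc <- cache$fusions[[fkey]]
      if (is.null(dc)) {
        dc <- fuse_and_score(library, keep[idx_sub],
                             library$entries[[f]]$labels, beta)
        cache$fusions[[fkey]] <- dc
      }
      dc
    }, disconnected_graph = function(cond) NA_real_)
    if (is.na(res)) failed <- failed + 1L
    per[f] <- res
  }
  if (failed > 0L)
    list(mean = NA_real_, sd = NA_real_, per_target = per, n_failed = failed)
  else
    list(mean = mean(per), sd = stats::sd(per), per_target = per,
         n_failed = 0L)
}

#' Leave-one-out accuracy of BASE (no-manifold) selection
#'
#' Same folds and fusion as [loocv_cell()] but atlases are selected with
#' [base_selection()] directly in the high-dimensional metric space, no
#' embedding involved. The downstream code path (STAPLE fusion, Dice) is
#' shared with the manifold route, so the two differ only in selection.
#'
#' @inheritParams loocv_cell
#' @return List with `mean`, `sd` and `per_target` Dice.
#' @export
loocv_base <- function(library, k_d, beta = 0.2, variant = "rms",
                       cache = NULL) {
  n <- length(library)
  if (is.null(cache)) cache <- new_loocv_cache(library, variant)
  per <- rep(NA_real_, n)
  names(per) <- library$ids
  for (f in seq_len(n)) {
    keep <- fold_keep(library, f)
    D_sub <- new_distance_matrix(cache$D[keep, keep, drop = FALSE],
                                 attr(cache$D, "ids")[keep], variant)
    sel <- base_selection(D_sub, as.numeric(cache$D[f, keep]), k_d)
    idx <- keep[attr(sel, "indices")]
    fkey <- paste(f, paste(sort(idx), collapse = ","), sep = "|")
    dc <- cache$fusions[[fkey]]
    if (is.null(dc)) {
      dc <- fuse_and_score(library, idx, library$entries[[f]]$labels, beta)
      cache$fusions[[fkey]] <- dc
    }
    per[f] <- dc
  }
  list(mean = mean(per), sd = stats::sd(per), per_target = per)
}

#' Leave-one-out grid search over technique and parameters
#'
#' Fills the 4-D matrix of mean Dice indices over (technique, d, k_D, k_d)
#' via [loocv_cell()], sharing the distance matrix, per-fold embeddings
#' (computed once at the largest `d` and sliced) and fusion results across
#' cells, and reports the argmax. Ties are broken by technique order as
#' listed in the grid, then smaller `d`, `k_D`, `k_d`.
#'
#' @param library An [atlas_library()].
#' @param grid A [param_grid()].
#' @param beta,variant,t,reg As in [loocv_cell()].
#' @param progress Print one line per (technique, k_D) block.
#' @return A `grid_result`: `mean_dice` and `sd_dice` (4-D named arrays with
#'   `NA` marking missing cells), `n_failed`, `best` (named list with the
#'   winning coordinates and its mean/sd), and the `grid`.
#' @export
grid_search <- function(library, grid, beta = 0.2, variant = "rms",
                        t = 1, reg = 1e-3, progress = FALSE) {
  stopifnot(inherits(grid, "param_grid"))
  cache <- new_loocv_cache(library, variant)
  cache$d_max <- max(grid$d_values)
  dn <- list(technique = grid$techniques,
             d = as.character(grid$d_values),
             k_D = as.character(grid$k_D_values),
             k_d = as.character(grid$k_d_values))
  shape <- lengths(dn)
  mean_dice <- sd_dice <- array(NA_real_, dim = shape, dimnames = dn)
  n_failed <- array(0L, dim = shape, dimnames = dn)
  for (ti in seq_along(grid$techniques)) {
    for (ki in seq_along(grid$k_D_values)) {
      if (progress)
        message(sprintf("grid: technique %s, k_D = %d",
                        grid$techniques[ti], grid$k_D_values[ki]))
      for (di in seq_along(grid$d_values)) {
        for (si in seq_along(grid$k_d_values)) {
          cell <- loocv_cell(library, grid$techniques[ti],
                             grid$d_values[di], grid$k_D_values[ki],
                             grid$k_d_values[si], beta = beta,
                             variant = variant, t = t, reg = reg,
                             cache = cache)
          mean_dice[ti, di, ki, si] <- cell$mean
          sd_dice[ti, di, ki, si] <- cell$sd
          n_failed[ti, di, ki, si] <- cell$n_failed
        }
      }
    }
  }
  if (all(is.na(mean_dice)))
    stop("every grid cell is missing (disconnected graphs throughout)",
         call. = FALSE)
  best <- find_best_cell(mean_dice, sd_dice, grid)
  structure(list(mean_dice = mean_dice, sd_dice = sd_dice,
                 n_failed = n_failed, best = best, grid = grid),
            class = "grid_result")
}

# Argmax over present cells; iteration order implements the tie-break
# (technique as listed, then smaller d, k_D, k_d) with strict improvement.
find_best_cell <- function(mean_dice, sd_dice, grid) {
  best <- NULL
  for (ti in seq_along(grid$techniques))
    for (di in seq_along(grid$d_values))
      for (ki in seq_along(grid$k_D_values))
        for (si in seq_along(grid$k_d_values)) {
          v <- mean_dice[ti, di, ki, si]
          if (!is.na(v) && (is.null(best) || v > best$mean)) {
            best <- list(technique = grid$techniques[ti],
                         d = grid$d_values[di],
                         k_D = grid$k_D_values[ki],
                         k_d = grid$k_d_values[si],
                         mean = v, sd = sd_dice[ti, di, ki, si])
          }
        }
  best
}

#' @export
print.grid_result <- function(x, ...) {
  b <- x$best
  cat(sprintf("<grid_result> %d cells (%d missing); best: %s, d = %d, k_D = %d, k_d = %d -> mean Dice %.4f (SD %.4f)\n",
              length(x$mean_dice), sum(is.na(x$mean_dice)),
              b$technique, b$d, b$k_D, b$k_d, b$mean, b$sd))
  invisible(x)
}

#' Long-format export of a grid result
#'
#' @param x A `grid_result`.
#' @param path Optional TSV path to write.
#' @return A data.frame with one row per cell (invisibly when written).
#' @export
grid_result_table <- function(x, path = NULL) {
  g <- x$grid
  rows <- expand.grid(k_d = g$k_d_values, k_D = g$k_D_values,
                      d = g$d_values, technique = g$techniques,
                      stringsAsFactors = FALSE)[, 4:1]
  rows$mean_dice <- as.numeric(aperm(x$mean_dice, c(4, 3, 2, 1)))
  rows$sd_dice <- as.numeric(aperm(x$sd_dice, c(4, 3, 2, 1)))
  rows$n_failed <- as.integer(aperm(x$n_failed, c(4, 3, 2, 1)))
  if (!is.null(path)) {
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(rows))
  }
  rows
}
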