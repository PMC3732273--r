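#' Deformation-field distance between two images
#'
#' Both images are represented by the displacement fields relating them to a
#' common average atlas, so their dissimilarity is measured by how differently
#' they deform toward that reference, with no pairwise registration. With
#' voxel-wise difference magnitudes \eqn{m(x) = \lVert u_a(x) - u_b(x) \rVert}
#' over the N grid voxels, the `rms` variant returns
#' \eqn{\sqrt{(1/N) \sum_x m(x)^2}} and the `mean_magnitude` variant
#' \eqn{(1/N) \sum_x m(x)}. Both are norm-induced metrics in mm; `rms` is
#' additionally Euclidean on the flattened fields (scaled by \eqn{1/\sqrt N}),
#' which the locally-linear-embedding Gram construction exploits.
#'
#' @param u_a,u_b [displacement_field()] objects on one grid.
#' @param variant `"rms"` (default) or `"mean_magnitude"`.
#' @param mask Optional [label_map()]; restricts the sum to its foreground.
#'   By default all grid voxels enter the sum.
#' @return Non-negative distance in mm.
#' @export
field_distance <- function(u_a, u_b, variant = c("rms", "mean_magnitude"),
                           mask = NULL) {
  variant <- match.arg(variant)
  check_same_grid(u_a, u_b, "displacement fields")
  da <- matrix(u_a$vectors, ncol = 3)
  db <- matrix(u_b$vectors, ncol = 3)
  sq <- rowSums((da - db)^2)
  if (!is.null(mask)) {
    check_same_grid(u_a, mask, "field and mask")
    keep <- as.logical(mask$values)
    if (!any(keep)) stop("mask has no foreground voxels", call. = FALSE)
    sq <- sq[keep]
  }
  if (variant == "rms") sqrt(mean(sq)) else mean(sqrt(sq))
}

#' Pairwise distance matrix of an atlas library
#'
#' All \eqn{n(n-1)/2} distances are evaluated from the stored fields to the
#' average atlas, avoiding any pairwise registration.
#'
#' @param library An [atlas_library()] with >= 2 entries.
#' @inheritParams field_distance
#' @return A `distance_matrix`: symmetric n x n matrix (mm) with zero
#'   diagonal, atlas ids as dimnames, and attributes `ids` and `variant`.
#' @export
distance_matrix <- function(library, variant = c("rms", "mean_magnitude"),
                            mask = NULL) {
  variant <- match.arg(variant)
  n <- length(library)
  if (n < 2L) stop("need >= 2 atlases for a distance matrix", call. = FALSE)
  fields <- library_fields(library)
  if (variant == "rms" && is.null(mask)) {
    # rms is Euclidean on flattened fields: one call to dist() does all pairs
    F <- t(vapply(fields, function(f) as.numeric(f$vectors),
                  numeric(length(fields[[1]]$vectors))))
    D <- as.matrix(stats::dist(F)) / sqrt(n_voxels(library$grid))
    dimnames(D) <- list(library$ids, library$ids)
  } else {
    D <- matrix(0, n, n, dimnames = list(library$ids, library$ids))
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        D[i, j] <- D[j, i] <- field_distance(fields[[i]], fields[[j]],
                                             variant = variant, mask = mask)
      }
    }
  }
  new_distance_matrix(D, library$ids, variant)
}

new_distance_matrix <- function(values, ids, variant) {
  structure(values, ids = ids, variant = variant,
            class = c("distance_matrix", "matrix", "array"))
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> %d atlases, variant '%s', range [0, %.4g] mm\n",
              nrow(x), attr(x, "variant"), max(x)))
  invisible(x)
}

#' Distances from a target image to every library atlas
#'
#' The target is represented by its displacement field to the same average
#' atlas; one registration to the reference yields its distance to every
#' atlas by field subtraction.
#'
#' @param u_target The target's [displacement_field()].
#' @inheritParams distance_matrix
#' @return Named numeric vector of length `length(library)`, mm.
#' @export
target_distances <- function(u_target, library,
                             variant = c("rms", "mean_magnitude"),
                             mask = NULL) {
  variant <- match.arg(variant)
  if (!grids_equal(u_target$grid, library$grid))
    stop_grid_mismatch("target field and library")
  d <- vapply(library_fields(library),
              function(f) field_distance(u_target, f, variant = variant,
                                         mask = mask),
              numeric(1))
  names(d) <- library$ids
  d
}

#' Write / read a distance matrix as TSV
#'
#' Plain-text serialization with an id header row and an id first column; the
#' metric variant is recorded in a `# variant:` comment line.
#'
#' @param D A `distance_matrix`.
#' @param path Output path.
#' @return `path` (write) or a `distance_matrix` (read).
#' @export
write_distance_matrix <- function(D, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# variant: %s", attr(D, "variant")), con)
  writeLines(paste(c("id", attr(D, "ids")), collapse = "\t"), con)
  ids <- attr(D, "ids")
  for (i in seq_len(nrow(D)))
    writeLines(paste(c(ids[i], format(D[i, ], digits = 17)), collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  lines <- readLines(path)
  variant <- sub("^# variant: *", "", lines[1])
  tab <- utils::read.delim(text = lines[-1], check.names = FALSE,
                           stringsAsFactors = FALSE)
  ids <- as.character(tab$id)
  M <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(M) <- "double"
  dimnames(M) <- list(ids, ids)
  new_distance_matrix(M, ids, variant)
}
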