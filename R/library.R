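#' Atlas library
#'
#' An ordered collection of atlases sharing one voxel grid. Each entry pairs
#' a binary label map with the displacement field relating that atlas to the
#' common average atlas, and carries a subject identifier plus a laterality
#' flag (`"native"` or `"flipped"`): mid-sagittal flipping doubles a
#' left-hippocampus library into left+right entries, and leave-one-out folds
#' must exclude both hippocampi of the held-out subject.
#'
#' @param entries A list; each element a list with fields `id` (unique
#'   character), `labels` ([label_map()]), `field` ([displacement_field()]),
#'   `subject_id` (character) and `laterality` (`"native"` or `"flipped"`).
#' @return An object of class `atlas_library`.
#' @export
atlas_library <- function(entries) {
  if (length(entries) == 0L) stop("an atlas library needs >= 1 entry", call. = FALSE)
  grid <- entries[[1]]$labels$grid
  ids <- character(length(entries))
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    if (is.null(e$id) || is.null(e$labels) || is.null(e$field) ||
        is.null(e$subject_id) || is.null(e$laterality))
      stop("each entry needs id, labels, field, subject_id, laterality", call. = FALSE)
    if (!e$laterality %in% c("native", "flipped"))
      stop("laterality must be 'native' or 'flipped'", call. = FALSE)
    if (!grids_equal(e$labels$grid, grid) || !grids_equal(e$field$grid, grid))
      stop_grid_mismatch(sprintf("library entry '%s' and the library", e$id))
    ids[i] <- e$id
  }
  if (anyDuplicated(ids)) stop("atlas ids must be unique", call. = FALSE)
  structure(list(entries = entries, grid = grid, ids = ids),
            class = "atlas_library")
}

#' @export
print.atlas_library <- function(x, ...) {
  nf <- sum(vapply(x$entries, function(e) e$laterality == "flipped", logical(1)))
  cat(sprintf("<atlas_library> %d atlases (%d flipped) on a %d x %d x %d grid\n",
              length(x$entries), nf,
              x$grid$dims[1], x$grid$dims[2], x$grid$dims[3]))
  invisible(x)
}

#' @export
length.atlas_library <- function(x) length(x$entries)

#' Subset an atlas library by position or id
#' @param x An [atlas_library()].
#' @param i Integer positions or character ids to keep, in order.
#' @param ... Ignored.
#' @return An [atlas_library()] with the selected entries.
#' @export
`[.atlas_library` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$ids)
  if (anyNA(i)) stop("unknown atlas id in subset", call. = FALSE)
  atlas_library(x$entries[i])
}

#' Double a library by mid-sagittal flipping
#'
#' Appends, for every native entry, a flipped sibling whose label map and
#' displacement field are reflected across the mid-sagittal plane (with the
#' left-right vector component negated). The sibling keeps its subject id so
#' leave-one-out folds can exclude both sides of a subject.
#'
#' @param library An [atlas_library()] of native entries.
#' @param suffix Appended to each native id to form the flipped id.
#' @return An [atlas_library()] of twice the size.
#' @export
augment_with_flipped <- function(library, suffix = "_flip") {
  if (any(vapply(library$entries, function(e) e$laterality == "flipped", logical(1))))
    stop("library already contains flipped entries", call. = FALSE)
  flipped <- lapply(library$entries, function(e) {
    list(id = paste0(e$id, suffix),
         labels = flip_mid_sagittal(e$labels),
         field = flip_mid_sagittal(e$field),
         subject_id = e$subject_id,
         laterality = "flipped")
  })
  atlas_library(c(library$entries, flipped))
}

library_fields <- function(library) lapply(library$entries, `[[`, "field")
library_labels <- function(library) lapply(library$entries, `[[`, "labels")
library_subjects <- function(library)
  vapply(library$entries, `[[`, character(1), "subject_id")
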