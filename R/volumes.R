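#' Voxel grid geometry
#'
#' A `voxel_grid` records the geometry shared by every volume in an atlas
#' library: integer dimensions, physical voxel spacing in mm, a physical
#' origin, and which voxel axis runs left-right (the sagittal axis, used by
#' [flip_mid_sagittal()]).
#'
#' @param dims Integer vector of length 3, voxel counts per axis (all >= 1).
#' @param spacing Numeric vector of length 3, voxel spacing in mm (all > 0).
#' @param origin Numeric vector of length 3, physical position of voxel
#'   (1,1,1) in mm.
#' @param sagittal_axis Which voxel axis (1, 2 or 3) is the left-right axis.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(dims, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       sagittal_axis = 1L) {
  dims <- as.integer(dims)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(dims) != 3L || any(dims < 1L))
    stop("`dims` must be three integers >= 1", call. = FALSE)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive values (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite values (mm)", call. = FALSE)
  sagittal_axis <- as.integer(sagittal_axis)
  if (!sagittal_axis %in% 1:3)
    stop("`sagittal_axis` must be 1, 2 or 3", call. = FALSE)
  structure(
    list(dims = dims, spacing = spacing, origin = origin,
         sagittal_axis = sagittal_axis),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm, sagittal axis %d\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3], x$sagittal_axis))
  invisible(x)
}

#' Number of voxels on a grid
#' @param grid A [voxel_grid()].
#' @return Integer voxel count (the N of the deformation metric).
#' @export
n_voxels <- function(grid) prod(grid$dims)

#' Test two grids for equality
#'
#' Dimensions must match exactly; spacing and origin within `tol` mm.
#'
#' @param a,b [voxel_grid()] objects.
#' @param tol Tolerance in mm for spacing/origin comparison.
#' @return Logical scalar.
#' @export
grids_equal <- function(a, b, tol = 1e-6) {
  identical(a$dims, b$dims) &&
    all(abs(a$spacing - b$spacing) <= tol) &&
    all(abs(a$origin - b$origin) <= tol)
}

stop_grid_mismatch <- function(what = "volumes") {
  stop(errorCondition(sprintf("%s are not on the same voxel grid", what),
                      class = c("grid_mismatch", "error")))
}

check_same_grid <- function(a, b, what = "volumes") {
  if (!grids_equal(a$grid, b$grid)) stop_grid_mismatch(what)
  invisible(TRUE)
}

#' Binary label map on a voxel grid
#'
#' Values are stored as a 3-D 0/1 integer array; any nonzero input value is
#' treated as foreground (manual masks are stored with heterogeneous positive
#' labels).
#'
#' @param values 3-D numeric/integer/logical array.
#' @param grid A [voxel_grid()]; its dims must match `dim(values)`.
#' @return An object of class `label_map`.
#' @export
label_map <- function(values, grid) {
  if (length(dim(values)) != 3L)
    stop("label map values must be a 3-D array", call. = FALSE)
  if (!identical(as.integer(dim(values)), grid$dims))
    stop("label map dimensions do not match the grid", call. = FALSE)
  if (any(!is.finite(values)))
    stop("label map contains non-finite values", call. = FALSE)
  v <- array(as.integer(values != 0), dim = grid$dims)
  structure(list(values = v, grid = grid), class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %d x %d x %d, %d foreground voxels (%.1f mm^3)\n",
              x$grid$dims[1], x$grid$dims[2], x$grid$dims[3],
              sum(x$values), volume_mm3(x)))
  invisible(x)
}

#' Displacement field on a voxel grid
#'
#' Per-voxel 3-vectors in mm, stored as a 4-D array with the vector component
#' as the last axis, expressed in the image's physical axis frame. A field
#' relates an image to the common average atlas and is the high-dimensional
#' representation of that image in this framework.
#'
#' @param vectors 4-D numeric array, `dim = c(grid$dims, 3)`.
#' @param grid A [voxel_grid()].
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(vectors, grid) {
  d <- dim(vectors)
  if (length(d) != 4L || d[4] != 3L)
    stop("displacement field must be a 4-D array with last axis of length 3",
         call. = FALSE)
  if (!identical(as.integer(d[1:3]), grid$dims))
    stop("displacement field dimensions do not match the grid", call. = FALSE)
  if (any(!is.finite(vectors)))
    stop("displacement field contains non-finite vectors", call. = FALSE)
  structure(list(vectors = array(as.numeric(vectors), dim = d), grid = grid),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  mags <- sqrt(rowSums(matrix(x$vectors, ncol = 3)^2))
  cat(sprintf("<displacement_field> %d x %d x %d, |u| mean %.3g mm, max %.3g mm\n",
              x$grid$dims[1], x$grid$dims[2], x$grid$dims[3],
              mean(mags), max(mags)))
  invisible(x)
}

#' Flip a volume across the mid-sagittal plane
#'
#' Reverses voxel order along the grid's designated sagittal (left-right)
#' axis. For a displacement field the sagittal vector component is
#' additionally negated, so the flipped field is the field of the mirrored
#' anatomy. Flipping left-hippocampus atlases yields valid right-hippocampus
#' atlases and doubles an atlas library.
#'
#' @param x A [label_map()] or [displacement_field()].
#' @return An object of the same class as `x`.
#' @export
flip_mid_sagittal <- function(x) UseMethod("flip_mid_sagittal")

flip_axis_index <- function(n) rev(seq_len(n))

#' @export
flip_mid_sagittal.label_map <- function(x) {
  ax <- x$grid$sagittal_axis
  idx <- list(seq_len(x$grid$dims[1]), seq_len(x$grid$dims[2]),
              seq_len(x$grid$dims[3]))
  idx[[ax]] <- flip_axis_index(x$grid$dims[ax])
  label_map(x$values[idx[[1]], idx[[2]], idx[[3]], drop = FALSE], x$grid)
}

#' @export
flip_mid_sagittal.displacement_field <- function(x) {
  ax <- x$grid$sagittal_axis
  idx <- list(seq_len(x$grid$dims[1]), seq_len(x$grid$dims[2]),
              seq_len(x$grid$dims[3]))
  idx[[ax]] <- flip_axis_index(x$grid$dims[ax])
  v <- x$vectors[idx[[1]], idx[[2]], idx[[3]], , drop = FALSE]
  v[, , , ax] <- -v[, , , ax]
  displacement_field(v, x$grid)
}
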