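#' Read a binary label map from a NIfTI-1 file
#'
#' The volume must be 3-D; any nonzero voxel is binarized to foreground.
#' Voxel spacing is taken from the header; the sagittal (left-right) axis
#' defaults to the first voxel axis unless overridden.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param sagittal_axis Voxel axis designated left-right (default 1).
#' @return A [label_map()].
#' @export
read_label_map <- function(path, sagittal_axis = 1L) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- a[, , , 1]
  if (length(dim(a)) != 3L)
    stop(sprintf("expected a 3-D label volume, got %d dimensions",
                 length(dim(a))), call. = FALSE)
  grid <- grid_from_header(img, dim(a), sagittal_axis)
  label_map(a, grid)
}

#' Write a label map as NIfTI-1
#'
#' @param x A [label_map()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_label_map <- function(x, path) {
  img <- RNifti::asNifti(array(as.integer(x$values), dim = x$grid$dims))
  img <- RNifti::`pixdim<-`(img, x$grid$spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a displacement field from a 4-D NIfTI-1 file
#'
#' The file must store a vector volume with the component axis last and of
#' length 3; vectors are interpreted in mm in the grid's physical axes.
#'
#' @inheritParams read_label_map
#' @param reference_grid Optional [voxel_grid()] the field must match.
#' @return A [displacement_field()].
#' @export
read_displacement_field <- function(path, sagittal_axis = 1L,
                                    reference_grid = NULL) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  d <- dim(a)
  if (length(d) == 5L && d[4] == 1L) {  # NIfTI vector convention: dim5 holds components
    a <- a[, , , 1, , drop = TRUE]
    d <- dim(a)
  }
  if (length(d) != 4L || d[4] != 3L)
    stop("expected a 4-D volume with a vector component axis of length 3",
         call. = FALSE)
  grid <- grid_from_header(img, d[1:3], sagittal_axis)
  if (!is.null(reference_grid) && !grids_equal(grid, reference_grid))
    stop_grid_mismatch("displacement field and reference grid")
  displacement_field(a, grid)
}

#' Write a displacement field as 4-D NIfTI-1
#'
#' @param x A [displacement_field()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_displacement_field <- function(x, path) {
  img <- RNifti::asNifti(x$vectors)
  img <- RNifti::`pixdim<-`(img, c(x$grid$spacing, 1))
  RNifti::writeNifti(img, path)
  invisible(path)
}

grid_from_header <- function(img, dims, sagittal_axis) {
  pd <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(pd)) || any(pd <= 0)) pd <- c(1, 1, 1)
  xf <- try(RNifti::xform(img), silent = TRUE)
  origin <- if (inherits(xf, "try-error")) c(0, 0, 0) else as.numeric(xf[1:3, 4])
  voxel_grid(dims, pd, origin, sagittal_axis)
}
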