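# Run `expr` with a private RNG stream: seeds locally, restores any global
# .Random.seed afterwards.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Smooth, spatially bounded vector basis fields: a separable sine window
# (zero on the grid boundary) times a cosine of distinct frequency along a
# distinct axis, acting on one vector component. Deterministic by index.
phantom_basis_field <- function(m, dims, spacing, amplitude) {
  p <- lapply(1:3, function(ax) {
    if (dims[ax] == 1L) rep(0.5, 1) else (seq_len(dims[ax]) - 1) / (dims[ax] - 1)
  })
  w1 <- sin(pi * p[[1]]); w2 <- sin(pi * p[[2]]); w3 <- sin(pi * p[[3]])
  window <- outer(outer(w1, w2), w3)
  comp <- ((m - 1L) %% 3L) + 1L
  axis <- (m %% 3L) + 1L
  freq <- 1L + (m - 1L) %/% 3L
  phase <- 0.4 * m
  osc1d <- cos(pi * freq * p[[axis]] + phase)
  osc <- switch(axis,
    outer(outer(osc1d, rep(1, dims[2])), rep(1, dims[3])),
    outer(outer(rep(1, dims[1]), osc1d), rep(1, dims[3])),
    outer(outer(rep(1, dims[1]), rep(1, dims[2])), osc1d))
  field <- array(0, dim = c(dims, 3))
  field[, , , comp] <- amplitude * window * osc
  field
}

ellipsoid_template <- function(grid, radii_frac = c(0.32, 0.26, 0.22)) {
  dims <- grid$dims
  centre <- (dims + 1) / 2
  radii <- pmax(radii_frac * dims, 1.5)
  x <- (seq_len(dims[1]) - centre[1]) / radii[1]
  y <- (seq_len(dims[2]) - centre[2]) / radii[2]
  z <- (seq_len(dims[3]) - centre[3]) / radii[3]
  v <- outer(outer(x^2, y^2, `+`), z^2, `+`) <= 1
  label_map(array(as.integer(v), dim = dims), grid)
}

# Nearest-neighbour pull-back: label(x) = template(round(x - u(x)/spacing)).
warp_label_nn <- function(template, field) {
  dims <- template$grid$dims
  sp <- template$grid$spacing
  idx <- arrayInd(seq_len(prod(dims)), dims)
  src <- idx - round(sweep(matrix(field$vectors, ncol = 3), 2, sp, `/`))
  ok <- src[, 1] >= 1 & src[, 1] <= dims[1] &
        src[, 2] >= 1 & src[, 2] <= dims[2] &
        src[, 3] >= 1 & src[, 3] <= dims[3]
  v <- integer(prod(dims))
  v[ok] <- template$values[src[ok, , drop = FALSE]]
  label_map(array(v, dim = dims), template$grid)
}

# Approximate Jacobian determinant of x -> x - u(x) by central differences;
# a non-positive value means the warp folds onto itself.
min_jacobian <- function(field) {
  sp <- field$grid$spacing
  J11 <- 1 - grad_axis(field$vectors[, , , 1], 1, sp[1])
  J22 <- 1 - grad_axis(field$vectors[, , , 2], 2, sp[2])
  J33 <- 1 - grad_axis(field$vectors[, , , 3], 3, sp[3])
  J12 <- -grad_axis(field$vectors[, , , 1], 2, sp[2])
  J13 <- -grad_axis(field$vectors[, , , 1], 3, sp[3])
  J21 <- -grad_axis(field$vectors[, , , 2], 1, sp[1])
  J23 <- -grad_axis(field$vectors[, , , 2], 3, sp[3])
  J31 <- -grad_axis(field$vectors[, , , 3], 1, sp[1])
  J32 <- -grad_axis(field$vectors[, , , 3], 2, sp[2])
  det <- J11 * (J22 * J33 - J23 * J32) -
         J12 * (J21 * J33 - J23 * J31) +
         J13 * (J21 * J32 - J22 * J31)
  min(det)
}

# Central-difference gradient of a 3-D array along one axis (one-sided at
# the boundary), in physical units given voxel size h.
grad_axis <- function(a, axis, h) {
  d <- dim(a)
  n <- d[axis]
  if (n < 2L) return(array(0, dim = d))
  idx_hi <- idx_lo <- lapply(d, seq_len)
  idx_hi[[axis]] <- pmin(seq_len(n) + 1L, n)
  idx_lo[[axis]] <- pmax(seq_len(n) - 1L, 1L)
  diff <- a[idx_hi[[1]], idx_hi[[2]], idx_hi[[3]], drop = FALSE] -
          a[idx_lo[[1]], idx_lo[[2]], idx_lo[[3]], drop = FALSE]
  per <- (idx_hi[[axis]] - idx_lo[[axis]]) * h
  span <- switch(axis,
    array(per, dim = d),
    aperm(array(per, dim = d[c(2, 1, 3)]), c(2, 1, 3)),
    aperm(array(per, dim = d[c(3, 1, 2)]), c(2, 3, 1)))
  diff / span
}

#' Generate a synthetic atlas library with known latent structure
#'
#' Builds n phantom atlases whose displacement fields are exact linear
#' combinations of `q` fixed smooth basis vector fields,
#' \eqn{u_i = \sum_m \theta_{im} b_m}, with latent coordinates
#' \eqn{\theta_i} sampled uniformly on \eqn{[-1,1]^q}. Because the rms field
#' metric is Euclidean on flattened fields, the squared distance between two
#' phantoms is the exact quadratic form
#' \eqn{(\theta_i - \theta_j)^\top G\, (\theta_i - \theta_j)} in the basis
#' Gram matrix `G` (see [latent_gram()]): latent geometry maps isometrically
#' into metric space, giving every manifold and out-of-sample test an
#' analytic ground truth. Label maps are an ellipsoid template warped by each
#' field with nearest-neighbour pull-back, so truth stays binary.
#'
#' Optionally, `noise_dim` additional high-frequency basis fields with
#' random per-atlas coefficients are added to the *stored* fields (not to
#' the anatomy that generates the labels), emulating registration error that
#' perturbs the high-dimensional representation without changing the true
#' segmentation.
#'
#' @param n Number of phantoms (>= 4).
#' @param q Latent dimension (>= 1).
#' @param grid_dims Voxel dimensions (default 16^3).
#' @param amplitude Basis-field scale in mm; must keep all warps invertible
#'   (checked via the approximate Jacobian).
#' @param seed Integer seed; the whole set is a deterministic function of it.
#' @param spacing Voxel spacing in mm.
#' @param noise_dim Number of high-frequency noise basis fields (0 = none).
#' @param noise_amplitude Standard deviation of the noise coefficients.
#' @param label_sensitivity,label_specificity Simulated manual-rater
#'   performance applied to each stored atlas label (the anatomy itself stays
#'   exact): each true-foreground voxel is kept with probability
#'   `label_sensitivity` and each background voxel flipped with probability
#'   `1 - label_specificity`. The defaults of 1 produce exact labels;
#'   values of about 0.97/0.999 emulate the intra-rater variability of a
#'   manual protocol (two such raters overlap at Dice about 0.96).
#' @return An object of class `phantom_set` with fields `latent` (n x q),
#'   `library` ([atlas_library()]), `reference` (the unwarped template
#'   [label_map()], the exact theta = 0 phantom), `basis`, `amplitude`,
#'   `seed` and (when used) `noise`.
#' @export
generate_library <- function(n, q, grid_dims = c(16, 16, 16),
                             amplitude = 1.8, seed = 1,
                             spacing = c(1, 1, 1),
                             noise_dim = 0, noise_amplitude = 0,
                             label_sensitivity = 1, label_specificity = 1) {
  n <- as.integer(n); q <- as.integer(q)
  if (n < 4L) stop("need n >= 4 phantoms", call. = FALSE)
  if (q < 1L) stop("latent dimension q must be >= 1", call. = FALSE)
  grid <- voxel_grid(grid_dims, spacing)
  template <- ellipsoid_template(grid)
  basis <- lapply(seq_len(q), phantom_basis_field, dims = grid$dims,
                  spacing = spacing, amplitude = amplitude)
  if (label_sensitivity <= 0 || label_sensitivity > 1 ||
      label_specificity <= 0 || label_specificity > 1)
    stop("label noise rates must lie in (0, 1]", call. = FALSE)
  noise <- NULL
  noise_basis <- if (noise_dim > 0)
    lapply(q + seq_len(noise_dim), phantom_basis_field,
           dims = grid$dims, spacing = spacing, amplitude = 1)
  built <- with_seed(seed, {
    theta <- matrix(stats::runif(n * q, -1, 1), n, q)
    eta <- if (noise_dim > 0)
      matrix(stats::rnorm(n * noise_dim, sd = noise_amplitude), n, noise_dim)
    entries <- vector("list", n)
    for (i in seq_len(n)) {
      anat <- combine_basis(basis, theta[i, ], grid)
      check_invertible(anat, i)
      labels <- warp_label_nn(template, anat)
      if (label_sensitivity < 1 || label_specificity < 1) {
        fg <- labels$values == 1L
        v <- integer(length(labels$values))
        v[fg] <- stats::rbinom(sum(fg), 1L, label_sensitivity)
        v[!fg] <- stats::rbinom(sum(!fg), 1L, 1 - label_specificity)
        labels <- label_map(array(v, dim = grid$dims), grid)
      }
      field <- anat
      if (noise_dim > 0) {
        nz <- combine_basis(noise_basis, eta[i, ], grid)
        field <- displacement_field(anat$vectors + nz$vectors, grid)
      }
      entries[[i]] <- list(id = sprintf("phantom%03d", i),
                           labels = labels, field = field,
                           subject_id = sprintf("subj%03d", i),
                           laterality = "native")
    }
    list(theta = theta, eta = eta, entries = entries)
  })
  theta <- built$theta
  entries <- built$entries
  if (noise_dim > 0)
    noise <- list(dim = as.integer(noise_dim), amplitude = noise_amplitude,
                  coeffs = built$eta, basis = noise_basis)
  structure(list(latent = theta, library = atlas_library(entries),
                 reference = template, basis = basis, amplitude = amplitude,
                 seed = seed, noise = noise),
            class = "phantom_set")
}

combine_basis <- function(basis, coeffs, grid) {
  acc <- array(0, dim = c(grid$dims, 3))
  for (m in seq_along(basis)) acc <- acc + coeffs[m] * basis[[m]]
  displacement_field(acc, grid)
}

check_invertible <- function(field, i) {
  if (min_jacobian(field) <= 0)
    stop(sprintf("amplitude too large: warp %d self-folds (non-positive Jacobian)", i),
         call. = FALSE)
  invisible(TRUE)
}

#' @export
print.phantom_set <- function(x, ...) {
  cat(sprintf("<phantom_set> %d phantoms, latent dim %d, amplitude %.3g mm, seed %d%s\n",
              nrow(x$latent), ncol(x$latent), x$amplitude, x$seed,
              if (is.null(x$noise)) ""
              else sprintf(", + %d noise fields (sd %.3g)",
                           x$noise$dim, x$noise$amplitude)))
  invisible(x)
}

#' Basis Gram matrix of a phantom set
#'
#' \eqn{G_{ml} = (1/N) \sum_x b_m(x) \cdot b_l(x)} so that the squared rms
#' field distance between phantoms i and j equals
#' \eqn{(\theta_i - \theta_j)^\top G (\theta_i - \theta_j)} exactly.
#'
#' @param ps A [generate_library()] result.
#' @return q x q positive semi-definite matrix (mm^2).
#' @export
latent_gram <- function(ps) {
  q <- length(ps$basis)
  N <- n_voxels(ps$reference$grid)
  G <- matrix(0, q, q)
  flat <- lapply(ps$basis, function(b) as.numeric(b))
  for (m in seq_len(q))
    for (l in m:q)
      G[m, l] <- G[l, m] <- sum(flat[[m]] * flat[[l]]) / N
  G
}

#' Construct an out-of-sample target phantom
#'
#' Built exactly as library entries (same template, basis and warp rule) but
#' not added to the library; its true label map serves as ground truth for
#' segmentation accuracy.
#'
#' @param ps A [generate_library()] result.
#' @param theta Latent coordinates, length q.
#' @return List with `truth` ([label_map()]) and `field`
#'   ([displacement_field()]).
#' @export
make_target <- function(ps, theta) {
  q <- ncol(ps$latent)
  if (length(theta) != q)
    stop(sprintf("theta must have length %d", q), call. = FALSE)
  grid <- ps$reference$grid
  field <- combine_basis(ps$basis, theta, grid)
  check_invertible(field, 0L)
  list(truth = warp_label_nn(ps$reference, field), field = field)
}

#' Simulate noisy raters from a known truth
#'
#' Each rater keeps every true-foreground voxel with probability `p`
#' (sensitivity) and flips every true-background voxel with probability
#' `1 - q_spec` (specificity `q_spec`), independently. Drives the STAPLE
#' parameter-recovery tests.
#'
#' @param truth A [label_map()].
#' @param p True sensitivity in (0, 1].
#' @param q_spec True specificity in (0, 1].
#' @param R Number of raters.
#' @param seed Integer seed.
#' @return A [rater_stack()].
#' @export
simulate_raters <- function(truth, p, q_spec, R, seed = 1) {
  if (p <= 0 || p > 1 || q_spec <= 0 || q_spec > 1)
    stop("p and q_spec must lie in (0, 1]", call. = FALSE)
  fg <- truth$values == 1L
  nfg <- sum(fg); nbg <- sum(!fg)
  maps <- with_seed(seed, {
    lapply(seq_len(R), function(r) {
      v <- integer(length(truth$values))
      v[fg] <- stats::rbinom(nfg, 1L, p)
      v[!fg] <- stats::rbinom(nbg, 1L, 1 - q_spec)
      label_map(array(v, dim = truth$grid$dims), truth$grid)
    })
  })
  rater_stack(maps)
}
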