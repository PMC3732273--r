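# Shared fixture builders and independent oracles. Everything is generated
# in code; expensive phantom sets are memoized for the duration of the run.

rand_field <- function(grid, seed, scale = 1) {
  set.seed(seed)
  displacement_field(array(stats::rnorm(prod(grid$dims) * 3, sd = scale),
                           dim = c(grid$dims, 3)), grid)
}

rand_label <- function(grid, seed, p_fg = 0.3) {
  set.seed(seed)
  label_map(array(stats::rbinom(prod(grid$dims), 1, p_fg), dim = grid$dims),
            grid)
}

# Brute-force field distance: explicit per-voxel loop, no linear algebra.
brute_field_distance <- function(u_a, u_b, variant = "rms") {
  dims <- u_a$grid$dims
  total <- 0
  for (k in seq_len(dims[3]))
    for (j in seq_len(dims[2]))
      for (i in seq_len(dims[1])) {
        dx <- u_a$vectors[i, j, k, 1] - u_b$vectors[i, j, k, 1]
        dy <- u_a$vectors[i, j, k, 2] - u_b$vectors[i, j, k, 2]
        dz <- u_a$vectors[i, j, k, 3] - u_b$vectors[i, j, k, 3]
        m2 <- dx^2 + dy^2 + dz^2
        total <- total + if (variant == "rms") m2 else sqrt(m2)
      }
  if (variant == "rms") sqrt(total / prod(dims)) else total / prod(dims)
}

# Brute-force k-nearest neighbours per row, ties to the smaller index.
ref_knn <- function(D, k) {
  out <- matrix(0L, nrow(D), k)
  for (i in seq_len(nrow(D))) {
    ord <- order(D[i, ], seq_len(ncol(D)))
    out[i, ] <- ord[ord != i][seq_len(k)]
  }
  out
}

# Library of identical atlases (degenerate geometry, Dice must be 1).
identical_library <- function(n = 6, dims = c(8, 8, 8)) {
  g <- voxel_grid(dims)
  lm <- label_map(array(as.integer(seq_len(prod(dims)) %% 7 == 0),
                        dim = dims), g)
  df <- displacement_field(array(0.5, dim = c(dims, 3)), g)
  atlas_library(lapply(seq_len(n), function(i)
    list(id = paste0("a", i), labels = lm, field = df,
         subject_id = paste0("s", i), laterality = "native")))
}

local_fixture_cache <- new.env(parent = emptyenv())
memo <- function(key, expr) {
  if (is.null(local_fixture_cache[[key]]))
    local_fixture_cache[[key]] <- force(expr)
  local_fixture_cache[[key]]
}

# The study conditions: 30 phantoms, 3 latent dims, rater-noise labels.
study_phantoms <- function() {
  memo("study", generate_library(n = 30, q = 3, grid_dims = c(16, 16, 16),
                                 amplitude = 1.8, seed = 5,
                                 label_sensitivity = 0.97,
                                 label_specificity = 0.999))
}

# Exact-label variant for geometric (manifold / out-of-sample) oracles.
clean_phantoms <- function() {
  memo("clean", generate_library(n = 30, q = 3, grid_dims = c(16, 16, 16),
                                 amplitude = 1.8, seed = 11))
}

# Latent coordinates mapped isometrically into metric space: theta %*% G^{1/2}.
latent_iso <- function(ps) {
  G <- latent_gram(ps)
  eg <- eigen(G, symmetric = TRUE)
  ps$latent %*% (eg$vectors %*% diag(sqrt(pmax(eg$values, 0)),
                                     length(eg$values)) %*% t(eg$vectors))
}

# Similarity-Procrustes residual of X onto Y (rotation/reflection, scale,
# translation), relative to Y's centred rms scale.
procrustes_residual <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  s <- svd(crossprod(Yc, Xc))
  R <- s$v %*% t(s$u)
  scl <- sum(s$d) / sum(Xc^2)
  resid <- Yc - scl * Xc %*% R
  sqrt(mean(rowSums(resid^2))) / sqrt(mean(rowSums(Yc^2)))
}

# Independent per-voxel STAPLE EM (beta = 0), written as plain loops against
# the definition: posterior on non-consensus voxels, performance parameters
# from all voxels with consensus posteriors fixed at their labels.
staple_em_oracle <- function(decisions, init_p = 0.99999, init_q = 0.99999,
                             tol = 1e-7, max_iter = 100) {
  V <- nrow(decisions); R <- ncol(decisions)
  votes <- rowSums(decisions)
  is_fg <- votes == R
  is_bg <- votes == 0
  nc <- which(!is_fg & !is_bg)
  W <- ifelse(is_fg, 1, 0)
  prior <- mean(decisions[nc, , drop = FALSE])
  prior <- min(max(prior, 1e-6), 1 - 1e-6)
  p <- rep(init_p, R); q <- rep(init_q, R)
  clamp <- function(v) pmin(pmax(v, 1e-6), 1 - 1e-6)
  for (it in seq_len(max_iter)) {
    for (x in nc) {
      a <- prior; b <- 1 - prior
      for (r in seq_len(R)) {
        if (decisions[x, r] == 1) { a <- a * p[r]; b <- b * (1 - q[r]) }
        else { a <- a * (1 - p[r]); b <- b * q[r] }
      }
      W[x] <- a / (a + b)
    }
    p_new <- q_new <- numeric(R)
    for (r in seq_len(R)) {
      num_p <- den_p <- num_q <- den_q <- 0
      for (x in seq_len(V)) {
        num_p <- num_p + W[x] * decisions[x, r]
        den_p <- den_p + W[x]
        num_q <- num_q + (1 - W[x]) * (1 - decisions[x, r])
        den_q <- den_q + (1 - W[x])
      }
      p_new[r] <- clamp(num_p / den_p)
      q_new[r] <- clamp(num_q / den_q)
    }
    delta <- abs(mean(c(p_new, q_new)) - mean(c(p, q)))
    p <- p_new; q <- q_new
    if (delta < tol) break
  }
  list(W = W, p = p, q = q)
}
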