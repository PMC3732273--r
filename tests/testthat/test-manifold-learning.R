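line_distance_matrix <- function(x) {
  D <- abs(outer(x, x, `-`))
  atlasmanifold:::new_distance_matrix(D, as.character(seq_along(x)), "rms")
}

test_that("k-NN graph matches a brute-force neighbour sort and handles ties by index", {
  # 3 nodes, k_D = 2 -> complete graph
  D3 <- line_distance_matrix(c(0, 1, 2.5))
  g3 <- build_knn_graph(D3, 2)
  expect_true(all(g3$edges[upper.tri(g3$edges)]))

  # collinear points, k_D = 1, union: only path-adjacent pairs
  Dl <- line_distance_matrix(0:9)
  gl <- build_knn_graph(Dl, 1)
  adj <- which(gl$edges, arr.ind = TRUE)
  expect_true(all(abs(adj[, 1] - adj[, 2]) == 1))

  set.seed(77)
  X <- matrix(rnorm(24), 12, 2)
  D <- atlasmanifold:::new_distance_matrix(as.matrix(dist(X)),
                                           as.character(1:12), "rms")
  for (k in c(1, 3, 5)) {
    g <- build_knn_graph(D, k)
    expect_identical(g$knn, ref_knn(D, k))
    # union: every node's own k nearest are adjacent to it
    for (i in 1:12) expect_true(all(g$edges[i, g$knn[i, ]]))
    # mutual is a subgraph of union
    gm <- build_knn_graph(D, k, "mutual")
    expect_true(all(!gm$edges | g$edges))
  }
  expect_error(build_knn_graph(D, 0), "k_D")
  expect_error(build_knn_graph(D, 12), "k_D")
})

test_that("connectivity assertion labels components and flags disconnection", {
  D3 <- line_distance_matrix(c(0, 1, 2))
  expect_equal(assert_connected(build_knn_graph(D3, 2)), rep(1L, 3))
  expect_equal(assert_connected(build_knn_graph(line_distance_matrix(0:9), 1)),
               rep(1L, 10))

  # two clusters 100 units apart, k_D too small to bridge them
  x <- c(0, 1, 2, 3, 100, 101, 102, 103)
  err <- tryCatch(assert_connected(build_knn_graph(line_distance_matrix(x), 2)),
                  disconnected_graph = function(e) e)
  expect_s3_class(err, "disconnected_graph")
  expect_equal(max(err$components), 2L)
})

test_that("isomap preserves geodesics on a flat manifold and is deterministic", {
  Dl <- line_distance_matrix(as.numeric(0:9))
  g <- build_knn_graph(Dl, 2)
  e <- embed_isomap(g, 1)
  emb_d <- as.matrix(dist(e$coords))
  expect_equal(max(abs(emb_d - unclass(Dl))), 0, tolerance = 1e-9)
  e2 <- embed_isomap(build_knn_graph(Dl, 2), 1)
  expect_identical(e$coords, e2$coords)
})

test_that("isomap recovers a 2-D latent family up to similarity", {
  ps <- generate_library(n = 200, q = 2, grid_dims = c(12, 12, 12),
                         amplitude = 1.8, seed = 42)
  D <- distance_matrix(ps$library)
  e <- embed_isomap(build_knn_graph(D, 10), 2)
  expect_lt(procrustes_residual(e$coords, latent_iso(ps)), 0.1)
})

test_that("LLE weights are affine, reconstruct affine-patch points, and match the vector Gram", {
  # points exactly on a 2-D affine patch of a 10-D space
  set.seed(5)
  theta <- matrix(runif(60, -1, 1), 30, 2)
  B <- matrix(rnorm(20), 2, 10)
  X <- sweep(theta %*% B, 2, rnorm(10), `+`)
  D <- atlasmanifold:::new_distance_matrix(as.matrix(dist(X)),
                                           as.character(1:30), "rms")
  g <- build_knn_graph(D, 5)
  for (i in 1:30) {
    nbrs <- g$knn[i, ]
    w <- atlasmanifold:::lle_weights(D[i, nbrs], D[nbrs, nbrs], reg = 1e-10)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    resid <- X[i, ] - as.numeric(w %*% X[nbrs, ])
    expect_lt(sqrt(sum(resid^2)), 1e-8)
  }

  # distance-based local Gram equals the centred inner-product Gram
  i <- 7; nbrs <- g$knn[i, ]
  C_dist <- 0.5 * (outer(D[i, nbrs]^2, rep(1, 5)) +
                     outer(rep(1, 5), D[i, nbrs]^2) -
                     D[nbrs, nbrs]^2)
  Xi <- sweep(X[nbrs, ], 2, X[i, ])
  expect_equal(C_dist, Xi %*% t(Xi), tolerance = 1e-9, ignore_attr = TRUE)

  # full embedding: every weight row of a default fit sums to 1
  e <- embed_lle(D, k_D = 5, d = 2)
  expect_equal(dim(e$coords), c(30, 2))
  expect_true(all(is.finite(e$coords)))
})

test_that("Laplacian eigenmaps yields Deg-orthonormal coordinates with the trivial mode discarded", {
  ps <- clean_phantoms()
  D <- distance_matrix(ps$library)
  g <- build_knn_graph(D, 8)
  e <- embed_lem(g, 3)

  W <- matrix(0, g$n, g$n)
  W[g$edges] <- exp(-g$adjacency[g$edges]^2 / 1)
  Deg <- diag(rowSums(W))
  FtDF <- t(e$coords) %*% Deg %*% e$coords
  expect_equal(FtDF, diag(3), tolerance = 1e-8, ignore_attr = TRUE)
  expect_lt(e$extension_cache$trivial_eigenvalue, 1e-9)
  # eigenvalue equation holds for the kept pairs (trivial constant mode gone)
  L <- Deg - W
  for (k in 1:3)
    expect_equal(as.numeric(L %*% e$coords[, k]),
                 e$eigenvalues[k] * as.numeric(Deg %*% e$coords[, k]),
                 tolerance = 1e-8)
  expect_error(embed_lem(g, 3, t = 0), "t must be")
})

test_that("LEM embedding of a path graph is monotone and matches a dense generalized solver", {
  Dl <- line_distance_matrix(as.numeric(0:9))
  g <- build_knn_graph(Dl, 1)
  e <- embed_lem(g, 1)
  expect_true(all(diff(e$coords[, 1]) > 0) || all(diff(e$coords[, 1]) < 0))

  # independent oracle: non-symmetric dense solve of Deg^{-1} L
  W <- matrix(0, 10, 10)
  W[g$edges] <- exp(-g$adjacency[g$edges]^2)
  Deg <- diag(rowSums(W))
  eo <- eigen(solve(Deg) %*% (Deg - W))
  ord <- order(Re(eo$values))
  f2 <- Re(eo$vectors[, ord[2]])
  expect_equal(abs(cor(f2, e$coords[, 1])), 1, tolerance = 1e-8)
  expect_equal(Re(eo$values[ord[2]]), e$eigenvalues[1], tolerance = 1e-8)
})

test_that("embeddings are permutation-equivariant and mutually distinct", {
  ps <- clean_phantoms()
  D <- distance_matrix(ps$library)
  n <- nrow(D)
  set.seed(123)
  perm <- sample(n)
  Dp <- atlasmanifold:::new_distance_matrix(D[perm, perm],
                                            attr(D, "ids")[perm], "rms")
  embs <- list()
  for (tech in c("isomap", "lle", "lem")) {
    e <- compute_embedding(D, tech, d = 3, k_D = 8)
    ep <- compute_embedding(Dp, tech, d = 3, k_D = 8)
    expect_equal(ep$coords, e$coords[perm, ], tolerance = 1e-6,
                 ignore_attr = TRUE)
    embs[[tech]] <- e$coords
  }
  # different objective functions produce measurably different embeddings
  expect_gt(procrustes_residual(embs$isomap, embs$lle), 1e-6)
  expect_gt(procrustes_residual(embs$isomap, embs$lem), 1e-6)
  expect_gt(procrustes_residual(embs$lle, embs$lem), 1e-6)
})

test_that("embeddings serialize to TSV with a metadata sidecar", {
  ps <- clean_phantoms()
  e <- compute_embedding(distance_matrix(ps$library), "lem", d = 2, k_D = 8)
  path <- tempfile(fileext = ".tsv")
  write_embedding(e, path)
  tab <- read.delim(path)
  expect_equal(dim(tab), c(30, 3))
  expect_equal(as.matrix(tab[, 2:3]), unname(e$coords), tolerance = 1e-12,
               ignore_attr = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  expect_equal(meta$technique, "lem")
  expect_equal(meta$k_D, 8)
  expect_equal(meta$t, 1)
  expect_length(meta$eigenvalues, 2)
  unlink(c(path, paste0(path, ".meta.json")))
})

test_that("all techniques preserve latent neighbourhoods better than a random embedding", {
  ps <- clean_phantoms()
  D <- distance_matrix(ps$library)
  lat <- latent_iso(ps)
  n <- nrow(lat)
  knn_of <- function(M, k = 7) {
    dd <- as.matrix(dist(M))
    t(sapply(seq_len(n), function(i) {
      ord <- order(dd[i, ], seq_len(n)); ord[ord != i][seq_len(k)]
    }))
  }
  lat_nn <- knn_of(lat)
  overlap <- function(M) {
    nn <- knn_of(M)
    mean(sapply(seq_len(n), function(i)
      length(intersect(nn[i, ], lat_nn[i, ])) / 7))
  }
  set.seed(99)
  random_overlap <- overlap(matrix(runif(n * 3), n, 3))
  for (tech in c("isomap", "lle", "lem"))
    expect_gt(overlap(compute_embedding(D, tech, d = 3, k_D = 8)$coords),
              random_overlap)
})
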