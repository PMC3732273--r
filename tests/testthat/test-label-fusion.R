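half_split_stack <- function() {
  g <- voxel_grid(c(8, 8, 8))
  v1 <- v2 <- array(0L, dim = g$dims)
  v1[1:4, , ] <- 1L
  v2[5:8, , ] <- 1L
  rater_stack(list(label_map(v1, g), label_map(v2, g)))
}

test_that("consensus split separates agreed and disputed voxels", {
  g <- voxel_grid(c(6, 6, 6))
  lm <- rand_label(g, seed = 42)
  same <- rater_stack(list(lm, lm, lm))
  cons <- consensus_split(same)
  expect_equal(sum(cons == 1L), 0)

  # complementary half-masks: everything is disputed
  cons2 <- consensus_split(half_split_stack())
  expect_true(all(cons2 == 1L))

  # counts match a brute-force per-voxel check
  set.seed(9)
  maps <- lapply(1:4, function(i) rand_label(g, seed = 50 + i))
  s <- rater_stack(maps)
  cons3 <- consensus_split(s)
  votes <- rowSums(s$decisions)
  expect_equal(as.integer(cons3),
               ifelse(votes == 4, 2L, ifelse(votes == 0, 0L, 1L)))
})

test_that("unanimous raters short-circuit to their shared mask with perfect performance", {
  g <- voxel_grid(c(6, 6, 6))
  lm <- rand_label(g, seed = 3)
  res <- staple(rater_stack(list(lm, lm, lm)))
  expect_identical(res$fused$values, lm$values)
  expect_equal(unname(res$sensitivity), rep(1, 3))
  expect_equal(unname(res$specificity), rep(1, 3))
  expect_equal(res$iterations, 0L)
})

test_that("beta = 0 STAPLE matches an independently coded per-voxel EM to 1e-10", {
  # 2 x 2 x 1 toy with fixed decision patterns: one consensus-fg voxel,
  # three disputed voxels
  g <- voxel_grid(c(2, 2, 1))
  mk <- function(v) label_map(array(v, dim = g$dims), g)
  s <- rater_stack(list(mk(c(1, 0, 1, 0)), mk(c(1, 1, 0, 0)),
                        mk(c(1, 0, 0, 1))))
  res <- staple(s, beta = 0)
  oracle <- staple_em_oracle(s$decisions)
  expect_equal(as.numeric(res$probability), oracle$W, tolerance = 1e-10)
  expect_equal(unname(res$sensitivity), oracle$p, tolerance = 1e-10)
  expect_equal(unname(res$specificity), oracle$q, tolerance = 1e-10)

  # also on a larger random stack
  g2 <- voxel_grid(c(5, 4, 3))
  maps <- lapply(1:4, function(i) rand_label(g2, seed = 70 + i, p_fg = 0.4))
  s2 <- rater_stack(maps)
  res2 <- staple(s2, beta = 0)
  o2 <- staple_em_oracle(s2$decisions)
  expect_equal(as.numeric(res2$probability), o2$W, tolerance = 1e-10)
  expect_equal(unname(res2$sensitivity), o2$p, tolerance = 1e-10)
})

test_that("STAPLE recovers simulated rater performance and beats no fusion", {
  g <- voxel_grid(c(24, 24, 24))
  truth <- atlasmanifold:::ellipsoid_template(g)
  s <- simulate_raters(truth, p = 0.90, q_spec = 0.95, R = 9, seed = 7)
  res <- staple(s, beta = 0)
  expect_lt(mean(abs(res$sensitivity - 0.90)), 0.03)
  expect_lt(mean(abs(res$specificity - 0.95)), 0.03)
  majority <- label_map(array(as.integer(rowSums(s$decisions) * 2 >
                                           ncol(s$decisions)),
                              dim = g$dims), g)
  expect_gte(dice(res$fused, truth), dice(majority, truth))
  expect_gt(dice(res$fused, truth), 0.99)
  expect_gt(dice(res$fused, truth),
            dice(label_map(array(s$decisions[, 1], dim = g$dims), g), truth))
})

test_that("EM respects probability bounds, consensus immutability, and ascends its likelihood at beta = 0", {
  g <- voxel_grid(c(10, 10, 10))
  truth <- atlasmanifold:::ellipsoid_template(g)
  s <- simulate_raters(truth, p = 0.85, q_spec = 0.9, R = 5, seed = 13)
  res <- staple(s, beta = 0)
  expect_true(all(res$probability >= 0 & res$probability <= 1))
  expect_true(all(res$probability[res$consensus == 2L] == 1))
  expect_true(all(res$probability[res$consensus == 0L] == 0))
  expect_true(all(diff(res$loglik_trace) > -1e-8))
  expect_true(all(res$sensitivity > 0 & res$sensitivity <= 1))
  expect_error(staple(s, beta = -0.1), "beta")
})

test_that("the mean-field MRF pulls isolated disagreements toward their neighbourhood", {
  g <- voxel_grid(c(5, 5, 5))
  cube <- array(0L, dim = g$dims); cube[2:4, 2:4, 2:4] <- 1L
  centre <- array(0L, dim = g$dims); centre[3, 3, 3] <- 1L
  # two raters omit the centre voxel of an agreed cube, one keeps it
  r_miss <- label_map(cube - centre, g)
  r_keep <- label_map(cube, g)
  s <- rater_stack(list(r_miss, r_miss, r_keep))
  expect_warning(r0 <- staple(s, beta = 0), "constant")
  p0 <- r0$probability[3, 3, 3]
  p_mrf <- suppressWarnings(staple(s, beta = 1))$probability[3, 3, 3]
  expect_gt(p_mrf, p0)
  # with only one disputed voxel the EM drives the raters' estimated
  # performance to the clamp, so the spatial term needs 6*beta to exceed
  # that log-odds before the label flips
  expect_equal(suppressWarnings(staple(s, beta = 2))$fused$values[3, 3, 3], 1L)
})

test_that("fuse_target propagates the selected atlases and is exact for k_d = 1", {
  ps <- study_phantoms()
  lib <- ps$library
  D <- distance_matrix(lib)
  e <- compute_embedding(D, "lle", d = 3, k_D = 8)
  tgt <- make_target(ps, c(0.2, 0.3, -0.1))
  te <- extend(e, target_distances(tgt$field, lib))

  one <- fuse_target(e, te, lib, k_d = 1)
  nearest_id <- nearest_on_manifold(e, te, 1)[1]
  expect_identical(one$fused$values,
                   lib$entries[[match(nearest_id, lib$ids)]]$labels$values)

  # nearest atlases fuse better than the farthest atlases fused the same way
  all_ids <- nearest_on_manifold(e, te, length(lib))
  idx <- attr(all_ids, "indices")
  near <- atlasmanifold:::fuse_and_score(lib, idx[1:7], tgt$truth, beta = 0.2)
  far <- atlasmanifold:::fuse_and_score(lib, rev(idx)[1:7], tgt$truth,
                                        beta = 0.2)
  expect_gt(near, far)

  # repeated runs are identical
  again <- fuse_target(e, te, lib, k_d = 1)
  expect_identical(one$probability, again$probability)
})
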