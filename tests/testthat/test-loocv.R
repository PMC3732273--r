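test_that("a library of identical atlases scores perfect Dice for any technique", {
  lib <- identical_library(6)
  for (tech in c("isomap", "lle", "lem")) {
    cell <- suppressWarnings(loocv_cell(lib, tech, d = 2, k_D = 2, k_d = 3))
    expect_equal(cell$mean, 1)
    expect_equal(cell$n_failed, 0L)
  }
})

test_that("each fold equals an independently scripted rerun of the components", {
  ps <- study_phantoms()
  lib <- ps$library[1:20]
  cell <- loocv_cell(lib, "lem", d = 2, k_D = 6, k_d = 5)
  subjects <- atlasmanifold:::library_subjects(lib)
  for (f in c(1, 11, 20)) {
    keep <- which(subjects != subjects[f])
    sub <- lib[keep]
    D_sub <- distance_matrix(sub)                       # recomputed from fields
    e <- compute_embedding(D_sub, "lem", d = 2, k_D = 6)
    dists <- target_distances(lib$entries[[f]]$field, sub)
    te <- extend(e, as.numeric(dists))
    sel <- nearest_on_manifold(e, te, 5)
    stack <- rater_stack(atlasmanifold:::library_labels(sub)[attr(sel, "indices")])
    fused <- staple(stack, beta = 0.2)$fused
    expect_equal(unname(cell$per_target[f]),
                 dice(fused, lib$entries[[f]]$labels), tolerance = 1e-12)
  }
})

test_that("held-out subjects never contribute their flipped sibling", {
  ps <- generate_library(n = 8, q = 2, grid_dims = c(12, 12, 12), seed = 3,
                         label_sensitivity = 0.97, label_specificity = 0.999)
  lib <- augment_with_flipped(ps$library)
  subjects <- atlasmanifold:::library_subjects(lib)
  cache <- atlasmanifold:::new_loocv_cache(lib, "rms")
  for (f in seq_along(lib)) {
    keep <- atlasmanifold:::fold_keep(lib, f)
    expect_false(f %in% keep)
    expect_false(any(subjects[keep] == subjects[f]))
    expect_length(keep, length(lib) - 2L)
  }
  # and the selected atlases in a fold obey the exclusion
  cell <- loocv_cell(lib, "lle", d = 2, k_D = 5, k_d = 3)
  expect_equal(cell$n_failed, 0L)
  expect_true(all(cell$per_target > 0))
})

test_that("BASE selection is a brute-force sort of the raw metric distances", {
  ps <- study_phantoms()
  lib <- ps$library
  D <- distance_matrix(lib)
  tgt <- make_target(ps, c(0.3, -0.2, 0.1))
  td <- target_distances(tgt$field, lib)
  sel <- base_selection(D, td, 5)
  expect_equal(attr(sel, "indices"), order(td, seq_along(td))[1:5])
  # target sitting on an atlas selects that atlas first
  sel3 <- base_selection(D, as.numeric(D[3, ]), 2)
  expect_equal(sel3[1], lib$ids[3])
  expect_error(base_selection(D, td, 0), "k_d")
})

test_that("grid search fills the 4-D matrix, picks the argmax, and caching is invisible", {
  ps <- generate_library(n = 12, q = 2, grid_dims = c(12, 12, 12), seed = 8,
                         label_sensitivity = 0.97, label_specificity = 0.999)
  lib <- ps$library
  grid <- param_grid(techniques = c("lle", "lem"), d_values = c(2, 3),
                     k_D_values = 5, k_d_values = c(3, 5))
  res <- grid_search(lib, grid)
  expect_equal(unname(dim(res$mean_dice)), c(2, 2, 1, 2))
  expect_true(all(res$mean_dice >= 0 & res$mean_dice <= 1, na.rm = TRUE))
  b <- res$best
  expect_equal(res$mean_dice[b$technique, as.character(b$d),
                             as.character(b$k_D), as.character(b$k_d)],
               max(res$mean_dice, na.rm = TRUE))

  # cache-free recomputation of every cell gives identical values
  for (tech in grid$techniques) for (d in grid$d_values)
    for (kd in grid$k_d_values) {
      cell <- loocv_cell(lib, tech, d = d, k_D = 5, k_d = kd)
      expect_identical(cell$mean,
                       res$mean_dice[tech, as.character(d), "5",
                                     as.character(kd)])
    }

  # single-cell grid: best is that cell
  g1 <- param_grid("lem", 2, 5, 3)
  r1 <- grid_search(lib, g1)
  expect_equal(r1$best$mean, r1$mean_dice[1, 1, 1, 1])

  tab <- grid_result_table(res)
  expect_equal(nrow(tab), 8)
  expect_equal(tab$mean_dice[tab$technique == b$technique & tab$d == b$d &
                               tab$k_D == b$k_D & tab$k_d == b$k_d],
               b$mean)
})

test_that("folds with disconnected graphs mark the cell missing instead of restricting it", {
  # two tight clusters far apart: small k_D cannot connect them
  g <- voxel_grid(c(8, 8, 8))
  mk_entry <- function(i, centre) {
    v <- array(stats::rnorm(prod(g$dims) * 3, mean = centre, sd = 0.01),
               dim = c(g$dims, 3))
    list(id = paste0("e", i), labels = rand_label(g, seed = i),
         field = displacement_field(v, g),
         subject_id = paste0("s", i), laterality = "native")
  }
  set.seed(55)
  lib <- atlas_library(c(lapply(1:5, mk_entry, centre = 0),
                         lapply(6:10, mk_entry, centre = 100)))
  cell <- loocv_cell(lib, "lem", d = 2, k_D = 2, k_d = 2)
  expect_true(is.na(cell$mean))
  expect_gt(cell$n_failed, 0)
})
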