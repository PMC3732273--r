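# atlasmanifold

Manifold-guided atlas selection and STAPLE label fusion for multi-atlas
segmentation of brain structures (built around hippocampus segmentation in
MRI of dementia cohorts).

In multi-atlas segmentation a target image is labelled by propagating and
fusing the manual segmentations of the atlases most similar to it. This
package implements the selection of those atlases on a learned manifold:

1. **Deformation metric.** Every image is represented by the displacement
   field *u* of the non-rigid transformation to one common average atlas;
   dissimilarity is the root-mean-square field difference
   d(i,j) = sqrt( (1/N) Σₓ ‖uᵢ(x) − uⱼ(x)‖² ) (mm), so any pair of images
   can be compared with one registration each, never one per pair.
2. **Manifold learning.** The n×n distance matrix feeds a connected
   k_D-nearest-neighbour graph and three non-linear embeddings into d ≪ N
   dimensions: Isomap (geodesic-preserving classical MDS), Locally Linear
   Embedding (affine reconstruction weights from a distance-based local
   Gram), and Laplacian Eigenmaps (heat-kernel graph Laplacian,
   generalized eigenproblem L f = λ Deg f).
3. **Out-of-sample extension.** A new target is placed on the learned
   manifold by a Nyström-style rule from its distance vector alone — no
   re-embedding — and its k_d nearest atlases in the embedding (plain L2)
   are selected.
4. **STAPLE fusion.** The selected labels are fused by EM estimation of a
   probabilistic true segmentation plus per-atlas sensitivity/specificity,
   with a mean-field Markov random field (strength β, 6-connectivity)
   regularizing the posterior, solved only on voxels where the atlases
   disagree.
5. **Leave-one-out optimization.** A grid search over (technique, d, k_D,
   k_d) fills the 4-D mean-Dice matrix (excluding each held-out subject's
   mirrored sibling), reports the optimum, and compares against BASE —
   nearest-atlas selection directly in the high-dimensional metric space.

A synthetic phantom generator with known low-dimensional latent structure
(displacement fields exactly linear in latent coordinates, analytic Gram
matrix, simulated noisy raters) makes the whole pipeline testable without
any imaging data. The methods vignette
(`vignettes/atlas-selection-methods.Rmd`) documents the models, parameter
choices and limitations.

## Worked example

```r
library(atlasmanifold)

# a synthetic library of 30 phantom atlases with 3 latent shape modes and
# simulated manual-rater label noise
ps  <- generate_library(n = 30, q = 3, seed = 5,
                        label_sensitivity = 0.97, label_specificity = 0.999)
lib <- ps$library

D <- distance_matrix(lib)                        # rms deformation metric
e <- compute_embedding(D, "lle", d = 3, k_D = 10)

# an unseen target drawn from the same latent family
tgt <- make_target(ps, c(0.25, -0.4, 0.3))
te  <- extend(e, target_distances(tgt$field, lib))
res <- fuse_target(e, te, lib, k_d = 5, beta = 0.2)
dice(res$fused, tgt$truth)
```

which prints (via the objects' `print` methods):

```
<phantom_set> 30 phantoms, latent dim 3, amplitude 1.8 mm, seed 5
<distance_matrix> 30 atlases, variant 'rms', range [0, 1.194] mm
<manifold_embedding> lle: 30 atlases -> 3 dimensions (k_D = 10)
<target_embedding> 'target' on lle manifold: (-0.08717, -0.03777, 0.08076)
<staple_result> 5 raters, 24 EM iterations (converged), fused volume 342.0 mm^3
  sensitivity 0.7971-0.8698, specificity 0.9937-0.9997, 217 non-consensus voxels
Dice vs ground truth: 0.8364
```

The five selected atlases act as "raters"; their estimated sensitivities
around 0.80–0.87 reflect genuine shape differences between neighbouring
phantoms and the simulated rater noise, and the fused segmentation overlaps
the ground-truth shape at Dice 0.84 — well above any single atlas.

`run_pipeline()` wraps steps 1–4 with a `pipeline_config()` whose defaults
are the optimized parameters from the leave-one-out study on the 110-atlas
hippocampus library (LLE, d = 11, k_D = 23, k_d = 7, β = 0.2);
`grid_search()` / `loocv_base()` reproduce the optimization experiment on
any library. A thin command-line launcher with `simulate`, `distances`,
`run` and `loocv` subcommands is installed at
`inst/cli/atlasmanifold.R`.

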