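---
title: "Methods: graph-transformer classification of whole-slide images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph-transformer classification of whole-slide images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

A whole-slide image (WSI) is a gigapixel scan of a stained tissue section
carrying a single slide-level label (for example, normal tissue versus one of
two lung tumor types). Patch-based classifiers assign the slide label to
every patch, which injects label noise and discards the spatial organization
of the tissue. `slidegraph` instead represents a slide as a graph whose nodes
are tissue patches and whose edges encode spatial adjacency, and classifies
the whole graph at once.

The pipeline has four stages.

**1. Tiling and background filtering.** The slide raster is cut into
non-overlapping `patch_size` x `patch_size` patches on a regular grid
(`tile_slide()`); partial border tiles are dropped rather than padded so
every node sees the same pixel budget. A patch is kept when its non-tissue
area is at most 50% (`filter_background()`). The source material does not pin
down what counts as a non-tissue pixel, only the 50% area rule, so the
package commits to one documented, overridable pixel rule: a pixel is
background when it is near-white (`min(R,G,B) >= 220`) or nearly unsaturated
(`max - min <= 15` on the 0-255 scale). Hematoxylin-eosin tissue is strongly
colored, glass is bright and gray-neutral, so a brightness-or-saturation test
is the standard heuristic. Kept patches carry 0-based `(row, col)` grid
coordinates; everything downstream (adjacency, heatmap reconstruction) is
exact in these indices. When patches overlap (`overlap_fraction > 0`, stride
`round(patch_size * (1 - overlap))`), adjacency is still defined on grid
indices, not pixel distances, so the overlap variant changes patch content
but not graph topology.

**2. Contrastive patch embedding.** A residual CNN is pre-trained with the
normalized-temperature cross-entropy (NT-Xent) objective: each mini-batch of
K patches is augmented twice (color distortion, Gaussian blur, random crop
and resize), giving 2K views; the two views of one patch form the positive
pair and the other 2K - 2 views act as negatives. For projected embeddings
z, the per-pair loss is

    l(i, j) = -log exp(sim(z_i, z_j)/tau) / sum_{k != i} exp(sim(z_i, z_k)/tau)

with cosine similarity `sim` and temperature `tau`, averaged over both
ordered members of every positive pair. The projection head (a 2-layer MLP)
exists only during pre-training; the backbone's global-average-pooled
features are the node features. The temperature, projection width, jitter
strengths and epoch budget are not pinned down by the source material; the
package defaults to the canonical `tau = 0.5`, a projection head as wide as
the feature dimension, color jitter factors U(1 - 0.8s, 1 + 0.8s) with
strength s = 0.5, blur sigma in [0.1, 2], and crop scale in [0.5, 1] — all
exposed in `augmentation_policy()` and `pretrain_encoder()`.

Two backbones ship. `"deep"` is the production-scale 18-layer residual
configuration (512-d features). `"small"` is the desk-scale profile used by
the test suite: 8 weight layers, 32-d features. Neither uses batch
normalization: at desk scale, with a few hundred pre-training steps, batch
statistics buy nothing and make inference depend on training-mode state; the
residual branches are instead damped at initialization (second conv of each
block scaled by 0.5) so the network starts near-identity. This is a
deliberate deviation from the textbook residual network and is the package's
own design choice.

**3. The slide graph.** Node features F (N x D) come from the encoder; two
nodes are adjacent when their grid coordinates are within Chebyshev distance
1 (8-connectivity, default) or Manhattan distance 1 (4-connectivity), so a
node has at most 8 neighbors. Graph convolution uses the self-looped,
symmetrically degree-normalized operator

    A_hat = D~^{-1/2} (A + I) D~^{-1/2},   H_{m+1} = ReLU(A_hat H_m W_m)

whose spectrum lies in [-1, 1]. Isolated nodes (possible after aggressive
filtering of real slides) violate the ideal "every patch has a neighbor"
expectation; they are permitted with a warning and keep only their self-loop,
so downstream stages never crash on them.

**4. Min-cut pooling and the transformer.** Self-attention is quadratic in
the token count, and slides can produce thousands of nodes, so a learnable
min-cut pooling layer reduces N nodes to `n_clusters` tokens: a linear map of
the GC output followed by a row softmax gives the soft assignment S (N x K),
pooled features are `X_pool = S' H`, and two auxiliary losses shape S — the
relaxed normalized-cut ratio `-Tr(S'AS) / Tr(S'DS)` (in [-1, 0]) and the
orthogonality residual `|| S'S/||S'S||_F - I/sqrt(K) ||_F` (>= 0). The source
material names the pooling layer and its custom-loss character but not its
formulas; the cited min-cut formulation is implemented exactly, with both
auxiliary weights defaulting to 1 (exposed as `lambda_cut`, `lambda_ortho`).
A learnable class token (truncated normal init, sd 0.02) is prepended to the
pooled tokens and L pre-LayerNorm transformer blocks follow: per head,
`[q,k,v] = x U_qkv`, `A = softmax(q k' / sqrt(D_h))`, `SA = A v`, heads
concatenated and mixed by `U_msa`, then a GELU MLP, both with residual
connections. No positional encoding is added: positional information enters
through the adjacency matrix in the GC stage and is preserved through the
dense learned assignment. The class-token output passes through a LayerNorm
(the slide representation) and a single linear head — the minimal faithful
reading of "the class-token state serves as the mapping to label space" —
followed by a softmax.

Because every stage is a sum or permutation-equivariant map over nodes,
slide predictions are invariant to node order; the test suite checks this to
1e-5 over random joint permutations.

**Training.** Adam with the printed schedule: initial learning rate 1e-3,
decayed to 1e-4 and 1e-5 at steps 30 and 100, batches of 8 graphs, 150
steps (`gtp_config("standard")`). Batching over variable-size graphs works
because every graph is pooled to the same K tokens; the implementation
evaluates the per-graph losses on one shared tape and averages, which is
numerically identical to block-diagonal batching of the GC stage. The state
with the lowest validation objective (the training objective evaluated on a
stratified carve-out, checked every `eval_every` steps) is kept; ties go to
the earliest step.

Two printed hyperparameter sets disagree — a single GC layer with hidden
size 64 versus the sweep's best row with 3 GC layers and hidden 128 — and
the source does not reconcile them, so both ship as presets (`"standard"`,
`"wide"`) and neither is treated as canonical.

## GraphCAM: class-specific saliency

To explain a prediction, relevance is propagated from the target class back
through the transformer. For each block l, the gradient of the target logit
with respect to every head's attention map, `grad A^(l)`, is combined with
the attention relevance `R(n_l)`, averaged over heads with negative
contributions clamped to zero, and an identity is added so a token never
inhibits itself:

    A_bar^(l) = E_h[(grad A^(l) * R(n_l))^+] + I,    C_t = A_bar^(L) ... A_bar^(1)

The class-token row of `C_t`, restricted to the pooled-node columns, is the
relevance of each cluster; `C_g = S r_pool` maps it back to nodes through
the same soft assignment used in pooling (the only direction in which the
dimensions work, and the dual of `X_pool = S' X`). Node relevances are
min-max normalized per slide and painted onto the kept patch footprints; a
constant relevance vector maps to 0.5 so the display contract is total.

The deep-Taylor recursion that originally defined `R(n_l)` is implemented
here in its gradient-weighted attention form: the relevance of the softmax
layer is taken to be the attention map itself, and class specificity enters
entirely through the gradient, which is computed from a one-hot logit
backpropagation. This simplification — later adopted by the originators of
the recipe — preserves the two properties the method is used for: a
zero-gradient forward yields the identity relevance (and exactly zero node
relevance), and maps for different target classes differ. Whether the
class-token column (not only its row) should contribute node relevance is
left unstated by the source; the row convention is adopted.

Localization is scored by binarizing the heatmap at thresholds 0.1, ...,
0.9 and reporting intersection-over-union against an annotation mask per
threshold, plus the best threshold and maximum IoU. An empty annotation
yields IoU 0 with a warning.

## Evaluation harness

Per-class metrics are one-vs-rest: precision TP/(TP+FP), recall TP/(TP+FN),
specificity TN/(TN+FP), with zero denominators mapped to 0 under a warning.
ROC curves sweep the unique score values; the trapezoidal AUC then equals
the Mann-Whitney statistic with midpoint tie handling (all-tied scores give
0.5), which is what the tests assert. PR curves use step interpolation
(conservative). Cross-validation is stratified by slide label with per-class
fold sizes differing by at most one and seeded fold assignment; patient-level
grouping is not implemented because the patient-to-slide mapping is
dataset-specific — users with multiple slides per patient should group folds
themselves or expect optimistic estimates. The trainer and predictor are
injectable, so the harness is testable with a cheap classifier and usable
with the graph-transformer.

## The synthetic cohort: what it does and does not show

`generate_cohort()` emulates the *structure* of the 3-class lung task
(normal vs. two tumor types) at desk scale, with no claim of histologic
realism. Each slide is a patch-aligned raster: a one-patch white margin ring
(so background filtering is exercised and its kept-count is exactly
predictable), a plain pink tissue texture, and — for tumor slides — one
contiguous lesion region (rectangle plus a few adjacent cells, uniformly
placed) of a class-specific texture: dark round nests for `tumor_A`,
oriented stripes for `tumor_B`. The lesion covers `lesion_fraction` (default
0.25) of the tissue patches within +-20% bookkeeping tolerance, and a
pixel-exact ground-truth mask accompanies every slide. Grids vary from 8x8
to 12x12 patches of 64 px across the default 120-slide cohort, emulating the
variable node counts of real slides while staying CPU-sized.

Separability is a design requirement, not an observation: a two-layer
convolutional probe must reach >= 95% patch-level accuracy on lesion versus
non-lesion patches (asserted in the tests), so an end-to-end failure
indicates a model bug, not inseparable data. Conversely, passing at desk
scale says nothing about stain variation, scanner artifacts, tissue folds,
nuclear morphology or magnification handling in real slides; those require
the real cohorts this package deliberately does not depend on.

## Numerical and engineering choices

* All training runs on a small reverse-mode autodiff tape written in base R
  (matrices only); gradients of every operator are tested against central
  finite differences, and the full model's parameter gradients agree with
  numeric differentiation to 1e-5 on small instances. Convolution is im2col
  plus matrix multiplication with cached gather indices.
* Cross-entropy is computed as a shifted log-sum-exp; the attention and
  assignment softmaxes subtract row maxima. The orthogonality loss adds
  1e-12 under its square root, since its gradient is undefined at exactly 0.
* A graph with no edges (single node) would make the cut ratio 0/0; the cut
  loss is defined as 0 there.
* The min-cut assignment's Frobenius normalization and the pooled adjacency
  re-normalization follow the cited pooling formulation; `A_pool` is
  recomputed, zero-diagonaled and degree-renormalized for the forward trace
  but is not consumed by the transformer (which uses no positional
  encoding).
* Graph bundles and checkpoints serialize as single RDS files with JSON
  sidecars; features, edges and coordinates round-trip exactly.
* Seeds: every stochastic step (cohort, split, augmentation sampling,
  initialization, batching, shuffled-relevance control) derives its own
  sub-seed from one master seed via `sample.int`, and all seeded code
  restores the caller's RNG state.

## Problem sizes used in the tests

The suite exercises the full method at sizes a laptop CPU handles in
minutes, chosen as the package's own desk-scale study conditions: the
120-slide cohort above; a `"desk"` model (hidden 32, 1 GC layer, 2 blocks,
4 heads, 16 clusters) trained for 300 steps with the step decay moved to
steps 200/280 to fit the longer schedule; contrastive pre-training for 60
steps with K = 16 on 400 sampled patches. Unit tests use graphs of at most
a few dozen nodes, where brute-force loop oracles are feasible.

## Known limitations

* No real-slide reader is bundled: pyramidal formats must be rasterized to
  the working magnification upstream (the CLI documents this); there is no
  stain normalization or multi-scale bag.
* The desk-scale CNN is far smaller than production backbones; absolute
  feature quality on real tissue is out of scope.
* Training is single-threaded CPU; the design favors correctness and
  testability over speed, and production-scale cohorts would need a GPU
  implementation of the same math.
* DeLong AUC comparisons, attention-rollout/LRP saliency baselines, and the
  comparator architectures from the source material's ablations are out of
  scope.
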