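# slidegraph

Slide-level classification of whole-slide pathology images (WSIs) with a
graph-transformer, plus class-specific saliency maps (GraphCAM).

## The problem

A WSI is a gigapixel scan with one label (e.g. normal vs. lung
adenocarcinoma vs. lung squamous cell carcinoma). Patch-based deep learning
assigns the slide label to every patch — injecting label noise — and ignores
how tissue regions are arranged. `slidegraph` classifies the slide as a
whole: patches become nodes of a spatial graph, and a transformer reads a
pooled version of that graph.

The pipeline:

1. **Tile & filter** — non-overlapping `p x p` patches on a grid; patches
   with more than 50% non-tissue area (near-white or unsaturated pixels) are
   discarded.
2. **Embed** — a residual CNN pre-trained with the contrastive NT-Xent loss
   on augmented patch pairs
   (`l_ij = -log exp(sim(z_i,z_j)/τ) / Σ_{k≠i} exp(sim(z_i,z_k)/τ)`)
   turns each kept patch into a feature vector.
3. **Graph → label** — nodes are adjacent at Chebyshev distance 1 on the
   patch grid (≤ 8 neighbors); graph convolution
   `H_{m+1} = ReLU(Â H_m W_m)` with `Â = D̃^{-1/2}(A + I)D̃^{-1/2}`
   propagates context, a learnable **min-cut pooling** layer
   (`X_pool = SᵀH`, with normalized-cut and orthogonality losses on the soft
   assignment `S`) compresses thousands of nodes to a fixed token count, and
   a class-token transformer (`A = softmax(qkᵀ/√D_h)` per head) predicts the
   label from the LayerNormed class-token state.
4. **Explain** — GraphCAM propagates relevance from the target logit:
   per block `Ā = E_h[(∇A ⊙ R)⁺] + I`, `C_t = Π_l Ā^(l)`; the class-token
   row is mapped back to nodes through the pooling assignment
   (`C_g = S r_pool`) and painted onto the patch footprints. Overlap with
   annotation masks is scored by IoU over a threshold sweep.

Everything — including the CNN and transformer training — runs on a small,
finite-difference-verified reverse-mode autodiff engine in base R, so the
package is self-contained and CPU-only. A synthetic-slide generator with
planted, mask-annotated lesions makes the whole method testable offline.

## Worked example

A deliberately small end-to-end run (30 synthetic slides, reduced training
budget; a few minutes on one CPU):

```r
library(slidegraph)
bm <- synthetic_benchmark(
  seed = 7, train_seeds = 1L, n_per_class = 10L, grid_range = c(6L, 9L),
  config = gtp_config("desk", steps = 150L, decay_steps = c(100L, 130L)),
  pretrain_steps = 30L, n_pretrain_patches = 200L)

bm$accuracies
#> [1] 0.8333333

fit <- bm$fits[[1]]
fit$model
#> <gtp> graph-transformer, 3 classes (normal, tumor_A, tumor_B)
#>   hidden 32 | 1 GC layer(s) | 2 transformer block(s) x 4 heads | 16 min-cut clusters
#>   best validation objective 0.7054 at step 80

table(truth = bm$labels[bm$test_idx], predicted = fit$pred)
#>          predicted
#> truth     normal tumor_A tumor_B
#>   normal       1       1       0
#>   tumor_A      0       2       0
#>   tumor_B      0       0       2
```

`synthetic_benchmark()` generated a balanced 3-class cohort, contrastively
pre-trained the small encoder on patches from the training slides, built one
graph per slide, trained the reduced graph-transformer, and scored the
held-out 25%: here 5 of 6 test slides are correct (one normal slide is
mistaken for `tumor_A`). Saliency on a held-out tumor slide:

```r
g <- bm$graphs[[bm$test_idx[which(bm$labels[bm$test_idx] == "tumor_A")[1]]]]
graphcam(fit$model, g)
#> <graphcam> slide_017_tumor_A: target = tumor_A, node relevances in [0.012, 0.0121]
#>   probabilities: normal 0.449, tumor_A 0.546, tumor_B 0.005

tum <- bm$test_idx[bm$labels[bm$test_idx] != "normal"]
loc <- graphcam_localization(fit$model, bm$graphs, tum)
round(c(mean_max_iou = mean(loc$max_iou[loc$correct]),
        shuffled_control = mean(loc$control_iou[loc$correct])), 3)
#>     mean_max_iou shuffled_control
#>            0.610            0.317
```

The GraphCAM heatmaps of correctly classified tumor slides overlap the
planted lesion masks (max-over-threshold IoU 0.61 on average here) roughly
twice as well as the same relevances randomly shuffled across nodes — the
map is localizing, not just covering tissue. At the full default scale (120
slides, 300 training steps, three seeds) both classification accuracy and
localization improve; see below.

`plot(fit$model)` draws the training curves and `plot(graphcam(...))` the
heatmap; `write_graphcam()` exports PNG/TIFF/JSON bundles.

A command-line wrapper for the same steps (synth / tile / pretrain / embed /
build-graph / train / predict / explain / cv) ships at
`inst/cli/slidegraph`.

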