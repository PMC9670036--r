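#' From slides to graphs
#'
#' Convenience wrappers that run the full per-slide pipeline: tile, filter
#' background, embed patches, build the graph. For synthetic cohorts the
#' planted lesion ground truth is carried along on each graph
#' (`$lesion_nodes`, one flag per kept node) so saliency maps can be scored
#' against it.
#'
#' @param cohort a `slide_cohort` from [generate_cohort()].
#' @param encoder a `patch_encoder` (pre-trained or not).
#' @param indices manifest rows to process (default all).
#' @param connectivity 8 or 4.
#' @param background_max background filter threshold.
#' @param overlap_fraction patch overlap for tiling.
#' @return list with `graphs` (list of `wsi_graph`) and `labels` (factor).
#' @export
cohort_graphs <- function(cohort, encoder, indices = NULL, connectivity = 8L,
                          background_max = 0.5, overlap_fraction = 0) {
  m <- cohort$manifest
  if (is.null(indices)) indices <- seq_len(nrow(m))
  graphs <- vector("list", length(indices))
  for (j in seq_along(indices)) {
    i <- indices[j]
    s <- cohort_slide(cohort, i)
    grid <- filter_background(
      tile_slide(s$slide, patch_size = m$patch_size[i], overlap_fraction = overlap_fraction),
      background_max = background_max)
    F <- extract_features(encoder, grid)
    g <- build_graph(F, grid$coords, connectivity = connectivity,
                     label = m$label[i], slide_id = m$slide_id[i],
                     patch_size = m$patch_size[i], slide_dim = dim(s$slide$pixels)[1:2])
    # ground truth: tissue cell (r, c) of the lesion mask sits at tiled grid
    # coord (r, c) because the white margin ring occupies coord 0
    lm <- s$lesion_patch_mask
    g$lesion_nodes <- vapply(seq_len(nrow(grid$coords)), function(k) {
      r <- grid$coords[k, 1]; cc <- grid$coords[k, 2]
      r >= 1 && r <= nrow(lm) && cc >= 1 && cc <= ncol(lm) && lm[r, cc]
    }, logical(1))
    graphs[[j]] <- g
  }
  list(graphs = graphs,
       labels = factor(m$label[indices], levels = cohort$classes))
}

#' @rdname cohort_graphs
#' @param n_patches total number of tissue patches to sample.
#' @param seed sampling seed.
#' @return `cohort_patches()` returns a list of RGB patch arrays sampled
#'   across the given slides, for contrastive pre-training.
#' @export
cohort_patches <- function(cohort, n_patches = 400L, indices = NULL, seed = 1L) {
  m <- cohort$manifest
  if (is.null(indices)) indices <- seq_len(nrow(m))
  with_seed(seed, {
    per <- ceiling(n_patches / length(indices))
    out <- list()
    for (i in indices) {
      s <- cohort_slide(cohort, i)
      grid <- filter_background(tile_slide(s$slide, patch_size = m$patch_size[i]))
      take <- sample.int(length(grid$patches), min(per, length(grid$patches)))
      out <- c(out, grid$patches[take])
      if (length(out) >= n_patches) break
    }
    out[seq_len(min(n_patches, length(out)))]
  })
}

#' End-to-end synthetic benchmark
#'
#' Runs the whole method at desk scale on a seeded synthetic cohort:
#' generates the cohort, contrastively pre-trains the small patch encoder on
#' patches sampled from the training slides, embeds all slides into graphs,
#' trains one graph-transformer per training seed on a stratified 75% split,
#' and evaluates on the held-out 25%.
#'
#' @param seed master seed; everything (cohort, split, pre-training,
#'   training seeds when not given) derives from it.
#' @param train_seeds integer vector of GTP training seeds (default: three
#'   seeds derived from `seed`).
#' @param n_per_class slides per class.
#' @param grid_range,patch_size,lesion_fraction cohort geometry, passed to
#'   [generate_cohort()].
#' @param config a [gtp_config()]; the default is the desk profile.
#' @param pretrain_steps,pretrain_batch,n_pretrain_patches contrastive
#'   pre-training budget.
#' @return list with the cohort, encoder, graphs, labels, train/test indices
#'   and one fit per training seed (`model`, probability matrix `P`,
#'   predicted classes, held-out `accuracy`).
#' @export
synthetic_benchmark <- function(seed = 1L, train_seeds = NULL, n_per_class = 40L,
                                grid_range = c(8L, 12L), patch_size = 64L,
                                lesion_fraction = 0.25,
                                config = gtp_config("desk"),
                                pretrain_steps = 60L, pretrain_batch = 16L,
                                n_pretrain_patches = 400L) {
  ds <- derive_seeds(seed, 6L)
  if (is.null(train_seeds)) train_seeds <- derive_seeds(ds[1], 3L)
  cohort <- generate_cohort(n_per_class = n_per_class, grid_range = grid_range,
                            patch_size = patch_size, lesion_fraction = lesion_fraction,
                            seed = ds[2])
  labels_all <- factor(cohort$manifest$label, levels = cohort$classes)
  test_idx <- with_seed(ds[3], stratified_split(as.integer(labels_all), 0.25))
  train_idx <- setdiff(seq_len(nrow(cohort$manifest)), test_idx)

  patches <- cohort_patches(cohort, n_patches = n_pretrain_patches,
                            indices = train_idx, seed = ds[4])
  encoder <- patch_encoder("small", seed = ds[5])
  encoder <- pretrain_encoder(encoder, patches, steps = pretrain_steps,
                              batch_size = pretrain_batch, seed = ds[6])

  gl <- cohort_graphs(cohort, encoder)
  graphs <- gl$graphs
  labels <- gl$labels

  fits <- lapply(train_seeds, function(s) {
    cfg <- config
    cfg$seed <- s
    model <- gtp_train(graphs[train_idx], labels[train_idx], cfg)
    P <- predict(model, graphs[test_idx])
    pred <- factor(colnames(P)[max.col(P, ties.method = "first")],
                   levels = levels(labels))
    list(model = model, P = P, pred = pred, seed = s,
         accuracy = mean(pred == labels[test_idx]))
  })
  list(cohort = cohort, encoder = encoder, graphs = graphs, labels = labels,
       train_idx = train_idx, test_idx = test_idx, fits = fits,
       accuracies = vapply(fits, `[[`, numeric(1), "accuracy"))
}

#' Score GraphCAM localization against planted lesions
#'
#' For each given tumor slide, computes the GraphCAM for the predicted class
#' at one-pixel-per-patch resolution, scores the max-over-threshold IoU
#' against the planted lesion mask, and repeats with the node relevances
#' randomly shuffled as a control.
#'
#' @param model a fitted `gtp`.
#' @param graphs list of `wsi_graph` objects carrying `$lesion_nodes`.
#' @param indices which graphs to score.
#' @param shuffle_seed seed for the shuffled-relevance control.
#' @return data frame: slide_id, predicted and true class, correctness,
#'   max_iou, best_threshold, control_iou.
#' @export
graphcam_localization <- function(model, graphs, indices = seq_along(graphs),
                                  shuffle_seed = 1L) {
  rows <- lapply(seq_along(indices), function(j) {
    g <- graphs[[indices[j]]]
    p <- g$patch_size
    cam <- graphcam(model, g, target_class = "auto", heatmap_scale = 1 / p)
    grid_dim <- dim(cam$heatmap)
    ann <- matrix(0, grid_dim[1], grid_dim[2])
    ann[cbind(g$coords[, 1] + 1L, g$coords[, 2] + 1L)] <- as.numeric(g$lesion_nodes)
    sc <- binarize_and_iou(cam$heatmap, ann)
    ctrl_rel <- with_seed(shuffle_seed + j, sample(cam$C_g))
    ctrl_hm <- reconstruct_heatmap(ctrl_rel, g$coords, p, g$slide_dim, scale = 1 / p)
    sc_ctrl <- binarize_and_iou(ctrl_hm, ann)
    data.frame(slide_id = g$slide_id, true = as.character(g$label),
               predicted = cam$target_class,
               correct = identical(cam$target_class, as.character(g$label)),
               max_iou = sc$max_iou, best_threshold = sc$best_threshold,
               control_iou = sc_ctrl$max_iou)
  })
  do.call(rbind, rows)
}
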