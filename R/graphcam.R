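#' Class-specific saliency for graph-transformers (GraphCAM)
#'
#' Relevance is propagated from a one-hot target logit back through the
#' transformer: for every block the gradient of the target logit with respect
#' to each head's attention map is combined with the attention relevance,
#' averaged over heads with negative contributions clamped to zero, and an
#' identity is added so a token never inhibits itself. The ordered product of
#' these per-block maps is the transformer relevance `C_t`; its class-token
#' row, restricted to the pooled-node columns, is mapped back to graph nodes
#' through the soft pooling assignment (`C_g = S r_pool`) and painted onto
#' the kept patch footprints as a heatmap.
#'
#' @param model a fitted `gtp` object.
#' @param graph a `wsi_graph`.
#' @param target_class `"auto"` (the predicted class), a class name, or a
#'   1-based class index.
#' @param heatmap_scale scale of the output raster relative to the slide
#'   (e.g. `1/graph$patch_size` gives one pixel per patch). `NA` skips the
#'   raster and keeps node relevances only.
#' @return an object of class `graphcam`: the target class, per-class
#'   probabilities, per-block attention/gradient/relevance triples, `C_t`,
#'   node relevances `C_g` (non-negative, aligned with `graph$coords`), and
#'   the reconstructed heatmap.
#' @export
graphcam <- function(model, graph, target_class = "auto", heatmap_scale = NULL) {
  tape <- ad_tape()
  px <- px_new(tape, model$params)
  out <- gtp_forward_nodes(px, graph, model$config, tape)
  probs <- as.vector(ad_value(out$probs))
  classes <- model$classes %||% paste0("class", seq_along(probs))
  names(probs) <- classes
  tgt <- if (identical(target_class, "auto")) as.integer(which.max(probs))
         else if (is.character(target_class)) match(target_class, classes)
         else as.integer(target_class)
  if (is.na(tgt) || tgt < 1L || tgt > length(probs)) stop("invalid target class")
  ad_backward(ad_cols(out$logits, tgt))
  blocks <- lapply(out$attn, function(bl) {
    A <- lapply(bl, ad_value)
    G <- lapply(bl, ad_grad)
    list(A = A, grad = G, R = A)   # attention relevance of the softmax layer
  })
  C_t <- transformer_relevance(lapply(blocks, `[[`, "A"),
                               lapply(blocks, `[[`, "grad"),
                               lapply(blocks, `[[`, "R"))
  S <- ad_value(out$S)
  r_pool <- C_t[1, -1]
  C_g <- reverse_pool(r_pool, S)
  if (is.null(heatmap_scale)) {
    heatmap_scale <- if (!is.null(graph$patch_size)) 1 / graph$patch_size else NA
  }
  slide_dim <- graph$slide_dim
  if (is.null(slide_dim) && !is.null(graph$patch_size)) {
    # no raster metadata: tightest raster covering every patch footprint
    slide_dim <- (apply(graph$coords, 2L, max) + 1L) * graph$patch_size
  }
  hm <- NULL
  if (!is.na(heatmap_scale) && !is.null(graph$patch_size)) {
    hm <- reconstruct_heatmap(C_g, graph$coords, graph$patch_size,
                              slide_dim, scale = heatmap_scale)
  }
  structure(list(target_class = classes[tgt], target_index = tgt,
                 probabilities = probs, blocks = blocks, C_t = C_t, C_g = C_g,
                 coords = graph$coords, patch_size = graph$patch_size,
                 slide_dim = slide_dim, heatmap = hm,
                 heatmap_scale = heatmap_scale, slide_id = graph$slide_id),
            class = "graphcam")
}

#' @rdname graphcam
#' @param A,grad,R lists (one element per block) of per-head attention maps,
#'   their gradients with respect to the target logit, and their relevances.
#' @return `transformer_relevance()` returns the `(1+Ng) x (1+Ng)` relevance
#'   map `C_t`: the ordered product over blocks of
#'   `mean_heads((grad * R)^+) + I`. If every gradient is zero, `C_t` is the
#'   identity and all node relevances vanish.
#' @export
transformer_relevance <- function(A, grad, R) {
  L <- length(A)
  if (L < 1L) stop("need at least one block")
  n <- nrow(A[[1]][[1]])
  C_t <- diag(n)
  for (l in seq_len(L)) {
    nh <- length(A[[l]])
    if (nrow(A[[l]][[1]]) != n) stop("mismatched block shapes")
    M <- matrix(0, n, n)
    for (h in seq_len(nh)) M <- M + pmax(grad[[l]][[h]] * R[[l]][[h]], 0)
    Abar <- M / nh + diag(n)
    C_t <- Abar %*% C_t
  }
  C_t
}

#' @rdname graphcam
#' @param r_pool relevance vector over the pooled nodes (length Ng).
#' @param S the N x Ng soft assignment from the same forward pass.
#' @return `reverse_pool()` returns `C_g = S r_pool`, the node relevance
#'   vector of length N: each node receives the assignment-weighted mix of
#'   its clusters' relevances.
#' @export
reverse_pool <- function(r_pool, S) {
  S <- as.matrix(S)
  if (length(r_pool) != ncol(S)) stop("relevance length must match the number of clusters")
  as.vector(S %*% r_pool)
}

#' @rdname graphcam
#' @param relevance node relevance vector aligned with `coords`.
#' @param coords N x 2 matrix of 0-based (row, col) grid indices.
#' @param patch_size patch side length in pixels.
#' @param slide_dim c(H, W) of the source raster.
#' @param scale output raster scale relative to the slide (1 = full
#'   resolution; `1/patch_size` = one pixel per patch).
#' @param stride grid stride in pixels (defaults to `patch_size`, i.e.
#'   non-overlapping patches).
#' @return `reconstruct_heatmap()` returns the heatmap raster: every kept
#'   patch footprint carries its min-max normalized relevance (if all
#'   relevances are equal the footprints map to the constant 0.5), the
#'   background is 0.
#' @export
reconstruct_heatmap <- function(relevance, coords, patch_size, slide_dim,
                                scale = 1, stride = patch_size) {
  coords <- matrix(as.integer(coords), ncol = 2)
  n <- nrow(coords)
  if (length(relevance) != n) stop("relevance must align with coords")
  if (any(coords[, 1] * stride + patch_size > slide_dim[1]) ||
      any(coords[, 2] * stride + patch_size > slide_dim[2])) {
    stop("coord outside slide")
  }
  rng <- range(relevance)
  rel <- if (diff(rng) < 1e-12) rep(0.5, n) else (relevance - rng[1]) / diff(rng)
  Hs <- max(1L, round(slide_dim[1] * scale))
  Ws <- max(1L, round(slide_dim[2] * scale))
  hm <- matrix(0, Hs, Ws)
  for (i in seq_len(n)) {
    r0 <- floor(coords[i, 1] * stride * scale) + 1L
    c0 <- floor(coords[i, 2] * stride * scale) + 1L
    r1 <- min(Hs, ceiling((coords[i, 1] * stride + patch_size) * scale))
    c1 <- min(Ws, ceiling((coords[i, 2] * stride + patch_size) * scale))
    hm[r0:r1, c0:c1] <- pmax(hm[r0:r1, c0:c1], rel[i])
  }
  hm
}

#' Binarize a heatmap and score overlap with an annotation mask
#'
#' Sweeps thresholds over the normalized heatmap and reports the
#' intersection-over-union with a binary annotation per threshold, plus the
#' best threshold and the maximum IoU.
#'
#' @param heatmap numeric raster in [0, 1].
#' @param annotation_mask binary mask of the same shape.
#' @param thresholds thresholds in (0, 1); default 0.1, 0.2, ..., 0.9.
#' @return list with `curve` (data frame of threshold and iou),
#'   `best_threshold` and `max_iou`. An empty annotation yields IoU 0 with a
#'   warning.
#' @export
binarize_and_iou <- function(heatmap, annotation_mask,
                             thresholds = seq(0.1, 0.9, by = 0.1)) {
  if (!all(dim(heatmap) == dim(annotation_mask))) stop("masks must have the same shape")
  ann <- annotation_mask > 0.5
  if (!any(ann)) {
    warning("empty annotation; IoU defined as 0")
    curve <- data.frame(threshold = thresholds, iou = 0)
    return(list(curve = curve, best_threshold = thresholds[1], max_iou = 0))
  }
  iou <- vapply(thresholds, function(t) {
    pred <- heatmap >= t
    u <- sum(pred | ann)
    if (u == 0) 0 else sum(pred & ann) / u
  }, numeric(1))
  best <- which.max(iou)
  list(curve = data.frame(threshold = thresholds, iou = iou),
       best_threshold = thresholds[best], max_iou = iou[best])
}

#' @export
print.graphcam <- function(x, ...) {
  cat(sprintf("<graphcam> %s: target = %s, node relevances in [%.3g, %.3g]\n",
              x$slide_id %||% "slide", x$target_class, min(x$C_g), max(x$C_g)))
  cat("  probabilities:", paste(sprintf("%s %.3f", names(x$probabilities),
                                        x$probabilities), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.graphcam <- function(x, ...) {
  if (is.null(x$heatmap)) stop("no heatmap in this bundle")
  cols <- grDevices::hcl.colors(64, "inferno")
  graphics::image(t(x$heatmap)[, nrow(x$heatmap):1, drop = FALSE], col = cols,
                  axes = FALSE, main = sprintf("GraphCAM: %s", x$target_class), ...)
  invisible(x)
}

#' Write a GraphCAM bundle to disk
#'
#' Colormapped PNG, raw single-channel TIFF, and a JSON summary (target
#' class, per-class probabilities, and -- when an annotation is supplied --
#' the IoU curve, best threshold and max IoU).
#'
#' @param cam a `graphcam`.
#' @param dir output directory.
#' @param annotation_mask optional binary annotation mask matching the
#'   heatmap shape.
#' @return the directory, invisibly.
#' @export
write_graphcam <- function(cam, dir, annotation_mask = NULL) {
  if (is.null(cam$heatmap)) stop("no heatmap in this bundle")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cols <- grDevices::hcl.colors(256, "inferno")
  idx <- pmin(255L, pmax(0L, as.integer(round(cam$heatmap * 255)))) + 1L
  rgbv <- grDevices::col2rgb(cols[idx]) / 255
  arr <- array(0, c(nrow(cam$heatmap), ncol(cam$heatmap), 3))
  for (k in 1:3) arr[, , k] <- matrix(rgbv[k, ], nrow(cam$heatmap), ncol(cam$heatmap))
  png::writePNG(arr, file.path(dir, "graphcam.png"))
  tiff::writeTIFF(cam$heatmap, file.path(dir, "graphcam_raw.tiff"), bits.per.sample = 32L)
  summ <- list(slide_id = cam$slide_id, target_class = cam$target_class,
               probabilities = as.list(cam$probabilities))
  if (!is.null(annotation_mask)) {
    sc <- binarize_and_iou(cam$heatmap, annotation_mask)
    summ$max_iou <- sc$max_iou
    summ$best_threshold <- sc$best_threshold
    summ$iou_curve <- sc$curve
  }
  jsonlite::write_json(summ, file.path(dir, "graphcam.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Attention maps, gradients and relevances for a target class
#'
#' Runs one forward pass, backpropagates the target-class logit, and returns
#' the per-block, per-head attention maps `A`, their gradients `grad`, and
#' the attention relevances `R` consumed by [transformer_relevance()].
#'
#' @inheritParams graphcam
#' @return list with one element per transformer block.
#' @export
capture_attention <- function(model, graph, target_class = "auto") {
  cam <- graphcam(model, graph, target_class, heatmap_scale = NA)
  cam$blocks
}
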