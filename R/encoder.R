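# The patch feature extractor: a normalization-free residual CNN built on the
# autodiff tape. Two presets are provided. "small" (the desk-scale profile
# used throughout the tests) has 8 weight layers and 32-d features; "deep" is
# the 18-layer residual configuration with 512-d features that matches the
# production-scale backbone. Neither uses batch statistics, so inference is a
# pure function of the weights.

encoder_plan <- function(arch) {
  switch(arch,
    small = list(
      stem = list(k = 3L, s = 2L, p = 1L, cin = 3L, cout = 16L),
      maxpool = FALSE,
      blocks = list(
        list(cin = 16L, cout = 32L, s = 2L),
        list(cin = 32L, cout = 32L, s = 2L)
      ),
      feature_dim = 32L, proj_dim = 32L
    ),
    deep = list(
      stem = list(k = 7L, s = 2L, p = 3L, cin = 3L, cout = 64L),
      maxpool = TRUE,
      blocks = list(
        list(cin = 64L,  cout = 64L,  s = 1L),
        list(cin = 64L,  cout = 64L,  s = 1L),
        list(cin = 64L,  cout = 128L, s = 2L),
        list(cin = 128L, cout = 128L, s = 1L),
        list(cin = 128L, cout = 256L, s = 2L),
        list(cin = 256L, cout = 256L, s = 1L),
        list(cin = 256L, cout = 512L, s = 2L),
        list(cin = 512L, cout = 512L, s = 1L)
      ),
      feature_dim = 512L, proj_dim = 128L
    ),
    stop("unknown architecture: ", arch)
  )
}

he_init <- function(nin, nout, scale = 1) {
  matrix(stats::rnorm(nin * nout, 0, scale * sqrt(2 / nin)), nin, nout)
}

#' Create a patch feature extractor
#'
#' Residual CNN backbone whose global-average-pooled output is the node
#' feature vector. A 2-layer MLP projection head is attached for contrastive
#' pre-training only; [pretrain_encoder()] strips it from the extractor it
#' returns, and [extract_features()] never uses it.
#'
#' @param arch "small" (8 weight layers, 32-d features; desk-scale default)
#'   or "deep" (18-layer residual configuration, 512-d features).
#' @param seed seed for weight initialization.
#' @return an object of class `patch_encoder`.
#' @export
patch_encoder <- function(arch = c("small", "deep"), seed = 1L) {
  arch <- match.arg(arch)
  plan <- encoder_plan(arch)
  params <- with_seed(seed, {
    p <- list()
    st <- plan$stem
    p$stem_W <- he_init(st$k^2 * st$cin, st$cout)
    p$stem_b <- matrix(0, 1, st$cout)
    for (i in seq_along(plan$blocks)) {
      bl <- plan$blocks[[i]]
      p[[sprintf("blk%d_W1", i)]] <- he_init(9L * bl$cin, bl$cout)
      p[[sprintf("blk%d_b1", i)]] <- matrix(0, 1, bl$cout)
      # second conv damped so the residual branch starts near-identity
      p[[sprintf("blk%d_W2", i)]] <- he_init(9L * bl$cout, bl$cout, scale = 0.5)
      p[[sprintf("blk%d_b2", i)]] <- matrix(0, 1, bl$cout)
      if (bl$s != 1L || bl$cin != bl$cout) {
        p[[sprintf("blk%d_Ws", i)]] <- he_init(bl$cin, bl$cout)
        p[[sprintf("blk%d_bs", i)]] <- matrix(0, 1, bl$cout)
      }
    }
    p$proj_W1 <- he_init(plan$feature_dim, plan$feature_dim)
    p$proj_b1 <- matrix(0, 1, plan$feature_dim)
    p$proj_W2 <- he_init(plan$feature_dim, plan$proj_dim)
    p$proj_b2 <- matrix(0, 1, plan$proj_dim)
    p
  })
  structure(list(arch = arch, plan = plan, params = params,
                 feature_dim = plan$feature_dim, has_projection = TRUE,
                 seed = seed, history = NULL),
            class = "patch_encoder")
}

#' @export
print.patch_encoder <- function(x, ...) {
  cat(sprintf("<patch_encoder> arch = %s, %d-d features, projection head %s%s\n",
              x$arch, x$feature_dim,
              if (isTRUE(x$has_projection)) "attached" else "removed",
              if (is.null(x$history)) "" else sprintf(" (pre-trained %d steps)",
                                                      nrow(x$history))))
  invisible(x)
}

# Parameter-node registry: lazily wraps plain matrices as tape leaves so a
# single forward pass can collect gradients by name afterwards.
px_new <- function(tape, params) {
  e <- new.env(parent = emptyenv())
  e$tape <- tape
  e$params <- params
  e$nodes <- list()
  e
}

px_get <- function(px, name) {
  nd <- px$nodes[[name]]
  if (is.null(nd)) {
    val <- px$params[[name]]
    if (is.null(val)) stop("unknown parameter: ", name)
    nd <- ad_param(px$tape, val)
    px$nodes[[name]] <- nd
  }
  nd
}

px_grads <- function(px) {
  lapply(px$nodes, function(nd) nd$grad)
}

# Pack a list of p x p x 3 patches (0-255) into the (B*p*p) x 3 layout,
# rescaled to [-1, 1].
pack_patches <- function(patches) {
  B <- length(patches)
  p <- dim(patches[[1]])[1]
  out <- matrix(0, B * p * p, 3)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * p * p + 1L):(b * p * p)
    for (k in 1:3) out[rows, k] <- as.vector(t(patches[[b]][, , k]))
  }
  out / 127.5 - 1
}

# Backbone forward; returns the B x feature_dim node.
encoder_backbone <- function(enc, px, x, B, H, W) {
  plan <- enc$plan
  st <- plan$stem
  info <- conv_index(B, H, W, st$k, st$s, st$p)
  h <- ad_relu(ad_conv2d(x, px_get(px, "stem_W"), px_get(px, "stem_b"), info))
  H <- info$Ho; W <- info$Wo
  if (isTRUE(plan$maxpool)) {
    info <- conv_index(B, H, W, 3L, 2L, 1L)
    h <- ad_maxpool(h, info)
    H <- info$Ho; W <- info$Wo
  }
  for (i in seq_along(plan$blocks)) {
    bl <- plan$blocks[[i]]
    i1 <- conv_index(B, H, W, 3L, bl$s, 1L)
    m <- ad_relu(ad_conv2d(h, px_get(px, sprintf("blk%d_W1", i)),
                           px_get(px, sprintf("blk%d_b1", i)), i1))
    i2 <- conv_index(B, i1$Ho, i1$Wo, 3L, 1L, 1L)
    m <- ad_conv2d(m, px_get(px, sprintf("blk%d_W2", i)),
                   px_get(px, sprintf("blk%d_b2", i)), i2)
    if (bl$s != 1L || bl$cin != bl$cout) {
      is <- conv_index(B, H, W, 1L, bl$s, 0L)
      skip <- ad_conv2d(h, px_get(px, sprintf("blk%d_Ws", i)),
                        px_get(px, sprintf("blk%d_bs", i)), is)
    } else {
      skip <- h
    }
    h <- ad_relu(ad_add(m, skip))
    H <- i1$Ho; W <- i1$Wo
  }
  ad_gap(h, B, H * W)
}

encoder_projection <- function(px, feat) {
  z <- ad_relu(ad_add(ad_mm(feat, px_get(px, "proj_W1")), px_get(px, "proj_b1")))
  ad_add(ad_mm(z, px_get(px, "proj_W2")), px_get(px, "proj_b2"))
}

#' Extract node features for a patch grid
#'
#' Runs the backbone in inference mode over the patches; row `i` of the
#' result is the embedding of patch `i`, in the order of `grid$coords`.
#' Deterministic given the encoder weights.
#'
#' @param encoder a `patch_encoder`.
#' @param grid a `patch_grid` from [filter_background()], or a bare list of
#'   RGB patch arrays (0-255).
#' @param batch_size patches per forward pass.
#' @return an N x D numeric feature matrix.
#' @export
extract_features <- function(encoder, grid, batch_size = 128L) {
  patches <- if (inherits(grid, "patch_grid")) grid$patches else grid
  n <- length(patches)
  if (n == 0L) stop("no patches to embed")
  p <- dim(patches[[1]])[1]
  out <- matrix(0, n, encoder$feature_dim)
  for (s in seq(1L, n, by = batch_size)) {
    e <- min(n, s + batch_size - 1L)
    tape <- ad_tape()
    px <- px_new(tape, encoder$params)
    x <- ad_const(tape, pack_patches(patches[s:e]))
    out[s:e, ] <- ad_value(encoder_backbone(encoder, px, x, e - s + 1L, p, p))
  }
  out
}
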