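#' Augmentation policy for contrastive pre-training
#'
#' Two independent draws of the policy applied to one patch form a positive
#' pair. The policy combines random color distortion (brightness, contrast,
#' saturation and hue jitter controlled by one strength scalar), random
#' Gaussian blur, and random cropping followed by resizing back to the
#' original patch size. Setting `color_strength = 0`, `blur_sigma = c(0, 0)`
#' and `crop_scale = c(1, 1)` yields the identity policy.
#'
#' @param color_strength jitter strength in [0, 1]; brightness/contrast/
#'   saturation factors are drawn from U(1 - 0.8 s, 1 + 0.8 s) and the hue is
#'   rotated by U(-0.1 s, 0.1 s) of the hue circle.
#' @param blur_sigma range (min, max) of the Gaussian blur sigma in pixels.
#' @param crop_scale range (min, max) of the retained area fraction for the
#'   random crop.
#' @return an `augmentation_policy` object.
#' @export
augmentation_policy <- function(color_strength = 0.5, blur_sigma = c(0.1, 2),
                                crop_scale = c(0.5, 1)) {
  if (crop_scale[1] > crop_scale[2]) stop("degenerate crop range (min > max)")
  if (blur_sigma[1] > blur_sigma[2]) stop("degenerate blur range (min > max)")
  structure(list(color_strength = color_strength, blur_sigma = blur_sigma,
                 crop_scale = crop_scale),
            class = "augmentation_policy")
}

as_ebimage <- function(x) EBImage::Image(aperm(x, c(2, 1, 3)) / 255, colormode = "Color")

from_ebimage <- function(img) {
  x <- aperm(EBImage::imageData(img), c(2, 1, 3)) * 255
  pmin(pmax(x, 0), 255)
}

augment_one <- function(patch, policy) {
  p <- dim(patch)[1]
  out <- patch
  # random crop + resize back
  if (policy$crop_scale[1] < 1 || policy$crop_scale[2] < 1) {
    s <- stats::runif(1, policy$crop_scale[1], policy$crop_scale[2])
    side <- max(8L, round(p * sqrt(s)))
    if (side < p) {
      i0 <- sample.int(p - side + 1L, 1L)
      j0 <- sample.int(p - side + 1L, 1L)
      crop <- out[i0:(i0 + side - 1L), j0:(j0 + side - 1L), , drop = FALSE]
      out <- from_ebimage(EBImage::resize(as_ebimage(crop), w = p, h = p))
    }
  }
  # color distortion
  s <- policy$color_strength
  if (s > 0) {
    f <- stats::runif(3, 1 - 0.8 * s, 1 + 0.8 * s)
    out <- out * f[1]
    mu <- mean(0.299 * out[, , 1] + 0.587 * out[, , 2] + 0.114 * out[, , 3])
    out <- (out - mu) * f[2] + mu
    gray <- 0.299 * out[, , 1] + 0.587 * out[, , 2] + 0.114 * out[, , 3]
    for (k in 1:3) out[, , k] <- gray + (out[, , k] - gray) * f[3]
    out <- pmin(pmax(out, 0), 255)
    dh <- stats::runif(1, -0.1 * s, 0.1 * s)
    if (abs(dh) > 1e-8) {
      hsv <- grDevices::rgb2hsv(r = as.vector(out[, , 1]), g = as.vector(out[, , 2]),
                                b = as.vector(out[, , 3]), maxColorValue = 255)
      hsv[1, ] <- (hsv[1, ] + dh) %% 1
      rgb <- grDevices::col2rgb(grDevices::hsv(hsv[1, ], hsv[2, ], hsv[3, ]))
      for (k in 1:3) out[, , k] <- matrix(rgb[k, ], p, p)
    }
  }
  # Gaussian blur
  sig <- stats::runif(1, policy$blur_sigma[1], policy$blur_sigma[2])
  if (sig > 0.05) {
    out <- from_ebimage(EBImage::gblur(as_ebimage(out), sigma = sig))
  }
  pmin(pmax(out, 0), 255)
}

#' Two augmented views of one patch
#'
#' @param patch RGB array on the 0-255 scale.
#' @param policy an [augmentation_policy()].
#' @param seed integer; given the same seed and inputs the pair is identical
#'   across calls.
#' @return list with elements `i` and `j`, the two views.
#' @export
augment_pair <- function(patch, policy = augmentation_policy(), seed = 1L) {
  assert_rgb(patch)
  with_seed(seed, list(i = augment_one(patch, policy), j = augment_one(patch, policy)))
}

#' Cosine similarity
#'
#' `sim(u, v) = u'v / (||u|| ||v||)`; symmetric and invariant to positive
#' rescaling of either argument.
#'
#' @param u,v non-zero numeric vectors of equal length.
#' @return a value in [-1, 1].
#' @export
cosine_sim <- function(u, v) {
  if (length(u) != length(v)) stop("u and v must have equal dimension")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("undefined similarity for a zero vector")
  sum(u * v) / (nu * nv)
}

#' Normalized-temperature cross-entropy (NT-Xent) contrastive loss
#'
#' For each augmented item i with positive partner j, the per-pair loss is
#' `-log( exp(sim(z_i, z_j)/tau) / sum_{k != i} exp(sim(z_i, z_k)/tau) )`;
#' the batch loss is the mean over all 2K ordered positive pairs, i.e. both
#' (i, j) and (j, i). Always non-negative; equal to 0 when K = 1 and to
#' `log(2K - 1)` when all embeddings coincide.
#'
#' @param z numeric 2K x d matrix of projected embeddings.
#' @param tau temperature, > 0. The default 0.5 is the canonical choice for
#'   this loss family.
#' @param pairs integer vector mapping row i to its positive partner; the
#'   default pairs row i with row i + K (and back), i.e. the two views of
#'   patch i sit at rows i and i + K.
#' @return the scalar loss.
#' @export
nt_xent_loss <- function(z, tau = 0.5, pairs = NULL) {
  z <- as.matrix(z)
  n <- nrow(z)
  if (n < 2L || n %% 2L != 0L) stop("need 2K >= 2 embeddings")
  if (tau <= 0) stop("tau must be > 0")
  K <- n %/% 2L
  if (is.null(pairs)) pairs <- c((K + 1L):n, 1L:K)
  if (any(pairs[pairs] != seq_len(n)) || any(pairs == seq_len(n))) {
    stop("pairs must be a fixed-point-free involution")
  }
  nrm <- sqrt(rowSums(z^2))
  if (any(nrm == 0)) stop("undefined similarity for a zero vector")
  S <- (z / nrm) %*% t(z / nrm) / tau
  diag(S) <- -Inf   # exclude k = i from the denominator
  m <- apply(S, 1L, max)
  lse <- m + log(rowSums(exp(S - m)))
  mean(lse - S[cbind(seq_len(n), pairs)])
}

# Tape version of the same loss (used during pre-training); asserts against
# the plain implementation in tests.
nt_xent_node <- function(z, tau, pairs) {
  n <- nrow(z$val)
  zn <- ad_row_l2norm(z)
  S <- ad_scale(ad_mm(zn, ad_t(zn)), 1 / tau)
  # mask the diagonal with a large negative constant before the logsumexp
  S <- ad_addc(S, diag(-1e9, n))
  lse <- ad_row_logsumexp(S)
  P <- matrix(0, n, n)
  P[cbind(seq_len(n), pairs)] <- 1
  pos <- ad_sum(ad_mul(S, ad_const(z$tape, P)))
  ad_scale(ad_sub(ad_sum(lse), pos), 1 / n)
}

#' Contrastive pre-training of the patch encoder
#'
#' SimCLR-style loop: each step samples a mini-batch of K patches, applies
#' the augmentation policy twice to every patch, embeds the 2K views with the
#' backbone plus projection head, and minimizes the NT-Xent loss with Adam
#' under cosine learning-rate annealing. The returned extractor has the
#' projection head removed; only the backbone embeds patches downstream.
#'
#' @param encoder a [patch_encoder()].
#' @param patches non-empty list of RGB patch arrays (0-255), all one size.
#' @param steps optimization steps.
#' @param batch_size K, the number of source patches per step (2K views).
#' @param tau NT-Xent temperature.
#' @param lr initial Adam learning rate (cosine-annealed to 0 over `steps`).
#' @param policy an [augmentation_policy()].
#' @param seed seed controlling sampling and augmentation.
#' @return the trained `patch_encoder`, with `$history` logging the loss per
#'   step and `$has_projection = FALSE`.
#' @export
pretrain_encoder <- function(encoder, patches, steps = 100L, batch_size = 16L,
                             tau = 0.5, lr = 1e-4, policy = augmentation_policy(),
                             seed = 1L) {
  stopifnot(inherits(encoder, "patch_encoder"))
  if (!isTRUE(encoder$has_projection)) stop("encoder already has its projection head removed")
  if (length(patches) == 0L) stop("empty patch stream")
  p <- dim(patches[[1]])[1]
  params <- encoder$params
  opt <- adam_state(params, lr = lr)
  log <- data.frame(step = integer(0), loss = numeric(0), lr = numeric(0))
  K <- batch_size
  pairs <- c((K + 1L):(2L * K), 1L:K)
  with_seed(seed, {
    for (step in seq_len(steps)) {
      idx <- sample.int(length(patches), K, replace = length(patches) < K)
      views <- vector("list", 2L * K)
      for (b in seq_len(K)) {
        views[[b]] <- augment_one(patches[[idx[b]]], policy)
        views[[K + b]] <- augment_one(patches[[idx[b]]], policy)
      }
      tape <- ad_tape()
      px <- px_new(tape, params)
      x <- ad_const(tape, pack_patches(views))
      feat <- encoder_backbone(encoder, px, x, 2L * K, p, p)
      z <- encoder_projection(px, feat)
      loss <- nt_xent_node(z, tau, pairs)
      ad_backward(loss)
      lr_t <- lr_cosine(step - 1L, steps, lr)
      upd <- adam_step(opt, params, px_grads(px), lr = lr_t)
      opt <- upd$opt
      params <- upd$params
      log <- rbind(log, data.frame(step = step, loss = ad_value(loss)[1], lr = lr_t))
    }
  })
  encoder$params <- params[setdiff(names(params), c("proj_W1", "proj_b1", "proj_W2", "proj_b2"))]
  encoder$has_projection <- FALSE
  encoder$history <- log
  encoder
}
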