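# Convolutional primitives on the autodiff tape.
#
# A feature map batch is a (B*H*W) x C matrix; row order is batch-major,
# then image row, then image column. Convolution is im2col + matmul; the
# im2col gather indices depend only on (B, H, W, k, stride, pad) and are
# cached across calls.

.conv_idx_cache <- new.env(parent = emptyenv())

conv_index <- function(B, H, W, k, stride, pad) {
  key <- paste(B, H, W, k, stride, pad, sep = "_")
  hit <- .conv_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  Ho <- (H + 2L * pad - k) %/% stride + 1L
  Wo <- (W + 2L * pad - k) %/% stride + 1L
  stopifnot(Ho >= 1L, Wo >= 1L)
  oi <- rep(seq_len(Ho), each = Wo)
  oj <- rep(seq_len(Wo), times = Ho)
  i0 <- (oi - 1L) * stride - pad
  j0 <- (oj - 1L) * stride - pad
  KK <- k * k
  base <- matrix(0L, Ho * Wo, KK)
  for (ki in seq_len(k)) {
    for (kj in seq_len(k)) {
      q <- (ki - 1L) * k + kj
      ii <- i0 + ki
      jj <- j0 + kj
      ok <- ii >= 1L & ii <= H & jj >= 1L & jj <= W
      v <- integer(Ho * Wo)
      v[ok] <- (ii[ok] - 1L) * W + jj[ok]
      base[, q] <- v
    }
  }
  sentinel <- B * H * W + 1L
  idx <- matrix(0L, B * Ho * Wo, KK)
  for (b in seq_len(B)) {
    blk <- base
    blk[base > 0L] <- base[base > 0L] + (b - 1L) * H * W
    blk[base == 0L] <- sentinel
    idx[((b - 1L) * Ho * Wo + 1L):(b * Ho * Wo), ] <- blk
  }
  info <- list(idx = idx, B = B, Ho = Ho, Wo = Wo, H = H, W = W,
               k = k, KK = KK, sentinel = sentinel)
  .conv_idx_cache[[key]] <- info
  info
}

# im2col gather: (B*Ho*Wo) x (KK*C), kernel-position-major column blocks.
ad_im2col <- function(x, info) {
  xa <- rbind(x$val, 0)
  idx <- info$idx
  KK <- info$KK
  C <- ncol(xa)
  R <- nrow(idx)
  out <- matrix(0, R, KK * C)
  for (q in seq_len(KK)) {
    out[, ((q - 1L) * C + 1L):(q * C)] <- xa[idx[, q], , drop = FALSE]
  }
  ad_node(x$tape, out, list(x), function(g, nd) {
    xv <- nd$parents[[1]]$val
    gs <- matrix(0, R * KK, C)
    for (q in seq_len(KK)) {
      gs[((q - 1L) * R + 1L):(q * R), ] <- g[, ((q - 1L) * C + 1L):(q * C), drop = FALSE]
    }
    acc <- rowsum(gs, group = as.vector(idx))
    keys <- as.integer(rownames(acc))
    keep <- keys != info$sentinel
    dx <- matrix(0, nrow(xv), ncol(xv))
    dx[keys[keep], ] <- acc[keep, , drop = FALSE]
    list(dx)
  })
}

# conv: weight (KK*C_in) x C_out, bias 1 x C_out.
ad_conv2d <- function(x, w, b, info) {
  ad_add(ad_mm(ad_im2col(x, info), w), b)
}

# Max pooling over a k x k window; padding contributes -Inf.
ad_maxpool <- function(x, info) {
  xa <- rbind(x$val, -Inf)
  idx <- info$idx
  R <- nrow(idx)
  C <- ncol(x$val)
  v <- matrix(0, R, C)
  amax <- matrix(0L, R, C)
  for (cc in seq_len(C)) {
    M <- matrix(xa[idx, cc], R, info$KK)
    j <- max.col(M, ties.method = "first")
    amax[, cc] <- idx[cbind(seq_len(R), j)]
    v[, cc] <- M[cbind(seq_len(R), j)]
  }
  ad_node(x$tape, v, list(x), function(g, nd) {
    xv <- nd$parents[[1]]$val
    dx <- matrix(0, nrow(xv), ncol(xv))
    for (cc in seq_len(C)) {
      acc <- rowsum(g[, cc], group = amax[, cc])
      keys <- as.integer(rownames(acc))
      keep <- keys <= nrow(xv)
      dx[keys[keep], cc] <- dx[keys[keep], cc] + acc[keep]
    }
    list(dx)
  })
}

# Global average pooling: (B*H*W) x C -> B x C.
ad_gap <- function(x, B, HW) {
  ad_group_mean(x, group = rep(seq_len(B), each = HW), ngroups = B)
}
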