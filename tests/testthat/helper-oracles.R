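# Independent oracles and small fixtures shared across test files.

sg <- asNamespace("slidegraph")

# central finite differences of a scalar function of a matrix
num_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# brute-force triple loop for ReLU(A H W)
gc_layer_loop <- function(H, A_hat, W) {
  n <- nrow(H); dout <- ncol(W)
  out <- matrix(0, n, dout)
  P <- matrix(0, n, ncol(H))
  for (i in seq_len(n)) for (j in seq_len(ncol(H))) {
    for (l in seq_len(n)) P[i, j] <- P[i, j] + A_hat[i, l] * H[l, j]
  }
  for (i in seq_len(n)) for (j in seq_len(dout)) {
    for (l in seq_len(ncol(H))) out[i, j] <- out[i, j] + P[i, l] * W[l, j]
    out[i, j] <- max(out[i, j], 0)
  }
  out
}

# row-wise softmax by explicit loops
softmax_loop <- function(Z) {
  out <- matrix(0, nrow(Z), ncol(Z))
  for (i in seq_len(nrow(Z))) {
    e <- numeric(ncol(Z))
    for (j in seq_len(ncol(Z))) e[j] <- exp(Z[i, j])
    out[i, ] <- e / sum(e)
  }
  out
}

# one-vs-rest confusion counts by explicit comparison
confusion_loop <- function(y_true, y_pred, n_classes) {
  out <- NULL
  for (cl in seq_len(n_classes)) {
    tp <- fp <- fn <- tn <- 0
    for (i in seq_along(y_true)) {
      if (y_true[i] == cl && y_pred[i] == cl) tp <- tp + 1
      if (y_true[i] != cl && y_pred[i] == cl) fp <- fp + 1
      if (y_true[i] == cl && y_pred[i] != cl) fn <- fn + 1
      if (y_true[i] != cl && y_pred[i] != cl) tn <- tn + 1
    }
    out <- rbind(out, c(tp = tp, fp = fp, fn = fn, tn = tn))
  }
  out
}

# Mann-Whitney pair counting: P(score_pos > score_neg) + 0.5 P(tie)
mw_auc <- function(truth, score) {
  pos <- score[truth]; neg <- score[!truth]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# random grid-subset graph with features
random_fixture_graph <- function(n_side = 4, d = 6, keep = 0.8, seed = 1,
                                 connectivity = 8L) {
  set.seed(seed)
  all_coords <- as.matrix(expand.grid(0:(n_side - 1), 0:(n_side - 1)))
  repeat {
    sel <- which(runif(nrow(all_coords)) < keep)
    if (length(sel) >= 2) break
  }
  coords <- all_coords[sel, , drop = FALSE]
  F <- matrix(rnorm(length(sel) * d), length(sel), d)
  suppressWarnings(build_graph(F, coords, connectivity = connectivity, label = "x"))
}

# small untrained model wrapper for forward-pass tests
tiny_model <- function(feature_dim = 6, n_classes = 3, seed = 7, ...) {
  cfg <- gtp_config("desk", hidden_dim = 8L, n_heads = 2L, n_clusters = 3L,
                    mlp_dim = 8L, n_blocks = 2L, n_classes = n_classes, ...)
  list(params = sg$gtp_init(cfg, feature_dim, seed = seed), config = cfg,
       classes = paste0("c", seq_len(n_classes)))
}

# flat test patch filled with one RGB color
flat_patch <- function(p, rgb) {
  out <- array(0, c(p, p, 3))
  for (k in 1:3) out[, , k] <- rgb[k]
  out
}
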