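#' Core model operations (standalone forms)
#'
#' Plain-matrix versions of the building blocks used inside
#' [gtp_forward()], exposed for inspection and testing. The trained model
#' evaluates the identical math on the autodiff tape.
#'
#' @param H node feature matrix (N x C_in).
#' @param A_hat symmetric normalized adjacency from [normalize_adjacency()].
#' @param W learnable filter matrix (C_in x C_out).
#' @return `gc_layer()` returns `ReLU(A_hat H W)`, the propagation and
#'   aggregation step of one graph-convolution layer.
#' @export
gc_layer <- function(H, A_hat, W) {
  H <- as.matrix(H); A_hat <- as.matrix(A_hat); W <- as.matrix(W)
  if (ncol(A_hat) != nrow(H) || ncol(H) != nrow(W)) stop("shape mismatch")
  if (!isTRUE(all.equal(A_hat, t(A_hat)))) stop("A_hat must be symmetric")
  pmax(A_hat %*% H %*% W, 0)
}

#' @rdname gc_layer
#' @param A binary adjacency (used by the min-cut objective).
#' @param S optional N x K soft assignment; when NULL it is computed as the
#'   row-softmax of `H %*% W_pool + b_pool`.
#' @param W_pool,b_pool assignment parameters (required when `S` is NULL).
#' @return `mincut_pool()` returns a list with the pooled features
#'   `X_pool = t(S) H`, the re-normalized pooled adjacency `A_pool`, the
#'   assignment `S` (rows sum to 1), and the auxiliary losses: `cut` (the
#'   negative relaxed normalized-cut ratio, in [-1, 0]) and `ortho` (the
#'   assignment-orthogonality residual, >= 0).
#' @export
mincut_pool <- function(H, A, S = NULL, W_pool = NULL, b_pool = NULL) {
  H <- as.matrix(H); A <- as.matrix(A)
  if (is.null(S)) {
    if (is.null(W_pool)) stop("provide S or W_pool")
    if (ncol(W_pool) < 1L) stop("n_clusters must be >= 1")
    Z <- H %*% W_pool
    if (!is.null(b_pool)) Z <- sweep(Z, 2L, as.vector(b_pool), "+")
    Z <- Z - apply(Z, 1L, max)
    S <- exp(Z) / rowSums(exp(Z))
  } else {
    S <- as.matrix(S)
  }
  K <- ncol(S)
  X_pool <- t(S) %*% H
  cut <- if (sum(A) > 0) {
    -sum(S * (A %*% S)) / sum(rowSums(A) * rowSums(S^2))
  } else 0
  SS <- t(S) %*% S
  ortho <- norm(SS / norm(SS, "F") - diag(K) / sqrt(K), "F")
  Ap <- t(S) %*% A %*% S
  diag(Ap) <- 0
  dp <- rowSums(Ap) + 1
  A_pool <- (Ap + diag(K)) * outer(1 / sqrt(dp), 1 / sqrt(dp))
  list(X_pool = X_pool, A_pool = A_pool, S = S, cut = cut, ortho = ortho)
}

#' @rdname gc_layer
#' @param q,k query and key matrices (tokens x head_dim).
#' @return `attention_map()` returns `softmax(q k' / sqrt(head_dim))`, one
#'   attention row per token (each row sums to 1).
#' @export
attention_map <- function(q, k) {
  q <- as.matrix(q); k <- as.matrix(k)
  if (ncol(q) != ncol(k)) stop("q and k must share the head dimension")
  Z <- q %*% t(k) / sqrt(ncol(q))
  Z <- Z - apply(Z, 1L, max)
  exp(Z) / rowSums(exp(Z))
}
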