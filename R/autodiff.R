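# Reverse-mode autodiff on a linear tape.
#
# Every value is a numeric matrix. Nodes are environments holding the value,
# the accumulated gradient, parent links and a backward closure; the tape
# records creation order, so reverse iteration is a valid topological order.
# This is the substrate for the contrastive CNN, the graph-transformer and
# GraphCAM's attention gradients.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  class(tp) <- "ad_tape"
  tp
}

ad_node <- function(tape, val, parents = list(), backfn = NULL, needs = NA) {
  if (!is.matrix(val)) val <- as.matrix(val)
  if (is.na(needs)) {
    needs <- FALSE
    for (p in parents) if (!is.null(p) && isTRUE(p$needs)) { needs <- TRUE; break }
  }
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- if (needs) backfn else NULL
  nd$needs <- needs
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd$id <- n
  nd$tape <- tape
  nd
}

ad_const <- function(tape, x) ad_node(tape, x, needs = FALSE)

ad_param <- function(tape, x) ad_node(tape, x, needs = TRUE)

ad_value <- function(nd) nd$val

ad_grad <- function(nd) {
  if (is.null(nd$grad)) array(0, dim(nd$val)) else nd$grad
}

#' @noRd
ad_backward <- function(loss) {
  stopifnot(length(loss$val) == 1L)
  tape <- loss$tape
  for (i in seq_len(tape$n)) tape$nodes[[i]]$grad <- NULL
  loss$grad <- matrix(1, 1, 1)
  for (i in seq.int(loss$id, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad, nd)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      if (is.null(p) || !isTRUE(p$needs) || is.null(gs[[j]])) next
      p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
    }
  }
  invisible(loss)
}

# ---- elementary ops ---------------------------------------------------------

ad_mm <- function(a, b) {
  ad_node(a$tape, a$val %*% b$val, list(a, b), function(g, nd) {
    list(g %*% t(nd$parents[[2]]$val), t(nd$parents[[1]]$val) %*% g)
  })
}

# Addition with row-vector (1 x n) and scalar (1 x 1) broadcasting on `b`.
ad_add <- function(a, b) {
  av <- a$val; bv <- b$val
  v <- if (identical(dim(av), dim(bv))) av + bv
       else if (all(dim(bv) == c(1L, ncol(av)))) sweep(av, 2L, as.vector(bv), "+")
       else if (length(bv) == 1L) av + bv[1L]
       else stop("ad_add: incompatible shapes")
  ad_node(a$tape, v, list(a, b), function(g, nd) {
    bv <- nd$parents[[2]]$val
    gb <- if (identical(dim(g), dim(bv))) g
          else if (length(bv) == 1L) matrix(sum(g), 1, 1)
          else matrix(colSums(g), 1L)
    list(g, gb)
  })
}

ad_sub <- function(a, b) ad_add(a, ad_scale(b, -1))

ad_scale <- function(a, s) {
  ad_node(a$tape, a$val * s, list(a), function(g, nd) list(g * s))
}

ad_addc <- function(a, k) {
  ad_node(a$tape, a$val + k, list(a), function(g, nd) list(g))
}

# Elementwise product; `b` may be 1 x 1.
ad_mul <- function(a, b) {
  av <- a$val; bv <- b$val
  v <- if (length(bv) == 1L) av * bv[1L] else av * bv
  ad_node(a$tape, v, list(a, b), function(g, nd) {
    av <- nd$parents[[1]]$val; bv <- nd$parents[[2]]$val
    if (length(bv) == 1L) list(g * bv[1L], matrix(sum(g * av), 1, 1))
    else list(g * bv, g * av)
  })
}

ad_div <- function(a, b) {
  av <- a$val; bv <- b$val
  v <- if (length(bv) == 1L) av / bv[1L] else av / bv
  ad_node(a$tape, v, list(a, b), function(g, nd) {
    av <- nd$parents[[1]]$val; bv <- nd$parents[[2]]$val
    if (length(bv) == 1L) list(g / bv[1L], matrix(-sum(g * av) / bv[1L]^2, 1, 1))
    else list(g / bv, -g * av / bv^2)
  })
}

ad_relu <- function(a) {
  ad_node(a$tape, pmax(a$val, 0), list(a), function(g, nd) {
    list(g * (nd$parents[[1]]$val > 0))
  })
}

ad_gelu <- function(a) {
  k <- sqrt(2 / pi)
  x <- a$val
  u <- k * (x + 0.044715 * x^3)
  th <- tanh(u)
  ad_node(a$tape, 0.5 * x * (1 + th), list(a), function(g, nd) {
    x <- nd$parents[[1]]$val
    u <- k * (x + 0.044715 * x^3)
    th <- tanh(u)
    d <- 0.5 * (1 + th) + 0.5 * x * (1 - th^2) * k * (1 + 3 * 0.044715 * x^2)
    list(g * d)
  })
}

ad_exp <- function(a) {
  v <- exp(a$val)
  ad_node(a$tape, v, list(a), local({ vv <- v; function(g, nd) list(g * vv) }))
}

ad_log <- function(a) {
  ad_node(a$tape, log(a$val), list(a), function(g, nd) list(g / nd$parents[[1]]$val))
}

ad_sqrt <- function(a) {
  v <- sqrt(a$val)
  ad_node(a$tape, v, list(a), local({ vv <- v; function(g, nd) list(g / (2 * vv)) }))
}

ad_sum <- function(a) {
  ad_node(a$tape, matrix(sum(a$val), 1, 1), list(a), function(g, nd) {
    list(array(g[1L], dim(nd$parents[[1]]$val)))
  })
}

ad_mean <- function(a) ad_scale(ad_sum(a), 1 / length(a$val))

ad_t <- function(a) {
  ad_node(a$tape, t(a$val), list(a), function(g, nd) list(t(g)))
}

ad_rbind2 <- function(a, b) {
  na <- nrow(a$val)
  ad_node(a$tape, rbind(a$val, b$val), list(a, b), function(g, nd) {
    na <- nrow(nd$parents[[1]]$val)
    list(g[seq_len(na), , drop = FALSE], g[-seq_len(na), , drop = FALSE])
  })
}

ad_cbind <- function(nodes) {
  vals <- lapply(nodes, `[[`, "val")
  widths <- vapply(vals, ncol, 1L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_node(nodes[[1]]$tape, do.call(cbind, vals), nodes, function(g, nd) {
    lapply(seq_along(nd$parents), function(j) g[, starts[j]:ends[j], drop = FALSE])
  })
}

ad_rows <- function(a, idx) {
  ad_node(a$tape, a$val[idx, , drop = FALSE], list(a), function(g, nd) {
    av <- nd$parents[[1]]$val
    out <- matrix(0, nrow(av), ncol(av))
    acc <- rowsum(g, group = idx)
    out[as.integer(rownames(acc)), ] <- acc
    list(out)
  })
}

ad_cols <- function(a, idx) {
  ad_node(a$tape, a$val[, idx, drop = FALSE], list(a), function(g, nd) {
    av <- nd$parents[[1]]$val
    out <- matrix(0, nrow(av), ncol(av))
    acc <- t(rowsum(t(g), group = idx))
    out[, as.integer(colnames(acc))] <- acc
    list(out)
  })
}

ad_row_softmax <- function(a) {
  x <- a$val
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  y <- e / rowSums(e)
  ad_node(a$tape, y, list(a), local({ yy <- y; function(g, nd) {
    list(yy * (g - rowSums(g * yy)))
  }}))
}

ad_row_logsumexp <- function(a) {
  x <- a$val
  m <- apply(x, 1L, max)
  v <- m + log(rowSums(exp(x - m)))
  ad_node(a$tape, matrix(v, ncol = 1L), list(a), function(g, nd) {
    x <- nd$parents[[1]]$val
    m <- apply(x, 1L, max)
    e <- exp(x - m)
    list(as.vector(g) * e / rowSums(e))
  })
}

# Row-wise layer normalization with learnable gain/bias (1 x d each).
ad_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- x$val
  n <- ncol(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  va <- rowMeans(xc^2)
  sd <- sqrt(va + eps)
  xhat <- xc / sd
  v <- sweep(sweep(xhat, 2L, as.vector(gamma$val), "*"), 2L, as.vector(beta$val), "+")
  ad_node(x$tape, v, list(x, gamma, beta), local({
    xh <- xhat; s <- sd
    function(g, nd) {
      gm <- nd$parents[[2]]$val
      dgamma <- matrix(colSums(g * xh), 1L)
      dbeta <- matrix(colSums(g), 1L)
      dxh <- sweep(g, 2L, as.vector(gm), "*")
      dx <- (dxh - rowMeans(dxh) - xh * rowMeans(dxh * xh)) / s
      list(dx, dgamma, dbeta)
    }
  }))
}

# Rows scaled to unit L2 norm.
ad_row_l2norm <- function(x) {
  xv <- x$val
  nrm <- sqrt(rowSums(xv^2))
  y <- xv / nrm
  ad_node(x$tape, y, list(x), local({ yy <- y; nn <- nrm; function(g, nd) {
    list((g - yy * rowSums(g * yy)) / nn)
  }}))
}

# Mean over row groups (e.g. global average pooling over spatial positions).
ad_group_mean <- function(x, group, ngroups) {
  cnt <- tabulate(group, nbins = ngroups)
  v <- rowsum(x$val, group = group) / cnt
  ad_node(x$tape, v, list(x), function(g, nd) {
    list(g[group, , drop = FALSE] / cnt[group])
  })
}
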