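test_that("the GC layer matches identity cases, hand values and a loop oracle", {
  H <- matrix(c(1, 2, 0, 3), 2, 2)
  expect_equal(gc_layer(H, diag(2), diag(2)), H)
  expect_equal(gc_layer(diag(2), matrix(0.5, 2, 2), diag(2)), matrix(0.5, 2, 2))
  set.seed(5)
  for (rep in 1:5) {
    g <- random_fixture_graph(4, d = 7, seed = rep)
    W <- matrix(rnorm(7 * 3), 7, 3)
    expect_equal(gc_layer(g$F, g$A_hat, W), gc_layer_loop(g$F, g$A_hat, W),
                 tolerance = 1e-6)
  }
  expect_error(gc_layer(matrix(0, 2, 2), diag(3), diag(2)), "shape")
})

test_that("min-cut pooling aggregates by the soft assignment and bounds its losses", {
  H <- rbind(c(1, 1), c(3, 3), c(5, 5))
  A <- build_adjacency(rbind(c(0, 0), c(0, 1), c(0, 2)), 4)
  # all nodes to one cluster: pooled row = column sums
  S1 <- matrix(1, 3, 1)
  expect_equal(mincut_pool(H, A, S = S1)$X_pool, matrix(c(9, 9), 1, 2))
  # identity assignment: pooling is a no-op
  expect_equal(mincut_pool(H, A, S = diag(3))$X_pool, H)
  # hand case: nodes {1,2} -> c1, {3} -> c2
  S2 <- rbind(c(1, 0), c(1, 0), c(0, 1))
  expect_equal(mincut_pool(H, A, S = S2)$X_pool, rbind(c(4, 4), c(5, 5)))
  expect_error(mincut_pool(H, A, W_pool = matrix(0, 2, 0)), "n_clusters")
  # learned assignment path: rows sum to 1, losses in their documented ranges
  set.seed(8)
  for (rep in 1:10) {
    g <- random_fixture_graph(4, d = 5, seed = rep)
    W <- matrix(rnorm(5 * 3), 5, 3)
    out <- mincut_pool(g$F, g$A, W_pool = W, b_pool = matrix(0.1, 1, 3))
    expect_equal(rowSums(out$S), rep(1, nrow(g$F)), tolerance = 1e-9)
    expect_gte(out$cut, -1)
    expect_lte(out$cut, 0)
    expect_gte(out$ortho, 0)
    # pooled features match the definition
    expect_equal(out$X_pool, t(out$S) %*% g$F, tolerance = 1e-9)
  }
})

test_that("attention maps are row-normalized softmax of scaled scores", {
  q <- rbind(1, 0)
  k <- rbind(1, 0)
  A <- attention_map(q, k)   # head_dim 1: rows softmax([1,0]) and [0.5,0.5]
  expect_equal(A[1, ], exp(c(1, 0)) / sum(exp(c(1, 0))), tolerance = 1e-6)
  expect_equal(A[2, ], c(0.5, 0.5))
  expect_equal(attention_map(matrix(2, 1, 1), matrix(2, 1, 1)), matrix(1, 1, 1))
  set.seed(3)
  q <- matrix(rnorm(12 * 4), 12, 4); k <- matrix(rnorm(12 * 4), 12, 4)
  A <- attention_map(q, k)
  expect_equal(rowSums(A), rep(1, 12), tolerance = 1e-9)
  expect_equal(A, softmax_loop(q %*% t(k) / sqrt(4)), tolerance = 1e-6)
})

test_that("forward pass components agree with standalone recomputation", {
  g <- random_fixture_graph(4, d = 6, seed = 13)
  mod <- tiny_model(feature_dim = 6, seed = 2)
  fw <- gtp_forward(mod, g)
  p <- mod$params
  # recompute the GC stack and pooling outside the tape
  H1 <- sweep(g$F %*% p$W_in, 2, as.vector(p$b_in), "+")
  H2 <- gc_layer(H1, g$A_hat, p$gc_W1)
  expect_equal(fw$trace$H[[1]], H2, tolerance = 1e-6)
  mp <- mincut_pool(H2, g$A, W_pool = p$pool_W, b_pool = p$pool_b)
  expect_equal(fw$trace$S, mp$S, tolerance = 1e-6)
  expect_equal(fw$trace$X_pool, mp$X_pool, tolerance = 1e-6)
  expect_equal(fw$trace$cut_loss, mp$cut, tolerance = 1e-6)
  expect_equal(fw$trace$ortho_loss, mp$ortho, tolerance = 1e-6)
  # attention rows sum to 1 in every block and head
  for (bl in fw$trace$attention) for (Ah in bl) {
    expect_equal(rowSums(Ah), rep(1, nrow(Ah)), tolerance = 1e-9)
    expect_equal(dim(Ah), rep(1L + mod$config$n_clusters, 2))
  }
  expect_equal(sum(fw$probabilities), 1, tolerance = 1e-6)
})

test_that("zero classifier head gives uniform class probabilities", {
  g <- random_fixture_graph(3, d = 4, keep = 1, seed = 4)
  mod <- tiny_model(feature_dim = 4, n_classes = 3)
  mod$params$head_W[] <- 0
  mod$params$head_b[] <- 0
  expect_equal(unname(gtp_forward(mod, g)$probabilities), rep(1 / 3, 3),
               tolerance = 1e-12)
})

test_that("forward is invariant to joint node permutations", {
  set.seed(42)
  for (rep in 1:5) {
    g <- random_fixture_graph(4, d = 6, keep = 0.85, seed = 100 + rep)
    mod <- tiny_model(feature_dim = 6, seed = rep)
    base <- gtp_forward(mod, g)$probabilities
    n <- nrow(g$F)
    for (k in 1:20) {
      perm <- sample(n)
      gp <- suppressWarnings(build_graph(g$F[perm, , drop = FALSE],
                                         g$coords[perm, , drop = FALSE], 8))
      expect_equal(gtp_forward(mod, gp)$probabilities, base, tolerance = 1e-5)
    }
  }
})

test_that("forward handles N = 1, 5 and 500 without reconfiguration", {
  mod <- tiny_model(feature_dim = 6, seed = 3)
  set.seed(6)
  for (n_side in c(1, 5, 23)) {   # 1, 25 - subset, 529 - subset nodes
    coords <- as.matrix(expand.grid(0:(n_side - 1), 0:(n_side - 1)))
    if (n_side == 5) coords <- coords[1:5, , drop = FALSE]
    if (n_side == 23) coords <- coords[1:500, , drop = FALSE]
    F <- matrix(rnorm(nrow(coords) * 6), ncol = 6)
    g <- suppressWarnings(build_graph(F, coords, 8))
    pr <- gtp_forward(mod, g)$probabilities
    expect_equal(sum(pr), 1, tolerance = 1e-6)
  }
  expect_error(sg$gtp_forward_nodes(NULL, list(F = matrix(0, 0, 6)), mod$config, NULL),
               "empty")
})

test_that("total loss combines cross-entropy with weighted auxiliaries", {
  expect_equal(total_loss(c(0, 1, 0), 2), 0)
  expect_equal(total_loss(rep(1 / 3, 3), 1), log(3), tolerance = 1e-12)
  expect_equal(total_loss(c(0.2, 0.8), 1, aux_losses = c(cut = -0.5, ortho = 0.3),
                          lambda_cut = 0, lambda_ortho = 0),
               -log(0.2), tolerance = 1e-12)
  expect_equal(total_loss(c(0.5, 0.5), 1, aux_losses = c(cut = -0.4, ortho = 0.2),
                          lambda_cut = 2, lambda_ortho = 1),
               -log(0.5) - 0.8 + 0.2, tolerance = 1e-12)
  expect_error(total_loss(c(0.5, 0.5), 3), "out of range")
})

test_that("the step-decay schedule reproduces the printed learning rates", {
  lr <- function(step) sg$lr_step_decay(step, 1e-3, c(30L, 100L), c(0.1, 0.01))
  expect_equal(lr(0), 1e-3)
  expect_equal(lr(29), 1e-3)
  expect_equal(lr(30), 1e-4)
  expect_equal(lr(99), 1e-4)
  expect_equal(lr(100), 1e-5)
  expect_equal(lr(149), 1e-5)
})

test_that("configuration validates head divisibility and cluster count", {
  expect_error(gtp_config("desk", hidden_dim = 30L, n_heads = 4L), "divisible")
  expect_error(gtp_config("desk", n_clusters = 0L), "n_clusters")
  cfg <- gtp_config("standard")
  expect_equal(cfg$head_dim * cfg$n_heads, cfg$hidden_dim)
  wide <- gtp_config("wide")
  expect_equal(wide$n_gc_layers, 3L)
  expect_equal(wide$n_clusters, 120L)
})

make_teaching_graphs <- function(n, seed) {
  # two classes separated by a mean shift in feature space
  set.seed(seed)
  graphs <- list(); labels <- character(n)
  for (i in seq_len(n)) {
    lab <- if (i %% 2 == 0) "a" else "b"
    mu <- if (lab == "a") 1 else -1
    coords <- as.matrix(expand.grid(0:2, 0:2))
    F <- matrix(rnorm(9 * 4, mean = mu, sd = 0.5), 9, 4)
    graphs[[i]] <- build_graph(F, coords, 8, label = lab)
    labels[i] <- lab
  }
  list(graphs = graphs, labels = labels)
}

test_that("training is reproducible and rejects degenerate label sets", {
  d <- make_teaching_graphs(8, seed = 1)
  cfg <- gtp_config("desk", hidden_dim = 8L, n_heads = 2L, n_clusters = 3L,
                    mlp_dim = 8L, n_blocks = 1L, n_classes = 2L,
                    steps = 10L, batch_size = 4L, val_fraction = 0.25,
                    eval_every = 5L, seed = 42L)
  f1 <- gtp_train(d$graphs, d$labels, cfg)
  f2 <- gtp_train(d$graphs, d$labels, cfg)
  expect_identical(f1$history$loss, f2$history$loss)
  expect_identical(f1$params, f2$params)
  expect_error(gtp_train(d$graphs, rep("a", 8), cfg), "single class")
  expect_error(gtp_train(d$graphs, d$labels, gtp_config("desk", n_classes = 3L,
                                                        steps = 5L)),
               "classes")
  # history logs every term separately
  expect_true(all(c("loss", "ce", "cut", "ortho", "lr", "val_loss") %in%
                  names(f1$history)))
  P <- predict(f1, d$graphs[1:2])
  expect_equal(rowSums(P), c(1, 1), tolerance = 1e-9)
  expect_s3_class(predict(f1, d$graphs[[1]], type = "class"), "factor")
})

test_that("a small GTP can overfit eight separable graphs (majority over 3 seeds)", {
  d <- make_teaching_graphs(8, seed = 3)
  wins <- 0L
  for (s in 1:3) {
    cfg <- gtp_config("desk", hidden_dim = 8L, n_heads = 2L, n_clusters = 4L,
                      mlp_dim = 8L, n_blocks = 1L, n_classes = 2L,
                      steps = 200L, batch_size = 8L, val_fraction = 0,
                      decay_steps = c(150L), decay_factors = c(0.1),
                      seed = s)
    fit <- gtp_train(d$graphs, d$labels, cfg)
    acc <- mean(predict(fit, d$graphs, type = "class") == d$labels)
    if (acc == 1) wins <- wins + 1L
  }
  expect_gte(wins, 2L)
})

test_that("checkpoints round-trip with a JSON sidecar", {
  d <- make_teaching_graphs(8, seed = 2)
  cfg <- gtp_config("desk", hidden_dim = 8L, n_heads = 2L, n_clusters = 3L,
                    mlp_dim = 8L, n_blocks = 1L, n_classes = 2L,
                    steps = 4L, batch_size = 4L, val_fraction = 0.25, seed = 9L)
  fit <- gtp_train(d$graphs, d$labels, cfg)
  path <- withr::local_tempfile(fileext = ".rds")
  save_gtp(fit, path)
  back <- load_gtp(path)
  expect_identical(back$params, fit$params)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$hidden_dim, 8L)
  expect_equal(unlist(side$classes), c("a", "b"))
})
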