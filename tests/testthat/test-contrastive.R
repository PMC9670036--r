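test_that("cosine similarity matches hand values and rejects zero vectors", {
  expect_equal(cosine_sim(c(1, 0), c(1, 0)), 1)
  expect_equal(cosine_sim(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_sim(c(1, 1), c(1, 0)), 1 / sqrt(2))
  expect_equal(cosine_sim(3 * c(1, 1), c(1, 0)), cosine_sim(c(1, 1), c(1, 0)))
  expect_error(cosine_sim(c(0, 0), c(1, 0)), "undefined")
  expect_error(cosine_sim(c(1, 0), c(1, 0, 0)), "dimension")
})

test_that("NT-Xent loss matches its closed forms", {
  # K = 1: the only other item is the positive partner, so each per-pair
  # loss is -log(1) = 0
  set.seed(1)
  z <- matrix(rnorm(2 * 8), 2, 8)
  expect_equal(nt_xent_loss(z, tau = 0.5), 0, tolerance = 1e-6)
  expect_equal(nt_xent_loss(z, tau = 3), 0, tolerance = 1e-6)
  # all 2K embeddings identical, K = 4: every similarity is 1, so the loss
  # is log(2K - 1) = log 7 for any tau
  z7 <- matrix(rep(c(1, 2, 3), each = 8), 8, 3)
  expect_equal(nt_xent_loss(z7, tau = 0.5), log(7), tolerance = 1e-6)
  # K = 2, tau = 0.5, positives identical, negatives orthogonal:
  # l = -log(e^2 / (e^2 + 2))
  z4 <- rbind(c(1, 0), c(0, 1), c(1, 0), c(0, 1))
  expect_equal(nt_xent_loss(z4, tau = 0.5), -log(exp(2) / (exp(2) + 2)),
               tolerance = 1e-6)
  expect_error(nt_xent_loss(z4, tau = 0), "tau")
  expect_error(nt_xent_loss(z4, pairs = c(2, 1, 4, 4)), "involution")
})

test_that("NT-Xent is non-negative and invariant to a common rotation", {
  set.seed(7)
  for (K in c(2, 4, 8)) {
    z <- matrix(rnorm(2 * K * 6), 2 * K, 6)
    l <- nt_xent_loss(z, tau = 0.5)
    expect_gte(l, 0)
    # cosine similarity is rotation invariant
    Q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
    expect_equal(nt_xent_loss(z %*% Q, tau = 0.5), l, tolerance = 1e-9)
  }
})

test_that("tape NT-Xent equals the plain loss and its gradient is exact", {
  set.seed(11)
  Z <- matrix(rnorm(4 * 5), 4, 5)
  pairs <- c(3, 4, 1, 2)
  tape <- sg$ad_tape()
  zn <- sg$ad_param(tape, Z)
  ln <- sg$nt_xent_node(zn, 0.5, pairs)
  expect_equal(sg$ad_value(ln)[1], nt_xent_loss(Z, 0.5, pairs), tolerance = 1e-10)
  sg$ad_backward(ln)
  nu <- num_grad(function(v) nt_xent_loss(v, 0.5, pairs), Z)
  expect_lt(max(abs(zn$grad - nu)), 1e-4)
})

test_that("augmentation pairs are reproducible and the identity policy is a no-op", {
  set.seed(2)
  patch <- array(runif(32 * 32 * 3, 40, 220), c(32, 32, 3))
  idp <- augmentation_policy(color_strength = 0, blur_sigma = c(0, 0),
                             crop_scale = c(1, 1))
  pr <- augment_pair(patch, idp, seed = 5)
  expect_equal(pr$i, patch)
  expect_equal(pr$j, patch)
  pol <- augmentation_policy()
  a <- augment_pair(patch, pol, seed = 9)
  b <- augment_pair(patch, pol, seed = 9)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$i, a$j)))
  expect_error(augmentation_policy(crop_scale = c(0.9, 0.5)), "degenerate")
})

test_that("aggressive cropping changes patch statistics for some seeds", {
  patch <- array(0, c(32, 32, 3))
  patch[17:32, , ] <- 255   # half black, half white
  pol <- augmentation_policy(color_strength = 0, blur_sigma = c(0, 0),
                             crop_scale = c(0.5, 0.5))
  means <- vapply(1:100, function(s) mean(augment_pair(patch, pol, seed = s)$i),
                  numeric(1))
  expect_gt(sum(abs(means - mean(patch)) > 1), 0)
})

test_that("feature extraction is deterministic and row-aligned", {
  enc <- patch_encoder("small", seed = 3)
  set.seed(4)
  p1 <- array(runif(32 * 32 * 3, 0, 255), c(32, 32, 3))
  p2 <- array(runif(32 * 32 * 3, 0, 255), c(32, 32, 3))
  F1 <- extract_features(enc, list(p1))
  expect_equal(dim(F1), c(1L, 32L))
  F3 <- extract_features(enc, list(p1, p2, p1))
  expect_equal(F3[1, ], F3[3, ], tolerance = 1e-12)
  expect_equal(F3[1, ], F1[1, ], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(F3[1, ], F3[2, ])))
  # batching does not change results
  F3b <- extract_features(enc, list(p1, p2, p1), batch_size = 2L)
  expect_equal(F3, F3b, tolerance = 1e-12)
})

test_that("the 18-layer backbone builds and embeds a patch", {
  enc <- patch_encoder("deep", seed = 1)
  expect_equal(enc$feature_dim, 512L)
  # 18 weight layers: stem + 2 convs in each of 8 blocks + projection inputs
  expect_equal(sum(grepl("^(stem|blk)", names(enc$params)) &
                   grepl("_W", names(enc$params))) , 20L)  # incl. 3 skip projections
  set.seed(1)
  p <- array(runif(64 * 64 * 3, 0, 255), c(64, 64, 3))
  F1 <- extract_features(enc, list(p))
  expect_equal(dim(F1), c(1L, 512L))
  expect_true(all(is.finite(F1)))
})

test_that("contrastive pre-training is seeded, reduces the loss, and drops the projection head", {
  set.seed(21)
  # small textured patch pool: two visually distinct families
  mk <- function(kind, s) {
    spec <- synthetic_slide_spec(2, 2, patch_size = 24,
                                 class_label = kind, lesion_fraction = 0.9, seed = s)
    g <- generate_slide(spec)
    g$slide$pixels[25:48, 25:48, , drop = FALSE]
  }
  pool <- c(lapply(1:12, function(s) mk("tumor_A", s)),
            lapply(1:12, function(s) mk("tumor_B", s)))
  enc0 <- patch_encoder("small", seed = 1)
  one <- pretrain_encoder(enc0, pool, steps = 1L, batch_size = 4L, seed = 3L)
  two <- pretrain_encoder(enc0, pool, steps = 1L, batch_size = 4L, seed = 3L)
  expect_identical(one$params, two$params)   # determinism given seed
  expect_false(isTRUE(one$has_projection))
  expect_null(one$params$proj_W1)
  expect_error(pretrain_encoder(one, pool), "projection head")
  expect_error(pretrain_encoder(enc0, list()), "empty")

  # training-progress property, majority over 3 seeds
  wins <- 0L
  for (s in 1:3) {
    fit <- pretrain_encoder(patch_encoder("small", seed = s), pool,
                            steps = 50L, batch_size = 4L, seed = 100L + s)
    h <- fit$history
    if (mean(tail(h$loss, 5)) < h$loss[1]) wins <- wins + 1L
  }
  expect_gte(wins, 2L)
})

test_that("pre-trained features give contrastive structure on distinct textures", {
  set.seed(33)
  mk <- function(kind, s) {
    g <- generate_slide(synthetic_slide_spec(2, 2, patch_size = 24,
                                             class_label = kind,
                                             lesion_fraction = 0.9, seed = s))
    g$slide$pixels[25:48, 25:48, , drop = FALSE]
  }
  pool <- c(lapply(1:10, function(s) mk("tumor_A", s)),
            lapply(1:10, function(s) mk("tumor_B", s)))
  enc <- pretrain_encoder(patch_encoder("small", seed = 2), pool,
                          steps = 40L, batch_size = 4L, seed = 5L)
  pa <- mk("tumor_A", 99)
  pb <- mk("tumor_B", 99)
  views <- augment_pair(pa, seed = 7)
  F <- extract_features(enc, list(pa, pb, views$i, views$j))
  between <- cosine_sim(F[1, ], F[2, ])
  within <- cosine_sim(F[3, ], F[4, ])
  expect_gt(within, between)
})
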