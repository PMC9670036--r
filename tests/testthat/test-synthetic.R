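test_that("slide specs validate their arguments", {
  expect_error(synthetic_slide_spec(1, 5), "2 x 2")
  expect_error(synthetic_slide_spec(4, 4, class_label = "tumor_A",
                                    lesion_fraction = 1.2), "lesion_fraction")
  expect_silent(synthetic_slide_spec(4, 4, class_label = "normal",
                                     lesion_fraction = 1.2))
})

test_that("normal slides carry an empty mask and rasters are reproducible", {
  sp <- synthetic_slide_spec(4, 5, patch_size = 16, class_label = "normal", seed = 7)
  s1 <- generate_slide(sp)
  expect_true(all(s1$mask == 0))
  expect_false(any(s1$lesion_patch_mask))
  s2 <- generate_slide(sp)
  expect_identical(s1$slide$pixels, s2$slide$pixels)
  expect_identical(s1$mask, s2$mask)
  # raster geometry: tissue grid plus one-patch margin ring
  expect_equal(dim(s1$slide$pixels)[1:2], c((4 + 2) * 16, (5 + 2) * 16))
  expect_equal(s1$n_tissue_patches, 20L)
})

test_that("planted lesions cover about the requested fraction and are connected", {
  for (s in 1:5) {
    sl <- generate_slide(synthetic_slide_spec(10, 10, patch_size = 16,
                                              class_label = "tumor_A",
                                              lesion_fraction = 0.25, seed = s))
    cnt <- sum(sl$lesion_patch_mask)
    expect_gte(cnt, 20L)
    expect_lte(cnt, 30L)
    # the lesion is one 8-connected component on the patch grid
    m <- sl$lesion_patch_mask
    lab <- matrix(0L, nrow(m), ncol(m))
    first <- which(m, arr.ind = TRUE)[1, ]
    queue <- list(first); lab[first[1], first[2]] <- 1L
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        i <- cur[1] + di; j <- cur[2] + dj
        if (i >= 1 && j >= 1 && i <= nrow(m) && j <= ncol(m) &&
            m[i, j] && lab[i, j] == 0L) {
          lab[i, j] <- 1L
          queue <- c(queue, list(c(i, j)))
        }
      }
    }
    expect_equal(sum(lab == 1L), cnt)
    # mask pixels match lesion patch footprints
    expect_equal(sum(sl$mask), cnt * 16 * 16)
  }
})

test_that("cohorts are balanced, size-varied and collision-free", {
  co <- generate_cohort(n_per_class = 5, grid_range = c(4, 6), patch_size = 16,
                        seed = 3)
  m <- co$manifest
  expect_equal(nrow(m), 15L)
  expect_equal(as.integer(table(m$label)), rep(5L, 3))
  expect_true(all(m$n_rows >= 4 & m$n_rows <= 6))
  expect_true(all(m$n_cols >= 4 & m$n_cols <= 6))
  expect_error(generate_cohort(n_per_class = 1), "n_per_class")
  # determinism of the manifest
  co2 <- generate_cohort(n_per_class = 5, grid_range = c(4, 6), patch_size = 16,
                         seed = 3)
  expect_identical(co$manifest, co2$manifest)
  # distinct seeds give distinct rasters (hash scan over a subset)
  hashes <- vapply(1:6, function(i) {
    paste(round(sum(cohort_slide(co, i)$slide$pixels)),
          paste(dim(cohort_slide(co, i)$slide$pixels), collapse = "x"))
  }, character(1))
  expect_equal(anyDuplicated(hashes), 0L)
})

test_that("the white margin is background and tissue patches all pass the filter", {
  s <- generate_slide(synthetic_slide_spec(5, 4, patch_size = 16,
                                           class_label = "tumor_B", seed = 11))
  grid <- filter_background(tile_slide(s$slide, 16))
  expect_equal(nrow(grid$coords), s$n_tissue_patches)
  # kept coords are exactly the tissue cells (ring occupies coords 0 and n+1)
  expect_true(all(grid$coords[, 1] >= 1 & grid$coords[, 1] <= 5))
  expect_true(all(grid$coords[, 2] >= 1 & grid$coords[, 2] <= 4))
})

test_that("lesion and non-lesion patches are separable by a small CNN probe", {
  # patch-level learnability guarantee: a 2-layer convolutional probe on a
  # modest patch sample reaches high accuracy, so slide-level failures
  # indicate model bugs rather than inseparable textures
  set.seed(55)
  pool_lesion <- list(); pool_normal <- list()
  for (s in 1:6) {
    sl <- generate_slide(synthetic_slide_spec(6, 6, patch_size = 24,
                                              class_label = if (s %% 2) "tumor_A" else "tumor_B",
                                              lesion_fraction = 0.3, seed = s))
    grid <- filter_background(tile_slide(sl$slide, 24))
    les <- vapply(seq_len(nrow(grid$coords)), function(k) {
      sl$lesion_patch_mask[grid$coords[k, 1], grid$coords[k, 2]]
    }, logical(1))
    pool_lesion <- c(pool_lesion, grid$patches[les])
    pool_normal <- c(pool_normal, grid$patches[!les])
  }
  n <- 40L
  set.seed(56)
  tr_le <- sample(pool_lesion, n); tr_no <- sample(pool_normal, n)
  patches <- c(tr_le, tr_no)
  y <- rep(c(1L, 0L), each = n)
  # 2-layer probe: one conv layer + linear head on pooled activations
  p <- 24L
  Wc <- matrix(rnorm(27 * 8, 0, sqrt(2 / 27)), 27, 8)
  bc <- matrix(0, 1, 8)
  Wl <- matrix(0, 8, 1); bl <- matrix(0, 1, 1)
  params <- list(Wc = Wc, bc = bc, Wl = Wl, bl = bl)
  opt <- sg$adam_state(params, lr = 5e-3)
  X <- sg$pack_patches(patches)
  for (step in 1:150) {
    tape <- sg$ad_tape()
    px <- sg$px_new(tape, params)
    info <- sg$conv_index(2L * n, p, p, 3L, 2L, 1L)
    h <- sg$ad_relu(sg$ad_conv2d(sg$ad_const(tape, X), sg$px_get(px, "Wc"),
                                 sg$px_get(px, "bc"), info))
    f <- sg$ad_gap(h, 2L * n, info$Ho * info$Wo)
    z <- sg$ad_add(sg$ad_mm(f, sg$px_get(px, "Wl")), sg$px_get(px, "bl"))
    # logistic loss via softplus: mean(log(1 + exp(z)) - y z)
    soft <- sg$ad_row_logsumexp(sg$ad_cbind(list(z, sg$ad_const(tape, matrix(0, 2 * n, 1)))))
    loss <- sg$ad_scale(sg$ad_sub(sg$ad_sum(soft),
                                  sg$ad_sum(sg$ad_mul(z, sg$ad_const(tape, matrix(y))))),
                        1 / (2 * n))
    sg$ad_backward(loss)
    upd <- sg$adam_step(opt, params, sg$px_grads(px))
    opt <- upd$opt; params <- upd$params
  }
  # evaluate on the training pool (capacity check)
  tape <- sg$ad_tape()
  px <- sg$px_new(tape, params)
  info <- sg$conv_index(2L * n, p, p, 3L, 2L, 1L)
  h <- sg$ad_relu(sg$ad_conv2d(sg$ad_const(tape, X), sg$px_get(px, "Wc"),
                               sg$px_get(px, "bc"), info))
  f <- sg$ad_gap(h, 2L * n, info$Ho * info$Wo)
  z <- sg$ad_value(sg$ad_add(sg$ad_mm(f, sg$px_get(px, "Wl")), sg$px_get(px, "bl")))
  acc <- mean((z > 0) == (y == 1L))
  expect_gte(acc, 0.95)
})

test_that("cohorts round-trip through PNG output", {
  co <- generate_cohort(n_per_class = 2, grid_range = c(3, 3), patch_size = 16,
                        seed = 5)
  dir <- withr::local_tempdir()
  mp <- write_cohort(co, dir)
  m <- utils::read.delim(mp)
  expect_equal(nrow(m), 6L)
  expect_true(all(file.exists(m$path)))
  s1 <- cohort_slide(co, 1)
  px <- png::readPNG(m$path[1]) * 255
  expect_equal(px, s1$slide$pixels, tolerance = 0.5)   # 8-bit quantization
})
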