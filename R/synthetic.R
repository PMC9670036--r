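#' Synthetic slides with planted lesions
#'
#' The generator emulates the structure of a 3-class slide-classification
#' task (normal tissue versus two tumor types) at desk scale. A slide is a
#' patch-aligned RGB raster: a white margin ring (exercising background
#' filtering), a tissue field with a plain pink texture, and -- for tumor
#' slides -- one contiguous lesion region with a class-specific texture
#' (dark blobs for `tumor_A`, oriented stripes for `tumor_B`) covering
#' approximately `lesion_fraction` of the tissue. A pixel-level ground-truth
#' lesion mask accompanies every slide. Rasters are deterministic given the
#' spec's seed.
#'
#' @param n_rows,n_cols tissue grid size in patches (>= 2 each).
#' @param patch_size patch side length in pixels.
#' @param class_label one of "normal", "tumor_A", "tumor_B".
#' @param lesion_fraction target fraction of tissue patches covered by the
#'   lesion, in (0, 1); ignored for class "normal".
#' @param texture optional list overriding texture parameters
#'   (`blob_density` blobs per patch area, `stripe_freq` cycles per patch).
#' @param seed integer seed fixing the raster.
#' @return `synthetic_slide_spec()` returns a spec object; [generate_slide()]
#'   turns it into a slide, mask and label.
#' @export
synthetic_slide_spec <- function(n_rows, n_cols, patch_size = 64L,
                                 class_label = c("normal", "tumor_A", "tumor_B"),
                                 lesion_fraction = 0.25, texture = list(),
                                 seed = 1L) {
  class_label <- match.arg(class_label)
  if (n_rows < 2L || n_cols < 2L) stop("grid must be at least 2 x 2")
  if (class_label != "normal" && (lesion_fraction <= 0 || lesion_fraction >= 1)) {
    stop("lesion_fraction must lie in (0, 1) for tumor classes")
  }
  tx <- utils::modifyList(list(blob_density = 6, stripe_freq = 3), texture)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 patch_size = as.integer(patch_size), class_label = class_label,
                 lesion_fraction = lesion_fraction, texture = tx,
                 seed = as.integer(seed)),
            class = "synthetic_slide_spec")
}

# Plain tissue: pink base, smooth low-frequency mottling plus pixel noise.
texture_plain <- function(h, w, p) {
  ii <- matrix(seq_len(h), h, w)
  jj <- matrix(seq_len(w), h, w, byrow = TRUE)
  mot <- 12 * sin(2 * pi * ii / (3.1 * p)) * cos(2 * pi * jj / (2.7 * p))
  base <- c(224, 168, 190)
  out <- array(0, c(h, w, 3))
  for (k in 1:3) out[, , k] <- base[k] + mot + matrix(stats::rnorm(h * w, 0, 9), h, w)
  out
}

# Blob-dense tumor texture: light ground with dark round nests.
texture_blobs <- function(h, w, p, density) {
  out <- texture_plain(h, w, p)
  out[, , 1] <- out[, , 1] - 15
  out[, , 3] <- out[, , 3] + 10
  n_blobs <- max(1L, round(density * h * w / p^2))
  ci <- stats::runif(n_blobs, 1, h)
  cj <- stats::runif(n_blobs, 1, w)
  rad <- stats::runif(n_blobs, 0.06, 0.13) * p
  blob_col <- c(92, 58, 138)
  for (b in seq_len(n_blobs)) {
    i0 <- max(1L, floor(ci[b] - rad[b])); i1 <- min(h, ceiling(ci[b] + rad[b]))
    j0 <- max(1L, floor(cj[b] - rad[b])); j1 <- min(w, ceiling(cj[b] + rad[b]))
    if (i0 > i1 || j0 > j1) next
    bi <- matrix(i0:i1, i1 - i0 + 1L, j1 - j0 + 1L)
    bj <- matrix(j0:j1, i1 - i0 + 1L, j1 - j0 + 1L, byrow = TRUE)
    d2 <- (bi - ci[b])^2 + (bj - cj[b])^2
    wgt <- pmax(0, 1 - d2 / rad[b]^2)
    for (k in 1:3) {
      blk <- out[i0:i1, j0:j1, k]
      out[i0:i1, j0:j1, k] <- blk * (1 - wgt) + blob_col[k] * wgt
    }
  }
  out
}

# Striped tumor texture: color oscillates along a random orientation.
texture_stripes <- function(h, w, p, freq) {
  theta <- stats::runif(1, 0, pi)
  ii <- matrix(seq_len(h), h, w)
  jj <- matrix(seq_len(w), h, w, byrow = TRUE)
  phase <- sin(2 * pi * freq * (ii * cos(theta) + jj * sin(theta)) / p)
  mix <- (phase + 1) / 2
  c1 <- c(206, 126, 158)
  c2 <- c(118, 44, 92)
  out <- array(0, c(h, w, 3))
  for (k in 1:3) {
    out[, , k] <- c1[k] * mix + c2[k] * (1 - mix) + matrix(stats::rnorm(h * w, 0, 7), h, w)
  }
  out
}

# Contiguous lesion footprint on the tissue grid: a rectangle whose area is
# close to the target, plus a few adjacent cells, uniformly placed.
lesion_patch_mask <- function(n_rows, n_cols, fraction) {
  n <- n_rows * n_cols
  target <- round(fraction * n)
  lo <- max(1L, floor(0.8 * target))
  hi <- ceiling(1.2 * target)
  aspect <- stats::runif(1, 0.75, 1.33)
  r <- max(1L, min(n_rows, round(sqrt(target * aspect))))
  cc <- max(1L, min(n_cols, round(target / r)))
  while (r * cc > hi && (r > 1L || cc > 1L)) { if (r >= cc) r <- r - 1L else cc <- cc - 1L }
  while (r * cc < lo && (r < n_rows || cc < n_cols)) { if (r <= cc && r < n_rows) r <- r + 1L else cc <- min(n_cols, cc + 1L) }
  i0 <- sample.int(n_rows - r + 1L, 1L)
  j0 <- sample.int(n_cols - cc + 1L, 1L)
  m <- matrix(FALSE, n_rows, n_cols)
  m[i0:(i0 + r - 1L), j0:(j0 + cc - 1L)] <- TRUE
  extra <- min(hi - r * cc, floor(0.1 * target))
  if (extra > 0L) {
    cand <- which(!m & (rbind(m[-1, , drop = FALSE], FALSE) |
                        rbind(FALSE, m[-n_rows, , drop = FALSE]) |
                        cbind(m[, -1, drop = FALSE], FALSE) |
                        cbind(FALSE, m[, -n_cols, drop = FALSE])))
    if (length(cand) > 0L) m[sample(cand, min(extra, length(cand)))] <- TRUE
  }
  m
}

#' Generate one synthetic slide
#'
#' @param spec a [synthetic_slide_spec()].
#' @return a list with elements `slide` (a [slide_image()] whose raster is the
#'   tissue grid surrounded by a one-patch white margin), `mask` (H x W 0/1
#'   lesion mask), `label`, `n_tissue_patches` (the exact number of patches
#'   the background filter should keep), and `lesion_patch_mask` (logical
#'   n_rows x n_cols matrix on the tissue grid).
#' @export
generate_slide <- function(spec) {
  stopifnot(inherits(spec, "synthetic_slide_spec"))
  with_seed(spec$seed, {
    p <- spec$patch_size
    ht <- spec$n_rows * p
    wt <- spec$n_cols * p
    H <- ht + 2L * p
    W <- wt + 2L * p
    px <- array(0, c(H, W, 3))
    glare <- matrix(stats::runif(H * W, 246, 255), H, W)
    for (k in 1:3) px[, , k] <- glare
    tissue <- texture_plain(ht, wt, p)
    lesion_cells <- matrix(FALSE, spec$n_rows, spec$n_cols)
    if (spec$class_label != "normal") {
      lesion_cells <- lesion_patch_mask(spec$n_rows, spec$n_cols, spec$lesion_fraction)
      lesion <- switch(spec$class_label,
        tumor_A = texture_blobs(ht, wt, p, spec$texture$blob_density),
        tumor_B = texture_stripes(ht, wt, p, spec$texture$stripe_freq))
      pm <- lesion_cells[rep(seq_len(spec$n_rows), each = p),
                         rep(seq_len(spec$n_cols), each = p)]
      for (k in 1:3) {
        tk <- tissue[, , k]
        tk[pm] <- lesion[, , k][pm]
        tissue[, , k] <- tk
      }
    }
    px[(p + 1L):(p + ht), (p + 1L):(p + wt), ] <- tissue
    px <- pmin(pmax(px, 0), 255)
    mask <- matrix(0L, H, W)
    if (any(lesion_cells)) {
      pm <- lesion_cells[rep(seq_len(spec$n_rows), each = p),
                         rep(seq_len(spec$n_cols), each = p)]
      sub <- mask[(p + 1L):(p + ht), (p + 1L):(p + wt)]
      sub[pm] <- 1L
      mask[(p + 1L):(p + ht), (p + 1L):(p + wt)] <- sub
    }
    list(
      slide = slide_image(px, slide_id = sprintf("synth_%s_%d", spec$class_label, spec$seed)),
      mask = mask,
      label = spec$class_label,
      n_tissue_patches = spec$n_rows * spec$n_cols,
      lesion_patch_mask = lesion_cells
    )
  })
}

#' Generate a balanced synthetic cohort
#'
#' Draws per-slide specs for a balanced 3-class cohort with variable grid
#' sizes (mirroring the variable patch counts of real slides). Slides are
#' materialized lazily with [generate_slide()] from the per-slide seeds in
#' the manifest, so arbitrarily large cohorts never hold all rasters at once.
#'
#' @param n_per_class slides per class (>= 2).
#' @param grid_range integer c(min, max) for both grid dimensions.
#' @param patch_size patch side length in pixels.
#' @param lesion_fraction target lesion coverage for tumor slides.
#' @param seed cohort seed; per-slide seeds are derived from it.
#' @return an object of class `slide_cohort` wrapping the manifest
#'   data frame (slide_id, label, n_rows, n_cols, seed).
#' @export
generate_cohort <- function(n_per_class = 40L, grid_range = c(8L, 12L),
                            patch_size = 64L, lesion_fraction = 0.25, seed = 1L) {
  if (n_per_class < 2L) stop("n_per_class must be >= 2")
  labels <- rep(c("normal", "tumor_A", "tumor_B"), each = n_per_class)
  n <- length(labels)
  seeds <- derive_seeds(seed, n)
  gr <- seq.int(grid_range[1], grid_range[2])
  dims <- with_seed(seed + 1L, cbind(
    gr[sample.int(length(gr), n, replace = TRUE)],
    gr[sample.int(length(gr), n, replace = TRUE)]
  ))
  manifest <- data.frame(
    slide_id = sprintf("slide_%03d_%s", seq_len(n), labels),
    label = labels,
    n_rows = dims[, 1], n_cols = dims[, 2],
    patch_size = as.integer(patch_size),
    lesion_fraction = lesion_fraction,
    seed = seeds,
    stringsAsFactors = FALSE
  )
  structure(list(manifest = manifest, classes = c("normal", "tumor_A", "tumor_B")),
            class = "slide_cohort")
}

#' @rdname generate_cohort
#' @param cohort a `slide_cohort`.
#' @param i row index into the manifest.
#' @export
cohort_slide <- function(cohort, i) {
  m <- cohort$manifest[i, ]
  generate_slide(synthetic_slide_spec(
    n_rows = m$n_rows, n_cols = m$n_cols, patch_size = m$patch_size,
    class_label = m$label, lesion_fraction = m$lesion_fraction, seed = m$seed))
}

#' @export
print.slide_cohort <- function(x, ...) {
  cat(sprintf("<slide_cohort> %d slides (%s)\n", nrow(x$manifest),
              paste(table(x$manifest$label), collapse = "/")))
  invisible(x)
}

#' Write a cohort to disk as PNG slides, PNG masks and a TSV manifest
#'
#' @param cohort a `slide_cohort`.
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- cohort$manifest
  m$path <- file.path(dir, paste0(m$slide_id, ".png"))
  m$mask_path <- file.path(dir, paste0(m$slide_id, "_mask.png"))
  for (i in seq_len(nrow(m))) {
    s <- cohort_slide(cohort, i)
    png::writePNG(s$slide$pixels / 255, m$path[i])
    png::writePNG(s$mask + 0, m$mask_path[i])
  }
  path <- file.path(dir, "manifest.tsv")
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
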