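#' Slide images and patch grids
#'
#' A slide is represented as an 8-bit RGB raster (values 0-255) together with
#' an identifier and optional magnification metadata. Tiling lays fixed-size
#' patches on a regular grid; background filtering keeps the patches whose
#' non-tissue area does not exceed a threshold, yielding a `patch_grid` whose
#' (row, col) indices later define the nodes and edges of the slide graph.
#'
#' @param pixels numeric H x W x 3 array with values in [0, 255].
#' @param slide_id character identifier.
#' @param magnification free-text magnification tag (e.g. "20x").
#' @param mpp optional microns per pixel.
#' @return `slide_image()` returns an object of class `slide_image`.
#' @export
slide_image <- function(pixels, slide_id = "slide", magnification = "20x", mpp = NULL) {
  assert_rgb(pixels, "slide pixels")
  if (min(pixels) < 0 || max(pixels) > 255) stop("pixel values must lie in [0, 255]")
  structure(list(slide_id = slide_id, pixels = pixels,
                 magnification = magnification, mpp = mpp),
            class = "slide_image")
}

#' @export
print.slide_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<slide_image> %s: %d x %d px, %s\n", x$slide_id, d[1], d[2], x$magnification))
  invisible(x)
}

#' Tile a slide into fixed-size patches
#'
#' Lays `patch_size` x `patch_size` RGB patches on a regular grid with stride
#' `round(patch_size * (1 - overlap_fraction))`. Border tiles that do not fit
#' a full patch are dropped, never padded. Coordinates are 0-based (row, col)
#' grid indices, row-major, with row increasing downward; adjacency downstream
#' is defined on these indices, also when patches overlap.
#'
#' @param slide a `slide_image` or an H x W x 3 numeric array (0-255).
#' @param patch_size patch side length in pixels (>= 16).
#' @param overlap_fraction fractional overlap between neighboring patches,
#'   in [0, 0.5). The default 0 gives non-overlapping patches.
#' @return an object of class `slide_tiles`: a list with one element per tile,
#'   each holding `coord` (0-based c(row, col)) and `patch` (RGB array), with
#'   the slide id and patch size stored as attributes.
#' @seealso [filter_background()], [tissue_fraction()]
#' @export
tile_slide <- function(slide, patch_size = 512L, overlap_fraction = 0) {
  if (inherits(slide, "slide_image")) {
    px <- slide$pixels
    sid <- slide$slide_id
  } else {
    assert_rgb(slide, "slide")
    px <- slide
    sid <- "slide"
  }
  patch_size <- as.integer(patch_size)
  if (patch_size < 16L) stop("patch_size must be >= 16")
  if (!is.numeric(overlap_fraction) || overlap_fraction < 0 || overlap_fraction >= 0.5) {
    stop("overlap_fraction must lie in [0, 0.5)")
  }
  H <- dim(px)[1]; W <- dim(px)[2]
  if (H < patch_size || W < patch_size) stop("slide too small")
  stride <- as.integer(round(patch_size * (1 - overlap_fraction)))
  n_rows <- (H - patch_size) %/% stride + 1L
  n_cols <- (W - patch_size) %/% stride + 1L
  tiles <- vector("list", n_rows * n_cols)
  t <- 0L
  for (r in seq_len(n_rows) - 1L) {
    for (cc in seq_len(n_cols) - 1L) {
      t <- t + 1L
      i0 <- r * stride
      j0 <- cc * stride
      tiles[[t]] <- list(
        coord = c(r, cc),
        patch = px[(i0 + 1L):(i0 + patch_size), (j0 + 1L):(j0 + patch_size), , drop = FALSE]
      )
    }
  }
  structure(tiles, slide_id = sid, patch_size = patch_size,
            slide_dim = c(H, W), stride = stride, class = "slide_tiles")
}

#' Fraction of tissue pixels in a patch
#'
#' A pixel counts as background when it is near-white (`min(R,G,B) >= 220`)
#' or nearly unsaturated (`max - min <= 15`, on the 0-255 scale); everything
#' else is tissue. This brightness/saturation rule is the standard heuristic
#' for hematoxylin-eosin scans, where tissue is strongly colored and glass is
#' bright and gray-neutral. Both thresholds are overridable.
#'
#' @param patch numeric H x W x 3 RGB array on the 0-255 scale.
#' @param white_min minimum channel value for the near-white rule.
#' @param saturation_max maximum (max - min) channel spread for the
#'   unsaturated rule.
#' @return the tissue fraction, a value in [0, 1]. Deterministic.
#' @export
tissue_fraction <- function(patch, white_min = 220, saturation_max = 15) {
  assert_rgb(patch)
  lo <- pmin(patch[, , 1], patch[, , 2], patch[, , 3])
  hi <- pmax(patch[, , 1], patch[, , 2], patch[, , 3])
  background <- (lo >= white_min) | ((hi - lo) <= saturation_max)
  1 - mean(background)
}

#' Discard background patches
#'
#' Keeps exactly the tiles whose non-tissue area does not exceed
#' `background_max` (patches with non-tissue area strictly greater than the
#' threshold are discarded), preserving tile order. Applying the filter twice
#' is a no-op.
#'
#' @param tiles a `slide_tiles` object from [tile_slide()], or a bare list of
#'   `list(coord =, patch =)` elements.
#' @param background_max maximum tolerated non-tissue fraction (default 0.5).
#' @param ... passed on to [tissue_fraction()].
#' @return an object of class `patch_grid`: kept patches, their 0-based
#'   (row, col) coords (N x 2 integer matrix) and tissue fractions.
#' @export
filter_background <- function(tiles, background_max = 0.5, ...) {
  if (length(tiles) == 0L) stop("tiles must be non-empty")
  tf <- vapply(tiles, function(t) tissue_fraction(t$patch, ...), numeric(1))
  keep <- (1 - tf) <= background_max
  if (!any(keep)) stop("no tissue patches")
  kept <- tiles[keep]
  patch_grid(
    slide_id = attr(tiles, "slide_id") %||% "slide",
    patch_size = attr(tiles, "patch_size") %||% dim(kept[[1]]$patch)[1],
    coords = do.call(rbind, lapply(kept, `[[`, "coord")),
    patches = lapply(kept, `[[`, "patch"),
    tissue_fraction = tf[keep],
    slide_dim = attr(tiles, "slide_dim")
  )
}

#' @rdname filter_background
#' @param slide_id,patch_size,coords,patches,slide_dim components of the grid;
#'   see Details of [filter_background()].
#' @export
patch_grid <- function(slide_id, patch_size, coords, patches, tissue_fraction,
                       slide_dim = NULL) {
  coords <- matrix(as.integer(coords), ncol = 2)
  n <- nrow(coords)
  if (n < 1L) stop("a patch_grid needs at least one patch")
  if (length(patches) != n || length(tissue_fraction) != n) {
    stop("coords, patches and tissue_fraction must have equal length")
  }
  if (anyDuplicated(paste(coords[, 1], coords[, 2]))) stop("duplicate coords")
  if (any(coords < 0L)) stop("coords must be non-negative")
  structure(list(slide_id = slide_id, patch_size = as.integer(patch_size),
                 coords = coords, patches = patches,
                 tissue_fraction = as.numeric(tissue_fraction),
                 slide_dim = slide_dim),
            class = "patch_grid")
}

#' @export
print.patch_grid <- function(x, ...) {
  cat(sprintf("<patch_grid> %s: %d patches of %d px (tissue fraction %.2f-%.2f)\n",
              x$slide_id, nrow(x$coords), x$patch_size,
              min(x$tissue_fraction), max(x$tissue_fraction)))
  invisible(x)
}

#' Write a patch-grid manifest
#'
#' Tab-separated manifest with one row per kept patch: slide id, grid row,
#' grid column, tissue fraction.
#'
#' @param grid a `patch_grid`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_patch_manifest <- function(grid, path) {
  df <- data.frame(slide_id = grid$slide_id, row = grid$coords[, 1],
                   col = grid$coords[, 2], tissue_fraction = grid$tissue_fraction)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
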