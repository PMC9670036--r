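#' WSI graph construction
#'
#' A slide graph has one node per kept patch. Two nodes are adjacent when
#' their grid coordinates are neighbors: Chebyshev distance 1 for
#' 8-connectivity (the default, "at most 8 adjacent patches") or Manhattan
#' distance 1 for 4-connectivity. The binary adjacency is symmetric with a
#' zero diagonal; the propagation operator adds a self-loop to every node and
#' normalizes symmetrically by degree.
#'
#' @param coords N x 2 matrix of unique (row, col) grid indices.
#' @param connectivity 8 (queen) or 4 (rook) neighborhood.
#' @return `build_adjacency()` returns the binary N x N adjacency matrix.
#' @export
build_adjacency <- function(coords, connectivity = 8L) {
  coords <- matrix(as.integer(coords), ncol = 2)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  n <- nrow(coords)
  if (anyDuplicated(paste(coords[, 1], coords[, 2]))) stop("duplicate coords")
  dr <- abs(outer(coords[, 1], coords[, 1], "-"))
  dc <- abs(outer(coords[, 2], coords[, 2], "-"))
  A <- if (connectivity == 8L) {
    (pmax(dr, dc) == 1L) * 1
  } else {
    ((dr + dc) == 1L) * 1
  }
  diag(A) <- 0
  A
}

#' @rdname build_adjacency
#' @param A binary symmetric adjacency with zero diagonal.
#' @return `normalize_adjacency()` returns the symmetric degree-normalized
#'   self-looped operator `D^{-1/2} (A + I) D^{-1/2}`, where `D` is the
#'   diagonal of row sums of `A + I`. Its eigenvalues lie in [-1, 1].
#' @export
normalize_adjacency <- function(A) {
  A <- as.matrix(A)
  if (!isTRUE(all.equal(A, t(A)))) stop("adjacency must be symmetric")
  if (any(diag(A) != 0)) stop("adjacency must have a zero diagonal")
  At <- A + diag(nrow(A))
  d <- rowSums(At)
  s <- 1 / sqrt(d)
  At * outer(s, s)
}

#' Bundle features, coordinates and adjacency into a slide graph
#'
#' @param F numeric N x D node feature matrix, rows aligned with `coords`.
#' @param coords N x 2 matrix of (row, col) grid indices.
#' @param connectivity 8 or 4.
#' @param label optional slide-level class label.
#' @param slide_id slide identifier.
#' @param patch_size patch side length in pixels (kept for heatmap
#'   reconstruction).
#' @param slide_dim optional c(H, W) of the source raster.
#' @return an object of class `wsi_graph` with fields `F`, `A`, `A_hat`,
#'   `coords`, `label`. Nodes with no neighbor are permitted (they keep only
#'   their self-loop) but trigger a warning, since isolated tissue islands
#'   are unusual on filtered slides.
#' @export
build_graph <- function(F, coords, connectivity = 8L, label = NULL,
                        slide_id = "slide", patch_size = NULL, slide_dim = NULL) {
  F <- as.matrix(F)
  coords <- matrix(as.integer(coords), ncol = 2)
  if (nrow(F) != nrow(coords)) stop("rows of F must align with coords")
  A <- build_adjacency(coords, connectivity)
  if (any(rowSums(A) == 0)) {
    warning("graph contains isolated nodes (self-loop only)")
  }
  structure(list(slide_id = slide_id, F = F, A = A,
                 A_hat = normalize_adjacency(A),
                 coords = coords, label = label,
                 connectivity = as.integer(connectivity),
                 patch_size = patch_size, slide_dim = slide_dim),
            class = "wsi_graph")
}

#' @export
print.wsi_graph <- function(x, ...) {
  cat(sprintf("<wsi_graph> %s: N = %d nodes, D = %d, %d-connected, %d edges%s\n",
              x$slide_id, nrow(x$F), ncol(x$F), x$connectivity, sum(x$A) / 2,
              if (is.null(x$label)) "" else paste0(", label = ", x$label)))
  invisible(x)
}

#' Serialize a slide graph
#'
#' Single-file graph bundle (features, sparse edge list, coords, metadata);
#' the round trip restores an identical graph.
#'
#' @param graph a `wsi_graph`.
#' @param path file path.
#' @return `path` / the restored graph.
#' @export
write_wsi_graph <- function(graph, path) {
  edges <- which(graph$A == 1 & upper.tri(graph$A), arr.ind = TRUE)
  saveRDS(list(slide_id = graph$slide_id, F = graph$F, edges = edges,
               coords = graph$coords, label = graph$label,
               connectivity = graph$connectivity, patch_size = graph$patch_size,
               slide_dim = graph$slide_dim, n = nrow(graph$F)),
          path)
  invisible(path)
}

#' @rdname write_wsi_graph
#' @export
read_wsi_graph <- function(path) {
  b <- readRDS(path)
  A <- matrix(0, b$n, b$n)
  if (nrow(b$edges) > 0) {
    A[b$edges] <- 1
    A[b$edges[, c(2, 1), drop = FALSE]] <- 1
  }
  structure(list(slide_id = b$slide_id, F = b$F, A = A,
                 A_hat = normalize_adjacency(A), coords = b$coords,
                 label = b$label, connectivity = b$connectivity,
                 patch_size = b$patch_size, slide_dim = b$slide_dim),
            class = "wsi_graph")
}
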