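# 2D chemical-space embedding of the truncate distance matrix, with a
# Gaussian kernel density surface for coverage visualization. The embedding
# is classical metric multidimensional scaling (principal coordinates) on
# the 1 - Tanimoto distance matrix: deterministic, hyperparameter-free, and
# fitted once jointly so per-set figures are views of a single frame.

#' Embed chemical space in two dimensions
#'
#' Principal-coordinates embedding (classical MDS) of a precomputed chemical
#' distance matrix. The embedding is computed jointly across all molecules
#' supplied; per-set plots should be produced with [subset_view()], never by
#' re-fitting, so that the projection is the same for each set.
#'
#' Embedded distances are a low-dimensional summary: cluster-level topology
#' is preserved for well-separated chemotypes, but pairwise embedded
#' distances need not track Tanimoto distances quantitatively.
#'
#' @param dist Square distance matrix (see [distance_matrix()]) with row
#'   labels.
#' @param seed Kept for interface stability; the fit itself is deterministic.
#' @return Object of class `chem_embedding`: list with `ids`, `coords`
#'   (n x 2 matrix) and `params`.
#' @export
embed_chemspace <- function(dist, seed = 42L) {
  stopifnot(is.matrix(dist), nrow(dist) == ncol(dist))
  if (nrow(dist) < 3) stop("need at least 3 points to embed", call. = FALSE)
  ids <- rownames(dist) %||% as.character(seq_len(nrow(dist)))
  coords <- suppressWarnings(stats::cmdscale(stats::as.dist(dist), k = 2))
  if (ncol(coords) < 2)
    coords <- cbind(coords, 0)[, 1:2, drop = FALSE]
  dimnames(coords) <- list(ids, c("x", "y"))
  structure(list(ids = ids, coords = coords,
                 params = list(method = "pcoa", k = 2L, seed = seed)),
            class = "chem_embedding")
}

#' @export
print.chem_embedding <- function(x, ...) {
  cat(sprintf("<chem_embedding> %d points (%s)\n", length(x$ids), x$params$method))
  invisible(x)
}

#' Restrict an embedding to a subset of ids
#'
#' Returns the same coordinates for the subset — per-set figures are views
#' of one joint embedding and are never re-fitted.
#'
#' @param embedding A [embed_chemspace()] result.
#' @param ids Character vector, a subset of `embedding$ids`.
#' @return A `chem_embedding` over `ids` with unchanged coordinates.
#' @export
subset_view <- function(embedding, ids) {
  stopifnot(inherits(embedding, "chem_embedding"))
  if (!length(ids)) stop("empty subset", call. = FALSE)
  miss <- setdiff(ids, embedding$ids)
  if (length(miss))
    stop("unknown ids: ", paste(utils::head(miss, 3), collapse = ", "), call. = FALSE)
  structure(list(ids = ids,
                 coords = embedding$coords[ids, , drop = FALSE],
                 params = embedding$params),
            class = "chem_embedding")
}

#' Gaussian kernel density surface over an embedding
#'
#' 2D Gaussian KDE (normal-reference bandwidth rule by default) on the
#' embedded coordinates; used as the grayscale coverage layer of
#' chemical-space figures. The returned density integrates to ~1 over the
#' grid.
#'
#' @param embedding A `chem_embedding` (>= 3 points with non-degenerate
#'   spread).
#' @param n Grid resolution per axis.
#' @param h Optional bandwidth vector `c(hx, hy)`; defaults to
#'   `MASS::bandwidth.nrd` per axis.
#' @param lims Optional plot limits `c(xmin, xmax, ymin, ymax)`; defaults to
#'   the coordinate range padded by 10%.
#' @return Object of class `chem_density`: list with `x`, `y`, `z` (as
#'   `MASS::kde2d`) plus the generating coordinates.
#' @export
chem_density <- function(embedding, n = 100L, h = NULL, lims = NULL) {
  stopifnot(inherits(embedding, "chem_embedding"))
  xy <- embedding$coords
  if (nrow(xy) < 3) stop("need at least 3 points for a density surface", call. = FALSE)
  if (stats::sd(xy[, 1]) < 1e-12 || stats::sd(xy[, 2]) < 1e-12)
    stop("degenerate spread: all points (near-)identical on one axis", call. = FALSE)
  if (is.null(h)) {
    h <- c(MASS::bandwidth.nrd(xy[, 1]), MASS::bandwidth.nrd(xy[, 2]))
    h[h <= 0] <- 4 * 1.06 * apply(xy, 2, stats::sd)[h <= 0] * nrow(xy)^(-1/5)
  }
  if (is.null(lims)) {
    # cover the kernel tails so the density integrates to ~1 over the grid
    pad <- 0.05 * c(diff(range(xy[, 1])), diff(range(xy[, 2]))) + 0.8 * h
    lims <- c(range(xy[, 1]) + c(-1, 1) * pad[1],
              range(xy[, 2]) + c(-1, 1) * pad[2])
  }
  kd <- MASS::kde2d(xy[, 1], xy[, 2], h = h, n = n, lims = lims)
  structure(list(x = kd$x, y = kd$y, z = kd$z, coords = xy, h = h),
            class = "chem_density")
}

#' Plot a chemical-space density view
#'
#' Grayscale image of the probability density (darker = denser), optionally
#' overlaid with selected points.
#'
#' @param x A [chem_density()].
#' @param points Optional 2-column matrix of coordinates to overlay.
#' @param main Plot title.
#' @param ... Passed to [graphics::image()].
#' @export
plot.chem_density <- function(x, points = NULL, main = "", ...) {
  graphics::image(x$x, x$y, -x$z, col = grDevices::gray.colors(64, 0, 1),
                  xlab = "dim 1", ylab = "dim 2", main = main, useRaster = TRUE, ...)
  if (!is.null(points))
    graphics::points(points[, 1], points[, 2], pch = 19, cex = 0.6,
                     col = grDevices::adjustcolor("firebrick", 0.8))
  invisible(x)
}

#' @export
plot.chem_embedding <- function(x, ...) {
  graphics::plot(x$coords, pch = 16, cex = 0.5,
                 col = grDevices::adjustcolor("black", 0.4),
                 xlab = "dim 1", ylab = "dim 2", ...)
  invisible(x)
}
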