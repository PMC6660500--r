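#' Polygonal region of interest
#'
#' Builds a simple-polygon ROI in image pixel coordinates. Coordinates are
#' 0-based and row-major throughout the package: a pixel at matrix position
#' `[r+1, c+1]` has its center at `(x = c, y = r)`.
#'
#' @param vertices Numeric matrix (or data.frame) with columns `x` and `y`
#'   holding the polygon vertices in order (open ring; the closing edge is
#'   implicit). At least 3 vertices.
#' @return An object of class `mibg_roi_polygon`.
#' @seealso [roi_square()], [mean_counts()]
#' @export
roi_polygon <- function(vertices) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 3L) {
    stop("polygon ROI needs a n x 2 matrix with >= 3 vertices")
  }
  if (anyNA(vertices) || any(!is.finite(vertices))) {
    stop("polygon vertices must be finite")
  }
  if (nrow(unique(vertices)) < 3L) {
    stop("degenerate polygon: fewer than 3 distinct vertices")
  }
  colnames(vertices) <- c("x", "y")
  structure(list(vertices = vertices), class = "mibg_roi_polygon")
}

#' Square mediastinal reference ROI
#'
#' The mediastinal reference region is a fixed-size square of pixels (7 x 7 by
#' convention), anchored at its top-left pixel.
#'
#' @param row0,col0 0-based row/column of the top-left pixel of the square.
#' @param size Side length in pixels; default 7.
#' @return An object of class `mibg_roi_square`.
#' @export
roi_square <- function(row0, col0, size = 7L) {
  row0 <- as.integer(row0); col0 <- as.integer(col0); size <- as.integer(size)
  if (size < 1L) stop("square ROI size must be >= 1")
  if (row0 < 0L || col0 < 0L) stop("square ROI anchor must be non-negative")
  structure(list(row0 = row0, col0 = col0, size = size),
            class = "mibg_roi_square")
}

# Even-odd ray-casting point-in-polygon test, vectorized over points.
# Half-open in y (an edge's lower endpoint is in, upper is out), which gives
# the left/top-in convention for pixel centers lying exactly on edges.
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py))
    if (any(crosses)) {
      xint <- (vx[j] - vx[i]) * (py[crosses] - vy[i]) /
        (vy[j] - vy[i]) + vx[i]
      hit <- px[crosses] < xint
      idx <- which(crosses)[hit]
      inside[idx] <- !inside[idx]
    }
    j <- i
  }
  inside
}

#' Pixels covered by an ROI
#'
#' Rasterizes an ROI against an image grid: a pixel belongs to the ROI iff its
#' center lies inside (even-odd rule for polygons; centers exactly on an edge
#' resolve by the half-open left/top-in convention).
#'
#' @param roi An ROI from [roi_polygon()] or [roi_square()].
#' @param dim Integer vector `c(nrow, ncol)` of the image.
#' @return Two-column integer matrix of 1-based `(row, col)` matrix indices.
#' @export
roi_pixels <- function(roi, dim) {
  nr <- dim[1]; nc <- dim[2]
  if (inherits(roi, "mibg_roi_square")) {
    rows <- roi$row0 + seq_len(roi$size) - 1L
    cols <- roi$col0 + seq_len(roi$size) - 1L
    if (max(rows) >= nr || max(cols) >= nc) {
      stop("square ROI extends beyond image bounds")
    }
    return(as.matrix(expand.grid(row = rows + 1L, col = cols + 1L)))
  }
  if (inherits(roi, "mibg_roi_polygon")) {
    v <- roi$vertices
    if (min(v[, "x"]) < -0.5 || max(v[, "x"]) > nc - 0.5 ||
        min(v[, "y"]) < -0.5 || max(v[, "y"]) > nr - 0.5) {
      stop("polygon ROI extends beyond image bounds")
    }
    r0 <- max(0L, floor(min(v[, "y"]))); r1 <- min(nr - 1L, ceiling(max(v[, "y"])))
    c0 <- max(0L, floor(min(v[, "x"]))); c1 <- min(nc - 1L, ceiling(max(v[, "x"])))
    grid <- expand.grid(row = r0:r1, col = c0:c1)
    keep <- point_in_polygon(grid$col, grid$row, v[, "x"], v[, "y"])
    if (!any(keep)) stop("ROI covers no pixel centers")
    return(cbind(row = grid$row[keep] + 1L, col = grid$col[keep] + 1L))
  }
  stop("unknown ROI type")
}
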