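#' A closed region-of-interest polygon on a slice
#'
#' Vertices are ordered 2D points in the slice-plane mm frame (the `u`, `v`
#' axes of [reslice()]); the polygon is closed implicitly. Validation
#' rejects polygons with fewer than three vertices, self-intersections, or
#' zero enclosed area.
#'
#' @param vertices n x 2 numeric matrix (or list of length-2 points), mm.
#' @param slice_label Optional label of the slice the ROI belongs to.
#' @return An object of class `roi_polygon`.
#' @export
roi_polygon <- function(vertices, slice_label = NA_character_) {
  if (is.list(vertices))
    vertices <- do.call(rbind, lapply(vertices, as.numeric))
  vertices <- matrix(as.numeric(vertices), ncol = 2L)
  if (nrow(vertices) < 3L)
    stop("ROI polygon needs at least 3 vertices", call. = FALSE)
  if (any(!is.finite(vertices)))
    stop("ROI polygon vertices must be finite", call. = FALSE)
  if (.polygon_self_intersects(vertices))
    stop("ROI polygon is self-intersecting", call. = FALSE)
  if (abs(.shoelace_area(vertices)) < 1e-12)
    stop("ROI polygon encloses zero area", call. = FALSE)
  structure(list(vertices = vertices, slice_label = slice_label),
            class = "roi_polygon")
}

# Signed shoelace area of a vertex ring (positive = counter-clockwise).
.shoelace_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) / 2
}

# Proper-crossing test between all non-adjacent edge pairs (O(E^2),
# vectorized over pairs).
.polygon_self_intersects <- function(v) {
  n <- nrow(v)
  if (n < 4L) return(FALSE)
  jn <- c(2:n, 1L)
  ax <- v[, 1]; ay <- v[, 2]; bx <- v[jn, 1]; by <- v[jn, 2]
  pairs <- which(outer(seq_len(n), seq_len(n), function(i, j) j > i + 1L &
                         !(i == 1L & j == n)), arr.ind = TRUE)
  if (nrow(pairs) == 0L) return(FALSE)
  i <- pairs[, 1]; j <- pairs[, 2]
  d1 <- (bx[i] - ax[i]) * (ay[j] - ay[i]) - (by[i] - ay[i]) * (ax[j] - ax[i])
  d2 <- (bx[i] - ax[i]) * (by[j] - ay[i]) - (by[i] - ay[i]) * (bx[j] - ax[i])
  d3 <- (bx[j] - ax[j]) * (ay[i] - ay[j]) - (by[j] - ay[j]) * (ax[i] - ax[j])
  d4 <- (bx[j] - ax[j]) * (by[i] - ay[j]) - (by[j] - ay[j]) * (bx[i] - ax[j])
  any(d1 * d2 < 0 & d3 * d4 < 0)
}

#' Rasterize an ROI polygon onto a slice grid
#'
#' A pixel belongs to the mask iff its centre lies inside the polygon under
#' the even-odd rule; centres lying exactly on an edge (within `edge_tol`)
#' count as inside. The grid is the pixel-centre frame produced by
#' [reslice()] (`grid$u`, `grid$v`).
#'
#' @param poly An [roi_polygon()] (or a vertex matrix, validated here).
#' @param grid List with numeric vectors `u` and `v` of pixel-centre mm
#'   coordinates.
#' @param edge_tol Distance below which a centre is treated as on an edge.
#' @return Logical nx x ny matrix.
#' @export
rasterize_roi <- function(poly, grid, edge_tol = 1e-9) {
  if (!inherits(poly, "roi_polygon")) poly <- roi_polygon(poly)
  u <- as.numeric(grid$u); v <- as.numeric(grid$v)
  if (length(u) < 1L || length(v) < 1L)
    stop("empty raster grid", call. = FALSE)
  nx <- length(u); ny <- length(v)
  vert <- poly$vertices
  n <- nrow(vert)
  jn <- c(2:n, 1L)
  inside <- matrix(FALSE, nx, ny)
  for (e in seq_len(n)) {
    x1 <- vert[e, 1]; y1 <- vert[e, 2]
    x2 <- vert[jn[e], 1]; y2 <- vert[jn[e], 2]
    rows <- which((y1 > v) != (y2 > v))
    for (j in rows) {
      xint <- x1 + (v[j] - y1) / (y2 - y1) * (x2 - x1)
      flip <- u < xint
      inside[flip, j] <- !inside[flip, j]
    }
  }
  # centres on an edge (within edge_tol) resolve as inside; only pixels in
  # each edge's bounding box (plus tolerance) need checking
  for (e in seq_len(n)) {
    x1 <- vert[e, 1]; y1 <- vert[e, 2]
    x2 <- vert[jn[e], 1]; y2 <- vert[jn[e], 2]
    iu <- which(u >= min(x1, x2) - edge_tol & u <= max(x1, x2) + edge_tol)
    iv <- which(v >= min(y1, y2) - edge_tol & v <= max(y1, y2) + edge_tol)
    if (!length(iu) || !length(iv)) next
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    px <- rep(u[iu], times = length(iv))
    py <- rep(v[iv], each = length(iu))
    t <- if (len2 > 0) pmin(pmax(((px - x1) * dx + (py - y1) * dy) / len2,
                                 0), 1) else 0
    dd <- (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
    hit <- which(dd <= edge_tol^2)
    if (length(hit))
      inside[cbind(iu[(hit - 1L) %% length(iu) + 1L],
                   iv[(hit - 1L) %/% length(iu) + 1L])] <- TRUE
  }
  inside
}

#' HU thresholds bounding mucosa
#'
#' The closed interval of Hounsfield units classified as mucosa: above air,
#' below bone. Defaults to \[-700, +700\] HU; both bounds inclusive.
#'
#' @param lo,hi Lower/upper bounds in HU, `lo < hi`.
#' @return An object of class `threshold_spec`.
#' @export
threshold_spec <- function(lo = -700, hi = 700) {
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  if (length(lo) != 1L || length(hi) != 1L || !is.finite(lo) ||
      !is.finite(hi) || lo >= hi)
    stop("thresholds must satisfy lo < hi", call. = FALSE)
  structure(list(lo = lo, hi = hi), class = "threshold_spec")
}

#' Mucosa mask inside an ROI by the bi-threshold rule
#'
#' A pixel is mucosa iff it lies in the ROI and its HU value falls in the
#' closed interval `[lo, hi]` — excluding both air (below `lo`) and bone
#' (above `hi`).
#'
#' @param img nx x ny HU matrix.
#' @param roi Logical matrix congruent with `img`.
#' @param th A [threshold_spec()].
#' @return Logical matrix.
#' @export
mucosa_mask <- function(img, roi, th = threshold_spec()) {
  stopifnot(inherits(th, "threshold_spec"))
  img <- as.matrix(img)
  if (!identical(dim(img), dim(roi)))
    stop("image and ROI mask shapes differ", call. = FALSE)
  roi & img >= th$lo & img <= th$hi
}

#' Area of a binary mask
#'
#' @param mask Logical matrix.
#' @param spacing Pixel size in mm: a scalar (square pixels) or length-2
#'   (dx, dy).
#' @return Area in mm^2 (count of TRUE pixels times pixel area).
#' @export
mask_area <- function(mask, spacing) {
  spacing <- as.numeric(spacing)
  if (any(spacing <= 0) || !length(spacing) %in% c(1L, 2L))
    stop("spacing must be positive (scalar or length 2)", call. = FALSE)
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  sum(mask) * spacing[1] * spacing[2]
}

#' Measure mucosa and cavity area on one slice
#'
#' Rasterizes the cavity ROI, applies the mucosa bi-threshold inside it, and
#' reports both areas and their ratio.
#'
#' @param img nx x ny HU matrix (from [reslice()]).
#' @param poly The cavity [roi_polygon()] for this slice.
#' @param grid Pixel-centre grid (`u`, `v`) matching `img`.
#' @param spacing Pixel size, mm.
#' @param th A [threshold_spec()].
#' @param slice_label Label recorded in the result.
#' @return A `mucosa_measurement`: list with `slice_label`, `roi_area_mm2`,
#'   `mucosa_area_mm2`, and `fraction` in \[0, 1\].
#' @export
measure_slice <- function(img, poly, grid, spacing, th = threshold_spec(),
                          slice_label = NULL) {
  if (!inherits(poly, "roi_polygon")) poly <- roi_polygon(poly)
  roi <- rasterize_roi(poly, grid)
  if (!identical(dim(as.matrix(img)), dim(roi)))
    stop("image and grid shapes differ", call. = FALSE)
  roi_area <- mask_area(roi, spacing)
  if (roi_area == 0)
    stop("degenerate ROI: no pixel centre falls inside the polygon",
         call. = FALSE)
  muc <- mucosa_mask(img, roi, th)
  muc_area <- mask_area(muc, spacing)
  if (is.null(slice_label)) slice_label <- poly$slice_label
  structure(list(slice_label = slice_label,
                 roi_area_mm2 = roi_area,
                 mucosa_area_mm2 = muc_area,
                 fraction = muc_area / roi_area),
            class = "mucosa_measurement")
}
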