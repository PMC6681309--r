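#' CT volume container
#'
#' A `ct_volume` holds a 3D grid of Hounsfield-unit (HU) voxels together with
#' the spatial metadata needed to place every voxel in the world frame:
#' per-axis spacing in mm, the world position of the centre of voxel
#' (0, 0, 0), and a 3x3 direction matrix whose columns map voxel axes to
#' world axes. The world frame is LPS (the DICOM convention), in millimetres;
#' voxel indices are 0-based.
#'
#' @param voxels 3D numeric array of HU values (finite).
#' @param spacing Numeric length-3, mm per voxel along each voxel axis;
#'   strictly positive.
#' @param origin Numeric length-3, world mm of the centre of voxel (0,0,0).
#' @param orientation 3x3 orthonormal direction matrix (columns are the world
#'   directions of the voxel axes). Defaults to the identity.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing, origin = c(0, 0, 0),
                      orientation = diag(3)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array", call. = FALSE)
  if (length(voxels) == 0L)
    stop("volume has zero voxels", call. = FALSE)
  storage.mode(voxels) <- "double"
  if (!all(is.finite(voxels)))
    stop("voxel values must be finite", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  orientation <- matrix(as.numeric(orientation), 3L, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive numbers", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be three finite numbers", call. = FALSE)
  if (max(abs(crossprod(orientation) - diag(3))) > 1e-6)
    stop("orientation matrix must be orthonormal", call. = FALSE)
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 orientation = orientation),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = " x ")))
  cat(sprintf("  HU range [%.1f, %.1f], origin (%s) mm\n",
              min(x$voxels), max(x$voxels),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' The 4x4 voxel-index-to-world affine of a volume
#'
#' Maps 0-based voxel indices (i, j, k) to world mm (LPS).
#'
#' @param vol A `ct_volume`.
#' @return 4x4 affine matrix.
#' @export
volume_affine <- function(vol) {
  stopifnot(inherits(vol, "ct_volume"))
  aff <- diag(4)
  aff[1:3, 1:3] <- vol$orientation %*% diag(vol$spacing)
  aff[1:3, 4] <- vol$origin
  aff
}

#' Convert world coordinates to continuous voxel indices
#'
#' @param vol A `ct_volume`.
#' @param pts n x 3 matrix of world mm points.
#' @return n x 3 matrix of 0-based continuous voxel indices.
#' @keywords internal
world_to_voxel <- function(vol, pts) {
  pts <- matrix(pts, ncol = 3L)
  rel <- sweep(pts, 2L, vol$origin) %*% vol$orientation  # = t(R) %*% (p - o)
  sweep(rel, 2L, vol$spacing, "/")
}

#' Apply a rigid motion to a volume's spatial frame
#'
#' Rotates/translates the volume in world space without touching voxel data:
#' origin and orientation are updated so that world point `R p + t` of the
#' moved volume corresponds to world point `p` of the original.
#'
#' @param vol A `ct_volume`.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 translation, mm.
#' @return The transformed `ct_volume`.
#' @export
transform_volume <- function(vol, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(inherits(vol, "ct_volume"))
  rotation <- matrix(as.numeric(rotation), 3L, 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation must be orthonormal", call. = FALSE)
  ct_volume(vol$voxels, vol$spacing,
            origin = as.numeric(rotation %*% vol$origin + translation),
            orientation = rotation %*% vol$orientation)
}

#' Window/level display mapping
#'
#' Linearly maps the HU interval `[level - width/2, level + width/2]` onto
#' 0..255 and clips outside it; values are rounded half-up so previews are
#' identical across platforms. The defaults are a wide bone-to-air CT window
#' (width 10,000 HU, level 2,000 HU).
#'
#' @param img 2D numeric array of HU values.
#' @param width Window width in HU, > 0.
#' @param level Window level (centre) in HU.
#' @return Integer matrix of the same shape with values in 0..255.
#' @export
render_window_level <- function(img, width = 10000, level = 2000) {
  if (!is.numeric(width) || length(width) != 1L || !is.finite(width) ||
      width <= 0)
    stop("window width must be a positive number", call. = FALSE)
  img <- as.matrix(img)
  g <- (img - (level - width / 2)) / width
  g <- pmin(pmax(g, 0), 1)
  out <- floor(g * 255 + 0.5)  # half-up
  storage.mode(out) <- "integer"
  out
}

#' Write an 8-bit grayscale preview PNG
#'
#' @param img 2D numeric array of HU values.
#' @param path Output file path.
#' @param width,level Window parameters passed to [render_window_level()].
#' @return Invisibly, the path written.
#' @export
write_preview_png <- function(img, path, width = 10000, level = 2000) {
  g <- render_window_level(img, width = width, level = level)
  # image row 1 at the top; transpose so x runs along the png width
  png::writePNG(t(g[, ncol(g):1, drop = FALSE]) / 255, target = path)
  invisible(path)
}
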