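.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("degenerate (near-zero) vector", call. = FALSE)
  v / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Named anatomical landmarks in world mm
#'
#' The six skull landmarks used to plan analysis slices: the anterior tip of
#' the nasal bone, the anterior arch of the atlas, the midpoint of the nasal
#' bone, the root of the upper incisor tooth, a point on the sagittal suture,
#' and the fronto-parietal joint. `sagittal_normal` is the unit normal of
#' the mid-sagittal plane; slice planes are constructed perpendicular to
#' that plane.
#'
#' @param nasal_bone_tip,atlas_anterior_arch,nasal_bone_mid,incisor_root,sagittal_suture,frontoparietal_joint
#'   Length-3 world coordinates in mm. Landmarks not needed for the plan
#'   being built may be `NULL`.
#' @param sagittal_normal Length-3 vector; normalized internally.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(nasal_bone_tip = NULL, atlas_anterior_arch = NULL,
                         nasal_bone_mid = NULL, incisor_root = NULL,
                         sagittal_suture = NULL, frontoparietal_joint = NULL,
                         sagittal_normal = c(0, 1, 0)) {
  pts <- list(nasal_bone_tip = nasal_bone_tip,
              atlas_anterior_arch = atlas_anterior_arch,
              nasal_bone_mid = nasal_bone_mid,
              incisor_root = incisor_root,
              sagittal_suture = sagittal_suture,
              frontoparietal_joint = frontoparietal_joint)
  for (nm in names(pts)) {
    p <- pts[[nm]]
    if (!is.null(p)) {
      p <- as.numeric(p)
      if (length(p) != 3L || any(!is.finite(p)))
        stop("landmark '", nm, "' must be three finite numbers",
             call. = FALSE)
      pts[[nm]] <- p
    }
  }
  if (!is.null(pts$nasal_bone_tip) && !is.null(pts$atlas_anterior_arch) &&
      sqrt(sum((pts$nasal_bone_tip - pts$atlas_anterior_arch)^2)) < 1e-9)
    stop("nasal_bone_tip and atlas_anterior_arch must be distinct",
         call. = FALSE)
  structure(c(pts, list(sagittal_normal = .unit(as.numeric(sagittal_normal)))),
            class = "landmark_set")
}

.require_landmarks <- function(lm, names) {
  missing <- names[vapply(names, function(n) is.null(lm[[n]]), logical(1))]
  if (length(missing))
    stop("missing landmark(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
}

#' Apply a rigid motion to every landmark
#'
#' @param lm A [landmark_set()].
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 translation, mm.
#' @return The transformed `landmark_set`.
#' @export
transform_landmarks <- function(lm, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  stopifnot(inherits(lm, "landmark_set"))
  out <- lm
  for (nm in setdiff(names(lm), "sagittal_normal"))
    if (!is.null(lm[[nm]]))
      out[[nm]] <- as.numeric(rotation %*% lm[[nm]] + translation)
  out$sagittal_normal <- as.numeric(rotation %*% lm$sagittal_normal)
  out
}

#' An oriented plane with an in-plane coordinate frame
#'
#' @param point A point on the plane, world mm.
#' @param normal Plane normal (normalized internally).
#' @param axis1 Optional in-plane direction for the first slice axis;
#'   projected onto the plane and normalized. Chosen automatically if `NULL`.
#' @return An object of class `ct_plane` with fields `point`, `normal`, and
#'   orthonormal `axis1`, `axis2` spanning the plane.
#' @export
ct_plane <- function(point, normal, axis1 = NULL) {
  point <- as.numeric(point)
  normal <- .unit(as.numeric(normal))
  if (is.null(axis1)) {
    seed <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis1 <- seed - sum(seed * normal) * normal
  } else {
    axis1 <- as.numeric(axis1)
    axis1 <- axis1 - sum(axis1 * normal) * normal
  }
  axis1 <- .unit(axis1)
  axis2 <- .cross3(normal, axis1)
  structure(list(point = point, normal = normal,
                 axis1 = axis1, axis2 = axis2),
            class = "ct_plane")
}

.shift_plane <- function(plane, offset)
  ct_plane(plane$point + offset * plane$normal, plane$normal,
           axis1 = plane$axis1)

#' Plane through two points, perpendicular to the mid-sagittal plane
#'
#' Constructs the plane containing both points whose normal is orthogonal to
#' `sagittal_normal`; this is how a slice boundary is defined by connecting
#' two skull landmarks on the sagittal view.
#'
#' @param p1,p2 Distinct world points, mm.
#' @param sagittal_normal Unit normal of the mid-sagittal plane.
#' @return A [ct_plane()] containing `p1` and `p2`, with `axis1` along
#'   `p2 - p1`.
#' @export
plane_through_two_points <- function(p1, p2, sagittal_normal = c(0, 1, 0)) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  d <- p2 - p1
  if (sqrt(sum(d^2)) < 1e-9)
    stop("geometry error: the two points coincide", call. = FALSE)
  s <- .unit(as.numeric(sagittal_normal))
  n <- .cross3(d, s)
  if (sqrt(sum(n^2)) < 1e-9 * sqrt(sum(d^2)))
    stop("geometry error: connecting direction parallel to sagittal normal",
         call. = FALSE)
  ct_plane(p1, n, axis1 = d)
}

.make_plan <- function(axis, base_plane, extent, n_segments, labels,
                       excluded) {
  thickness <- extent / n_segments
  slabs <- vector("list", n_segments)
  for (i in seq_len(n_segments)) {
    lo <- (i - 1) * thickness
    hi <- i * thickness
    slabs[[i]] <- list(label = labels[i], lower_mm = lo, upper_mm = hi,
                       center = .shift_plane(base_plane, (lo + hi) / 2))
  }
  structure(list(axis = axis, slabs = slabs, extent_mm = extent,
                 thickness_mm = thickness, excluded_labels = excluded),
            class = "slice_plan")
}

#' @export
print.slice_plan <- function(x, ...) {
  cat(sprintf("<slice_plan> %s: %d slabs of %.4g mm (%d excluded)\n",
              x$axis, length(x$slabs), x$thickness_mm,
              length(x$excluded_labels)))
  for (s in x$slabs)
    cat(sprintf("  %-3s [%.4g, %.4g] mm%s\n", s$label, s$lower_mm, s$upper_mm,
                if (s$label %in% x$excluded_labels) "  (excluded)" else ""))
  invisible(x)
}

#' Analysis slabs of a slice plan
#'
#' @param plan A `slice_plan`.
#' @return The slab list with excluded slabs removed.
#' @export
analysis_slabs <- function(plan) {
  stopifnot(inherits(plan, "slice_plan"))
  Filter(function(s) !(s$label %in% plan$excluded_labels), plan$slabs)
}

#' Build the axial slice plan from landmarks
#'
#' The base (lowest) plane connects the anterior tip of the nasal bone and
#' the anterior arch of the atlas, perpendicular to the mid-sagittal plane.
#' The span from that plane up to the middle of the nasal bone is divided
#' into `n_segments` parallel slabs of equal thickness. The lowest
#' `n_excluded_lowest` slabs are flagged as excluded (they contain the oral
#' cavity); the remaining slabs are labelled `A1..` from bottom to top and
#' each carries its centre plane.
#'
#' @param lm A [landmark_set()] with `nasal_bone_tip`, `atlas_anterior_arch`
#'   and `nasal_bone_mid`.
#' @param n_segments Total number of slabs (default 7).
#' @param n_excluded_lowest Number of lowest slabs excluded from analysis
#'   (default 2).
#' @return A `slice_plan` with `axis = "axial"`.
#' @export
build_axial_plan <- function(lm, n_segments = 7L, n_excluded_lowest = 2L) {
  stopifnot(inherits(lm, "landmark_set"))
  n_segments <- as.integer(n_segments)
  n_excluded_lowest <- as.integer(n_excluded_lowest)
  if (n_segments < 1L || n_excluded_lowest < 0L ||
      n_excluded_lowest >= n_segments)
    stop("need 0 <= n_excluded_lowest < n_segments", call. = FALSE)
  .require_landmarks(lm, c("nasal_bone_tip", "atlas_anterior_arch",
                           "nasal_bone_mid"))
  base <- plane_through_two_points(lm$nasal_bone_tip, lm$atlas_anterior_arch,
                                   lm$sagittal_normal)
  h <- sum(base$normal * (lm$nasal_bone_mid - base$point))
  if (h < 0) {  # orient the normal toward the nasal-bone midpoint
    base <- ct_plane(base$point, -base$normal, axis1 = base$axis1)
    h <- -h
  }
  if (h < 1e-9)
    stop("geometry error: nasal_bone_mid lies on or below the base plane",
         call. = FALSE)
  n_excl <- n_excluded_lowest
  labels <- c(if (n_excl > 0) paste0("X", seq_len(n_excl)),
              paste0("A", seq_len(n_segments - n_excl)))
  .make_plan("axial", base, h, n_segments, labels,
             excluded = labels[seq_len(n_excl)])
}

#' Build the coronal slice plan from landmarks
#'
#' The most anterior plane connects the root of the upper incisor tooth and
#' the sagittal suture, perpendicular to the mid-sagittal plane; the
#' posterior boundary is the parallel plane through the fronto-parietal
#' joint. The interval is divided into `n_segments` equal slabs labelled
#' `C1..` from anterior to posterior, none excluded.
#'
#' @param lm A [landmark_set()] with `incisor_root`, `sagittal_suture` and
#'   `frontoparietal_joint`.
#' @param n_segments Number of slabs (default 5).
#' @return A `slice_plan` with `axis = "coronal"`.
#' @export
build_coronal_plan <- function(lm, n_segments = 5L) {
  stopifnot(inherits(lm, "landmark_set"))
  n_segments <- as.integer(n_segments)
  if (n_segments < 1L) stop("n_segments must be >= 1", call. = FALSE)
  .require_landmarks(lm, c("incisor_root", "sagittal_suture",
                           "frontoparietal_joint"))
  ant <- plane_through_two_points(lm$incisor_root, lm$sagittal_suture,
                                  lm$sagittal_normal)
  ext <- sum(ant$normal * (lm$frontoparietal_joint - ant$point))
  if (ext < 0) {
    ant <- ct_plane(ant$point, -ant$normal, axis1 = ant$axis1)
    ext <- -ext
  }
  if (ext < 1e-9)
    stop("geometry error: frontoparietal_joint lies on the anterior plane",
         call. = FALSE)
  labels <- paste0("C", seq_len(n_segments))
  .make_plan("coronal", ant, ext, n_segments, labels, excluded = character(0))
}

#' Resample an oblique slice from a volume
#'
#' Trilinear interpolation of the volume at a regular 2D grid of points in
#' the plane, centred on `plane$point`: pixel (i, j) (0-based) sits at
#' `point + (i - (nx-1)/2) * s * axis1 + (j - (ny-1)/2) * s * axis2`.
#' Sample points outside the volume are filled with -1000 HU (air), so
#' padding can never be counted as tissue by the mucosa threshold.
#'
#' @param vol A [ct_volume()].
#' @param plane A [ct_plane()].
#' @param out_spacing Pixel size of the output grid, mm (> 0).
#' @param out_size Length-2 integer (nx, ny).
#' @return A list with `pixels` (nx x ny HU matrix), `spacing`, and
#'   `grid` (the in-plane mm coordinates `u`, `v` of pixel centres).
#' @export
reslice <- function(vol, plane, out_spacing, out_size) {
  stopifnot(inherits(vol, "ct_volume"), inherits(plane, "ct_plane"))
  if (!is.numeric(out_spacing) || out_spacing <= 0)
    stop("out_spacing must be positive", call. = FALSE)
  out_size <- as.integer(out_size)
  if (length(out_size) != 2L || any(out_size < 1L))
    stop("out_size must be two positive integers", call. = FALSE)
  g <- c(abs(sum(plane$axis1 * plane$axis2)),
         abs(sqrt(sum(plane$axis1^2)) - 1), abs(sqrt(sum(plane$axis2^2)) - 1))
  if (max(g) > 1e-6)
    stop("geometry error: plane axes are not orthonormal", call. = FALSE)
  nx <- out_size[1]; ny <- out_size[2]
  u <- (seq_len(nx) - 1 - (nx - 1) / 2) * out_spacing
  v <- (seq_len(ny) - 1 - (ny - 1) / 2) * out_spacing
  uu <- rep(u, times = ny)
  vv <- rep(v, each = nx)
  pts <- cbind(plane$point[1] + uu * plane$axis1[1] + vv * plane$axis2[1],
               plane$point[2] + uu * plane$axis1[2] + vv * plane$axis2[2],
               plane$point[3] + uu * plane$axis1[3] + vv * plane$axis2[3])
  vals <- .trilinear_sample(vol, pts, fill = -1000)
  list(pixels = matrix(vals, nrow = nx, ncol = ny),
       spacing = out_spacing, grid = list(u = u, v = v), plane = plane)
}

#' Rigidly move a volume and resample it onto a fresh axis-aligned grid
#'
#' Unlike [transform_volume()], which only rewrites the spatial frame, this
#' rotates the image content: the moved object is sampled by trilinear
#' interpolation onto a new axis-aligned isotropic grid that covers it,
#' with -1000 HU (air) outside the original field of view. Useful for
#' testing that measurements are invariant under rigid motion of the
#' subject.
#'
#' @param vol A [ct_volume()].
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 translation, mm.
#' @param spacing Isotropic voxel size of the output grid; defaults to the
#'   smallest input spacing.
#' @return A `ct_volume` with identity orientation.
#' @export
resample_volume <- function(vol, rotation = diag(3),
                            translation = c(0, 0, 0), spacing = NULL) {
  stopifnot(inherits(vol, "ct_volume"))
  if (is.null(spacing)) spacing <- min(vol$spacing)
  d <- dim(vol$voxels)
  corners <- as.matrix(expand.grid(c(0, d[1] - 1), c(0, d[2] - 1),
                                   c(0, d[3] - 1)))
  wc <- t(vol$orientation %*% (t(corners) * vol$spacing) + vol$origin)
  wc <- t(rotation %*% t(wc) + translation)
  lo <- apply(wc, 2, min); hi <- apply(wc, 2, max)
  n <- pmax(1L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  gx <- lo[1] + (seq_len(n[1]) - 1) * spacing
  gy <- lo[2] + (seq_len(n[2]) - 1) * spacing
  gz <- lo[3] + (seq_len(n[3]) - 1) * spacing
  out <- array(-1000, n)
  # pull back in z-chunks to bound peak memory: the value at moved point p'
  # is the original volume at R^T (p' - t)
  plane_n <- n[1] * n[2]
  chunk <- max(1L, as.integer(ceiling(2e6 / plane_n)))
  pxy <- cbind(rep(gx, times = n[2]), rep(gy, each = n[1]))
  for (k0 in seq(1L, n[3], by = chunk)) {
    ks <- k0:min(k0 + chunk - 1L, n[3])
    pts <- cbind(rep(pxy[, 1], times = length(ks)),
                 rep(pxy[, 2], times = length(ks)),
                 rep(gz[ks], each = plane_n))
    back <- sweep(pts, 2L, translation) %*% rotation  # = t(R^T (p - t))
    out[, , ks] <- .trilinear_sample(vol, back, fill = -1000)
  }
  ct_volume(out, spacing = rep(spacing, 3), origin = lo)
}

# Trilinear interpolation at world points; outside the grid -> fill.
.trilinear_sample <- function(vol, pts, fill = -1000) {
  idx <- world_to_voxel(vol, pts)
  d <- dim(vol$voxels)
  x <- idx[, 1]; y <- idx[, 2]; z <- idx[, 3]
  inside <- x >= 0 & x <= d[1] - 1 & y >= 0 & y <= d[2] - 1 &
    z >= 0 & z <= d[3] - 1
  out <- rep(fill, nrow(idx))
  if (!any(inside)) return(out)
  x <- x[inside]; y <- y[inside]; z <- z[inside]
  x0 <- pmin(floor(x), d[1] - 2); y0 <- pmin(floor(y), d[2] - 2)
  z0 <- pmin(floor(z), d[3] - 2)
  if (d[1] == 1L) x0 <- rep(0, length(x))
  if (d[2] == 1L) y0 <- rep(0, length(y))
  if (d[3] == 1L) z0 <- rep(0, length(z))
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  x1 <- pmin(x0 + 1, d[1] - 1); y1 <- pmin(y0 + 1, d[2] - 1)
  z1 <- pmin(z0 + 1, d[3] - 1)
  lin <- function(i, j, k) vol$voxels[1 + i + d[1] * (j + d[2] * k)]
  c000 <- lin(x0, y0, z0); c100 <- lin(x1, y0, z0)
  c010 <- lin(x0, y1, z0); c110 <- lin(x1, y1, z0)
  c001 <- lin(x0, y0, z1); c101 <- lin(x1, y0, z1)
  c011 <- lin(x0, y1, z1); c111 <- lin(x1, y1, z1)
  val <- (c000 * (1 - fx) + c100 * fx) * (1 - fy) * (1 - fz) +
         (c010 * (1 - fx) + c110 * fx) * fy * (1 - fz) +
         (c001 * (1 - fx) + c101 * fx) * (1 - fy) * fz +
         (c011 * (1 - fx) + c111 * fx) * fy * fz
  out[inside] <- val
  out
}
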