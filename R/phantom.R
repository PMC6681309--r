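# Synthetic head phantom: an idealized nasal cavity modelled as a vertical
# annular cylinder -- an air-filled lumen lined by a soft-tissue mucosa layer,
# wrapped in a high-attenuation bone shell, in an air background. The
# geometry is analytic, so every slice has a known mucosa-area fraction.

.eval_radius <- function(r, z) {
  if (is.function(r)) vapply(z, r, numeric(1)) else rep(as.numeric(r),
                                                        length(z))
}

#' Specification of a synthetic head phantom
#'
#' @param spacing Isotropic voxel size, mm (default 0.02, near the 19.71 um
#'   voxels of high-resolution micro-CT).
#' @param radius_outer Outer cavity radius R, mm: scalar or function of the
#'   axial height z. The cavity ROI is the disk of radius R.
#' @param radius_lumen Lumen (air) radius r, mm: scalar or function of z;
#'   mucosa occupies the annulus r < rho <= R.
#' @param septum_mm Optional thickness of a soft-tissue septum crossing the
#'   lumen (0 = none).
#' @param hu_air,hu_mucosa,hu_bone Class HU means. They must straddle the
#'   mucosa bi-threshold: air < -700 < mucosa < +700 < bone.
#' @param bone_shell_mm Thickness of the bone shell outside the cavity.
#' @param axial_extent_mm Height from the base plane to the nasal-bone
#'   midpoint landmark; the axial plan divides this span.
#' @param coronal_band_mm Length-2 (z1, z2): heights of the anterior plane
#'   and of the fronto-parietal joint for the coronal plan.
#' @param center_xy In-plane position of the cavity axis, mm.
#' @param noise_sd Gaussian HU noise standard deviation (0 = none).
#' @param blur_sigma_mm Isotropic Gaussian PSF sigma, mm (0 = none).
#' @param seed Integer RNG seed; fixed seed gives identical volumes.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(spacing = 0.02, radius_outer = 2,
                         radius_lumen = 1, septum_mm = 0,
                         hu_air = -1000, hu_mucosa = 40, hu_bone = 1500,
                         bone_shell_mm = 0.3, axial_extent_mm = 2.1,
                         coronal_band_mm = c(0.3, 1.8),
                         center_xy = c(0, 0),
                         noise_sd = 0, blur_sigma_mm = 0, seed = 1L) {
  spec <- list(spacing = as.numeric(spacing), radius_outer = radius_outer,
               radius_lumen = radius_lumen, septum_mm = as.numeric(septum_mm),
               hu_air = hu_air, hu_mucosa = hu_mucosa, hu_bone = hu_bone,
               bone_shell_mm = as.numeric(bone_shell_mm),
               axial_extent_mm = as.numeric(axial_extent_mm),
               coronal_band_mm = as.numeric(coronal_band_mm),
               center_xy = as.numeric(center_xy),
               noise_sd = as.numeric(noise_sd),
               blur_sigma_mm = as.numeric(blur_sigma_mm),
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

#' Validate a phantom specification
#'
#' Checks the geometric and radiometric invariants: 0 < r(z) < R(z) over the
#' sampled heights, positive spacing, and HU class means that straddle the
#' default mucosa bi-threshold so the three tissue classes are separable.
#'
#' @param spec A `phantom_spec`.
#' @return Invisibly `spec`; errors describe the violated invariant.
#' @export
validate_phantom_spec <- function(spec) {
  if (spec$spacing <= 0) stop("spacing must be positive", call. = FALSE)
  if (spec$noise_sd < 0 || spec$blur_sigma_mm < 0)
    stop("noise_sd and blur_sigma_mm must be >= 0", call. = FALSE)
  if (!(spec$hu_air < -700 && -700 < spec$hu_mucosa &&
        spec$hu_mucosa < 700 && 700 < spec$hu_bone))
    stop("HU means must satisfy air < -700 < mucosa < +700 < bone",
         call. = FALSE)
  zs <- seq(0, spec$axial_extent_mm, length.out = 33L)
  R <- .eval_radius(spec$radius_outer, zs)
  r <- .eval_radius(spec$radius_lumen, zs)
  if (any(!(r > 0)) || any(!(r < R)))
    stop("phantom requires 0 < lumen radius < outer radius at every height",
         call. = FALSE)
  if (length(spec$coronal_band_mm) != 2L ||
      diff(spec$coronal_band_mm) <= 0)
    stop("coronal_band_mm must be an increasing pair", call. = FALSE)
  invisible(spec)
}

# Area of {|y - cy| <= w/2} inside a circle of radius r (the septum strip).
.strip_area <- function(r, w) {
  if (w <= 0) return(0)
  h <- min(w / 2, r)
  2 * (h * sqrt(max(r^2 - h^2, 0)) + r^2 * asin(h / r))
}

#' Analytic mucosa fraction of a circular cavity section
#'
#' For a section with outer radius R, lumen radius r, and optional septum
#' width w: fraction = (pi (R^2 - r^2) + strip(r, w)) / (pi R^2); without a
#' septum this is (R^2 - r^2) / R^2.
#'
#' @param R,r Outer and lumen radii, mm.
#' @param septum_mm Septum thickness, mm.
#' @return The analytic mucosa-area fraction.
#' @export
analytic_fraction <- function(R, r, septum_mm = 0) {
  (pi * (R^2 - r^2) + .strip_area(r, septum_mm)) / (pi * R^2)
}

#' Landmarks consistent with a phantom's geometry
#'
#' In the phantom's canonical frame the base axial plane is z = 0, the
#' nasal-bone midpoint sits at the top of the axial span, and the coronal
#' band spans `coronal_band_mm`; the mid-sagittal plane is y = cy.
#'
#' @param spec A `phantom_spec`.
#' @return A [landmark_set()].
#' @export
phantom_landmarks <- function(spec) {
  cx <- spec$center_xy[1]; cy <- spec$center_xy[2]
  half <- max(.eval_radius(spec$radius_outer,
                           seq(0, spec$axial_extent_mm, length.out = 33L))) +
    spec$bone_shell_mm
  landmark_set(
    nasal_bone_tip = c(cx - half, cy, 0),
    atlas_anterior_arch = c(cx + half, cy, 0),
    nasal_bone_mid = c(cx, cy, spec$axial_extent_mm),
    incisor_root = c(cx - half, cy, spec$coronal_band_mm[1]),
    sagittal_suture = c(cx + half, cy, spec$coronal_band_mm[1]),
    frontoparietal_joint = c(cx, cy, spec$coronal_band_mm[2]),
    sagittal_normal = c(0, 1, 0))
}

# Separable replicate-padded Gaussian blur along all three axes.
.gaussian_blur3 <- function(arr, sigma_vox) {
  if (sigma_vox <= 0) return(arr)
  rad <- max(1L, as.integer(ceiling(3 * sigma_vox)))
  w <- exp(-((-rad):rad)^2 / (2 * sigma_vox^2))
  w <- w / sum(w)
  d <- dim(arr)
  for (axis in 1:3) {
    n <- d[axis]
    out <- array(0, d)
    for (j in (-rad):rad) {
      idx <- pmin(pmax(seq_len(n) + j, 1L), n)
      shifted <- switch(axis,
                        arr[idx, , , drop = FALSE],
                        arr[, idx, , drop = FALSE],
                        arr[, , idx, drop = FALSE])
      out <- out + w[j + rad + 1L] * shifted
    }
    arr <- out
  }
  arr
}

#' Generate a synthetic head phantom volume with analytic ground truth
#'
#' Voxels take the HU mean of the tissue class their centre falls in
#' (lumen air / mucosa annulus / bone shell / background air), optionally
#' blurred by an isotropic Gaussian PSF, with Gaussian HU noise added under
#' the spec's seed. The returned truth carries the landmark set, the true
#' cavity ROI circles, the analytic per-slab mucosa fractions for both
#' plans, and the swelling parameter (mucosa thickness) per slab.
#'
#' @param spec A [phantom_spec()].
#' @param margin_mm Air margin around the bone shell and beyond the axial
#'   span, mm.
#' @return List with `volume` (a [ct_volume()]) and `truth` (list:
#'   `landmarks`, `axial`, `coronal` — each a data.frame of label, z,
#'   R, r, fraction — and `spec`).
#' @export
generate_phantom <- function(spec, margin_mm = 0.1) {
  validate_phantom_spec(spec)
  s <- spec$spacing
  zs_probe <- seq(0, spec$axial_extent_mm, length.out = 33L)
  Rmax <- max(.eval_radius(spec$radius_outer, zs_probe))
  half <- Rmax + spec$bone_shell_mm + margin_mm
  nx <- as.integer(ceiling(2 * half / s))
  zmin <- -margin_mm - s
  zmax <- spec$axial_extent_mm + margin_mm + s
  nz <- as.integer(ceiling((zmax - zmin) / s))
  cx <- spec$center_xy[1]; cy <- spec$center_xy[2]
  xc <- cx + (seq_len(nx) - 1 - (nx - 1) / 2) * s
  yc <- cy + (seq_len(nx) - 1 - (nx - 1) / 2) * s
  zc <- zmin + (seq_len(nz) - 0.5) * s

  rho <- sqrt(outer((xc - cx)^2, (yc - cy)^2, "+"))
  in_septum <- if (spec$septum_mm > 0)
    outer(rep(TRUE, nx), abs(yc - cy) <= spec$septum_mm / 2, "&") else NULL

  vox <- array(spec$hu_air, dim = c(nx, nx, nz))
  Rz <- .eval_radius(spec$radius_outer, zc)
  rz <- .eval_radius(spec$radius_lumen, zc)
  for (k in seq_len(nz)) {
    R <- Rz[k]; r <- rz[k]
    sl <- matrix(spec$hu_air, nx, nx)
    sl[rho <= R + spec$bone_shell_mm] <- spec$hu_bone
    sl[rho <= R] <- spec$hu_mucosa
    lum <- rho <= r
    sl[lum] <- spec$hu_air
    if (!is.null(in_septum)) sl[lum & in_septum] <- spec$hu_mucosa
    vox[, , k] <- sl
  }
  if (spec$blur_sigma_mm > 0)
    vox <- .gaussian_blur3(vox, spec$blur_sigma_mm / s)
  if (spec$noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, globalenv()))
    set.seed(spec$seed)
    vox <- vox + array(stats::rnorm(length(vox), 0, spec$noise_sd), dim(vox))
  }

  vol <- ct_volume(vox, spacing = c(s, s, s),
                   origin = c(xc[1], yc[1], zc[1]))
  lm <- phantom_landmarks(spec)
  slab_truth <- function(plan) {
    slabs <- analysis_slabs(plan)
    z <- vapply(slabs, function(sl) (sl$lower_mm + sl$upper_mm) / 2,
                numeric(1))
    # axial base plane is z = 0 in the canonical frame, coronal anterior
    # plane is z = coronal_band_mm[1]
    z0 <- if (plan$axis == "coronal") spec$coronal_band_mm[1] else 0
    R <- .eval_radius(spec$radius_outer, z + z0)
    r <- .eval_radius(spec$radius_lumen, z + z0)
    data.frame(label = vapply(slabs, function(sl) sl$label, character(1)),
               z = z + z0, R = R, r = r, thickness = R - r,
               fraction = analytic_fraction(R, r, spec$septum_mm),
               stringsAsFactors = FALSE)
  }
  axial_plan <- build_axial_plan(lm)
  coronal_plan <- build_coronal_plan(lm)
  truth <- list(landmarks = lm,
                axial = slab_truth(axial_plan),
                coronal = slab_truth(coronal_plan),
                spec = spec)
  list(volume = vol, truth = truth)
}

#' True cavity ROI polygons for a phantom under a slice plan
#'
#' For each analysis slab, the cavity outline is the circle of radius R at
#' that height, centred on the cavity axis; it is returned as a regular
#' polygon expressed in the slab centre plane's in-plane frame, ready for
#' [measure_volume()]. Valid for the phantom's own plan and for any rigid
#' motion applied jointly to volume and landmarks (proper rotations).
#'
#' @param truth The `truth` element of [generate_phantom()].
#' @param plan A `slice_plan` built from (possibly transformed) phantom
#'   landmarks.
#' @param n_vertices Number of polygon vertices per circle.
#' @return Named list of [roi_polygon()] keyed by slice label.
#' @export
phantom_rois <- function(truth, plan, n_vertices = 180L) {
  stopifnot(inherits(plan, "slice_plan"))
  tab <- if (plan$axis == "axial") truth$axial else truth$coronal
  # In-plane (u, v) coordinates are computed in the phantom's canonical
  # frame; a proper rigid motion applied jointly to volume + landmarks
  # leaves them unchanged, so the same ROIs serve a transformed plan.
  canon <- if (plan$axis == "axial") build_axial_plan(truth$landmarks,
    n_segments = length(plan$slabs),
    n_excluded_lowest = length(plan$excluded_labels))
  else build_coronal_plan(truth$landmarks, n_segments = length(plan$slabs))
  ang <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  cxy <- truth$spec$center_xy
  out <- list()
  for (sl in analysis_slabs(canon)) {
    row <- tab[tab$label == sl$label, ]
    if (nrow(row) != 1L)
      stop("no truth row for slab ", sl$label, call. = FALSE)
    ctr <- sl$center
    axis_pt <- c(cxy[1], cxy[2], row$z)  # cavity axis at this slab's height
    u0 <- sum((axis_pt - ctr$point) * ctr$axis1)
    v0 <- sum((axis_pt - ctr$point) * ctr$axis2)
    verts <- cbind(u0 + row$R * cos(ang), v0 + row$R * sin(ang))
    out[[sl$label]] <- roi_polygon(verts, slice_label = sl$label)
  }
  out
}

#' Saturating swelling model for the phantom mucosa
#'
#' Methacholine-induced thickening follows an Emax dose term times a
#' piecewise-linear kinetic pulse: `t(dose, time) = t0 + m * delta_max *
#' dose / (dose + ec50) * k(time)`, where `m` is the group multiplier and
#' `k` interpolates the kinetic knots (flat beyond the last knot). The lumen
#' shrinks (`r = R - t`); the outer cavity wall is fixed.
#'
#' @param t0 Baseline mucosa thickness, mm (> 0).
#' @param delta_max Maximal thickness gain at saturating dose, mm (> 0).
#' @param ec50 Dose of half-maximal effect, mg/mL (> 0).
#' @param kinetics data.frame with columns `time` (min) and `k` in \[0, 1\].
#' @param multipliers Named non-negative multipliers applied to `delta_max`
#'   per experimental group.
#' @param t0_sd Between-animal SD of the baseline thickness, mm (used by the
#'   experiment drivers).
#' @return An object of class `swelling_model`.
#' @export
swelling_model <- function(t0 = 0.25, delta_max = 0.5, ec50 = 0.5,
                           kinetics = data.frame(
                             time = c(0, 15, 60, 120),
                             k = c(0, 1, 1, 0)),
                           multipliers = c(control = 1, AR = 2, AR_dex = 1),
                           t0_sd = 0.02) {
  if (t0 <= 0 || delta_max <= 0 || ec50 <= 0 || t0_sd < 0)
    stop("t0, delta_max, ec50 must be > 0 and t0_sd >= 0", call. = FALSE)
  if (!all(c("time", "k") %in% names(kinetics)) ||
      any(kinetics$k < 0 | kinetics$k > 1))
    stop("kinetics needs columns time, k with k in [0, 1]", call. = FALSE)
  if (any(multipliers < 0) || is.null(names(multipliers)))
    stop("multipliers must be named and non-negative", call. = FALSE)
  structure(list(t0 = t0, delta_max = delta_max, ec50 = ec50,
                 kinetics = kinetics[order(kinetics$time), ],
                 multipliers = multipliers, t0_sd = t0_sd),
            class = "swelling_model")
}

#' Kinetic pulse value at a time point
#'
#' Piecewise-linear interpolation of the model's kinetic knots; constant
#' beyond the first/last knot.
#'
#' @param model A [swelling_model()].
#' @param time_min Time since administration, minutes.
#' @return k in \[0, 1\].
#' @export
kinetic_factor <- function(model, time_min) {
  stats::approx(model$kinetics$time, model$kinetics$k, xout = time_min,
                rule = 2)$y
}

#' Mucosa thickness under the swelling model
#'
#' @param model A [swelling_model()].
#' @param dose Methacholine dose, mg/mL (>= 0).
#' @param time_min Minutes since administration (>= 0).
#' @param group Name of the group multiplier to apply.
#' @param t0 Baseline thickness override (e.g. per-animal), mm.
#' @return Thickness in mm.
#' @export
swelling_thickness <- function(model, dose, time_min = 15,
                               group = "control", t0 = model$t0) {
  stopifnot(inherits(model, "swelling_model"))
  if (dose < 0 || time_min < 0)
    stop("dose and time must be non-negative", call. = FALSE)
  if (!group %in% names(model$multipliers))
    stop("unknown group '", group, "'; known: ",
         paste(names(model$multipliers), collapse = ", "), call. = FALSE)
  m <- model$multipliers[[group]]
  t0 + m * model$delta_max * dose / (dose + model$ec50) *
    kinetic_factor(model, time_min)
}

#' Apply methacholine-induced swelling to a phantom spec
#'
#' Thickens the mucosa according to the swelling model: the lumen radius
#' becomes `R - t(dose, time)` while the outer cavity radius is unchanged.
#'
#' @param spec A [phantom_spec()] with scalar `radius_outer`.
#' @param dose Dose in mg/mL (>= 0).
#' @param time_min Minutes since administration.
#' @param model A [swelling_model()].
#' @param group Group multiplier name.
#' @param t0 Baseline thickness override, mm.
#' @return The swollen `phantom_spec`.
#' @export
swell <- function(spec, dose, time_min = 15, model = swelling_model(),
                  group = "control", t0 = model$t0) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.function(spec$radius_outer))
    stop("swell() requires a constant outer radius", call. = FALSE)
  t_new <- swelling_thickness(model, dose, time_min, group, t0)
  if (t_new >= spec$radius_outer)
    stop("swollen thickness ", signif(t_new, 4),
         " mm would close the lumen (R = ", spec$radius_outer, " mm)",
         call. = FALSE)
  spec$radius_lumen <- spec$radius_outer - t_new
  validate_phantom_spec(spec)
  spec
}
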