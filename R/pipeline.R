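#' Measure the mucosa index of a volume under a slice plan
#'
#' For every analysis slab, resamples the slab-centre plane from the volume,
#' rasterizes that slice's cavity ROI, applies the mucosa bi-threshold, and
#' aggregates the per-slice fractions with [compute_index()]. The resampling
#' grid is symmetric about the plane point and sized to cover the ROI
#' polygon plus a margin.
#'
#' @param vol A [ct_volume()].
#' @param plan A `slice_plan` from [build_axial_plan()] /
#'   [build_coronal_plan()].
#' @param rois Named list of [roi_polygon()], keyed by slice label; every
#'   analysis label must be present.
#' @param th A [threshold_spec()].
#' @param out_spacing In-plane pixel size of the resampled slices, mm;
#'   defaults to the smallest voxel spacing of `vol`.
#' @param margin_mm Extra margin around the ROI bounding box, mm.
#' @param pooled Passed to [compute_index()].
#' @return A `mucosa_index`.
#' @export
measure_volume <- function(vol, plan, rois, th = threshold_spec(),
                           out_spacing = NULL, margin_mm = 0.1,
                           pooled = FALSE) {
  stopifnot(inherits(vol, "ct_volume"), inherits(plan, "slice_plan"))
  if (is.null(out_spacing)) out_spacing <- min(vol$spacing)
  slabs <- analysis_slabs(plan)
  measurements <- lapply(slabs, function(s) {
    poly <- rois[[s$label]]
    if (is.null(poly))
      stop("ROI missing for analysis slice '", s$label, "'", call. = FALSE)
    if (!inherits(poly, "roi_polygon"))
      poly <- roi_polygon(poly, slice_label = s$label)
    half <- max(abs(poly$vertices)) + margin_mm
    n <- 2L * as.integer(ceiling(half / out_spacing))
    sl <- reslice(vol, s$center, out_spacing, c(n, n))
    measure_slice(sl$pixels, poly, sl$grid, out_spacing, th,
                  slice_label = s$label)
  })
  compute_index(measurements, pooled = pooled)
}
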