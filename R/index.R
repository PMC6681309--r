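#' Aggregate per-slice measurements into the mucosa index
#'
#' The mucosa index is the unweighted arithmetic mean of the per-slice
#' fractions (mucosal area / cavity ROI area) over the analysis slices —
#' a mean of ratios, not a pooled ratio of summed areas. Set
#' `pooled = TRUE` to get the pooled alternative
#' (sum of mucosa areas / sum of ROI areas) instead.
#'
#' @param measurements Non-empty list of `mucosa_measurement` objects (from
#'   [measure_slice()]), or a numeric vector of fractions.
#' @param pooled Use the pooled-area ratio instead of the mean of ratios.
#'   Requires area-bearing measurements.
#' @return A `mucosa_index`: list with `value`, `n_slices`, `per_slice`.
#' @export
compute_index <- function(measurements, pooled = FALSE) {
  if (is.numeric(measurements))
    measurements <- lapply(measurements, function(f)
      structure(list(slice_label = NA_character_, roi_area_mm2 = NA_real_,
                     mucosa_area_mm2 = NA_real_, fraction = f),
                class = "mucosa_measurement"))
  if (!is.list(measurements) || length(measurements) == 0L)
    stop("need a non-empty list of measurements", call. = FALSE)
  fr <- vapply(measurements, function(m) m$fraction, numeric(1))
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1))
    stop("fractions must be finite and in [0, 1]", call. = FALSE)
  if (pooled) {
    roi <- vapply(measurements, function(m) m$roi_area_mm2, numeric(1))
    muc <- vapply(measurements, function(m) m$mucosa_area_mm2, numeric(1))
    if (any(!is.finite(roi)) || any(!is.finite(muc)))
      stop("pooled index needs per-slice areas", call. = FALSE)
    value <- sum(muc) / sum(roi)
  } else {
    value <- mean(fr)
  }
  structure(list(value = value, n_slices = length(fr),
                 per_slice = measurements, pooled = pooled),
            class = "mucosa_index")
}

#' @export
print.mucosa_index <- function(x, ...) {
  cat(sprintf("<mucosa_index> %.4f over %d slice(s)%s\n", x$value,
              x$n_slices, if (x$pooled) " (pooled areas)" else ""))
  invisible(x)
}

#' Per-slice measurements as a data frame
#'
#' @param idx A `mucosa_index` or list of `mucosa_measurement`.
#' @return data.frame with slice_label, roi_area_mm2, mucosa_area_mm2,
#'   fraction.
#' @export
measurements_table <- function(idx) {
  ms <- if (inherits(idx, "mucosa_index")) idx$per_slice else idx
  data.frame(
    slice_label = vapply(ms, function(m) as.character(m$slice_label),
                         character(1)),
    roi_area_mm2 = vapply(ms, function(m) m$roi_area_mm2, numeric(1)),
    mucosa_area_mm2 = vapply(ms, function(m) m$mucosa_area_mm2, numeric(1)),
    fraction = vapply(ms, function(m) m$fraction, numeric(1)),
    stringsAsFactors = FALSE)
}
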