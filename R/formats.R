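# JSON interchange for landmarks, ROI sets, and slice plans.

#' Read a landmark file
#'
#' JSON with named entries `{name: [x, y, z]}` in world mm plus an optional
#' `"sagittal_normal"` entry (default (0, 1, 0)).
#'
#' @param path JSON file path.
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("nasal_bone_tip", "atlas_anterior_arch", "nasal_bone_mid",
             "incisor_root", "sagittal_suture", "frontoparietal_joint")
  args <- j[intersect(names(j), known)]
  args$sagittal_normal <- if (!is.null(j$sagittal_normal))
    j$sagittal_normal else c(0, 1, 0)
  do.call(landmark_set, args)
}

#' Write a landmark file
#'
#' @param lm A [landmark_set()].
#' @param path Output JSON path.
#' @return Invisibly, the path.
#' @export
write_landmarks <- function(lm, path) {
  stopifnot(inherits(lm, "landmark_set"))
  out <- Filter(Negate(is.null), unclass(lm))
  jsonlite::write_json(out, path, digits = NA, auto_unbox = FALSE,
                       pretty = TRUE)
  invisible(path)
}

#' Read a per-volume ROI set
#'
#' JSON of the form `{slice_label: [[u, v], ...], ...}` with vertices in
#' slice-plane mm coordinates.
#'
#' @param path JSON file path.
#' @return Named list of [roi_polygon()].
#' @export
read_roi_set <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  j <- j[!vapply(names(j), function(n) startsWith(n, "_"), logical(1))]
  out <- lapply(names(j), function(lbl)
    roi_polygon(matrix(as.numeric(unlist(j[[lbl]])), ncol = 2L,
                       byrow = is.list(j[[lbl]])) ,
                slice_label = lbl))
  names(out) <- names(j)
  out
}

#' Write a per-volume ROI set
#'
#' @param rois Named list of [roi_polygon()] (names are slice labels).
#' @param path Output JSON path.
#' @return Invisibly, the path.
#' @export
write_roi_set <- function(rois, path) {
  out <- lapply(rois, function(p) {
    if (!inherits(p, "roi_polygon")) p <- roi_polygon(p)
    unname(lapply(seq_len(nrow(p$vertices)),
                  function(i) as.numeric(p$vertices[i, ])))
  })
  jsonlite::write_json(out, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Export a slice plan as JSON
#'
#' One record per slab: label, lower/upper boundary offsets from the base
#' plane (mm), whether it is excluded, and its centre plane (point, normal,
#' in-plane axes).
#'
#' @param plan A `slice_plan`.
#' @param path Output JSON path.
#' @return Invisibly, the path.
#' @export
write_slice_plan <- function(plan, path) {
  stopifnot(inherits(plan, "slice_plan"))
  slabs <- lapply(plan$slabs, function(s)
    list(label = s$label, lower_mm = s$lower_mm, upper_mm = s$upper_mm,
         excluded = s$label %in% plan$excluded_labels,
         center = list(point = s$center$point, normal = s$center$normal,
                       axis1 = s$center$axis1, axis2 = s$center$axis2)))
  jsonlite::write_json(
    list(axis = plan$axis, extent_mm = plan$extent_mm,
         thickness_mm = plan$thickness_mm,
         excluded_labels = plan$excluded_labels, slabs = slabs),
    path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
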