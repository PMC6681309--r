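# NIfTI affines are RAS+; the package's world frame is LPS (DICOM).
# Conversion flips the sign of the first two world axes.
.ras_lps_flip <- diag(c(-1, -1, 1, 1))

#' Load a CT volume
#'
#' Reads a volume from disk into a [ct_volume()]. NIfTI files are assumed to
#' be pre-calibrated to Hounsfield units (no scl_slope/scl_inter is
#' reapplied); DICOM series are calibrated via rescale slope/intercept. The
#' NIfTI RAS affine is converted to the package's LPS world frame.
#'
#' @param path A `.nii`/`.nii.gz` file or a directory holding a DICOM series.
#' @param format `"nifti"`, `"dicom_series"`, or `"auto"` (directories are
#'   treated as DICOM series, files as NIfTI).
#' @return A `ct_volume`.
#' @export
load_volume <- function(path, format = c("auto", "nifti", "dicom_series")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path)) "dicom_series" else "nifti"
  if (format == "dicom_series")
    return(load_dicom_series(path))
  if (!file.exists(path))
    stop("no such file: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  if (length(dim(arr)) != 3L)
    stop("expected a 3D NIfTI volume, got ", length(dim(arr)), " dims",
         call. = FALSE)
  aff_ras <- structure(RNifti::xform(img), class = "matrix")
  aff <- .ras_lps_flip %*% aff_ras[1:4, 1:4]
  lin <- aff[1:3, 1:3]
  spacing <- sqrt(colSums(lin^2))
  if (any(spacing <= 0) || any(!is.finite(spacing)))
    stop("NIfTI affine has a degenerate axis", call. = FALSE)
  orientation <- sweep(lin, 2L, spacing, "/")
  ct_volume(arr, spacing = spacing, origin = aff[1:3, 4],
            orientation = orientation)
}

#' Save a CT volume as NIfTI
#'
#' Writes voxels and the full spatial frame (spacing, origin, orientation) so
#' that reloading with [load_volume()] reproduces the volume. The LPS affine
#' is converted to the NIfTI RAS convention on write.
#'
#' @param vol A `ct_volume`.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return Invisibly, the path written.
#' @export
save_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  if (!dir.exists(dirname(path)))
    stop("output directory does not exist: ", dirname(path), call. = FALSE)
  aff <- .ras_lps_flip %*% volume_affine(vol)
  img <- RNifti::asNifti(vol$voxels)
  RNifti::pixdim(img) <- vol$spacing
  # qform cannot carry an arbitrary affine; the sform is authoritative here
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}
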