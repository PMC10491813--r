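#' Write a CT volume to NIfTI with a JSON sidecar
#'
#' The voxel grid and spacing go into a NIfTI-1 file; axis hint and
#' provenance go into a JSON sidecar next to it (`<path>.json`).
#'
#' @param volume a [ct_volume].
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  img <- RNifti::asNifti(structure(volume$voxels, pixdim = volume$spacing),
                         datatype = "double")
  RNifti::writeNifti(img, path)
  side <- list(spacing = volume$spacing, provenance = volume$provenance)
  if (!is.null(volume$axis_hint))
    side$axis_hint <- list(point = volume$axis_hint$point,
                           direction = volume$axis_hint$direction)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a CT volume from NIfTI
#'
#' Spacing comes from the NIfTI header; axis hint and provenance are
#' restored from the JSON sidecar when present.  (DICOM series are not
#' supported; convert to NIfTI first.)
#'
#' @param path a NIfTI file.
#' @return a [ct_volume].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  img <- RNifti::readNifti(path)
  vox <- array(as.numeric(img), dim = dim(img))
  if (length(dim(vox)) != 3L) stop("expected a 3-D NIfTI volume")
  spacing <- RNifti::pixdim(img)[1:3]
  axis_hint <- NULL; prov <- list(source = path)
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    side <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(side$axis_hint))
      axis_hint <- list(point = as.numeric(side$axis_hint$point),
                        direction = as.numeric(side$axis_hint$direction))
    if (!is.null(side$provenance)) prov <- side$provenance
  }
  ct_volume(vox, spacing = spacing, axis_hint = axis_hint, provenance = prov)
}

sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
}

#' Read a reader-score table from CSV
#'
#' Expects long format with columns `reader`, `stent`, `reconstruction`,
#' `criterion`, `score`.
#'
#' @param path CSV file.
#' @return a validated `likert_table` data.frame.
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  as_likert_table(utils::read.csv(path, stringsAsFactors = FALSE))
}
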