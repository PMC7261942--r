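# NIfTI input/output and the on-disk cohort layout.
#
# Layout: <root>/<patient_id>/<token>.nii.gz for sequences (tokens t1, flair,
# dwi, t2star) and <root>/<patient_id>/truth_<class>.nii.gz (or
# pred_<class>.nii.gz) for masks. NIfTI stores grids (i, j, k) = (col, row,
# slice); arrays are transposed on the way in/out so the in-memory convention
# stays [slice, row, col].

.to_nifti_array <- function(values) aperm(values, c(3, 2, 1))
.from_nifti_array <- function(arr) aperm(arr, c(3, 2, 1))

.write_nifti_grid <- function(values, in_plane, slice_sp, path) {
  img <- RNifti::asNifti(.to_nifti_array(values))
  RNifti::pixdim(img) <- c(in_plane, in_plane, slice_sp)
  ok <- tryCatch({
    suppressWarnings(RNifti::writeNifti(img, path))
    TRUE
  }, error = function(e) e)
  # RNifti signals some failures (missing directory) as warnings only, so
  # verify the file actually landed
  if (!isTRUE(ok) || !file.exists(path)) {
    msg <- if (!isTRUE(ok)) conditionMessage(ok) else "file not created"
    abort(paste0("cannot write NIfTI file ", path, ": ", msg),
          class = "csvdseg_error_io")
  }
  invisible(path)
}

.read_nifti_grid <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  list(
    values = .from_nifti_array(as.array(img)),
    in_plane_spacing = pd[1],
    slice_spacing = pd[3]
  )
}

#' Read a patient's multi-sequence study from the cohort layout
#'
#' Discovers all modality files (`t1`, `flair`, `dwi`, `t2star`, extension
#' `.nii` or `.nii.gz`) under `<root_path>/<patient_id>/` and assembles a
#' [patient_study()]. Volumes must share one grid; geometry is taken from the
#' NIfTI headers.
#'
#' @param root_path cohort root directory.
#' @param patient_id patient sub-directory name.
#' @return A [patient_study()].
#' @export
read_study <- function(root_path, patient_id) {
  dir <- file.path(root_path, patient_id)
  if (!dir.exists(dir)) {
    abort(paste0("no study directory for patient '", patient_id, "' under ",
                 root_path),
          class = "csvdseg_error_not_found")
  }
  vols <- list()
  for (mod in csvd_modalities()) {
    tok <- modality_token(mod)
    cand <- file.path(dir, paste0(tok, c(".nii.gz", ".nii")))
    hit <- cand[file.exists(cand)]
    if (length(hit) == 0L) next
    g <- .read_nifti_grid(hit[1])
    vols[[mod]] <- sequence_volume(g$values, mod, g$in_plane_spacing,
                                   g$slice_spacing)
  }
  if (length(vols) == 0L) {
    abort(paste0("no modality files found for patient '", patient_id, "'"),
          class = "csvdseg_error_not_found")
  }
  patient_study(patient_id, vols)
}

#' Write and read binary lesion masks as NIfTI
#'
#' The round trip is voxel-exact: masks are stored as integer payloads with
#' the in-plane and slice spacings recorded in the header `pixdim`.
#'
#' @param mask a [lesion_mask()].
#' @param path output file (`.nii` or `.nii.gz`).
#' @return `write_mask()` returns `path` invisibly; `read_mask()` returns a
#'   [lesion_mask()].
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "lesion_mask"))
  .write_nifti_grid(mask$values, mask$in_plane_spacing, mask$slice_spacing,
                    path)
}

#' @rdname write_mask
#' @param lesion_class class to tag the mask read from `path` with.
#' @export
read_mask <- function(path, lesion_class) {
  g <- .read_nifti_grid(path)
  vals <- g$values
  vals[] <- as.integer(round(vals))
  lesion_mask(vals, lesion_class, g$in_plane_spacing, g$slice_spacing)
}

#' Write a study (and optionally its ground truth) into the cohort layout
#'
#' @param study a [patient_study()].
#' @param root_path cohort root; the patient sub-directory is created.
#' @param truth optional ground truth as returned by [generate_study()]; its
#'   masks are written as `truth_<class>.nii.gz`.
#' @return The patient directory, invisibly.
#' @export
write_study <- function(study, root_path, truth = NULL) {
  dir <- file.path(root_path, study$patient_id)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) {
    abort(paste0("cannot create study directory ", dir),
          class = "csvdseg_error_io")
  }
  for (mod in names(study$volumes)) {
    v <- study$volumes[[mod]]
    .write_nifti_grid(v$intensities, v$in_plane_spacing, v$slice_spacing,
                      file.path(dir, paste0(modality_token(mod), ".nii.gz")))
  }
  if (!is.null(truth)) {
    for (cls in names(truth$masks)) {
      write_mask(truth$masks[[cls]],
                 file.path(dir, paste0("truth_", tolower(cls), ".nii.gz")))
    }
  }
  invisible(dir)
}

#' @rdname write_study
#' @param prefix mask file prefix, `"truth"` or `"pred"`.
#' @param patient_id patient sub-directory to read masks from.
#' @param root_path cohort root directory.
#' @export
read_masks <- function(root_path, patient_id, prefix = c("truth", "pred")) {
  prefix <- match.arg(prefix)
  dir <- file.path(root_path, patient_id)
  out <- list()
  for (cls in csvd_classes()) {
    f <- file.path(dir, paste0(prefix, "_", tolower(cls), ".nii.gz"))
    if (file.exists(f)) out[[cls]] <- read_mask(f, cls)
  }
  out
}
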