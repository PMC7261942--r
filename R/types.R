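#' @useDynLib csvdseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort %||% .data
#' @importFrom stats rnorm runif setNames
#' @keywords internal
"_PACKAGE"

# -- controlled vocabularies ---------------------------------------------------

#' MRI sequence (modality) and lesion-class vocabularies
#'
#' The pipeline handles four conventional MRI contrasts and four imaging signs
#' of cerebral small vessel disease. `csvd_modalities()` and `csvd_classes()`
#' return the canonical code sets; `modality_token()` / `token_modality()`
#' convert bijectively between modality codes and the lower-case file-name
#' tokens used in the on-disk layout.
#'
#' @return Character vectors of codes, or single translated codes.
#' @examples
#' csvd_modalities()
#' modality_token("T2FLAIR")
#' token_modality("dwi")
#' @export
csvd_modalities <- function() c("T1", "T2FLAIR", "DWI_B1000", "T2STAR")

#' @rdname csvd_modalities
#' @export
csvd_classes <- function() c("LACUNE", "WMH", "INFARCT", "MICROBLEED")

.modality_tokens <- c(
  T1 = "t1", T2FLAIR = "flair", DWI_B1000 = "dwi", T2STAR = "t2star"
)

#' @rdname csvd_modalities
#' @param modality one of `csvd_modalities()`.
#' @export
modality_token <- function(modality) {
  modality <- match.arg(modality, csvd_modalities())
  unname(.modality_tokens[modality])
}

#' @rdname csvd_modalities
#' @param token one of the file-name tokens `"t1"`, `"flair"`, `"dwi"`,
#'   `"t2star"`.
#' @export
token_modality <- function(token) {
  idx <- match(token, .modality_tokens)
  if (is.na(idx)) {
    abort(paste0("unknown modality token: '", token, "'"),
          class = "csvdseg_error_token")
  }
  names(.modality_tokens)[idx]
}

# -- sequence volume -----------------------------------------------------------

#' A single MRI contrast for one patient
#'
#' A `sequence_volume` carries one 3D intensity grid, indexed
#' `[slice, row, col]`, together with its acquisition geometry: the in-plane
#' pixel spacing (mm per pixel along rows and columns, assumed isotropic
#' in-plane) and the spacing between consecutive slices (mm). Generated data
#' keep the in-plane spacing within 0.36-1.44 mm and the slice spacing within
#' 6-8 mm, mirroring conventional stroke-protocol MRI where through-plane
#' resolution is much coarser than in-plane resolution.
#'
#' @param intensities numeric 3D array `[slice, row, col]`, non-negative.
#' @param modality one of `csvd_modalities()`.
#' @param in_plane_spacing mm per pixel along row and col.
#' @param slice_spacing mm between slice centers.
#' @return An object of class `sequence_volume`.
#' @export
sequence_volume <- function(intensities, modality, in_plane_spacing,
                            slice_spacing) {
  modality <- match.arg(modality, csvd_modalities())
  if (!is.array(intensities) || length(dim(intensities)) != 3L) {
    abort("intensities must be a 3D array [slice, row, col]",
          class = "csvdseg_error_contract")
  }
  if (any(intensities < 0)) {
    abort("intensities must be non-negative", class = "csvdseg_error_contract")
  }
  stopifnot(in_plane_spacing > 0, slice_spacing > 0)
  structure(
    list(
      modality = modality,
      intensities = intensities,
      in_plane_spacing = as.numeric(in_plane_spacing),
      slice_spacing = as.numeric(slice_spacing)
    ),
    class = "sequence_volume"
  )
}

#' @export
print.sequence_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "<sequence_volume %s  %d slices x %d x %d  %.2f mm in-plane, %.1f mm between slices>\n",
    x$modality, d[1], d[2], d[3], x$in_plane_spacing, x$slice_spacing
  ))
  invisible(x)
}

# -- lesion mask ---------------------------------------------------------------

#' A binary lesion mask on the shared patient grid
#'
#' @param values binary (0/1) 3D array `[slice, row, col]`.
#' @param lesion_class one of `csvd_classes()`.
#' @param in_plane_spacing,slice_spacing geometry, as for [sequence_volume()].
#' @return An object of class `lesion_mask`.
#' @export
lesion_mask <- function(values, lesion_class, in_plane_spacing, slice_spacing) {
  lesion_class <- match.arg(lesion_class, csvd_classes())
  if (!is.array(values) || length(dim(values)) != 3L) {
    abort("mask values must be a 3D array [slice, row, col]",
          class = "csvdseg_error_contract")
  }
  if (!all(values %in% c(0, 1))) {
    abort("mask values must be binary 0/1", class = "csvdseg_error_contract")
  }
  storage.mode(values) <- "integer"
  structure(
    list(
      lesion_class = lesion_class,
      values = values,
      in_plane_spacing = as.numeric(in_plane_spacing),
      slice_spacing = as.numeric(slice_spacing)
    ),
    class = "lesion_mask"
  )
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf(
    "<lesion_mask %s  %s  %d positive voxels>\n",
    x$lesion_class, paste(dim(x$values), collapse = "x"), sum(x$values)
  ))
  invisible(x)
}

# -- patient study -------------------------------------------------------------

#' A patient's co-registered multi-sequence study
#'
#' Bundles the available [sequence_volume()]s of one patient under a single
#' identifier. All member volumes must share one voxel grid: the pipeline
#' assumes the sequences are already co-registered (registration itself is out
#' of scope), so inconsistent grid shapes are rejected at construction.
#'
#' @param patient_id opaque string identifier.
#' @param volumes named list of [sequence_volume()], keyed by modality code.
#' @return An object of class `patient_study`.
#' @export
patient_study <- function(patient_id, volumes) {
  if (length(volumes) < 1L) {
    abort("a study needs at least one sequence volume",
          class = "csvdseg_error_contract")
  }
  mods <- vapply(volumes, function(v) v$modality, character(1))
  names(volumes) <- mods
  dims <- lapply(volumes, function(v) dim(v$intensities))
  if (length(unique(lapply(dims, as.integer))) != 1L) {
    abort(
      paste0(
        "geometry mismatch across modalities of patient ", patient_id, ": ",
        paste(vapply(seq_along(volumes), function(i) {
          paste0(mods[i], "=", paste(dims[[i]], collapse = "x"))
        }, character(1)), collapse = ", ")
      ),
      class = "csvdseg_error_geometry"
    )
  }
  structure(
    list(patient_id = as.character(patient_id), volumes = volumes),
    class = "patient_study"
  )
}

#' @export
print.patient_study <- function(x, ...) {
  d <- dim(x$volumes[[1]]$intensities)
  cat(sprintf(
    "<patient_study %s  grid %s  modalities: %s>\n",
    x$patient_id, paste(d, collapse = "x"),
    paste(names(x$volumes), collapse = ", ")
  ))
  invisible(x)
}

#' @rdname patient_study
#' @param study a `patient_study`.
#' @export
study_grid <- function(study) dim(study$volumes[[1]]$intensities)

# internal: shared binary-array check for pairs of grids
check_same_shape <- function(a, b, what = "grids") {
  da <- dim(a) %||% length(a)
  db <- dim(b) %||% length(b)
  if (!identical(as.integer(da), as.integer(db))) {
    abort(
      paste0("shape mismatch between ", what, ": ",
             paste(da, collapse = "x"), " vs ", paste(db, collapse = "x")),
      class = "csvdseg_error_contract"
    )
  }
  invisible(TRUE)
}
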