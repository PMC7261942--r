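# Pixel-level mutual exclusivity of WMH, lacune and subcortical infarction.
#
# WMH and recent subcortical infarcts share signal properties on T2-FLAIR, and
# the independently trained segmentors can therefore claim the same voxels.
# The final output removes the overlaps by mask subtraction in a fixed order;
# microbleeds live on a different contrast (T2*) and are never touched.

#' Combine the four per-disease masks into a mutually exclusive prediction
#'
#' Applies, in order: `wmh := wmh \ infarct`, `wmh := wmh \ lacune_raw`,
#' `lacune := lacune \ infarct`. The subtraction of lacune from WMH uses the
#' *raw* lacune mask by default — a voxel removed from WMH by a lacune voxel
#' that is itself subsequently ceded to infarct stays removed (and ends up
#' labeled infarct). Set `use_cleaned_lacune = TRUE` to subtract the
#' infarct-cleaned lacune mask instead; both orders leave the three masks
#' pairwise disjoint. The microbleed mask is returned unchanged.
#'
#' @param lacune,wmh,infarct,microbleed [lesion_mask()] objects on one grid.
#' @param use_cleaned_lacune subtract the cleaned instead of raw lacune mask
#'   from WMH.
#' @return An object of class `csvd_combined`: list with `masks` (class ->
#'   [lesion_mask()]) and `provenance` (class -> `"raw"` or `"combined"`).
#' @export
combine_masks <- function(lacune, wmh, infarct, microbleed,
                          use_cleaned_lacune = FALSE) {
  ms <- list(LACUNE = lacune, WMH = wmh, INFARCT = infarct,
             MICROBLEED = microbleed)
  dims <- lapply(ms, function(m) dim(m$values))
  if (length(unique(lapply(dims, as.integer))) != 1L) {
    abort("combine_masks requires all four masks on one grid",
          class = "csvdseg_error_geometry")
  }
  lac_raw <- lacune$values
  inf_v <- infarct$values
  lac_clean <- lac_raw * (1L - inf_v)
  wmh_v <- wmh$values * (1L - inf_v)
  wmh_v <- wmh_v * (1L - if (use_cleaned_lacune) lac_clean else lac_raw)
  out <- ms
  out$WMH$values <- wmh_v
  out$LACUNE$values <- lac_clean
  structure(
    list(
      masks = out,
      provenance = c(LACUNE = "combined", WMH = "combined",
                     INFARCT = "raw", MICROBLEED = "raw")
    ),
    class = "csvd_combined"
  )
}

#' @export
print.csvd_combined <- function(x, ...) {
  counts <- vapply(x$masks, function(m) sum(m$values), numeric(1))
  cat("<csvd_combined>\n")
  for (cls in names(counts)) {
    cat(sprintf("  %-10s %8d voxels (%s)\n", cls, counts[[cls]],
                x$provenance[[cls]]))
  }
  invisible(x)
}

#' Finalize a patient's prediction and summarize present diseases
#'
#' Runs [combine_masks()] and reduces the result to the patient-level
#' multi-label view: the set of classes with at least one positive voxel
#' after combination.
#'
#' @param masks named list with elements `LACUNE`, `WMH`, `INFARCT`,
#'   `MICROBLEED` (empty masks allowed).
#' @param ... passed to [combine_masks()].
#' @return List with `combined` (a `csvd_combined`) and `present` (character
#'   vector of detected classes).
#' @export
finalize_patient <- function(masks, ...) {
  missing <- setdiff(csvd_classes(), names(masks))
  if (length(missing) > 0L) {
    abort(paste0("finalize_patient needs all four class masks; missing: ",
                 paste(missing, collapse = ", ")),
          class = "csvdseg_error_contract")
  }
  comb <- combine_masks(masks$LACUNE, masks$WMH, masks$INFARCT,
                        masks$MICROBLEED, ...)
  present <- names(Filter(function(m) sum(m$values) > 0, comb$masks))
  list(combined = comb, present = present)
}
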