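# Slice standardization: pad to square, resize to the network input size, and
# align intensities on the white-matter histogram peak.

#' Preprocessing parameters
#'
#' @param target_size square edge (pixels) slices are resized to before being
#'   fed to a segmentor; must be divisible by `2^depth` of the paired network.
#' @param wm_reference_value intensity the white-matter histogram peak is
#'   mapped to (arbitrary units; 1 by default so normalized white matter sits
#'   near 1).
#' @param histogram_bins number of equal-width bins used for peak detection.
#' @param background_threshold voxels at or below this value are treated as
#'   background (zero-padded border, air) and excluded from the histogram.
#' @return A list of class `preprocess_spec`.
#' @export
preprocess_spec <- function(target_size = 256L, wm_reference_value = 1,
                            histogram_bins = 256L, background_threshold = 0) {
  stopifnot(target_size >= 4L, wm_reference_value > 0, histogram_bins >= 2L,
            background_threshold >= 0)
  structure(
    list(
      target_size = as.integer(target_size),
      wm_reference_value = as.numeric(wm_reference_value),
      histogram_bins = as.integer(histogram_bins),
      background_threshold = as.numeric(background_threshold)
    ),
    class = "preprocess_spec"
  )
}

#' Pad a slice to a square with centered content
#'
#' The output edge is `max(nrow, ncol)`; the original content is centered and
#' the border filled with zeros, so the total intensity is preserved and
#' [crop_from_square()] recovers the input exactly.
#'
#' @param slice 2D numeric matrix.
#' @return Square matrix.
#' @export
pad_to_square <- function(slice) {
  if (!is.matrix(slice) || length(slice) == 0L) {
    abort("slice must be a non-empty matrix", class = "csvdseg_error_contract")
  }
  nr <- nrow(slice); nc <- ncol(slice)
  edge <- max(nr, nc)
  if (nr == edge && nc == edge) return(slice)
  out <- matrix(0, edge, edge)
  r0 <- (edge - nr) %/% 2L
  c0 <- (edge - nc) %/% 2L
  out[r0 + seq_len(nr), c0 + seq_len(nc)] <- slice
  out
}

#' @rdname pad_to_square
#' @param padded square matrix produced by `pad_to_square()`.
#' @param orig_dim `c(rows, cols)` of the original slice.
#' @export
crop_from_square <- function(padded, orig_dim) {
  edge <- nrow(padded)
  nr <- orig_dim[1]; nc <- orig_dim[2]
  r0 <- (edge - nr) %/% 2L
  c0 <- (edge - nc) %/% 2L
  padded[r0 + seq_len(nr), c0 + seq_len(nc), drop = FALSE]
}

#' Resize a square slice
#'
#' Intensity slices are resampled with bilinear interpolation; masks with
#' nearest neighbor, which keeps them binary. Resizing to the input size is
#' the identity.
#'
#' @param slice square 2D matrix.
#' @param target output edge in pixels.
#' @param mode `"INTENSITY"` (bilinear) or `"MASK"` (nearest neighbor).
#' @return `target x target` matrix.
#' @export
resize_slice <- function(slice, target, mode = c("INTENSITY", "MASK")) {
  mode <- match.arg(mode)
  if (nrow(slice) != ncol(slice)) {
    abort("resize_slice expects a square input (pad first)",
          class = "csvdseg_error_contract")
  }
  if (nrow(slice) == target) return(slice)
  filt <- if (mode == "INTENSITY") "bilinear" else "none"
  out <- EBImage::imageData(EBImage::resize(slice, w = target, h = target,
                                            filter = filt))
  if (mode == "MASK") {
    out <- matrix(as.integer(out > 0.5), target, target)
  }
  out
}

#' Align a volume's white-matter histogram peak to a reference value
#'
#' Intensities of MRI scans are in arbitrary scanner-dependent units; to
#' standardize scans across acquisitions the histogram peak corresponding to
#' normal white matter is detected and the whole volume rescaled
#' multiplicatively so that the peak lands on `spec$wm_reference_value`. Peak
#' detection builds a `histogram_bins`-bin histogram of above-background
#' voxels; for T1 and DWI (where white matter is among the brightest tissue)
#' the peak is the highest-count bin whose midpoint lies in the upper half of
#' the above-background range, for FLAIR and T2* the global above-background
#' mode is used (white matter is the dominant compartment by volume). A
#' `tissue_hint` mask overrides the heuristic with the mode inside the hint.
#'
#' The map is purely multiplicative, so the zero background is preserved and
#' the operation is invariant under global positive rescaling of the input.
#'
#' @param volume a [sequence_volume()].
#' @param spec a [preprocess_spec()].
#' @param tissue_hint optional logical/0-1 array marking known white matter.
#' @return The rescaled [sequence_volume()].
#' @export
normalize_wm <- function(volume, spec = preprocess_spec(),
                         tissue_hint = NULL) {
  v <- volume$intensities
  fg <- v > spec$background_threshold
  if (!any(fg)) {
    abort("degenerate volume: no voxels above background threshold",
          class = "csvdseg_error_degenerate")
  }
  p <- .wm_peak(v, fg, volume$modality, spec, tissue_hint)
  if (!is.finite(p) || p <= 0) {
    abort("degenerate volume: white-matter peak is zero",
          class = "csvdseg_error_degenerate")
  }
  out <- volume
  out$intensities <- v * (spec$wm_reference_value / p)
  out
}

.wm_peak <- function(v, fg, modality, spec, tissue_hint = NULL) {
  vals <- if (!is.null(tissue_hint)) {
    v[tissue_hint > 0 & fg]
  } else {
    v[fg]
  }
  lo <- min(vals); hi <- max(vals)
  if (hi <= lo) return(lo)
  breaks <- seq(lo, hi, length.out = spec$histogram_bins + 1L)
  bin <- findInterval(vals, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(bin, nbins = spec$histogram_bins)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  if (is.null(tissue_hint) && modality %in% c("T1", "DWI_B1000")) {
    upper <- mids >= (lo + hi) / 2
    counts[!upper] <- -1L
  }
  mids[which.max(counts)]
}
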