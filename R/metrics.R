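# Evaluation suite: per-patient Dice, patch-discretized Dice, region-wise
# (lesion-level) precision/recall/F1, and a binary-adapted FROC.

#' Dice overlap between two binary masks
#'
#' `2|P∩R| / (|P| + |R|)`. When both masks are empty the score is defined as
#' 1 and the result carries attribute `empty_pair = TRUE`, so cohort
#' aggregation can include or exclude lesion-negative patients explicitly.
#'
#' @param pred,ref binary arrays of identical shape (any dimensionality).
#' @return Numeric scalar in `[0, 1]`.
#' @export
dice <- function(pred, ref) {
  check_same_shape(pred, ref, "pred and ref")
  p <- sum(pred != 0); r <- sum(ref != 0)
  if (p + r == 0) {
    return(structure(1, empty_pair = TRUE))
  }
  i <- sum(pred != 0 & ref != 0)
  2 * i / (p + r)
}

#' Discretize a mask into square patches by max-pooling
#'
#' Divides the pixel grid into `patch_edge x patch_edge` blocks (boundary
#' blocks may be smaller) and marks a patch positive as soon as at least one
#' of its pixels is positive — a max-pooling over blocks. With
#' `patch_edge = 1` the mask is returned unchanged; with `patch_edge` equal
#' to the image edge a non-empty mask collapses to a single positive cell,
#' the presence/absence (multi-label classification) limit.
#'
#' @param mask binary 2D matrix.
#' @param patch_edge block edge in pixels, `>= 1`.
#' @return Binary matrix of patch cells
#'   (`ceiling(nrow/patch_edge) x ceiling(ncol/patch_edge)`).
#' @export
patch_discretize <- function(mask, patch_edge) {
  if (patch_edge < 1) {
    abort("patch_edge must be >= 1", class = "csvdseg_error_contract")
  }
  patch_edge <- as.integer(patch_edge)
  if (patch_edge == 1L) {
    return(matrix(as.integer(mask != 0), nrow(mask), ncol(mask)))
  }
  gi <- ceiling(seq_len(nrow(mask)) / patch_edge)
  gj <- ceiling(seq_len(ncol(mask)) / patch_edge)
  pos <- rowsum(t(rowsum((mask != 0) + 0, gi)), gj)
  m <- t(pos) > 0
  matrix(as.integer(m), nrow(m), ncol(m))
}

#' Patch-wise Dice: a tolerance-of-a-few-pixels alternative to pixel Dice
#'
#' Both masks are discretized with [patch_discretize()] and the Dice score of
#' the patch grids is returned, so predictions that miss the reference by
#' less than a patch still count as agreement. The default patch edge is
#' `round(sqrt(max(nrow, ncol)))` — approximately the square root of the
#' image dimension; for inputs padded to square the two dimensions agree.
#'
#' @inheritParams dice
#' @param patch_edge patch edge in pixels; `NULL` for the default.
#' @return Numeric scalar in `[0, 1]`.
#' @export
patch_dice <- function(pred, ref, patch_edge = NULL) {
  check_same_shape(pred, ref, "pred and ref")
  if (is.null(patch_edge)) {
    patch_edge <- round(sqrt(max(nrow(pred), ncol(pred))))
  }
  dice(patch_discretize(pred, patch_edge), patch_discretize(ref, patch_edge))
}

#' Label connected lesion components
#'
#' Maximal connected components under 8-connectivity for 2D masks and
#' 26-connectivity for 3D masks (the two natural "touching counts as one
#' lesion" rules).
#'
#' @param mask binary 2D or 3D array.
#' @param connectivity `"auto"` picks 8 for 2D and 26 for 3D inputs.
#' @return Integer array of component labels (0 = background) with attribute
#'   `n_components`.
#' @export
region_components <- function(mask, connectivity = c("auto", "8", "26")) {
  connectivity <- match.arg(connectivity)
  d <- dim(mask) %||% length(mask)
  if (length(d) == 2L) {
    lab <- label_components_2d(matrix(as.integer(mask != 0), d[1], d[2]))
  } else if (length(d) == 3L) {
    lab <- label_components_3d(array(as.integer(mask != 0), d))
  } else {
    abort("mask must be 2D or 3D", class = "csvdseg_error_contract")
  }
  structure(lab, n_components = max(lab))
}

#' Region-wise (lesion-level) detection scores
#'
#' Treats every connected lesion equally instead of every pixel: a reference
#' lesion overlapped by at least one predicted positive pixel is a true
#' positive, an untouched reference lesion a false negative, and a predicted
#' component that overlaps no reference lesion a false positive. With the
#' default `matching = "any"` rule one predicted component spanning two
#' reference lesions scores two true positives and no false positive;
#' `matching = "one_to_one"` greedily pairs components by overlap size so
#' each prediction can claim at most one lesion.
#'
#' Both-empty pairs score precision = recall = f1 = 1 with an `empty_pair`
#' flag; an empty prediction against a non-empty reference scores 0.
#'
#' @inheritParams dice
#' @param connectivity passed to [region_components()].
#' @param matching `"any"` (default) or `"one_to_one"`.
#' @return A list with `precision`, `recall`, `f1`, `tp`, `fp`, `fn`,
#'   `empty_pair`.
#' @export
region_f1 <- function(pred, ref, connectivity = "auto",
                      matching = c("any", "one_to_one")) {
  matching <- match.arg(matching)
  check_same_shape(pred, ref, "pred and ref")
  lp <- region_components(pred, connectivity)
  lr <- region_components(ref, connectivity)
  np <- attr(lp, "n_components"); nr <- attr(lr, "n_components")
  if (np == 0 && nr == 0) {
    return(list(precision = 1, recall = 1, f1 = 1, tp = 0L, fp = 0L, fn = 0L,
                empty_pair = TRUE))
  }
  both <- lp > 0 & lr > 0
  if (matching == "any") {
    tp <- length(unique(lr[both]))
    fn <- nr - tp
    fp <- np - length(unique(lp[both]))
  } else {
    # greedy one-to-one by overlap size
    if (any(both)) {
      ov <- table(pred_lab = lp[both], ref_lab = lr[both])
      pairs <- as.data.frame(ov, stringsAsFactors = FALSE)
      pairs <- pairs[pairs$Freq > 0, , drop = FALSE]
      pairs <- pairs[order(-pairs$Freq), , drop = FALSE]
      used_p <- used_r <- character(0)
      tp <- 0L
      for (k in seq_len(nrow(pairs))) {
        if (pairs$pred_lab[k] %in% used_p || pairs$ref_lab[k] %in% used_r) next
        used_p <- c(used_p, pairs$pred_lab[k])
        used_r <- c(used_r, pairs$ref_lab[k])
        tp <- tp + 1L
      }
    } else {
      tp <- 0L
    }
    fn <- nr - tp
    fp <- np - tp
  }
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(precision = precision, recall = recall, f1 = f1,
       tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
       empty_pair = FALSE)
}

#' Binary-adapted free-response operating characteristic
#'
#' Thresholds a probability map at each requested cut, then scores the binary
#' mask with the lesion-level counting rules of [region_f1()]. Because the
#' positive set shrinks as the threshold rises, lesion sensitivity is
#' non-increasing in the threshold; false-positive component counts usually
#' fall too but may transiently rise when a shrinking component splits.
#'
#' @param prob_map numeric array of probabilities in `[0, 1]`.
#' @param ref binary reference of the same shape.
#' @param thresholds ascending probability cuts.
#' @param connectivity passed to [region_components()].
#' @return A tibble with columns `threshold`, `tp`, `fp`, `fn`,
#'   `sensitivity`.
#' @export
froc_curve <- function(prob_map, ref,
                       thresholds = seq(0.1, 0.9, by = 0.1),
                       connectivity = "auto") {
  check_same_shape(prob_map, ref, "prob_map and ref")
  if (is.unsorted(thresholds)) {
    abort("thresholds must be ascending", class = "csvdseg_error_contract")
  }
  rows <- purrr::map(thresholds, function(t) {
    r <- region_f1((prob_map >= t) + 0, ref, connectivity = connectivity)
    tibble::tibble(
      threshold = t, tp = r$tp, fp = r$fp, fn = r$fn,
      sensitivity = if (r$tp + r$fn > 0) r$tp / (r$tp + r$fn) else 1
    )
  })
  dplyr::bind_rows(rows)
}
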