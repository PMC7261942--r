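# Cohort-level evaluation reports.

#' Evaluate predicted masks against ground truth over a cohort
#'
#' Computes, per patient and class, whole-volume Dice, patch-wise Dice
#' (per-slice discretization, Dice over the stacked patch grids), and the
#' lesion-level detection scores of [region_f1()]. Aggregates are unweighted
#' arithmetic means over patients within each class; the `OVERALL` row is
#' reported both as the mean of the four class means (`mean_of_class_means`)
#' and as the mean over all patient-class pairs pooled (`pooled_mean`) —
#' published summaries rarely say which of the two they use, so both are
#' emitted.
#'
#' @param predictions named list `patient_id -> (class -> lesion_mask)`.
#' @param ground_truths named list `patient_id -> (class -> lesion_mask)`.
#' @param classes classes to score.
#' @param patch_edge patch edge for the patch-wise Dice; `NULL` for the
#'   per-image default of [patch_dice()].
#' @param include_empty_pairs whether patients where prediction and reference
#'   are both empty for a class (score 1, flagged) enter the class means.
#' @param connectivity,matching passed to [region_f1()].
#' @return An object of class `csvd_report`: list with tibbles `per_patient`
#'   and `aggregate`, plus `patch_edge_used` and the evaluation options.
#' @export
evaluate_cohort <- function(predictions, ground_truths,
                            classes = csvd_classes(),
                            patch_edge = NULL,
                            include_empty_pairs = TRUE,
                            connectivity = "auto",
                            matching = "any") {
  pids <- names(predictions)
  if (!setequal(pids, names(ground_truths))) {
    abort(
      paste0(
        "patient sets differ; only in predictions: ",
        paste(setdiff(pids, names(ground_truths)), collapse = ", "),
        "; only in ground truth: ",
        paste(setdiff(names(ground_truths), pids), collapse = ", ")
      ),
      class = "csvdseg_error_contract"
    )
  }
  rows <- purrr::map(pids, function(pid) {
    purrr::map(classes, function(cls) {
      pm <- predictions[[pid]][[cls]]
      gm <- ground_truths[[pid]][[cls]]
      if (is.null(pm) || is.null(gm)) {
        abort(paste0("missing ", cls, " mask for patient ", pid),
              class = "csvdseg_error_contract")
      }
      p <- if (inherits(pm, "lesion_mask")) pm$values else pm
      g <- if (inherits(gm, "lesion_mask")) gm$values else gm
      d <- dice(p, g)
      pe <- patch_edge %||% round(sqrt(max(dim(p)[2], dim(p)[3])))
      pd_pred <- .discretize_volume(p, pe)
      pd_ref <- .discretize_volume(g, pe)
      rf <- region_f1(p, g, connectivity = connectivity, matching = matching)
      tibble::tibble(
        patient_id = pid, class = cls,
        dice = as.numeric(d),
        patch_dice = as.numeric(dice(pd_pred, pd_ref)),
        region_precision = rf$precision, region_recall = rf$recall,
        region_f1 = rf$f1,
        tp = rf$tp, fp = rf$fp, fn = rf$fn,
        empty_pair = isTRUE(attr(d, "empty_pair")),
        patch_edge = as.integer(pe)
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  scored <- if (include_empty_pairs) rows else
    dplyr::filter(rows, !.data$empty_pair)
  by_class <- scored |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      n_patients = dplyr::n(),
      dplyr::across(c("dice", "patch_dice", "region_precision",
                      "region_recall", "region_f1"), mean),
      .groups = "drop"
    )
  metric_cols <- c("dice", "patch_dice", "region_precision", "region_recall",
                   "region_f1")
  overall_ccm <- by_class |>
    dplyr::summarise(
      class = "OVERALL", aggregation = "mean_of_class_means",
      n_patients = sum(.data$n_patients),
      dplyr::across(dplyr::all_of(metric_cols), mean)
    )
  overall_pool <- scored |>
    dplyr::summarise(
      class = "OVERALL", aggregation = "pooled_mean",
      n_patients = dplyr::n(),
      dplyr::across(dplyr::all_of(metric_cols), mean)
    )
  aggregate <- dplyr::bind_rows(
    dplyr::mutate(by_class, aggregation = "class_mean", .after = "class"),
    overall_ccm, overall_pool
  )
  structure(
    list(
      per_patient = rows,
      aggregate = aggregate,
      patch_edge_used = unique(rows$patch_edge),
      options = list(include_empty_pairs = include_empty_pairs,
                     connectivity = connectivity, matching = matching)
    ),
    class = "csvd_report"
  )
}

.discretize_volume <- function(vol, patch_edge) {
  d <- dim(vol)
  out <- lapply(seq_len(d[1]), function(s) {
    patch_discretize(matrix(vol[s, , ], d[2], d[3]), patch_edge)
  })
  array(unlist(out), c(dim(out[[1]]), length(out)))
}

#' @export
print.csvd_report <- function(x, ...) {
  cat("<csvd_report>\n")
  print(x$aggregate)
  invisible(x)
}

#' Tidy and summarize evaluation reports
#'
#' `tidy()` returns the per-patient metric table; `glance()` a one-row
#' overall summary (mean-of-class-means aggregation).
#'
#' @param x a `csvd_report`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.csvd_report <- function(x, ...) x$per_patient

#' @rdname tidy.csvd_report
#' @export
glance.csvd_report <- function(x, ...) {
  x$aggregate |>
    dplyr::filter(.data$class == "OVERALL",
                  .data$aggregation == "mean_of_class_means") |>
    dplyr::select(dplyr::all_of(c("dice", "patch_dice", "region_f1",
                                  "n_patients")))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

# -- serialization -------------------------------------------------------------

#' Serialize evaluation reports
#'
#' `write_report()` stores the full report as JSON (losslessly: numbers are
#' written at full precision) and `read_report()` restores it;
#' `write_report_csv()` exports the aggregate table with one row per class,
#' mirroring the usual per-disease results layout.
#'
#' @param report a `csvd_report`.
#' @param path output file.
#' @return `read_report()` returns a `csvd_report`; the writers return `path`
#'   invisibly.
#' @export
write_report <- function(report, path) {
  payload <- list(
    per_patient = report$per_patient,
    aggregate = report$aggregate,
    patch_edge_used = report$patch_edge_used,
    options = report$options
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      per_patient = tibble::as_tibble(payload$per_patient),
      aggregate = tibble::as_tibble(payload$aggregate),
      patch_edge_used = payload$patch_edge_used,
      options = payload$options
    ),
    class = "csvd_report"
  )
}

#' @rdname write_report
#' @export
write_report_csv <- function(report, path) {
  utils::write.csv(report$aggregate, path, row.names = FALSE)
  invisible(path)
}
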