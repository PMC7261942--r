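# Training loop with the overfitting-divergence stopping rule, plus slice
# extraction, checkpointing and whole-volume prediction.

#' Mean per-item Dice of thresholded predictions
#'
#' The pipeline's training/validation "accuracy": probabilities are
#' binarized at `threshold` and the Dice score against the reference is
#' averaged over the batch items, with empty-against-empty pairs scoring 1.
#' Plain pixel accuracy would sit near 1 for any model because lesions are
#' sparse, which would make an accuracy-threshold stopping rule meaningless;
#' mean Dice keeps it informative.
#'
#' @param pred_probs probability maps: `[H, W, N]` or `[H, W, 1, N]` array,
#'   or a list of matrices.
#' @param ref reference binary masks in the same layout.
#' @param threshold binarization cut.
#' @return Mean Dice in `[0, 1]`.
#' @export
training_accuracy <- function(pred_probs, ref, threshold = 0.5) {
  pl <- .as_slice_list(pred_probs)
  rl <- .as_slice_list(ref)
  if (length(pl) != length(rl)) {
    abort("pred and ref batches differ in length",
          class = "csvdseg_error_contract")
  }
  scores <- vapply(seq_along(pl), function(i) {
    check_same_shape(pl[[i]], rl[[i]], "pred and ref items")
    as.numeric(dice(pl[[i]] >= threshold, rl[[i]] != 0))
  }, numeric(1))
  mean(scores)
}

.as_slice_list <- function(x) {
  if (is.list(x)) return(x)
  d <- dim(x)
  if (length(d) == 4L) {
    lapply(seq_len(d[4]), function(i) x[, , 1, i])
  } else if (length(d) == 3L) {
    lapply(seq_len(d[3]), function(i) x[, , i])
  } else {
    list(x)
  }
}

#' The training stop rule
#'
#' Training halts once the model demonstrably overfits: training accuracy
#' above 0.98 while exceeding the validation accuracy by more than 0.15.
#' Both conditions are strict inequalities of `train` and `train - val`.
#'
#' @param state a `csvd_train_state`, or any list with `train_accuracy` and
#'   `val_accuracy` fields.
#' @return Logical flag.
#' @export
should_stop <- function(state) {
  tr <- state$train_accuracy
  va <- state$val_accuracy
  isTRUE(tr > 0.98 && (tr - va) > 0.15)
}

# -- slice dataset -------------------------------------------------------------

# Extract preprocessed 2D training tensors for one class from a cohort.
# Returns X [S,S,C,n], Y [S,S,1,n], patient index per slice.
.build_slice_dataset <- function(spec, cohort, pp) {
  size <- spec$input_size
  xs <- list(); ys <- list(); pidx <- integer(0)
  for (i in seq_along(cohort)) {
    study <- cohort[[i]]$study
    truth <- cohort[[i]]$truth
    miss <- setdiff(spec$input_modalities, names(study$volumes))
    if (length(miss) > 0L) {
      abort(paste0("patient ", study$patient_id, " lacks routed modality: ",
                   paste(miss, collapse = ", ")),
            class = "csvdseg_error_routing")
    }
    vols <- lapply(spec$input_modalities, function(m) {
      normalize_wm(study$volumes[[m]], pp)$intensities
    })
    mask <- truth$masks[[spec$lesion_class]]$values
    ns <- dim(mask)[1]
    for (s in seq_len(ns)) {
      ch <- lapply(vols, function(v) {
        resize_slice(pad_to_square(matrix(v[s, , ], dim(v)[2], dim(v)[3])),
                     size, "INTENSITY")
      })
      x <- array(unlist(ch), c(size, size, length(ch)))
      y <- resize_slice(pad_to_square(matrix(mask[s, , ],
                                             dim(mask)[2], dim(mask)[3])),
                        size, "MASK")
      xs[[length(xs) + 1L]] <- x
      ys[[length(ys) + 1L]] <- y
      pidx <- c(pidx, i)
    }
  }
  n <- length(xs)
  nch <- dim(xs[[1]])[3]
  list(
    x = array(unlist(xs), c(size, size, nch, n)),
    y = array(unlist(ys), c(size, size, 1, n)),
    patient = pidx
  )
}

# random zoom augmentation: resize content by factor f, center crop/pad back
.augment_zoom <- function(x, y, zoom_range) {
  f <- runif(1, zoom_range[1], zoom_range[2])
  size <- dim(x)[1]
  zs <- max(4L, 2L * as.integer(round(size * f / 2)))
  fit <- function(m, mode) {
    r <- resize_slice(m, zs, mode)
    if (zs >= size) {
      o <- (zs - size) %/% 2L
      r[o + seq_len(size), o + seq_len(size)]
    } else {
      pad <- matrix(0, size, size)
      o <- (size - zs) %/% 2L
      pad[o + seq_len(zs), o + seq_len(zs)] <- r
      pad
    }
  }
  x2 <- array(0, dim(x))
  for (c in seq_len(dim(x)[3])) x2[, , c] <- fit(x[, , c], "INTENSITY")
  list(x = x2, y = fit(y[, , 1], "MASK"))
}

# -- training ------------------------------------------------------------------

#' Train one per-disease segmentor on a phantom or real cohort
#'
#' Slices the routed, preprocessed sequences of every patient into 2D
#' training pairs, splits the cohort by patient into training and validation
#' parts, and optimizes the U-Net with Adam. After each epoch the mean-Dice
#' training and validation accuracies are recorded; training stops at
#' `max_epochs` or as soon as [should_stop()] fires, and the returned model
#' carries the weights of the epoch with the best validation accuracy (the
#' stopping rule deliberately fires *after* overfitting sets in, so the
#' final-epoch weights are not the ones you want).
#'
#' Training under this loss landscape is bistable: a run can settle into the
#' all-empty local optimum (every probability below threshold) and, with a
#' saturated sigmoid, never leave it. The trainer detects that outcome — the
#' best-validation model scoring (near-)zero Dice on the lesion-bearing
#' validation slices — and restarts with a shifted initialization seed, up
#' to `max_restarts` times. Restarts are part of the deterministic schedule:
#' the same `spec$seed` always yields the same sequence of attempts.
#'
#' @param spec a [segmentor_spec()].
#' @param cohort list of `list(study =, truth =)` as from
#'   [generate_cohort()].
#' @param split fractions `c(train, val)` of patients.
#' @param pp a [preprocess_spec()]; defaults to one whose `target_size` is
#'   the network input size.
#' @param verbose print per-epoch progress.
#' @param max_restarts additional attempts after a collapsed run.
#' @return List with `model` (a `csvd_unet`, best-validation weights) and
#'   `state` (a `csvd_train_state`; `$restarts` counts collapsed attempts).
#' @export
train_segmentor <- function(spec, cohort, split = c(0.75, 0.25),
                            pp = NULL, verbose = FALSE, max_restarts = 2L) {
  stopifnot(inherits(spec, "segmentor_spec"))
  pp <- pp %||% preprocess_spec(target_size = spec$input_size)
  ds <- .build_slice_dataset(spec, cohort, pp)
  n_pat <- length(cohort)
  fit <- NULL
  for (attempt in 0:max_restarts) {
    spec_a <- spec
    spec_a$seed <- as.integer((spec$seed + attempt * 100003L) %%
                                .Machine$integer.max)
    fit <- .train_once(spec_a, ds, n_pat, split, verbose)
    fit$state$restarts <- attempt
    if (!fit$collapsed) break
    if (verbose) {
      message(sprintf("[%s] collapsed to empty predictions; restarting",
                      spec$lesion_class))
    }
  }
  fit$model$spec <- spec
  list(model = fit$model, state = fit$state)
}

.train_once <- function(spec, ds, n_pat, split, verbose) {
  model <- build_unet(spec)  # seeds the RNG stream deterministically
  perm_pat <- sample(n_pat)
  n_train_pat <- max(1L, min(n_pat - 1L, ceiling(split[1] * n_pat)))
  if (n_pat == 1L) n_train_pat <- 1L
  train_pat <- perm_pat[seq_len(n_train_pat)]
  tr_idx <- which(ds$patient %in% train_pat)
  va_idx <- setdiff(seq_along(ds$patient), tr_idx)
  if (length(va_idx) == 0L) va_idx <- tr_idx  # single-patient degenerate case

  if (sum(ds$y[, , , tr_idx]) == 0) {
    abort(paste0("no positive ", spec$lesion_class,
                 " voxels in the training slices"),
          class = "csvdseg_error_training_data")
  }

  adam <- .adam_init(model$params)
  history <- list()
  best <- list(val = -Inf, params = model$params, epoch = 0L)
  stopped <- FALSE
  tr_acc <- va_acc <- NA_real_

  # forced-foreground sampling: lesion-bearing slices are a small minority,
  # and batches without any keep pushing the model toward the all-empty
  # local optimum; guaranteeing every batch about a third of positive
  # slices keeps real gradient signal in every update
  pos_slices <- tr_idx[vapply(tr_idx, function(i) sum(ds$y[, , 1, i]) > 0,
                              logical(1))]
  for (epoch in seq_len(spec$max_epochs)) {
    # step decay: fine-tune at a lower rate over the last quarter of the
    # epoch budget (sharpens small-lesion boundaries)
    lr_epoch <- spec$learning_rate *
      if (epoch > 0.75 * spec$max_epochs) 0.3 else 1
    order_idx <- tr_idx[sample(length(tr_idx))]
    batches <- split(order_idx, ceiling(seq_along(order_idx) /
                                          spec$batch_size))
    n_force <- max(1L, spec$batch_size %/% 3L)
    batches <- lapply(batches, function(b) {
      if (sum(ds$y[, , , b, drop = FALSE]) > 0) return(b)
      fg <- pos_slices[sample.int(length(pos_slices),
                                  min(n_force, length(pos_slices)))]
      c(b[seq_len(max(0L, length(b) - length(fg)))], fg)
    })
    for (b in batches) {
      xb <- ds$x[, , , b, drop = FALSE]
      yb <- ds$y[, , , b, drop = FALSE]
      if (!is.null(spec$augment_zoom_range)) {
        for (j in seq_along(b)) {
          az <- .augment_zoom(array(xb[, , , j], dim(xb)[1:3]),
                              array(yb[, , , j], dim(yb)[1:3]),
                              spec$augment_zoom_range)
          xb[, , , j] <- az$x
          yb[, , 1, j] <- az$y
        }
      }
      fw <- unet_forward(model, xb, keep_cache = TRUE)
      ls <- .seg_loss(fw$probs, yb, spec$loss)
      gr <- unet_backward(model, fw$cache, ls$dlogits)
      adam <- .adam_step(adam, gr, lr_epoch)
      model$params <- adam$params
    }
    tr_acc <- .batched_accuracy(model, ds, tr_idx, spec$threshold)
    va_acc <- .batched_accuracy(model, ds, va_idx, spec$threshold)
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, train_accuracy = tr_acc, val_accuracy = va_acc
    )
    if (verbose) {
      message(sprintf("[%s] epoch %d  train %.3f  val %.3f",
                      spec$lesion_class, epoch, tr_acc, va_acc))
    }
    if (va_acc >= best$val) {
      best <- list(val = va_acc, params = model$params, epoch = epoch)
    }
    if (should_stop(list(train_accuracy = tr_acc, val_accuracy = va_acc))) {
      stopped <- TRUE
      break
    }
  }

  model$params <- best$params
  # collapse check: Dice of the best model on lesion-bearing validation
  # slices; (near-)zero means the run fell into the all-empty optimum
  pos_va <- va_idx[vapply(va_idx, function(i) sum(ds$y[, , 1, i]) > 0,
                          logical(1))]
  collapsed <- length(history) > 0 && length(pos_va) > 0 &&
    .batched_accuracy(model, ds, pos_va, spec$threshold) < 0.05
  state <- structure(
    list(
      epoch = length(history),
      train_accuracy = tr_acc,
      val_accuracy = va_acc,
      best_val_accuracy = if (is.finite(best$val)) best$val else NA_real_,
      best_epoch = best$epoch,
      stopped = stopped,
      restarts = 0L,
      history = dplyr::bind_rows(history)
    ),
    class = "csvd_train_state"
  )
  list(model = model, state = state, collapsed = collapsed)
}

.batched_accuracy <- function(model, ds, idx, threshold, chunk = 32L) {
  if (length(idx) == 0L) return(NA_real_)
  scores <- numeric(0)
  for (part in split(idx, ceiling(seq_along(idx) / chunk))) {
    fw <- unet_forward(model, ds$x[, , , part, drop = FALSE])
    for (j in seq_along(part)) {
      scores <- c(scores, as.numeric(
        dice(fw$probs[, , 1, j] >= threshold, ds$y[, , 1, part[j]] != 0)
      ))
    }
  }
  mean(scores)
}

.adam_init <- function(params) {
  list(params = params,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

.adam_step <- function(st, grads, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  st$t <- st$t + 1L
  b1t <- 1 - beta1^st$t
  b2t <- 1 - beta2^st$t
  for (nm in names(st$params)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    mhat <- st$m[[nm]] / b1t
    vhat <- st$v[[nm]] / b2t
    st$params[[nm]] <- st$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  st
}

#' @export
print.csvd_train_state <- function(x, ...) {
  cat(sprintf(
    "<csvd_train_state  %d epochs  train %.3f  val %.3f  best val %.3f (epoch %d)%s>\n",
    x$epoch, x$train_accuracy, x$val_accuracy, x$best_val_accuracy,
    x$best_epoch, if (x$stopped) "  [stopped]" else ""
  ))
  invisible(x)
}

#' @rdname tidy.csvd_report
#' @export
tidy.csvd_train_state <- function(x, ...) x$history

#' @rdname tidy.csvd_report
#' @export
glance.csvd_train_state <- function(x, ...) {
  tibble::tibble(
    epochs = x$epoch, train_accuracy = x$train_accuracy,
    val_accuracy = x$val_accuracy, best_val_accuracy = x$best_val_accuracy,
    best_epoch = x$best_epoch, stopped = x$stopped
  )
}

# -- checkpoints ---------------------------------------------------------------

#' Save and load segmentor checkpoints
#'
#' Single-file, versioned checkpoints holding the spec, the weights and the
#' training history.
#'
#' @param model a `csvd_unet`.
#' @param state optional `csvd_train_state` stored alongside.
#' @param path checkpoint file.
#' @return `load_checkpoint()` returns `list(model, state)`.
#' @export
save_checkpoint <- function(model, path, state = NULL) {
  saveRDS(list(format_version = 1L, spec = model$spec, params = model$params,
               encoder_channels = model$encoder_channels,
               bottleneck_channels = model$bottleneck_channels,
               state = state),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (is.null(ck$format_version) || ck$format_version != 1L) {
    abort("unrecognized checkpoint format", class = "csvdseg_error_io")
  }
  model <- structure(
    list(spec = ck$spec, params = ck$params,
         encoder_channels = ck$encoder_channels,
         bottleneck_channels = ck$bottleneck_channels),
    class = "csvd_unet"
  )
  list(model = model, state = ck$state)
}

# -- prediction ----------------------------------------------------------------

#' Predict a lesion mask for a whole study
#'
#' The study's routed sequences are normalized, each slice is padded to
#' square and resized to the network input, all slices are pushed through
#' the U-Net in one batch, the probability maps are thresholded, resized
#' back (nearest neighbor) and cropped to the native grid, and the slice
#' masks are concatenated into the 3D prediction.
#'
#' @param model a `csvd_unet`.
#' @param study a [patient_study()] containing all routed modalities.
#' @param spec spec override; defaults to `model$spec`.
#' @param pp a [preprocess_spec()]; default matches the input size.
#' @return A [lesion_mask()] on the study's grid (pre-combination).
#' @export
predict_volume <- function(model, study, spec = model$spec, pp = NULL) {
  pp <- pp %||% preprocess_spec(target_size = spec$input_size)
  miss <- setdiff(spec$input_modalities, names(study$volumes))
  if (length(miss) > 0L) {
    abort(paste0("study ", study$patient_id, " lacks routed modality: ",
                 paste(miss, collapse = ", ")),
          class = "csvdseg_error_routing")
  }
  vols <- lapply(spec$input_modalities, function(m) {
    normalize_wm(study$volumes[[m]], pp)$intensities
  })
  gd <- dim(vols[[1]])
  ns <- gd[1]; nr <- gd[2]; nc <- gd[3]
  edge <- max(nr, nc)
  size <- spec$input_size
  x <- array(0, c(size, size, length(vols), ns))
  for (s in seq_len(ns)) {
    for (c in seq_along(vols)) {
      x[, , c, s] <- resize_slice(
        pad_to_square(matrix(vols[[c]][s, , ], nr, nc)), size, "INTENSITY"
      )
    }
  }
  fw <- unet_forward(model, x)
  out <- array(0L, gd)
  for (s in seq_len(ns)) {
    m <- matrix(as.integer(fw$probs[, , 1, s] >= spec$threshold), size, size)
    m <- resize_slice(m, edge, "MASK")
    out[s, , ] <- crop_from_square(m, c(nr, nc))
  }
  v1 <- study$volumes[[spec$input_modalities[1]]]
  lesion_mask(out, spec$lesion_class, v1$in_plane_spacing, v1$slice_spacing)
}
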