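# Compact 2D U-Net: encoder/decoder with skip connections, built from the
# Rcpp layer primitives. Parameters live in a flat named list so the
# optimizer and checkpointing stay trivial.

.default_routing <- function() {
  list(
    INFARCT = "DWI_B1000",
    WMH = "T2FLAIR",
    LACUNE = c("T1", "T2FLAIR"),
    MICROBLEED = "T2STAR"
  )
}

#' Per-disease segmentor configuration
#'
#' Each of the four lesion classes gets its own independently trained U-Net,
#' reading only the MRI sequences the sign is visible on: infarcts from DWI
#' b1000, WMH from T2-FLAIR, microbleeds from T2*-weighted GRE, and lacunes
#' from T1 plus T2-FLAIR (lacunes are identified as CSF-like T1
#' hypointensities with FLAIR as the reference sequence; set
#' `input_modalities = "T1"` for a single-channel variant).
#'
#' @param lesion_class one of `csvd_classes()`.
#' @param input_modalities ordered modality routing; defaults per class as
#'   above.
#' @param depth number of encoder (downsampling) levels.
#' @param base_channels feature channels at the first level.
#' @param channel_growth channel multiplier per downsampling (2 doubles the
#'   channels each time the resolution halves).
#' @param input_size square network input edge; must be divisible by
#'   `2^depth`.
#' @param threshold probability cut for binarizing the output map.
#' @param loss `"SUM"` (soft dice plus binary cross-entropy, the default),
#'   `"SOFT_DICE"`, or `"BCE"`. The cross-entropy term keeps gradients alive
#'   when the sigmoid saturates; pure soft dice can collapse to empty
#'   predictions on cohorts where most slices carry no lesion.
#' @param max_epochs,batch_size,learning_rate optimization parameters (Adam).
#' @param seed RNG seed governing weight initialization, the train/validation
#'   split and batch shuffling.
#' @param augment_zoom_range optional `c(lo, hi)` zoom-factor interval for
#'   random-resize augmentation (scale invariance across the in-plane
#'   spacings seen in practice); `NULL` disables it.
#' @return A list of class `segmentor_spec`.
#' @export
segmentor_spec <- function(lesion_class,
                           input_modalities = NULL,
                           depth = 2L, base_channels = 8L,
                           channel_growth = 2L,
                           input_size = 64L, threshold = 0.5,
                           loss = c("SUM", "SOFT_DICE", "BCE"),
                           max_epochs = 30L, batch_size = 8L,
                           learning_rate = 2e-3, seed = 1L,
                           augment_zoom_range = NULL) {
  lesion_class <- match.arg(lesion_class, csvd_classes())
  loss <- match.arg(loss)
  if (is.null(input_modalities)) {
    input_modalities <- .default_routing()[[lesion_class]]
  }
  input_modalities <- vapply(input_modalities, match.arg, character(1),
                             choices = csvd_modalities())
  if (input_size %% 2^depth != 0) {
    abort(sprintf("input_size %d is not divisible by 2^depth = %d",
                  input_size, 2^depth),
          class = "csvdseg_error_config")
  }
  structure(
    list(
      lesion_class = lesion_class,
      input_modalities = unname(input_modalities),
      depth = as.integer(depth),
      base_channels = as.integer(base_channels),
      channel_growth = as.integer(channel_growth),
      input_size = as.integer(input_size),
      threshold = threshold,
      loss = loss,
      max_epochs = as.integer(max_epochs),
      batch_size = as.integer(batch_size),
      learning_rate = learning_rate,
      seed = as.integer(seed),
      augment_zoom_range = augment_zoom_range
    ),
    class = "segmentor_spec"
  )
}

#' Build (initialize) a U-Net from a segmentor spec
#'
#' The encoder has `depth` blocks of two same-padded 3x3 convolutions with
#' ReLU followed by 2x2 max-pooling; channels are
#' `base_channels * channel_growth^level`. A two-convolution bottleneck sits
#' at the bottom. The decoder mirrors the encoder: a 2x2 stride-2 transpose
#' convolution halves the channels and doubles the resolution, the matching
#' encoder output is concatenated (skip connection), and two 3x3
#' convolutions fuse the features. A final 1x1 convolution with a sigmoid
#' yields a one-channel probability map of the input's spatial size. Weights
#' use He-normal initialization, deterministic for `spec$seed`.
#'
#' @param spec a [segmentor_spec()].
#' @return An object of class `csvd_unet` (spec + named parameter list).
#' @export
build_unet <- function(spec) {
  stopifnot(inherits(spec, "segmentor_spec"))
  set.seed(spec$seed)
  d <- spec$depth
  g <- spec$channel_growth
  ch <- spec$base_channels * g^(0:d)  # ch[l+1] = channels at level l
  in_ch <- length(spec$input_modalities)

  he <- function(kh, kw, cin, cout) {
    array(rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
          c(kh, kw, cin, cout))
  }
  p <- list()
  prev <- in_ch
  for (l in seq_len(d)) {
    p[[paste0("enc", l, "_a_w")]] <- he(3, 3, prev, ch[l])
    p[[paste0("enc", l, "_a_b")]] <- numeric(ch[l])
    p[[paste0("enc", l, "_b_w")]] <- he(3, 3, ch[l], ch[l])
    p[[paste0("enc", l, "_b_b")]] <- numeric(ch[l])
    prev <- ch[l]
  }
  p[["bot_a_w"]] <- he(3, 3, ch[d], ch[d + 1])
  p[["bot_a_b"]] <- numeric(ch[d + 1])
  p[["bot_b_w"]] <- he(3, 3, ch[d + 1], ch[d + 1])
  p[["bot_b_b"]] <- numeric(ch[d + 1])
  for (l in rev(seq_len(d))) {
    p[[paste0("dec", l, "_up_w")]] <- he(2, 2, ch[l + 1], ch[l])
    p[[paste0("dec", l, "_up_b")]] <- numeric(ch[l])
    p[[paste0("dec", l, "_a_w")]] <- he(3, 3, 2 * ch[l], ch[l])
    p[[paste0("dec", l, "_a_b")]] <- numeric(ch[l])
    p[[paste0("dec", l, "_b_w")]] <- he(3, 3, ch[l], ch[l])
    p[[paste0("dec", l, "_b_b")]] <- numeric(ch[l])
  }
  p[["out_w"]] <- he(1, 1, ch[1], 1)
  p[["out_b"]] <- numeric(1)

  structure(
    list(spec = spec, params = p,
         encoder_channels = ch[seq_len(d)], bottleneck_channels = ch[d + 1]),
    class = "csvd_unet"
  )
}

#' @export
print.csvd_unet <- function(x, ...) {
  cat(sprintf(
    "<csvd_unet %s  input %dx%dx%d  encoder channels %s  %d parameters>\n",
    x$spec$lesion_class, x$spec$input_size, x$spec$input_size,
    length(x$spec$input_modalities),
    paste(x$encoder_channels, collapse = ","),
    sum(vapply(x$params, length, numeric(1)))
  ))
  invisible(x)
}

# concatenate two [H,W,C,N] arrays along the channel axis
.cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

.relu <- function(a) {
  a[a < 0] <- 0
  a
}

#' Forward pass of a U-Net
#'
#' @param model a `csvd_unet`.
#' @param x input batch `[H, W, C, N]` with `C = length(input_modalities)`.
#' @param keep_cache retain intermediates for [unet_backward()].
#' @return List with `probs` (`[H, W, 1, N]` sigmoid probabilities), `logits`
#'   and (optionally) `cache`.
#' @export
unet_forward <- function(model, x, keep_cache = FALSE) {
  p <- model$params
  d <- model$spec$depth
  cache <- if (keep_cache) list(x = x) else NULL
  h <- x
  skips <- vector("list", d)
  for (l in seq_len(d)) {
    a1 <- conv2d_fwd(h, p[[paste0("enc", l, "_a_w")]],
                     p[[paste0("enc", l, "_a_b")]])
    r1 <- .relu(a1)
    a2 <- conv2d_fwd(r1, p[[paste0("enc", l, "_b_w")]],
                     p[[paste0("enc", l, "_b_b")]])
    r2 <- .relu(a2)
    pool <- maxpool2_fwd(r2)
    if (keep_cache) {
      cache[[paste0("enc", l)]] <- list(in_a = h, r1 = r1, r2 = r2,
                                        argmax = pool$argmax,
                                        a1 = a1, a2 = a2)
    }
    skips[[l]] <- r2
    h <- pool$y
  }
  ba1 <- conv2d_fwd(h, p$bot_a_w, p$bot_a_b)
  br1 <- .relu(ba1)
  ba2 <- conv2d_fwd(br1, p$bot_b_w, p$bot_b_b)
  br2 <- .relu(ba2)
  if (keep_cache) {
    cache$bot <- list(in_a = h, r1 = br1, a1 = ba1, a2 = ba2)
  }
  h <- br2
  for (l in rev(seq_len(d))) {
    u <- upconv2_fwd(h, p[[paste0("dec", l, "_up_w")]],
                     p[[paste0("dec", l, "_up_b")]])
    cc <- .cat_channels(u, skips[[l]])
    a1 <- conv2d_fwd(cc, p[[paste0("dec", l, "_a_w")]],
                     p[[paste0("dec", l, "_a_b")]])
    r1 <- .relu(a1)
    a2 <- conv2d_fwd(r1, p[[paste0("dec", l, "_b_w")]],
                     p[[paste0("dec", l, "_b_b")]])
    r2 <- .relu(a2)
    if (keep_cache) {
      cache[[paste0("dec", l)]] <- list(in_up = h, cc = cc, r1 = r1,
                                        a1 = a1, a2 = a2)
    }
    h <- r2
  }
  logits <- conv2d_fwd(h, p$out_w, p$out_b)
  if (keep_cache) cache$out_in <- h
  probs <- 1 / (1 + exp(-logits))
  list(probs = probs, logits = logits, cache = cache)
}

#' Backward pass: parameter gradients from a logit gradient
#'
#' @param model a `csvd_unet`.
#' @param cache forward cache from `unet_forward(..., keep_cache = TRUE)`.
#' @param dlogits gradient of the loss w.r.t. the logits, `[H, W, 1, N]`.
#' @return Named list of gradients matching `model$params`.
#' @export
unet_backward <- function(model, cache, dlogits) {
  p <- model$params
  d <- model$spec$depth
  g <- list()
  bw <- conv2d_bwd(cache$out_in, p$out_w, dlogits)
  g$out_w <- bw$gw; g$out_b <- bw$gb
  dh <- bw$gx
  for (l in seq_len(d)) {  # decoder blocks, shallowest first = reverse of fwd
    cl <- cache[[paste0("dec", l)]]
    dh[cl$a2 <= 0] <- 0
    bw <- conv2d_bwd(cl$r1, p[[paste0("dec", l, "_b_w")]], dh)
    g[[paste0("dec", l, "_b_w")]] <- bw$gw
    g[[paste0("dec", l, "_b_b")]] <- bw$gb
    dh <- bw$gx
    dh[cl$a1 <= 0] <- 0
    bw <- conv2d_bwd(cl$cc, p[[paste0("dec", l, "_a_w")]], dh)
    g[[paste0("dec", l, "_a_w")]] <- bw$gw
    g[[paste0("dec", l, "_a_b")]] <- bw$gb
    dcc <- bw$gx
    n_up <- dim(cl$in_up)  # channels entering the up-convolution
    c_up <- dim(p[[paste0("dec", l, "_up_w")]])[4]
    du <- dcc[, , seq_len(c_up), , drop = FALSE]
    dskip <- dcc[, , c_up + seq_len(dim(dcc)[3] - c_up), , drop = FALSE]
    bw <- upconv2_bwd(cl$in_up, p[[paste0("dec", l, "_up_w")]], du)
    g[[paste0("dec", l, "_up_w")]] <- bw$gw
    g[[paste0("dec", l, "_up_b")]] <- bw$gb
    dh <- bw$gx
    # stash the skip gradient for the matching encoder level
    g[[paste0(".skip", l)]] <- dskip
  }
  cb <- cache$bot
  dh[cb$a2 <= 0] <- 0
  bw <- conv2d_bwd(cb$r1, p$bot_b_w, dh)
  g$bot_b_w <- bw$gw; g$bot_b_b <- bw$gb
  dh <- bw$gx
  dh[cb$a1 <= 0] <- 0
  bw <- conv2d_bwd(cb$in_a, p$bot_a_w, dh)
  g$bot_a_w <- bw$gw; g$bot_a_b <- bw$gb
  dh <- bw$gx
  for (l in rev(seq_len(d))) {  # encoder blocks, deepest first
    cl <- cache[[paste0("enc", l)]]
    dr2 <- maxpool2_bwd(dh, cl$argmax, dim(cl$r2)[1], dim(cl$r2)[2])
    dr2 <- dr2 + g[[paste0(".skip", l)]]
    g[[paste0(".skip", l)]] <- NULL
    dr2[cl$a2 <= 0] <- 0
    bw <- conv2d_bwd(cl$r1, p[[paste0("enc", l, "_b_w")]], dr2)
    g[[paste0("enc", l, "_b_w")]] <- bw$gw
    g[[paste0("enc", l, "_b_b")]] <- bw$gb
    dh <- bw$gx
    dh[cl$a1 <= 0] <- 0
    bw <- conv2d_bwd(cl$in_a, p[[paste0("enc", l, "_a_w")]], dh)
    g[[paste0("enc", l, "_a_w")]] <- bw$gw
    g[[paste0("enc", l, "_a_b")]] <- bw$gb
    dh <- bw$gx
  }
  g[names(model$params)]
}

# -- losses --------------------------------------------------------------------

# returns list(loss, dlogits); probs/labels are [H,W,1,N]. pos_weight
# rebalances the cross-entropy toward the sparse lesion pixels: "auto" uses
# the batch's background/lesion ratio capped at 50.
.seg_loss <- function(probs, labels, kind, eps = 1e-6, pos_weight = "auto") {
  n <- dim(probs)[4]
  dl_dice <- dl_bce <- NULL
  loss_d <- loss_b <- 0
  if (kind %in% c("SOFT_DICE", "SUM")) {
    dl_dice <- array(0, dim(probs))
    per <- numeric(n)
    for (i in seq_len(n)) {
      pp <- probs[, , 1, i]; yy <- labels[, , 1, i]
      A <- 2 * sum(pp * yy) + eps
      B <- sum(pp) + sum(yy) + eps
      per[i] <- 1 - A / B
      dl_dice[, , 1, i] <- -(2 * yy * B - A) / B^2 / n
    }
    loss_d <- mean(per)
  }
  if (kind %in% c("BCE", "SUM")) {
    npos <- sum(labels)
    w <- if (identical(pos_weight, "auto")) {
      if (npos > 0) min((length(labels) - npos) / npos, 50) else 1
    } else pos_weight
    wt <- 1 + (w - 1) * labels
    pc <- pmin(pmax(probs, 1e-7), 1 - 1e-7)
    loss_b <- -sum(wt * (labels * log(pc) + (1 - labels) * log(1 - pc))) /
      sum(wt)
    # d BCE / d logit simplifies to (p - y); computing it in logit space
    # keeps the gradient alive when the sigmoid saturates
    dlb_logit <- wt * (pc - labels) / sum(wt)
  }
  dlogits <- switch(kind,
    SOFT_DICE = dl_dice * probs * (1 - probs),
    BCE = dlb_logit,
    SUM = dl_dice * probs * (1 - probs) + dlb_logit
  )
  list(loss = loss_d + loss_b, dlogits = dlogits)
}
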