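test_that("architecture channel and shape laws hold", {
  # depth 3, base 8: encoder channels 8, 16, 32
  spec <- segmentor_spec("WMH", depth = 3L, base_channels = 8L,
                         input_size = 64L)
  m <- build_unet(spec)
  expect_equal(m$encoder_channels, c(8, 16, 32))
  expect_equal(m$bottleneck_channels, 64)
  expect_equal(dim(m$params$enc1_a_w), c(3, 3, 1, 8))
  expect_equal(dim(m$params$out_w), c(1, 1, 8, 1))

  # lacune routes two sequences: first conv accepts 2 channels
  lac <- build_unet(segmentor_spec("LACUNE", depth = 2L, input_size = 32L))
  expect_equal(dim(lac$params$enc1_a_w)[3], 2)

  # output spatial size equals input spatial size, one channel
  x <- array(runif(64 * 64 * 1 * 3), c(64, 64, 1, 3))
  fw <- unet_forward(m, x)
  expect_equal(dim(fw$probs), c(64, 64, 1, 3))
  expect_true(all(fw$probs > 0 & fw$probs < 1))

  expect_error(segmentor_spec("WMH", depth = 3L, input_size = 50L),
               class = "csvdseg_error_config")
})

test_that("forward/backward gradients match finite differences", {
  spec <- segmentor_spec("WMH", depth = 1L, base_channels = 2L,
                         input_size = 8L, seed = 3)
  m <- build_unet(spec)
  # jitter all parameters away from ReLU kinks (biases initialize at the
  # kink exactly, where the subgradient convention differs from a central
  # difference)
  set.seed(33)
  m$params <- lapply(m$params, function(p) p + rnorm(length(p), 0, 0.05))
  x <- array(runif(8 * 8 * 1 * 2), c(8, 8, 1, 2))
  y <- array(rbinom(8 * 8 * 2, 1, .3), c(8, 8, 1, 2))
  for (kind in c("SOFT_DICE", "BCE", "SUM")) {
    fw <- unet_forward(m, x, keep_cache = TRUE)
    ls <- csvdseg:::.seg_loss(fw$probs, y, kind)
    gr <- unet_backward(m, fw$cache, ls$dlogits)
    lossfn <- function(mm) {
      csvdseg:::.seg_loss(unet_forward(mm, x)$probs, y, kind)$loss
    }
    for (nm in c("enc1_a_w", "enc1_b_b", "bot_b_w", "dec1_up_w",
                 "dec1_a_w", "out_w", "out_b")) {
      j <- sample(length(m$params[[nm]]), 1)
      eps <- 1e-5
      m2 <- m; m2$params[[nm]][j] <- m$params[[nm]][j] + eps
      m3 <- m; m3$params[[nm]][j] <- m$params[[nm]][j] - eps
      num <- (lossfn(m2) - lossfn(m3)) / (2 * eps)
      expect_equal(gr[[nm]][j], num, tolerance = 1e-4,
                   label = paste(kind, nm))
    }
  }
})

test_that("training accuracy is the mean per-item dice", {
  h <- 4
  perfect <- array(0, c(h, h, 2)); perfect[1, 1, ] <- 0.9
  ref <- array(0, c(h, h, 2)); ref[1, 1, ] <- 1
  expect_equal(training_accuracy(perfect, ref), 1.0)

  zero <- array(0, c(h, h, 2))
  expect_equal(training_accuracy(zero, ref), 0.0)

  # one item dice 0.5, one dice 1 -> 0.75
  p <- array(0, c(h, h, 2)); r <- array(0, c(h, h, 2))
  p[1, 1:2, 1] <- 0.9; r[1, 2:3, 1] <- 1   # dice 0.5
  p[2, 2, 2] <- 0.9; r[2, 2, 2] <- 1       # dice 1
  expect_equal(training_accuracy(p, r), 0.75)

  # empty-against-empty items count as 1
  expect_equal(training_accuracy(array(0, c(h, h, 1)),
                                 array(0, c(h, h, 1))), 1.0)

  expect_error(
    training_accuracy(array(0, c(4, 4, 1)), array(0, c(5, 5, 1))),
    class = "csvdseg_error_contract"
  )
})

test_that("the stop rule is the printed double inequality", {
  expect_true(should_stop(list(train_accuracy = 0.99, val_accuracy = 0.80)))
  expect_false(should_stop(list(train_accuracy = 0.99, val_accuracy = 0.90)))
  expect_false(should_stop(list(train_accuracy = 0.97, val_accuracy = 0.70)))
  # boundary: both conditions strict
  expect_false(should_stop(list(train_accuracy = 0.98, val_accuracy = 0.5)))
  expect_false(should_stop(list(train_accuracy = 0.99, val_accuracy = 0.85)))
  set.seed(91)
  for (i in 1:200) {
    tr <- runif(1); va <- runif(1)
    expect_identical(
      should_stop(list(train_accuracy = tr, val_accuracy = va)),
      tr > 0.98 && (tr - va) > 0.15
    )
  }
})

test_that("training is deterministic and respects epoch boundaries", {
  cohort <- generate_cohort(tiny_config(201, grid = c(4L, 32L, 32L)), 4,
                            positive_fractions = c(LACUNE = 1, WMH = 1,
                                                   INFARCT = 1,
                                                   MICROBLEED = 1))
  spec <- segmentor_spec("WMH", depth = 2L, base_channels = 4L,
                         input_size = 32L, max_epochs = 2L, seed = 5)
  f1 <- train_segmentor(spec, cohort)
  f2 <- train_segmentor(spec, cohort)
  expect_identical(f1$state$history, f2$state$history)
  expect_identical(f1$model$params, f2$model$params)
  expect_equal(nrow(f1$state$history), f1$state$epoch)

  # max_epochs 0: untrained model, not stopped, empty history
  spec0 <- segmentor_spec("WMH", depth = 2L, base_channels = 4L,
                          input_size = 32L, max_epochs = 0L, seed = 5)
  f0 <- train_segmentor(spec0, cohort)
  expect_false(f0$state$stopped)
  expect_equal(f0$state$epoch, 0L)
  expect_identical(f0$model$params, build_unet(spec0)$params)

  # a cohort with no positive voxels for the class is a training-data error
  neg <- generate_cohort(tiny_config(202, grid = c(4L, 32L, 32L)), 2,
                         positive_fractions = c(LACUNE = 1, WMH = 0,
                                                INFARCT = 1, MICROBLEED = 1))
  expect_error(train_segmentor(spec, neg),
               class = "csvdseg_error_training_data")
})

test_that("prediction enforces routing and returns the native grid", {
  g <- generate_study(tiny_config(210, grid = c(4L, 32L, 32L)))
  spec <- segmentor_spec("MICROBLEED", depth = 2L, base_channels = 4L,
                         input_size = 32L)
  model <- build_unet(spec)

  # a study lacking T2* cannot be used for microbleed prediction
  no_t2s <- patient_study("X", g$study$volumes[c("T1", "T2FLAIR",
                                                 "DWI_B1000")])
  expect_error(predict_volume(model, no_t2s),
               class = "csvdseg_error_routing")

  pm <- predict_volume(model, g$study)
  expect_s3_class(pm, "lesion_mask")
  expect_equal(dim(pm$values), c(4L, 32L, 32L))

  # a model forced to probability ~0 everywhere yields an empty mask
  zero <- model
  zero$params$out_w[] <- 0
  zero$params$out_b[] <- -50
  pz <- predict_volume(zero, g$study)
  expect_equal(sum(pz$values), 0)
})

test_that("checkpoints round-trip the model and training state", {
  spec <- segmentor_spec("INFARCT", depth = 2L, base_channels = 4L,
                         input_size = 32L)
  m <- build_unet(spec)
  f <- tempfile(fileext = ".ckpt")
  save_checkpoint(m, f)
  back <- load_checkpoint(f)
  expect_identical(back$model$params, m$params)
  expect_equal(back$model$spec$lesion_class, "INFARCT")
})

test_that("tidy and glance summarize training states", {
  cohort <- generate_cohort(tiny_config(220, grid = c(4L, 32L, 32L)), 3,
                            positive_fractions = c(LACUNE = 1, WMH = 1,
                                                   INFARCT = 1,
                                                   MICROBLEED = 1))
  spec <- segmentor_spec("WMH", depth = 2L, base_channels = 4L,
                         input_size = 32L, max_epochs = 2L, seed = 5)
  fit <- train_segmentor(spec, cohort)
  td <- tidy(fit$state)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("epoch", "train_accuracy", "val_accuracy"))
  gl <- glance(fit$state)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$epochs, 2L)
})
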