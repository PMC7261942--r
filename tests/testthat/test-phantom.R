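test_that("study generation is bit-reproducible for a fixed seed", {
  cfg <- tiny_config(7)
  a <- generate_study(cfg)
  b <- generate_study(cfg)
  expect_identical(a$study$volumes$T1$intensities,
                   b$study$volumes$T1$intensities)
  expect_identical(a$truth$masks$WMH$values, b$truth$masks$WMH$values)
  c <- generate_study(tiny_config(8))
  expect_false(identical(a$study$volumes$T1$intensities,
                         c$study$volumes$T1$intensities))
})

test_that("lesion contrast directions follow the radiological table", {
  # single-class phantoms; lesion voxels compared to surrounding WM
  for (seed in c(3, 4)) {
    for (cls in csvd_classes()) {
      cfg <- tiny_config(seed * 100 + match(cls, csvd_classes()),
                         classes_on = cls)
      g <- generate_study(cfg, classes = cls)
      les <- g$truth$masks[[cls]]$values == 1L
      expect_gt(sum(les), 0)
      wm <- g$truth$tissue_map == 1L & !les
      for (mod in csvd_modalities()) {
        v <- g$study$volumes[[mod]]$intensities
        dirn <- cfg$contrast_table[cls, mod]
        dmean <- mean(v[les]) - mean(v[wm])
        info <- paste(cls, mod, dirn)
        if (dirn == "DOWN") expect_lt(dmean, 0, label = info)
        if (dirn == "UP") expect_gt(dmean, 0, label = info)
        if (dirn == "NEUTRAL") {
          expect_lt(abs(dmean), 3 * cfg$noise_sd, label = info)
        }
      }
    }
  }
})

test_that("lacune is CSF-like hypointense on T1 and microbleed dark on T2*", {
  g <- generate_study(tiny_config(21, classes_on = "LACUNE"),
                      classes = "LACUNE")
  les <- g$truth$masks$LACUNE$values == 1L
  wm <- g$truth$tissue_map == 1L & !les
  t1 <- g$study$volumes$T1$intensities
  expect_lt(mean(t1[les]), mean(t1[wm]))

  g2 <- generate_study(tiny_config(22, classes_on = "MICROBLEED"),
                       classes = "MICROBLEED")
  les2 <- g2$truth$masks$MICROBLEED$values == 1L
  wm2 <- g2$truth$tissue_map == 1L & !les2
  t2s <- g2$study$volumes$T2STAR$intensities
  dwi <- g2$study$volumes$DWI_B1000$intensities
  expect_lt(mean(t2s[les2]), mean(t2s[wm2]))
  expect_lt(abs(mean(dwi[les2]) - mean(dwi[wm2])), 3 * 5)
})

test_that("sampled lesion diameters respect the configured mm ranges", {
  cfg <- phantom_config(grid_shape = c(6L, 96L, 96L))
  set.seed(13)
  for (cls in c("LACUNE", "INFARCT", "MICROBLEED")) {
    rng <- cfg$diameter_ranges_mm[[cls]]
    for (spacing in c(0.5, 1.0, 1.44)) {
      d <- replicate(60, attr(
        sample_lesion_geometry(cls, cfg, in_plane_spacing = spacing),
        "diameter_mm"))
      expect_true(all(d <= rng[2] + 1e-9), label = paste(cls, spacing, "hi"))
      # lower bound holds whenever a single voxel is not already too coarse
      lo <- max(rng[1], spacing)
      expect_true(all(d >= lo - 1e-9), label = paste(cls, spacing, "lo"))
    }
  }
})

test_that("degenerate diameter range collapses to one voxel-quantized size", {
  cfg <- phantom_config(grid_shape = c(6L, 96L, 96L),
                        diameter_ranges_mm = list(
                          LACUNE = c(5, 5), WMH = c(4, 18),
                          INFARCT = c(2, 20), MICROBLEED = c(2, 10)))
  set.seed(14)
  d <- replicate(50, attr(
    sample_lesion_geometry("LACUNE", cfg, in_plane_spacing = 1.0),
    "diameter_mm"))
  expect_true(all(d == 5))
  cfg$diameter_ranges_mm$LACUNE <- c(6, 3)
  expect_error(sample_lesion_geometry("LACUNE", cfg),
               class = "csvdseg_error_config")
})

test_that("WMH footprints are connected unions of blobs inside the grid", {
  cfg <- phantom_config(grid_shape = c(6L, 64L, 64L))
  set.seed(15)
  for (i in 1:10) {
    fp <- sample_lesion_geometry("WMH", cfg, in_plane_spacing = 1.0)
    expect_gt(nrow(fp), 3)
    expect_true(all(fp[, "row"] >= 1 & fp[, "row"] <= 64))
  }
})

test_that("lesion masks stay inside the brain", {
  for (seed in c(31, 32, 33)) {
    g <- generate_study(tiny_config(seed))
    brain <- g$truth$tissue_map > 0L
    for (cls in csvd_classes()) {
      m <- g$truth$masks[[cls]]$values == 1L
      expect_true(all(brain[m]), label = paste(seed, cls))
    }
  }
})

test_that("impossible placement errors out after bounded retries", {
  cfg <- phantom_config(grid_shape = c(4L, 12L, 12L),
                        in_plane_spacing_range = c(0.36, 0.36))
  # 15 mm at 0.36 mm/px needs ~42 px; the 12-px brain cannot host it
  cfg$diameter_ranges_mm$LACUNE <- c(15, 15)
  cfg$lesion_counts <- list(LACUNE = c(1L, 1L), WMH = c(0L, 0L),
                            INFARCT = c(0L, 0L), MICROBLEED = c(0L, 0L))
  cfg$seed <- 5L
  expect_error(generate_study(cfg, classes = "LACUNE"),
               class = "csvdseg_error_placement")
})

test_that("cohort positivity follows the requested fractions", {
  cfg <- tiny_config(51)
  co <- generate_cohort(cfg, 60, positive_fractions = c(
    LACUNE = 1, WMH = 0, INFARCT = 1, MICROBLEED = 0.42))
  n_pos <- function(cls) {
    sum(vapply(co, function(it) sum(it$truth$masks[[cls]]$values) > 0,
               logical(1)))
  }
  expect_equal(n_pos("WMH"), 0L)
  expect_equal(n_pos("LACUNE"), 60L)
  # binomial sampling tolerance: 0.42 * 60 = 25.2, sd ~ 3.8
  expect_gt(n_pos("MICROBLEED"), 25.2 - 4 * 3.83)
  expect_lt(n_pos("MICROBLEED"), 25.2 + 4 * 3.83)

  expect_error(generate_cohort(cfg, 0), class = "csvdseg_error_config")
  expect_error(generate_cohort(cfg, 5, positive_fractions = c(LACUNE = 1.2)),
               class = "csvdseg_error_config")
})

test_that("generated geometry stays in the conventional spacing ranges", {
  cfg <- phantom_config(grid_shape = c(6L, 32L, 32L), seed = 71)
  g <- generate_study(cfg)
  v <- g$study$volumes$T1
  expect_gte(v$in_plane_spacing, 0.36); expect_lte(v$in_plane_spacing, 1.44)
  expect_gte(v$slice_spacing, 6); expect_lte(v$slice_spacing, 8)
})
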