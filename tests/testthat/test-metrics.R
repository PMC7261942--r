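test_that("dice matches direct set counting, including printed example", {
  # |P| = 4, |R| = 2, |P∩R| = 2 -> 2*2 / 6
  p <- matrix(0, 4, 4); p[1, 1:4] <- 1
  r <- matrix(0, 4, 4); r[1, 1:2] <- 1
  expect_equal(dice(p, r), 2 / 3, tolerance = 1e-12)

  m <- matrix(rbinom(64, 1, .4), 8, 8)
  expect_equal(as.numeric(dice(m, m)), 1)
  d <- matrix(0, 8, 8); d[8, 8] <- 1
  m2 <- matrix(0, 8, 8); m2[1, 1] <- 1
  expect_equal(dice(d, m2), 0)

  e <- dice(matrix(0, 3, 3), matrix(0, 3, 3))
  expect_equal(as.numeric(e), 1)
  expect_true(attr(e, "empty_pair"))

  expect_error(dice(matrix(0, 2, 2), matrix(0, 3, 3)),
               class = "csvdseg_error_contract")
})

test_that("dice is symmetric", {
  set.seed(11)
  for (i in 1:20) {
    a <- random_mask(9, 9); b <- random_mask(9, 9)
    expect_identical(as.numeric(dice(a, b)), as.numeric(dice(b, a)))
  }
})

test_that("patch_discretize max-pools blocks, with ragged boundaries", {
  m <- matrix(0, 4, 4); m[1, 1] <- 1
  out <- patch_discretize(m, 2)
  expect_equal(dim(out), c(2, 2))
  expect_equal(out, matrix(c(1L, 0L, 0L, 0L), 2, 2))

  # identity limit
  set.seed(3)
  m <- random_mask(7, 5)
  expect_equal(patch_discretize(m, 1), matrix(as.integer(m != 0), 7, 5))

  # whole-image patch: single presence cell
  expect_equal(patch_discretize(m, 7), matrix(as.integer(any(m != 0)), 1, 1))

  # ragged edges against the brute-force block OR
  for (edge in c(2, 3, 4)) {
    mm <- random_mask(10, 13)
    expect_equal(patch_discretize(mm, edge), oracle_patch(mm, edge))
  }

  expect_error(patch_discretize(m, 0), class = "csvdseg_error_contract")
})

test_that("patch_dice forgives sub-patch localization error", {
  # pred at (1,1), ref at (2,2): same 2x2 patch, pixel dice 0, patch dice 1
  p <- matrix(0, 4, 4); p[1, 1] <- 1
  r <- matrix(0, 4, 4); r[2, 2] <- 1
  expect_equal(as.numeric(dice(p, r)), 0)
  expect_equal(as.numeric(patch_dice(p, r, 2)), 1)

  set.seed(5)
  m <- random_mask(16, 16)
  expect_equal(as.numeric(patch_dice(m, m, 4)), 1)
  # patch_edge 1 reduces to pixel dice
  m2 <- random_mask(16, 16)
  expect_equal(as.numeric(patch_dice(m, m2, 1)), as.numeric(dice(m, m2)))
})

test_that("region_components matches flood-fill oracle and connectivity rules", {
  # two diagonally touching pixels form one component under 8-connectivity
  m <- matrix(0, 4, 4); m[1, 1] <- 1; m[2, 2] <- 1
  expect_equal(attr(region_components(m), "n_components"), 1L)

  expect_equal(attr(region_components(matrix(0, 5, 5)), "n_components"), 0L)

  m3 <- matrix(0, 9, 9); m3[1, 1] <- 1; m3[5, 5] <- 1; m3[9, 1] <- 1
  expect_equal(attr(region_components(m3), "n_components"), 3L)

  set.seed(8)
  for (i in 1:25) {
    mm <- random_mask(12, 12, 0.3)
    lab <- region_components(mm)
    ora <- oracle_components_2d(mm)
    expect_equal(attr(lab, "n_components"), max(ora))
    # identical partition up to label permutation: the cross-table of labels
    # on positive pixels has exactly one non-zero cell per row and column
    if (max(ora) > 0) {
      tab <- table(lab[lab > 0], ora[ora > 0])
      expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
    }
  }
})

test_that("3D components use 26-connectivity across slices", {
  a <- array(0L, c(3, 4, 4))
  a[1, 1, 1] <- 1L; a[2, 2, 2] <- 1L  # diagonal in 3D: single component
  expect_equal(attr(region_components(a), "n_components"), 1L)
  a[3, 4, 4] <- 1L
  expect_equal(attr(region_components(a), "n_components"), 2L)
})

test_that("region_f1 counts lesions per component with any-overlap matching", {
  # 3 ref lesions, predictions hit 2, plus one spurious prediction
  ref <- matrix(0, 12, 12)
  ref[1:2, 1:2] <- 1; ref[6:7, 6:7] <- 1; ref[11:12, 11:12] <- 1
  pred <- matrix(0, 12, 12)
  pred[1, 1] <- 1; pred[6, 6:7] <- 1; pred[1, 12] <- 1
  r <- region_f1(pred, ref)
  expect_equal(r$tp, 2L); expect_equal(r$fp, 1L); expect_equal(r$fn, 1L)
  expect_equal(r$precision, 2 / 3, tolerance = 1e-12)
  expect_equal(r$recall, 2 / 3, tolerance = 1e-12)
  expect_equal(r$f1, 2 / 3, tolerance = 1e-12)

  perfect <- region_f1(ref, ref)
  expect_equal(perfect$f1, 1)

  # one predicted component spanning two ref lesions: 2 TP, 0 FP
  span <- matrix(0, 12, 12); span[1:7, 1] <- 1
  ref2 <- matrix(0, 12, 12); ref2[1, 1] <- 1; ref2[7, 1] <- 1
  rs <- region_f1(span, ref2)
  expect_equal(rs$tp, 2L); expect_equal(rs$fp, 0L)
  # ... while one-to-one matching awards a single TP and one FP-free pred
  r11 <- region_f1(span, ref2, matching = "one_to_one")
  expect_equal(r11$tp, 1L); expect_equal(r11$fn, 1L); expect_equal(r11$fp, 0L)

  both_empty <- region_f1(matrix(0, 4, 4), matrix(0, 4, 4))
  expect_true(both_empty$empty_pair)
  expect_equal(both_empty$f1, 1)
  none <- region_f1(matrix(0, 12, 12), ref)
  expect_equal(none$f1, 0)
})

test_that("froc sensitivity is non-increasing in the threshold", {
  set.seed(21)
  for (i in 1:10) {
    prob <- matrix(runif(16 * 16), 16, 16)
    ref <- random_mask(16, 16, 0.15)
    fc <- froc_curve(prob, ref, thresholds = seq(0.05, 0.95, by = 0.05))
    expect_true(all(diff(fc$sensitivity) <= 1e-12))
  }
  # degenerate ends: no positives survive t > max(prob)
  prob <- matrix(0.4, 8, 8)
  ref <- matrix(0, 8, 8); ref[3, 3] <- 1
  fc <- froc_curve(prob, ref, thresholds = c(0.1, 0.9))
  expect_equal(fc$sensitivity, c(1, 0))
  expect_equal(fc$fp[2], 0L)
})

test_that("evaluate_cohort aggregates are arithmetic means and round-trip JSON", {
  set.seed(31)
  gt <- list(); pr <- list()
  for (pid in c("A", "B")) {
    gt[[pid]] <- list(); pr[[pid]] <- list()
    for (cls in csvd_classes()) {
      g <- random_mask_3d(3, 12, 12, 0.1)
      p <- random_mask_3d(3, 12, 12, 0.1)
      gt[[pid]][[cls]] <- as_mask(g, cls)
      pr[[pid]][[cls]] <- as_mask(p, cls)
    }
  }
  rep <- evaluate_cohort(pr, gt)
  expect_s3_class(rep$per_patient, "tbl_df")
  expect_equal(nrow(rep$per_patient), 8)

  # conservation: aggregate equals recomputed mean of per-patient values
  for (cls in csvd_classes()) {
    agg <- rep$aggregate$dice[rep$aggregate$class == cls]
    expect_equal(agg, mean(rep$per_patient$dice[rep$per_patient$class == cls]))
  }
  ccm <- rep$aggregate[rep$aggregate$class == "OVERALL" &
                        rep$aggregate$aggregation == "mean_of_class_means", ]
  cls_means <- rep$aggregate$dice[rep$aggregate$class != "OVERALL"]
  expect_equal(ccm$dice, mean(cls_means))
  pool <- rep$aggregate[rep$aggregate$class == "OVERALL" &
                          rep$aggregate$aggregation == "pooled_mean", ]
  expect_equal(pool$dice, mean(rep$per_patient$dice))

  # two patients at dice 0.5 and 0.7 average to 0.6
  gt2 <- list(A = list(WMH = as_mask(rbind(c(1, 1, 1, 1), matrix(0, 3, 4)))),
              B = list(WMH = as_mask(rbind(c(1, 1, 0, 0), matrix(0, 3, 4)))))
  pr2 <- list(A = list(WMH = as_mask(rbind(c(1, 0, 0, 0), matrix(0, 3, 4)))),
              B = list(WMH = as_mask(rbind(c(1, 1, 0, 0), matrix(0, 3, 4)))))
  r2 <- evaluate_cohort(pr2, gt2, classes = "WMH")
  expect_equal(sort(r2$per_patient$dice), c(0.4, 1.0))
  expect_equal(r2$aggregate$dice[r2$aggregate$class == "WMH"], 0.7)

  # JSON round trip preserves every number exactly
  f <- tempfile(fileext = ".json")
  write_report(rep, f)
  back <- read_report(f)
  expect_equal(back$per_patient$dice, rep$per_patient$dice)
  expect_equal(back$aggregate$region_f1, rep$aggregate$region_f1)
  expect_equal(back$per_patient$patient_id, rep$per_patient$patient_id)

  expect_error(evaluate_cohort(pr[1], gt), class = "csvdseg_error_contract")
})
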