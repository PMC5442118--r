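test_that("the normal ROI is the second-from-most-basal slice", {
  for (nsl in c(7L, 6L)) {
    v <- array(0, c(4, 4, nsl))
    for (k in seq_len(nsl)) v[, , k] <- k   # value encodes the slice index
    m <- manual_map(v)
    roi <- select_normal_roi(m, array(TRUE, dim(v)), list(min_pixels = 10))
    expect_identical(roi$slice, nsl - 1L)
    expect_identical(roi$mean, as.numeric(nsl - 1L))
    expect_identical(roi$sd, 0)
    expect_identical(roi$n_pixels, 16L)
  }
  expect_error(select_normal_roi(manual_map(array(1, c(2, 2, 1))),
                                 array(TRUE, c(2, 2, 1))), "2 slices")
  # too few valid pixels flags the animal unanalyzable
  v <- array(1, c(3, 3, 3))
  expect_error(select_normal_roi(manual_map(v), array(TRUE, dim(v)),
                                 list(min_pixels = 30)), "unanalyzable")
})

test_that("SD thresholds apply strict inequalities and nest", {
  v <- array(c(25, 19, 17, 14), c(4, 1, 2))
  v[, , 2] <- 20                       # reference slice: mean 20
  m <- manual_map(v)
  mask <- array(TRUE, dim(v))
  stats <- structure(list(mean = 20, sd = 2, n_pixels = 4, slice = 2L,
                          units = "a.u."), class = "roi_stats")
  t1 <- threshold_map(m, mask, stats, k = 1, direction = "below")  # cut 18
  expect_identical(sum(t1$flagged_mask), 2L)
  expect_equal(t1$area_fraction_pct, 100 * 2 / 8)
  t2 <- threshold_map(m, mask, stats, k = 2, direction = "below")  # cut 16
  expect_identical(sum(t2$flagged_mask), 1L)
  expect_true(all(t1$flagged_mask[t2$flagged_mask]))   # 2SD nested in 1SD
  # a pixel exactly at the cut is never flagged (18 is not < 18)
  v18 <- array(18, c(2, 2, 2))
  t3 <- threshold_map(manual_map(v18), array(TRUE, dim(v18)), stats, 1, "below")
  expect_identical(sum(t3$flagged_mask), 0L)
  # uniform map with sd 0: nothing is strictly beyond the mean
  su <- structure(list(mean = 18, sd = 0, n_pixels = 4, slice = 2L,
                       units = "a.u."), class = "roi_stats")
  expect_identical(
    sum(threshold_map(manual_map(v18), array(TRUE, dim(v18)), su, 1,
                      "above")$flagged_mask), 0L)
})

test_that("cluster filtering removes speckle but keeps contiguous sectors", {
  flg <- array(FALSE, c(20, 20, 1))
  flg[2:11, 2:5, 1] <- TRUE            # 40-px block
  flg[15, 15, 1] <- TRUE               # isolated pixel
  flg[18:19, 18, 1] <- TRUE            # 2-px cluster
  out <- filter_small_clusters(flg, 10)
  expect_identical(sum(out), 40L)
  expect_true(all(out[2:11, 2:5, 1]))
  expect_identical(filter_small_clusters(flg, 0), flg)
})

test_that("planimetry counts labels exactly", {
  lab <- array(0L, c(10, 10, 1))
  lab[1:50] <- 2L                      # 50 myocardial pixels
  lab[1:20] <- 3L                      # 20 of them AAR
  lab[1:10] <- 4L                      # 10 of those infarct
  rl <- aarcmr:::new_region_labels(lab)
  p <- planimetry(rl)
  expect_identical(p$is_lv_pct, 20)
  expect_identical(p$aar_lv_pct, 40)
  expect_identical(p$is_aar_pct, 50)
  # AAR = whole myocardium
  lab2 <- array(0L, c(4, 4, 1)); lab2[1:8] <- 3L
  expect_identical(planimetry(aarcmr:::new_region_labels(lab2))$aar_lv_pct, 100)
  expect_error(planimetry(aarcmr:::new_region_labels(array(0L, c(4, 4, 1)))),
               "no myocardium")
})

test_that("noiseless phantoms recover regional metrics across modalities", {
  cfg <- small_config(aar_fraction = 0.5, is_fraction_of_aar = 0.5)
  an <- simulate_animal("a1", "control", cfg, noise_sd = 0)
  maps <- fit_animal(an)
  q <- quantify_animal(an, maps)
  truth <- an$truth
  for (col in c("t2_aar_lv_pct", "asl_aar_lv_pct", "t1_aar_lv_pct")) {
    expect_lt(abs(q[[col]] - truth$aar_lv_pct), 3)
  }
  expect_lt(abs(q$lge_is_lv_pct - truth$is_lv_pct), 3)
  expect_identical(q$hist_aar_lv_pct, truth$aar_lv_pct)
  expect_identical(q$hist_is_lv_pct, truth$is_lv_pct)
  # zero-edema/zero-AAR phantom: every metric is (near) zero
  an0 <- simulate_animal("a0", "control", small_config(aar_fraction = 0),
                         noise_sd = 0)
  q0 <- quantify_animal(an0, fit_animal(an0))
  expect_identical(q0$t2_aar_lv_pct, 0)
  expect_identical(q0$asl_aar_lv_pct, 0)
  expect_identical(q0$lge_is_lv_pct, 0)
})

test_that("reduced edema extent biases T2/T1 but not ASL", {
  cfg <- small_config(aar_fraction = 0.55, is_fraction_of_aar = 0.3,
                      edema_extent_multiplier = 0.85)
  an <- simulate_animal("ipc1", "IPC", cfg, noise_sd = 0)
  q <- quantify_animal(an, fit_animal(an))
  truth <- an$truth$aar_lv_pct
  expect_lt(q$t2_aar_lv_pct - truth, -3)    # underestimation
  expect_lt(q$t1_aar_lv_pct - truth, -3)
  expect_lt(abs(q$t2_aar_lv_pct - 0.85 * truth), 3)
  expect_lt(abs(q$asl_aar_lv_pct - truth), 3)
})

test_that("ASL infarct mask nests inside the ASL AAR mask", {
  cfg <- small_config(aar_fraction = 0.5, is_fraction_of_aar = 0.5, seed = 9)
  an <- simulate_animal("a2", "control", cfg)
  maps <- fit_animal(an)
  asl <- aar_is_from_asl(maps$perfusion, region_mask(an$labels, "myocardium"))
  expect_true(all(asl$flagged_aar[asl$flagged_is]))
  expect_lte(asl$is_lv_pct, asl$aar_lv_pct)
})

test_that("LGE delineation recovers infarct and is monotone in its threshold", {
  cfg <- small_config(aar_fraction = 0.5, is_fraction_of_aar = 0.5)
  an <- simulate_animal("a3", "control", cfg, noise_sd = 0)
  myo <- region_mask(an$labels, "myocardium")
  d <- delineate_lge(an$stacks$lge, myo)
  expect_lt(abs(d$is_lv_pct - an$truth$is_lv_pct), 3)
  # identity enhancement: nothing delineated
  p1 <- tissue_params(infarct = list(T1_s = 2.1, T2_ms = 38, S0 = 100, mbf = 2,
                                     lge_enhancement = 1))
  an1 <- simulate_animal("a4", "control", cfg, params = p1, noise_sd = 0)
  expect_identical(delineate_lge(an1$stacks$lge, myo)$is_lv_pct, 0)
  # monotone in k_lge
  an2 <- simulate_animal("a5", "control", small_config(
    aar_fraction = 0.5, is_fraction_of_aar = 0.5, seed = 10))
  areas <- vapply(c(2, 5, 8), function(k)
    delineate_lge(an2$stacks$lge, myo, k_lge = k)$is_lv_pct, numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("metrics tables assemble cleanly and round-trip through CSV", {
  cfg <- small_config()
  an <- simulate_animal("m1", "control", cfg, noise_sd = 0)
  row1 <- quantify_animal(an, fit_animal(an))
  row2 <- row1; row2$id <- "m2"
  tab <- assemble_metrics(list(row1, row2))
  expect_identical(nrow(tab), 2L)
  expect_error(assemble_metrics(list(row1, row1)), "duplicate")
  expect_identical(nrow(assemble_metrics(list())), 0L)
  f <- tempfile(fileext = ".csv")
  write.csv(tab, f, row.names = FALSE)
  back <- read.csv(f, stringsAsFactors = FALSE)
  expect_equal(back$t2_aar_lv_pct, tab$t2_aar_lv_pct, tolerance = 1e-12)
  expect_identical(back$id, tab$id)
})
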