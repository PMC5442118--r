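test_that("geometry matches an exhaustive lattice-scan oracle", {
  cfg <- phantom_config(matrix_size = 128, n_slices = 3, r_outer = 20,
                        r_inner = 10, aar_slice_span = 1)
  geo <- make_geometry(cfg)
  expect_identical(dim(geo$labels), c(128L, 128L, 3L))
  oracle <- annulus_count_oracle(128, 64.5, 64.5, 10, 20)
  expect_identical(sum(geo$labels[, , 1] == 2L), oracle)
  # blood disk: r < r_inner
  expect_identical(sum(geo$labels[, , 1] == 1L),
                   annulus_count_oracle(128, 64.5, 64.5, 0, 10))
  # degenerate annulus: r_inner = 0 gives a full disk of myocardium
  cfg0 <- phantom_config(matrix_size = 48, n_slices = 3, r_outer = 10,
                         r_inner = 0, aar_slice_span = 1)
  geo0 <- make_geometry(cfg0)
  expect_identical(sum(geo0$labels[, , 1] != 0L),
                   annulus_count_oracle(48, 24.5, 24.5, 0, 10))
  expect_identical(sum(geo0$labels[, , 1] == 1L), 0L)
})

test_that("geometry configuration errors are caught", {
  expect_error(phantom_config(r_inner = 10, r_outer = 9), "r_inner")
  expect_error(phantom_config(matrix_size = 24, r_outer = 13), "r_outer")
  expect_error(phantom_config(n_slices = 5, aar_slice_span = 4:5),
               "basal")
})

test_that("region assignment hits the requested fractions within quantization", {
  for (f in c(0.3, 0.5, 0.643)) {
    cfg <- small_config(aar_fraction = f, is_fraction_of_aar = 0.506)
    lab <- make_phantom_labels(cfg)
    n_myo <- sum(region_mask(lab, "myocardium"))
    tol_pct <- 100 * 2 / sqrt(n_myo)
    expect_lt(abs(lab$achieved$aar_lv_pct - 100 * f), tol_pct)
    expect_lt(abs(lab$achieved$is_aar_pct - 50.6), tol_pct)
  }
  # zero AAR: empty sector
  lab0 <- make_phantom_labels(small_config(aar_fraction = 0))
  expect_identical(sum(region_mask(lab0, "aar")), 0L)
  expect_identical(lab0$achieved$aar_lv_pct, 0)
  # full-LV request is impossible with a remote reference slice
  geo <- make_geometry(small_config())
  expect_error(assign_regions(geo, small_config(), aar_fraction = 1),
               "normal reference")
})

test_that("labels partition the volume and regions nest", {
  lab <- make_phantom_labels(small_config(aar_fraction = 0.55,
                                          is_fraction_of_aar = 0.4,
                                          edema_extent_multiplier = 0.85))
  expect_true(all(lab$labels %in% 0:4))
  inf <- region_mask(lab, "infarct")
  aar <- region_mask(lab, "aar")
  myo <- region_mask(lab, "myocardium")
  ede <- region_mask(lab, "edema")
  expect_true(all(aar[inf]))        # infarct inside AAR
  expect_true(all(myo[aar]))        # AAR inside myocardium
  expect_true(all(ede[inf]))        # infarct is always edematous
  expect_true(all(aar[ede]))        # edema confined to the AAR
  # AAR confined to the allowed slices
  basal <- dim(lab$labels)[3] - c(0L, 1L)
  expect_identical(sum(aar[, , basal]), 0L)
})

test_that("edema mask extent tracks the multiplier", {
  lab <- make_phantom_labels(small_config(aar_fraction = 0.5,
                                          edema_extent_multiplier = 0.85))
  n_aar <- sum(region_mask(lab, "aar"))
  ratio <- sum(region_mask(lab, "edema")) / n_aar
  expect_lt(abs(ratio - 0.85), 2 / sqrt(n_aar))
})

test_that("T2 series follows the mono-exponential signal model", {
  lab <- make_phantom_labels(small_config())
  # direct formula point: S0 = 100, T2 = 25 ms at TE = 25 ms
  st <- simulate_t2_series(lab, meta = acq_multi_echo_se(c(1e-9, 25)),
                           noise_sd = 0)
  rem <- which(region_mask(lab, "remote"))[1]
  flat <- matrix(st$data, ncol = 2)
  expect_equal(flat[rem, 1], 100, tolerance = 1e-6)       # TE -> 0 limit
  expect_equal(flat[rem, 2], 100 * exp(-1), tolerance = 1e-9)
  # seeded noisy series matches an independent one-line generator bit-for-bit
  meta <- acq_multi_echo_se()
  expect_identical(meta$te_list_ms, c(3.5, 7, 10, 12, 15, 17, 20, 25, 30))
  st2 <- simulate_t2_series(lab, meta = meta, noise_sd = 2, seed = 1L)
  t2v <- array(25, dim(lab$labels))
  t2v[lab$labels == 1L] <- 30; t2v[lab$labels == 3L] <- 35
  t2v[lab$labels == 4L] <- 38
  s0v <- array(100, dim(lab$labels)); s0v[lab$labels == 0L] <- 0
  ref <- array(0, c(dim(lab$labels), 9))
  for (j in 1:9) ref[, , , j] <- s0v * exp(-meta$te_list_ms[j] / t2v)
  set.seed(1L)
  ref <- ref + rnorm(length(ref), sd = 2)
  expect_identical(st2$data, ref)
})

test_that("IR series: zero perfusion makes selective and global identical", {
  p <- tissue_params(
    remote = list(T1_s = 1.7, T2_ms = 25, S0 = 100, mbf = 1e-9, lge_enhancement = 1),
    aar_salvaged = list(T1_s = 2.0, T2_ms = 35, S0 = 100, mbf = 0, lge_enhancement = 1),
    infarct = list(T1_s = 2.1, T2_ms = 38, S0 = 100, mbf = 0, lge_enhancement = 3),
    blood = list(T1_s = 2.4, T2_ms = 30, S0 = 100, mbf = 0, lge_enhancement = 1))
  lab <- make_phantom_labels(small_config())
  sel <- simulate_ir_series(lab, p, acq_look_locker("selective"), noise_sd = 0)
  glo <- simulate_ir_series(lab, p, acq_look_locker("global"), noise_sd = 0)
  expect_equal(sel$data, glo$data, tolerance = 1e-7)
})

test_that("IR signal parameters match scalar arithmetic and limits", {
  # T1* for T1_eff = 1.5 s, flip 5 deg, tr_rf 3 ms
  ll <- aarcmr:::.ll_signal_params(1.5, 100, 5, 3)
  expect_equal(ll$t1_star, 1 / (1 / 1.5 + abs(log(cos(5 * pi / 180))) / 0.003),
               tolerance = 1e-12)
  expect_equal(ll$b, ll$a + 100, tolerance = 1e-12)
  # t -> Inf limit: signal tends to the steady state A
  lab <- make_phantom_labels(small_config(aar_fraction = 0))
  meta <- acq_look_locker("global", ti_list_s = c(0.1, 500))
  st <- simulate_ir_series(lab, meta = meta, noise_sd = 0)
  rem <- which(region_mask(lab, "remote"))[1]
  lim <- aarcmr:::.ll_signal_params(1.7, 100, 5, 3)
  expect_equal(matrix(st$data, ncol = 2)[rem, 2], lim$a, tolerance = 1e-6)
  expect_error(acq_look_locker("global", flip_angle_deg = 95), "flip")
})

test_that("LGE image enhances only the infarct", {
  lab <- make_phantom_labels(small_config())
  st <- simulate_lge_image(lab, noise_sd = 0)
  img <- st$data[, , , 1]
  expect_true(all(img[region_mask(lab, "infarct")] == 300))
  expect_true(all(img[region_mask(lab, "remote")] == 100))
  expect_true(all(img[region_mask(lab, "aar_salvaged")] == 100))
  # identity enhancement: infarct indistinguishable from remote
  p <- tissue_params(infarct = list(T1_s = 2.1, T2_ms = 38, S0 = 100, mbf = 2,
                                    lge_enhancement = 1))
  st1 <- simulate_lge_image(lab, p, noise_sd = 0)
  expect_true(all(st1$data[, , , 1][region_mask(lab, "myocardium")] == 100))
})

test_that("simulated histology reproduces and conserves ground truth", {
  lab <- make_phantom_labels(small_config(n_slices = 7))
  h <- simulate_histology(lab)
  expect_identical(dim(h$labels)[3], 7L)
  expect_identical(planimetry(h)$aar_lv_pct, lab$achieved$aar_lv_pct)
  # re-slicing to a different count conserves per-class fractions within 2%
  h6 <- simulate_histology(lab, n_slices_out = 6)
  p7 <- planimetry(lab); p6 <- planimetry(h6)
  expect_lt(abs(p6$aar_lv_pct - p7$aar_lv_pct) / p7$aar_lv_pct, 0.02)
  expect_lt(abs(p6$is_lv_pct - p7$is_lv_pct) / p7$is_lv_pct, 0.02)
})

test_that("cohort sampling matches a direct-resampling oracle", {
  g <- list(control = group_spec("control", 64.3, 6.1, 50.6, 6.9, n_animals = 100))
  base <- phantom_config(matrix_size = 48, n_slices = 7, r_outer = 9, r_inner = 4)
  cohort <- generate_cohort(g, base, noise_sd = 0, seed = 11)
  expect_identical(nrow(cohort$manifest), 100L)
  # oracle: resample the same truncated distributions directly
  geo <- make_geometry(base)
  cap <- sum(geo$labels[, , 1:5] == 2L) / sum(geo$labels == 2L)
  set.seed(99)
  draw <- function(mu, sd, lo, hi) {
    x <- rnorm(4e4, mu, sd); mean(x[x > lo & x < hi])
  }
  mu_aar <- draw(64.3, 6.1, 5, 100 * min(0.95, cap))
  mu_is <- draw(50.6, 6.9, 5, 95)
  expect_lt(abs(mean(cohort$manifest$truth_aar_lv_pct) - mu_aar),
            2 * 6.1 / sqrt(100))
  expect_lt(abs(mean(cohort$manifest$truth_is_aar_pct) - mu_is),
            2 * 6.9 / sqrt(100))
})

test_that("cohorts are deterministic and respect group sizes", {
  g <- list(control = group_spec("control", 64.3, 6.1, 50.6, 6.9, n_animals = 2))
  base <- small_config()
  c1 <- generate_cohort(g, base, seed = 7)
  c2 <- generate_cohort(g, base, seed = 7)
  expect_identical(c1$animals[[1]]$stacks$t2$data, c2$animals[[1]]$stacks$t2$data)
  expect_identical(c1$animals[[2]]$stacks$ir_global$data,
                   c2$animals[[2]]$stacks$ir_global$data)
  expect_identical(c1$manifest, c2$manifest)
  # empty cohort
  g0 <- list(control = group_spec("control", 64.3, 6.1, 50.6, 6.9, n_animals = 0))
  expect_identical(length(generate_cohort(g0, base, seed = 1)$animals), 0L)
})
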