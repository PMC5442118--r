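test_that("exact mono-exponential signals are recovered to printed precision", {
  te <- c(10, 20, 30)
  sig <- 100 * exp(-te / 10)
  f <- fit_t2_pixel(sig, te)
  expect_true(f$valid)
  expect_equal(f$T2_ms, 10, tolerance = 1e-4)
  expect_equal(f$S0, 100, tolerance = 1e-4)
  # noiseless series over the nine-echo protocol, true T2 = 25 ms
  te9 <- acq_multi_echo_se()$te_list_ms
  f9 <- fit_t2_pixel(80 * exp(-te9 / 25), te9)
  expect_lt(abs(f9$T2_ms - 25) / 25, 0.001)
  expect_error(fit_t2_pixel(c(1, 2), c(10, 20)), "3 echoes")
  expect_false(fit_t2_pixel(rep(0, 5), c(1, 2, 3, 4, 5))$valid)
})

test_that("noisy T2 fits agree with the dense grid-search oracle", {
  te <- acq_multi_echo_se()$te_list_ms
  set.seed(42)
  for (i in 1:25) {
    t2_true <- runif(1, 15, 45)
    s0_true <- runif(1, 60, 140)
    sig <- s0_true * exp(-te / t2_true) + rnorm(length(te), sd = s0_true / 20)
    f <- fit_t2_pixel(sig, te)
    o <- t2_grid_oracle(sig, te)
    expect_lt(abs(f$T2_ms - o$T2_ms) / o$T2_ms, 0.005)
    expect_lt(abs(f$S0 - o$S0) / o$S0, 0.005)
  }
})

test_that("T2 maps: uniform stacks give constant maps, edema is elevated", {
  lab <- make_phantom_labels(small_config(aar_fraction = 0))
  st <- simulate_t2_series(lab, noise_sd = 0)
  myo <- region_mask(lab, "myocardium")
  m <- fit_t2_map(st, myo)
  expect_equal(m$n_invalid + m$n_valid, sum(myo))
  expect_lt(diff(range(m$values[m$valid])), 1e-4)
  # control phantom: AAR median exceeds remote median
  lab2 <- make_phantom_labels(small_config(aar_fraction = 0.5))
  st2 <- simulate_t2_series(lab2, seed = 5)
  m2 <- fit_t2_map(st2, region_mask(lab2, "myocardium"))
  med <- function(msk) median(m2$values[msk & m2$valid])
  expect_gt(med(region_mask(lab2, "aar")), med(region_mask(lab2, "remote")))
  expect_warning(fit_t2_map(st, array(FALSE, dim(myo))), "empty")
})

test_that("median T2 error is non-decreasing in noise level", {
  lab <- make_phantom_labels(small_config(aar_fraction = 0, n_slices = 3))
  myo <- region_mask(lab, "myocardium")
  errs <- vapply(c(0, 2, 5, 10), function(sd) {
    st <- simulate_t2_series(lab, noise_sd = sd, seed = 31)
    m <- fit_t2_map(st, myo)
    median(abs(m$values[m$valid] - 25))
  }, numeric(1))
  expect_true(all(diff(errs) >= 0))
})

test_that("polarity restoration recovers the signed recovery curve", {
  ti <- acq_look_locker("global")$ti_list_s
  s_true <- 1 - 2 * exp(-ti / 1.2)
  r <- restore_polarity(abs(s_true), ti)
  expect_equal(r$signal, s_true, tolerance = 1e-9)
  # all-positive late-sampled recovery is returned unchanged
  pos <- 1 - 0.5 * exp(-ti / 0.3)
  expect_equal(restore_polarity(pos, ti)$signal, pos)
})

test_that("Look-Locker pixel fits are exact on noiseless data", {
  ti <- acq_look_locker("global")$ti_list_s
  f <- fit_ll_pixel(1 - 2 * exp(-ti / 1.2), ti)
  expect_true(f$valid)
  expect_lt(abs(f$A - 1), 5e-7)
  expect_lt(abs(f$B - 2), 1e-6)
  expect_lt(abs(f$T1star_s - 1.2) / 1.2, 5e-7)
  # degenerate flat series (B = 0) is invalid, not an error
  expect_false(fit_ll_pixel(rep(1, 50), ti)$valid)
  expect_error(fit_ll_pixel(c(1, 2, 3), c(1, 2, 3)), "5 recovery samples")
})

test_that("noisy Look-Locker fits agree with the dense grid-search oracle", {
  ti <- acq_look_locker("global")$ti_list_s
  expect_identical(length(ti), 50L)
  set.seed(17)
  for (i in 1:15) {
    a <- runif(1, 20, 60); b <- a + runif(1, 60, 120); tau <- runif(1, 0.3, 1.2)
    sig <- a - b * exp(-ti / tau) + rnorm(50, sd = 5)
    f <- fit_ll_pixel(sig, ti)
    o <- ll_grid_oracle(sig, ti)
    expect_lt(abs(f$A - o$A) / o$A, 0.01)
    expect_lt(abs(f$B - o$B) / o$B, 0.01)
    expect_lt(abs(f$T1star_s - o$T1star_s) / o$T1star_s, 0.01)
  }
})

test_that("Look-Locker correction follows T1 = T1* (B/A - 1)", {
  expect_equal(correct_t1(1, 2, 1.5), 1.5)          # B = 2A: fully relaxed
  expect_equal(correct_t1(1, 1.8, 1.0), 0.8)
  expect_true(is.na(correct_t1(1, 0.9, 1.0)))       # B <= A is unphysical
  expect_true(is.na(correct_t1(-1, 2, 1.0)))
})

test_that("T1 maps close the loop with the simulator", {
  lab <- make_phantom_labels(small_config(aar_fraction = 0.5))
  myo <- region_mask(lab, "myocardium")
  glo <- simulate_ir_series(lab, meta = acq_look_locker("global"), noise_sd = 0)
  sel <- simulate_ir_series(lab, meta = acq_look_locker("selective"), noise_sd = 0)
  mg <- fit_t1_map(glo, myo)
  ms <- fit_t1_map(sel, myo)
  truth <- array(1.7, dim(myo))
  truth[lab$labels == 3L] <- 2.0; truth[lab$labels == 4L] <- 2.1
  expect_lt(max(abs(mg$values[myo] - truth[myo]) / truth[myo]), 0.001)
  # selective map is pixel-wise below the global map wherever mbf > 0
  expect_true(all(ms$values[myo] < mg$values[myo]))
  # AAR T1 elevated over remote on the global map
  expect_gt(median(mg$values[region_mask(lab, "aar")]),
            median(mg$values[region_mask(lab, "remote")]))
})

test_that("magnitude IR data are fitted after automatic polarity restoration", {
  lab <- make_phantom_labels(small_config(aar_fraction = 0, n_slices = 3))
  myo <- region_mask(lab, "myocardium")
  mag <- simulate_ir_series(lab, meta = acq_look_locker("global", magnitude = TRUE),
                            noise_sd = 0)
  expect_true(all(mag$data >= 0))
  m <- fit_t1_map(mag, myo)
  expect_lt(max(abs(m$values[m$valid] - 1.7) / 1.7), 0.001)
})
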