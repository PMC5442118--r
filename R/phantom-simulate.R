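#' Multi-slice, multi-timepoint image stack
#'
#' Internal constructor for simulated acquisitions: a 4-D array
#' (x, y, slice, timepoint) plus the acquisition metadata needed to fit it.
#'
#' @keywords internal
new_slice_stack <- function(data, meta, noise = list()) {
  stopifnot(length(dim(data)) == 4L, inherits(meta, "acq_meta"))
  structure(list(data = data, meta = meta, noise = noise),
            class = "slice_stack")
}

#' @export
print.slice_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<slice_stack> %s: %dx%d, %d slices, %d timepoints\n",
              x$meta$modality, d[1], d[2], d[3], d[4]))
  if (!is.null(x$meta$inversion_scope)) {
    cat("  inversion scope:", x$meta$inversion_scope, "\n")
  }
  if (length(x$noise)) {
    cat(sprintf("  noise: %s, sd = %.3g, seed = %s\n", x$noise$model,
                x$noise$sd, format(x$noise$seed)))
  }
  invisible(x)
}

# Additive Gaussian noise by default; "rician" takes the magnitude of the
# complex-valued signal with independent Gaussian noise on both channels,
# the physically correct model for magnitude MR data.
.add_noise <- function(signal, noise_sd, seed, model = c("gaussian", "rician")) {
  model <- match.arg(model)
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (noise_sd == 0) return(signal)
  if (!is.null(seed)) set.seed(seed)
  if (model == "gaussian") {
    signal + stats::rnorm(length(signal), sd = noise_sd)
  } else {
    re <- signal + stats::rnorm(length(signal), sd = noise_sd)
    im <- stats::rnorm(length(signal), sd = noise_sd)
    sqrt(re^2 + im^2)
  }
}

# Per-pixel tissue parameter volume. Edema rule: salvaged AAR pixels outside
# the edema mask carry remote T2/T1 (their water content is normal), while
# perfusion deficit spans the whole AAR regardless of edema.
.param_volume <- function(labels, params, field) {
  lab <- labels$labels
  v <- array(params$remote[[field]], dim(lab))
  v[lab == REGION_CODES[["blood"]]] <- params$blood[[field]]
  sal <- lab == REGION_CODES[["aar_salvaged"]]
  inf <- lab == REGION_CODES[["infarct"]]
  if (field %in% c("T2_ms", "T1_s")) {
    v[sal & labels$edema] <- params$aar_salvaged[[field]]
    v[inf] <- params$infarct[[field]]
  } else {
    v[sal] <- params$aar_salvaged[[field]]
    v[inf] <- params$infarct[[field]]
  }
  v[lab == REGION_CODES[["background"]]] <-
    if (field == "S0") 0 else params$remote[[field]]
  v
}

#' Simulate a multi-echo spin-echo T2 series
#'
#' Noiseless pixel signal follows mono-exponential transverse decay
#' `S(TE) = S0 * exp(-TE / T2)` with region T2/S0 values (edematous AAR values
#' only inside the edema mask); seeded noise is then added.
#'
#' @param labels A fully labelled `region_labels` phantom.
#' @param params [tissue_params()].
#' @param meta [acq_multi_echo_se()] metadata.
#' @param noise_sd Noise standard deviation in signal units; the default gives
#'   SNR 20 at the remote equilibrium signal.
#' @param seed RNG seed; defaults to the labels' phantom seed when `NULL`.
#' @param noise_model `"gaussian"` (additive) or `"rician"` (magnitude).
#' @return A `slice_stack`.
#' @export
simulate_t2_series <- function(labels, params = tissue_params(),
                               meta = acq_multi_echo_se(),
                               noise_sd = params$remote$S0 / 20, seed = 1L,
                               noise_model = "gaussian") {
  stopifnot(inherits(labels, "region_labels"), inherits(params, "tissue_params"))
  if (meta$modality != "multi_echo_se") stop("meta must describe a multi-echo SE series")
  t2 <- .param_volume(labels, params, "T2_ms")
  s0 <- .param_volume(labels, params, "S0")
  te <- meta$te_list_ms
  d <- c(dim(labels$labels), length(te))
  sig <- array(0, d)
  for (j in seq_along(te)) sig[, , , j] <- s0 * exp(-te[j] / t2)
  sig <- .add_noise(sig, noise_sd, seed, noise_model)
  new_slice_stack(sig, meta,
                  list(model = noise_model, sd = noise_sd, seed = seed))
}

# Look-Locker steady-state parameters for a given true (effective) T1.
# Continuous small-flip readout shortens the apparent relaxation time:
#   1/T1* = 1/T1_eff + |ln cos(alpha)| / tr_rf
# and drives recovery towards the reduced steady state A = S0 * T1* / T1_eff,
# giving s(t) = A - B exp(-t/T1*) with B = A + S0 after full inversion.
.ll_signal_params <- function(t1_eff, s0, flip_angle_deg, tr_rf_ms) {
  r1_star <- 1 / t1_eff + abs(log(cos(flip_angle_deg * pi / 180))) / (tr_rf_ms / 1000)
  t1_star <- 1 / r1_star
  a <- s0 * t1_star / t1_eff
  list(t1_star = t1_star, a = a, b = a + s0)
}

#' Simulate a Look-Locker inversion-recovery series
#'
#' Under global inversion each pixel recovers with its tissue T1. Under
#' slice-selective inversion, inflowing uninverted blood accelerates apparent
#' recovery; the effective T1 is constructed by inverting the blood-pool-input
#' perfusion equation, `T1_eff = T1 / (1 + mbf * T1_blood / (60 * lambda))`,
#' so that quantification closes the loop exactly on noiseless data.
#'
#' @inheritParams simulate_t2_series
#' @param meta [acq_look_locker()] metadata (sets the inversion scope and
#'   whether magnitude data are produced).
#' @param constants [asl_constants()].
#' @return A `slice_stack`.
#' @export
simulate_ir_series <- function(labels, params = tissue_params(),
                               meta = acq_look_locker("global"),
                               constants = asl_constants(),
                               noise_sd = params$remote$S0 / 20, seed = 1L,
                               noise_model = "gaussian") {
  stopifnot(inherits(labels, "region_labels"), inherits(constants, "asl_constants"))
  if (meta$modality != "look_locker_ir") stop("meta must describe a Look-Locker IR series")
  t1 <- .param_volume(labels, params, "T1_s")
  s0 <- .param_volume(labels, params, "S0")
  t1_eff <- t1
  if (meta$inversion_scope == "selective") {
    mbf <- .param_volume(labels, params, "mbf")
    t1_eff <- t1 / (1 + mbf * constants$t1_blood_s /
                      (60 * constants$lambda_ml_per_g))
  }
  ll <- .ll_signal_params(t1_eff, s0, meta$flip_angle_deg, meta$tr_rf_ms)
  ti <- meta$ti_list_s
  d <- c(dim(labels$labels), length(ti))
  sig <- array(0, d)
  for (j in seq_along(ti)) {
    sig[, , , j] <- ll$a - ll$b * exp(-ti[j] / ll$t1_star)
  }
  if (meta$magnitude && noise_sd == 0) sig <- abs(sig)
  model <- if (meta$magnitude && noise_sd > 0) "rician" else noise_model
  sig <- .add_noise(sig, noise_sd, seed, model)
  new_slice_stack(sig, meta, list(model = model, sd = noise_sd, seed = seed))
}

#' Simulate a late gadolinium enhancement image
#'
#' Single-timepoint stack in which infarcted pixels carry the remote signal
#' multiplied by their enhancement factor; all other myocardium (and blood)
#' stays at the remote/base signal.
#'
#' @inheritParams simulate_t2_series
#' @return A `slice_stack` with one timepoint.
#' @export
simulate_lge_image <- function(labels, params = tissue_params(),
                               noise_sd = params$remote$S0 / 20, seed = 1L,
                               noise_model = "gaussian") {
  stopifnot(inherits(labels, "region_labels"))
  s0 <- params$remote$S0
  enh <- .param_volume(labels, params, "lge_enhancement")
  sig <- s0 * enh
  sig[labels$labels == REGION_CODES[["background"]]] <- 0
  sig <- array(sig, c(dim(labels$labels), 1L))
  sig <- .add_noise(sig, noise_sd, seed, noise_model)
  new_slice_stack(sig, acq_lge(),
                  list(model = noise_model, sd = noise_sd, seed = seed))
}

#' Simulate histology label slices
#'
#' Returns the ground-truth label volume playing the role of the stained and
#' photographed ex-vivo slices; planimetry on the output defines "histology
#' truth". Optionally re-slices to a different slice count: output per-class
#' pixel counts are thickness-weighted combinations of the input slices and
#' regions are re-drawn as angular sectors, which conserves whole-heart
#' per-class fractions up to rounding.
#'
#' @param labels A fully labelled `region_labels` phantom.
#' @param n_slices_out Output slice count; `NULL` keeps the input slicing.
#' @param sector_axis_rad Sector axis used when re-drawing regions.
#' @return A `region_labels` volume.
#' @export
simulate_histology <- function(labels, n_slices_out = NULL, sector_axis_rad = 0) {
  stopifnot(inherits(labels, "region_labels"))
  n_in <- dim(labels$labels)[3]
  if (is.null(n_slices_out) || n_slices_out == n_in) {
    return(new_region_labels(labels$labels, labels$edema, labels$lv_center,
                             labels$achieved))
  }
  n_out <- as.integer(n_slices_out)
  if (n_out < 1) stop("n_slices_out must be positive")
  m <- dim(labels$labels)[1]
  lab_in <- labels$labels
  # thickness overlap of input slice i with output slice j (unit total depth)
  w <- matrix(0, n_in, n_out)
  for (i in seq_len(n_in)) {
    for (j in seq_len(n_out)) {
      lo <- max((i - 1) / n_in, (j - 1) / n_out)
      hi <- min(i / n_in, j / n_out)
      w[i, j] <- max(0, hi - lo) * n_in   # fraction of input slice i in j
    }
  }
  aar_in <- vapply(seq_len(n_in), function(i)
    sum(lab_in[, , i] >= REGION_CODES[["aar_salvaged"]]), numeric(1))
  is_in <- vapply(seq_len(n_in), function(i)
    sum(lab_in[, , i] == REGION_CODES[["infarct"]]), numeric(1))
  # nearest input slice provides the annulus geometry of each output slice
  nearest <- pmin(n_in, pmax(1L, ceiling(((seq_len(n_out)) - 0.5) * n_in / n_out)))
  out <- array(REGION_CODES[["background"]], c(m, m, n_out))
  for (j in seq_len(n_out)) {
    base <- lab_in[, , nearest[j]]
    base[base >= REGION_CODES[["aar_salvaged"]]] <- REGION_CODES[["remote"]]
    out[, , j] <- base
    scale <- n_out / n_in   # output slice is thicker/thinner than inputs
    a_j <- round(sum(w[, j] * aar_in) * scale)
    i_j <- round(sum(w[, j] * is_in) * scale)
    if (a_j > 0) {
      tmp <- new_region_labels(array(base, c(m, m, 1)),
                               lv_center = labels$lv_center)
      ord <- .sector_order(tmp$labels, labels$lv_center, 1L, sector_axis_rad)
      a_j <- min(a_j, nrow(ord))
      take <- ord[seq_len(a_j), ]
      sl <- out[, , j]
      sl[cbind(take$x, take$y)] <- REGION_CODES[["aar_salvaged"]]
      if (i_j > 0) {
        ii <- take[seq_len(min(i_j, a_j)), ]
        sl[cbind(ii$x, ii$y)] <- REGION_CODES[["infarct"]]
      }
      out[, , j] <- sl
    }
  }
  new_region_labels(out, lv_center = labels$lv_center,
                    achieved = labels$achieved["n_myocardium" != names(labels$achieved)])
}
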