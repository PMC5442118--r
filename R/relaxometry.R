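#' Fit options for pixel-wise relaxometry
#'
#' @param t2_bounds_ms Search bounds for T2 (ms).
#' @param t1star_bounds_s Search bounds for the apparent Look-Locker T1* (s).
#' @param amp_max_factor Amplitudes (S0, A, B) above
#'   `amp_max_factor * max(signal)` flag the pixel invalid.
#' @param polarity_restoration `TRUE`/`FALSE`, or `NULL` to enable it
#'   automatically for magnitude IR data.
#' @param min_r2 Minimum coefficient of determination for a fit to count as
#'   valid. The default (0.5) rejects flat/garbage series while retaining
#'   slow-decay tissue: r-squared of a correctly specified exponential fit
#'   scales with the decay dynamic range over the sampling window, so a
#'   tight cut systematically rejects long-T2 (edematous) pixels whose decay
#'   is only partially sampled.
#' @param tol Absolute tolerance of the 1-D profile search.
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(t2_bounds_ms = c(1, 300), t1star_bounds_s = c(0.05, 5),
                        amp_max_factor = 10, polarity_restoration = NULL,
                        min_r2 = 0.5, tol = 1e-9) {
  if (t2_bounds_ms[1] >= t2_bounds_ms[2] || t1star_bounds_s[1] >= t1star_bounds_s[2]) {
    stop("bounds must satisfy lower < upper")
  }
  if (t2_bounds_ms[1] <= 0 || t1star_bounds_s[1] <= 0) stop("bounds must be positive")
  structure(list(t2_bounds_ms = t2_bounds_ms, t1star_bounds_s = t1star_bounds_s,
                 amp_max_factor = amp_max_factor,
                 polarity_restoration = polarity_restoration,
                 min_r2 = min_r2, tol = tol),
            class = "fit_options")
}

# Profile residual sum of squares of S0*exp(-te/T2) with S0 solved linearly.
.t2_profile <- function(signal, te, t2) {
  e <- exp(-te / t2)
  s0 <- sum(signal * e) / sum(e * e)
  list(s0 = s0, rss = sum((signal - s0 * e)^2))
}

#' Fit a mono-exponential T2 decay to one pixel
#'
#' Bounded least squares via variable projection: the amplitude is solved
#' linearly for each candidate T2 and the profiled residual is minimised over
#' the T2 bounds.
#'
#' @param signal Signal intensities at the echo times.
#' @param te_list_ms Echo times (ms), length >= 3.
#' @param options [fit_options()].
#' @return List with `S0`, `T2_ms`, `valid`, and `diagnostics` (rss, r2).
#' @export
fit_t2_pixel <- function(signal, te_list_ms, options = fit_options()) {
  if (length(te_list_ms) < 3) stop("at least 3 echoes are required")
  if (length(signal) != length(te_list_ms)) stop("signal/TE length mismatch")
  invalid <- function(msg) list(
    S0 = NA_real_, T2_ms = NA_real_, valid = FALSE,
    diagnostics = list(rss = NA_real_, r2 = NA_real_, reason = msg))
  if (!any(is.finite(signal)) || all(signal <= 0)) return(invalid("no positive signal"))
  b <- options$t2_bounds_ms
  opt <- stats::optimize(function(t2) .t2_profile(signal, te_list_ms, t2)$rss,
                         interval = b, tol = max(options$tol, 1e-8))
  t2 <- opt$minimum
  pr <- .t2_profile(signal, te_list_ms, t2)
  tss <- sum((signal - mean(signal))^2)
  r2 <- if (tss > 0) 1 - pr$rss / tss else NA_real_
  at_bound <- (t2 - b[1]) < 1e-6 || (b[2] - t2) < 1e-6
  valid <- is.finite(pr$s0) && pr$s0 > 0 &&
    pr$s0 <= options$amp_max_factor * max(signal) &&
    !at_bound && !is.na(r2) && r2 >= options$min_r2
  list(S0 = pr$s0, T2_ms = t2, valid = valid,
       diagnostics = list(rss = pr$rss, r2 = r2, reason = NA_character_))
}

#' Fit a T2 map over an analysis mask
#'
#' Applies [fit_t2_pixel()] to every masked pixel of a multi-echo spin-echo
#' stack and assembles a `parameter_map` with a validity mask and diagnostics.
#'
#' @param stack A `slice_stack` with modality `multi_echo_se`.
#' @param analysis_mask Logical array (x, y, slice); typically the myocardium.
#' @param options [fit_options()].
#' @return A `parameter_map` (values in ms).
#' @export
fit_t2_map <- function(stack, analysis_mask, options = fit_options()) {
  stopifnot(inherits(stack, "slice_stack"))
  if (stack$meta$modality != "multi_echo_se") stop("stack is not a multi-echo SE series")
  d <- dim(stack$data)
  if (!identical(dim(analysis_mask), d[1:3])) stop("mask/stack shape mismatch")
  idx <- which(analysis_mask)
  values <- array(NA_real_, d[1:3]); valid <- array(FALSE, d[1:3])
  s0_arr <- array(NA_real_, d[1:3]); r2_arr <- array(NA_real_, d[1:3])
  if (length(idx) == 0) {
    warning("empty analysis mask; returning empty map")
  }
  nvox <- prod(d[1:3])
  te <- stack$meta$te_list_ms
  dat <- matrix(stack$data, nrow = nvox)
  for (i in idx) {
    f <- fit_t2_pixel(dat[i, ], te, options)
    values[i] <- if (f$valid) f$T2_ms else NA_real_
    valid[i] <- f$valid
    s0_arr[i] <- f$S0; r2_arr[i] <- f$diagnostics$r2
  }
  new_parameter_map(values, valid, quantity = "T2", units = "ms",
                    analysis_mask = analysis_mask,
                    diagnostics = list(S0 = s0_arr, r2 = r2_arr))
}

#' Restore the polarity of a magnitude inversion-recovery series
#'
#' Magnitude IR data lose the sign of the early, inverted samples. Candidate
#' zero-crossing positions up to one past the series minimum are tried; for
#' each, the leading samples are negated and a Look-Locker model is fitted.
#' The signed series with the smallest fit residual is returned.
#'
#' @param signal Magnitude series sampled on increasing times.
#' @param ti_list_s Sample times (s).
#' @param options [fit_options()].
#' @return List with `signal` (signed series), `n_flipped`, and the winning
#'   fit's residual `rss`.
#' @export
restore_polarity <- function(signal, ti_list_s, options = fit_options()) {
  imin <- which.min(signal)
  candidates <- 0:min(length(signal), imin + 1)
  best <- NULL
  for (j in candidates) {
    s <- signal
    if (j > 0) s[seq_len(j)] <- -s[seq_len(j)]
    f <- .ll_varpro(s, ti_list_s, options)
    if (is.null(best) || (is.finite(f$rss) && f$rss < best$rss)) {
      best <- list(signal = s, n_flipped = j, rss = f$rss)
    }
  }
  best
}

# Variable-projection Look-Locker fit: for each candidate T1* the linear
# parameters (A, B) of A - B*exp(-t/T1*) are solved in closed form from the
# normal equations; the profiled RSS is minimised over the T1* bounds.
.ll_varpro <- function(signal, ti, options) {
  n <- length(signal)
  sy <- sum(signal)
  profile <- function(tau) {
    e <- exp(-ti / tau)
    se <- sum(e); see <- sum(e * e); sye <- sum(signal * e)
    det <- n * see - se * se
    if (abs(det) < 1e-12) return(list(a = NA_real_, b = NA_real_, rss = Inf))
    a <- (sy * see - se * sye) / det
    bb <- (a * se - sye) / see
    list(a = a, b = bb, rss = sum((signal - a + bb * e)^2))
  }
  b <- options$t1star_bounds_s
  opt <- stats::optimize(function(tau) profile(tau)$rss, interval = b,
                         tol = max(options$tol, 1e-9))
  tau <- opt$minimum
  pr <- profile(tau)
  list(A = pr$a, B = pr$b, T1star_s = tau, rss = pr$rss)
}

#' Fit the three-parameter Look-Locker model to one pixel
#'
#' Fits `s(t) = A - B * exp(-t / T1*)` by bounded variable-projection least
#' squares, optionally restoring polarity of magnitude data first.
#'
#' @param signal Series sampled at `ti_list_s` (signed, or magnitude with
#'   `polarity_restoration`).
#' @param ti_list_s Recovery sample times (s), length >= 5.
#' @param options [fit_options()]; `polarity_restoration = TRUE` enables the
#'   magnitude branch (the `NULL` default means "off" at pixel level).
#' @return List with `A`, `B`, `T1star_s`, `valid` and `diagnostics`.
#' @export
fit_ll_pixel <- function(signal, ti_list_s, options = fit_options()) {
  if (length(signal) < 5) stop("at least 5 recovery samples are required")
  if (length(signal) != length(ti_list_s)) stop("signal/TI length mismatch")
  invalid <- function(msg) list(
    A = NA_real_, B = NA_real_, T1star_s = NA_real_, valid = FALSE,
    diagnostics = list(rss = NA_real_, r2 = NA_real_, reason = msg))
  if (!any(is.finite(signal))) return(invalid("non-finite signal"))
  rng <- diff(range(signal))
  if (rng <= 1e-9 * max(abs(signal), 1e-12)) return(invalid("flat series"))
  restore <- isTRUE(options$polarity_restoration)
  if (restore) {
    rp <- restore_polarity(signal, ti_list_s, options)
    signal <- rp$signal
  }
  f <- .ll_varpro(signal, ti_list_s, options)
  tss <- sum((signal - mean(signal))^2)
  r2 <- if (tss > 0) 1 - f$rss / tss else NA_real_
  bnd <- options$t1star_bounds_s
  at_bound <- (f$T1star_s - bnd[1]) < 1e-6 || (bnd[2] - f$T1star_s) < 1e-6
  amp_cap <- options$amp_max_factor * max(abs(signal))
  valid <- is.finite(f$A) && is.finite(f$B) && f$A > 0 && f$B > 0 &&
    f$A <= amp_cap && f$B <= 2 * amp_cap && !at_bound &&
    !is.na(r2) && r2 >= options$min_r2
  list(A = f$A, B = f$B, T1star_s = f$T1star_s, valid = valid,
       diagnostics = list(rss = f$rss, r2 = r2, reason = NA_character_))
}

#' Correct an apparent Look-Locker T1* to true T1
#'
#' Classical three-parameter correction `T1 = T1* * (B / A - 1)`. Pixels with
#' `B <= A` (no physically sensible inversion) yield `NA`.
#'
#' @param A,B,T1star_s Fitted Look-Locker parameters (vectorised).
#' @return True T1 in seconds (`NA` where undefined).
#' @export
correct_t1 <- function(A, B, T1star_s) {
  out <- T1star_s * (B / A - 1)
  out[!is.finite(out) | A <= 0 | B <= A | T1star_s <= 0] <- NA_real_
  out
}

#' Fit a corrected T1 map over an analysis mask
#'
#' Pixel-wise Look-Locker fit plus apparent-to-true T1 correction for one
#' inversion scope of a FAIR acquisition. Polarity restoration defaults to the
#' stack's magnitude flag.
#'
#' @param stack A `slice_stack` with modality `look_locker_ir`.
#' @param analysis_mask Logical array (x, y, slice).
#' @param options [fit_options()].
#' @return A `parameter_map` (values in s) with per-pixel `A`, `B`, `T1star_s`
#'   diagnostics and the inversion scope recorded.
#' @export
fit_t1_map <- function(stack, analysis_mask, options = fit_options()) {
  stopifnot(inherits(stack, "slice_stack"))
  if (stack$meta$modality != "look_locker_ir") {
    stop("stack is not a Look-Locker IR series")
  }
  d <- dim(stack$data)
  if (!identical(dim(analysis_mask), d[1:3])) stop("mask/stack shape mismatch")
  if (is.null(options$polarity_restoration)) {
    options$polarity_restoration <- isTRUE(stack$meta$magnitude)
  }
  idx <- which(analysis_mask)
  if (length(idx) == 0) warning("empty analysis mask; returning empty map")
  values <- array(NA_real_, d[1:3]); valid <- array(FALSE, d[1:3])
  a_arr <- array(NA_real_, d[1:3]); b_arr <- array(NA_real_, d[1:3])
  tstar <- array(NA_real_, d[1:3]); r2_arr <- array(NA_real_, d[1:3])
  ti <- stack$meta$ti_list_s
  dat <- matrix(stack$data, nrow = prod(d[1:3]))
  for (i in idx) {
    f <- fit_ll_pixel(dat[i, ], ti, options)
    a_arr[i] <- f$A; b_arr[i] <- f$B; tstar[i] <- f$T1star_s
    r2_arr[i] <- f$diagnostics$r2
    if (f$valid) {
      t1 <- correct_t1(f$A, f$B, f$T1star_s)
      if (!is.na(t1)) {
        values[i] <- t1; valid[i] <- TRUE
      }
    }
  }
  new_parameter_map(values, valid, quantity = "T1", units = "s",
                    analysis_mask = analysis_mask,
                    diagnostics = list(A = a_arr, B = b_arr, T1star_s = tstar,
                                       r2 = r2_arr),
                    extra = list(inversion_scope = stack$meta$inversion_scope))
}

#' Per-pixel fitted parameter map
#'
#' @param values Numeric array (x, y, slice); `NA` outside the valid mask.
#' @param valid Logical array marking successful fits.
#' @param quantity,units What the values are (e.g. `"T2"`, `"ms"`).
#' @param analysis_mask The mask fitting was attempted on.
#' @param diagnostics Named list of per-pixel diagnostic arrays.
#' @param extra Additional metadata (e.g. inversion scope).
#' @return An object of class `parameter_map`.
#' @keywords internal
new_parameter_map <- function(values, valid, quantity, units,
                              analysis_mask = NULL, diagnostics = list(),
                              extra = list()) {
  stopifnot(identical(dim(values), dim(valid)))
  if (is.null(analysis_mask)) analysis_mask <- array(TRUE, dim(values))
  structure(list(values = values, valid = valid, quantity = quantity,
                 units = units, analysis_mask = analysis_mask,
                 n_valid = sum(valid),
                 n_invalid = sum(analysis_mask) - sum(valid),
                 diagnostics = diagnostics, extra = extra),
            class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<parameter_map> %s (%s): %dx%dx%d; %d valid, %d invalid pixels\n",
              x$quantity, x$units, d[1], d[2], d[3], x$n_valid, x$n_invalid))
  if (x$n_valid > 0) {
    q <- stats::quantile(x$values[x$valid], c(.05, .5, .95))
    cat(sprintf("  5/50/95%%: %.3g / %.3g / %.3g %s\n", q[1], q[2], q[3], x$units))
  }
  invisible(x)
}
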