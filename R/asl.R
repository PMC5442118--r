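#' Estimate blood T1 from the blood-pool ROI of a global-inversion T1 map
#'
#' Median of the valid global-inversion T1 values over the blood pool. When no
#' mask is supplied the configured default is returned with a warning, so a
#' run log records that the blood-pool input function was not measured.
#'
#' @param t1_global A `parameter_map` of global-inversion T1 (s).
#' @param blood_mask Logical array selecting blood-pool pixels, or `NULL`.
#' @param default Fallback blood T1 (s), e.g. `asl_constants()$t1_blood_s`.
#' @return Blood T1 in seconds.
#' @export
estimate_blood_t1 <- function(t1_global, blood_mask = NULL, default = NULL) {
  stopifnot(inherits(t1_global, "parameter_map"))
  if (is.null(blood_mask)) {
    if (is.null(default)) stop("no blood mask supplied and no default configured")
    warning("no blood-pool mask supplied; using configured blood T1 default")
    return(default)
  }
  sel <- blood_mask & t1_global$valid
  if (!any(sel)) {
    if (is.null(default)) stop("blood ROI contains no valid pixels and no default configured")
    warning("blood ROI contains no valid pixels; using configured blood T1 default")
    return(default)
  }
  stats::median(t1_global$values[sel])
}

#' Compute a perfusion map from paired selective/global T1 maps
#'
#' Blood-pool-input FAIR quantification: per pixel
#' `MBF = 60 * (lambda / T1_blood) * (T1_global / T1_selective - 1)` in
#' ml/g/min. Pixels where the selective T1 exceeds the global T1 yield
#' negative perfusion; they are retained (so downstream normal-ROI statistics
#' stay unbiased) but flagged. Pixels invalid in either input are invalid.
#'
#' @param t1_selective,t1_global `parameter_map`s (s) sharing geometry.
#' @param constants [asl_constants()] providing the partition coefficient.
#' @param t1_blood_s Blood T1 (s); defaults to the constant, or supply the
#'   output of [estimate_blood_t1()].
#' @return A `parameter_map` in ml/g/min with a `negative` flag array in
#'   `$diagnostics` and the quantification constants in `$extra`.
#' @export
compute_perfusion_map <- function(t1_selective, t1_global,
                                  constants = asl_constants(),
                                  t1_blood_s = constants$t1_blood_s) {
  stopifnot(inherits(t1_selective, "parameter_map"),
            inherits(t1_global, "parameter_map"))
  if (!identical(dim(t1_selective$values), dim(t1_global$values))) {
    stop("selective and global maps must share geometry")
  }
  if (t1_blood_s <= 0 || constants$lambda_ml_per_g <= 0) {
    stop("blood T1 and lambda must be positive")
  }
  valid <- t1_selective$valid & t1_global$valid
  bad_sel <- valid & !(t1_selective$values > 0)
  valid[bad_sel] <- FALSE
  mbf <- array(NA_real_, dim(valid))
  mbf[valid] <- 60 * (constants$lambda_ml_per_g / t1_blood_s) *
    (t1_global$values[valid] / t1_selective$values[valid] - 1)
  negative <- array(FALSE, dim(valid))
  negative[valid] <- mbf[valid] < 0
  mask <- t1_selective$analysis_mask & t1_global$analysis_mask
  new_parameter_map(mbf, valid, quantity = "perfusion", units = "ml/g/min",
                    analysis_mask = mask,
                    diagnostics = list(negative = negative),
                    extra = list(lambda_ml_per_g = constants$lambda_ml_per_g,
                                 t1_blood_s = t1_blood_s))
}

#' Quality-control summary of a perfusion map
#'
#' @param map A perfusion `parameter_map`.
#' @return A list of class `qc_report`: counts of invalid and negative pixels
#'   and per-slice medians of the valid values.
#' @export
perfusion_qc <- function(map) {
  stopifnot(inherits(map, "parameter_map"))
  nsl <- dim(map$values)[3]
  med <- vapply(seq_len(nsl), function(k) {
    v <- map$values[, , k][map$valid[, , k]]
    if (length(v)) stats::median(v) else NA_real_
  }, numeric(1))
  neg <- map$diagnostics$negative
  structure(list(
    n_valid = map$n_valid, n_invalid = map$n_invalid,
    n_negative = if (is.null(neg)) 0L else sum(neg),
    slice_medians = med, units = map$units
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d valid, %d invalid, %d negative pixels\n",
              x$n_valid, x$n_invalid, x$n_negative))
  cat("  slice medians:", paste(sprintf("%.2f", x$slice_medians), collapse = " "),
      x$units, "\n")
  invisible(x)
}
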