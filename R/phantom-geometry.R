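# Integer codes used in label volumes. Kept stable so label images written to
# disk round-trip without a lookup table.
REGION_CODES <- c(background = 0L, blood = 1L, remote = 2L,
                  aar_salvaged = 3L, infarct = 4L)

#' Region label volume
#'
#' Internal constructor for the per-pixel class volume shared by phantoms and
#' simulated histology. `labels` codes: 0 background, 1 blood pool, 2 remote
#' myocardium, 3 salvaged area-at-risk, 4 infarct. `edema` marks the subset of
#' the AAR that expresses edema on T2/T1 (always a superset of the infarct).
#'
#' @param labels Integer array (x, y, slice).
#' @param edema Logical array of the same dimension.
#' @param lv_center LV centre in pixel coordinates.
#' @param achieved Named list of achieved ground-truth fractions.
#' @return An object of class `region_labels`.
#' @keywords internal
new_region_labels <- function(labels, edema = NULL, lv_center = NULL,
                              achieved = list()) {
  storage.mode(labels) <- "integer"
  if (is.null(edema)) edema <- array(FALSE, dim(labels))
  stopifnot(identical(dim(labels), dim(edema)))
  structure(list(labels = labels, edema = edema, lv_center = lv_center,
                 achieved = achieved),
            class = "region_labels")
}

#' @export
print.region_labels <- function(x, ...) {
  d <- dim(x$labels)
  cnt <- tabulate(x$labels + 1L, nbins = 5L)
  names(cnt) <- names(REGION_CODES)
  cat(sprintf("<region_labels> %dx%dx%d\n", d[1], d[2], d[3]))
  print(cnt)
  if (length(x$achieved)) {
    cat(sprintf("  achieved AAR/LV %.2f%%, IS/AAR %.2f%%\n",
                x$achieved$aar_lv_pct, x$achieved$is_aar_pct))
  }
  invisible(x)
}

#' Extract a logical mask for a tissue class or compound region
#'
#' @param x A `region_labels` object.
#' @param region One of `"background"`, `"blood"`, `"remote"`,
#'   `"aar_salvaged"`, `"infarct"`, or the compound regions `"myocardium"`
#'   (remote + salvaged + infarct), `"aar"` (salvaged + infarct) and
#'   `"edema"` (the edematous subset of the AAR).
#' @return Logical array with the dimensions of the label volume.
#' @export
region_mask <- function(x, region) {
  stopifnot(inherits(x, "region_labels"))
  lab <- x$labels
  switch(region,
    myocardium = lab >= REGION_CODES[["remote"]],
    aar = lab >= REGION_CODES[["aar_salvaged"]],
    edema = x$edema,
    background = ,
    blood = ,
    remote = ,
    aar_salvaged = ,
    infarct = lab == REGION_CODES[[region]],
    stop("unknown region '", region, "'")
  )
}

#' Build the annular LV geometry of a phantom
#'
#' Labels each slice as blood pool (distance from the LV centre `< r_inner`),
#' myocardium (`r_inner <= distance < r_outer`, initially all remote) or
#' background. Deterministic given the configuration.
#'
#' @param config A [phantom_config()].
#' @return A `region_labels` volume containing blood and remote myocardium.
#' @export
make_geometry <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  m <- config$matrix_size
  n <- config$n_slices
  cx <- config$lv_center[1]; cy <- config$lv_center[2]
  r <- sqrt(outer((seq_len(m) - cx)^2, (seq_len(m) - cy)^2, `+`))
  labels <- array(REGION_CODES[["background"]], c(m, m, n))
  for (k in seq_len(n)) {
    sl <- matrix(REGION_CODES[["background"]], m, m)
    sl[r < config$r_inner[k]] <- REGION_CODES[["blood"]]
    sl[r >= config$r_inner[k] & r < config$r_outer[k]] <- REGION_CODES[["remote"]]
    labels[, , k] <- sl
  }
  new_region_labels(labels, lv_center = c(cx, cy))
}

# Angular distance of myocardial pixels from the sector axis, used both to
# carve the AAR sector and to re-slice histology conservatively. Returns a
# data.frame ordered by increasing angular distance (ties broken by slice then
# linear index, so the ordering is deterministic).
.sector_order <- function(labels_arr, lv_center, slices, sector_axis_rad = 0) {
  idx <- which(labels_arr >= REGION_CODES[["remote"]], arr.ind = TRUE)
  idx <- idx[idx[, 3] %in% slices, , drop = FALSE]
  if (nrow(idx) == 0) {
    return(data.frame(x = integer(), y = integer(), slice = integer(),
                      delta = numeric()))
  }
  th <- atan2(idx[, 2] - lv_center[2], idx[, 1] - lv_center[1])
  delta <- abs(atan2(sin(th - sector_axis_rad), cos(th - sector_axis_rad)))
  ord <- order(delta, idx[, 3], idx[, 1], idx[, 2])
  data.frame(x = idx[ord, 1], y = idx[ord, 2], slice = idx[ord, 3],
             delta = delta[ord])
}

#' Assign area-at-risk, infarct and edema regions to a phantom
#'
#' A contiguous transmural angular sector of the myocardium, confined to
#' `aar_slice_span`, is labelled as AAR so that the achieved AAR/LV pixel
#' fraction matches `aar_fraction` up to pixel quantization; a nested angular
#' core is labelled infarct at `is_fraction_of_aar` of the AAR. The innermost
#' `edema_extent_multiplier` fraction of the AAR is recorded as the edema mask
#' used by the T2/T1 signal simulators (the infarct is always edematous).
#'
#' @param geometry A `region_labels` volume from [make_geometry()].
#' @param aar_fraction,is_fraction_of_aar,aar_slice_span,edema_extent_multiplier
#'   Override the corresponding fields of `config`; defaults come from `config`.
#' @param config The [phantom_config()] the geometry was built from.
#' @param sector_axis_rad Direction (radians) of the sector centre-line.
#' @return A fully labelled `region_labels` volume with achieved fractions in
#'   `$achieved`.
#' @export
assign_regions <- function(geometry, config,
                           aar_fraction = config$aar_fraction,
                           is_fraction_of_aar = config$is_fraction_of_aar,
                           aar_slice_span = config$aar_slice_span,
                           edema_extent_multiplier = config$edema_extent_multiplier,
                           sector_axis_rad = 0) {
  stopifnot(inherits(geometry, "region_labels"))
  lab <- geometry$labels
  myo <- lab >= REGION_CODES[["remote"]]
  n_myo <- sum(myo)
  if (n_myo == 0) stop("geometry contains no myocardium")
  if (aar_fraction < 0 || aar_fraction > 1 ||
      is_fraction_of_aar < 0 || is_fraction_of_aar > 1) {
    stop("fractions must lie in [0, 1]")
  }

  ord <- .sector_order(lab, geometry$lv_center, aar_slice_span, sector_axis_rad)
  capacity <- nrow(ord)
  n_target <- round(aar_fraction * n_myo)
  if (n_target > capacity) {
    if (aar_fraction >= 1) {
      stop("aar_fraction = 1 leaves no normal reference slice; reduce it")
    }
    # a transmural sector confined to the allowed slices cannot exceed the
    # span's myocardium; clamp and record the request
    n_target <- capacity
  }
  edema <- array(FALSE, dim(lab))
  if (n_target > 0) {
    take <- ord[seq_len(n_target), ]
    n_is <- round(is_fraction_of_aar * n_target)
    n_ed <- max(n_is, round(edema_extent_multiplier * n_target))
    lin <- take$x + (take$y - 1L) * dim(lab)[1] +
      (take$slice - 1L) * dim(lab)[1] * dim(lab)[2]
    lab[lin] <- REGION_CODES[["aar_salvaged"]]
    if (n_is > 0) lab[lin[seq_len(n_is)]] <- REGION_CODES[["infarct"]]
    if (n_ed > 0) edema[lin[seq_len(n_ed)]] <- TRUE
  } else {
    n_is <- 0L; n_ed <- 0L
  }

  achieved <- list(
    aar_lv_pct = 100 * n_target / n_myo,
    is_lv_pct = 100 * n_is / n_myo,
    is_aar_pct = if (n_target > 0) 100 * n_is / n_target else NA_real_,
    edema_fraction_of_aar = if (n_target > 0) n_ed / n_target else NA_real_,
    requested_aar_lv_pct = 100 * aar_fraction,
    requested_is_aar_pct = 100 * is_fraction_of_aar,
    n_myocardium = n_myo
  )
  new_region_labels(lab, edema, geometry$lv_center, achieved)
}

#' Build a fully labelled phantom in one call
#'
#' @param config A [phantom_config()].
#' @inheritParams assign_regions
#' @return A `region_labels` volume.
#' @export
make_phantom_labels <- function(config, sector_axis_rad = 0) {
  assign_regions(make_geometry(config), config, sector_axis_rad = sector_axis_rad)
}
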