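#' Normal-ROI statistics from the reference slice
#'
#' The normal reference region is, by convention, the entire valid myocardium
#' of the second-from-most-basal slice (slices ordered apex to base), which is
#' expected to be remote tissue in this infarct model. An angular sub-sector
#' can be selected instead via `roi_spec$sector`.
#'
#' @param map A `parameter_map`.
#' @param myocardial_mask Logical array (x, y, slice).
#' @param roi_spec List with optional elements `slice` (1-based index,
#'   default `n_slices - 1`), `min_pixels` (default 30) and `sector`
#'   (`c(centre_rad, half_width_rad)` with `lv_center` taken from the map
#'   caller; default whole slice).
#' @return A list of class `roi_stats`: `mean`, `sd`, `n_pixels`, `slice`,
#'   `units`.
#' @export
select_normal_roi <- function(map, myocardial_mask,
                              roi_spec = list(slice = NULL, min_pixels = 30)) {
  stopifnot(inherits(map, "parameter_map"))
  d <- dim(map$values)
  if (d[3] < 2) stop("map must contain at least 2 slices")
  slice <- roi_spec$slice
  if (is.null(slice)) slice <- d[3] - 1L
  if (slice < 1 || slice > d[3]) stop("ROI slice index out of range")
  min_pixels <- roi_spec$min_pixels
  if (is.null(min_pixels)) min_pixels <- 30L
  sel <- myocardial_mask[, , slice] & map$valid[, , slice]
  vals <- map$values[, , slice][sel]
  if (length(vals) < min_pixels) {
    stop(sprintf("normal ROI has %d valid pixels (< %d); animal unanalyzable",
                 length(vals), min_pixels))
  }
  structure(list(mean = mean(vals), sd = stats::sd(vals),
                 n_pixels = length(vals), slice = slice, units = map$units),
            class = "roi_stats")
}

#' Threshold a parameter map against normal-ROI statistics
#'
#' Flags pixels strictly beyond `mean + k*sd` (direction `"above"`) or
#' `mean - k*sd` (`"below"`); a pixel exactly at the cut is never flagged.
#' The flagged area is expressed as a percentage of the valid myocardial
#' pixels of all slices.
#'
#' @param map A `parameter_map`.
#' @param myocardial_mask Logical array.
#' @param stats A `roi_stats` from [select_normal_roi()].
#' @param k SD multiplier (1 and 2 in the study design; any positive value
#'   accepted).
#' @param direction `"above"` or `"below"`.
#' @return A list of class `threshold_result`: `k`, `direction`,
#'   `threshold_value`, `flagged_mask`, `area_fraction_pct`, `n_valid`,
#'   `n_invalid`.
#' @export
threshold_map <- function(map, myocardial_mask, stats, k,
                          direction = c("above", "below")) {
  direction <- match.arg(direction)
  stopifnot(inherits(map, "parameter_map"), inherits(stats, "roi_stats"))
  if (stats$sd < 0) stop("ROI sd must be non-negative")
  cut <- if (direction == "above") stats$mean + k * stats$sd
         else stats$mean - k * stats$sd
  valid <- myocardial_mask & map$valid
  flagged <- array(FALSE, dim(valid))
  flagged[valid] <- if (direction == "above") map$values[valid] > cut
                    else map$values[valid] < cut
  n_valid <- sum(valid)
  structure(list(k = k, direction = direction, threshold_value = cut,
                 flagged_mask = flagged,
                 area_fraction_pct = if (n_valid > 0) 100 * sum(flagged) / n_valid else NA_real_,
                 n_valid = n_valid,
                 n_invalid = sum(myocardial_mask & !map$valid)),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> %s %g SD (cut %.4g): %.2f%% of %d valid px (%d invalid)\n",
              x$direction, x$k, x$threshold_value, x$area_fraction_pct,
              x$n_valid, x$n_invalid))
  invisible(x)
}

#' Remove small connected clusters from a flagged mask
#'
#' Per-slice 4-connected component labelling; clusters smaller than
#' `min_cluster` pixels are dropped. Used to suppress the isolated
#' noise-driven pixels that a per-pixel k-SD rule inevitably flags, while
#' leaving the contiguous lesion sector intact. `min_cluster <= 1` is a no-op.
#'
#' @param flagged Logical array (x, y, slice).
#' @param min_cluster Minimum surviving cluster size in pixels.
#' @return Filtered logical array.
#' @export
filter_small_clusters <- function(flagged, min_cluster) {
  if (is.null(min_cluster) || min_cluster <= 1) return(flagged)
  out <- flagged
  for (k in seq_len(dim(flagged)[3])) {
    sl <- flagged[, , k]
    if (!any(sl)) next
    lab <- EBImage::bwlabel(sl * 1)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_cluster)
    out[, , k] <- lab %in% keep & sl
  }
  out
}

# Area of a flagged mask as % of valid myocardial pixels.
.area_pct <- function(flagged, valid) {
  nv <- sum(valid)
  if (nv == 0) return(NA_real_)
  100 * sum(flagged & valid) / nv
}

# Shared composition: normal ROI -> threshold -> optional cluster filter.
.threshold_metric <- function(map, myocardial_mask, k, direction, roi_spec,
                              min_cluster) {
  stats <- select_normal_roi(map, myocardial_mask, roi_spec)
  thr <- threshold_map(map, myocardial_mask, stats, k, direction)
  flt <- filter_small_clusters(thr$flagged_mask, min_cluster)
  valid <- myocardial_mask & map$valid
  list(roi = stats, threshold = thr, flagged = flt,
       area_pct = .area_pct(flt, valid), n_invalid = thr$n_invalid)
}

#' Putative AAR from a T2 map
#'
#' Pixels with T2 more than 1 SD above the normal-ROI mean are counted as
#' edema-based area-at-risk, expressed as a percentage of the valid
#' myocardium.
#'
#' @param t2_map A T2 `parameter_map`.
#' @param myocardial_mask Logical array.
#' @param roi_spec See [select_normal_roi()].
#' @param k SD multiplier.
#' @param min_cluster Minimum cluster size kept (see
#'   [filter_small_clusters()]); `0` disables filtering.
#' @return List with `aar_lv_pct`, the ROI stats, threshold detail and the
#'   invalid-pixel count.
#' @export
aar_from_t2 <- function(t2_map, myocardial_mask,
                        roi_spec = list(), k = 1, min_cluster = 10) {
  m <- .threshold_metric(t2_map, myocardial_mask, k, "above", roi_spec, min_cluster)
  list(aar_lv_pct = m$area_pct, roi = m$roi, threshold = m$threshold,
       flagged_mask = m$flagged, n_invalid = m$n_invalid)
}

#' Putative AAR from the global-inversion T1 map
#'
#' @inheritParams aar_from_t2
#' @param t1_global_map Global-inversion T1 `parameter_map`.
#' @return As [aar_from_t2()].
#' @export
aar_from_t1 <- function(t1_global_map, myocardial_mask,
                        roi_spec = list(), k = 1, min_cluster = 10) {
  m <- .threshold_metric(t1_global_map, myocardial_mask, k, "above", roi_spec,
                         min_cluster)
  list(aar_lv_pct = m$area_pct, roi = m$roi, threshold = m$threshold,
       flagged_mask = m$flagged, n_invalid = m$n_invalid)
}

#' Putative AAR and infarct from an ASL perfusion map
#'
#' Perfusion below the normal-ROI mean minus 1 SD marks the putative AAR;
#' below mean minus 2 SD marks the putative infarct. Both areas are
#' percentages of the valid myocardium; the infarct mask is nested in the AAR
#' mask by construction.
#'
#' @inheritParams aar_from_t2
#' @param perfusion_map A perfusion `parameter_map`.
#' @param k_aar,k_is SD multipliers for the AAR and infarct cuts.
#' @return List with `aar_lv_pct`, `is_lv_pct`, ROI stats, both threshold
#'   details and the invalid count.
#' @export
aar_is_from_asl <- function(perfusion_map, myocardial_mask,
                            roi_spec = list(), k_aar = 1, k_is = 2,
                            min_cluster = 10) {
  stats <- select_normal_roi(perfusion_map, myocardial_mask, roi_spec)
  thr1 <- threshold_map(perfusion_map, myocardial_mask, stats, k_aar, "below")
  thr2 <- threshold_map(perfusion_map, myocardial_mask, stats, k_is, "below")
  f1 <- filter_small_clusters(thr1$flagged_mask, min_cluster)
  f2 <- filter_small_clusters(thr2$flagged_mask, min_cluster)
  valid <- myocardial_mask & perfusion_map$valid
  list(aar_lv_pct = .area_pct(f1, valid), is_lv_pct = .area_pct(f2, valid),
       roi = stats, threshold_aar = thr1, threshold_is = thr2,
       flagged_aar = f1, flagged_is = f2, n_invalid = thr1$n_invalid)
}

#' Infarct size from a late gadolinium enhancement stack
#'
#' The commercial auto-delineation used clinically is replaced by a
#' transparent remote-remote SD rule: pixels brighter than the remote-ROI
#' mean plus `k_lge` SD count as enhanced, as a percentage of the myocardium.
#'
#' @param lge_stack A single-timepoint `slice_stack` (modality `lge`).
#' @param myocardial_mask Logical array.
#' @param roi_spec See [select_normal_roi()]; the remote ROI follows the same
#'   second-from-most-basal-slice convention.
#' @param k_lge SD multiplier (default 5).
#' @param min_cluster Minimum cluster size kept.
#' @return List with `is_lv_pct`, ROI stats and threshold detail.
#' @export
delineate_lge <- function(lge_stack, myocardial_mask, roi_spec = list(),
                          k_lge = 5, min_cluster = 10) {
  stopifnot(inherits(lge_stack, "slice_stack"))
  if (lge_stack$meta$modality != "lge") stop("stack is not an LGE image")
  img <- lge_stack$data[, , , 1]
  map <- new_parameter_map(img, array(TRUE, dim(img)), quantity = "LGE signal",
                           units = "a.u.", analysis_mask = myocardial_mask)
  m <- .threshold_metric(map, myocardial_mask, k_lge, "above", roi_spec,
                         min_cluster)
  list(is_lv_pct = m$area_pct, roi = m$roi, threshold = m$threshold,
       flagged_mask = m$flagged, n_invalid = m$n_invalid)
}

#' Planimetry of histology label slices
#'
#' Pixel-counting on stained-slice labels: `IS/LV% = 100 |infarct| /
#' |myocardium|`, `AAR/LV% = 100 |AAR| / |myocardium|`, `IS/AAR% =
#' 100 |infarct| / |AAR|`.
#'
#' @param labels A `region_labels` volume (simulated histology or phantom
#'   truth).
#' @return List with `is_lv_pct`, `aar_lv_pct`, `is_aar_pct` and the pixel
#'   counts.
#' @export
planimetry <- function(labels) {
  stopifnot(inherits(labels, "region_labels"))
  n_myo <- sum(region_mask(labels, "myocardium"))
  if (n_myo == 0) stop("histology labels contain no myocardium")
  n_aar <- sum(region_mask(labels, "aar"))
  n_is <- sum(region_mask(labels, "infarct"))
  list(is_lv_pct = 100 * n_is / n_myo,
       aar_lv_pct = 100 * n_aar / n_myo,
       is_aar_pct = if (n_aar > 0) 100 * n_is / n_aar else NA_real_,
       n_myocardium = n_myo, n_aar = n_aar, n_infarct = n_is)
}

#' Assemble per-animal regional metrics into one table
#'
#' @param rows List of one-row data frames (one per animal), as produced by
#'   [quantify_animal()]. Missing modalities stay `NA`; they are never
#'   imputed.
#' @return A `data.frame` with one row per animal.
#' @export
assemble_metrics <- function(rows) {
  if (length(rows) == 0) {
    return(data.frame(id = character(), group = character(),
                      stringsAsFactors = FALSE))
  }
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (cl in setdiff(all_cols, names(r))) r[[cl]] <- NA
    r[all_cols]
  })
  out <- do.call(rbind, rows)
  if (anyDuplicated(out$id)) stop("duplicate animal id in metrics table")
  rownames(out) <- NULL
  out
}
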