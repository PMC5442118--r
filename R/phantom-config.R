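#' Phantom geometry and study-condition configuration
#'
#' Describes one synthetic short-axis left ventricle: an annular myocardium
#' (blood pool inside, background outside) replicated over `n_slices` slices
#' ordered apex to base, with a transmural angular area-at-risk (AAR) sector
#' containing a nested infarct core.
#'
#' @param matrix_size Pixels per image side (square matrix).
#' @param n_slices Number of short-axis slices, ordered apex to base.
#' @param lv_center Numeric length-2 centre of the LV in pixel coordinates;
#'   defaults to the image centre `(matrix_size + 1) / 2`.
#' @param r_outer,r_inner Epicardial / endocardial radii in pixels; either
#'   scalars or per-slice vectors of length `n_slices`.
#' @param aar_fraction Target AAR/LV as a fraction of all myocardial pixels.
#' @param is_fraction_of_aar Target infarct size as a fraction of the AAR.
#' @param aar_slice_span Integer indices (1-based, apex to base) of slices that
#'   may contain AAR. The two most basal slices are always excluded so that the
#'   second-from-most-basal slice used as the normal reference region is truly
#'   remote myocardium.
#' @param edema_extent_multiplier Fraction of the AAR that is edematous
#'   (elevated T2/T1); 1 except for preconditioning-like phantoms.
#' @param seed Integer RNG seed attached to this phantom's simulations.
#' @return An object of class `phantom_config` (a validated list).
#' @export
phantom_config <- function(matrix_size = 128L,
                           n_slices = 7L,
                           lv_center = NULL,
                           r_outer = 13,
                           r_inner = 8,
                           aar_fraction = 0.643,
                           is_fraction_of_aar = 0.506,
                           aar_slice_span = NULL,
                           edema_extent_multiplier = 1,
                           seed = 1L) {
  matrix_size <- as.integer(matrix_size)
  n_slices <- as.integer(n_slices)
  if (matrix_size < 8L) stop("matrix_size must be at least 8 pixels")
  if (n_slices < 3L) stop("n_slices must be at least 3")
  if (is.null(lv_center)) lv_center <- rep((matrix_size + 1) / 2, 2)
  r_outer <- rep_len(as.numeric(r_outer), n_slices)
  r_inner <- rep_len(as.numeric(r_inner), n_slices)
  if (any(r_inner < 0)) stop("r_inner must be non-negative")
  if (any(r_inner >= r_outer)) stop("configuration error: r_inner must be < r_outer")
  if (any(r_outer >= matrix_size / 2)) {
    stop("configuration error: r_outer must be < matrix_size / 2")
  }
  if (aar_fraction < 0 || aar_fraction > 1) stop("aar_fraction must lie in [0, 1]")
  if (is_fraction_of_aar < 0 || is_fraction_of_aar > 1) {
    stop("is_fraction_of_aar must lie in [0, 1]")
  }
  if (edema_extent_multiplier <= 0 || edema_extent_multiplier > 1) {
    stop("edema_extent_multiplier must lie in (0, 1]")
  }
  if (is.null(aar_slice_span)) aar_slice_span <- seq_len(max(n_slices - 2L, 1L))
  aar_slice_span <- sort(unique(as.integer(aar_slice_span)))
  if (any(aar_slice_span < 1L) || any(aar_slice_span > n_slices)) {
    stop("aar_slice_span indices out of range")
  }
  # both basal slices must remain remote so the normal ROI slice is normal
  if (any(aar_slice_span > n_slices - 2L)) {
    stop("aar_slice_span must exclude the two most basal slices")
  }
  structure(list(
    matrix_size = matrix_size, n_slices = n_slices, lv_center = lv_center,
    r_outer = r_outer, r_inner = r_inner,
    aar_fraction = aar_fraction, is_fraction_of_aar = is_fraction_of_aar,
    aar_slice_span = aar_slice_span,
    edema_extent_multiplier = edema_extent_multiplier,
    seed = as.integer(seed)
  ), class = "phantom_config")
}

#' @export
print.phantom_config <- function(x, ...) {
  cat(sprintf(
    "<phantom_config> %dx%d, %d slices; r = [%.1f, %.1f] px; AAR/LV %.1f%%, IS/AAR %.1f%%, edema x%.2f; seed %d\n",
    x$matrix_size, x$matrix_size, x$n_slices, x$r_inner[1], x$r_outer[1],
    100 * x$aar_fraction, 100 * x$is_fraction_of_aar,
    x$edema_extent_multiplier, x$seed
  ))
  invisible(x)
}

#' Per-region tissue parameters
#'
#' Relaxation times, equilibrium signal, perfusion and late-enhancement factor
#' for the four phantom tissue classes. Defaults are representative of mouse
#' myocardium at 9.4 T three days after ischemia-reperfusion: edema raises T2
#' and T1 in the injured zone, perfusion is reduced throughout the area-at-risk
#' and most severely in the infarct, and only infarct enhances after contrast.
#'
#' @param remote,aar_salvaged,infarct,blood Named lists with elements `T1_s`,
#'   `T2_ms`, `S0`, `mbf` (ml/g/min) and `lge_enhancement`.
#' @return An object of class `tissue_params`.
#' @export
tissue_params <- function(
    remote = list(T1_s = 1.7, T2_ms = 25, S0 = 100, mbf = 16.9, lge_enhancement = 1),
    aar_salvaged = list(T1_s = 2.0, T2_ms = 35, S0 = 100, mbf = 6, lge_enhancement = 1),
    infarct = list(T1_s = 2.1, T2_ms = 38, S0 = 100, mbf = 2, lge_enhancement = 3),
    blood = list(T1_s = 2.4, T2_ms = 30, S0 = 100, mbf = 0, lge_enhancement = 1)) {
  p <- list(remote = remote, aar_salvaged = aar_salvaged,
            infarct = infarct, blood = blood)
  for (nm in names(p)) {
    r <- p[[nm]]
    need <- c("T1_s", "T2_ms", "S0", "mbf", "lge_enhancement")
    if (!all(need %in% names(r))) {
      stop("tissue region '", nm, "' must supply ", paste(need, collapse = ", "))
    }
    if (r$T1_s <= 0 || r$T2_ms <= 0 || r$S0 <= 0) {
      stop("configuration error: relaxation times and S0 must be positive (", nm, ")")
    }
    if (r$mbf < 0) stop("mbf must be non-negative (", nm, ")")
  }
  if (!(p$aar_salvaged$T2_ms > p$remote$T2_ms && p$infarct$T2_ms > p$remote$T2_ms)) {
    stop("edema ordering violated: AAR T2 values must exceed remote T2")
  }
  if (!(p$aar_salvaged$T1_s > p$remote$T1_s && p$infarct$T1_s > p$remote$T1_s)) {
    stop("edema ordering violated: AAR T1 values must exceed remote T1")
  }
  if (!(p$infarct$mbf <= p$aar_salvaged$mbf && p$aar_salvaged$mbf < p$remote$mbf)) {
    stop("perfusion ordering violated: need mbf(infarct) <= mbf(salvaged) < mbf(remote)")
  }
  structure(p, class = "tissue_params")
}

#' Acquisition metadata constructors
#'
#' @param te_list_ms Echo times (ms) of the multi-echo spin-echo T2 series;
#'   strictly increasing and positive.
#' @param slice_thickness_mm Slice thickness.
#' @return An object of class `acq_meta`.
#' @export
acq_multi_echo_se <- function(te_list_ms = c(3.5, 7, 10, 12, 15, 17, 20, 25, 30),
                              slice_thickness_mm = 1) {
  if (length(te_list_ms) < 2 || any(te_list_ms <= 0) || any(diff(te_list_ms) <= 0)) {
    stop("te_list_ms must be strictly increasing and positive")
  }
  structure(list(modality = "multi_echo_se", te_list_ms = te_list_ms,
                 slice_thickness_mm = slice_thickness_mm),
            class = "acq_meta")
}

#' @rdname acq_multi_echo_se
#' @param inversion_scope `"selective"` (slice-selective inversion, the FAIR
#'   control condition) or `"global"` (the tagged condition).
#' @param n_points Number of samples on the inversion-recovery curve.
#' @param ti_range Range (s) over which the recovery curve is sampled
#'   uniformly; the Look-Locker readout runs continuously after inversion.
#' @param ti_list_s Explicit sample times (s); overrides `n_points`/`ti_range`.
#' @param flip_angle_deg Look-Locker readout flip angle (degrees, < 90).
#' @param tr_rf_ms Spacing between readout excitations (ms).
#' @param tr_inv_s Inversion repetition time (s).
#' @param magnitude Logical; if `TRUE` the series is magnitude data (the sign
#'   of the inverted signal is lost and must be restored before fitting).
#' @export
acq_look_locker <- function(inversion_scope = c("selective", "global"),
                            n_points = 50L, ti_range = c(0.05, 10),
                            ti_list_s = NULL,
                            flip_angle_deg = 5, tr_rf_ms = 3, tr_inv_s = 13.5,
                            magnitude = FALSE, slice_thickness_mm = 1) {
  inversion_scope <- match.arg(inversion_scope)
  if (is.null(ti_list_s)) {
    ti_list_s <- seq(ti_range[1], ti_range[2], length.out = n_points)
  }
  if (ti_list_s[1] <= 0 || any(diff(ti_list_s) <= 0)) {
    stop("ti_list_s must be strictly increasing and start > 0")
  }
  if (flip_angle_deg >= 90 || flip_angle_deg <= 0) {
    stop("flip angle must lie in (0, 90) degrees")
  }
  if (tr_rf_ms <= 0 || tr_inv_s <= 0) stop("repetition times must be positive")
  structure(list(modality = "look_locker_ir", inversion_scope = inversion_scope,
                 ti_list_s = ti_list_s, n_points = length(ti_list_s),
                 flip_angle_deg = flip_angle_deg, tr_rf_ms = tr_rf_ms,
                 tr_inv_s = tr_inv_s, magnitude = magnitude,
                 slice_thickness_mm = slice_thickness_mm),
            class = "acq_meta")
}

#' @rdname acq_multi_echo_se
#' @export
acq_lge <- function(slice_thickness_mm = 1) {
  structure(list(modality = "lge", slice_thickness_mm = slice_thickness_mm),
            class = "acq_meta")
}

#' Constants of blood-pool-input ASL perfusion quantification
#'
#' @param lambda_ml_per_g Blood-tissue water partition coefficient (ml/g).
#' @param t1_blood_s Longitudinal relaxation time of arterial blood (s);
#'   default appropriate for 9.4 T, overridable or estimable from a blood-pool
#'   ROI with [estimate_blood_t1()].
#' @return An object of class `asl_constants`.
#' @export
asl_constants <- function(lambda_ml_per_g = 0.95, t1_blood_s = 2.4) {
  if (lambda_ml_per_g <= 0 || t1_blood_s <= 0) {
    stop("ASL constants must be strictly positive")
  }
  structure(list(lambda_ml_per_g = lambda_ml_per_g, t1_blood_s = t1_blood_s),
            class = "asl_constants")
}

#' Treatment-group specification for cohort simulation
#'
#' Per-animal ground-truth AAR/LV and IS/AAR fractions are drawn from the
#' group's Normal distributions (percent scale); `edema_extent_multiplier`
#' controls which fraction of the true AAR expresses edema on T2/T1, and
#' `normal_mbf` sets remote-myocardium perfusion.
#'
#' @param name Group name.
#' @param aar_mean_pct,aar_sd_pct Histology AAR/LV%% distribution.
#' @param isaar_mean_pct,isaar_sd_pct Histology IS/AAR%% distribution.
#' @param edema_extent_multiplier Fraction of the AAR that is edematous.
#' @param normal_mbf Remote-myocardium perfusion (ml/g/min).
#' @param n_animals Number of animals in the group.
#' @return An object of class `group_spec`.
#' @export
group_spec <- function(name, aar_mean_pct, aar_sd_pct,
                       isaar_mean_pct, isaar_sd_pct,
                       edema_extent_multiplier = 1,
                       normal_mbf = 16.9, n_animals) {
  if (n_animals < 0) stop("n_animals must be non-negative")
  if (edema_extent_multiplier <= 0 || edema_extent_multiplier > 1) {
    stop("edema_extent_multiplier must lie in (0, 1]")
  }
  if (aar_sd_pct < 0 || isaar_sd_pct < 0) stop("SDs must be non-negative")
  if (normal_mbf <= 0) stop("normal_mbf must be positive")
  structure(list(name = name,
                 aar_mean_pct = aar_mean_pct, aar_sd_pct = aar_sd_pct,
                 isaar_mean_pct = isaar_mean_pct, isaar_sd_pct = isaar_sd_pct,
                 edema_extent_multiplier = edema_extent_multiplier,
                 normal_mbf = normal_mbf, n_animals = as.integer(n_animals)),
            class = "group_spec")
}

#' Default four-group study design
#'
#' Control and ischemic-preconditioning (IPC) arms plus vehicle and
#' cyclosporin-A (CsA) arms, with the histology AAR/LV and IS/AAR
#' distributions, group sizes, IPC edema-extent reduction and CsA
#' normal-perfusion elevation of the emulated mouse study.
#'
#' @return Named list of four [group_spec()] objects.
#' @export
default_groups <- function() {
  list(
    control = group_spec("control", 64.3, 6.1, 50.6, 6.9,
                         edema_extent_multiplier = 1, normal_mbf = 16.9,
                         n_animals = 6),
    IPC = group_spec("IPC", 59.8, 7.9, 27.9, 3.7,
                     edema_extent_multiplier = 0.85, normal_mbf = 16.9,
                     n_animals = 10),
    vehicle = group_spec("vehicle", 65.4, 7.0, 56.6, 13.6,
                         edema_extent_multiplier = 1, normal_mbf = 16.9,
                         n_animals = 7),
    CsA = group_spec("CsA", 58.0, 12.6, 38.6, 7.8,
                     edema_extent_multiplier = 1, normal_mbf = 28.9,
                     n_animals = 9)
  )
}
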