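#' Study configuration
#'
#' Bundles everything a full synthetic study needs: group specs, phantom
#' geometry, tissue parameters, acquisition metadata, ASL constants, noise
#' level, threshold settings and the global seed. Round-trips losslessly
#' through YAML via [write_study_config()] / [read_study_config()].
#'
#' @param groups Named list of [group_spec()]s.
#' @param phantom Base [phantom_config()] shared by all animals.
#' @param tissue [tissue_params()].
#' @param constants [asl_constants()].
#' @param t2_meta,asl_selective,asl_global Acquisition metadata.
#' @param noise List with `sd` (signal units) and `model`
#'   (`"gaussian"`/`"rician"`).
#' @param thresholds List with `k_aar`, `k_is`, `k_lge`, `min_cluster`,
#'   `min_roi_pixels`.
#' @param fit [fit_options()].
#' @param seed Global study seed.
#' @return An object of class `study_config`.
#' @export
study_config <- function(groups = default_groups(),
                         phantom = phantom_config(),
                         tissue = tissue_params(),
                         constants = asl_constants(),
                         t2_meta = acq_multi_echo_se(),
                         asl_selective = acq_look_locker("selective"),
                         asl_global = acq_look_locker("global"),
                         noise = list(sd = 5, model = "gaussian"),
                         thresholds = list(k_aar = 1, k_is = 2, k_lge = 5,
                                           min_cluster = 10, min_roi_pixels = 30),
                         fit = fit_options(),
                         seed = 1L) {
  def_thr <- list(k_aar = 1, k_is = 2, k_lge = 5, min_cluster = 10,
                  min_roi_pixels = 30)
  bad <- setdiff(names(thresholds), names(def_thr))
  if (length(bad)) stop("unknown key '", bad[1], "' in section 'thresholds'")
  thresholds <- utils::modifyList(def_thr, thresholds)
  bad <- setdiff(names(noise), c("sd", "model"))
  if (length(bad)) stop("unknown key '", bad[1], "' in section 'noise'")
  structure(list(groups = groups, phantom = phantom, tissue = tissue,
                 constants = constants, t2_meta = t2_meta,
                 asl_selective = asl_selective, asl_global = asl_global,
                 noise = noise, thresholds = thresholds, fit = fit,
                 seed = as.integer(seed)),
            class = "study_config")
}

# recursively strip classes so yaml serialises plain lists
.unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, .unclass_deep)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' Write / read a study configuration as YAML
#'
#' @param config A [study_config()].
#' @param path YAML file path.
#' @return `write_study_config` returns `path` invisibly;
#'   `read_study_config` returns a validated `study_config`.
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  yaml::write_yaml(.unclass_deep(config), path, precision = 15)
  invisible(path)
}

.rebuild <- function(fun, args, section) {
  known <- names(formals(fun))
  bad <- setdiff(names(args), known)
  if (length(bad)) stop("unknown key '", bad[1], "' in section '", section, "'")
  do.call(fun, args)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  need <- c("groups", "phantom", "tissue", "constants", "t2_meta",
            "asl_selective", "asl_global", "noise", "thresholds", "fit", "seed")
  bad <- setdiff(names(raw), need)
  if (length(bad)) stop("unknown key '", bad[1], "' in study config")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing key '", miss[1], "' in study config")
  groups <- lapply(names(raw$groups), function(nm) {
    .rebuild(group_spec, raw$groups[[nm]], paste0("groups/", nm))
  })
  names(groups) <- names(raw$groups)
  ll_args <- function(a) {
    a$n_points <- NULL; a$ti_range <- NULL   # implied by explicit ti_list_s
    a
  }
  study_config(
    groups = groups,
    phantom = .rebuild(phantom_config, raw$phantom, "phantom"),
    tissue = .rebuild(tissue_params, raw$tissue, "tissue"),
    constants = .rebuild(asl_constants, raw$constants, "constants"),
    t2_meta = .rebuild(acq_multi_echo_se,
                       raw$t2_meta[setdiff(names(raw$t2_meta), "modality")],
                       "t2_meta"),
    asl_selective = .rebuild(acq_look_locker,
                             ll_args(raw$asl_selective[setdiff(names(raw$asl_selective), "modality")]),
                             "asl_selective"),
    asl_global = .rebuild(acq_look_locker,
                          ll_args(raw$asl_global[setdiff(names(raw$asl_global), "modality")]),
                          "asl_global"),
    noise = raw$noise,
    thresholds = raw$thresholds,
    fit = .rebuild(fit_options, raw$fit, "fit"),
    seed = raw$seed
  )
}

#' Fit all parameter maps for one animal
#'
#' Pixel-wise T2 map over the myocardium, Look-Locker T1 maps for both
#' inversion scopes (the global map additionally covers the blood pool of the
#' normal-ROI slice so the blood input function can be measured), and the
#' blood-pool-input perfusion map.
#'
#' @param animal An `animal_dataset`.
#' @param fit [fit_options()].
#' @param blood_t1_from_roi Estimate blood T1 from the blood-pool ROI
#'   (default); otherwise the configured constant is used.
#' @return List of `parameter_map`s (`t2`, `t1_selective`, `t1_global`,
#'   `perfusion`) plus `blood_t1_s`.
#' @export
fit_animal <- function(animal, fit = fit_options(), blood_t1_from_roi = TRUE) {
  stopifnot(inherits(animal, "animal_dataset"))
  myo <- region_mask(animal$labels, "myocardium")
  nsl <- dim(myo)[3]
  roi_slice <- nsl - 1L
  blood_roi <- array(FALSE, dim(myo))
  blood_roi[, , roi_slice] <- region_mask(animal$labels, "blood")[, , roi_slice]

  t2 <- fit_t2_map(animal$stacks$t2, myo, fit)
  t1_sel <- fit_t1_map(animal$stacks$ir_selective, myo, fit)
  t1_glob <- fit_t1_map(animal$stacks$ir_global, myo | blood_roi, fit)
  blood_t1 <- if (blood_t1_from_roi) {
    estimate_blood_t1(t1_glob, blood_roi, default = animal$constants$t1_blood_s)
  } else {
    animal$constants$t1_blood_s
  }
  perf <- compute_perfusion_map(t1_sel, t1_glob, animal$constants,
                                t1_blood_s = blood_t1)
  list(t2 = t2, t1_selective = t1_sel, t1_global = t1_glob, perfusion = perf,
       blood_t1_s = blood_t1)
}

#' Regional metrics for one animal across all modalities
#'
#' Histology planimetry plus the SD-threshold metrics of every imaging
#' modality, with the phantom's ground truth alongside.
#'
#' @param animal An `animal_dataset`.
#' @param maps Output of [fit_animal()].
#' @param thresholds Threshold settings (see [study_config()]).
#' @return A one-row data frame.
#' @export
quantify_animal <- function(animal, maps,
                            thresholds = list(k_aar = 1, k_is = 2, k_lge = 5,
                                              min_cluster = 10,
                                              min_roi_pixels = 30)) {
  myo <- region_mask(animal$labels, "myocardium")
  roi_spec <- list(min_pixels = thresholds$min_roi_pixels)
  hist <- planimetry(animal$histology)
  t2m <- aar_from_t2(maps$t2, myo, roi_spec, k = thresholds$k_aar,
                     min_cluster = thresholds$min_cluster)
  asl <- aar_is_from_asl(maps$perfusion, myo, roi_spec,
                         k_aar = thresholds$k_aar, k_is = thresholds$k_is,
                         min_cluster = thresholds$min_cluster)
  t1m <- aar_from_t1(maps$t1_global, myo, roi_spec, k = thresholds$k_aar,
                     min_cluster = thresholds$min_cluster)
  lge <- delineate_lge(animal$stacks$lge, myo, roi_spec,
                       k_lge = thresholds$k_lge,
                       min_cluster = thresholds$min_cluster)
  data.frame(
    id = animal$id, group = animal$group, seed = animal$config$seed,
    hist_is_lv_pct = hist$is_lv_pct, hist_aar_lv_pct = hist$aar_lv_pct,
    hist_is_aar_pct = hist$is_aar_pct,
    lge_is_lv_pct = lge$is_lv_pct,
    t2_aar_lv_pct = t2m$aar_lv_pct,
    asl_aar_lv_pct = asl$aar_lv_pct, asl_is_lv_pct = asl$is_lv_pct,
    t1_aar_lv_pct = t1m$aar_lv_pct,
    t2_normal_mean = t2m$roi$mean, t2_normal_sd = t2m$roi$sd,
    asl_normal_mean = asl$roi$mean, asl_normal_sd = asl$roi$sd,
    t1_normal_mean = t1m$roi$mean, t1_normal_sd = t1m$roi$sd,
    blood_t1_s = maps$blood_t1_s,
    n_invalid_t2 = t2m$n_invalid, n_invalid_asl = asl$n_invalid,
    n_invalid_t1 = t1m$n_invalid,
    truth_aar_lv_pct = animal$truth$aar_lv_pct,
    truth_is_lv_pct = animal$truth$is_lv_pct,
    truth_is_aar_pct = animal$truth$is_aar_pct,
    stringsAsFactors = FALSE
  )
}

# modality/metric pairs compared against histology
.comparisons <- function() {
  data.frame(
    modality = c("LGE", "T2", "ASL_1SD", "ASL_2SD", "T1"),
    method_col = c("lge_is_lv_pct", "t2_aar_lv_pct", "asl_aar_lv_pct",
                   "asl_is_lv_pct", "t1_aar_lv_pct"),
    reference_col = c("hist_is_lv_pct", "hist_aar_lv_pct", "hist_aar_lv_pct",
                      "hist_is_lv_pct", "hist_aar_lv_pct"),
    metric = c("IS/LV%", "AAR/LV%", "AAR/LV%", "IS/LV%", "AAR/LV%"),
    stringsAsFactors = FALSE
  )
}

#' Agreement analysis of a metrics table
#'
#' Per group and per CMR modality: Bland-Altman agreement and paired t-test
#' against histology; across groups: one-way ANOVA with Bonferroni pairwise
#' comparisons of the histology AAR/LV%; plus group mean ± SD summaries.
#'
#' @param metrics Metrics data frame from [quantify_animal()] rows.
#' @return A list of class `study_comparison` with `agreement`, `anova`,
#'   `summary` and the Bland-Altman objects in `$bland_altman`.
#' @export
compare_metrics <- function(metrics) {
  cmp <- .comparisons()
  rows <- list(); bas <- list()
  for (g in unique(metrics$group)) {
    sub <- metrics[metrics$group == g, , drop = FALSE]
    if (nrow(sub) < 2) next
    for (i in seq_len(nrow(cmp))) {
      ref <- sub[[cmp$reference_col[i]]]
      met <- sub[[cmp$method_col[i]]]
      if (sum(is.finite(ref) & is.finite(met)) < 2) next
      ba <- bland_altman(ref, met, reference_label = "histology",
                         method_label = cmp$modality[i])
      tt <- paired_t(ref, met)
      key <- paste(g, cmp$modality[i], sep = "_")
      bas[[key]] <- ba
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, modality = cmp$modality[i], metric = cmp$metric[i],
        n = ba$n, bias = ba$bias, sd_diff = ba$sd_diff,
        loa_low = ba$loa_low, loa_high = ba$loa_high,
        t = tt$statistic, df = tt$df, p = tt$p, stringsAsFactors = FALSE)
    }
  }
  agreement <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group = character(), modality = character(), metric = character(),
               n = integer(), bias = numeric(), sd_diff = numeric(),
               loa_low = numeric(), loa_high = numeric(), t = numeric(),
               df = numeric(), p = numeric(), stringsAsFactors = FALSE)
  grps <- split(metrics$hist_aar_lv_pct, metrics$group)
  grps <- grps[vapply(grps, function(v) sum(is.finite(v)) >= 2, logical(1))]
  anova <- if (length(grps) >= 2) anova_bonferroni(grps) else NULL
  structure(list(agreement = agreement, anova = anova,
                 summary = if (nrow(metrics)) group_summary(metrics) else NULL,
                 bland_altman = bas),
            class = "study_comparison")
}

#' @export
print.study_comparison <- function(x, ...) {
  cat("<study_comparison>\n")
  if (nrow(x$agreement)) {
    print(x$agreement[, c("group", "modality", "metric", "n", "bias", "p")],
          digits = 3)
  }
  if (!is.null(x$anova)) {
    cat("Histology AAR/LV% across groups: ")
    print(x$anova$omnibus)
  }
  invisible(x)
}

#' Run the full synthetic study in memory
#'
#' Simulate the cohort, fit every animal's maps, quantify regional metrics
#' and compute the agreement statistics, all without touching disk.
#'
#' @param config A [study_config()].
#' @param progress Print one line per animal.
#' @return A list of class `study_result`: `cohort` manifest, `metrics`,
#'   `comparison`, and the `config` used.
#' @export
run_study <- function(config = study_config(), progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  cohort <- generate_cohort(
    groups = config$groups, base_config = config$phantom,
    params = config$tissue, constants = config$constants,
    noise_sd = config$noise$sd, noise_model = config$noise$model,
    t2_meta = config$t2_meta, asl_meta_selective = config$asl_selective,
    asl_meta_global = config$asl_global, seed = config$seed
  )
  rows <- vector("list", length(cohort$animals))
  for (i in seq_along(cohort$animals)) {
    an <- cohort$animals[[i]]
    if (progress) message("fitting ", an$id)
    maps <- fit_animal(an, config$fit)
    rows[[i]] <- quantify_animal(an, maps, config$thresholds)
  }
  metrics <- assemble_metrics(rows)
  comparison <- if (nrow(metrics)) compare_metrics(metrics) else NULL
  structure(list(manifest = cohort$manifest, metrics = metrics,
                 comparison = comparison, config = config),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d animals, seed %d\n", nrow(x$metrics),
              x$config$seed))
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}
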