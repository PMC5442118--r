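# On-disk study layout: one directory per animal under animals/, fitted maps
# under maps/, tables and plots at the cohort root. NIfTI is written
# uncompressed so reruns are byte-identical.

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

.read_json <- function(path) {
  if (!file.exists(path)) stop("missing sidecar: ", path)
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

# plain numeric array, shorn of niftiImage attributes
.nii_array <- function(path) {
  x <- as.array(RNifti::readNifti(path))
  array(as.vector(x), dim(x))
}

#' Write / read a simulated slice stack as NIfTI + JSON sidecar
#'
#' @param stack A `slice_stack`.
#' @param prefix File path without extension; writes `<prefix>.nii` and
#'   `<prefix>.json`.
#' @return The prefix (write) or a reconstructed `slice_stack` (read).
#' @export
write_stack <- function(stack, prefix) {
  stopifnot(inherits(stack, "slice_stack"))
  # single precision: ample for SNR-20 magnitude data, halves the footprint
  RNifti::writeNifti(stack$data, paste0(prefix, ".nii"), datatype = "float")
  .write_json(list(meta = .unclass_deep(stack$meta), noise = stack$noise),
              paste0(prefix, ".json"))
  invisible(prefix)
}

#' @rdname write_stack
#' @export
read_stack <- function(prefix) {
  nii <- paste0(prefix, ".nii")
  if (!file.exists(nii)) stop("missing image file: ", nii)
  side <- .read_json(paste0(prefix, ".json"))
  meta <- side$meta
  meta <- switch(meta$modality,
    multi_echo_se = acq_multi_echo_se(meta$te_list_ms, meta$slice_thickness_mm),
    look_locker_ir = acq_look_locker(
      inversion_scope = meta$inversion_scope, ti_list_s = meta$ti_list_s,
      flip_angle_deg = meta$flip_angle_deg, tr_rf_ms = meta$tr_rf_ms,
      tr_inv_s = meta$tr_inv_s, magnitude = isTRUE(meta$magnitude),
      slice_thickness_mm = meta$slice_thickness_mm),
    lge = acq_lge(meta$slice_thickness_mm),
    stop("unknown modality in sidecar: ", meta$modality)
  )
  dat <- .nii_array(nii)
  if (length(dim(dat)) == 3L) dim(dat) <- c(dim(dat), 1L)
  new_slice_stack(dat, meta, as.list(side$noise))
}

#' Write / read a fitted parameter map as NIfTI + JSON sidecar
#'
#' The values and the validity mask are written as images; units, quantity,
#' pixel accounting and any extra metadata (inversion scope, ASL constants)
#' go in the sidecar.
#'
#' @param map A `parameter_map`.
#' @param prefix Path without extension.
#' @return The prefix (write) or a `parameter_map` (read).
#' @export
write_map <- function(map, prefix) {
  stopifnot(inherits(map, "parameter_map"))
  vals <- map$values
  vals[!map$valid] <- 0
  RNifti::writeNifti(vals, paste0(prefix, ".nii"))
  RNifti::writeNifti(map$valid * 1L, paste0(prefix, "_valid.nii"))
  RNifti::writeNifti(map$analysis_mask * 1L, paste0(prefix, "_mask.nii"))
  .write_json(list(quantity = map$quantity, units = map$units,
                   n_valid = map$n_valid, n_invalid = map$n_invalid,
                   extra = map$extra),
              paste0(prefix, ".json"))
  invisible(prefix)
}

#' @rdname write_map
#' @export
read_map <- function(prefix) {
  side <- .read_json(paste0(prefix, ".json"))
  vals <- .nii_array(paste0(prefix, ".nii"))
  valid <- .nii_array(paste0(prefix, "_valid.nii")) > 0
  mask <- .nii_array(paste0(prefix, "_mask.nii")) > 0
  vals[!valid] <- NA_real_
  new_parameter_map(vals, valid, side$quantity, side$units,
                    analysis_mask = mask, extra = as.list(side$extra))
}

.write_labels <- function(labels, dir) {
  RNifti::writeNifti(labels$labels, file.path(dir, "labels.nii"))
  RNifti::writeNifti(labels$edema * 1L, file.path(dir, "edema.nii"))
  .write_json(list(lv_center = labels$lv_center, achieved = labels$achieved),
              file.path(dir, "labels.json"))
}

.read_labels <- function(dir) {
  lab <- .nii_array(file.path(dir, "labels.nii"))
  ede <- .nii_array(file.path(dir, "edema.nii")) > 0
  side <- .read_json(file.path(dir, "labels.json"))
  new_region_labels(lab, ede, side$lv_center, as.list(side$achieved))
}

#' Simulate a study cohort to disk
#'
#' Writes, per animal, every simulated acquisition (NIfTI + JSON sidecar),
#' the label and edema volumes, simulated histology and the ground truth;
#' plus the cohort manifest CSV and the resolved configuration YAML.
#' Deterministic for a given config, so reruns are byte-identical.
#'
#' @param config A [study_config()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
simulate_study <- function(config, dir) {
  stopifnot(inherits(config, "study_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(dir, 2) != 0) stop("output directory is not writable: ", dir)
  cohort <- generate_cohort(
    groups = config$groups, base_config = config$phantom,
    params = config$tissue, constants = config$constants,
    noise_sd = config$noise$sd, noise_model = config$noise$model,
    t2_meta = config$t2_meta, asl_meta_selective = config$asl_selective,
    asl_meta_global = config$asl_global, seed = config$seed
  )
  write_study_config(config, file.path(dir, "config.yaml"))
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  for (an in cohort$animals) {
    adir <- file.path(dir, "animals", an$id)
    dir.create(adir, showWarnings = FALSE, recursive = TRUE)
    write_stack(an$stacks$t2, file.path(adir, "t2"))
    write_stack(an$stacks$ir_selective, file.path(adir, "ir_selective"))
    write_stack(an$stacks$ir_global, file.path(adir, "ir_global"))
    write_stack(an$stacks$lge, file.path(adir, "lge"))
    .write_labels(an$labels, adir)
    RNifti::writeNifti(an$histology$labels, file.path(adir, "histology.nii"))
    .write_json(list(id = an$id, group = an$group, seed = an$config$seed,
                     truth = an$truth,
                     normal_mbf = an$params$remote$mbf),
                file.path(adir, "truth.json"))
  }
  invisible(dir)
}

# reconstruct an animal_dataset (sans tissue params) from its directory
.read_animal <- function(dir, config) {
  truth <- .read_json(file.path(dir, "truth.json"))
  labels <- .read_labels(dir)
  hist_lab <- .nii_array(file.path(dir, "histology.nii"))
  params <- config$tissue
  params$remote$mbf <- truth$normal_mbf
  structure(list(
    id = truth$id, group = truth$group,
    config = list(seed = truth$seed), params = params,
    constants = config$constants, labels = labels,
    histology = new_region_labels(hist_lab, lv_center = labels$lv_center,
                                  achieved = as.list(truth$truth)),
    stacks = list(t2 = read_stack(file.path(dir, "t2")),
                  ir_selective = read_stack(file.path(dir, "ir_selective")),
                  ir_global = read_stack(file.path(dir, "ir_global")),
                  lge = read_stack(file.path(dir, "lge"))),
    truth = as.list(truth$truth)
  ), class = "animal_dataset")
}

.animal_dirs <- function(dir) {
  root <- file.path(dir, "animals")
  if (!dir.exists(root)) stop("no animals/ directory under ", dir,
                              "; run simulate_study first")
  sort(list.dirs(root, recursive = FALSE))
}

#' Fit parameter maps for every animal of an on-disk study
#'
#' Reads each animal's stacks, fits T2/T1/perfusion maps and writes them under
#' `maps/<id>/` with a per-animal fit log. Animals whose maps are already
#' complete are skipped unless `force = TRUE`.
#'
#' @param dir Study directory from [simulate_study()].
#' @param force Refit even if outputs exist.
#' @return Invisibly, the vector of animal ids processed (fitted or skipped).
#' @export
fit_study <- function(dir, force = FALSE) {
  config <- read_study_config(file.path(dir, "config.yaml"))
  ids <- character()
  for (adir in .animal_dirs(dir)) {
    id <- basename(adir)
    mdir <- file.path(dir, "maps", id)
    done <- file.path(mdir, "fit_log.csv")
    if (file.exists(done) && !force) { ids <- c(ids, id); next }
    an <- .read_animal(adir, config)
    maps <- fit_animal(an, config$fit)
    dir.create(mdir, showWarnings = FALSE, recursive = TRUE)
    write_map(maps$t2, file.path(mdir, "t2_map"))
    write_map(maps$t1_selective, file.path(mdir, "t1_selective"))
    write_map(maps$t1_global, file.path(mdir, "t1_global"))
    write_map(maps$perfusion, file.path(mdir, "perfusion"))
    log <- data.frame(
      map = c("t2", "t1_selective", "t1_global", "perfusion"),
      n_valid = c(maps$t2$n_valid, maps$t1_selective$n_valid,
                  maps$t1_global$n_valid, maps$perfusion$n_valid),
      n_invalid = c(maps$t2$n_invalid, maps$t1_selective$n_invalid,
                    maps$t1_global$n_invalid, maps$perfusion$n_invalid),
      blood_t1_s = maps$blood_t1_s)
    utils::write.csv(log, done, row.names = FALSE)
    ids <- c(ids, id)
  }
  invisible(ids)
}

#' Quantify regional metrics for an on-disk study
#'
#' Reads fitted maps, labels and histology for every animal and writes the
#' assembled metrics table to `metrics.csv`.
#'
#' @param dir Study directory (after [fit_study()]).
#' @return The metrics data frame, invisibly.
#' @export
quantify_study <- function(dir) {
  config <- read_study_config(file.path(dir, "config.yaml"))
  rows <- list()
  for (adir in .animal_dirs(dir)) {
    id <- basename(adir)
    mdir <- file.path(dir, "maps", id)
    if (!file.exists(file.path(mdir, "fit_log.csv"))) {
      stop("maps missing for animal ", id, "; run fit_study first")
    }
    an <- .read_animal(adir, config)
    log <- utils::read.csv(file.path(mdir, "fit_log.csv"))
    maps <- list(t2 = read_map(file.path(mdir, "t2_map")),
                 t1_selective = read_map(file.path(mdir, "t1_selective")),
                 t1_global = read_map(file.path(mdir, "t1_global")),
                 perfusion = read_map(file.path(mdir, "perfusion")),
                 blood_t1_s = log$blood_t1_s[1])
    rows[[length(rows) + 1L]] <- quantify_animal(an, maps, config$thresholds)
  }
  metrics <- assemble_metrics(rows)
  utils::write.csv(metrics, file.path(dir, "metrics.csv"), row.names = FALSE)
  invisible(metrics)
}

#' Agreement report for an on-disk study
#'
#' Reads `metrics.csv`, computes the per-group Bland-Altman/paired-t
#' comparisons and the across-group ANOVA, and writes `agreement.csv`,
#' `anova_pairwise.csv`, `group_summary.csv` and one Bland-Altman PNG per
#' group and modality under `plots/`.
#'
#' @param dir Study directory (after [quantify_study()]).
#' @param plots Write PNG panels.
#' @return The `study_comparison`, invisibly.
#' @export
compare_study <- function(dir, plots = TRUE) {
  mpath <- file.path(dir, "metrics.csv")
  if (!file.exists(mpath)) stop("metrics.csv not found; run quantify_study first")
  metrics <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  if (nrow(metrics) == 0) {
    utils::write.csv(data.frame(), file.path(dir, "agreement.csv"),
                     row.names = FALSE)
    return(invisible(NULL))
  }
  cmpr <- compare_metrics(metrics)
  utils::write.csv(cmpr$agreement, file.path(dir, "agreement.csv"),
                   row.names = FALSE)
  if (!is.null(cmpr$anova)) {
    utils::write.csv(cmpr$anova$pairwise, file.path(dir, "anova_pairwise.csv"),
                     row.names = FALSE)
  }
  if (!is.null(cmpr$summary)) {
    utils::write.csv(cmpr$summary, file.path(dir, "group_summary.csv"),
                     row.names = FALSE)
  }
  if (plots && length(cmpr$bland_altman)) {
    pdir <- file.path(dir, "plots")
    dir.create(pdir, showWarnings = FALSE)
    for (key in names(cmpr$bland_altman)) {
      grDevices::png(file.path(pdir, paste0(key, ".png")),
                     width = 600, height = 450)
      plot(cmpr$bland_altman[[key]], main = key)
      grDevices::dev.off()
    }
  }
  invisible(cmpr)
}

#' Run all four study stages on disk
#'
#' `simulate_study` then [fit_study()], [quantify_study()] and
#' [compare_study()] in sequence.
#'
#' @param config A [study_config()].
#' @param dir Output directory.
#' @param plots Write Bland-Altman PNG panels.
#' @return The `study_comparison`, invisibly.
#' @export
run_study_dir <- function(config, dir, plots = TRUE) {
  simulate_study(config, dir)
  fit_study(dir)
  quantify_study(dir)
  compare_study(dir, plots = plots)
}
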