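# Truncated-normal draw by rejection; bounds are open. Used for per-animal
# ground-truth fractions so phantoms stay geometrically realisable.
.rtruncnorm1 <- function(mean, sd, lo, hi) {
  if (sd == 0) return(min(max(mean, lo), hi))
  for (i in 1:10000) {
    x <- stats::rnorm(1, mean, sd)
    if (x > lo && x < hi) return(x)
  }
  stop("truncated-normal sampling failed; check group spec against bounds")
}

#' Generate a seeded synthetic cohort
#'
#' For each animal: samples ground-truth AAR/LV and IS/AAR fractions from its
#' group distributions (truncated to (0.05, 0.95) and to the geometric
#' capacity of the AAR slice span), builds the phantom, simulates all
#' acquisitions (multi-echo T2, Look-Locker IR under both inversion scopes,
#' LGE) and histology, and records ground truth. Per-animal seeds are derived
#' deterministically from the cohort seed, so identical calls are
#' bit-identical.
#'
#' @param groups List of [group_spec()] objects (default [default_groups()]).
#' @param base_config [phantom_config()] shared by all animals (per-animal
#'   fractions and seeds are overridden).
#' @param params [tissue_params()]; each group's `normal_mbf` replaces the
#'   remote perfusion value.
#' @param constants [asl_constants()].
#' @param noise_sd Acquisition noise SD in signal units (default SNR 20 at the
#'   remote equilibrium signal); `0` gives a noiseless cohort.
#' @param noise_model `"gaussian"` or `"rician"`.
#' @param asl_meta_selective,asl_meta_global,t2_meta Acquisition metadata.
#' @param seed Cohort seed.
#' @return An object of class `phantom_cohort`: a list of `animal_dataset`
#'   objects plus a manifest data frame.
#' @export
generate_cohort <- function(groups = default_groups(),
                            base_config = phantom_config(),
                            params = tissue_params(),
                            constants = asl_constants(),
                            noise_sd = params$remote$S0 / 20,
                            noise_model = "gaussian",
                            t2_meta = acq_multi_echo_se(),
                            asl_meta_selective = acq_look_locker("selective"),
                            asl_meta_global = acq_look_locker("global"),
                            seed = 1L) {
  stopifnot(inherits(base_config, "phantom_config"))
  for (g in groups) {
    if (!inherits(g, "group_spec")) stop("groups must be group_spec objects")
  }
  n_total <- sum(vapply(groups, function(g) g$n_animals, integer(1)))
  animals <- vector("list", n_total)
  set.seed(seed)
  animal_seeds <- if (n_total > 0) {
    sample.int(.Machine$integer.max - 8L, n_total)
  } else integer(0)

  # geometric capacity of the AAR span as a fraction of all myocardium
  geom <- make_geometry(base_config)
  n_myo <- sum(region_mask(geom, "myocardium"))
  cap <- sum(apply(geom$labels, 3, function(sl)
    sum(sl >= REGION_CODES[["remote"]]))[base_config$aar_slice_span]) / n_myo
  lo <- 0.05; hi <- min(0.95, cap)

  k <- 0L
  for (g in groups) {
    for (a in seq_len(g$n_animals)) {
      k <- k + 1L
      aar_f <- .rtruncnorm1(g$aar_mean_pct / 100, g$aar_sd_pct / 100, lo, hi)
      is_f <- .rtruncnorm1(g$isaar_mean_pct / 100, g$isaar_sd_pct / 100, 0.05, 0.95)
      cfg <- phantom_config(
        matrix_size = base_config$matrix_size, n_slices = base_config$n_slices,
        lv_center = base_config$lv_center, r_outer = base_config$r_outer,
        r_inner = base_config$r_inner, aar_fraction = aar_f,
        is_fraction_of_aar = is_f, aar_slice_span = base_config$aar_slice_span,
        edema_extent_multiplier = g$edema_extent_multiplier,
        seed = animal_seeds[k]
      )
      p <- params
      p$remote$mbf <- g$normal_mbf
      p <- tissue_params(p$remote, p$aar_salvaged, p$infarct, p$blood)
      animals[[k]] <- simulate_animal(
        id = sprintf("%s_%02d", g$name, a), group = g$name, config = cfg,
        params = p, constants = constants, noise_sd = noise_sd,
        noise_model = noise_model, t2_meta = t2_meta,
        asl_meta_selective = asl_meta_selective, asl_meta_global = asl_meta_global
      )
    }
  }
  manifest <- if (n_total > 0) {
    do.call(rbind, lapply(animals, function(an) {
      data.frame(id = an$id, group = an$group, seed = an$config$seed,
                 truth_aar_lv_pct = an$truth$aar_lv_pct,
                 truth_is_lv_pct = an$truth$is_lv_pct,
                 truth_is_aar_pct = an$truth$is_aar_pct,
                 normal_mbf = an$params$remote$mbf,
                 edema_extent = an$config$edema_extent_multiplier,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(id = character(), group = character(), seed = integer(),
               truth_aar_lv_pct = numeric(), truth_is_lv_pct = numeric(),
               truth_is_aar_pct = numeric(), normal_mbf = numeric(),
               edema_extent = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(animals = animals, manifest = manifest, seed = seed,
                 constants = constants,
                 noise = list(model = noise_model, sd = noise_sd)),
            class = "phantom_cohort")
}

#' Simulate one complete animal dataset
#'
#' @param id,group Animal identifier and group name.
#' @param config [phantom_config()] carrying the animal's true fractions and seed.
#' @inheritParams generate_cohort
#' @return An object of class `animal_dataset`.
#' @export
simulate_animal <- function(id, group, config, params = tissue_params(),
                            constants = asl_constants(),
                            noise_sd = params$remote$S0 / 20,
                            noise_model = "gaussian",
                            t2_meta = acq_multi_echo_se(),
                            asl_meta_selective = acq_look_locker("selective"),
                            asl_meta_global = acq_look_locker("global")) {
  labels <- make_phantom_labels(config)
  s <- config$seed
  stacks <- list(
    t2 = simulate_t2_series(labels, params, t2_meta, noise_sd, seed = s,
                            noise_model = noise_model),
    ir_selective = simulate_ir_series(labels, params, asl_meta_selective,
                                      constants, noise_sd, seed = s + 1L,
                                      noise_model = noise_model),
    ir_global = simulate_ir_series(labels, params, asl_meta_global,
                                   constants, noise_sd, seed = s + 2L,
                                   noise_model = noise_model),
    lge = simulate_lge_image(labels, params, noise_sd, seed = s + 3L,
                             noise_model = noise_model)
  )
  truth <- labels$achieved
  structure(list(id = id, group = group, config = config, params = params,
                 constants = constants, labels = labels,
                 histology = simulate_histology(labels),
                 stacks = stacks, truth = truth),
            class = "animal_dataset")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d animals, seed %d, noise %s sd %.3g\n",
              length(x$animals), x$seed, x$noise$model, x$noise$sd))
  if (nrow(x$manifest)) print(table(x$manifest$group))
  invisible(x)
}

#' @export
print.animal_dataset <- function(x, ...) {
  cat(sprintf("<animal_dataset> %s (%s): truth AAR/LV %.1f%%, IS/AAR %.1f%%\n",
              x$id, x$group, x$truth$aar_lv_pct, x$truth$is_aar_pct))
  invisible(x)
}
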