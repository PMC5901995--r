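#' Default analysis configuration
#'
#' One source of truth for every tunable: the printed constants of the study
#' design are the defaults (decay rates 0.002 and 1.55 per metre, 10
#' available steps, the 40- and 20-location minima, species stationary
#' thresholds, independence-cluster spans, the 200-m pack rule, 100-m buffer,
#' 100 cross-validation reps, 1000 bootstrap replicates at alpha 0.05).
#' Configurations round-trip losslessly through YAML.
#'
#' @param ... overrides of individual entries.
#' @return named list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    species = "wolf", sex = NULL, season = NULL,
    rarefy_interval_h = NULL, rarefy_tolerance_min = 5,
    stationary = list(wolf = list(radius_m = 300, min_duration_h = 6),
                      bear = list(radius_m = 100, min_duration_h = 7)),
    cluster_gap_h = list(wolf = 120, bear = 24),
    pack_radius_m = 200,
    min_locs_ssf = 40, min_locs_rate = 20,
    k_available = 10,
    edist_rate = 0.002, ewam_rate = 1.55,
    lt_ta_threshold = 0.115,
    screen_r_max = 0.6, screen_vif_max = 3,
    cv_reps = 100, cv_train_frac = 0.8,
    buffer_m = 100,
    n_boot = 1000, alpha = 0.05,
    seed = 1L)
  over <- list(...)
  cfg[names(over)] <- over
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Write / read a configuration as YAML
#' @param config a [default_config()] list.
#' @param path YAML file path.
#' @return `path` invisibly (write); a `run_config` (read).
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  base[names(cfg)] <- cfg
  base
}

prepare_steps <- function(fixes, config) {
  species <- config$species
  counts <- list(n_fixes = nrow(fixes))
  fixes <- fixes[fixes$species == species, , drop = FALSE]
  if (!is.null(config$sex))
    fixes <- fixes[fixes$sex %in% config$sex, , drop = FALSE]
  if (!nrow(fixes)) stop("no fixes for the requested species/sex")
  counts$n_fixes_species <- nrow(fixes)
  st <- config$stationary[[species]]
  steps_by_animal <- lapply(split(fixes, fixes$animal_id), function(tr) {
    tr <- tr[order(tr$t), , drop = FALSE]
    if (!is.null(config$rarefy_interval_h))
      tr <- rarefy(tr, config$rarefy_interval_h, config$rarefy_tolerance_min)
    lab <- classify_stationary(tr, st$radius_m, st$min_duration_h)
    s <- build_steps(tr, states = lab)
    if (nrow(s))
      s$cluster <- paste0(s$animal_id[1], "_",
                          assign_clusters(s$t_start,
                                          config$cluster_gap_h[[species]]))
    s
  })
  steps <- do.call(rbind, steps_by_animal[vapply(steps_by_animal, nrow, 0) > 0])
  rownames(steps) <- NULL
  counts$n_movement_steps <- nrow(steps)
  if (!is.null(config$season))
    steps <- steps[steps$season %in% config$season, , drop = FALSE]
  if (species == "wolf") {
    steps <- filter_pack_correlated(steps, config$pack_radius_m,
                                    seed = config$seed)
    counts$n_pack_correlated_removed <- attr(steps, "n_removed")
  }
  list(steps = steps, counts = counts)
}

#' Run the broad-scale step-selection analysis end to end
#'
#' Orchestrates: species/sex filtering, optional rarefaction, stationary
#' classification, step building, pack decorrelation (wolves), the 40-location
#' inclusion filter, independence clustering, the length/turn-angle
#' correlation gate, used/available stratum construction, collinearity
#' screening, QIC_U competition of the candidate models on the pooled strata,
#' per-individual refits of the winner pooled by inverse-variance weighting,
#' and rank-frequency k-fold cross-validation. Deterministic under a fixed
#' `config$seed`; every exclusion is counted in the manifest.
#'
#' @param fixes fix data frame (or path to a fix CSV).
#' @param segments attributed `line_segments` edge table (or a
#'   `seismic_landscape`).
#' @param config a [default_config()] list.
#' @param models candidate formulas (default [ssf_model_set()]).
#' @param out_dir optional directory; when given, the QIC table, population
#'   coefficients, CV summary and manifest are written as CSV/JSON.
#' @param extent study-area rectangle for reflecting available endpoints
#'   (taken from the landscape when one is passed as `segments`).
#' @param cov_index optional [covariate_index()] forwarded to
#'   [build_strata()].
#' @return list of class `ssf_run`: `qic_table`, `best_model`, `population`,
#'   `cv`, `fits`, `strata`, `screen`, `manifest`.
#' @export
run_ssf_analysis <- function(fixes, segments, config = default_config(),
                             models = ssf_model_set(), out_dir = NULL,
                             extent = NULL, cov_index = NULL) {
  if (is.character(fixes)) fixes <- read_fixes_csv(fixes)
  if (inherits(segments, "seismic_landscape")) {
    if (is.null(extent)) extent <- segments$extent
    segments <- segments$segments
  }
  prep <- prepare_steps(fixes, config)
  steps <- prep$steps
  counts <- prep$counts
  filt <- apply_inclusion_filters(steps, config$min_locs_ssf)
  steps <- filt$steps
  counts$n_after_inclusion <- nrow(steps)
  rho <- check_lt_ta_correlation(steps, config$lt_ta_threshold)
  strata <- build_strata(steps, segments, K = config$k_available,
                         seed = config$seed,
                         edist_rate = config$edist_rate, extent = extent,
                         cov_index = cov_index)
  counts$n_strata <- length(unique(strata$stratum))
  counts$n_strata_skipped <- attr(strata, "n_skipped")
  counts$n_clusters <- length(unique(strata$cluster))
  scr <- screen_collinearity(
    strata[strata$used == 0, c("eDist", "Veght", "eWAM", "Density")],
    config$screen_r_max, config$screen_vif_max)
  usable <- vapply(models, function(f) {
    all(all.vars(f) %in% c("used", "fLand", scr$keep))
  }, TRUE)
  models <- models[usable]
  fits <- lapply(models, function(f)
    fit_clogit(f, strata, strata = "stratum", weights = "weight",
               cluster = "cluster"))
  qic <- qicu_select(fits)
  best <- qic$model[1]
  # per-individual refits of the winning model, pooled across animals
  ind_fits <- lapply(split(strata, strata$animal_id), function(d) {
    tryCatch(fit_clogit(models[[best]], d, strata = "stratum",
                        weights = "weight", cluster = "cluster"),
             error = function(e) structure(list(converged = FALSE),
                                           class = "clogit_fit"))
  })
  pop <- population_average(ind_fits)
  cv <- kfold_cv(models[[best]], strata, strata = "stratum",
                 reps = config$cv_reps, train_frac = config$cv_train_frac,
                 seed = config$seed, weights = "weight")
  manifest <- list(config = unclass(config), counts = counts,
                   lt_ta_rho = as.numeric(rho),
                   screened_out = scr$dropped,
                   models_fit = names(models), best_model = best)
  res <- structure(list(qic_table = qic, best_model = best,
                        population = pop, cv = cv, fits = fits,
                        individual_fits = ind_fits, strata = strata,
                        screen = scr, manifest = manifest),
                   class = "ssf_run")
  if (!is.null(out_dir)) write_ssf_artifacts(res, out_dir)
  res
}

write_ssf_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$qic_table, file.path(out_dir, "qic_table.csv"),
                   row.names = FALSE)
  utils::write.csv(res$population$table,
                   file.path(out_dir, "population_coefficients.csv"),
                   row.names = FALSE)
  cv <- res$cv
  utils::write.csv(
    data.frame(statistic = c("rs1_mean", "rs1_min", "rs1_max",
                             "rs0_mean", "rs0_min", "rs0_max"),
               value = c(cv$rs1_mean, cv$rs1_range, cv$rs0_mean,
                         cv$rs0_range)),
    file.path(out_dir, "cv_summary.csv"), row.names = FALSE)
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' @export
print.ssf_run <- function(x, ...) {
  cat("Step-selection analysis\n")
  cat(sprintf("  best model: %s (QIC_U weight %.3f)\n", x$best_model,
              x$qic_table$weight[1]))
  print(x$population)
  cat(sprintf("  k-fold CV: mean r_s1 %.3f, mean r_s0 %.3f\n",
              x$cv$rs1_mean, x$cv$rs0_mean))
  invisible(x)
}

#' Run the fine-scale movement-rate analysis end to end
#'
#' Orchestrates: step preparation (as in [run_ssf_analysis()]), the 100-m
#' buffer and 20-location inclusion filter, random-structure choice
#' (individual vs individual within pack, by AICc), AICc competition of the
#' candidate fixed structures, and — when the winning model retains the
#' vegetation-height term — post-hoc hinge regression of log rate on
#' `log(Veght + 1)` with a case-resampling bootstrap CI, the breakpoint
#' reported in metres of vegetation height.
#'
#' @param fixes fix data frame (or path to a fix CSV).
#' @param segments attributed `line_segments` edge table (or landscape).
#' @param config a [default_config()] list.
#' @param models candidate fixed structures (default [rate_model_set()]).
#' @param posthoc_subset optional logical-index function applied to the rate
#'   data frame to select the season/landcover slice for the hinge fit
#'   (default: forested observations).
#' @param out_dir optional artifact directory.
#' @return list of class `rate_run`: `aicc_table`, `best_model`, `best_fit`,
#'   `breakpoint` (NULL when the winner has no height term), `data`,
#'   `manifest`.
#' @export
run_rate_analysis <- function(fixes, segments, config = default_config(),
                              models = rate_model_set(),
                              posthoc_subset = function(d) d$fFor == 1,
                              out_dir = NULL) {
  if (is.character(fixes)) fixes <- read_fixes_csv(fixes)
  if (inherits(segments, "seismic_landscape")) segments <- segments$segments
  prep <- prepare_steps(fixes, config)
  counts <- prep$counts
  rd <- build_rate_dataset(prep$steps, segments,
                           max_distance = config$buffer_m,
                           min_per_season = config$min_locs_rate)
  counts$n_within_buffer <- rd$n_within_buffer
  counts$n_rate_obs <- nrow(rd$data)
  # random structure: individual vs individual nested in pack, by AICc
  random <- "individual"
  if (length(unique(rd$data$group)) > 1) {
    f0 <- fit_rate_lmm(models[[1]], rd$data, random = "individual")
    f1 <- tryCatch(
      fit_rate_lmm(models[[1]], rd$data, random = "individual_in_group"),
      error = function(e) NULL)
    if (!is.null(f1) && f1$aicc < f0$aicc) random <- "individual_in_group"
  }
  sel <- select_rate_model(rd$data, models, random = random)
  best <- sel$table$model[1]
  best_fit <- sel$fits[[best]]
  bp <- NULL
  if ("log_veght" %in% all.vars(best_fit$fixed)) {
    sub <- rd$data[posthoc_subset(rd$data), , drop = FALSE]
    if (nrow(sub) >= 20) {
      pw <- piecewise_fit(sub$log_veght, sub$log_rate)
      ci <- bootstrap_breakpoint_ci(pw, n_boot = config$n_boot,
                                    alpha = config$alpha,
                                    seed = config$seed)
      bp <- list(breakpoint_m = expm1(pw$breakpoint),
                 ci_m = expm1(ci$ci),
                 ci_halfwidth_m = diff(expm1(ci$ci)) / 2,
                 slope_left = unname(pw$coefficients["slope_left"]),
                 slope_right = unname(pw$coefficients["slope_right"]),
                 n = pw$n, n_boot = ci$n_boot, fit = pw)
    }
  }
  manifest <- list(config = unclass(config), counts = counts,
                   random_structure = random, best_model = best,
                   exclusions = rd$report[!rd$report$retained, ])
  res <- structure(list(aicc_table = sel$table, best_model = best,
                        best_fit = best_fit, fits = sel$fits,
                        breakpoint = bp, data = rd$data,
                        manifest = manifest),
                   class = "rate_run")
  if (!is.null(out_dir)) write_rate_artifacts(res, out_dir)
  res
}

write_rate_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$aicc_table, file.path(out_dir, "aicc_table.csv"),
                   row.names = FALSE)
  utils::write.csv(res$best_fit$coefficients,
                   file.path(out_dir, "coefficients.csv"), row.names = FALSE)
  if (!is.null(res$breakpoint)) {
    bp <- res$breakpoint
    jsonlite::write_json(
      list(breakpoint_m = bp$breakpoint_m, ci_m = bp$ci_m,
           ci_halfwidth_m = bp$ci_halfwidth_m,
           slope_left = bp$slope_left, slope_right = bp$slope_right,
           n = bp$n, n_boot = bp$n_boot),
      file.path(out_dir, "breakpoint.json"), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  invisible(out_dir)
}

#' @export
print.rate_run <- function(x, ...) {
  cat("Movement-rate analysis\n")
  cat(sprintf("  best model: %s (AICc weight %.3f, random: %s)\n",
              x$best_model, x$aicc_table$weight[1],
              x$manifest$random_structure))
  if (!is.null(x$breakpoint))
    cat(sprintf("  breakpoint: %.3f m (95%% CI %.3f-%.3f m)\n",
                x$breakpoint$breakpoint_m, x$breakpoint$ci_m[1],
                x$breakpoint$ci_m[2]))
  invisible(x)
}
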