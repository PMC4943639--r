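# End-to-end driver: configuration, multi-animal study simulation, the full
# cluster -> home range -> table -> model -> cross-validation -> functional
# response pipeline, and report I/O.

#' Simulate a multi-animal feeding-site study
#'
#' Generates one track per animal over the landscape, assigns sexes, and
#' plants feeding clusters under known sex-specific selection coefficients
#' using a single landscape-wide standardization so the same coefficient
#' vector applies to every animal.
#'
#' @param ls a \code{"landscape"}.
#' @param n_animals number of monitored animals.
#' @param frac_male fraction of males (default 0.6, as in a male-biased
#'   collared sample).
#' @param days monitoring days per animal.
#' @param beta_true named coefficients of the female selection model (on
#'   the standardized scale).
#' @param sex_effects named coefficients added for males (sex
#'   interactions); default none.
#' @param kills_per_animal number of feeding sites per animal (recycled).
#' @param seed integer seed.
#' @param dstack optional precomputed \code{\link{distance_stack}}.
#' @return List: \code{fixes} (all animals), \code{metadata} (animal_id,
#'   sex_male), \code{truth} (per-animal planting truth), \code{scaling}
#'   (the shared standardization), \code{beta_true}, \code{sex_effects}.
#' @export
simulate_study <- function(ls, n_animals = 8, frac_male = 0.6, days = 40,
                           beta_true = c(d_developed = -1, d_riparian = 0.7,
                                         elevation = -0.9, slope = 0.25),
                           sex_effects = NULL, kills_per_animal = 12,
                           seed = 1L, dstack = NULL) {
  covnames <- union(names(beta_true), names(sex_effects))
  if (is.null(dstack))
    dstack <- distance_stack(ls, intersect(covnames, names(.covariate_names())))
  # landscape-wide scaling shared by all animals
  X <- vapply(covnames, function(nm) {
    lay <- if (nm == "elevation") ls$elevation
           else if (nm == "slope") ls$slope else dstack[[nm]]
    as.vector(lay)
  }, numeric(ls$n_rows * ls$n_cols))
  scaling <- data.frame(covariate = covnames, mean = colMeans(X),
                        sd = apply(X, 2, stats::sd), row.names = NULL)
  n_male <- round(frac_male * n_animals)
  sex <- rep(c(1L, 0L), c(n_male, n_animals - n_male))
  kills <- rep_len(kills_per_animal, n_animals)
  fixes <- list(); truth <- list()
  for (i in seq_len(n_animals)) {
    aid <- sprintf("P%02d", i)
    trk <- generate_track(ls, animal_config(animal_id = aid), days = days,
                          seed = seed * 1000L + i)
    b <- beta_true
    if (sex[i] == 1L && length(sex_effects)) {
      add <- stats::setNames(rep(0, length(covnames)), covnames)
      add[names(beta_true)] <- beta_true
      add[names(sex_effects)] <- add[names(sex_effects)] + sex_effects
      b <- add
    } else {
      b0 <- stats::setNames(rep(0, length(covnames)), covnames)
      b0[names(beta_true)] <- beta_true
      b <- b0
    }
    pl <- plant_feeding_clusters(trk, ls, b, n_kills = kills[i],
                                 seed = seed * 1000L + 500L + i,
                                 dstack = dstack, scaling = scaling)
    fixes[[i]] <- pl$track
    truth[[aid]] <- pl$truth
  }
  list(fixes = do.call(rbind, fixes),
       metadata = data.frame(animal_id = sprintf("P%02d", seq_len(n_animals)),
                             sex_male = sex),
       truth = truth, scaling = scaling,
       beta_true = beta_true, sex_effects = sex_effects)
}

#' Pipeline configuration
#'
#' Every tunable constant of the analysis in one place.  The defaults are
#' the study conventions: 50 m chaining radius, 2 night fixes, 24 h span,
#' 18:00-06:00 night window, 150 m availability spacing, 0.5 correlation
#' threshold, 5-fold cross-validation with 10 bins, and a 5-site minimum
#' for functional-response proportions.
#'
#' @param ... overrides for the keys listed above; unknown keys are
#'   rejected.
#' @return A list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    # synthetic-data mode
    synthetic = TRUE, n_animals = 8, days = 40, frac_male = 0.6,
    kills_per_animal = 12,
    beta_true = c(d_developed = -1, d_riparian = 0.7,
                  elevation = -0.9, slope = 0.25),
    sex_effects = NULL,
    landscape = landscape_config(),
    # user-data mode
    telemetry_path = NULL, metadata_path = NULL, landscape_dir = NULL,
    output_dir = NULL,
    # cluster detection
    cluster_radius_m = 50, min_night = 2, min_span_h = 24,
    night_window = c(18, 6),
    # availability
    spacing_m = 150, isopleth = 100,
    # modeling
    covariates = c("d_chaparral", "d_riparian", "d_upland", "d_prairie",
                   "d_water", "d_trail", "d_developed", "d_altered_open",
                   "d_coastal_sage", "elevation", "slope"),
    screen_threshold = 0.5,
    screen_priority = c("elevation", "slope", "d_developed", "d_altered_open",
                        "d_trail", "d_chaparral", "d_riparian", "d_upland",
                        "d_prairie", "d_water", "d_coastal_sage"),
    interaction_candidates = NULL,   # NULL = all retained covariates
    retain_level = 0.85, support_threshold = 5,
    cv_k = 5, cv_bins = 10,
    # functional response
    fr_features = c("d_developed", "d_altered_open"), min_sites = 5,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  structure(defaults, class = "pipeline_config")
}

#' Run the full feeding-site resource-selection pipeline
#'
#' Executes, in order: night classification, cluster detection, feeding
#' sites, a-LoCoH home ranges, distance rasters, use-availability table,
#' correlation screen, Gelman standardization, the model ladder (null /
#' main effects / all sex interactions / reduced interactions), AIC
#' comparison, k-fold cross-validation of the best model, per-sex
#' prediction maps, and functional responses for developed and altered-open
#' areas.  Every decision (exclusions, retained interactions, seeds) is
#' recorded in the returned report.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param quiet suppress progress messages.
#' @return A list of class \code{"rsf_report"} with the fitted objects
#'   (\code{fits}, \code{cv}, \code{functional_responses}, \code{maps}) and
#'   a JSON-serializable \code{report}.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (isTRUE(config$synthetic)) {
    say("* generating synthetic landscape and telemetry")
    ls <- stage("landscape", generate_landscape(config$landscape, config$seed))
    sim <- stage("simulate", simulate_study(
      ls, n_animals = config$n_animals, frac_male = config$frac_male,
      days = config$days, beta_true = config$beta_true,
      sex_effects = config$sex_effects,
      kills_per_animal = config$kills_per_animal, seed = config$seed))
    fixes <- sim$fixes; metadata <- sim$metadata
  } else {
    say("* reading user data")
    ls <- stage("landscape", read_landscape(config$landscape_dir))
    fixes <- stage("telemetry", read_telemetry(config$telemetry_path,
                                               config$night_window))
    metadata <- stage("metadata", read_metadata(config$metadata_path))
    sim <- NULL
  }
  fixes <- stage("classify_night", classify_night(fixes, config$night_window))
  say("* detecting feeding-site clusters")
  clusters <- stage("detect_clusters", detect_clusters(
    fixes, radius_m = config$cluster_radius_m, min_night = config$min_night,
    min_span_h = config$min_span_h))
  sites <- stage("feeding_sites", clusters_to_feeding_sites(clusters))
  say("* estimating a-LoCoH home ranges (", nrow(sites), " sites)")
  ranges <- stage("home_ranges", estimate_home_ranges(
    fixes, isopleth = config$isopleth))
  say("* building use-availability table")
  dstack <- stage("distance_rasters", distance_stack(ls))
  table <- stage("build_table", build_table(sites, ranges, ls, metadata,
                                            spacing_m = config$spacing_m,
                                            dstack = dstack))
  say("* screening covariates")
  covs <- intersect(config$covariates, names(table))
  scr <- stage("correlation_screen", correlation_screen(
    table, covs, threshold = config$screen_threshold,
    priority = config$screen_priority))
  retained <- scr$retained
  std <- stage("standardize", standardize_gelman(table))
  say("* fitting the model ladder")
  cand <- config$interaction_candidates
  if (is.null(cand)) cand <- retained
  cand <- intersect(cand, retained)
  fits <- list()
  fits$null <- stage("fit_null", rsf_fit(std, retained, null_model = TRUE))
  fits$main_effects <- stage("fit_main", rsf_fit(std, retained))
  two_sexes <- length(unique(metadata$sex_male)) > 1L
  if (two_sexes) {
    fits$all_interactions <- stage("fit_all_int",
                                   rsf_fit(std, retained, cand))
    red <- stage("reduce_interactions",
                 reduce_interactions(fits$all_interactions,
                                     config$retain_level))
    if (length(red$interactions) &&
        length(red$interactions) < length(cand)) {
      fits$reduced_interactions <- stage("fit_reduced",
        rsf_fit(std, retained, red$interactions))
    }
  } else red <- list(interactions = character(0))
  comparison <- stage("compare_aic", compare_aic(fits, config$support_threshold))
  best_name <- comparison$model[1]
  best <- fits[[best_name]]
  say("* cross-validating the best model (", best_name, ")")
  cv <- stage("kfold_cv", kfold_cv(std, best$covariates, best$interactions,
                                   k = config$cv_k, n_bins = config$cv_bins,
                                   seed = config$seed))
  say("* predicting relative probability of use")
  maps <- list()
  maps$female <- stage("predict_map_f", predict_map(best, ls, dstack, 0))
  if (two_sexes)
    maps$male <- stage("predict_map_m", predict_map(best, ls, dstack, 1))
  say("* functional responses")
  fr <- list()
  for (feat in config$fr_features) {
    props <- stage(paste0("aggregate_", feat),
                   aggregate_animals(table, feat, config$min_sites))
    if (nrow(props) >= 6) {
      f <- stage(paste0("fit_beta_", feat), fit_beta_fr(props))
      attr(f, "props") <- props
      fr[[feat]] <- f
    } else {
      say("  (", feat, ": only ", nrow(props),
          " animals above the site threshold; skipping fit)")
      fr[feat] <- list(NULL)
    }
  }
  report <- list(
    config = list(cluster_radius_m = config$cluster_radius_m,
                  min_night = config$min_night,
                  min_span_h = config$min_span_h,
                  spacing_m = config$spacing_m,
                  screen_threshold = config$screen_threshold,
                  cv_k = config$cv_k, cv_bins = config$cv_bins,
                  min_sites = config$min_sites, seed = config$seed),
    n_fixes = nrow(fixes), n_clusters = nrow(clusters),
    n_sites = nrow(sites), n_ranges = length(ranges),
    range_area_km2 = vapply(ranges, function(r) r$area_km2, numeric(1)),
    n_rows_table = nrow(table),
    screened_out = scr$excluded,
    retained_covariates = retained,
    retained_interactions = red$interactions,
    model_comparison = as.data.frame(comparison),
    best_model = best_name,
    coefficients = lapply(fits, function(f)
      list(beta = as.list(f$beta),
           ci95 = apply(f$ci[["95"]], 1, as.list),
           aic = f$aic)),
    selection = if (length(best$covariates)) infer_selection(best) else NULL,
    cv = list(k = cv$k, bin_frequencies = cv$bin_frequencies,
              spearman_r = cv$spearman_r),
    functional_responses = lapply(fr, function(f) if (is.null(f)) NULL else
      list(edf = f$edf, chi_sq = f$chi_sq, p_value = f$p_value,
           deviance_explained = f$deviance_explained, linear = f$linear)))
  out <- list(landscape = ls, fixes = fixes, clusters = clusters,
              sites = sites, ranges = ranges, table = table, fits = fits,
              comparison = comparison, cv = cv, maps = maps,
              functional_responses = fr, truth = if (!is.null(sim)) sim$truth,
              sim = sim, report = report)
  class(out) <- "rsf_report"
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(report, file.path(config$output_dir, "report.json"))
  }
  out
}

#' @export
print.rsf_report <- function(x, ...) {
  r <- x$report
  cat("Feeding-site RSF pipeline report\n")
  cat(sprintf("  %d fixes -> %d clusters -> %d feeding sites; %d home ranges\n",
              r$n_fixes, r$n_clusters, r$n_sites, r$n_ranges))
  cat(sprintf("  table: %d rows; retained covariates: %s\n", r$n_rows_table,
              paste(r$retained_covariates, collapse = ", ")))
  cat(sprintf("  best model: %s; CV r_s = %.2f\n", r$best_model,
              r$cv$spearman_r))
  for (nm in names(r$functional_responses)) {
    f <- r$functional_responses[[nm]]
    if (!is.null(f))
      cat(sprintf("  functional response %s: chi-sq %.2f, P = %.3g, edf %.1f\n",
                  nm, f$chi_sq, f$p_value, f$edf))
  }
  invisible(x)
}

#' Read animal metadata (sex table)
#'
#' @param path CSV with columns \code{animal_id} and \code{sex_male}
#'   (0 female / 1 male) or \code{sex} (F/M).
#' @return \code{data.frame} with \code{animal_id}, \code{sex_male}.
#' @export
read_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"animal_id" %in% names(df))
    stop("metadata file missing column: animal_id")
  if (!"sex_male" %in% names(df)) {
    if ("sex" %in% names(df)) {
      df$sex_male <- as.integer(toupper(substr(df$sex, 1, 1)) == "M")
    } else stop("metadata file missing column: sex_male (or sex)")
  }
  if (!all(df$sex_male %in% c(0, 1)))
    stop("sex_male must be 0 or 1")
  df[, c("animal_id", "sex_male")]
}

#' Write / read a pipeline report as JSON
#' @param report the \code{report} element of a \code{\link{run_pipeline}}
#'   result (any JSON-serializable list).
#' @param path output file.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = 10,
                       force = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
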