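#' Analysis configuration
#'
#' Collects every tunable parameter of the pipeline so a run is fully
#' described (and reproducible from) one object; the configuration and its
#' hash are embedded in all outputs.
#'
#' @param threshold_minutes Independence threshold for events (minutes).
#' @param anchor Event-chaining anchor, see [build_events()].
#' @param mass_edges Body-mass class edges (kg), see
#'   [assign_body_mass_class()].
#' @param transform Response transformation for the mixed model.
#' @param covariates Candidate covariate columns for BIC selection
#'   (empty = fit the base model only).
#' @param max_exhaustive,allow_quadratic Search bounds, see
#'   [select_model()].
#' @param sensitivity_thresholds Thresholds (minutes) for the event-count
#'   sensitivity table.
#' @param habituation_window Days analysed by [habituation_test()].
#' @param status_interval_h Scheduled status-photo interval (hours).
#' @param keep_indet Retain unidentifiable records, see [load_photos()].
#' @param n_mc,seed Multivariate-t adjustment settings, see [mvt_adjust()].
#' @return A list of class `ctp_config`.
#' @export
run_config <- function(threshold_minutes = 10,
                       anchor = "last_photo",
                       mass_edges = c(1, 10, 30, 100),
                       transform = c("identity", "log1p"),
                       covariates = character(),
                       max_exhaustive = 2,
                       allow_quadratic = TRUE,
                       sensitivity_thresholds = c(10, 30, 60, 1440),
                       habituation_window = 68,
                       status_interval_h = 12,
                       keep_indet = FALSE,
                       n_mc = 1e5,
                       seed = 1L) {
  transform <- match.arg(transform)
  structure(
    list(
      threshold_minutes = threshold_minutes, anchor = anchor,
      mass_edges = mass_edges, transform = transform,
      covariates = covariates, max_exhaustive = max_exhaustive,
      allow_quadratic = allow_quadratic,
      sensitivity_thresholds = sensitivity_thresholds,
      habituation_window = habituation_window,
      status_interval_h = status_interval_h,
      keep_indet = keep_indet, n_mc = n_mc, seed = as.integer(seed)
    ),
    class = "ctp_config"
  )
}

#' Read a configuration from a YAML file
#'
#' @param path YAML file whose keys match [run_config()] arguments.
#' @return A `ctp_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(run_config)))
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(run_config, vals)
}

analysis_levels <- c("all", "body_mass_class", "iucn", "taxon")

#' Run the full paired camera-trap analysis
#'
#' Orchestrates the pipeline: validate inputs, collapse photos into
#' independent detection events, compute sampling effort, derive encounter
#' rates at every grouping level, fit the nested mixed models (with BIC
#' covariate selection when candidates are configured), estimate
#' multivariate-t adjusted certification contrasts and FSC:non-FSC ratios,
#' compute the biomass index and its paired test, the hunting-sign test,
#' the threshold-sensitivity table, and the habituation check.
#'
#' @param photos Photo table or CSV path.
#' @param deployments Deployment table or CSV path.
#' @param traits Trait table or CSV path.
#' @param config A [run_config()].
#' @return A list of class `ctp_results` with elements `config`,
#'   `config_hash`, `disposition`, `events`, `effort`, `rates` (camera- and
#'   concession-level tables per grouping level), `sensitivity`, `fits`,
#'   `selection` (when covariates were searched), `ratios` (one
#'   `ctp_contrasts` per analysis level), `biomass`, `biomass_test`,
#'   `hunting_test`, `habituation`.
#' @export
run_pipeline <- function(photos, deployments, traits, config = run_config()) {
  stopifnot(inherits(config, "ctp_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  traits <- stage("ingest", load_traits(traits, config$mass_edges))
  deployments <- stage("ingest", load_deployments(deployments))
  photos <- stage("ingest", load_photos(photos, traits, keep_indet = config$keep_indet))

  events <- stage("events", build_events(photos, config$threshold_minutes, config$anchor))
  effort <- stage("events", compute_effort(deployments, photos, config$status_interval_h))
  sensitivity <- stage(
    "events",
    sensitivity_table(photos, traits, config$sensitivity_thresholds, config$anchor)
  )

  rates <- list()
  for (lv in c(analysis_levels, "species")) {
    rates[[paste0(lv, "_concession")]] <- stage(
      "rates", encounter_rate(events, effort, traits, lv, unit = "concession")
    )
  }
  cov_cols <- intersect(config$covariates, names(deployments))
  for (lv in analysis_levels) {
    cam <- stage("rates", encounter_rate(events, effort, traits, lv, unit = "camera"))
    if (length(cov_cols) > 0) {
      cam <- dplyr::left_join(
        cam, dplyr::select(deployments, "camera_id", dplyr::all_of(cov_cols)),
        by = "camera_id"
      )
    }
    rates[[paste0(lv, "_camera")]] <- cam
  }

  base_spec <- lmm_spec(transform = config$transform)
  fits <- list(); ratios <- list(); selection <- list()
  for (lv in analysis_levels) {
    cam <- rates[[paste0(lv, "_camera")]]
    if (length(cov_cols) > 0) {
      sel <- stage("inference", select_model(
        cam, cov_cols, base_spec,
        max_exhaustive = config$max_exhaustive,
        allow_quadratic = config$allow_quadratic
      ))
      selection[[lv]] <- sel$bic_table
      fits[[lv]] <- sel$best_fit
    } else {
      fits[[lv]] <- stage("inference", fit_lmm(cam, base_spec))
    }
    ratios[[lv]] <- stage("inference", certification_ratios(
      fits[[lv]], n_mc = config$n_mc, seed = config$seed
    ))
  }

  biomass <- stage("rates", biomass_proxy(rates$species_concession, traits))
  biomass_test <- stage(
    "paired_tests",
    wilcoxon_signed_rank(pair_values(biomass, "biomass_index"))
  )
  hunting <- stage("paired_tests", hunting_sign_test(deployments))
  habituation <- stage(
    "paired_tests",
    habituation_test(daily_counts(events, deployments), config$habituation_window)
  )

  out <- list(
    config = config,
    config_hash = config_hash(unclass(config)),
    disposition = attr(photos, "disposition"),
    events = events,
    effort = effort,
    sensitivity = sensitivity,
    rates = rates,
    fits = fits,
    selection = if (length(selection)) selection,
    ratios = ratios,
    biomass = biomass,
    biomass_test = biomass_test,
    hunting_test = hunting,
    habituation = habituation
  )
  class(out) <- "ctp_results"
  out
}

#' @export
print.ctp_results <- function(x, ...) {
  cat("Paired camera-trap analysis (config ", substr(x$config_hash, 1, 8), ")\n", sep = "")
  cat(" ", nrow(x$events), "independent detections from",
      nrow(x$effort), "cameras;",
      round(sum(x$effort$active_days)), "camera-days of effort\n")
  for (lv in names(x$ratios)) {
    r <- x$ratios[[lv]]
    cat("  FSC:non-FSC ratios (", lv, "): ",
        paste0(r$group, " = ", round(r$ratio, 1), collapse = ", "), "\n", sep = "")
  }
  cat("  hunting-sign test p =", signif(x$hunting_test$p.value, 3),
      "| biomass test p =", signif(x$biomass_test$p.value, 3), "\n")
  invisible(x)
}

#' Write the result bundle to disk
#'
#' Writes tidy CSV tables (each prefixed with a comment line carrying the
#' configuration hash), and a machine-readable JSON summary with the
#' configuration, ratio tables and test results.
#'
#' @param results A [run_pipeline()] bundle.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir) {
  stopifnot(inherits(results, "ctp_results"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hash_line <- paste0("# camtrappair config_hash=", results$config_hash)
  emit <- function(df, name) {
    path <- file.path(dir, paste0(name, ".csv"))
    writeLines(hash_line, path)
    readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  }
  emit(results$events, "events")
  emit(results$effort, "effort")
  emit(results$sensitivity, "sensitivity")
  for (nm in names(results$rates)) emit(results$rates[[nm]], paste0("rates_", nm))
  for (nm in names(results$ratios)) {
    emit(tibble::as_tibble(results$ratios[[nm]]), paste0("ratios_", nm))
  }
  if (!is.null(results$selection)) {
    for (nm in names(results$selection)) emit(results$selection[[nm]], paste0("bic_", nm))
  }
  emit(results$biomass, "biomass")
  emit(results$hunting_test, "hunting_test")
  emit(results$habituation, "habituation")

  summary <- list(
    config = unclass(results$config),
    config_hash = results$config_hash,
    n_events = nrow(results$events),
    total_effort_days = sum(results$effort$active_days),
    ratios = purrr::map(results$ratios, tibble::as_tibble),
    biomass_test = results$biomass_test,
    hunting_test = results$hunting_test,
    habituation = results$habituation
  )
  jsonlite::write_json(
    summary, file.path(dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}
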