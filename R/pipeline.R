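# Orchestration: a run configuration (paths, thresholds, MCMC settings,
# seed) and staged execution with deterministic artifact paths and a
# structured log. Stage outputs are pure functions of (inputs, config,
# seed): re-running with the same seed gives byte-identical CSVs.

#' Run configuration
#'
#' @param fixes,metadata,regions Input paths (fixes CSV, metadata CSV,
#'   regions GeoJSON). `NULL` fixes/metadata mean "simulate them".
#' @param out_dir Output directory for artifacts.
#' @param stopover_km,min_duration_days,cycle_gap_h,uncertainty_max_days,wa_sahara_uncertainty_days
#'   Segmentation and milestone thresholds (defaults 50 km, 1 day, 10 h,
#'   5 days, 2 days).
#' @param sim A [sim_config()] used by the simulate stage.
#' @param mcmc [mcmc_settings()].
#' @param seed Integer seed, mandatory for stochastic stages.
#' @return A validated `run_config` list.
#' @export
run_config <- function(fixes = NULL, metadata = NULL,
                       regions = default_regions_path(),
                       out_dir = tempfile("migrapath_run_"),
                       stopover_km = 50, min_duration_days = 1,
                       cycle_gap_h = 10, uncertainty_max_days = 5,
                       wa_sahara_uncertainty_days = 2,
                       sim = sim_config(seed = seed), mcmc = mcmc_settings(seed = seed),
                       seed = 1L) {
  cfg <- list(fixes = fixes, metadata = metadata, regions = regions,
              out_dir = out_dir, stopover_km = stopover_km,
              min_duration_days = min_duration_days, cycle_gap_h = cycle_gap_h,
              uncertainty_max_days = uncertainty_max_days,
              wa_sahara_uncertainty_days = wa_sahara_uncertainty_days,
              sim = sim, mcmc = mcmc, seed = as.integer(seed))
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  for (f in c("stopover_km", "min_duration_days", "cycle_gap_h",
              "uncertainty_max_days", "wa_sahara_uncertainty_days")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) {
      stop("run_config field '", f, "' must be a positive number")
    }
  }
  if (is.null(cfg$seed) || is.na(cfg$seed)) stop("run_config: seed is mandatory")
  if (!is.null(cfg$regions) && !file.exists(cfg$regions)) {
    stop("regions file not found: ", cfg$regions)
  }
  invisible(cfg)
}

#' Read / write a run configuration as YAML
#' @param path YAML file path.
#' @return For `read_run_config`, a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  mcmc_args <- y$mcmc %||% list()
  y$sim <- NULL; y$mcmc <- NULL
  args <- y
  args$seed <- as.integer(y$seed %||% 1L)
  sim_args <- sim_args[intersect(names(sim_args), names(formals(sim_config)))]
  mcmc_args <- mcmc_args[intersect(names(mcmc_args),
                                   names(formals(mcmc_settings)))]
  sim_args$seed <- args$seed
  mcmc_args$seed <- args$seed
  args$sim <- do.call(sim_config, sim_args)
  args$mcmc <- do.call(mcmc_settings, mcmc_args)
  args <- args[intersect(names(args), names(formals(run_config)))]
  do.call(run_config, args)
}

#' @rdname read_run_config
#' @param cfg A `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  out <- cfg
  out$sim <- cfg$sim[setdiff(names(cfg$sim), c("dag", "mortality_logit"))]
  out$mcmc <- cfg$mcmc
  yaml::write_yaml(out, path)
  invisible(path)
}

log_stage <- function(verbose, stage, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, paste0(..., collapse = "")))
}

#' Run the pipeline
#'
#' Stages: `simulate` (synthetic cohort), `segment` (cycles + stopovers),
#' `milestones` (extraction, uncertainty, datasets, routes),
#' `repeatability` (per-milestone variance-components fits), `path-timing`
#' (timing path model on dates and anomalies), `path-mortality`
#' (per-milestone and combined mortality fits), `report` (summary tables),
#' or `all`. Artifacts are written under `cfg$out_dir` with fixed names.
#'
#' @param stage One of the stage names above.
#' @param cfg A [run_config()].
#' @param verbose Log stage progress.
#' @return Invisibly, a list of in-memory results per stage run.
#' @export
run_pipeline <- function(stage = "all", cfg = run_config(), verbose = TRUE) {
  stages <- c("simulate", "segment", "milestones", "repeatability",
              "path-timing", "path-mortality", "report", "all")
  if (!stage %in% stages) stop("unknown stage: ", stage)
  validate_run_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  want <- function(s) stage %in% c(s, "all")
  regions <- read_regions(cfg$regions)

  if (want("simulate") || (is.null(cfg$fixes) && stage != "simulate")) {
    log_stage(verbose, "simulate", "generating synthetic cohort (seed ",
              cfg$seed, ")")
    cohort <- simulate_cohort(cfg$sim)
    write_fixes(cohort$fixes, file.path(cfg$out_dir, "fixes.csv"))
    utils::write.csv(cohort$meta, file.path(cfg$out_dir, "metadata.csv"),
                     row.names = FALSE)
    utils::write.csv(
      dplyr::mutate(cohort$truth, dplyr::across(dplyr::where(is.numeric),
                                                ~ round(.x, 6))),
      file.path(cfg$out_dir, "truth.csv"), row.names = FALSE)
    res$cohort <- cohort
    log_stage(verbose, "simulate", nrow(cohort$fixes), " fixes, ",
              nrow(cohort$truth), " bird-years")
  }
  if (stage == "simulate") return(invisible(res))

  fixes <- if (!is.null(res$cohort)) res$cohort$fixes else read_fixes(cfg$fixes)
  meta <- if (!is.null(res$cohort)) res$cohort$meta else
    tibble::as_tibble(utils::read.csv(cfg$metadata))

  seg <- segment_track(fixes, cfg$cycle_gap_h, cfg$stopover_km,
                       cfg$min_duration_days,
                       cfg$sim$duty_on_hours, cfg$sim$duty_off_hours)
  utils::write.csv(
    dplyr::select(seg$stopovers, "bird_id", "start", "end", "lat", "lon",
                  "n_cycles", "gap_extended"),
    file.path(cfg$out_dir, "stopovers.csv"), row.names = FALSE)
  res$segmentation <- seg
  log_stage(verbose, "segment", nrow(seg$best_fixes), " cycles -> ",
            nrow(seg$stopovers), " stopovers")
  if (stage == "segment") return(invisible(res))

  ms <- extract_milestones(seg$stopovers, seg$best_fixes, regions, meta)
  routes <- classify_routes(seg$best_fixes, regions)
  ds <- build_datasets(ms, cfg$uncertainty_max_days)
  utils::write.csv(
    ms |> dplyr::mutate(retained = !is.na(.data$uncertainty_days) &
                          .data$uncertainty_days <= cfg$uncertainty_max_days),
    file.path(cfg$out_dir, "milestones.csv"), row.names = FALSE)
  res$milestones <- ms; res$datasets <- ds; res$routes <- routes
  log_stage(verbose, "milestones", nrow(ds$full), " milestones from ",
            dplyr::n_distinct(paste(ds$full$bird_id, ds$full$cycle_id)),
            " migratory cycles for ",
            dplyr::n_distinct(ds$full$bird_id), " birds retained (",
            nrow(ms) - nrow(ds$full), " excluded)")
  if (stage == "milestones") return(invisible(res))

  if (want("repeatability")) {
    fits <- list()
    for (k in MILESTONE_KINDS) {
      d <- ds$full[ds$full$kind == k, ]
      if (dplyr::n_distinct(d$bird_id) >= 2 &&
          any(table(d$bird_id) >= 2)) {
        fits[[k]] <- fit_variance_components(d$cycle_day, d$bird_id, cfg$mcmc)
      }
    }
    rsum <- repeatability_summary(fits)
    utils::write.csv(rsum, file.path(cfg$out_dir, "repeatability.csv"),
                     row.names = FALSE)
    res$repeatability <- list(fits = fits, summary = rsum)
    log_stage(verbose, "repeatability", "mean R = ",
              round(attr(rsum, "mean_R"), 3),
              "; all Rhat < 1.1: ", all(rsum$converged))
    if (stage == "repeatability") return(invisible(res))
  }

  if (want("path-timing")) {
    dat <- path_data_from_milestones(ds$full, meta, routes)
    fit <- fit_path_model(dat, cfg$sim$dag, cfg$mcmc)
    utils::write.csv(fit$edges, file.path(cfg$out_dir, "path_timing_edges.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summarize_paths(fit),
                         file.path(cfg$out_dir, "path_timing.json"),
                         auto_unbox = TRUE, digits = NA)
    res$path_timing <- fit
    log_stage(verbose, "path-timing", sum(fit$edges$p_nonzero >= 0.8),
              " supported edges; converged: ", fit$converged)
    if (stage == "path-timing") return(invisible(res))
  }

  if (want("path-mortality")) {
    deaths <- if (!is.null(res$cohort)) {
      deaths_from_truth(res$cohort$truth, start_year = cfg$sim$start_year)
    } else {
      tibble::tibble(bird_id = character(), cycle_id = integer(),
                     kind = character(), certain = logical())
    }
    rec <- build_mortality_dataset(ds$full, deaths, meta)
    fits <- list()
    for (k in setdiff(unique(rec$kind), "depart_winter")) {
      rk <- rec[rec$kind == k, ]
      if (nrow(rk) >= 10) {
        fits[[k]] <- suppressWarnings(fit_mortality_model(rk, cfg$mcmc))
      }
    }
    comb_rec <- rec[rec$kind %in% c("complete_sahara_south",
                                    "depart_west_africa", "arrive_breeding"), ]
    comb <- if (nrow(comb_rec) >= 10) {
      suppressWarnings(combined_milestones_fit(comb_rec, cfg$mcmc))
    }
    res$path_mortality <- list(records = rec, fits = fits, combined = comb)
    log_stage(verbose, "path-mortality", nrow(rec), " records, ",
              sum(rec$died), " deaths")
    if (stage == "path-mortality") return(invisible(res))
  }

  if (want("report")) {
    rep_tab <- if (!is.null(res$repeatability)) res$repeatability$summary
    path_tab <- if (!is.null(res$path_timing)) summarize_paths(res$path_timing)
    report <- list(
      milestone_counts = ds$full |> dplyr::count(.data$kind),
      n_milestones = nrow(ds$full),
      n_cycles = dplyr::n_distinct(paste(ds$full$bird_id, ds$full$cycle_id)),
      n_birds = dplyr::n_distinct(ds$full$bird_id),
      repeatability = rep_tab,
      supported_paths = path_tab)
    jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    res$report <- report
  }
  invisible(res)
}

#' Build the path-model data table from retained milestones
#'
#' One row per bird-cycle with standardized milestone dates and exogenous
#' covariates (habitat and route coded 0/1 then standardized; coordinates
#' standardized). Unobserved milestones become `NA`, ready for the
#' imputation-aware sampler. The last-European-stopover latitude and
#' West-African-stopover longitude covariates are taken from the basis
#' locations of the Sahara-crossing and West-Africa-departure milestones.
#'
#' @param milestones Retained milestone tibble.
#' @param meta Bird metadata.
#' @param routes Output of [classify_routes()] (optional; `route` from
#'   `meta` is used for cycles it does not cover).
#' @param anomaly Use within-individual anomalies instead of dates (repeat
#'   dataset).
#' @return Standardized tibble with one column per DAG node plus ids.
#' @export
path_data_from_milestones <- function(milestones, meta, routes = NULL,
                                      anomaly = FALSE) {
  val <- if (anomaly) {
    within_individual_anomaly(milestones) |>
      dplyr::select("bird_id", "cycle_id", "kind", value = "anomaly_days")
  } else {
    dplyr::select(milestones, "bird_id", "cycle_id", "kind",
                  value = "cycle_day")
  }
  wide <- val |>
    tidyr::pivot_wider(names_from = "kind", values_from = "value")
  for (k in MILESTONE_KINDS) if (!k %in% names(wide)) wide[[k]] <- NA_real_
  covs <- milestones |>
    dplyr::filter(.data$kind %in% c("complete_sahara_south", "depart_west_africa")) |>
    dplyr::mutate(what = ifelse(.data$kind == "complete_sahara_south",
                                "euro_stopover_lat", "wa_stopover_lon"),
                  coord = ifelse(.data$kind == "complete_sahara_south",
                                 .data$basis_lat, .data$basis_lon)) |>
    dplyr::select("bird_id", "cycle_id", "what", "coord") |>
    tidyr::pivot_wider(names_from = "what", values_from = "coord")
  for (k in c("euro_stopover_lat", "wa_stopover_lon")) {
    if (!k %in% names(covs)) covs[[k]] <- NA_real_
  }
  dat <- wide |>
    dplyr::left_join(covs, by = c("bird_id", "cycle_id")) |>
    dplyr::left_join(meta |> dplyr::select("bird_id", "habitat", "route",
                                           "breeding_lat", "breeding_lon"),
                     by = "bird_id")
  if (!is.null(routes)) {
    dat <- dat |>
      dplyr::left_join(dplyr::rename(routes, route_cycle = "route"),
                       by = c("bird_id", "cycle_id")) |>
      dplyr::mutate(route = dplyr::coalesce(
        dplyr::na_if(.data$route_cycle, "unclassified"), .data$route)) |>
      dplyr::select(-"route_cycle")
  }
  dat <- dat |>
    dplyr::mutate(habitat = as.numeric(.data$habitat == "upland"),
                  route = as.numeric(.data$route == "SW"))
  standardize(dat, c(MILESTONE_KINDS, "habitat", "route", "breeding_lat",
                     "breeding_lon", "euro_stopover_lat", "wa_stopover_lon"))
}
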