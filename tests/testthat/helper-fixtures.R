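# Shared fixtures, built once per test run. All synthetic, all seeded.

regions_fixture <- default_regions()

# A clean cohort: no positional noise, no missed cycles, no mortality.
clean_cfg <- sim_config(n_birds = 15, n_years = 2, p_missed_cycle = 0,
                        fix_noise_km = 0, seed = 301)
clean_cohort <- simulate_cohort(clean_cfg)
clean_seg <- segment_track(clean_cohort$fixes)
clean_ms <- extract_milestones(clean_seg$stopovers, clean_seg$best_fixes,
                               regions_fixture, clean_cohort$meta)

truth_long <- function(cohort, start_year = 2015L) {
  cohort$truth |>
    dplyr::select("bird_id", "year", dplyr::starts_with("date_")) |>
    tidyr::pivot_longer(dplyr::starts_with("date_"), names_to = "kind",
                        values_to = "true_day", names_prefix = "date_") |>
    dplyr::mutate(cycle_id = start_year + .data$year - 1L) |>
    dplyr::filter(!is.na(.data$true_day))
}

# Standardized node table straight from simulator truth (no tracking noise),
# for sampler-oracle tests.
truth_node_table <- function(truth) {
  zc <- paste0("z_", migrapath:::MILESTONE_KINDS)
  dat <- truth[, c(zc, "z_habitat", "z_route", "z_breeding_lat",
                   "z_breeding_lon", "z_euro_stopover_lat", "z_wa_stopover_lon")]
  names(dat) <- sub("^z_", "", names(dat))
  dat
}

fast_mcmc <- function(seed = 1L) {
  mcmc_settings(chains = 2, burnin = 400, draws = 800, seed = seed)
}

# Hand-built fix tibble helper
make_fixes <- function(bird_id, hours, lat, lon, lc = "3",
                       origin = as.POSIXct("2015-06-01", tz = "UTC")) {
  tibble::tibble(bird_id = bird_id, t = origin + hours * 3600,
                 lat = lat, lon = lon, lc = lc)
}
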