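# Synthetic-data generator: true annual schedules from a linear-Gaussian
# DAG with per-bird random intercepts, stage-wise Bernoulli mortality, and
# duty-cycled satellite tracks rendered along great-circle corridors.
#
# Milestones are generated on a standardized latent scale (every node has
# unit marginal variance, so the configured edge coefficients ARE the true
# standardized path coefficients) and mapped to dates as
# date = mean_days + sd_days * z, in cycle time: continuous days since
# 1 June of the cycle's starting year, so all six milestones are monotone
# within a cycle and never wrap at New Year.

# Per-milestone date scale (days since 1 June; SD in days). Means give a
# staged cycle: depart breeding early July, cross the Sahara mid August,
# winter arrival mid October, winter departure mid February, leave West
# Africa mid April, arrive back early May. SDs echo the observed pattern of
# most variance at winter arrival and a sharp minimum at West Africa
# departure.
MILESTONE_SCALE <- tibble::tibble(
  kind = MILESTONE_KINDS,
  mean_days = c(30, 75, 135, 255, 315, 340),
  sd_days = c(12, 14, 25, 22, 9, 10)
)

#' Configuration for the synthetic cohort
#'
#' @param n_birds,n_years Cohort size and number of annual cycles.
#' @param duty_on_hours,duty_off_hours Tag duty cycle (default 10 h
#'   transmitting, 48 h charging).
#' @param p_missed_cycle Probability that a whole transmission cycle is
#'   missed (no fixes received).
#' @param fix_noise_km Isotropic Gaussian positional noise SD, km.
#' @param flight_speed_kmh Great-circle cruise speed between stopovers.
#' @param dag A [dag_spec()] with true `beta` coefficients
#'   (default [default_timing_dag()]).
#' @param sigma_between Named numeric: per-milestone SD (days) of the bird
#'   random intercept, setting true repeatability. `NULL` derives it from
#'   `target_repeatability`.
#' @param target_repeatability Fraction of each milestone's residual (non
#'   parent-explained) variance placed between birds when `sigma_between`
#'   is `NULL`.
#' @param mortality_logit Tibble with columns `stage` (1-6), `intercept`,
#'   `slope`: per-stage log-odds of death after milestone `stage` as
#'   `intercept + slope * z` where `z` is the standardized true date of that
#'   milestone. Default intercepts -50 (no mortality), slopes 0.
#' @param seed Integer seed; every stochastic stage is derived from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_birds = 60, n_years = 3,
                       duty_on_hours = 10, duty_off_hours = 48,
                       p_missed_cycle = 0.05, fix_noise_km = 1,
                       flight_speed_kmh = 50,
                       dag = default_timing_dag(),
                       sigma_between = NULL,
                       target_repeatability = 0.35,
                       mortality_logit = tibble::tibble(
                         stage = 1:6, intercept = -50, slope = 0),
                       seed = 1L) {
  stopifnot(n_birds >= 1, n_years >= 1,
            p_missed_cycle >= 0, p_missed_cycle <= 1,
            fix_noise_km >= 0, flight_speed_kmh >= 0,
            duty_on_hours + duty_off_hours > 0,
            target_repeatability >= 0, target_repeatability < 1)
  if (!inherits(dag, "dag_spec")) stop("dag must be a dag_spec")
  if (!is.null(sigma_between)) {
    stopifnot(all(MILESTONE_KINDS %in% names(sigma_between)),
              all(sigma_between >= 0))
  }
  structure(list(
    n_birds = n_birds, n_years = n_years,
    duty_on_hours = duty_on_hours, duty_off_hours = duty_off_hours,
    p_missed_cycle = p_missed_cycle, fix_noise_km = fix_noise_km,
    flight_speed_kmh = flight_speed_kmh, dag = dag,
    sigma_between = sigma_between,
    target_repeatability = target_repeatability,
    mortality_logit = tibble::as_tibble(mortality_logit),
    start_year = 2015L, seed = as.integer(seed)
  ), class = "sim_config")
}

# Exogenous covariate scales used to map standardized draws to natural units.
EXO_SCALE <- list(
  breeding_lat = c(mean = 53.5, sd = 2.0),
  breeding_lon = c(mean = -2.0, sd = 2.2),
  euro_stopover_lat = c(mean = 40.0, sd = 1.6),
  wa_stopover_lon = c(mean = -2.0, sd = 3.0)
)

#' Simulate true annual schedules from the configured DAG
#'
#' Each bird-year's six milestone dates are a linear combination of the
#' DAG parents (on the standardized scale) plus a per-bird random intercept
#' and residual noise. Residual variances are solved so that every
#' milestone has unit marginal variance, making the configured edge
#' coefficients true standardized path coefficients. Mortality is then
#' applied stage-wise ([simulate_mortality()]); a dead bird contributes no
#' later cycles and no milestones after its death stage.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per bird-year: identifiers, covariates
#'   (natural and standardized), the six true milestone dates in cycle days
#'   (`NA` after death), and `death_stage` (`NA` if the bird survived the
#'   cycle).
#' @export
simulate_schedules <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  dag <- config$dag
  m <- MILESTONE_KINDS
  nb <- config$n_birds; ny <- config$n_years

  birds <- tibble::tibble(
    bird_id = sprintf("bird%03d", seq_len(nb)),
    habitat = ifelse(stats::runif(nb) < 0.5, "upland", "lowland"),
    route = ifelse(stats::runif(nb) < 0.5, "SW", "SE"),
    z_breeding_lat = stats::rnorm(nb),
    z_breeding_lon = stats::rnorm(nb)
  ) |>
    dplyr::mutate(
      breeding_lat = EXO_SCALE$breeding_lat["mean"] +
        EXO_SCALE$breeding_lat["sd"] * .data$z_breeding_lat,
      breeding_lon = EXO_SCALE$breeding_lon["mean"] +
        EXO_SCALE$breeding_lon["sd"] * .data$z_breeding_lon,
      tagging_site = paste0("site_", .data$habitat, "_",
                            1 + (seq_len(nb) %% 6))
    )

  # variance bookkeeping: joint covariance of all nodes in topological
  # order, so each node's residual variance solves b' Sigma b + resid = 1
  nodes <- c(dag$exogenous, dag$order)
  Sigma <- diag(length(nodes)); dimnames(Sigma) <- list(nodes, nodes)
  resid_var <- stats::setNames(numeric(length(dag$order)), dag$order)
  for (v in dag$order) {
    pa <- dag$edges[dag$edges$to == v, , drop = FALSE]
    if (nrow(pa) == 0) { resid_var[v] <- 1; next }
    b <- pa$beta
    S <- Sigma[pa$from, pa$from, drop = FALSE]
    explained <- drop(t(b) %*% S %*% b)
    resid_var[v] <- max(1 - explained, 0.02)
    Sigma[v, ] <- Sigma[, v] <- drop(Sigma[, pa$from, drop = FALSE] %*% b)
    Sigma[v, v] <- explained + resid_var[v]
  }

  scale <- MILESTONE_SCALE
  sig_b <- stats::setNames(numeric(6), m)
  for (k in m) {
    if (!is.null(config$sigma_between)) {
      sig_b[k] <- min(config$sigma_between[[k]] / scale$sd_days[scale$kind == k],
                      sqrt(resid_var[k] * 0.98))
    } else {
      sig_b[k] <- sqrt(config$target_repeatability * resid_var[k])
    }
  }
  sig_e <- sqrt(pmax(resid_var[m] - sig_b[m]^2, 1e-4))

  intercepts <- matrix(stats::rnorm(nb * 6, 0, rep(sig_b, each = nb)),
                       nrow = nb, dimnames = list(birds$bird_id, m))

  sched <- tidyr::expand_grid(bird_id = birds$bird_id, year = seq_len(ny)) |>
    dplyr::left_join(birds, by = "bird_id") |>
    dplyr::mutate(
      z_habitat = ifelse(.data$habitat == "upland", 1, -1),
      z_route = ifelse(.data$route == "SW", 1, -1),
      z_euro_stopover_lat = stats::rnorm(dplyr::n()),
      z_wa_stopover_lon = stats::rnorm(dplyr::n()),
      euro_stopover_lat = EXO_SCALE$euro_stopover_lat["mean"] +
        EXO_SCALE$euro_stopover_lat["sd"] * .data$z_euro_stopover_lat,
      wa_stopover_lon = EXO_SCALE$wa_stopover_lon["mean"] +
        EXO_SCALE$wa_stopover_lon["sd"] * .data$z_wa_stopover_lon
    )

  n <- nrow(sched)
  z <- matrix(NA_real_, n, 6, dimnames = list(NULL, m))
  zx <- cbind(habitat = sched$z_habitat, route = sched$z_route,
              breeding_lat = sched$z_breeding_lat,
              breeding_lon = sched$z_breeding_lon,
              euro_stopover_lat = sched$z_euro_stopover_lat,
              wa_stopover_lon = sched$z_wa_stopover_lon)
  bidx <- match(sched$bird_id, birds$bird_id)
  for (v in dag$order) {
    pa <- dag$edges[dag$edges$to == v, , drop = FALSE]
    mu <- rep(0, n)
    for (j in seq_len(nrow(pa))) {
      src <- pa$from[j]
      xv <- if (src %in% colnames(zx)) zx[, src] else z[, src]
      mu <- mu + pa$beta[j] * xv
    }
    z[, v] <- mu + intercepts[cbind(bidx, match(v, m))] +
      stats::rnorm(n, 0, sig_e[v])
  }

  dates <- sweep(sweep(z, 2, scale$sd_days, "*"), 2, scale$mean_days, "+")
  # enforce strict monotonicity of true dates within a cycle by resampling
  # residual-driven rows (rare at the default scales)
  for (attempt in 1:50) {
    bad <- which(apply(dates, 1, function(d) any(diff(d) <= 0)))
    if (length(bad) == 0) break
    for (i in bad) {
      for (v in dag$order) {
        pa <- dag$edges[dag$edges$to == v, , drop = FALSE]
        mu <- 0
        for (j in seq_len(nrow(pa))) {
          src <- pa$from[j]
          mu <- mu + pa$beta[j] *
            (if (src %in% colnames(zx)) zx[i, src] else z[i, src])
        }
        z[i, v] <- mu + intercepts[bidx[i], match(v, m)] +
          stats::rnorm(1, 0, sig_e[v])
      }
      dates[i, ] <- scale$mean_days * NA
      dates[i, ] <- scale$mean_days + scale$sd_days * z[i, ]
    }
  }
  bad <- which(apply(dates, 1, function(d) any(diff(d) <= 0)))
  if (length(bad) > 0) { # last resort: nudge into order
    for (i in bad) dates[i, ] <- cummax_strict(dates[i, ])
  }

  colnames(dates) <- paste0("date_", m)
  colnames(z) <- paste0("z_", m)
  out <- dplyr::bind_cols(sched, tibble::as_tibble(dates), tibble::as_tibble(z))
  out <- simulate_mortality(out, config)
  out
}

cummax_strict <- function(x, eps = 0.5) {
  for (i in seq_along(x)[-1]) if (x[i] <= x[i - 1]) x[i] <- x[i - 1] + eps
  x
}

#' Apply the stage-wise mortality process to true schedules
#'
#' For each bird-year in chronological order, a Bernoulli death draw is made
#' after each milestone with log-odds `intercept + slope * z` (z the
#' standardized true date of that milestone). The first success sets the
#' death stage; milestones after it are set to `NA`, and the bird
#' contributes no later cycles.
#'
#' @param schedules Output of the schedule generator (before mortality).
#' @param config A [sim_config()]; uses `config$mortality_logit`.
#' @return `schedules` with `death_stage` and `death_day` columns and
#'   post-death milestones blanked; rows for years after a death removed.
#' @export
simulate_mortality <- function(schedules, config) {
  ml <- config$mortality_logit
  stopifnot(all(1:6 %in% ml$stage))
  out <- schedules |> dplyr::arrange(.data$bird_id, .data$year)
  out$death_stage <- NA_integer_
  out$death_day <- NA_real_
  drop_rows <- logical(nrow(out))
  dead_birds <- character(0)
  for (i in seq_len(nrow(out))) {
    if (out$bird_id[i] %in% dead_birds) { drop_rows[i] <- TRUE; next }
    for (s in 1:6) {
      zi <- out[[paste0("z_", MILESTONE_KINDS[s])]][i]
      row <- ml[ml$stage == s, ]
      p <- stats::plogis(row$intercept + row$slope * zi)
      if (stats::runif(1) < p) {
        out$death_stage[i] <- s
        d0 <- out[[paste0("date_", MILESTONE_KINDS[s])]][i]
        d1 <- if (s < 6) out[[paste0("date_", MILESTONE_KINDS[s + 1])]][i] else d0 + 30
        out$death_day[i] <- stats::runif(1, d0, d1)
        if (s < 6) {
          for (k in (s + 1):6) {
            out[[paste0("date_", MILESTONE_KINDS[k])]][i] <- NA_real_
          }
        }
        dead_birds <- c(dead_birds, out$bird_id[i])
        break
      }
    }
  }
  out[!drop_rows, , drop = FALSE]
}

# --- track rendering ---------------------------------------------------

# Corridor waypoints. Southbound goes via the bird's European pre-Sahara
# stopover (Iberia for SW, Italy for SE), a post-crossing Sahel hold, then
# the wintering grounds. Northbound returns via the West African stopover
# and a fixed Iberian staging site.
route_waypoints <- function(row) {
  lon_eu <- if (row$route == "SW") -2.0 else 12.0
  lon_sahel <- if (row$route == "SW") -1.0 else 14.0
  list(
    breeding = c(lat = row$breeding_lat, lon = row$breeding_lon),
    euro_s = c(lat = row$euro_stopover_lat, lon = lon_eu),
    sahel_s = c(lat = 15.5, lon = lon_sahel),
    winter = c(lat = 1.0, lon = 22.0),
    wa_n = c(lat = 10.5, lon = row$wa_stopover_lon),
    euro_n = c(lat = 40.0, lon = -2.0)
  )
}

# Build hold/flight segments (in cycle days) for one bird-year.
# Returns a data frame: t0, t1, lat0, lon0, lat1, lon1.
year_segments <- function(row, speed_kmh) {
  wp <- route_waypoints(row)
  fly_d <- function(a, b) {
    if (speed_kmh <= 0) {
      if (haversine_km(a["lat"], a["lon"], b["lat"], b["lon"]) > 0.001) {
        stop("zero flight speed with distinct waypoints")
      }
      return(0)
    }
    haversine_km(a["lat"], a["lon"], b["lat"], b["lon"]) / speed_kmh / 24
  }
  d <- function(k) row[[paste0("date_", MILESTONE_KINDS[k])]]
  stages <- list() # each: list(loc_from, loc_to, depart, arrive) or hold
  # anchors: holds at breeding [0, M1]; euro_s; sahel_s [M2-ish, ...];
  # winter [M3, M4]; wa_n [., M5]; euro_n; breeding [M6, year end]
  death <- if (!is.na(row$death_day)) row$death_day else Inf
  pts <- list(wp$breeding, wp$euro_s, wp$sahel_s, wp$winter,
              wp$wa_n, wp$euro_n, wp$breeding)
  # departure time of each hold (NA when the bird died earlier):
  # hold i is at pts[[i]]; flight i connects hold i to hold i+1
  ft <- vapply(1:6, function(i) fly_d(pts[[i]], pts[[i + 1]]), double(1))
  # arrival anchors per hold 2..7
  m1 <- d(1); m2 <- d(2); m3 <- d(3); m4 <- d(4); m5 <- d(5); m6 <- d(6)
  arr <- c(0,
           ifelse(is.na(m1), NA, m1 + ft[1]),
           m2,                  # the Sahel hold starts as the crossing completes
           m3,
           ifelse(is.na(m4), NA, m4 + ft[4]),
           ifelse(is.na(m5), NA, m5 + ft[5]),
           m6)
  dep <- c(m1,
           ifelse(is.na(m2), NA, m2 - ft[2]),
           ifelse(is.na(m3), NA, m3 - ft[3]),
           m4,
           m5,
           ifelse(is.na(m6), NA, m6 - ft[6]),
           365)
  seg <- list()
  for (i in 1:7) {
    if (is.na(arr[i]) || is.na(dep[i])) break
    t0 <- arr[i]; t1 <- max(dep[i], t0) # clamp degenerate holds
    seg[[length(seg) + 1L]] <- data.frame(
      t0 = t0, t1 = t1, lat0 = pts[[i]]["lat"], lon0 = pts[[i]]["lon"],
      lat1 = pts[[i]]["lat"], lon1 = pts[[i]]["lon"])
    if (i < 7 && !is.na(arr[i + 1])) {
      seg[[length(seg) + 1L]] <- data.frame(
        t0 = t1, t1 = max(arr[i + 1], t1),
        lat0 = pts[[i]]["lat"], lon0 = pts[[i]]["lon"],
        lat1 = pts[[i + 1]]["lat"], lon1 = pts[[i + 1]]["lon"])
    }
  }
  segs <- do.call(rbind, seg)
  rownames(segs) <- NULL
  if (is.finite(death)) segs <- segs[segs$t0 < death, , drop = FALSE]
  if (is.finite(death) && nrow(segs) > 0) {
    last <- nrow(segs)
    if (segs$t1[last] > death) {
      f <- (death - segs$t0[last]) / max(segs$t1[last] - segs$t0[last], 1e-9)
      p <- gc_interpolate(segs$lat0[last], segs$lon0[last],
                          segs$lat1[last], segs$lon1[last], f)
      segs$t1[last] <- death
      segs$lat1[last] <- p$lat; segs$lon1[last] <- p$lon
    }
  }
  segs
}

position_at <- function(segs, t_days) {
  lat <- rep(NA_real_, length(t_days)); lon <- rep(NA_real_, length(t_days))
  for (i in seq_len(nrow(segs))) {
    sel <- which(t_days >= segs$t0[i] & t_days <= segs$t1[i] & is.na(lat))
    if (length(sel) == 0) next
    f <- (t_days[sel] - segs$t0[i]) / max(segs$t1[i] - segs$t0[i], 1e-9)
    p <- gc_interpolate(segs$lat0[i], segs$lon0[i], segs$lat1[i], segs$lon1[i],
                        pmin(pmax(f, 0), 1))
    lat[sel] <- p$lat; lon[sel] <- p$lon
  }
  list(lat = lat, lon = lon)
}

#' Render duty-cycled fixes for a simulated cohort
#'
#' Moves each bird piecewise along great circles between its corridor
#' waypoints at `flight_speed_kmh`, holds position during stopovers, emits
#' fixes only inside on-windows of the duty cycle (a burst of three fixes
#' around mid-window, so each transmission cycle has a well-defined
#' location), drops whole cycles with probability `p_missed_cycle`, adds
#' isotropic positional noise with SD `fix_noise_km`, and truncates the
#' track at death.
#'
#' @param schedules Output of [simulate_schedules()].
#' @param config The same [sim_config()].
#' @return A fix tibble (`bird_id`, `t`, `lat`, `lon`, `lc`), time-sorted.
#' @export
render_tracks <- function(schedules, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  cyc_h <- config$duty_on_hours + config$duty_off_hours
  rows <- list()
  origin1 <- as.POSIXct(sprintf("%d-06-01 00:00:00", config$start_year),
                        tz = "UTC")
  for (b in unique(schedules$bird_id)) {
    sb <- schedules[schedules$bird_id == b, , drop = FALSE]
    phase_h <- stats::runif(1, 0, cyc_h)
    # segments for all years on one absolute clock (days since tagging-year
    # 1 June), so the tag's duty schedule runs continuously across years
    seg_list <- list()
    for (r in seq_len(nrow(sb))) {
      row <- sb[r, , drop = FALSE]
      segs <- year_segments(row, config$flight_speed_kmh)
      if (is.null(segs) || nrow(segs) == 0) next
      origin_y <- as.POSIXct(sprintf("%d-06-01 00:00:00",
                                     config$start_year + row$year - 1L),
                             tz = "UTC")
      off <- as.numeric(difftime(origin_y, origin1, units = "days"))
      segs$t0 <- segs$t0 + off
      segs$t1 <- segs$t1 + off
      seg_list[[length(seg_list) + 1L]] <- segs
    }
    if (length(seg_list) == 0) next
    segs <- do.call(rbind, seg_list)
    t_end <- max(segs$t1)
    win_starts <- seq(phase_h / 24, t_end, by = cyc_h / 24)
    keep <- stats::runif(length(win_starts)) >= config$p_missed_cycle
    win_starts <- win_starts[keep]
    if (length(win_starts) == 0) next
    fix_off <- c(4.75, 5, 5.25) / 24 # a tight mid-window burst of three fixes
    tt <- as.vector(outer(fix_off, win_starts, "+"))
    tt <- sort(tt[tt <= t_end & tt >= min(segs$t0)])
    if (length(tt) == 0) next
    p <- position_at(segs, tt)
    ok <- !is.na(p$lat)
    tt <- tt[ok]; plat <- p$lat[ok]; plon <- p$lon[ok]
    if (length(tt) == 0) next
    if (config$fix_noise_km > 0) {
      dx <- stats::rnorm(length(tt), 0, config$fix_noise_km)
      dy <- stats::rnorm(length(tt), 0, config$fix_noise_km)
      o <- offset_km(plat, plon, dx, dy)
      plat <- o$lat; plon <- o$lon
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      bird_id = b, t = origin1 + round(tt * 86400),
      lat = plat, lon = plon, lc = "3")
  }
  if (length(rows) == 0) {
    return(tibble::tibble(bird_id = character(),
                          t = as.POSIXct(character(), tz = "UTC"),
                          lat = double(), lon = double(), lc = character()))
  }
  dplyr::bind_rows(rows) |> dplyr::arrange(.data$bird_id, .data$t)
}

#' Simulate a full cohort: schedules, metadata and duty-cycled fixes
#'
#' @param config A [sim_config()].
#' @return List with `truth` (bird-year schedule tibble), `meta` (one row
#'   per bird: habitat, route, breeding coordinates, tagging site) and
#'   `fixes` (Movebank-style fix tibble).
#' @export
simulate_cohort <- function(config) {
  truth <- simulate_schedules(config)
  meta <- truth |>
    dplyr::distinct(.data$bird_id, .data$habitat, .data$route,
                    .data$breeding_lat, .data$breeding_lon, .data$tagging_site)
  fixes <- render_tracks(truth, config)
  list(truth = truth, meta = meta, fixes = fixes)
}

#' Convert cycle-time days to calendar dates and Julian days
#'
#' Cycle time counts continuous days since 1 June of the cycle's starting
#' year.
#'
#' @param cycle_days Numeric days since 1 June.
#' @param start_year Calendar year the cycle starts in.
#' @return Tibble with `date` (POSIXct) and `julian_day` (day of calendar
#'   year, 1-366).
#' @export
cycle_days_to_julian <- function(cycle_days, start_year = 2015L) {
  origin <- as.POSIXct(sprintf("%d-06-01 00:00:00", start_year), tz = "UTC")
  date <- origin + cycle_days * 86400
  tibble::tibble(date = date,
                 julian_day = as.integer(format(date, "%j")))
}
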