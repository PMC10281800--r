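# Extraction of the six migratory milestones from segmented tracks,
# per-milestone timing uncertainty, the uncertainty filter, route
# classification, within-individual anomalies and dataset assembly.
#
# Milestones (in annual-cycle order):
#   depart_breeding        end of the last stopover on the breeding-site
#                          disc before the first fix well south of it
#   complete_sahara_south  first fix south of the Sahara polygon after a
#                          northern-side fix, on southbound migration
#   arrive_winter          start of the first stopover inside the
#                          wintering-grounds polygon
#   depart_winter          end of the last stopover inside the
#                          wintering-grounds polygon
#   depart_west_africa     end of the last West African stopover before a
#                          northbound Sahara-interior or trans-Sahara fix
#   arrive_breeding        first fix within the breeding-site disc in spring
#
# "Southbound"/"northbound" are disambiguated by calendar window: the
# post-breeding window runs June-December of the cycle, the pre-breeding
# window January-May, because the same polygons are crossed twice a year.

DEPARTURE_KINDS <- c("depart_breeding", "depart_winter", "depart_west_africa")

cycle_origin <- function(cycle_id) {
  as.POSIXct(sprintf("%d-06-01 00:00:00", cycle_id), tz = "UTC")
}

#' Assign an annual-cycle identifier to timestamps
#'
#' A cycle runs from 1 June to 31 May and is labelled by its starting
#' calendar year.
#' @param t POSIXct timestamps.
#' @return Integer cycle ids.
#' @export
cycle_of <- function(t) {
  as.integer(format(t - 151 * 86400, "%Y"))
}

south_of_region <- function(lat, region) lat < min(region[, "lat"])
north_of_region <- function(lat, region) lat > max(region[, "lat"])

#' Extract the six migratory milestones for every bird and cycle
#'
#' @param stopovers Stopover tibble from [detect_stopovers()] /
#'   [extend_through_gaps()].
#' @param best_fixes Best-location tibble from [cycle_best_fixes()].
#' @param regions A [read_regions()] set containing `sahara`,
#'   `wintering_grounds`, `west_africa` and (for route work) `iberia`,
#'   `italy`.
#' @param meta Bird metadata tibble with `bird_id`, `breeding_lat`,
#'   `breeding_lon`.
#' @param breeding_radius_km Radius of the breeding-site disc used for
#'   departure/arrival at the breeding grounds (default 50 km, matching the
#'   stopover radius).
#' @param depart_dist_km Distance from the breeding site that marks the
#'   first clearly southbound fix (default 100 km).
#' @return Tibble with one row per detected milestone: `bird_id`,
#'   `cycle_id`, `kind`, `date` (POSIXct), `cycle_day` (days since 1 June
#'   of the cycle), `julian_day`, `basis_t`, `basis_lat`, `basis_lon`,
#'   `uncertainty_days`. Milestones a bird never reached are simply absent.
#' @export
extract_milestones <- function(stopovers, best_fixes, regions, meta,
                               breeding_radius_km = 50, depart_dist_km = 100) {
  for (nm in c("sahara", "wintering_grounds", "west_africa")) {
    if (!nm %in% names(regions)) stop("missing region: ", nm)
  }
  out <- list()
  for (b in unique(best_fixes$bird_id)) {
    bf <- best_fixes[best_fixes$bird_id == b, , drop = FALSE]
    st <- stopovers[stopovers$bird_id == b, , drop = FALSE]
    mrow <- meta[meta$bird_id == b, , drop = FALSE]
    if (nrow(mrow) == 0) stop("bird absent from metadata: ", b)
    for (cyc in sort(unique(cycle_of(bf$t)))) {
      out[[length(out) + 1L]] <-
        extract_one_cycle(bf, st, regions, mrow, cyc,
                          breeding_radius_km, depart_dist_km)
    }
  }
  ms <- dplyr::bind_rows(out)
  if (nrow(ms) == 0) return(ms)
  ms <- ms |> dplyr::arrange(.data$bird_id, .data$cycle_id,
                             match(.data$kind, MILESTONE_KINDS))
  ms$uncertainty_days <- milestone_uncertainty(ms, best_fixes, regions)
  ms
}

extract_one_cycle <- function(bf, st, regions, mrow, cyc,
                              breeding_radius_km, depart_dist_km) {
  t0 <- cycle_origin(cyc)
  t_mid <- t0 + 214 * 86400          # ~1 January: post-/pre-breeding split
  t_end <- t0 + 366 * 86400
  sb <- bf[bf$t >= t0 & bf$t <= t_mid, , drop = FALSE]
  nb <- bf[bf$t > t_mid & bf$t <= t_end, , drop = FALSE]
  res <- list()
  add <- function(kind, date, basis_t, basis_lat, basis_lon) {
    res[[length(res) + 1L]] <<- tibble::tibble(
      bird_id = mrow$bird_id, cycle_id = cyc, kind = kind, date = date,
      cycle_day = as.numeric(difftime(date, t0, units = "days")),
      julian_day = as.integer(format(date, "%j")),
      basis_t = basis_t, basis_lat = basis_lat, basis_lon = basis_lon)
  }
  b_lat <- mrow$breeding_lat; b_lon <- mrow$breeding_lon

  # depart_breeding
  if (nrow(sb) > 0) {
    dist_b <- haversine_km(sb$lat, sb$lon, b_lat, b_lon)
    away <- which(dist_b > depart_dist_km & sb$lat < b_lat)
    if (length(away) > 0) {
      t_away <- sb$t[away[1]]
      cand <- st[haversine_km(st$lat, st$lon, b_lat, b_lon) <= breeding_radius_km &
                   st$end <= t_away & st$end >= t0 - 120 * 86400, , drop = FALSE]
      if (nrow(cand) > 0) {
        i <- which.max(cand$end)
        add("depart_breeding", cand$end[i], cand$end[i], cand$lat[i], cand$lon[i])
      }
    }
  }

  # complete_sahara_south
  if (nrow(sb) > 0) {
    south <- south_of_region(sb$lat, regions$sahara)
    northside <- north_of_region(sb$lat, regions$sahara)
    first_south <- which(south & cumsum(northside) > 0)
    if (length(first_south) > 0) {
      i <- first_south[1]
      add("complete_sahara_south", sb$t[i], sb$t[i], sb$lat[i], sb$lon[i])
    }
  }

  # arrive_winter / depart_winter
  win <- st[point_in_region(st$lat, st$lon, regions$wintering_grounds) &
              st$start >= t0 & st$start <= t_end, , drop = FALSE]
  if (nrow(win) > 0) {
    i <- which.min(win$start)
    add("arrive_winter", win$start[i], win$start[i], win$lat[i], win$lon[i])
    j <- which.max(win$end)
    add("depart_winter", win$end[j], win$end[j], win$lat[j], win$lon[j])
  }

  # depart_west_africa
  if (nrow(nb) > 0) {
    trans <- which(point_in_region(nb$lat, nb$lon, regions$sahara) |
                     north_of_region(nb$lat, regions$sahara))
    if (length(trans) > 0) {
      t_trans <- nb$t[trans[1]]
      wa <- st[point_in_region(st$lat, st$lon, regions$west_africa) &
                 st$end > t_mid & st$end <= t_trans, , drop = FALSE]
      if (nrow(wa) > 0) {
        i <- which.max(wa$end)
        add("depart_west_africa", wa$end[i], wa$end[i], wa$lat[i], wa$lon[i])
      } else if (point_in_region(nb$lat[trans[1]], nb$lon[trans[1]],
                                 regions$sahara)) {
        # departure only witnessed by a fix already out in the desert
        i <- trans[1]
        add("depart_west_africa", nb$t[i], nb$t[i], nb$lat[i], nb$lon[i])
      }
    }
  }

  # arrive_breeding
  if (nrow(nb) > 0) {
    home <- which(haversine_km(nb$lat, nb$lon, b_lat, b_lon) <= breeding_radius_km)
    if (length(home) > 0) {
      i <- home[1]
      add("arrive_breeding", nb$t[i], nb$t[i], nb$lat[i], nb$lon[i])
    }
  }
  dplyr::bind_rows(res)
}

#' Timing uncertainty of each milestone
#'
#' For departure-type milestones (departure from the breeding grounds, the
#' wintering grounds, or West Africa) the uncertainty is the gap, in days,
#' from the basis fix to the NEXT fix; for arrival-type milestones the gap
#' to the PREVIOUS fix. If a West-Africa departure is based on a fix inside
#' the Sahara polygon the uncertainty is set to exactly 2 days (little time
#' is spent on the desert crossing). Milestones with no neighbouring fix
#' get `NA`.
#'
#' @param milestones Milestone tibble with `basis_t`, `basis_lat`,
#'   `basis_lon`.
#' @param best_fixes Best-location tibble for the same birds.
#' @param regions Region set (for the Sahara test).
#' @param wa_sahara_uncertainty_days The fixed desert-crossing uncertainty.
#' @return Numeric vector of uncertainties in days.
#' @export
milestone_uncertainty <- function(milestones, best_fixes, regions,
                                  wa_sahara_uncertainty_days = 2) {
  if (nrow(milestones) == 0) return(numeric(0))
  if (any(is.na(milestones$basis_t))) stop("milestone with missing basis fix")
  vapply(seq_len(nrow(milestones)), function(i) {
    m <- milestones[i, ]
    if (m$kind == "depart_west_africa" &&
        point_in_region(m$basis_lat, m$basis_lon, regions$sahara)) {
      return(wa_sahara_uncertainty_days)
    }
    bf <- best_fixes[best_fixes$bird_id == m$bird_id, , drop = FALSE]
    if (m$kind %in% DEPARTURE_KINDS) {
      nxt <- bf$t[bf$t > m$basis_t + 1]
      if (length(nxt) == 0) return(NA_real_)
      as.numeric(difftime(min(nxt), m$basis_t, units = "days"))
    } else {
      prv <- bf$t[bf$t < m$basis_t - 1]
      if (length(prv) == 0) return(NA_real_)
      as.numeric(difftime(m$basis_t, max(prv), units = "days"))
    }
  }, double(1))
}

#' Drop milestones whose uncertainty exceeds a threshold
#'
#' Milestones with uncertainty strictly above `threshold` days are removed
#' (a milestone at exactly the threshold is kept); milestones with unknown
#' (`NA`) uncertainty are also removed.
#'
#' @param milestones Milestone tibble with `uncertainty_days`.
#' @param threshold Days; default 5.
#' @return The retained rows.
#' @export
filter_uncertain <- function(milestones, threshold = 5) {
  dplyr::filter(milestones,
                !is.na(.data$uncertainty_days),
                .data$uncertainty_days <= threshold)
}

#' Classify the post-breeding migratory route of each bird-cycle
#'
#' A cycle is `SW` if any southbound best fix, or the great-circle chord
#' between successive best fixes, intersects the Iberia polygon, and `SE`
#' analogously for Italy (first transit wins if both are touched). Cycles
#' lost before either polygon inherit the bird's previous-year route;
#' otherwise `unclassified`.
#'
#' @param best_fixes Best-location tibble.
#' @param regions Region set with `iberia` and `italy`.
#' @param chord_step_km Sampling step along inter-fix chords.
#' @return Tibble `bird_id`, `cycle_id`, `route`.
#' @export
classify_routes <- function(best_fixes, regions, chord_step_km = 20) {
  out <- list()
  for (b in unique(best_fixes$bird_id)) {
    bf <- best_fixes[best_fixes$bird_id == b, , drop = FALSE]
    prev <- NA_character_
    for (cyc in sort(unique(cycle_of(bf$t)))) {
      t0 <- cycle_origin(cyc); t_mid <- t0 + 214 * 86400
      sb <- bf[bf$t >= t0 & bf$t <= t_mid, , drop = FALSE]
      r <- route_of_track(sb, regions, chord_step_km)
      if (is.na(r)) r <- prev
      if (is.na(r)) r <- "unclassified"
      out[[length(out) + 1L]] <- tibble::tibble(bird_id = b, cycle_id = cyc,
                                                route = r)
      if (r %in% c("SW", "SE")) prev <- r
    }
  }
  dplyr::bind_rows(out)
}

route_of_track <- function(sb, regions, chord_step_km = 20) {
  if (nrow(sb) == 0) return(NA_character_)
  hit_time <- c(SW = Inf, SE = Inf)
  polys <- list(SW = regions$iberia, SE = regions$italy)
  for (r in names(polys)) {
    inpoly <- point_in_region(sb$lat, sb$lon, polys[[r]])
    if (any(inpoly)) hit_time[r] <- min(as.numeric(sb$t[inpoly]))
  }
  if (all(is.infinite(hit_time)) && nrow(sb) >= 2) {
    for (i in seq_len(nrow(sb) - 1)) {
      d <- haversine_km(sb$lat[i], sb$lon[i], sb$lat[i + 1], sb$lon[i + 1])
      if (d < 1) next
      f <- seq(0, 1, length.out = max(3, ceiling(d / chord_step_km)))
      p <- gc_interpolate(sb$lat[i], sb$lon[i], sb$lat[i + 1], sb$lon[i + 1], f)
      for (r in names(polys)) {
        if (is.infinite(hit_time[r]) &&
            any(point_in_region(p$lat, p$lon, polys[[r]]))) {
          hit_time[r] <- min(hit_time[r], as.numeric(sb$t[i]))
        }
      }
      if (any(is.finite(hit_time))) break
    }
  }
  if (all(is.infinite(hit_time))) return(NA_character_)
  names(hit_time)[which.min(hit_time)]
}

#' Within-individual timing anomalies
#'
#' For each bird and milestone kind observed in more than one year, the
#' anomaly is the milestone date minus that bird's mean date for the kind
#' across all its years. Per bird-kind, anomalies sum to zero.
#'
#' @param milestones Milestone tibble with `cycle_day`.
#' @return The qualifying rows with `anomaly_days` and `n_years` columns.
#' @export
within_individual_anomaly <- function(milestones) {
  milestones |>
    dplyr::group_by(.data$bird_id, .data$kind) |>
    dplyr::filter(dplyr::n() > 1) |>
    dplyr::mutate(anomaly_days = .data$cycle_day - mean(.data$cycle_day),
                  n_years = dplyr::n()) |>
    dplyr::ungroup()
}

#' Assemble the full and repeat datasets
#'
#' The full dataset is the uncertainty-filtered milestone set (minus birds
#' excluded upstream, e.g. those that died before leaving the breeding
#' country); the repeat dataset keeps only bird-kind groups observed in at
#' least two years and carries the within-individual anomaly.
#'
#' @param milestones Milestone tibble with `uncertainty_days`.
#' @param threshold Uncertainty threshold in days (default 5).
#' @param exclude_birds Bird ids to drop entirely (e.g. died before leaving
#'   the breeding grounds).
#' @return List with `full`, `repeat_` (anomaly rows), and
#'   `repeat_histogram` (per-bird count of contributing cycles).
#' @export
build_datasets <- function(milestones, threshold = 5, exclude_birds = character()) {
  full <- milestones |>
    dplyr::filter(!.data$bird_id %in% exclude_birds) |>
    filter_uncertain(threshold)
  rpt <- within_individual_anomaly(full)
  hist <- if (nrow(rpt) == 0) {
    tibble::tibble(max_cycles = integer(), n_birds = integer())
  } else {
    rpt |>
      dplyr::distinct(.data$bird_id, .data$kind, .data$n_years) |>
      dplyr::group_by(.data$bird_id) |>
      dplyr::summarise(max_cycles = max(.data$n_years), .groups = "drop") |>
      dplyr::count(.data$max_cycles, name = "n_birds")
  }
  list(full = full, repeat_ = rpt, repeat_histogram = hist)
}

#' Check milestone monotonicity within each bird-cycle
#'
#' @param milestones Milestone tibble.
#' @return `TRUE` invisibly, or an error naming the offending bird-cycle.
#' @export
assert_milestone_order <- function(milestones) {
  bad <- milestones |>
    dplyr::arrange(.data$bird_id, .data$cycle_id,
                   match(.data$kind, MILESTONE_KINDS)) |>
    dplyr::group_by(.data$bird_id, .data$cycle_id) |>
    dplyr::summarise(ok = all(diff(.data$cycle_day) > 0), .groups = "drop") |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0) {
    stop("non-monotone milestones for ",
         paste(bad$bird_id, bad$cycle_id, sep = "/", collapse = ", "))
  }
  invisible(TRUE)
}
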