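# Segmentation of per-bird fix streams into transmission cycles and
# stopovers. A duty-cycled tag transmits in on-windows; fixes more than
# `cycle_gap_h` apart belong to different transmission cycles. Stopovers are
# runs of consecutive cycles whose best locations cluster within
# `stopover_km` of each other, at least two cycles and one day long.

#' Partition fixes into transmission cycles
#'
#' A new cycle starts exactly when the gap to the previous fix of the same
#' bird exceeds `cycle_gap_h` hours (strictly greater than).
#'
#' @param fixes Tibble of fixes (`bird_id`, `t`, `lat`, `lon`, `lc`),
#'   time-sorted within bird (sorted internally if not).
#' @param cycle_gap_h Gap, in hours, beyond which consecutive fixes are
#'   assigned to different transmission cycles. Default 10 h, the on-window
#'   length of a 10 h-on / 48 h-off duty cycle.
#' @return The input with an integer `cycle` column (1-based per bird).
#' @export
assign_cycles <- function(fixes, cycle_gap_h = 10) {
  if (nrow(fixes) == 0) {
    return(dplyr::mutate(fixes, cycle = integer()))
  }
  fixes |>
    dplyr::arrange(.data$bird_id, .data$t) |>
    dplyr::group_by(.data$bird_id) |>
    dplyr::mutate(
      .gap_h = as.numeric(difftime(.data$t, dplyr::lag(.data$t), units = "hours")),
      cycle = 1L + cumsum(dplyr::coalesce(.data$.gap_h > cycle_gap_h, FALSE))
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-".gap_h")
}

#' Best location per transmission cycle
#'
#' Selects one representative fix per (bird, cycle): the highest Argos
#' quality class, ties broken by smallest distance to the cycle's
#' coordinate-wise median position, remaining ties by earliest time.
#'
#' @param fixes Output of [assign_cycles()].
#' @param lc_ranking Quality classes from best to worst.
#' @return One row per (bird, cycle) with the chosen fix.
#' @export
cycle_best_fixes <- function(fixes, lc_ranking = c("3", "2", "1", "0", "A", "B", "Z")) {
  fixes |>
    dplyr::group_by(.data$bird_id, .data$cycle) |>
    dplyr::group_modify(function(df, key) {
      rk <- lc_rank(df$lc, lc_ranking)
      cand <- which(rk == min(rk))
      if (length(cand) > 1) {
        med_lat <- stats::median(df$lat)
        med_lon <- stats::median(df$lon)
        d <- haversine_km(df$lat[cand], df$lon[cand], med_lat, med_lon)
        cand <- cand[d == min(d)]
        if (length(cand) > 1) cand <- cand[which.min(df$t[cand])]
      }
      df[cand[1], , drop = FALSE]
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$bird_id, .data$t)
}

#' Detect stopovers from cycle best locations
#'
#' Greedy left-to-right chaining: a cycle joins the open stopover if its
#' best location is within `stopover_km` (inclusive) of the stopover's
#' running centroid; otherwise the stopover closes and a new candidate
#' opens. A closed run is emitted as a stopover only if it has at least two
#' member cycles and spans at least `min_duration_days` between its first
#' and last member best-fix times. The centroid is the arithmetic mean of
#' member best-fix coordinates.
#'
#' @param best_fixes Output of [cycle_best_fixes()].
#' @param stopover_km Clustering radius, km (boundary inclusive). Default 50.
#' @param min_duration_days Minimum elapsed duration, days. Default 1.
#' @return Tibble with one row per stopover: `bird_id`, `start`, `end`,
#'   `lat`, `lon` (centroid), `n_cycles`, `first_cycle`, `last_cycle`,
#'   `gap_extended` (always `FALSE` here; see [extend_through_gaps()]).
#' @export
detect_stopovers <- function(best_fixes, stopover_km = 50, min_duration_days = 1) {
  empty <- tibble::tibble(
    bird_id = character(), start = as.POSIXct(character(), tz = "UTC"),
    end = as.POSIXct(character(), tz = "UTC"), lat = double(), lon = double(),
    n_cycles = integer(), first_cycle = integer(), last_cycle = integer(),
    gap_extended = logical())
  if (nrow(best_fixes) == 0) return(empty)
  out <- best_fixes |>
    dplyr::group_by(.data$bird_id) |>
    dplyr::group_map(function(df, key) {
      detect_stopovers_one(df, key$bird_id, stopover_km, min_duration_days)
    }) |>
    dplyr::bind_rows()
  if (nrow(out) == 0) empty else out
}

detect_stopovers_one <- function(df, bird_id, stopover_km, min_duration_days) {
  n <- nrow(df)
  runs <- list()
  open <- 1L # index of first member of the open run
  members <- 1L
  for (i in seq_len(n)[-1]) {
    c_lat <- mean(df$lat[members]); c_lon <- mean(df$lon[members])
    if (haversine_km(df$lat[i], df$lon[i], c_lat, c_lon) <= stopover_km) {
      members <- c(members, i)
    } else {
      runs[[length(runs) + 1L]] <- members
      members <- i
    }
  }
  runs[[length(runs) + 1L]] <- members
  keep <- Filter(function(m) {
    length(m) >= 2 &&
      as.numeric(difftime(df$t[m[length(m)]], df$t[m[1]], units = "days")) >=
        min_duration_days
  }, runs)
  if (length(keep) == 0) return(NULL)
  tibble::tibble(
    bird_id = bird_id,
    start = do.call(c, lapply(keep, function(m) df$t[m[1]])),
    end = do.call(c, lapply(keep, function(m) df$t[m[length(m)]])),
    lat = vapply(keep, function(m) mean(df$lat[m]), double(1)),
    lon = vapply(keep, function(m) mean(df$lon[m]), double(1)),
    n_cycles = lengths(keep),
    first_cycle = vapply(keep, function(m) df$cycle[m[1]], integer(1)),
    last_cycle = vapply(keep, function(m) df$cycle[m[length(m)]], integer(1)),
    gap_extended = FALSE
  )
}

#' Extend stopover ends through missed transmission cycles
#'
#' When whole transmission cycles are missing between a stopover's last
#' member cycle and the next observed location somewhere else (more than
#' `stopover_km` away), the bird is assumed to have remained at the stopover
#' until the expected on-window of the last missed cycle, computed from the
#' duty schedule anchored on the last received cycle. If the next observed
#' location is within `stopover_km`, the missing cycles are bridged inside
#' the stopover and no extension is applied.
#'
#' @param stopovers Output of [detect_stopovers()].
#' @param best_fixes Output of [cycle_best_fixes()] for the same birds.
#' @param duty_on_hours,duty_off_hours Duty-cycle parameters (default 10/48).
#' @param stopover_km Radius used to decide "moved elsewhere". Default 50.
#' @return `stopovers` with `end` moved forward and `gap_extended = TRUE`
#'   where the rule applies.
#' @export
extend_through_gaps <- function(stopovers, best_fixes,
                                duty_on_hours = 10, duty_off_hours = 48,
                                stopover_km = 50) {
  cycle_h <- duty_on_hours + duty_off_hours
  if (cycle_h <= 0) stop("duty_on_hours + duty_off_hours must be positive")
  if (nrow(stopovers) == 0) return(stopovers)
  stopovers |>
    dplyr::group_by(.data$bird_id) |>
    dplyr::group_modify(function(st, key) {
      bf <- dplyr::filter(best_fixes, .data$bird_id == key$bird_id)
      for (i in seq_len(nrow(st))) {
        nxt <- bf[bf$t > st$end[i], , drop = FALSE]
        if (nrow(nxt) == 0) next
        gap_h <- as.numeric(difftime(nxt$t[1], st$end[i], units = "hours"))
        if (gap_h < 0) stop("schedule inconsistency: negative gap after stopover")
        n_missed <- max(0, round(gap_h / cycle_h) - 1)
        moved <- haversine_km(nxt$lat[1], nxt$lon[1], st$lat[i], st$lon[i]) >
          stopover_km
        if (n_missed >= 1 && moved) {
          st$end[i] <- st$end[i] + n_missed * cycle_h * 3600
          st$gap_extended[i] <- TRUE
        }
      }
      st
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate("bird_id")
}

#' Segment fixes into stopovers in one call
#'
#' Convenience wrapper: [assign_cycles()], [cycle_best_fixes()],
#' [detect_stopovers()], [extend_through_gaps()].
#'
#' @param fixes Fix tibble.
#' @param cycle_gap_h,stopover_km,min_duration_days,duty_on_hours,duty_off_hours
#'   Passed to the respective stages.
#' @return List with elements `best_fixes` and `stopovers`.
#' @export
segment_track <- function(fixes, cycle_gap_h = 10, stopover_km = 50,
                          min_duration_days = 1,
                          duty_on_hours = 10, duty_off_hours = 48) {
  cyc <- assign_cycles(fixes, cycle_gap_h)
  bf <- cycle_best_fixes(cyc)
  st <- detect_stopovers(bf, stopover_km, min_duration_days)
  st <- extend_through_gaps(st, bf, duty_on_hours, duty_off_hours, stopover_km)
  list(best_fixes = bf, stopovers = st)
}
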