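test_that("cycle assignment splits exactly at gaps over the threshold", {
  # gaps of 9.9 h throughout: one cycle
  fx <- make_fixes("b1", seq(0, by = 9.9, length.out = 6), 50, 0)
  expect_equal(unique(assign_cycles(fx)$cycle), 1L)
  # alternating 1 h / 11 h gaps over 6 fixes: 3 cycles of 2
  fx2 <- make_fixes("b1", cumsum(c(0, 1, 11, 1, 11, 1)), 50, 0)
  cyc <- assign_cycles(fx2)$cycle
  expect_equal(cyc, c(1L, 1L, 2L, 2L, 3L, 3L))
  # single fix: one cycle; empty input: empty output
  expect_equal(assign_cycles(make_fixes("b1", 0, 50, 0))$cycle, 1L)
  expect_equal(nrow(assign_cycles(make_fixes(character(), numeric(),
                                             numeric(), numeric()))), 0)
  # boundary is strict: exactly 10 h stays in one cycle
  fx3 <- make_fixes("b1", c(0, 10, 20.0001), 50, 0)
  expect_equal(assign_cycles(fx3)$cycle, c(1L, 1L, 2L))
})

test_that("best-of-cycle honours quality, median distance, then time", {
  one <- assign_cycles(make_fixes("b1", 5, 50, 0))
  expect_equal(nrow(cycle_best_fixes(one)), 1)
  # classes (3,1,3) with equidistant positions: earlier class-3 fix wins
  fx <- assign_cycles(make_fixes("b1", c(0, 1, 2), c(50, 50, 50),
                                 c(0.1, 0, -0.1), lc = c("3", "1", "3")))
  best <- cycle_best_fixes(fx)
  expect_equal(best$t, fx$t[1])
  # 20 noisy fixes with one 200-km outlier of equal class: outlier rejected
  set.seed(9)
  lat <- 50 + rnorm(20, 0, 0.01); lon <- rnorm(20, 0, 0.01)
  lat[7] <- 51.8   # ~200 km north
  fx2 <- assign_cycles(make_fixes("b1", seq(0, 9.5, length.out = 20),
                                  lat, lon))
  best2 <- cycle_best_fixes(fx2)
  expect_lt(haversine_km(best2$lat, best2$lon, 50, 0), 10)
})

test_that("stopover detection applies the 50-km and one-day rules", {
  mk <- function(sep_km, span_h) {
    fx <- make_fixes("b1", c(0, span_h), c(20, 20 + sep_km / 111.1949), 0)
    cycle_best_fixes(assign_cycles(fx))
  }
  # 49.9 km apart over 58 h: one stopover
  expect_equal(nrow(detect_stopovers(mk(49.9, 58))), 1)
  # 50.1 km apart: none (50-km test is inclusive, this is beyond it)
  expect_equal(nrow(detect_stopovers(mk(50.1, 58))), 0)
  # co-located but only 20 h span: omitted (< 1 day)
  expect_equal(nrow(detect_stopovers(mk(0, 20))), 0)
  # co-located for 25 h: retained
  st <- detect_stopovers(mk(0, 25))
  expect_equal(nrow(st), 1)
  expect_equal(st$n_cycles, 2L)
  # exactly 24 h: retained (boundary inclusive)
  expect_equal(nrow(detect_stopovers(mk(0, 24))), 1)
})

test_that("stopover centroid test uses the running centroid", {
  # drifting chain: consecutive best fixes 40 km apart; the third is 80 km
  # from the first but only ~53 km from the running centroid -> rejected,
  # while a 30-km drift chain stays in one stopover
  drift <- function(step_km, n) {
    fx <- make_fixes("b1", seq(0, by = 58, length.out = n),
                     20 + (0:(n - 1)) * step_km / 111.1949, 0)
    detect_stopovers(cycle_best_fixes(assign_cycles(fx)))
  }
  expect_equal(nrow(drift(30, 4)), 1)   # centroid keeps up
  expect_equal(nrow(drift(60, 4)), 0)   # every step beyond the radius
})

test_that("gap extension moves the stopover end by whole missed cycles", {
  # five cycles at one site (last at cycle k = 4 x 58 h), then the next fix
  # three cycle lengths later, with the bird elsewhere
  hrs <- c(seq(0, by = 58, length.out = 5), 4 * 58 + 3 * 58)
  lat <- c(rep(20, 5), 25)   # ~550 km away afterwards
  bf <- cycle_best_fixes(assign_cycles(make_fixes("b1", hrs, lat, 0)))
  st0 <- detect_stopovers(bf)
  expect_equal(nrow(st0), 1)
  st <- extend_through_gaps(st0, bf)
  expect_true(st$gap_extended)
  # last fix at cycle k, next observed at k+3: end extended by 2 x 58 h
  expect_equal(as.numeric(difftime(st$end, st0$end, units = "hours")), 2 * 58)

  # no missing cycles: unchanged
  bf2 <- cycle_best_fixes(assign_cycles(make_fixes(
    "b1", c(seq(0, by = 58, length.out = 5), 5 * 58), c(rep(20, 5), 25), 0)))
  st2 <- detect_stopovers(bf2)
  expect_equal(extend_through_gaps(st2, bf2)$end, st2$end)
  expect_false(extend_through_gaps(st2, bf2)$gap_extended)

  # missing cycles followed by a fix at the SAME location: bridged inside
  # the stopover, no extension flag
  hrs3 <- c(seq(0, by = 58, length.out = 5), 4 * 58 + 3 * 58)
  bf3 <- cycle_best_fixes(assign_cycles(make_fixes("b1", hrs3, 20, 0)))
  st3 <- extend_through_gaps(detect_stopovers(bf3), bf3)
  expect_equal(nrow(st3), 1)
  expect_false(st3$gap_extended)
  expect_equal(as.numeric(difftime(st3$end, st3$start, units = "hours")),
               7 * 58)
})

test_that("stopovers are time-ordered, non-overlapping, and idempotent", {
  st <- clean_seg$stopovers
  by_bird <- split(st, st$bird_id)
  for (s in by_bird) {
    if (nrow(s) < 2) next
    s <- s[order(s$start), ]
    expect_true(all(as.numeric(diff(s$start)) > 0))
    expect_true(all(s$start[-1] >= s$end[-nrow(s)]))
  }
  # re-running detection on the member best fixes reproduces each stopover
  bf <- clean_seg$best_fixes
  s1 <- st[st$bird_id == st$bird_id[1], ][1, ]
  members <- bf[bf$bird_id == s1$bird_id &
                  bf$cycle >= s1$first_cycle & bf$cycle <= s1$last_cycle, ]
  again <- detect_stopovers(members)
  expect_equal(nrow(again), 1)
  expect_equal(again$lat, s1$lat, tolerance = 1e-9)
  expect_equal(again$n_cycles, s1$n_cycles)
})

test_that("noise-free stopover centroids sit on true waypoints", {
  # every detected stopover in the clean cohort should be within ~1 km of
  # one of the bird's true hold locations
  coh <- clean_cohort
  dmin <- c()
  for (b in unique(coh$truth$bird_id)) {
    rows <- coh$truth[coh$truth$bird_id == b, ]
    holds <- do.call(rbind, lapply(seq_len(nrow(rows)), function(r) {
      do.call(rbind, migrapath:::route_waypoints(rows[r, ]))
    }))
    st <- clean_seg$stopovers[clean_seg$stopovers$bird_id == b, ]
    for (i in seq_len(nrow(st))) {
      dmin <- c(dmin, min(haversine_km(st$lat[i], st$lon[i], holds[, "lat"],
                                       holds[, "lon"])))
    }
  }
  # a departure-straddling transmission burst can pull a centroid a little
  # off the waypoint; the bulk sit on it exactly
  expect_gt(mean(dmin < 1), 0.95)
  expect_lt(max(dmin), 5)
})
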