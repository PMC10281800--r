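test_that("noise-free extraction recovers every true milestone within one duty cycle", {
  tl <- truth_long(clean_cohort)
  cmp <- dplyr::inner_join(clean_ms, tl, by = c("bird_id", "cycle_id", "kind"))
  # nearly every true milestone is found (rare end-of-window cases excepted)
  expect_gt(nrow(cmp) / nrow(tl), 0.97)
  err_h <- (cmp$cycle_day - cmp$true_day) * 24
  expect_true(all(abs(err_h) <= 58))
})

test_that("milestone dates are monotone within each bird-cycle", {
  expect_true(assert_milestone_order(clean_ms))
  bad <- clean_ms[1:2, ]
  bad$kind <- c("depart_breeding", "complete_sahara_south")
  bad$cycle_id <- 2015L
  bad$cycle_day <- c(100, 50)
  expect_error(assert_milestone_order(bad), "non-monotone")
})

test_that("a hand-placed southbound Sahara straddle dates the crossing", {
  # northern-side fix then a fix south of the Sahara on day 80
  fx <- make_fixes("b1", c(
    seq(0, by = 58, length.out = 3),              # breeding stopover
    30 * 24,                                      # southbound, mid Europe
    80 * 24,                                      # south of the Sahara
    seq(130 * 24, by = 58, length.out = 3),       # wintering stopover
    seq(250 * 24, by = 58, length.out = 2)),
    c(53, 53, 53, 45, 14, 1, 1, 1, 1, 1),
    c(-1, -1, -1, 0, -1, 22, 22, 22, 22, 22))
  meta <- tibble::tibble(bird_id = "b1", breeding_lat = 53, breeding_lon = -1)
  seg <- segment_track(fx)
  ms <- extract_milestones(seg$stopovers, seg$best_fixes, regions_fixture, meta)
  m2 <- ms[ms$kind == "complete_sahara_south", ]
  expect_equal(nrow(m2), 1)
  expect_equal(m2$cycle_day, 80, tolerance = 1e-9)
  # arrival-type uncertainty: gap back to the previous fix (50 days)
  expect_equal(m2$uncertainty_days, 50, tolerance = 1e-6)
})

test_that("a bird dying right after leaving the breeding grounds yields only departure", {
  ml <- tibble::tibble(stage = 1:6, intercept = c(50, rep(-50, 5)), slope = 0)
  cfg <- sim_config(n_birds = 5, n_years = 1, p_missed_cycle = 0,
                    fix_noise_km = 0, mortality_logit = ml, seed = 81)
  coh <- simulate_cohort(cfg)
  seg <- segment_track(coh$fixes)
  ms <- extract_milestones(seg$stopovers, seg$best_fixes, regions_fixture,
                           coh$meta)
  expect_true(all(ms$kind == "depart_breeding"))
})

test_that("uncertainty follows the next/previous-fix rule with the Sahara override", {
  bf <- make_fixes("b1", c(0, 3.2 * 24, 9.2 * 24), c(10.5, 10.5, 25), 0)
  # departure milestone based at t=0: gap to NEXT fix = 3.2 days
  m_dep <- tibble::tibble(bird_id = "b1", kind = "depart_winter",
                          basis_t = bf$t[1], basis_lat = 1, basis_lon = 22)
  expect_equal(milestone_uncertainty(m_dep, bf, regions_fixture), 3.2,
               tolerance = 1e-6)
  # arrival milestone at the second fix: gap to PREVIOUS fix
  m_arr <- tibble::tibble(bird_id = "b1", kind = "arrive_winter",
                          basis_t = bf$t[2], basis_lat = 1, basis_lon = 22)
  expect_equal(milestone_uncertainty(m_arr, bf, regions_fixture), 3.2,
               tolerance = 1e-6)
  # West-Africa departure based on a Sahara-interior fix: exactly 2 days,
  # regardless of a 6-day neighbouring gap
  m_wa <- tibble::tibble(bird_id = "b1", kind = "depart_west_africa",
                         basis_t = bf$t[3], basis_lat = 25, basis_lon = 0)
  expect_equal(milestone_uncertainty(m_wa, bf, regions_fixture), 2)
  # same milestone based outside the Sahara keeps the fix-gap rule
  m_wa2 <- tibble::tibble(bird_id = "b1", kind = "depart_west_africa",
                          basis_t = bf$t[1], basis_lat = 10.5, basis_lon = 0)
  expect_equal(milestone_uncertainty(m_wa2, bf, regions_fixture), 3.2,
               tolerance = 1e-6)
  # adjacent fix in the same on-window: small gaps pass through
  bf2 <- make_fixes("b1", c(0, 0.2 * 24), 10.5, 0)
  m3 <- tibble::tibble(bird_id = "b1", kind = "depart_winter",
                       basis_t = bf2$t[1], basis_lat = 1, basis_lon = 22)
  expect_equal(milestone_uncertainty(m3, bf2, regions_fixture), 0.2,
               tolerance = 1e-6)
})

test_that("the uncertainty filter keeps the boundary and is monotone", {
  ms <- tibble::tibble(bird_id = "b", cycle_id = 2015L, kind = "arrive_winter",
                       uncertainty_days = c(4.9, 5.0, 5.1))
  kept <- filter_uncertain(ms)
  expect_equal(kept$uncertainty_days, c(4.9, 5.0))
  expect_equal(nrow(filter_uncertain(ms[0, ])), 0)
  # monotone: raising the threshold never removes a retained milestone
  set.seed(13)
  ms2 <- tibble::tibble(bird_id = "b", cycle_id = 2015L, kind = "x",
                        uncertainty_days = runif(200, 0, 10))
  k5 <- filter_uncertain(ms2, 5)
  k7 <- filter_uncertain(ms2, 7)
  expect_true(all(k5$uncertainty_days %in% k7$uncertainty_days))
  # retained fraction matches a direct count
  expect_equal(nrow(k5), sum(ms2$uncertainty_days <= 5))
})

test_that("route classification uses transit, chords, then carry-forward", {
  # fix inside Iberia -> SW
  fx_sw <- make_fixes("b1", c(0, 58, 116, 200), c(53, 53, 40, 30),
                      c(-1, -1, -4, -8))
  bf <- cycle_best_fixes(assign_cycles(fx_sw))
  expect_equal(classify_routes(bf, regions_fixture)$route, "SW")
  # chord from (46N, 5E) to (40N, 12E) crosses the Italy polygon
  fx_se <- make_fixes("b1", c(0, 58, 116, 174), c(53, 53, 46, 40),
                      c(-1, -1, 5, 12.5))
  bf2 <- cycle_best_fixes(assign_cycles(fx_se))
  expect_equal(classify_routes(bf2, regions_fixture)$route, "SE")
  # lost before either polygon in year 2: inherit year 1's route
  origin <- as.POSIXct("2015-06-01", tz = "UTC")
  fx_y2 <- dplyr::bind_rows(
    fx_sw,
    make_fixes("b1", c(365 * 24, 365 * 24 + 58), 53, -1))
  bf3 <- cycle_best_fixes(assign_cycles(fx_y2))
  r <- classify_routes(bf3, regions_fixture)
  expect_equal(r$route, c("SW", "SW"))
  # never classifiable: unclassified
  fx_uk <- make_fixes("b1", c(0, 58), 53, -1)
  bf4 <- cycle_best_fixes(assign_cycles(fx_uk))
  expect_equal(classify_routes(bf4, regions_fixture)$route, "unclassified")
})

test_that("within-individual anomalies centre each bird-kind at zero", {
  ms <- tibble::tibble(
    bird_id = c("a", "a", "b", "b", "b", "c"),
    cycle_id = c(2015L, 2016L, 2015L, 2016L, 2017L, 2015L),
    kind = "arrive_winter",
    cycle_day = c(100, 104, 10, 20, 30, 50))
  an <- within_individual_anomaly(ms)
  expect_equal(an$anomaly_days[an$bird_id == "a"], c(-2, 2))
  expect_equal(an$anomaly_days[an$bird_id == "b"], c(-10, 0, 10))
  # the single-year bird is excluded from the repeat dataset
  expect_false("c" %in% an$bird_id)
  # sums are zero per bird-kind on real extracted milestones too
  an2 <- within_individual_anomaly(clean_ms)
  sums <- tapply(an2$anomaly_days, paste(an2$bird_id, an2$kind), sum)
  expect_true(all(abs(sums) < 1e-9))
})

test_that("dataset assembly separates full and repeat memberships", {
  ms <- tibble::tibble(
    bird_id = c("a", "a", "a", "b", "b", "c"),
    cycle_id = c(2015L, 2015L, 2016L, 2015L, 2016L, 2015L),
    kind = c("arrive_winter", "depart_winter", "arrive_winter",
             "arrive_winter", "arrive_winter", "arrive_winter"),
    cycle_day = c(130, 250, 140, 120, 125, 133),
    uncertainty_days = c(1, 2, 1, 8, 1, 1))
  ds <- build_datasets(ms)
  # the uncertain milestone dropped bird b's repeat membership
  expect_equal(nrow(ds$full), 5)
  expect_setequal(unique(ds$repeat_$bird_id), "a")
  # only the repeated kind enters the repeat dataset
  expect_setequal(unique(ds$repeat_$kind), "arrive_winter")
  # all single-year birds: empty repeat dataset
  ds2 <- build_datasets(ms[c(1, 2, 6), ])
  expect_equal(nrow(ds2$repeat_), 0)
  # exclusion list removes a bird entirely
  ds3 <- build_datasets(ms, exclude_birds = "a")
  expect_false("a" %in% ds3$full$bird_id)
  # histogram matches a known repeat structure
  expect_equal(ds$repeat_histogram$max_cycles, 2L)
  expect_equal(ds$repeat_histogram$n_birds, 1L)
})
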