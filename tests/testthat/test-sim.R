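test_that("seeded simulation is bit-reproducible", {
  c1 <- simulate_cohort(sim_config(n_birds = 4, n_years = 2, seed = 5))
  c2 <- simulate_cohort(sim_config(n_birds = 4, n_years = 2, seed = 5))
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$fixes, c2$fixes)
  c3 <- simulate_cohort(sim_config(n_birds = 4, n_years = 2, seed = 6))
  expect_false(identical(c1$fixes, c3$fixes))
})

test_that("a cyclic DAG is rejected with a cycle report", {
  ed <- tibble::tibble(from = c("arrive_winter", "depart_winter"),
                       to = c("depart_winter", "arrive_winter"),
                       beta = c(0.5, 0.5))
  expect_error(dag_spec(ed, endogenous = c("arrive_winter", "depart_winter"),
                        exogenous = character()),
               "cycle")
})

test_that("a null DAG yields i.i.d. milestone dates around their intercepts", {
  dag <- default_timing_dag()
  dag$edges$beta <- 0
  cfg <- sim_config(n_birds = 250, n_years = 1, dag = dag,
                    target_repeatability = 0, seed = 21)
  tr <- simulate_schedules(cfg)
  sc <- migrapath:::MILESTONE_SCALE
  for (i in seq_len(6)) {
    d <- tr[[paste0("date_", sc$kind[i])]]
    expect_equal(mean(d), sc$mean_days[i], tolerance = 0.25 * sc$sd_days[i])
    expect_equal(sd(d), sc$sd_days[i], tolerance = 0.15 * sc$sd_days[i])
    # no correlation with the adjacent milestone beyond noise
    if (i > 1) {
      r <- cor(d, tr[[paste0("date_", sc$kind[i - 1])]])
      expect_lt(abs(r), 3 / sqrt(nrow(tr)) + 0.05)
    }
  }
})

test_that("an OLS oracle on generated tables recovers a configured edge", {
  # only the Sahara-crossing -> West-Africa-departure edge, at 0.52
  dag <- default_timing_dag()
  dag$edges$beta <- 0
  dag$edges$beta[dag$edges$from == "complete_sahara_south" &
                   dag$edges$to == "depart_west_africa"] <- 0.52
  cfg <- sim_config(n_birds = 300, n_years = 1, dag = dag,
                    target_repeatability = 0, seed = 31)
  tr <- simulate_schedules(cfg)
  m2 <- scale(tr$date_complete_sahara_south)
  m5 <- scale(tr$date_depart_west_africa)
  f <- lm(m5 ~ m2)
  se <- summary(f)$coefficients["m2", "Std. Error"]
  expect_lt(abs(coef(f)["m2"] - 0.52), 3 * se)
})

test_that("the between-bird intercept SD sets true repeatability", {
  # sigma_between chosen for R = 0.5 on arrival at the wintering grounds
  dag <- default_timing_dag()
  dag$edges$beta <- 0
  sb <- setNames(migrapath:::MILESTONE_SCALE$sd_days * sqrt(0.5),
                 migrapath:::MILESTONE_KINDS)
  cfg <- sim_config(n_birds = 200, n_years = 4, dag = dag,
                    sigma_between = sb, seed = 41)
  tr <- simulate_schedules(cfg)
  d <- tr[, c("bird_id", "date_arrive_winter")]
  f <- lme4::lmer(date_arrive_winter ~ 1 + (1 | bird_id), data = d)
  vc <- as.data.frame(lme4::VarCorr(f))
  ratio <- vc$vcov[1] / vc$vcov[2]  # between / within, truth 1
  expect_gt(ratio, 0.75)
  expect_lt(ratio, 1.35)
})

test_that("duty cycling shapes the emitted fix stream", {
  cfg <- sim_config(n_birds = 3, n_years = 1, p_missed_cycle = 0,
                    fix_noise_km = 0, seed = 51)
  coh <- simulate_cohort(cfg)
  for (b in unique(coh$fixes$bird_id)) {
    tt <- coh$fixes$t[coh$fixes$bird_id == b]
    expect_true(all(diff(as.numeric(tt)) > 0))   # strictly increasing
    gaps_h <- diff(as.numeric(tt)) / 3600
    # between-burst gaps are at least the off time
    expect_true(all(gaps_h[gaps_h > 2] >= 48))
    # expected on-windows over a stationary 29-day stretch: 29*24/58 = 12
    tr <- coh$truth[coh$truth$bird_id == b, ][1, ]
    origin <- as.POSIXct("2015-06-01", tz = "UTC")
    w0 <- tr$date_arrive_winter + 1; w1 <- w0 + 29
    in_win <- tt[tt >= origin + w0 * 86400 & tt < origin + w1 * 86400]
    n_bursts <- sum(diff(as.numeric(in_win)) / 3600 > 2) + 1
    expect_equal(n_bursts, 12, tolerance = 1e-9)
  }
})

test_that("stage-wise mortality follows the configured logits", {
  # intercepts at -50: nobody dies
  cfg0 <- sim_config(n_birds = 40, n_years = 2, seed = 61)
  expect_true(all(is.na(simulate_schedules(cfg0)$death_stage)))
  # intercept 0, slope 0 at stage 1: death probability one half
  ml <- tibble::tibble(stage = 1:6, intercept = c(0, rep(-50, 5)), slope = 0)
  cfg1 <- sim_config(n_birds = 600, n_years = 1, mortality_logit = ml,
                     seed = 62)
  tr1 <- simulate_schedules(cfg1)
  expect_true(all(is.na(tr1$death_stage) | tr1$death_stage == 1))
  expect_equal(mean(!is.na(tr1$death_stage)), 0.5, tolerance = 0.07)
  # a logistic fit on truth recovers the generating slope
  ml2 <- tibble::tibble(stage = 1:6,
                        intercept = c(-50, -2, rep(-50, 4)),
                        slope = c(0, -1.5, 0, 0, 0, 0))
  cfg2 <- sim_config(n_birds = 2000, n_years = 1, mortality_logit = ml2,
                     seed = 63)
  tr2 <- simulate_schedules(cfg2)
  died <- as.integer(!is.na(tr2$death_stage))
  f <- glm(died ~ tr2$z_complete_sahara_south, family = binomial)
  se <- summary(f)$coefficients[2, "Std. Error"]
  expect_lt(abs(coef(f)[2] - (-1.5)), 3 * se)
})

test_that("death truncates the track before the next milestone region", {
  ml <- tibble::tibble(stage = 1:6, intercept = c(50, rep(-50, 5)), slope = 0)
  cfg <- sim_config(n_birds = 6, n_years = 1, mortality_logit = ml, seed = 71)
  coh <- simulate_cohort(cfg)
  expect_true(all(coh$truth$death_stage == 1))
  # no fixes south of the Sahara polygon
  sah <- regions_fixture$sahara
  expect_true(all(coh$fixes$lat >= min(sah[, "lat"])))
})

test_that("true milestone dates are strictly increasing within a cycle", {
  tr <- clean_cohort$truth
  dts <- as.matrix(tr[, paste0("date_", migrapath:::MILESTONE_KINDS)])
  for (i in seq_len(nrow(dts))) {
    d <- dts[i, !is.na(dts[i, ])]
    expect_true(all(diff(d) > 0))
  }
})
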