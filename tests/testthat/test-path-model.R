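test_that("standardization has the closed form and is idempotent", {
  d <- data.frame(x = c(0, 10, 20))
  z <- standardize(d, "x")$x
  expect_equal(z, c(-1, 0, 1))        # sample-SD convention
  d2 <- data.frame(x = c(0, 10, 20, NA))
  z2 <- standardize(d2, "x")$x
  expect_equal(mean(z2, na.rm = TRUE), 0)
  expect_equal(sd(z2, na.rm = TRUE), 1)
  expect_error(standardize(data.frame(x = rep(3, 5)), "x"), "constant")
  expect_equal(standardize(standardize(d, "x"), "x")$x, z, tolerance = 1e-12)
})

test_that("edge probability is the probability of direction", {
  expect_equal(edge_probability(rep(2, 100)), 1)
  expect_equal(edge_probability(c(-1, 1, -2, 2)), 0.5)
  set.seed(2)
  expect_equal(edge_probability(rnorm(4000, 1, 1)), pnorm(1), tolerance = 0.02)
})

test_that("the variance-share calculus reproduces squared-coefficient arithmetic", {
  expect_equal(variance_explained(0.883), 77.97, tolerance = 0.005)
  expect_equal(round(variance_explained(0.883), 1), 78.0)
  expect_equal(variance_explained(0), 0)
  expect_equal(variance_explained(-0.329), variance_explained(0.329))
  expect_equal(round(variance_explained(-0.329), 1), 10.8)
  # chained shares multiply
  expect_equal(chain_variance_share(c(15.8, 26.6, 78.0)), 3.278, tolerance = 0.01)
  expect_equal(chain_variance_share(c(50, 0, 80)), 0)
  expect_equal(chain_variance_share(c(7.5, 78.0)), 5.85, tolerance = 0.01)
  # residual decomposition
  expect_equal(residual_share(c(78.0, 10.8)), 11.2, tolerance = 1e-9)
})

test_that("posterior means match node-wise least squares on complete data", {
  dag <- default_timing_dag()
  cfg <- sim_config(n_birds = 400, n_years = 1, target_repeatability = 0,
                    seed = 91)
  dat <- truth_node_table(simulate_schedules(cfg))
  dat <- standardize(dat)
  fit <- fit_path_model(dat, dag, fast_mcmc(5))
  expect_true(fit$converged)
  for (v in dag$endogenous) {
    pa <- dag$edges$from[dag$edges$to == v]
    lmf <- lm(reformulate(pa, v), data = dat)
    for (p in pa) {
      post <- fit$edges[fit$edges$from == p & fit$edges$to == v, ]
      expect_lt(abs(post$mean - coef(lmf)[p]) / post$sd, 3)
    }
  }
  # R^2 equals the squared coefficient draw-wise
  e <- fit$draws[, "depart_west_africa->arrive_breeding"]
  expect_equal(median(100 * e^2),
               fit$edges$r2_pct[fit$edges$from == "depart_west_africa" &
                                  fit$edges$to == "arrive_breeding"],
               tolerance = 1e-12)
})

test_that("a strong generating edge is recovered through missing data", {
  dag <- default_timing_dag()
  cfg <- sim_config(n_birds = 150, n_years = 1, target_repeatability = 0,
                    seed = 92)
  dat <- truth_node_table(simulate_schedules(cfg))
  set.seed(7)
  for (k in migrapath:::MILESTONE_KINDS) {
    dat[[k]][runif(nrow(dat)) < 0.2] <- NA   # 20% missing at random
  }
  dat <- standardize(dat)
  fit <- fit_path_model(dat, dag, fast_mcmc(6))
  key <- fit$edges[fit$edges$from == "depart_west_africa" &
                     fit$edges$to == "arrive_breeding", ]
  expect_lt(abs(key$mean - 0.883) / key$sd, 3)
  expect_equal(key$tier, "very well-supported")
})

test_that("non-identifiable nodes are rejected by name", {
  dag <- default_timing_dag()
  dat <- standardize(truth_node_table(
    simulate_schedules(sim_config(n_birds = 200, n_years = 1, seed = 93))))
  expect_error(fit_path_model(dat[1:5, ], dag, fast_mcmc(1)),
               "non-identifiable")
})

test_that("indirect effects multiply edge draws along the declared path", {
  dag <- default_timing_dag()
  cfg <- sim_config(n_birds = 300, n_years = 1, target_repeatability = 0,
                    seed = 94)
  dat <- standardize(truth_node_table(simulate_schedules(cfg)))
  fit <- fit_path_model(dat, dag, fast_mcmc(7))
  ie <- indirect_effect(fit, c("depart_breeding", "complete_sahara_south",
                               "depart_west_africa", "arrive_breeding"))
  manual <- fit$draws[, "depart_breeding->complete_sahara_south"] *
    fit$draws[, "complete_sahara_south->depart_west_africa"] *
    fit$draws[, "depart_west_africa->arrive_breeding"]
  expect_equal(ie$median, median(manual), tolerance = 1e-12)
  # chained share equals the product of stage shares exactly
  s <- vapply(c("depart_breeding->complete_sahara_south",
                "complete_sahara_south->depart_west_africa",
                "depart_west_africa->arrive_breeding"),
              function(k) median(100 * fit$draws[, k]^2), double(1))
  expect_equal(ie$share_pct, 100 * prod(s / 100), tolerance = 1e-12)
  expect_error(indirect_effect(fit, c("arrive_breeding", "depart_breeding")),
               "absent edge")
})

test_that("directed-separation testing flags the edge the DAG misses", {
  # saturated two-node DAG: empty basis set
  sat <- dag_spec(tibble::tibble(from = "a", to = "b", beta = 1),
                  endogenous = "b", exogenous = "a")
  d0 <- data.frame(a = rnorm(50), b = rnorm(50))
  r0 <- dsep_test(d0, sat)
  expect_equal(nrow(r0$claims), 0)
  expect_equal(r0$C, 0); expect_equal(r0$p_value, 1)

  # data generated with a strong Sahara-crossing -> West-Africa edge, fitted
  # DAG lacking it: the claim for that pair is rejected at small p
  dag_full <- default_timing_dag()
  dag_red <- dag_full
  dag_red$edges <- dag_red$edges[!(dag_red$edges$from == "complete_sahara_south" &
                                     dag_red$edges$to == "depart_west_africa"), ]
  cfg <- sim_config(n_birds = 137, n_years = 1, target_repeatability = 0,
                    seed = 95)
  dat <- standardize(truth_node_table(simulate_schedules(cfg)))
  r <- dsep_test(dat, dag_red)
  claim <- r$claims[r$claims$from == "complete_sahara_south" &
                      r$claims$to == "depart_west_africa", ]
  expect_equal(nrow(claim), 1)
  expect_lt(claim$p, 0.01)
  expect_lt(r$p_value, 0.05)
})

test_that("path summaries tier and suppress edges by support", {
  dag <- default_timing_dag()
  cfg <- sim_config(n_birds = 400, n_years = 1, target_repeatability = 0,
                    seed = 96)
  dat <- standardize(truth_node_table(simulate_schedules(cfg)))
  fit <- fit_path_model(dat, dag, fast_mcmc(8))
  tab <- summarize_paths(fit)
  expect_true(all(tab$p_nonzero >= 0.80))
  # the strong generating edges all reach the top tier
  strong <- dag$edges[abs(dag$edges$beta) >= 0.3, ]
  for (i in seq_len(nrow(strong))) {
    row <- tab[tab$from == strong$from[i] & tab$to == strong$to[i], ]
    expect_equal(row$tier, "very well-supported")
  }
  expect_equal(migrapath:::support_tier(c(0.94, 0.79, 0.96, 0.85)),
               c("well-supported", "unsupported", "very well-supported",
                 "likely"))
})
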