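# Timing -> mortality path models: for each milestone (departure from the
# wintering grounds excluded), a two-equation model of (1) standardized
# milestone timing on breeding habitat and migration route, and (2) death
# during the following migration stage as a Bayesian logistic regression on
# timing, habitat, route and the habitat x timing interaction. A combined
# fit pools the three milestones whose stages most positively impact
# breeding-grounds arrival, with milestone-specific intercepts and a shared
# timing slope (timing standardized within milestone before pooling).

#' Assemble per-milestone mortality records
#'
#' One record per bird-cycle-milestone: standardized timing (within
#' milestone kind), habitat and route covariates (0/1), and a binary
#' indicator of death during the following migration stage. Records whose
#' death is flagged uncertain (possible tag failure) are dropped and
#' counted. Departure from the wintering grounds is excluded.
#'
#' @param milestones Retained milestone tibble (`bird_id`, `cycle_id`,
#'   `kind`, `cycle_day`).
#' @param deaths Tibble of death events: `bird_id`, `cycle_id`, `kind`
#'   (the milestone after which the bird died), `certain` (logical).
#' @param meta Bird metadata (`bird_id`, `habitat`, `route`).
#' @param exclude_kinds Milestones excluded from the analysis.
#' @return Tibble of records with attribute `n_uncertain_dropped`.
#' @export
build_mortality_dataset <- function(milestones, deaths, meta,
                                    exclude_kinds = "depart_winter") {
  deaths <- tibble::as_tibble(deaths)
  uncertain <- deaths[!deaths$certain, , drop = FALSE]
  certain <- deaths[deaths$certain, , drop = FALSE]
  rec <- milestones |>
    dplyr::filter(!.data$kind %in% exclude_kinds) |>
    dplyr::left_join(
      certain |> dplyr::mutate(died = 1L) |>
        dplyr::select("bird_id", "cycle_id", "kind", "died"),
      by = c("bird_id", "cycle_id", "kind")) |>
    dplyr::mutate(died = dplyr::coalesce(.data$died, 0L)) |>
    dplyr::anti_join(uncertain |> dplyr::select("bird_id", "cycle_id", "kind"),
                     by = c("bird_id", "cycle_id", "kind")) |>
    dplyr::left_join(meta |> dplyr::select("bird_id", "habitat", "route"),
                     by = "bird_id") |>
    dplyr::mutate(
      upland = as.integer(.data$habitat == "upland"),
      sw_route = as.integer(.data$route == "SW")) |>
    dplyr::group_by(.data$kind) |>
    dplyr::mutate(timing_z = (.data$cycle_day - mean(.data$cycle_day)) /
                    stats::sd(.data$cycle_day)) |>
    dplyr::ungroup() |>
    dplyr::select("bird_id", "cycle_id", "kind", "timing_z", "upland",
                  "sw_route", "died")
  attr(rec, "n_uncertain_dropped") <- nrow(uncertain)
  rec
}

# Random-walk Metropolis for logistic regression with N(0, prior_sd^2)
# priors; proposal covariance from the ML fit where available, step size
# adapted during burn-in toward ~23% acceptance.
bayes_logistic <- function(X, y, mcmc, prior_sd = 5) {
  p <- ncol(X); n <- nrow(X)
  loglik <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - log1p(exp(eta))) - sum(b^2) / (2 * prior_sd^2)
  }
  Lprop <- tryCatch({
    fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
    eta <- drop(X %*% fit$coefficients)
    w <- stats::plogis(eta) * (1 - stats::plogis(eta))
    H <- crossprod(X * sqrt(w)) + diag(1 / prior_sd^2, p)
    t(chol(chol2inv(chol(H))))
  }, error = function(e) diag(0.5, p))
  total <- mcmc$burnin + mcmc$draws
  chains <- vector("list", mcmc$chains)
  accept <- numeric(mcmc$chains)
  for (ch in seq_len(mcmc$chains)) {
    b <- stats::rnorm(p, 0, 0.5)
    ll <- loglik(b)
    step <- 2.38 / sqrt(p)
    out <- matrix(NA_real_, mcmc$draws, p)
    acc <- 0L
    for (it in seq_len(total)) {
      prop <- b + step * drop(Lprop %*% stats::rnorm(p))
      llp <- loglik(prop)
      if (log(stats::runif(1)) < llp - ll) {
        b <- prop; ll <- llp
        if (it > mcmc$burnin) acc <- acc + 1L
        if (it <= mcmc$burnin) step <- step * 1.02
      } else if (it <= mcmc$burnin) step <- step * 0.99
      if (it > mcmc$burnin) out[it - mcmc$burnin, ] <- b
    }
    colnames(out) <- colnames(X)
    chains[[ch]] <- out
    accept[ch] <- acc / mcmc$draws
  }
  list(chains = chains, draws = do.call(rbind, chains), accept = accept)
}

summarize_coef_draws <- function(draws, chains) {
  tibble::tibble(
    term = colnames(draws),
    median = unname(apply(draws, 2, stats::median)),
    mean = unname(colMeans(draws)),
    sd = unname(apply(draws, 2, stats::sd)),
    lower = unname(apply(draws, 2, stats::quantile, 0.025)),
    upper = unname(apply(draws, 2, stats::quantile, 0.975)),
    p_nonzero = unname(apply(draws, 2, edge_probability)),
    rhat = vapply(seq_len(ncol(draws)), function(j) {
      gelman_rubin(sapply(chains, function(m) m[, j]))
    }, double(1)))
}

#' Fit the per-milestone timing -> mortality path model
#'
#' Bayesian logistic regression of death during the following stage on
#' standardized timing, habitat (upland), route (southwest) and the
#' habitat x timing interaction, together with a linear sub-model of
#' timing on habitat and route. Priors: Normal(0, 5^2) on all logistic
#' coefficients. An all-survivor (or all-death) outcome yields a flagged
#' prior-dominated fit with a warning, not an error.
#'
#' @param records Records for one milestone from
#'   [build_mortality_dataset()].
#' @param mcmc [mcmc_settings()].
#' @param prior_sd Prior SD on logistic coefficients.
#' @param interaction Include the habitat x timing interaction (default
#'   TRUE).
#' @return A `mortality_fit`: `coefficients` (posterior summary including
#'   `lowland_slope` and `upland_slope` timing contrasts), `timing_model`
#'   (posterior summary of the timing sub-model), `draws`, `converged`,
#'   `prior_dominated`, `n`, `n_deaths`.
#' @export
fit_mortality_model <- function(records, mcmc = mcmc_settings(), prior_sd = 5,
                                interaction = TRUE) {
  y <- records$died
  X <- cbind(intercept = 1, timing = records$timing_z,
             upland = records$upland, sw_route = records$sw_route)
  if (interaction) X <- cbind(X, `upland:timing` = records$upland * records$timing_z)
  prior_dominated <- length(unique(y)) < 2
  if (prior_dominated) {
    warning("outcome has a single class; fit is prior-dominated")
  }
  set.seed(mcmc$seed)
  bl <- bayes_logistic(X, y, mcmc, prior_sd)
  coefs <- summarize_coef_draws(bl$draws, bl$chains)
  # within-stratum timing effects
  low <- bl$draws[, "timing"]
  up <- if (interaction) low + bl$draws[, "upland:timing"] else low
  strata <- tibble::tibble(
    term = c("lowland_slope", "upland_slope"),
    median = c(stats::median(low), stats::median(up)),
    mean = c(mean(low), mean(up)),
    sd = c(stats::sd(low), stats::sd(up)),
    lower = c(stats::quantile(low, 0.025), stats::quantile(up, 0.025)),
    upper = c(stats::quantile(low, 0.975), stats::quantile(up, 0.975)),
    p_nonzero = c(edge_probability(low), edge_probability(up)),
    rhat = NA_real_)
  # linear sub-model: timing on habitat + route (conjugate, closed form
  # draws via normal-inverse-gamma Gibbs)
  tm <- bayes_linear(cbind(intercept = 1, upland = records$upland,
                           sw_route = records$sw_route),
                     records$timing_z, mcmc)
  structure(list(
    coefficients = dplyr::bind_rows(coefs, strata),
    timing_model = tm$summary,
    draws = bl$draws, accept = bl$accept,
    converged = all(coefs$rhat < 1.1, tm$summary$rhat < 1.1),
    prior_dominated = prior_dominated,
    n = nrow(records), n_deaths = sum(y)), class = "mortality_fit")
}

bayes_linear <- function(X, y, mcmc, prior_sd = 5, prior_a = 0.001,
                         prior_b = 0.001) {
  p <- ncol(X); n <- nrow(X)
  total <- mcmc$burnin + mcmc$draws
  chains <- vector("list", mcmc$chains)
  for (ch in seq_len(mcmc$chains)) {
    s2 <- 1
    out <- matrix(NA_real_, mcmc$draws, p, dimnames = list(NULL, colnames(X)))
    XtX <- crossprod(X); Xty <- crossprod(X, y)
    for (it in seq_len(total)) {
      Vinv <- XtX / s2 + diag(1 / prior_sd^2, p)
      chV <- chol(Vinv)
      m <- backsolve(chV, forwardsolve(t(chV), Xty / s2))
      b <- drop(m + backsolve(chV, stats::rnorm(p)))
      s2 <- 1 / stats::rgamma(1, prior_a + n / 2,
                              prior_b + sum((y - X %*% b)^2) / 2)
      if (it > mcmc$burnin) out[it - mcmc$burnin, ] <- b
    }
    chains[[ch]] <- out
  }
  draws <- do.call(rbind, chains)
  list(draws = draws, summary = summarize_coef_draws(draws, chains))
}

#' Combined three-milestone mortality fit
#'
#' Pools the records of the milestones following the stages that most
#' positively impact breeding-grounds arrival (southbound Sahara crossing,
#' departure from West Africa, arrival at the breeding grounds) with
#' milestone-specific intercepts and a shared timing slope. Timing must
#' already be standardized within milestone (as
#' [build_mortality_dataset()] does).
#'
#' @param records Pooled records (column `kind` distinguishes milestones).
#' @param mcmc [mcmc_settings()].
#' @param prior_sd Prior SD on coefficients.
#' @return A `mortality_fit` with terms `timing` (shared slope) and one
#'   intercept per milestone present.
#' @export
combined_milestones_fit <- function(records, mcmc = mcmc_settings(),
                                    prior_sd = 5) {
  kinds <- unique(records$kind)
  Xk <- sapply(kinds, function(k) as.integer(records$kind == k))
  colnames(Xk) <- paste0("intercept_", kinds)
  X <- cbind(Xk, timing = records$timing_z)
  y <- records$died
  prior_dominated <- length(unique(y)) < 2
  if (prior_dominated) {
    warning("outcome has a single class; fit is prior-dominated")
  }
  set.seed(mcmc$seed)
  bl <- bayes_logistic(X, y, mcmc, prior_sd)
  coefs <- summarize_coef_draws(bl$draws, bl$chains)
  structure(list(
    coefficients = coefs, timing_model = NULL, draws = bl$draws,
    accept = bl$accept, converged = all(coefs$rhat < 1.1),
    prior_dominated = prior_dominated,
    n = nrow(records), n_deaths = sum(y)), class = "mortality_fit")
}

#' @export
print.mortality_fit <- function(x, ...) {
  cat("Bayesian timing->mortality fit:", x$n, "records,", x$n_deaths,
      "deaths", if (x$converged) "(converged)\n" else "(NOT converged)\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
tidy.mortality_fit <- function(x, ...) x$coefficients

#' @export
glance.mortality_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_deaths = x$n_deaths, converged = x$converged,
                 prior_dominated = x$prior_dominated)
}

#' Deaths table from simulated truth
#'
#' Converts the simulator's per-cycle `death_stage` into the deaths format
#' consumed by [build_mortality_dataset()].
#'
#' @param truth Output of [simulate_schedules()].
#' @param p_uncertain Probability a death event is flagged uncertain
#'   (emulating possible tag failures); default 0.
#' @param start_year First calendar year of the simulation (cycle ids).
#' @return Tibble `bird_id`, `cycle_id`, `kind`, `certain`.
#' @export
deaths_from_truth <- function(truth, p_uncertain = 0, start_year = 2015L) {
  d <- truth |>
    dplyr::filter(!is.na(.data$death_stage)) |>
    dplyr::mutate(
      cycle_id = as.integer(start_year) + .data$year - 1L,
      kind = MILESTONE_KINDS[.data$death_stage],
      certain = stats::runif(dplyr::n()) >= p_uncertain) |>
    dplyr::select("bird_id", "cycle_id", "kind", "certain")
  d
}
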