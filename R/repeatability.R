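# Timing variance, F-tests between consecutive milestones, and Bayesian
# variance-components repeatability. The variance-components model is the
# one-way random-intercept normal model
#   date_ij = mu + b_i + e_ij,  b_i ~ N(0, s2_between), e_ij ~ N(0, s2_within)
# fitted by a conjugate Gibbs sampler (normal / inverse-gamma updates).
# Repeatability R = s2_between / (s2_between + s2_within), draw-wise.

#' Sample variance of milestone dates with a posterior interval
#'
#' The point estimate is the ordinary sample variance (denominator n-1).
#' The 95% interval is the posterior of the variance in a normal model with
#' a flat prior on the mean and an inverse-gamma(`a`, `b`) prior on the
#' variance, which is available in closed form:
#' s2 | y ~ IG(a + (n-1)/2, b + SS/2).
#'
#' @param dates Numeric vector of dates (days), length >= 2.
#' @param level Interval level (default 0.95).
#' @param a,b Inverse-gamma prior parameters (default 0.001, 0.001).
#' @return Tibble with `variance`, `lower`, `upper`, `n`, `degenerate`.
#' @export
milestone_variance <- function(dates, level = 0.95, a = 0.001, b = 0.001) {
  dates <- dates[!is.na(dates)]
  n <- length(dates)
  if (n < 2) stop("need at least 2 dates to estimate a variance")
  v <- stats::var(dates)
  ss <- sum((dates - mean(dates))^2)
  shape <- a + (n - 1) / 2
  rate <- b + ss / 2
  alpha <- (1 - level) / 2
  degenerate <- v <= 0
  tibble::tibble(
    variance = v,
    lower = if (degenerate) 0 else 1 / stats::qgamma(1 - alpha, shape, rate),
    upper = if (degenerate) 0 else 1 / stats::qgamma(alpha, shape, rate),
    n = n, degenerate = degenerate)
}

#' Two-sided F-test comparing two timing variances
#'
#' @param v1,v2 Sample variances.
#' @param n1,n2 Sample sizes (df are n-1).
#' @return Tibble with `F`, `df1`, `df2`, `p` (two-sided,
#'   `2 * min(P(F<=f), P(F>=f))` capped at 1).
#' @export
variance_f_test <- function(v1, n1, v2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, v2 > 0)
  f <- v1 / v2
  df1 <- n1 - 1; df2 <- n2 - 1
  p <- 2 * min(stats::pf(f, df1, df2), stats::pf(f, df1, df2, lower.tail = FALSE))
  tibble::tibble(F = f, df1 = df1, df2 = df2, p = min(p, 1))
}

#' MCMC settings
#'
#' Defaults follow the fitting conventions used throughout: 4 chains, the
#' first 2000 iterations discarded as burn-in and the next 4000 retained,
#' convergence declared iff split-chain Rhat < 1.1 for all parameters.
#'
#' @param chains,burnin,draws,seed Integers.
#' @return A list.
#' @export
mcmc_settings <- function(chains = 4, burnin = 2000, draws = 4000, seed = 1L) {
  stopifnot(chains >= 1, burnin >= 0, draws >= 2)
  list(chains = as.integer(chains), burnin = as.integer(burnin),
       draws = as.integer(draws), seed = as.integer(seed))
}

#' Fit the Bayesian variance-components (repeatability) model
#'
#' Gibbs sampler for the one-way random-intercept normal model with no
#' fixed effects: date as response, individual as random effect. Priors:
#' inverse-gamma(0.001, 0.001) on both variances, Normal(0, 1000^2 days)
#' on the grand mean.
#'
#' @param dates Numeric response (days).
#' @param bird_ids Grouping factor (one level per individual).
#' @param mcmc [mcmc_settings()].
#' @param prior_a,prior_b Inverse-gamma prior parameters.
#' @return An object of class `vc_fit`: list with `draws` (tibble: chain,
#'   iter, mu, s2_between, s2_within, R), `summary`, `rhat`, `converged`,
#'   `n`, `n_birds`. Non-convergence flags the fit, it does not error.
#' @export
fit_variance_components <- function(dates, bird_ids, mcmc = mcmc_settings(),
                                    prior_a = 0.001, prior_b = 0.001) {
  keep <- !is.na(dates) & !is.na(bird_ids)
  y <- as.numeric(dates[keep])
  g <- factor(bird_ids[keep])
  n <- length(y); I <- nlevels(g)
  if (I < 2) stop("need at least 2 birds")
  ni <- as.numeric(table(g))
  if (max(ni) < 2) stop("need at least one bird with >= 2 records")
  gi <- as.integer(g)
  ysum_i <- as.numeric(rowsum(y, gi))
  total <- mcmc$burnin + mcmc$draws
  chains_out <- vector("list", mcmc$chains)
  set.seed(mcmc$seed)
  for (ch in seq_len(mcmc$chains)) {
    mu <- mean(y) + stats::rnorm(1, 0, stats::sd(y) / 4)
    s2b <- stats::var(y) / 2 * stats::runif(1, 0.5, 2)
    s2w <- stats::var(y) / 2 * stats::runif(1, 0.5, 2)
    b <- rep(0, I)
    out <- matrix(NA_real_, mcmc$draws, 3,
                  dimnames = list(NULL, c("mu", "s2_between", "s2_within")))
    for (it in seq_len(total)) {
      prec <- ni / s2w + 1 / s2b
      bmean <- (ysum_i - ni * mu) / s2w / prec
      b <- stats::rnorm(I, bmean, sqrt(1 / prec))
      r <- y - b[gi]
      prec_mu <- n / s2w + 1 / 1000^2
      mu <- stats::rnorm(1, sum(r) / s2w / prec_mu, sqrt(1 / prec_mu))
      s2b <- 1 / stats::rgamma(1, prior_a + I / 2, prior_b + sum(b^2) / 2)
      ssr <- sum((y - mu - b[gi])^2)
      s2w <- 1 / stats::rgamma(1, prior_a + n / 2, prior_b + ssr / 2)
      if (it > mcmc$burnin) out[it - mcmc$burnin, ] <- c(mu, s2b, s2w)
    }
    chains_out[[ch]] <- out
  }
  draws <- dplyr::bind_rows(lapply(seq_along(chains_out), function(ch) {
    tibble::as_tibble(chains_out[[ch]]) |>
      dplyr::mutate(chain = ch, iter = dplyr::row_number(), .before = 1)
  })) |>
    dplyr::mutate(R = .data$s2_between / (.data$s2_between + .data$s2_within))
  rhat <- vapply(c("mu", "s2_between", "s2_within"), function(p) {
    gelman_rubin(sapply(chains_out, function(m) m[, p]))
  }, double(1))
  qs <- function(x) stats::quantile(x, c(0.5, 0.025, 0.975), names = FALSE)
  summ <- dplyr::bind_rows(lapply(
    c("mu", "s2_between", "s2_within", "R"),
    function(p) {
      q <- qs(draws[[p]])
      tibble::tibble(parameter = p, median = q[1], lower = q[2], upper = q[3],
                     mean = mean(draws[[p]]))
    }))
  structure(list(draws = draws, summary = summ, rhat = rhat,
                 converged = all(rhat < 1.1), n = n, n_birds = I),
            class = "vc_fit")
}

#' @export
print.vc_fit <- function(x, ...) {
  cat("Bayesian variance-components fit:", x$n, "records,", x$n_birds,
      "birds\n")
  cat(sprintf("  repeatability R = %.3f [%.3f, %.3f]\n",
              x$summary$median[x$summary$parameter == "R"],
              x$summary$lower[x$summary$parameter == "R"],
              x$summary$upper[x$summary$parameter == "R"]))
  cat(sprintf("  max Rhat = %.4f (%s)\n", max(x$rhat),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.vc_fit <- function(x, ...) x$summary

#' @export
glance.vc_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_birds = x$n_birds, max_rhat = max(x$rhat),
                 converged = x$converged,
                 R = x$summary$median[x$summary$parameter == "R"])
}

#' Split-chain Gelman-Rubin statistic
#'
#' Each chain is split in half and the potential scale reduction factor
#' computed over the resulting half-chains.
#'
#' @param chains Matrix, iterations x chains (or a list of equal-length
#'   numeric vectors).
#' @return Rhat (>= 1 up to numerical tolerance).
#' @export
gelman_rubin <- function(chains) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  chains <- as.matrix(chains)
  n <- nrow(chains)
  half <- floor(n / 2)
  splits <- do.call(cbind, lapply(seq_len(ncol(chains)), function(j) {
    cbind(chains[seq_len(half), j], chains[half + seq_len(half), j])
  }))
  m <- ncol(splits); nn <- nrow(splits)
  means <- colMeans(splits)
  W <- mean(apply(splits, 2, stats::var))
  B <- nn * stats::var(means)
  if (W <= 0) return(1)
  # finite-sample noise can push the ratio fractionally below 1; report 1
  max(sqrt(((nn - 1) / nn * W + B / nn) / W), 1)
}

#' Summarise repeatability across milestones
#'
#' @param fits Named list of `vc_fit` objects (one per milestone), or a
#'   numeric vector of repeatability estimates.
#' @return Tibble per milestone (estimate, lower, upper, converged) with
#'   attributes `mean_R` and `range_R`; the cross-milestone mean and range
#'   are also printed columns of the attached summary row set.
#' @export
repeatability_summary <- function(fits) {
  if (is.numeric(fits)) {
    tab <- tibble::tibble(milestone = names(fits) %||% as.character(seq_along(fits)),
                          estimate = unname(fits),
                          lower = NA_real_, upper = NA_real_, converged = NA)
  } else {
    tab <- dplyr::bind_rows(lapply(names(fits), function(k) {
      s <- fits[[k]]$summary
      tibble::tibble(milestone = k,
                     estimate = s$median[s$parameter == "R"],
                     lower = s$lower[s$parameter == "R"],
                     upper = s$upper[s$parameter == "R"],
                     converged = fits[[k]]$converged)
    }))
  }
  attr(tab, "mean_R") <- mean(tab$estimate)
  attr(tab, "range_R") <- range(tab$estimate)
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a
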