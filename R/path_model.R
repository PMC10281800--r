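# Bayesian path analysis ("timing model"): a system of linear-normal node
# equations over a declared DAG, fitted by a joint Gibbs sampler that
# imputes missing entries (in predictors and responses) from their full
# conditionals, so imputation uncertainty propagates into the coefficient
# posteriors. Coefficients are standardized path coefficients; squaring one
# gives the percentage of the child's variance explained by that direct
# path, and the product of the steps along a multi-edge path gives the
# indirect effect.

#' Standardize columns of a data frame
#'
#' Each named column is centred and scaled to mean 0, SD 1 (sample SD,
#' computed over non-missing entries). Binary covariates should be coded
#' 0/1 first and are then standardized identically, which makes their path
#' coefficients comparable with continuous ones.
#'
#' @param data A data frame.
#' @param columns Character vector of columns to standardize (default: all
#'   numeric columns).
#' @return The data with the named columns standardized. Idempotent up to
#'   floating point. A constant column is an error (zero SD).
#' @export
standardize <- function(data, columns = NULL) {
  if (is.null(columns)) {
    columns <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  for (cl in columns) {
    x <- data[[cl]]
    s <- stats::sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) stop("cannot standardize constant column: ", cl)
    data[[cl]] <- (x - mean(x, na.rm = TRUE)) / s
  }
  data
}

#' Fit the Bayesian path model over a declared DAG
#'
#' Joint Gibbs sampler over the system of linear-normal node equations
#' (one regression per endogenous node on its DAG parents, with intercept).
#' Missing entries in any variable are sampled each sweep from their full
#' conditional given the node's own equation and the equations of its
#' children; exogenous nodes get a normal marginal model (or a Bernoulli
#' with beta-prior mean when the column takes exactly two values). Priors:
#' Normal(0, 10^2) on coefficients, inverse-gamma(0.001, 0.001) on residual
#' variances. Convergence is declared iff split-chain Rhat < 1.1 on every
#' edge coefficient; a non-converged fit is flagged, not an error.
#'
#' @param data Data frame containing a standardized column for every DAG
#'   node (see [standardize()]); `NA`s allowed anywhere.
#' @param dag A [dag_spec()].
#' @param mcmc [mcmc_settings()].
#' @param coef_prior_sd Prior SD on standardized coefficients.
#' @param prior_a,prior_b Inverse-gamma prior on residual variances.
#' @return An object of class `path_fit` with elements `edges` (per-edge
#'   posterior summary: median, mean, sd, 95% interval, `p_nonzero`,
#'   `r2_pct` = 100 x median(coef^2), `tier`, `rhat`), `draws` (matrix of
#'   retained draws x edges), `sigma2` (residual-variance draws), `dag`,
#'   `converged`, `n`.
#' @export
fit_path_model <- function(data, dag, mcmc = mcmc_settings(),
                           coef_prior_sd = 10, prior_a = 0.001, prior_b = 0.001) {
  stopifnot(inherits(dag, "dag_spec"))
  nodes <- c(dag$exogenous, dag$endogenous)
  missing_cols <- setdiff(nodes, names(data))
  if (length(missing_cols) > 0) {
    stop("data lacks DAG node column(s): ", paste(missing_cols, collapse = ", "))
  }
  Z0 <- as.matrix(data[nodes])
  n <- nrow(Z0)
  for (v in dag$endogenous) {
    p <- length(parents_of(dag, v)) + 1L
    if (p > n) stop("non-identifiable node (more parents than observations): ", v)
  }
  miss <- lapply(nodes, function(v) which(is.na(Z0[, v])))
  names(miss) <- nodes
  has_miss <- vapply(miss, length, integer(1)) > 0
  binary_support <- lapply(nodes, function(v) {
    u <- sort(unique(Z0[!is.na(Z0[, v]), v]))
    if (length(u) == 2) u else NULL
  })
  names(binary_support) <- nodes
  parents <- lapply(dag$endogenous, function(v) parents_of(dag, v))
  names(parents) <- dag$endogenous
  children <- lapply(nodes, function(v) dag$edges$to[dag$edges$from == v])
  names(children) <- nodes
  edge_key <- paste0(dag$edges$from, "->", dag$edges$to)
  n_edges <- length(edge_key)
  prec0 <- 1 / coef_prior_sd^2

  total <- mcmc$burnin + mcmc$draws
  edge_draw_chains <- vector("list", mcmc$chains)
  sig_draw_chains <- vector("list", mcmc$chains)
  set.seed(mcmc$seed)
  for (ch in seq_len(mcmc$chains)) {
    Z <- Z0
    for (v in nodes) Z[miss[[v]], v] <- 0
    beta <- lapply(dag$endogenous, function(v) rep(0, length(parents[[v]]) + 1L))
    names(beta) <- dag$endogenous
    s2 <- stats::setNames(rep(1, length(dag$endogenous)), dag$endogenous)
    theta <- stats::setNames(rep(0, length(nodes)), nodes)
    tau2 <- stats::setNames(rep(1, length(nodes)), nodes)
    pb <- stats::setNames(rep(0.5, length(nodes)), nodes)
    edraw <- matrix(NA_real_, mcmc$draws, n_edges,
                    dimnames = list(NULL, edge_key))
    sdraw <- matrix(NA_real_, mcmc$draws, length(dag$endogenous),
                    dimnames = list(NULL, dag$endogenous))
    for (it in seq_len(total)) {
      # node equations
      for (v in dag$endogenous) {
        X <- cbind(1, Z[, parents[[v]], drop = FALSE])
        y <- Z[, v]
        p <- ncol(X)
        Vinv <- crossprod(X) / s2[v] + diag(prec0, p)
        ch_V <- chol(Vinv)
        m <- backsolve(ch_V, forwardsolve(t(ch_V), crossprod(X, y) / s2[v]))
        beta[[v]] <- drop(m + backsolve(ch_V, stats::rnorm(p)))
        ssr <- sum((y - X %*% beta[[v]])^2)
        s2[v] <- 1 / stats::rgamma(1, prior_a + n / 2, prior_b + ssr / 2)
      }
      # exogenous marginals (only needed where imputation happens)
      for (v in dag$exogenous[has_miss[dag$exogenous]]) {
        x <- Z[, v]
        if (!is.null(binary_support[[v]])) {
          k <- sum(x == binary_support[[v]][2])
          pb[v] <- stats::rbeta(1, 1 + k, 1 + n - k)
        } else {
          pr <- n / tau2[v] + prec0
          theta[v] <- stats::rnorm(1, sum(x) / tau2[v] / pr, sqrt(1 / pr))
          tau2[v] <- 1 / stats::rgamma(1, prior_a + n / 2,
                                       prior_b + sum((x - theta[v])^2) / 2)
        }
      }
      # imputation from full conditionals
      for (v in nodes[has_miss]) {
        idx <- miss[[v]]
        if (v %in% dag$endogenous) {
          Xv <- cbind(1, Z[idx, parents[[v]], drop = FALSE])
          mu_own <- drop(Xv %*% beta[[v]])
          s2_own <- s2[v]
        } else {
          mu_own <- rep(theta[v], length(idx))
          s2_own <- tau2[v]
        }
        if (is.null(binary_support[[v]])) {
          prec <- rep(1 / s2_own, length(idx))
          msum <- mu_own / s2_own
          for (cnd in children[[v]]) {
            Xc <- cbind(1, Z[idx, parents[[cnd]], drop = FALSE])
            bc <- beta[[cnd]]
            j <- match(v, parents[[cnd]]) + 1L
            r <- Z[idx, cnd] - drop(Xc %*% bc) + bc[j] * Z[idx, v]
            prec <- prec + bc[j]^2 / s2[cnd]
            msum <- msum + bc[j] * r / s2[cnd]
          }
          Z[idx, v] <- stats::rnorm(length(idx), msum / prec, sqrt(1 / prec))
        } else {
          sup <- binary_support[[v]]
          if (v %in% dag$endogenous) {
            ll0 <- stats::dnorm(sup[1], mu_own, sqrt(s2_own), log = TRUE)
            ll1 <- stats::dnorm(sup[2], mu_own, sqrt(s2_own), log = TRUE)
          } else {
            ll0 <- rep(log(1 - pb[v]), length(idx))
            ll1 <- rep(log(pb[v]), length(idx))
          }
          for (cnd in children[[v]]) {
            Xc <- cbind(1, Z[idx, parents[[cnd]], drop = FALSE])
            bc <- beta[[cnd]]
            j <- match(v, parents[[cnd]]) + 1L
            base <- drop(Xc %*% bc) - bc[j] * Z[idx, v]
            ll0 <- ll0 + stats::dnorm(Z[idx, cnd], base + bc[j] * sup[1],
                                      sqrt(s2[cnd]), log = TRUE)
            ll1 <- ll1 + stats::dnorm(Z[idx, cnd], base + bc[j] * sup[2],
                                      sqrt(s2[cnd]), log = TRUE)
          }
          p1 <- 1 / (1 + exp(ll0 - ll1))
          Z[idx, v] <- ifelse(stats::runif(length(idx)) < p1, sup[2], sup[1])
        }
      }
      if (it > mcmc$burnin) {
        k <- it - mcmc$burnin
        edraw[k, ] <- vapply(seq_len(n_edges), function(e) {
          v <- dag$edges$to[e]
          beta[[v]][match(dag$edges$from[e], parents[[v]]) + 1L]
        }, double(1))
        sdraw[k, ] <- s2[dag$endogenous]
      }
    }
    edge_draw_chains[[ch]] <- edraw
    sig_draw_chains[[ch]] <- sdraw
  }
  draws <- do.call(rbind, edge_draw_chains)
  sigma2 <- do.call(rbind, sig_draw_chains)
  rhat <- vapply(seq_len(n_edges), function(e) {
    gelman_rubin(sapply(edge_draw_chains, function(m) m[, e]))
  }, double(1))
  edges <- dag$edges |>
    dplyr::mutate(
      median = unname(apply(draws, 2, stats::median)),
      mean = unname(colMeans(draws)),
      sd = unname(apply(draws, 2, stats::sd)),
      lower = unname(apply(draws, 2, stats::quantile, 0.025)),
      upper = unname(apply(draws, 2, stats::quantile, 0.975)),
      p_nonzero = unname(apply(draws, 2, edge_probability)),
      r2_pct = unname(apply(draws, 2, function(d) stats::median(100 * d^2))),
      tier = support_tier(.data$p_nonzero),
      rhat = rhat
    )
  structure(list(edges = edges, draws = draws, sigma2 = sigma2, dag = dag,
                 converged = all(rhat < 1.1), n = n),
            class = "path_fit")
}

#' Posterior probability that an edge coefficient is non-zero
#'
#' `p = max(fraction of draws > 0, fraction of draws < 0)`; by construction
#' in `[0.5, 1]`.
#'
#' @param draws Numeric vector of posterior draws.
#' @return Probability of direction.
#' @export
edge_probability <- function(draws) {
  max(mean(draws > 0), mean(draws < 0))
}

support_tier <- function(p) {
  dplyr::case_when(
    p >= 0.95 ~ "very well-supported",
    p >= 0.90 ~ "well-supported",
    p >= 0.80 ~ "likely",
    TRUE ~ "unsupported"
  )
}

#' Percentage of variance explained by a direct path
#'
#' The square of a standardized path coefficient, as a percentage of the
#' child's variance. Sign-invariant: -0.329 explains the same share as
#' 0.329.
#'
#' @param coefficient Standardized coefficient(s) (vectorised; may be
#'   posterior draws).
#' @return `100 * coefficient^2`.
#' @export
variance_explained <- function(coefficient) 100 * coefficient^2

#' Variance share transmitted along a multi-edge path
#'
#' The chained share of the terminal node's variance is the product of the
#' per-stage shares: `100 * prod(shares_pct / 100)`.
#'
#' @param shares_pct Per-stage variance shares, in percent (each a squared
#'   standardized coefficient x 100).
#' @return Percentage of the terminal node's variance.
#' @export
chain_variance_share <- function(shares_pct) 100 * prod(shares_pct / 100)

#' Residual "unexplained" share of a node
#'
#' The printed decomposition convention: 100 minus the sum of the direct
#' shares, e.g. 100 - 78.0 - 10.8 = 11.2. The statistically standard
#' `1 - R^2` of the node equation is available from the fit's residual
#' variances instead.
#'
#' @param direct_shares_pct Direct variance shares, percent.
#' @return Percentage left unexplained by the listed direct paths.
#' @export
residual_share <- function(direct_shares_pct) 100 - sum(direct_shares_pct)

#' Indirect effect along an ordered node path
#'
#' Draw-wise product of the edge coefficients along `path` (a character
#' vector of nodes, e.g. departure from the breeding grounds through the
#' Sahara crossing and West Africa departure to breeding arrival), plus the
#' chained variance share (product of stage shares).
#'
#' @param fit A `path_fit`.
#' @param path Character vector of node names (length >= 2) tracing
#'   consecutive DAG edges.
#' @return Tibble with the path label, posterior median/interval of the
#'   coefficient product, `p_nonzero`, and `share_pct` (the chained
#'   variance share based on posterior-median stage shares).
#' @export
indirect_effect <- function(fit, path) {
  stopifnot(inherits(fit, "path_fit"), length(path) >= 2)
  keys <- paste0(path[-length(path)], "->", path[-1])
  missing <- setdiff(keys, colnames(fit$draws))
  if (length(missing) > 0) stop("path uses absent edge(s): ",
                                paste(missing, collapse = ", "))
  prod_draws <- apply(fit$draws[, keys, drop = FALSE], 1, prod)
  stage_shares <- vapply(keys, function(k) {
    stats::median(variance_explained(fit$draws[, k]))
  }, double(1))
  tibble::tibble(
    path = paste(path, collapse = " -> "),
    median = stats::median(prod_draws),
    lower = stats::quantile(prod_draws, 0.025, names = FALSE),
    upper = stats::quantile(prod_draws, 0.975, names = FALSE),
    p_nonzero = edge_probability(prod_draws),
    share_pct = chain_variance_share(stage_shares))
}

#' Test of directed separation (Fisher's C)
#'
#' The union basis set contains every non-adjacent ordered node pair
#' (pairs of exogenous covariates excluded, their association being
#' unconstrained), each claim tested as the partial regression coefficient
#' of the earlier node in a normal linear fit of the later node on it plus
#' the parents of both. `C = -2 sum(log p)` on 2k df is chi-square under
#' the DAG.
#'
#' @param data Standardized data frame with a column per node (complete
#'   cases used per claim).
#' @param dag A [dag_spec()].
#' @return List with `claims` (tibble: from, to, conditioning set, p),
#'   `C`, `df`, `p_value`.
#' @export
dsep_test <- function(data, dag) {
  nodes <- c(dag$exogenous, dag$order)
  adj <- paste0(dag$edges$from, "|", dag$edges$to)
  claims <- list()
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (j <= i) next
      u <- nodes[i]; v <- nodes[j]
      if (u %in% dag$exogenous && v %in% dag$exogenous) next
      if (paste0(u, "|", v) %in% adj || paste0(v, "|", u) %in% adj) next
      cond <- setdiff(union(
        dag$edges$from[dag$edges$to == v],
        dag$edges$from[dag$edges$to == u]), c(u, v))
      df_uv <- data[stats::complete.cases(data[c(u, v, cond)]), , drop = FALSE]
      rhs <- paste(c(u, cond), collapse = " + ")
      fit <- stats::lm(stats::as.formula(paste(v, "~", rhs)), data = df_uv)
      pval <- summary(fit)$coefficients[u, "Pr(>|t|)"]
      claims[[length(claims) + 1L]] <- tibble::tibble(
        from = u, to = v, conditioning = paste(cond, collapse = ","),
        n = nrow(df_uv), p = pval)
    }
  }
  claims <- dplyr::bind_rows(claims)
  if (nrow(claims) == 0) {
    return(list(claims = claims, C = 0, df = 0L, p_value = 1))
  }
  C <- -2 * sum(log(pmax(claims$p, 1e-300)))
  df <- 2L * nrow(claims)
  list(claims = claims, C = C, df = df,
       p_value = stats::pchisq(C, df, lower.tail = FALSE))
}

#' Headline table of supported paths
#'
#' Edges at or above the lowest support threshold, annotated with tier,
#' sign and posterior summary; edges below it are suppressed from the
#' headline table but remain in `fit$edges`.
#'
#' @param fit A `path_fit`.
#' @param thresholds Support tiers (default 0.80 likely / 0.90
#'   well-supported / 0.95 very well-supported).
#' @return Tibble of supported edges, strongest first.
#' @export
summarize_paths <- function(fit, thresholds = c(0.80, 0.90, 0.95)) {
  fit$edges |>
    dplyr::filter(.data$p_nonzero >= min(thresholds)) |>
    dplyr::mutate(sign = ifelse(.data$median >= 0, "+", "-")) |>
    dplyr::select("from", "to", "median", "lower", "upper",
                  "p_nonzero", "tier", "sign", "r2_pct") |>
    dplyr::arrange(dplyr::desc(.data$p_nonzero), dplyr::desc(abs(.data$median)))
}

#' @export
print.path_fit <- function(x, ...) {
  cat("Bayesian path model:", nrow(x$dag$edges), "edges,", x$n, "rows",
      if (x$converged) "(converged)\n" else "(NOT converged)\n")
  print(summarize_paths(x), n = 20)
  invisible(x)
}

#' @export
tidy.path_fit <- function(x, ...) x$edges

#' @export
glance.path_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_edges = nrow(x$edges),
                 max_rhat = max(x$edges$rhat), converged = x$converged)
}
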