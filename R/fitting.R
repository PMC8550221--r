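#' Define a fitting window
#'
#' A window binds the observation series, input series and initial
#' conditions over which one set of model parameters is estimated. Two
#' window conventions are supported for the initial pool
#' \eqn{\Delta^{14}}C: `"window1"` (fast pool from the one-pool spin-up at
#' the fitted `k1`, or a fixed value estimated iteratively; slow pool pinned
#' at -42.0 per mil) and `"window2"` (both pools from the one-pool spin-up
#' at the proposed rates of each run).
#'
#' Radiocarbon observations are required at or near both ends of the window
#' — without the \eqn{\Delta^{14}}C constraint the stock data alone cannot
#' separate decomposition from transfer.
#'
#' @param start_year,end_year Window bounds, `start_year < end_year`.
#' @param observations An [observation_series()] covering the window.
#' @param inputs An [input_series()] covering the window.
#' @param initial_stock Total stock at `start_year`; default from
#'   [fit_initial_stock()] (degree-2 polynomial) on the observations.
#' @param initial_delta_mode `"window1"` or `"window2"`.
#' @param delta_fast0 Optional fixed initial fast-pool Delta-14C (per mil)
#'   for window-1 fits (see [estimate_initial_fast_delta()]); `NULL` means
#'   compute from each run's `k1`.
#' @param delta_slow0 Slow-pool initial Delta-14C for window-1 fits; default
#'   -42.0 per mil.
#' @return An object of class `fit_window`.
#' @export
fit_window <- function(start_year, end_year, observations, inputs,
                       initial_stock = NULL,
                       initial_delta_mode = c("window2", "window1"),
                       delta_fast0 = NULL, delta_slow0 = -42.0) {
  initial_delta_mode <- match.arg(initial_delta_mode)
  if (start_year >= end_year) stop("start_year must precede end_year")
  stopifnot(inherits(observations, "observation_series"),
            inherits(inputs, "input_series"))
  obs <- observations[observations$year >= start_year &
                        observations$year <= end_year, ]
  if (nrow(obs) == 0) stop("no observations inside the window")
  dyr <- obs$year[!is.na(obs$delta14c)]
  if (length(dyr) == 0)
    stop("window has no Delta-14C observations: the fit requires the joint ",
         "stock + radiocarbon constraint")
  if (min(dyr) > start_year + 5 || max(dyr) < end_year - 5)
    stop("need a Delta-14C observation near both the start and the end ",
         "of the window")
  if (is.null(initial_stock)) {
    # observations represent mid-year states; regress on year + 0.5 so the
    # polynomial evaluated at start_year refers to the window-start instant
    obs_mid <- obs
    obs_mid$year <- obs_mid$year + 0.5
    initial_stock <- fit_initial_stock(obs_mid, degree = 2,
                                       at_year = start_year)
  }
  structure(list(start_year = start_year, end_year = end_year,
                 observations = obs, inputs = inputs,
                 initial_stock = initial_stock,
                 initial_delta_mode = initial_delta_mode,
                 delta_fast0 = delta_fast0, delta_slow0 = delta_slow0),
            class = "fit_window")
}

# initial pool deltas for a window given proposed params
window_initial_deltas <- function(params, window, atm, lambda = LAMBDA_14C) {
  # suppressWarnings: proposals with very small k2 trip the conservative
  # spin-up-length warning on every cost evaluation
  if (window$initial_delta_mode == "window1") {
    fast <- if (!is.null(window$delta_fast0)) window$delta_fast0
            else delta_from_ratio(suppressWarnings(one_pool_equilibrium_ratio(
              params$k1, atm, window$start_year, lambda = lambda)))
    list(fast = fast, slow = rep(window$delta_slow0, 2))
  } else {
    d <- suppressWarnings(
      initial_pool_deltas(params, atm, window$start_year, "window2",
                          lambda = lambda))
    list(fast = d[["fast"]], slow = unname(d[-1]))
  }
}

#' Weighted residuals of a window fit
#'
#' Simulates the window from its initial state and returns
#' `(model - observed) / sd` for every stock observation and every
#' \eqn{\Delta^{14}}C observation, concatenated. Model values are taken at
#' the mid-point of each sampling year.
#'
#' @param params A [pool_params()].
#' @param window A [fit_window()].
#' @param atm An [atmosphere_record()].
#' @param dt Integration step, yr.
#' @param lambda 14C decay rate, yr^-1.
#' @return Named numeric vector of weighted residuals.
#' @export
window_residuals <- function(params, window, atm, dt = 1 / 12,
                             lambda = LAMBDA_14C) {
  d0 <- window_initial_deltas(params, window, atm, lambda)
  state0 <- initial_state(window$initial_stock, params, d0$fast, d0$slow,
                          window$start_year)
  traj <- tryCatch(
    simulate_pools(params, window$inputs, atm, state0,
                   window$end_year + 0.5, dt, lambda),
    error = function(e) stop("simulation failed at k1 = ", params$k1,
                             ", k2 = ", params$k2, ", a21 = ", params$a21,
                             ", slowProp = ", params$slowProp, ": ",
                             conditionMessage(e)))
  obs <- window$observations
  idx <- round((obs$year + 0.5 - window$start_year) / dt) + 1L
  rs <- (traj$total_stock[idx] - obs$stock) / obs$stock_sd
  names(rs) <- paste0("stock_", obs$year)
  keep_d <- !is.na(obs$delta14c)
  rd <- (traj$delta14c_bulk[idx[keep_d]] - obs$delta14c[keep_d]) /
    obs$delta_sd[keep_d]
  names(rd) <- paste0("delta_", obs$year[keep_d])
  c(rs[!is.na(rs)], rd)
}

#' Scalar cost: sum of squared weighted residuals
#'
#' @inheritParams window_residuals
#' @return Non-negative scalar.
#' @export
window_cost <- function(params, window, atm, dt = 1 / 12,
                        lambda = LAMBDA_14C) {
  sum(window_residuals(params, window, atm, dt, lambda)^2)
}

#' Default parameter bounds for the MCMC
#'
#' Wide uniform bounds bracketing all published parameter means:
#' `k1` in `[0.01, 1]`, `k2` in `[1e-4, 0.05]`, `a21` and `slowProp` in
#' `[0, 1]`; for three pools additionally `k3` in `[1e-5, 1e-3]` and `a32`
#' in `[0, 1]`.
#'
#' @param n_pools 2 or 3.
#' @return List with numeric vectors `lower` and `upper`.
#' @export
default_parameter_bounds <- function(n_pools = 2) {
  lower <- c(k1 = 0.01, k2 = 1e-4, a21 = 0, slowProp = 0)
  upper <- c(k1 = 1, k2 = 0.05, a21 = 1, slowProp = 1)
  if (n_pools == 3) {
    lower <- c(lower, k3 = 1e-5, a32 = 0)
    upper <- c(upper, k3 = 1e-3, a32 = 1)
  }
  list(lower = lower, upper = upper)
}

params_from_vector <- function(v) {
  pool_params(v[["k1"]], v[["k2"]], v[["a21"]], v[["slowProp"]],
              k3 = if ("k3" %in% names(v)) v[["k3"]] else NULL,
              a32 = if ("a32" %in% names(v)) v[["a32"]] else NULL,
              check = FALSE)
}

vector_valid <- function(v, bounds) {
  if (any(v < bounds$lower) || any(v > bounds$upper)) return(FALSE)
  if (v[["k1"]] <= v[["k2"]]) return(FALSE)
  if ("k3" %in% names(v) && v[["k3"]] >= v[["k2"]]) return(FALSE)
  TRUE
}

#' Random-walk Metropolis MCMC over the model parameters
#'
#' Samples the posterior with likelihood proportional to `exp(-cost/2)`
#' under flat priors inside the bounds. Gaussian proposals; the proposal
#' scale is adapted during the burn-in (discarded, 20% of the chain by
#' default) and then frozen so the retained chain is Markovian.
#' Reproducible given `seed`.
#'
#' @param window A [fit_window()].
#' @param atm An [atmosphere_record()].
#' @param bounds Parameter bounds, see [default_parameter_bounds()].
#' @param n_iter Total iterations; default 10000.
#' @param seed RNG seed.
#' @param burn_frac Fraction of `n_iter` used (and discarded) as adaptive
#'   burn-in.
#' @param init Optional named initial parameter vector; must have finite
#'   cost. Default: midpoint of the bounds.
#' @param dt Integration step, yr.
#' @param lambda 14C decay rate, yr^-1.
#' @return An object of class `mcmc_posterior`: post-burn-in `draws` (data
#'   frame with a `cost` column), `acceptance_rate`, `seed`, `bounds`,
#'   per-parameter `summary` (mean, SD, 99% interval) and the minimum-cost
#'   parameter vector `best`.
#' @export
run_mcmc <- function(window, atm, bounds = default_parameter_bounds(),
                     n_iter = 10000, seed = 1L, burn_frac = 0.2,
                     init = NULL, dt = 1 / 12, lambda = LAMBDA_14C) {
  stopifnot(inherits(window, "fit_window"))
  lower <- bounds$lower; upper <- bounds$upper
  npar <- length(lower)
  if (is.null(init)) init <- (lower + upper) / 2
  init <- init[names(lower)]
  cost_fn <- function(v) window_cost(params_from_vector(v), window, atm,
                                     dt, lambda)
  if (!vector_valid(init, bounds)) stop("initial point violates bounds")
  c_cur <- cost_fn(init)
  if (!is.finite(c_cur)) stop("cost is not finite at the initial point")

  n_burn <- floor(burn_frac * n_iter)
  n_keep <- n_iter - n_burn
  all_draws <- matrix(NA_real_, n_iter, npar,
                      dimnames = list(NULL, names(lower)))
  costs <- numeric(n_keep)
  # proposal: scaled multivariate normal; diagonal at first, then the
  # empirical burn-in covariance (2.38^2/d scaling), frozen after burn-in
  prop_chol <- diag(0.05 * (upper - lower), npar)
  scale <- 1
  have_cov <- FALSE
  cur <- init
  best <- init; c_best <- c_cur
  acc_keep <- 0L; acc_batch <- 0L

  with_seed(seed, {
    for (i in seq_len(n_iter)) {
      prop <- cur + scale * drop(rnorm(npar) %*% prop_chol)
      names(prop) <- names(lower)
      accept <- FALSE
      if (vector_valid(prop, bounds)) {
        c_prop <- cost_fn(prop)
        if (is.finite(c_prop) &&
            log(runif(1)) < (c_cur - c_prop) / 2) {
          cur <- prop; c_cur <- c_prop; accept <- TRUE
          if (c_cur < c_best) { best <- cur; c_best <- c_cur }
        }
      }
      all_draws[i, ] <- cur
      if (i <= n_burn) {
        acc_batch <- acc_batch + accept
        if (i %% 50 == 0) {
          rate <- acc_batch / 50
          scale <- max(1e-3, min(100, scale * exp(rate - 0.3)))
          acc_batch <- 0L
        }
        if (i >= max(200, n_burn %/% 2) && i %% 200 == 0) {
          # second half of the burn-in so far: past the initial descent
          S <- stats::cov(all_draws[(i %/% 2):i, , drop = FALSE]) +
            diag(1e-10, npar)
          ch <- tryCatch(chol(2.38^2 / npar * S), error = function(e) NULL)
          if (!is.null(ch)) {
            prop_chol <- ch
            if (!have_cov) { scale <- 1; have_cov <- TRUE }
          }
        }
      } else {
        costs[i - n_burn] <- c_cur
        acc_keep <- acc_keep + accept
      }
    }
  })
  draws <- all_draws[(n_burn + 1):n_iter, , drop = FALSE]

  acc_rate <- acc_keep / n_keep
  if (acc_rate < 0.01)
    warning("MCMC acceptance rate below 1% after adaptation (",
            signif(100 * acc_rate, 2), "%)")
  qs <- apply(draws, 2, quantile, probs = c(0.005, 0.995))
  summary <- data.frame(parameter = colnames(draws),
                        mean = colMeans(draws),
                        sd = apply(draws, 2, sd),
                        ci99_lower = qs[1, ], ci99_upper = qs[2, ],
                        row.names = NULL)
  structure(list(draws = cbind(as.data.frame(draws), cost = costs),
                 acceptance_rate = acc_rate, seed = seed, bounds = bounds,
                 summary = summary, best = best, best_cost = c_best,
                 n_iter = n_iter, n_burn = n_burn),
            class = "mcmc_posterior")
}

#' @export
print.mcmc_posterior <- function(x, ...) {
  cat(sprintf("MCMC posterior: %d retained draws (of %d, %d burn-in), ",
              nrow(x$draws), x$n_iter, x$n_burn))
  cat(sprintf("acceptance %.1f%%, seed %d\n", 100 * x$acceptance_rate,
              x$seed))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Posterior mean parameters as a `pool_params` object
#' @param posterior An `mcmc_posterior`.
#' @return A [pool_params()].
#' @export
posterior_mean_params <- function(posterior) {
  m <- posterior$summary$mean
  names(m) <- posterior$summary$parameter
  params_from_vector(m)
}

#' Iteratively estimate the initial fast-pool Delta-14C (window 1)
#'
#' Alternates fitting and recomputation: fit the window, feed the posterior
#' mean `k1` through the one-pool spin-up to get the fast pool's
#' \eqn{\Delta^{14}}C at the window start, pin that value, and refit, until
#' the value changes by less than `tol`. The slow pool stays pinned at
#' -42.0 per mil throughout.
#'
#' @param window A [fit_window()] with `initial_delta_mode = "window1"`.
#' @param atm An [atmosphere_record()].
#' @param tol Convergence tolerance, per mil; `Inf` returns the first-pass
#'   value.
#' @param max_iter Maximum fit/recompute cycles.
#' @param n_iter MCMC iterations per cycle.
#' @param seed RNG seed (incremented per cycle).
#' @param ... Passed to [run_mcmc()].
#' @return The converged initial fast-pool Delta-14C (per mil), with
#'   attributes `k1` and `iterations`.
#' @export
estimate_initial_fast_delta <- function(window, atm, tol = 0.5,
                                        max_iter = 10, n_iter = 2000,
                                        seed = 1L, ...) {
  if (window$initial_delta_mode != "window1")
    stop("iterative initial-delta estimation applies to window-1 fits")
  delta_prev <- NA_real_
  for (iter in seq_len(max_iter)) {
    post <- run_mcmc(window, atm, n_iter = n_iter, seed = seed + iter, ...)
    k1_hat <- post$summary$mean[post$summary$parameter == "k1"]
    delta_new <- delta_from_ratio(
      one_pool_equilibrium_ratio(k1_hat, atm, window$start_year))
    if (is.infinite(tol) ||
        (!is.na(delta_prev) && abs(delta_new - delta_prev) < tol)) {
      return(structure(delta_new, k1 = k1_hat, iterations = iter))
    }
    delta_prev <- delta_new
    window$delta_fast0 <- delta_new
  }
  stop("initial fast-pool delta did not converge after ", max_iter,
       " iterations (last two iterates: ", signif(delta_prev, 6), ", ",
       signif(delta_new, 6), " per mil)")
}

#' Bootstrap confidence interval for a derived quantity
#'
#' Applies `derived_fn` (e.g. the median transit time) to `n_boot` parameter
#' sets resampled with replacement from the posterior draws and returns the
#' percentile interval at the requested level.
#'
#' @param posterior An `mcmc_posterior`.
#' @param derived_fn Function taking a [pool_params()] and returning a
#'   scalar.
#' @param n_boot Number of resampled parameter sets; default 1000.
#' @param level Interval level; default 0.99.
#' @param seed RNG seed for the resampling.
#' @return List with `lower`, `upper`, `mean`, `median`, `level` and the
#'   resampled `values`.
#' @export
bootstrap_summaries <- function(posterior, derived_fn, n_boot = 1000,
                                level = 0.99, seed = 1L) {
  draws <- posterior$draws[, setdiff(names(posterior$draws), "cost"),
                           drop = FALSE]
  if (nrow(draws) == 0) stop("posterior is empty")
  idx <- with_seed(seed, sample.int(nrow(draws), n_boot, replace = TRUE))
  vals <- vapply(seq_len(n_boot), function(b) {
    v <- unlist(draws[idx[b], ])
    tryCatch(derived_fn(params_from_vector(v)),
             error = function(e) stop("derived_fn failed on resampled row ",
                                      idx[b], ": ", conditionMessage(e)))
  }, numeric(1))
  alpha <- (1 - level) / 2
  q <- quantile(vals, c(alpha, 1 - alpha), names = FALSE)
  list(lower = q[1], upper = q[2], mean = mean(vals), median = median(vals),
       level = level, values = vals)
}

#' Least-squares Akaike information criterion
#'
#' `AIC = n_obs * ln(rss / n_obs) + 2 * n_params`, on the weighted residual
#' sum of squares.
#'
#' @param rss Residual sum of squares (> 0).
#' @param n_obs Number of residuals (> `n_params`).
#' @param n_params Number of fitted parameters.
#' @return Scalar AIC.
#' @export
aic_ls <- function(rss, n_obs, n_params) {
  if (rss <= 0) stop("rss must be positive")
  if (n_obs <= n_params) stop("n_obs must exceed n_params")
  n_obs * log(rss / n_obs) + 2 * n_params
}

#' Goodness-of-fit summary at the minimum-cost parameters
#'
#' Reports unweighted RMSEs in native units (Mg C ha^-1 for stocks, per mil
#' for \eqn{\Delta^{14}}C) plus the least-squares AIC on the weighted
#' residuals.
#'
#' @param posterior An `mcmc_posterior` for `window`.
#' @param window The fitted [fit_window()].
#' @param atm An [atmosphere_record()].
#' @param dt Integration step, yr.
#' @return A list of class `fit_result`: `params`, `rmse_stock`,
#'   `rmse_delta`, `aic`, `posterior`.
#' @export
evaluate_fit <- function(posterior, window, atm, dt = 1 / 12) {
  best <- params_from_vector(posterior$best)
  r <- window_residuals(best, window, atm, dt)
  obs <- window$observations
  rs <- r[startsWith(names(r), "stock_")] *
    obs$stock_sd[match(sub("stock_", "", names(r)[startsWith(names(r),
                                                             "stock_")]),
                       obs$year)]
  rd <- r[startsWith(names(r), "delta_")] *
    obs$delta_sd[match(sub("delta_", "", names(r)[startsWith(names(r),
                                                             "delta_")]),
                       obs$year)]
  structure(list(params = best,
                 rmse_stock = sqrt(mean(rs^2)),
                 rmse_delta = sqrt(mean(rd^2)),
                 aic = aic_ls(sum(r^2), length(r),
                              length(posterior$best)),
                 posterior = posterior),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit: RMSE stock %.2f Mg C ha^-1, RMSE delta %.2f permil, AIC %.1f\n",
              x$rmse_stock, x$rmse_delta, x$aic))
  print(x$params)
  invisible(x)
}

#' Compare two- and three-pool model structures by AIC
#'
#' Fits both structures to the same window by MCMC and computes the
#' least-squares AIC at each structure's minimum-cost parameters. The
#' three-pool variant adds a passive pool (`k3`, `a32`) in series.
#'
#' @param window A [fit_window()].
#' @param atm An [atmosphere_record()].
#' @param n_iter MCMC iterations per structure.
#' @param seed RNG seed.
#' @param ... Passed to [run_mcmc()].
#' @return Data frame with one row per structure: `n_params`, `rss`, `aic`.
#' @export
compare_pool_structures <- function(window, atm, n_iter = 3000, seed = 1L,
                                    ...) {
  p2 <- run_mcmc(window, atm, default_parameter_bounds(2), n_iter = n_iter,
                 seed = seed, ...)
  p3 <- run_mcmc(window, atm, default_parameter_bounds(3), n_iter = n_iter,
                 seed = seed, ...)
  n_obs <- length(window_residuals(params_from_vector(p2$best), window, atm))
  data.frame(model = c("2-pool", "3-pool"),
             n_params = c(4L, 6L),
             rss = c(p2$best_cost, p3$best_cost),
             aic = c(aic_ls(p2$best_cost, n_obs, 4L),
                     aic_ls(p3$best_cost, n_obs, 6L)))
}
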