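#' Two-pool (or three-pool) series model parameters
#'
#' The fitted quantities of the compartmental model: `k1` and `k2` are
#' first-order decomposition rates (yr^-1) of the fast and slow pool,
#' `a21` is the fraction of the fast-pool loss flux transferred to the slow
#' pool (the transfer flux is `k1 * a21 * C1`), and `slowProp` is the
#' fraction of total carbon sitting in the slow pool at the start of the
#' modelled window. An optional third, passive pool (rate `k3`, transfer
#' fraction `a32` out of pool 2) supports model-structure comparison.
#'
#' @param k1,k2 Decomposition rates, yr^-1, with `k1 > k2 > 0`.
#' @param a21 Transfer fraction in `[0, 1]`.
#' @param slowProp Initial slow-pool fraction in `[0, 1]`.
#' @param k3,a32 Optional passive-pool rate (`0 < k3 < k2`) and transfer
#'   fraction out of pool 2.
#' @param check Validate invariants (disable only for deliberately degenerate
#'   systems, e.g. a closed system with `k2 = 0`).
#' @return An object of class `pool_params`.
#' @export
pool_params <- function(k1, k2, a21, slowProp = 0.5, k3 = NULL, a32 = NULL,
                        check = TRUE) {
  p <- structure(list(k1 = k1, k2 = k2, a21 = a21, slowProp = slowProp,
                      k3 = k3, a32 = a32),
                 class = "pool_params")
  if (check) validate_pool_params(p)
  p
}

validate_pool_params <- function(p) {
  with(p, {
    if (!is.numeric(k1) || !is.numeric(k2) || k1 <= 0 || k2 <= 0 || k1 <= k2)
      stop("pool_params requires k1 > k2 > 0 (got k1 = ", k1,
           ", k2 = ", k2, ")")
    if (a21 < 0 || a21 > 1) stop("a21 must lie in [0, 1]")
    if (slowProp < 0 || slowProp > 1) stop("slowProp must lie in [0, 1]")
    if (!is.null(k3)) {
      if (k3 <= 0 || k3 >= k2) stop("k3 must satisfy 0 < k3 < k2")
      if (is.null(a32) || a32 < 0 || a32 > 1)
        stop("a32 must be supplied in [0, 1] when k3 is given")
    }
  })
  invisible(p)
}

n_pools <- function(params) if (is.null(params$k3)) 2L else 3L

#' @export
print.pool_params <- function(x, ...) {
  cat("pool_params:", n_pools(x), "pool series\n")
  cat(sprintf("  k1 = %g yr^-1, k2 = %g yr^-1, a21 = %g, slowProp = %g\n",
              x$k1, x$k2, x$a21, x$slowProp))
  if (!is.null(x$k3))
    cat(sprintf("  k3 = %g yr^-1, a32 = %g\n", x$k3, x$a32))
  invisible(x)
}

#' Rate matrix of the series compartmental model
#'
#' For two pools returns
#' \deqn{A = \begin{pmatrix} -k_1 & 0 \\ a_{21} k_1 & -k_2 \end{pmatrix}}
#' so the fast-to-slow flux is `k1 * a21 * C1`. Eigenvalues are `-k1, -k2`
#' (and `-k3`); column sums are non-positive, so mass is never created.
#'
#' @param params A [pool_params()] object.
#' @return A square rate matrix, yr^-1.
#' @export
build_system_matrix <- function(params) {
  np <- n_pools(params)
  ks <- c(params$k1, params$k2, params$k3)[seq_len(np)]
  as <- c(params$a21, params$a32)[seq_len(np - 1)]
  A <- diag(-ks, np)
  for (i in seq_len(np - 1)) A[i + 1, i] <- as[i] * ks[i]
  A
}

#' Model state: pool stocks and 14C ratios at a point in time
#'
#' @param time Calendar year.
#' @param C Numeric vector of pool stocks (Mg C ha^-1), all >= 0.
#' @param F Numeric vector of pool 14C ratios (dimensionless, > 0).
#' @return An object of class `model_state`.
#' @export
model_state <- function(time, C, F) {
  if (length(C) != length(F)) stop("C and F must have equal length")
  if (any(C < 0)) stop("pool stocks must be non-negative")
  if (any(F <= 0)) stop("pool 14C ratios must be positive")
  structure(list(time = time, C = as.numeric(C), F = as.numeric(F)),
            class = "model_state")
}

#' Initial model state from a total stock and pool deltas
#'
#' Splits `total_stock` as `slowProp` into the slow pool and the remainder
#' into the fast pool; 14C ratios come from the per-mil deltas. For a
#' three-pool parameterisation the slow share is split evenly between pools
#' 2 and 3.
#'
#' @param total_stock Total carbon stock, Mg C ha^-1 (>= 0).
#' @param params A [pool_params()].
#' @param delta_fast,delta_slow Initial pool Delta-14C, per mil. For three
#'   pools `delta_slow` may have length 2 (pools 2 and 3).
#' @param year Calendar year of the state.
#' @return A [model_state()].
#' @export
initial_state <- function(total_stock, params, delta_fast, delta_slow, year) {
  if (total_stock < 0) stop("total_stock must be non-negative")
  np <- n_pools(params)
  sp <- params$slowProp
  if (np == 2L) {
    C <- c(total_stock * (1 - sp), total_stock * sp)
    F <- ratio_from_delta(c(delta_fast, delta_slow[1]))
  } else {
    ds <- rep_len(delta_slow, 2)
    C <- c(total_stock * (1 - sp), rep(total_stock * sp / 2, 2))
    F <- ratio_from_delta(c(delta_fast, ds))
  }
  model_state(year, C, F)
}

#' Input series: annual total carbon inputs to the fast pool
#'
#' @param year Integer-valued calendar years, contiguous.
#' @param input Total C input flux I(t), Mg C ha^-1 yr^-1, all >= 0.
#' @return A data frame of class `input_series`.
#' @export
input_series <- function(year, input) {
  input <- rep_len(input, length(year))
  if (any(input < 0)) stop("input fluxes must be non-negative")
  if (length(year) > 1 && any(diff(year) != 1))
    stop("input series years must be contiguous")
  structure(data.frame(year = year, input = input),
            class = c("input_series", "data.frame"))
}

#' Simulate the pool model forward in time
#'
#' Integrates the carbon balance `dC/dt = I(t) + A C` and the coupled tracer
#' balance `d(F C)/dt = F_atm(t) I(t) + A (F C) - lambda (F C)` with a
#' fixed-step 4th-order Runge-Kutta scheme. Inputs are piecewise constant
#' within each calendar year; the atmospheric ratio is interpolated linearly
#' with flat extension outside the record.
#'
#' @param params A [pool_params()].
#' @param inputs An [input_series()], or a single number for constant inputs.
#' @param atm An [atmosphere_record()].
#' @param state0 Initial [model_state()].
#' @param t_end Final year (`> state0$time`).
#' @param dt Time step in years; must divide 1 year evenly. Default 1/12.
#' @param lambda 14C decay rate, yr^-1.
#' @return A data frame of class `pool_trajectory` with one row per step:
#'   `time`, `C1..`, `F1..`, `total_stock`, `delta14c_bulk`.
#' @export
simulate_pools <- function(params, inputs, atm, state0, t_end, dt = 1 / 12,
                           lambda = LAMBDA_14C) {
  stopifnot(inherits(state0, "model_state"), inherits(atm, "atmosphere_record"))
  if (state0$time >= t_end) stop("state0$time must be earlier than t_end")
  nsub <- 1 / dt
  if (abs(nsub - round(nsub)) > 1e-8)
    stop("dt must divide 1 year evenly (e.g. 1/12)")
  if (is.numeric(inputs) && is.null(dim(inputs)) && length(inputs) == 1 &&
      !is.data.frame(inputs)) {
    inputs <- input_series(floor(state0$time), inputs)
  }
  np <- length(state0$C)
  ks <- c(params$k1, params$k2, params$k3)[seq_len(np)]
  as <- if (np > 1) c(params$a21, params$a32)[seq_len(np - 1)] else numeric(0)
  mat <- cpp_simulate(ks, as, lambda,
                      inputs$year[1], inputs$input,
                      atm$year, ratio_from_delta(atm$delta14c),
                      state0$C, state0$F,
                      state0$time, t_end, dt)
  colnames(mat) <- c("time", paste0("C", seq_len(np)), paste0("F", seq_len(np)))
  df <- as.data.frame(mat)
  Cs <- as.matrix(df[, paste0("C", seq_len(np)), drop = FALSE])
  Fs <- as.matrix(df[, paste0("F", seq_len(np)), drop = FALSE])
  df$total_stock <- rowSums(Cs)
  df$delta14c_bulk <- delta_from_ratio(rowSums(Cs * Fs) / pmax(df$total_stock,
                                                               1e-300))
  structure(df, class = c("pool_trajectory", "data.frame"))
}

#' Bulk Delta-14C of a model state
#'
#' The stock-weighted mean ratio of all pools, reported in per mil; this is
#' what a bulk-soil measurement sees.
#'
#' @param state A [model_state()].
#' @return Per-mil value.
#' @export
bulk_delta14c <- function(state) {
  tot <- sum(state$C)
  if (tot <= 0) stop("bulk Delta-14C undefined for zero total stock")
  delta_from_ratio(sum(state$C * state$F) / tot)
}

#' Write a two-pool trajectory to CSV
#'
#' Columns: `year,C1,C2,total_stock,delta14C_bulk,delta14C_fast,delta14C_slow`.
#'
#' @param traj A `pool_trajectory` from [simulate_pools()] (two pools).
#' @param path Output file path.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "pool_trajectory"))
  out <- data.frame(year = traj$time, C1 = traj$C1, C2 = traj$C2,
                    total_stock = traj$total_stock,
                    delta14C_bulk = traj$delta14c_bulk,
                    delta14C_fast = delta_from_ratio(traj$F1),
                    delta14C_slow = delta_from_ratio(traj$F2))
  write.csv(format(out, digits = 12, trim = TRUE), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Equilibrium 14C ratio of a one-pool system after spin-up
#'
#' Runs the tracer balance of a one-pool model held at steady-state stock,
#' `dF/dt = k F_atm(t) - (k + lambda) F`, from `year - spinup_years` to
#' `year` under the flat-extended atmosphere, and returns the pool ratio at
#' `year`. Under a constant atmosphere this converges to the closed form
#' `k F_atm / (k + lambda)`.
#'
#' @param k Decomposition rate, yr^-1 (> 0).
#' @param atm An [atmosphere_record()].
#' @param year Target calendar year.
#' @param spinup_years Spin-up length; default 12000 yr.
#' @param dt Integration step over the record years, yr.
#' @param lambda 14C decay rate, yr^-1.
#' @return Dimensionless pool ratio.
#' @export
one_pool_equilibrium_ratio <- function(k, atm, year, spinup_years = 12000,
                                       dt = 1 / 12, lambda = LAMBDA_14C) {
  if (k <= 0) stop("k must be positive")
  stopifnot(inherits(atm, "atmosphere_record"))
  if (spinup_years < 5 / (k + lambda))
    warning("spin-up shorter than 5/(k + lambda); equilibrium not reached")
  cpp_one_pool_ratio(k, lambda, atm$year, ratio_from_delta(atm$delta14c),
                     year, spinup_years, dt)
}

#' Initial pool Delta-14C values for a fitting window
#'
#' For the second window (`mode = "window2"`) both pools take the one-pool
#' spin-up equilibrium at `window_start` for their respective rates. For the
#' first window (`mode = "window1"`) only the fast pool does; the slow pool
#' is pinned at -42.0 per mil, the assumed pre-window value for every trial.
#'
#' @param params A [pool_params()].
#' @param atm An [atmosphere_record()].
#' @param window_start Calendar year the window begins.
#' @param mode `"window1"` or `"window2"`.
#' @param lambda 14C decay rate, yr^-1.
#' @return Named numeric vector `c(fast = ..., slow = ...)` in per mil (a
#'   third element `passive` for three-pool parameterisations).
#' @export
initial_pool_deltas <- function(params, atm, window_start,
                                mode = c("window2", "window1"),
                                lambda = LAMBDA_14C) {
  mode <- match.arg(mode)
  fast <- delta_from_ratio(one_pool_equilibrium_ratio(params$k1, atm,
                                                      window_start,
                                                      lambda = lambda))
  if (mode == "window1") {
    slow <- -42.0
    pass <- -42.0
  } else {
    slow <- delta_from_ratio(one_pool_equilibrium_ratio(params$k2, atm,
                                                        window_start,
                                                        lambda = lambda))
    pass <- if (!is.null(params$k3))
      delta_from_ratio(one_pool_equilibrium_ratio(params$k3, atm, window_start,
                                                  lambda = lambda))
    else NULL
  }
  if (is.null(params$k3)) c(fast = fast, slow = slow)
  else c(fast = fast, slow = slow, passive = pass)
}
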