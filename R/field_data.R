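#' Trial configuration: management and conversion constants
#'
#' Collects the per-trial constants used to turn field measurements into
#' model quantities: the grazing return factor `theta_ag` (fraction of
#' aboveground production returned to soil under sheep grazing), the rooting
#' factor `theta_bg` (fraction of 0-20 cm root production located in the
#' modelled 0-7.5 cm horizon), and the bulk density and depth used for stock
#' arithmetic.
#'
#' @param name Trial label.
#' @param irrigation_trigger Soil moisture (%) that triggers irrigation, or
#'   `NA` for dryland.
#' @param fertilizer_rate Superphosphate rate, kg ha^-1 yr^-1.
#' @param theta_ag,theta_bg Conversion fractions in `[0, 1]`; defaults 0.29
#'   and 0.70.
#' @param bulk_density Soil bulk density, g cm^-3; default 1.14.
#' @param depth Modelled soil depth, cm; default 7.5.
#' @return An object of class `trial_config`.
#' @export
trial_config <- function(name = "trial", irrigation_trigger = NA,
                         fertilizer_rate = 0, theta_ag = 0.29,
                         theta_bg = 0.70, bulk_density = 1.14, depth = 7.5) {
  if (theta_ag < 0 || theta_ag > 1 || theta_bg < 0 || theta_bg > 1)
    stop("theta factors must lie in [0, 1]")
  if (bulk_density <= 0 || depth <= 0)
    stop("bulk_density and depth must be positive")
  structure(list(name = name, irrigation_trigger = irrigation_trigger,
                 fertilizer_rate = fertilizer_rate, theta_ag = theta_ag,
                 theta_bg = theta_bg, bulk_density = bulk_density,
                 depth = depth),
            class = "trial_config")
}

#' Pasture production series
#'
#' Annual above- and belowground pasture production, Mg ha^-1 yr^-1. Either
#' column may contain missing years (`NA`), to be filled with [gap_fill()].
#'
#' @param year Calendar years.
#' @param aboveground,belowground Production values, >= 0 where present.
#' @return A data frame of class `production_series`.
#' @export
production_series <- function(year, aboveground, belowground) {
  aboveground <- rep_len(aboveground, length(year))
  belowground <- rep_len(belowground, length(year))
  if (any(aboveground < 0, na.rm = TRUE) || any(belowground < 0, na.rm = TRUE))
    stop("production values must be non-negative")
  structure(data.frame(year = year, aboveground = aboveground,
                       belowground = belowground),
            class = c("production_series", "data.frame"))
}

#' Observation series of carbon stock and bulk Delta-14C
#'
#' The fitting targets: per-year topsoil C stock (Mg C ha^-1) and, for a
#' subset of years, bulk \eqn{\Delta^{14}}C (per mil), each with a 1-sigma
#' uncertainty. Default uncertainties are 1.5 Mg C ha^-1 for stocks and
#' 8.9 per mil for \eqn{\Delta^{14}}C (4 per mil analytical accuracy and
#' 8 per mil spatial variability added in quadrature).
#'
#' @param year Calendar years (unique).
#' @param stock C stocks, Mg C ha^-1.
#' @param delta14c Bulk Delta-14C, per mil; `NA` for years without a
#'   radiocarbon measurement.
#' @param stock_sd,delta_sd 1-sigma uncertainties.
#' @return A data frame of class `observation_series`.
#' @export
observation_series <- function(year, stock, delta14c = NA_real_,
                               stock_sd = 1.5, delta_sd = 8.9) {
  if (anyDuplicated(year)) stop("observation years must be unique")
  if (any(stock < 0, na.rm = TRUE)) stop("stocks must be non-negative")
  structure(data.frame(year = year, stock = stock,
                       stock_sd = rep_len(stock_sd, length(year)),
                       delta14c = rep_len(delta14c, length(year)),
                       delta_sd = rep_len(delta_sd, length(year))),
            class = c("observation_series", "data.frame"))
}

#' Read a production CSV (`year,aboveground,belowground`; blanks = missing)
#' @param source Path or connection.
#' @return A [production_series()].
#' @export
read_production_table <- function(source) {
  df <- read.csv(source, comment.char = "#", strip.white = TRUE)
  need <- c("year", "aboveground", "belowground")
  if (!all(need %in% tolower(names(df))))
    stop("production table needs columns year, aboveground, belowground")
  names(df) <- tolower(names(df))
  production_series(df$year, df$aboveground, df$belowground)
}

#' Read an observation CSV (`year,stock,stock_sd,delta14c,delta_sd`)
#'
#' Missing `stock_sd`/`delta_sd` columns get the package defaults.
#'
#' @param source Path or connection.
#' @return An [observation_series()].
#' @export
read_observation_table <- function(source) {
  df <- read.csv(source, comment.char = "#", strip.white = TRUE)
  names(df) <- tolower(names(df))
  if (!all(c("year", "stock") %in% names(df)))
    stop("observation table needs at least columns year and stock")
  observation_series(df$year, df$stock,
                     delta14c = if ("delta14c" %in% names(df)) df$delta14c
                                else NA_real_,
                     stock_sd = if ("stock_sd" %in% names(df)) df$stock_sd
                                else 1.5,
                     delta_sd = if ("delta_sd" %in% names(df)) df$delta_sd
                                else 8.9)
}

#' Convert production to total carbon inputs
#'
#' `I(y) = theta_ag * AG(y) + theta_bg * BG(y)`, linear in both columns.
#' Missing values must be filled first (see [gap_fill()]).
#'
#' @param prod A [production_series()] without gaps.
#' @param cfg A [trial_config()] supplying the theta factors.
#' @return An [input_series()].
#' @export
total_inputs <- function(prod, cfg = trial_config()) {
  miss <- prod$year[is.na(prod$aboveground) | is.na(prod$belowground)]
  if (length(miss))
    stop("production has missing values in years ",
         paste(miss, collapse = ", "), "; run gap_fill() first")
  input_series(prod$year,
               cfg$theta_ag * prod$aboveground + cfg$theta_bg * prod$belowground)
}

#' Fill production gaps with per-trial means
#'
#' Missing entries in each column are replaced by the mean of that column's
#' observed entries; observed entries are untouched. Idempotent.
#'
#' @param series A [production_series()].
#' @return A gap-free [production_series()].
#' @export
gap_fill <- function(series) {
  for (col in c("aboveground", "belowground")) {
    x <- series[[col]]
    if (all(is.na(x)))
      stop("cannot gap-fill `", col, "`: no observed values")
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    series[[col]] <- x
  }
  series
}

#' Carbon stock from carbon content, bulk density and depth
#'
#' `stock = percent_c/100 * bulk_density * depth * 100`, converting
#' g C cm^-2 to Mg C ha^-1. E.g. 2 cm of soil with 5% C at 1.14 g cm^-3
#' holds 11.4 Mg C ha^-1 (the scraping-loss arithmetic for border-dyke
#' construction).
#'
#' @param percent_c Carbon content, % by mass.
#' @param bulk_density g cm^-3.
#' @param depth cm.
#' @return Stock, Mg C ha^-1.
#' @export
stock_from_carbon_content <- function(percent_c, bulk_density = 1.14,
                                      depth = 7.5) {
  if (any(percent_c < 0) || any(bulk_density < 0) || any(depth < 0))
    stop("arguments must be non-negative")
  percent_c / 100 * bulk_density * depth * 100
}

#' Initial stock from a polynomial regression of the stock time series
#'
#' Fits a least-squares polynomial of the given degree to (year, stock) and
#' evaluates it at `at_year`. This weights all stock observations equally
#' instead of trusting the first year of a window.
#'
#' @param obs An [observation_series()].
#' @param degree Polynomial degree; default 2.
#' @param at_year Year at which to evaluate the fit.
#' @return Fitted stock, Mg C ha^-1.
#' @export
fit_initial_stock <- function(obs, degree = 2, at_year) {
  keep <- !is.na(obs$stock)
  if (sum(keep) < degree + 2)
    stop("need at least degree + 2 stock observations")
  yr <- obs$year[keep] - at_year   # centre for conditioning
  fit <- lm(obs$stock[keep] ~ poly(yr, degree, raw = TRUE))
  if (anyNA(coef(fit))) stop("rank-deficient polynomial design")
  unname(predict(fit, newdata = list(yr = 0)))
}

#' Capture efficiency: percent of inputs stored as SOC increase
#'
#' `100 * mean_soc_increase / mean_inputs`; the ratio consistent with the
#' published per-trial values.
#'
#' @param mean_soc_increase Mean annual SOC increase, Mg C ha^-1 yr^-1.
#' @param mean_inputs Mean annual C inputs, Mg C ha^-1 yr^-1 (> 0).
#' @return Percentage.
#' @export
capture_efficiency <- function(mean_soc_increase, mean_inputs) {
  if (any(mean_inputs <= 0)) stop("mean_inputs must be positive")
  100 * mean_soc_increase / mean_inputs
}

#' Accumulation rate in per mille of a reference stock
#'
#' `1000 * rate / reference_stock`, the "4 per mille" style metric.
#'
#' @param rate Accumulation rate, Mg C ha^-1 yr^-1.
#' @param reference_stock Reference stock, Mg C ha^-1 (> 0).
#' @return Per mille yr^-1.
#' @export
accumulation_permille <- function(rate, reference_stock) {
  if (any(reference_stock <= 0)) stop("reference_stock must be positive")
  1000 * rate / reference_stock
}

#' Published summaries of the Winchmore grazing trials
#'
#' Per-trial means from the long-term irrigation and superphosphate
#' fertilizer experiments at Winchmore (New Zealand): mean annual above- and
#' belowground pasture production (Mg ha^-1 yr^-1, SD for aboveground),
#' mean total C inputs after theta-factor conversion, mean annual SOC
#' increase in the top 7.5 cm, and capture efficiency (% of inputs stored).
#'
#' @return A data frame, one row per trial.
#' @export
winchmore_trials <- function() {
  data.frame(
    trial = c("Unfert", "Res. fert", "High fert", "Dry", "Irr. 10", "Irr. 20"),
    irrigation_trigger = c(15, 15, 15, NA, 10, 20),
    fertilizer_rate = c(0, 250, 376, 250, 250, 250),
    ag_mean = c(1.9, 3.8, 4.8, 2.8, 4.0, 4.8),
    ag_sd = c(0.53, 1.35, 0.79, 0.80, 0.78, 0.73),
    bg_mean = c(1.9, 2.1, 2.3, 2.0, 2.1, 2.1),
    inputs_mean = c(1.9, 2.6, 3.0, 2.2, 2.6, 2.8),
    inputs_sd = c(0.2, 0.4, 0.2, 0.2, 0.2, 0.2),
    soc_increase = c(0.22, 0.23, 0.20, 0.16, 0.15, 0.13),
    capture_efficiency = c(11.6, 8.8, 6.7, 7.3, 5.8, 4.6)
  )
}

#' Published fitted parameter means for the Winchmore trials
#'
#' MCMC posterior mean parameter values (`k1`, `k2`, `a21`, `slowProp`) of
#' the two-pool series model for each trial and fitting window (1958-1992
#' and 1985-2010), together with the published ensemble median transit time
#' (`median_tt`, years).
#'
#' @return A data frame, one row per trial x window.
#' @export
winchmore_parameters <- function() {
  rbind(
    data.frame(
      trial = c("Unfert", "Res. fert", "High fert", "Dry", "Irr. 10",
                "Irr. 20"),
      window = "1958-1992",
      k1 = c(0.14, 0.18, 0.29, 0.18, 0.17, 0.26),
      k2 = c(0.005, 0.009, 0.013, 0.02, 0.01, 0.015),
      a21 = c(0.15, 0.13, 0.15, 0.24, 0.13, 0.13),
      slowProp = c(0.50, 0.55, 0.65, 0.79, 0.52, 0.64),
      median_tt = c(6.6, 4.7, 4.3, 5.8, 5.0, 3.3)
    ),
    data.frame(
      trial = c("Unfert", "Res. fert", "High fert", "Dry", "Irr. 10",
                "Irr. 20"),
      window = "1985-2010",
      k1 = c(0.11, 0.16, 0.18, 0.13, 0.14, 0.19),
      k2 = c(0.005, 0.007, 0.008, 0.011, 0.010, 0.009),
      a21 = c(0.09, 0.08, 0.07, 0.11, 0.06, 0.07),
      slowProp = c(0.52, 0.51, 0.48, 0.59, 0.57, 0.55),
      median_tt = c(7.0, 4.8, 4.3, 6.3, 5.6, 4.0)
    )
  )
}
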