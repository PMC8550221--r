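#' Read a run configuration
#'
#' Configurations are YAML with top-level keys `output_dir`, `seed`,
#' `atmosphere` (CSV path, or `"synthetic"` for the built-in bomb curve),
#' `mcmc` (`n_iter`, `burn_frac`), `bootstrap` (`n`, `level`), `windows`
#' (list of `start`, `end`, `mode`) and `trials` (list of `name`,
#' `production`, `observations` CSV paths and optional theta/bulk-density
#' overrides). Paths are resolved relative to the config file.
#'
#' @param path YAML file path.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$base_dir <- dirname(normalizePath(path))
  structure(cfg, class = "run_config")
}

resolve_path <- function(p, base) {
  if (is.null(base) || file.exists(p)) p else file.path(base, p)
}

# tiny polynomial rolling hash for provenance stamps (no binary deps)
config_hash <- function(cfg) {
  txt <- yaml::as.yaml(cfg[setdiff(names(cfg), "base_dir")])
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full per-trial, per-window analysis
#'
#' For every trial and window: convert production to inputs, fit the
#' two-pool model by MCMC, summarise the posterior, compute median and mean
#' transit times with bootstrap confidence intervals, and extrapolate
#' steady-state stocks and times to 95% of steady state. Writes per-fit
#' posterior CSVs, a combined parameter table, a steady-state table and a
#' JSON run manifest (seeds, config hash, timings) to `output_dir`. A
#' failing trial/window is recorded and the remaining fits continue.
#'
#' @param config A `run_config` (see [read_run_config()]) or a list with
#'   the same structure.
#' @return Invisibly, a list with `parameters`, `steady`, `failures` and
#'   `manifest`.
#' @export
run_full_analysis <- function(config) {
  cfg <- config
  out_dir <- cfg$output_dir %||% "soilc14-results"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed %||% 1L)
  n_iter <- cfg$mcmc$n_iter %||% 10000
  burn_frac <- cfg$mcmc$burn_frac %||% 0.2
  n_boot <- cfg$bootstrap$n %||% 1000
  level <- cfg$bootstrap$level %||% 0.99
  hash <- config_hash(cfg)

  atm <- if (is.null(cfg$atmosphere) || identical(cfg$atmosphere, "synthetic"))
    synth_atmosphere()
  else read_atmosphere_table(resolve_path(cfg$atmosphere, cfg$base_dir))

  param_rows <- list(); steady_rows <- list(); failures <- list()
  stages <- list()
  fit_i <- 0L
  for (trial in cfg$trials) {
    tcfg <- trial_config(trial$name %||% "trial",
                         theta_ag = trial$theta_ag %||% 0.29,
                         theta_bg = trial$theta_bg %||% 0.70,
                         bulk_density = trial$bulk_density %||% 1.14)
    for (w in cfg$windows) {
      fit_i <- fit_i + 1L
      label <- paste0(tcfg$name, "_", w$start, "-", w$end)
      t0 <- Sys.time()
      res <- tryCatch({
        prod <- gap_fill(read_production_table(
          resolve_path(trial$production, cfg$base_dir)))
        obs <- read_observation_table(
          resolve_path(trial$observations, cfg$base_dir))
        inputs <- total_inputs(prod, tcfg)
        win <- fit_window(w$start, w$end, obs, inputs,
                          initial_delta_mode = w$mode %||% "window2")
        post <- run_mcmc(win, atm, n_iter = n_iter, seed = seed + fit_i,
                         burn_frac = burn_frac)
        fitres <- evaluate_fit(post, win, atm)
        med_ci <- bootstrap_summaries(post,
                                      function(p) tt_quantile(p, 0.5),
                                      n_boot = n_boot, level = level,
                                      seed = seed + fit_i)
        mean_ci <- bootstrap_summaries(post, tt_mean, n_boot = n_boot,
                                       level = level, seed = seed + fit_i)
        pbar <- posterior_mean_params(post)
        mean_input <- mean(inputs$input[inputs$year >= w$start &
                                          inputs$year <= w$end])
        d0 <- window_initial_deltas(pbar, win, atm)
        st0 <- initial_state(win$initial_stock, pbar, d0$fast, d0$slow,
                             w$start)
        ssr <- steady_state_report(pbar, mean_input, st0)

        post_path <- file.path(out_dir, paste0(label, "_posterior.csv"))
        writeLines(c(sprintf("# seed: %d", post$seed),
                     sprintf("# config: %s", hash),
                     sprintf("# bounds: %s",
                             paste(names(post$bounds$lower),
                                   post$bounds$lower, post$bounds$upper,
                                   sep = ":", collapse = " "))),
                   post_path)
        suppressWarnings(write.table(
          format(post$draws, digits = 12, trim = TRUE), post_path,
          sep = ",", row.names = FALSE, quote = FALSE, append = TRUE))

        s <- post$summary
        param_rows[[label]] <- data.frame(
          trial = tcfg$name, window = paste0(w$start, "-", w$end),
          parameter = c(s$parameter, "median_tt", "mean_tt"),
          mean = c(s$mean, med_ci$mean, mean_ci$mean),
          sd = c(s$sd, sd(med_ci$values), sd(mean_ci$values)),
          ci_lower = c(s$ci99_lower, med_ci$lower, mean_ci$lower),
          ci_upper = c(s$ci99_upper, med_ci$upper, mean_ci$upper))
        steady_rows[[label]] <- data.frame(
          trial = tcfg$name, window = paste0(w$start, "-", w$end),
          mean_input = mean_input, C1ss = ssr$C1ss, C2ss = ssr$C2ss,
          total_ss = ssr$total_ss, t95_fast = ssr$t95_fast,
          t95_system = ssr$t95_system,
          rmse_stock = fitres$rmse_stock, rmse_delta = fitres$rmse_delta,
          aic = fitres$aic)
        TRUE
      }, error = function(e) {
        failures[[label]] <<- conditionMessage(e)
        FALSE
      })
      stages[[label]] <- list(ok = res,
                              seconds = round(as.numeric(
                                difftime(Sys.time(), t0, units = "secs")), 2))
    }
  }

  parameters <- do.call(rbind, c(param_rows, list(make.row.names = FALSE)))
  steady <- do.call(rbind, c(steady_rows, list(make.row.names = FALSE)))
  if (!is.null(parameters))
    write.csv(format(parameters, digits = 10, trim = TRUE),
              file.path(out_dir, "parameters.csv"), row.names = FALSE,
              quote = FALSE)
  if (!is.null(steady))
    write.csv(format(steady, digits = 10, trim = TRUE),
              file.path(out_dir, "steady_state.csv"), row.names = FALSE,
              quote = FALSE)
  manifest <- list(package = "soilc14",
                   version = as.character(utils::packageVersion("soilc14")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   seed = seed, config_hash = hash, stages = stages,
                   failures = failures)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(parameters = parameters, steady = steady,
                 failures = failures, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
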