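# shared fixtures: built in code, no files

# constant atmosphere at a given delta (per mil), wide span
const_atm <- function(delta = 0, span = c(1000, 2500)) {
  atmosphere_record(span, rep(delta, 2))
}

# the published per-trial parameter means (both windows) as pool_params list
published_param_sets <- function() {
  tab <- winchmore_parameters()
  lapply(seq_len(nrow(tab)), function(i)
    pool_params(tab$k1[i], tab$k2[i], tab$a21[i], tab$slowProp[i]))
}

# small canonical two-pool parameter set used across tests
demo_params <- function() pool_params(0.15, 0.008, 0.10, 0.55)
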