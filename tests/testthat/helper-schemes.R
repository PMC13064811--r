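# Shared fixtures: small schemes and a fast low-resolution protocol for
# tests that only need qualitative trace structure.

scheme_mk801 <- function(po = 0.066, extent = 0.4, tau_d = 0.5,
                         blocker_conc = 1) {
  ko <- 250 * po / (1 - po)
  gating_scheme(kd = extent / tau_d, kr = (1 - extent) / tau_d, ko = ko,
                kc = 250, kb = 25, blocker_conc = blocker_conc)
}

fast_protocol <- function(..., sampling_rate = 2000) {
  trace_protocol(..., sampling_rate = sampling_rate)
}

random_scheme <- function() {
  gating_scheme(kd = stats::runif(1, 0, 500), kr = stats::runif(1, 1, 500),
                ko = stats::runif(1, 0, 500), kc = stats::runif(1, 1, 500),
                kb = 25, blocker_conc = stats::runif(1, 0, 2))
}
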