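# small, fast parameter sets used across unit tests (full-scale defaults are
# exercised in test-acceptance.R)
fast_params <- function(...) {
  cell_params(T_end = 10, N_rac = 60L, N_rho = 60L, ...)
}

# parameters with all stochastic kinetics switched off
frozen_params <- function(...) {
  cell_params(k_on = 0, k_off = 0, k_fb = 0, init_noise = 0, ...)
}

circ_dev <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}
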