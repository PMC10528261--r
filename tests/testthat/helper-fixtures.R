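# Shared fixtures, built in code once per test run. The small array
# (4 TX + 4 RX = 16 channels) and order-8 sequence keep unit tests
# fast; acceptance tests build the full 256-channel setup themselves.

tiny_geom <- build_default_array(n_tx = 4, n_rx = 4)
tiny_acq <- acquisition_config(mseq_order = 8, scatterer_dz = 0.01)
default_phantom <- phantom_model()

artery_truth <- matrix(c(0.05, 0, 0, 0.04, -0.03, 0, 0, -0.02),
                       ncol = 2, byrow = TRUE)

# one pulsating point scatterer (degenerate z extent) at a given spot
point_scenario <- function(xy = c(0.02, 0.01), z = -0.05,
                           delta_d = 0.15e-3, pulsating = TRUE) {
  custom_scenario(list(artery_model(xy, delta_d = delta_d,
                                    pulsating = pulsating,
                                    z_extent = c(z, z))),
                  default_phantom)
}

scenario1_cube <- simulate_cube(build_scenario(1), tiny_geom, tiny_acq)
scenario1_resid <- remove_background(scenario1_cube)

# brute-force circular autocorrelation (independent oracle)
circ_autocorr_oracle <- function(x) {
  n <- length(x)
  vapply(0:(n - 1), function(k)
    sum(x * x[((seq_len(n) - 1 + k) %% n) + 1]), 0)
}

image_argmax <- function(img) {
  am <- which(img$values == max(img$values), arr.ind = TRUE)[1, ]
  c(img$ax1[am[1]], img$ax2[am[2]])
}
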