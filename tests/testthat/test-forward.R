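# Forward simulator: pulsation waveform, channel response, full cube.

test_that("radius waveform follows the pressure drive", {
  a <- artery_model(c(0.02, 0), delta_d = 0.15e-3, nu = 0.08)
  expect_equal(radius_waveform(a, 0), 0.15e-3)            # cos(0) phase
  expect_equal(radius_waveform(a, 3.125), 0, tolerance = 1e-18) # cos(pi/2)
  expect_equal(radius_waveform(a, 1 / 0.08), 0.15e-3)
  ap <- artery_model(c(0.02, 0), delta_d = 0, nu = 0.08)
  expect_equal(radius_waveform(ap, seq(0, 10)), rep(0, 11))
  rigid <- artery_model(c(0.02, 0), pulsating = FALSE)
  expect_error(radius_waveform(rigid, 0), "pulsating")
})

test_that("channel response superposes point scatterers with 1/r spreading", {
  m <- generate_msequence(8, chip_rate = 13e9)
  irf <- system_irf(10, fs = 13e9)
  ph <- default_phantom
  # co-located tx/rx so both legs are equal, and radii chosen so the
  # round-trip delay lands on an integer fast-time sample (no
  # fractional-delay splitting): 2*0.04 m -> 19.0 samples at 13 GHz in
  # the eps=30 gel
  tx <- c(0, 0, 0); rx <- c(0, 0, 0)
  scat1 <- data.frame(x = 0, y = 0.04, z = 0, lambda0 = 0.5, pi_amp = 0,
                      delta_d = 0, nu = 0, pulsating = FALSE)
  scat2 <- scat1; scat2$y <- 0.08  # doubles both ri and rj
  none <- scat1[0, ]
  expect_equal(channel_response(none, tx, rx, 0, ph, irf, m),
               numeric(m$length))
  y1 <- channel_response(scat1, tx, rx, 0, ph, irf, m)
  y2 <- channel_response(scat2, tx, rx, 0, ph, irf, m)
  # compressed peak amplitude scales by 1/4 per the two 1/(2 pi r) legs
  expect_equal(max(abs(y2)) / max(abs(y1)), 0.25, tolerance = 0.01)
  # delay doubles: peak positions differ by the extra round trip
  cc <- propagation_speed(30)
  expect_lte(abs((which.max(abs(y2)) - which.max(abs(y1))) -
                 2 * 0.04 / cc * 13e9), 1.5)
  # static scatterer: identical trace for every observation time
  expect_equal(channel_response(scat1, tx, rx, 17.3, ph, irf, m), y1)
  # both scatterers together superpose
  y12 <- channel_response(rbind(scat1, scat2), tx, rx, 0, ph, irf, m)
  expect_equal(y12, y1 + y2, tolerance = 1e-12)
  # scatterer on top of an antenna is singular
  bad <- scat1; bad$x <- tx[1]; bad$y <- tx[2]; bad$z <- tx[3]
  expect_error(channel_response(bad, tx, rx, 0, ph, irf, m), "singular")
})

test_that("compressed peak delay matches the round-trip time within 1 sample", {
  sc <- point_scenario(c(0.02, 0.01), z = -0.05)
  cube <- simulate_cube(sc, tiny_geom, acquisition_config(
    mseq_order = 8, clutter = FALSE))
  cc <- propagation_speed(30)
  fs <- cube$meta$fs
  sysdel <- cube$meta$system_delay_samples
  for (ch in c(1, 7, 16)) {
    tx <- tiny_geom$antennas[cube$channel_tx[ch], ]
    rx <- tiny_geom$antennas[cube$channel_rx[ch], ]
    tau <- (sqrt(sum((tx - c(0.02, 0.01, -0.05))^2)) +
            sqrt(sum((rx - c(0.02, 0.01, -0.05))^2))) / cc
    peak <- which.max(abs(cube$data[, 1, ch])) - 1
    expect_lte(abs(peak - (round(fs * tau) + sysdel)), 1)
  }
})

test_that("pulsating channels are sinusoidal at the drive frequency", {
  # non-pulsating scenario: constant along slow time
  sc_static <- point_scenario(pulsating = FALSE)
  cube_s <- simulate_cube(sc_static, tiny_geom, tiny_acq)
  expect_equal(max(abs(sweep(cube_s$data, c(1, 3),
                             cube_s$data[, 1, ]))), 0)
  # pulsating: slow-time FFT at the artery's range bin peaks at 0.08 Hz
  cube <- simulate_cube(point_scenario(), tiny_geom,
                        acquisition_config(mseq_order = 8, clutter = FALSE))
  resid <- remove_background(cube)
  ch <- 1L
  bin <- which.max(abs(resid$data[, 1, ch]))
  spec <- Mod(stats::fft(resid$data[bin, , ch]))
  n <- length(spec)
  freqs <- (0:(n - 1)) * cube$meta$slow_rate / n
  expect_equal(freqs[which.max(spec[2:(n %/% 2 + 1)]) + 1], 0.08)
})

test_that("the cube is linear in the pulsation amplitude", {
  acq <- acquisition_config(mseq_order = 8, clutter = FALSE)
  cube_s <- simulate_cube(point_scenario(delta_d = 0), tiny_geom, acq)
  cube_a <- simulate_cube(point_scenario(delta_d = 0.05e-3), tiny_geom, acq)
  cube_2a <- simulate_cube(point_scenario(delta_d = 0.1e-3), tiny_geom, acq)
  expect_equal(cube_2a$data - cube_s$data, 2 * (cube_a$data - cube_s$data),
               tolerance = 1e-10)
})

test_that("superposition: scatterer sets add (noiseless)", {
  acq <- acquisition_config(mseq_order = 8, clutter = FALSE)
  a1 <- artery_model(c(0.02, 0.01), z_extent = c(-0.05, -0.05))
  a2 <- artery_model(c(-0.01, 0.03), z_extent = c(-0.06, -0.06))
  cA <- simulate_cube(custom_scenario(list(a1)), tiny_geom, acq)
  cB <- simulate_cube(custom_scenario(list(a2)), tiny_geom, acq)
  cAB <- simulate_cube(custom_scenario(list(a1, a2)), tiny_geom, acq)
  expect_equal(cAB$data, cA$data + cB$data, tolerance = 1e-10)
})

test_that("slow-time mean of whole periods equals the static channel", {
  acq <- acquisition_config(mseq_order = 8, clutter = FALSE)
  cube <- simulate_cube(point_scenario(), tiny_geom, acq)   # 10 periods
  cube_s <- simulate_cube(point_scenario(delta_d = 0), tiny_geom, acq)
  mean_trace <- apply(cube$data, c(1, 3), mean)
  expect_equal(mean_trace, cube_s$data[, 1, ], tolerance = 1e-12)
})

test_that("additive noise matches the configured SNR within 1 dB", {
  acq_n <- acquisition_config(mseq_order = 9, snr_db = 20, seed = 42,
                              scatterer_dz = 0.01)
  acq_c <- acquisition_config(mseq_order = 9, scatterer_dz = 0.01)
  sc <- build_scenario(1)
  noisy <- simulate_cube(sc, tiny_geom, acq_n)   # 511*100*16 > 1e5 samples
  clean <- simulate_cube(sc, tiny_geom, acq_c)
  p_sig <- mean(clean$data^2)
  p_noise <- mean((noisy$data - clean$data)^2)
  expect_lt(abs(10 * log10(p_sig / p_noise) - 20), 1)
  # seed is mandatory with noise; determinism with equal seeds
  expect_error(simulate_cube(sc, tiny_geom,
                             acquisition_config(snr_db = 20)), "seed")
  noisy2 <- simulate_cube(sc, tiny_geom, acq_n)
  expect_identical(noisy$data, noisy2$data)
})

test_that("degenerate acquisitions are rejected or flagged", {
  sc <- point_scenario()
  expect_error(simulate_cube(sc, tiny_geom,
                             acquisition_config(duration = 0)), "positive")
  expect_warning(simulate_cube(sc, tiny_geom,
                               acquisition_config(mseq_order = 6,
                                                  slow_rate = 0.1,
                                                  duration = 50)),
                 "alias")
})
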