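# Slow-time FFT, pulsation-slice extraction, delay-and-sum, post-filter.

test_that("slow-time FFT concentrates statics at DC and cosines at their bin", {
  # constant cube: all energy in DC
  d <- array(rep(3, 8 * 10 * 2), c(8, 10, 2))
  cube <- radar_data_cube(d, (0:7) / 1e9, 0:9, c(1L, 1L), c(2L, 2L),
                          list(compressed = TRUE, fs = 1e9))
  rd <- slow_time_fft(cube)
  expect_equal(Mod(rd$data[, 1, ]), matrix(3, 8, 2))
  expect_equal(max(Mod(rd$data[, -1, ])), 0)
  # cosine at a bin frequency: peaks exactly at bins +/-10 (1-based 11, 91)
  slow_t <- (0:99) / 0.8
  d2 <- array(0, c(4, 100, 1))
  d2[2, , 1] <- cos(2 * pi * 0.08 * slow_t)
  cube2 <- radar_data_cube(d2, (0:3) / 1e9, slow_t, 1L, 2L,
                           list(compressed = TRUE, fs = 1e9))
  rd2 <- slow_time_fft(cube2)
  mags <- Mod(rd2$data[2, , 1])
  expect_equal(which(mags > 1e-9), c(11, 91))
  expect_equal(mags[11], 0.5, tolerance = 1e-12)   # 1/n scaling: A/2
  # Parseval under 1/n forward scaling
  expect_equal(sum(Mod(cube2$data)^2), 100 * sum(Mod(rd2$data)^2),
               tolerance = 1e-9)
  expect_error(slow_time_fft(radar_data_cube(array(0, c(4, 1, 1)),
                                             (0:3) / 1e9, 0, 1L, 2L)),
               "slow-time")
})

test_that("pulsation slice picks the nearest bin and refuses DC/Nyquist", {
  rd <- slow_time_fft(scenario1_resid)
  sl <- extract_pulsation_slice(rd, 0.08)
  expect_equal(sl$bin_freq_hz, 0.08)          # exact bin on the 1/125 grid
  expect_equal(sl$selected_bin, 11)           # bin 10, 1-based
  expect_equal(dim(sl$data), c(dim(scenario1_resid$data)[1], 16))
  expect_error(extract_pulsation_slice(rd, 0), "DC")
  expect_error(extract_pulsation_slice(rd, -1), "DC")
  expect_error(extract_pulsation_slice(rd, 0.4), "Nyquist")
  # below half the first positive bin: nearest bin is > half a bin away
  expect_warning(extract_pulsation_slice(rd, 0.003), "leakage")
  # static-only cube: zero slice at any positive frequency
  cube_s <- simulate_cube(point_scenario(pulsating = FALSE), tiny_geom,
                          tiny_acq)
  sl_s <- extract_pulsation_slice(slow_time_fft(cube_s), 0.08)
  expect_lt(max(Mod(sl_s$data)), 1e-12 * max(abs(cube_s$data)))
})

test_that("delay table implements tau = (ri+rj)/c and ga = ri*rj", {
  g1 <- build_default_array(n_tx = 1, n_rx = 1, ring_z = -0.05)
  grid <- voxel_grid("lateral", at = -0.05, voxel = 0.01,
                     lim1 = c(0, 0), lim2 = c(0, 0))   # single center voxel
  tab <- delay_table(grid, g1, default_phantom)
  # both antennas on the ring: ri = rj = 0.065 laterally at same z
  expect_equal(tab$tau_s[1, 1], 2 * 0.065 / propagation_speed(30),
               tolerance = 1e-12)
  expect_equal(tab$gain[1, 1], 0.065^2, tolerance = 1e-12)
  # closed form: voxel 3 cm from each antenna -> tau ~ 1.096 ns
  expect_equal(0.06 / propagation_speed(30), 1.0962e-9, tolerance = 1e-4)
  # symmetry under swapping TX and RX roles
  g <- tiny_geom
  grid2 <- voxel_grid("lateral", at = -0.05, voxel = 0.02)
  tab2 <- delay_table(grid2, g, default_phantom)
  swapped <- g
  swapped$channels <- data.frame(tx = g$channels$rx, rx = g$channels$tx)
  tab3 <- delay_table(grid2, swapped, default_phantom)
  expect_equal(tab2$tau_s, tab3$tau_s)
  expect_equal(tab2$gain, tab3$gain)
  # voxel on an antenna is singular
  bad <- voxel_grid("lateral", at = -0.05,
                    lim1 = c(0.065, 0.065), lim2 = c(0, 0))
  expect_error(delay_table(bad, build_default_array(ring_z = -0.05),
                           default_phantom), "coincident")
})

single_point_slice <- local({
  cube <- simulate_cube(point_scenario(c(0.02, 0.01), z = -0.05),
                        tiny_geom,
                        acquisition_config(mseq_order = 8, clutter = FALSE))
  extract_pulsation_slice(slow_time_fft(remove_background(cube)), 0.08)
})

test_that("coherent DAS localizes a single pulsating scatterer", {
  grid <- voxel_grid("lateral", at = -0.05, voxel = 0.002)
  tab <- delay_table(grid, tiny_geom, default_phantom)
  img <- das_coherent(single_point_slice, tab)
  expect_true(all(img$values >= 0))
  err <- sqrt(sum((image_argmax(img) - c(0.02, 0.01))^2))
  expect_lte(err, 8.4e-3)   # half a wavelength in the gel at 3.25 GHz
  # argmax is stable across gating windows 4..10
  for (w in c(6, 8, 10)) {
    iw <- das_coherent(single_point_slice, tab, beamformer_config(w))
    expect_equal(image_argmax(iw), image_argmax(img))
  }
  # static scene images to numerical zero
  cube_s <- simulate_cube(point_scenario(pulsating = FALSE), tiny_geom,
                          acquisition_config(mseq_order = 8,
                                             clutter = FALSE))
  sl_s <- extract_pulsation_slice(slow_time_fft(cube_s), 0.08)
  img_s <- das_coherent(sl_s, tab)
  expect_lt(max(img_s$values), 1e-20 * max(img$values))
  expect_error(das_coherent(single_point_slice, tab,
                            beamformer_config(10000)), "window")
})

test_that("image peak scales with the square of the pulsation amplitude", {
  acq <- acquisition_config(mseq_order = 8, clutter = FALSE)
  grid <- voxel_grid("lateral", at = -0.05, voxel = 0.005,
                     lim1 = c(0.0, 0.04), lim2 = c(-0.01, 0.03))
  tab <- delay_table(grid, tiny_geom, default_phantom)
  peak_for <- function(dd) {
    cube <- simulate_cube(point_scenario(delta_d = dd), tiny_geom, acq)
    sl <- extract_pulsation_slice(slow_time_fft(remove_background(cube)),
                                  0.08)
    max(das_coherent(sl, tab)$values)
  }
  p1 <- peak_for(0.05e-3)
  p2 <- peak_for(0.10e-3)
  expect_equal(p2 / p1, 4, tolerance = 1e-6)
  # monotone response over the small-signal range
  expect_gt(peak_for(0.15e-3), p2)
})

test_that("incoherent DAS dominates coherent voxelwise, equals it for 1 channel", {
  grid <- voxel_grid("lateral", at = -0.05, voxel = 0.005)
  tab <- delay_table(grid, tiny_geom, default_phantom)
  ic <- das_coherent(single_point_slice, tab)
  ii <- das_incoherent(single_point_slice, tab)
  expect_true(all(ii$values >= ic$values - 1e-12 * max(ic$values)))
  # single-channel array: identical images
  g1 <- build_default_array(n_tx = 1, n_rx = 1, ring_z = -0.05)
  cube1 <- simulate_cube(point_scenario(), g1,
                         acquisition_config(mseq_order = 8,
                                            clutter = FALSE))
  sl1 <- extract_pulsation_slice(slow_time_fft(remove_background(cube1)),
                                 0.08)
  tab1 <- delay_table(grid, g1, default_phantom)
  expect_equal(das_incoherent(sl1, tab1)$values,
               das_coherent(sl1, tab1)$values, tolerance = 1e-12)
})

test_that("incoherent argmax survives channel phase errors", {
  set.seed(11)
  sl <- single_point_slice
  phases <- stats::runif(ncol(sl$data), -pi / 2, pi / 2)
  sl_err <- sl
  sl_err$data <- sweep(sl$data, 2, exp(1i * phases), `*`)
  grid <- voxel_grid("lateral", at = -0.05, voxel = 0.002)
  tab <- delay_table(grid, tiny_geom, default_phantom)
  ii <- das_incoherent(sl_err, tab)
  err <- sqrt(sum((image_argmax(ii) - c(0.02, 0.01))^2))
  expect_lte(err, 8.4e-3)
  # coherent peak value degrades under the same phase errors
  expect_lt(max(das_coherent(sl_err, tab)$values),
            max(das_coherent(sl, tab)$values))
})

test_that("FFT-then-DAS equals DAS-then-FFT on the complex path", {
  cube <- simulate_cube(build_scenario(1), tiny_geom, tiny_acq)
  resid <- remove_background(cube)
  g5 <- voxel_grid("lateral", at = -0.05, voxel = 0.005,
                   lim1 = c(0.03, 0.05), lim2 = c(-0.01, 0.01))  # 5x5
  expect_equal(unname(dim(g5$points)[1]), 25)
  sl <- extract_pulsation_slice(slow_time_fft(resid), 0.08)
  tab <- delay_table(g5, tiny_geom, default_phantom)
  main <- das_coherent(sl, tab)
  ref <- beamform_then_fft_reference(resid, g5, tiny_geom,
                                     default_phantom, 0.08)
  expect_lt(max(abs(main$values - ref$values)), 1e-9 * max(ref$values))
  # zero cube -> zero image; single slow-time sample degenerates cleanly
  zero <- resid
  zero$data[] <- 0
  expect_equal(max(beamform_then_fft_reference(zero, g5, tiny_geom,
                                               default_phantom,
                                               0.08)$values), 0)
  one <- resid
  one$data <- resid$data[, 1, , drop = FALSE]
  one$slow_time_s <- resid$slow_time_s[1]
  expect_true(all(beamform_then_fft_reference(one, g5, tiny_geom,
                                              default_phantom,
                                              0.08)$values >= 0))
})

test_that("post-filter smooths noise and degenerates predictably", {
  # constant image: zero variance everywhere -> all-zero output
  const <- matrix(5, 20, 20)
  expect_equal(postfilter(const), matrix(0, 20, 20))
  # white noise: smoothing strictly reduces variance (before power-of-3,
  # checked through the spread of the output)
  set.seed(3)
  noisy <- matrix(stats::rnorm(40 * 40), 40, 40)
  sm <- postfilter(noisy, normalize = FALSE)
  expect_lt(stats::var(as.vector(sm)), stats::var(as.vector(noisy)))
  expect_error(postfilter(noisy, c(4, 4)), "odd")
  # image-object round trip keeps geometry and flags
  grid <- voxel_grid("lateral", at = -0.05, voxel = 0.01)
  tab <- delay_table(grid, tiny_geom, default_phantom)
  img <- das_coherent(single_point_slice, tab)
  pf <- postfilter(img)
  expect_s3_class(pf, "mw_image")
  expect_true(all(pf$values >= 0 & pf$values <= 1))
  expect_true(pf$meta$postfiltered)
})
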