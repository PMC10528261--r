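# Forward simulation of the L1 radar data cube: M-sequence sounding,
# antenna/propagation impulse-response chain, and pulsation-modulated
# point-scatterer reflectivity.

#' Radar data cube container
#'
#' The L1 measurement tensor `y(t, T, channel)`: fast time (propagation
#' delay, nanoseconds) x slow time (observation time, seconds) x MIMO
#' channel, with axis metadata.
#'
#' @param data numeric array `[n_fast, n_slow, n_channel]`.
#' @param fast_time_s strictly increasing uniform fast-time axis (s).
#' @param slow_time_s strictly increasing uniform slow-time axis (s).
#' @param channel_tx,channel_rx antenna index per channel.
#' @param meta named list of attributes (permittivity, pulsation_hz,
#'   seed, compressed flag, fast rate `fs`, `system_delay_s`, ...).
#' @return object of class `mw_cube`.
#' @export
radar_data_cube <- function(data, fast_time_s, slow_time_s,
                            channel_tx, channel_rx, meta = list()) {
  stopifnot(length(dim(data)) == 3,
            dim(data)[1] == length(fast_time_s),
            dim(data)[2] == length(slow_time_s),
            dim(data)[3] == length(channel_tx),
            length(channel_tx) == length(channel_rx))
  .check_uniform_axis(fast_time_s, "fast_time_s")
  if (length(slow_time_s) > 1) .check_uniform_axis(slow_time_s, "slow_time_s")
  structure(list(data = data, fast_time_s = fast_time_s,
                 slow_time_s = slow_time_s,
                 channel_tx = as.integer(channel_tx),
                 channel_rx = as.integer(channel_rx), meta = meta),
            class = "mw_cube")
}

.check_uniform_axis <- function(ax, name) {
  d <- diff(ax)
  if (any(d <= 0) || (length(d) > 1 && max(abs(d - d[1])) > 1e-9 * d[1]))
    stop(name, " must be strictly increasing and uniform")
  invisible(TRUE)
}

#' @export
print.mw_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("radar data cube: %d fast x %d slow x %d channels (%s)\n",
              d[1], d[2], d[3],
              if (isTRUE(x$meta$compressed)) "compressed" else "raw"))
  cat(sprintf("  fast time %.2f ns @ %.3g GHz, slow time %.1f s @ %.3g Hz\n",
              1e9 * (max(x$fast_time_s) + diff(x$fast_time_s[1:2])),
              1e-9 / diff(x$fast_time_s[1:2]),
              max(x$slow_time_s) + if (length(x$slow_time_s) > 1)
                diff(x$slow_time_s[1:2]) else 0,
              if (length(x$slow_time_s) > 1)
                1 / diff(x$slow_time_s[1:2]) else NA))
  invisible(x)
}

#' Antenna system impulse response
#'
#' Gaussian-windowed band-limiting pulse of about 10 fast-time samples
#' support, used (identically) for every transmit and receive antenna.
#' At the default 13 GHz fast-time rate the 3.25 GHz carrier is 0.25
#' cycles per sample.
#'
#' @param n_samples support length in fast-time samples.
#' @param fc carrier (center) frequency, Hz.
#' @param fs fast-time sampling rate, Hz.
#' @return object of class `mw_irf` with `tx_irf`, `rx_irf`,
#'   `effective_length`.
#' @export
system_irf <- function(n_samples = 10, fc = 3.25e9, fs = 13e9) {
  stopifnot(n_samples >= 1, fs > 0, fc >= 0, fc <= fs / 2)
  t0 <- (n_samples - 1) / 2
  n <- seq_len(n_samples) - 1
  g <- exp(-0.5 * ((n - t0) / (n_samples / 5))^2) *
    cos(2 * pi * (fc / fs) * (n - t0))
  g <- g / sqrt(sum(g^2))
  structure(list(tx_irf = g, rx_irf = g, effective_length = n_samples),
            class = "mw_irf")
}

#' Point-scatterer set of a scenario
#'
#' Discretizes each artery into a vertical line of point scatterers and
#' assigns reflectivities from the Fresnel amplitude between the gel and
#' the tube fill: `L0 = (sqrt(eps_gel) - sqrt(eps_fill)) /
#' (sqrt(eps_gel) + sqrt(eps_fill))` (air about +0.69, water about
#' -0.23), with modulation gain `Pi_amp = L0 / d0` per metre of radius
#' change. Optionally adds a static clutter ring near the phantom
#' boundary to exercise background removal.
#'
#' @param scenario an `mw_scenario`.
#' @param dz vertical scatterer spacing in metres.
#' @param clutter logical; include static boundary scatterers.
#' @return data.frame with columns `x, y, z, lambda0, pi_amp, delta_d,
#'   nu, pulsating`.
#' @export
scenario_scatterers <- function(scenario, dz = 0.005, clutter = TRUE) {
  stopifnot(inherits(scenario, "mw_scenario"))
  eps_gel <- scenario$phantom$rel_permittivity
  rows <- list()
  for (a in scenario$arteries) {
    eps_fill <- switch(a$fill, air = 1, water = 78)
    l0 <- (sqrt(eps_gel) - sqrt(eps_fill)) / (sqrt(eps_gel) + sqrt(eps_fill))
    zs <- seq(max(a$z_extent), min(a$z_extent), by = -dz)
    rows[[length(rows) + 1L]] <- data.frame(
      x = a$center_xy[1], y = a$center_xy[2], z = zs,
      lambda0 = l0,
      pi_amp = if (a$pulsating) l0 / a$d0 else 0,
      delta_d = if (a$pulsating) a$delta_d else 0,
      nu = a$nu, pulsating = a$pulsating)
  }
  if (clutter) {
    ang <- 2 * pi * (0:15) / 16
    r_cl <- 0.85 * scenario$phantom$radius
    rows[[length(rows) + 1L]] <- data.frame(
      x = r_cl * cos(ang), y = r_cl * sin(ang), z = -0.05,
      lambda0 = 0.3, pi_amp = 0, delta_d = 0, nu = 0, pulsating = FALSE)
  }
  do.call(rbind, rows)
}

#' Artery radius excursion over observation time
#'
#' `delta_d(T) = (dP / K) * cos(2 pi nu T)`: the radial excursion driven
#' by the sinusoidal pressure wave, positive (inflated) at `T = 0`.
#'
#' @param artery an `mw_artery` (must be pulsating with `nu > 0`).
#' @param T observation time(s) in seconds.
#' @return radius change in metres, same length as `T`.
#' @export
radius_waveform <- function(artery, T) {
  stopifnot(inherits(artery, "mw_artery"))
  if (!artery$pulsating || artery$nu <= 0)
    stop("radius_waveform requires a pulsating artery with nu > 0")
  (artery$delta_p / artery$stiffness) * cos(2 * pi * artery$nu * T)
}

# place weighted Dirac impulses at fractional sample delays on a
# circular fast-time grid (linear split between adjacent samples)
.impulse_train <- function(n_fast, delay_samples, amps) {
  h <- numeric(n_fast)
  i0 <- floor(delay_samples)
  w <- delay_samples - i0
  lo <- (i0 %% n_fast) + 1L
  hi <- ((i0 + 1L) %% n_fast) + 1L
  for (k in seq_along(amps)) {
    h[lo[k]] <- h[lo[k]] + amps[k] * (1 - w[k])
    h[hi[k]] <- h[hi[k]] + amps[k] * w[k]
  }
  h
}

# impulse-level (pre-sounding) channel response at observation time T:
# sum over scatterers of amplitude/(2 pi ri)(2 pi rj) at delay (ri+rj)/c,
# convolved with the tx and rx antenna IRFs
.channel_impulse <- function(scat, tx_pos, rx_pos, T, medium, irf,
                             n_fast, fs) {
  if (nrow(scat) == 0) return(numeric(n_fast))
  cc <- propagation_speed(medium$rel_permittivity)
  ri <- sqrt((scat$x - tx_pos[1])^2 + (scat$y - tx_pos[2])^2 +
             (scat$z - tx_pos[3])^2)
  rj <- sqrt((scat$x - rx_pos[1])^2 + (scat$y - rx_pos[2])^2 +
             (scat$z - rx_pos[3])^2)
  if (any(ri < 1e-9 | rj < 1e-9))
    stop("scatterer coincides with an antenna (singular 1/r)")
  lam <- scat$lambda0 + scat$delta_d * cos(2 * pi * scat$nu * T) * scat$pi_amp
  amps <- lam / ((2 * pi * ri) * (2 * pi * rj))
  h <- .impulse_train(n_fast, (ri + rj) / cc * fs, amps)
  h <- .circ_conv(h, .padded(irf$tx_irf, n_fast))
  .circ_conv(h, .padded(irf$rx_irf, n_fast))
}

.padded <- function(v, n) c(v, numeric(n - length(v)))

#' Single-channel fast-time trace at one observation time
#'
#' The received-signal model for one bistatic channel: the sounding
#' sequence is convolved with the transmit antenna response, delayed by
#' `ri/c` with spherical-spreading amplitude `1/(2 pi ri)`, scaled by
#' the time-variant reflectivity `L0 + delta_d(T) * Pi_amp`, delayed by
#' `rj/c` with amplitude `1/(2 pi rj)`, and convolved with the receive
#' antenna response; contributions of all scatterers superpose.
#' Fractional delays are linearly interpolated on the fast-time grid.
#'
#' @param scat scatterer data.frame (see [scenario_scatterers()]).
#' @param tx_pos,rx_pos antenna positions (x, y, z) in metres.
#' @param T observation time in seconds.
#' @param medium an `mw_phantom` (supplies the wave speed).
#' @param irf an `mw_irf`.
#' @param m an `mw_mseq` sounding sequence.
#' @param compress return the pulse-compressed trace (default) or the
#'   raw chip-level received signal.
#' @return numeric fast-time trace of length `m$length`.
#' @export
channel_response <- function(scat, tx_pos, rx_pos, T, medium, irf, m,
                             compress = TRUE) {
  stopifnot(inherits(m, "mw_mseq"), inherits(irf, "mw_irf"))
  n_fast <- m$length
  h <- .channel_impulse(scat, tx_pos, rx_pos, T, medium, irf,
                        n_fast, m$chip_rate)
  b <- .circ_conv(h, m$chips)
  if (compress) .circ_corr(b, m$chips) else b
}

# fast-time index (0-based) of the compressed zero-delay point response
# peak: the calibration constant that aligns beamforming delays
.system_delay_samples <- function(irf, m) {
  n_fast <- m$length
  h <- .impulse_train(n_fast, 0, 1)
  h <- .circ_conv(h, .padded(irf$tx_irf, n_fast))
  h <- .circ_conv(h, .padded(irf$rx_irf, n_fast))
  y <- .circ_corr(.circ_conv(h, m$chips), m$chips)
  which.max(abs(y)) - 1L
}

#' Default acquisition configuration
#'
#' Fast time: 13 GHz chip rate (twice the 6.5 GHz bandwidth) with an
#' order-9 M-sequence (511 chips). Slow time: 0.8 Hz over 125 s, i.e.
#' 100 samples covering exactly 10 pulsation periods at 0.08 Hz, so the
#' pulsation falls exactly on FFT bin 10 with zero leakage.
#'
#' @param fs fast-time chip rate, Hz.
#' @param mseq_order M-sequence order.
#' @param slow_rate slow-time sampling rate, Hz.
#' @param duration total observation time TI, s.
#' @param snr_db additive white Gaussian noise level in dB relative to
#'   the mean signal power; `Inf` disables noise.
#' @param seed RNG seed (mandatory when noise is enabled).
#' @param clutter include static boundary clutter scatterers.
#' @param irf_samples antenna impulse-response support.
#' @param scatterer_dz vertical scatterer spacing, m.
#' @return named list of acquisition parameters.
#' @export
acquisition_config <- function(fs = 13e9, mseq_order = 9, slow_rate = 0.8,
                               duration = 125, snr_db = Inf, seed = NULL,
                               clutter = TRUE, irf_samples = 10,
                               scatterer_dz = 0.005) {
  list(fs = fs, mseq_order = mseq_order, slow_rate = slow_rate,
       duration = duration, snr_db = snr_db, seed = seed,
       clutter = clutter, irf_samples = irf_samples,
       scatterer_dz = scatterer_dz)
}

#' Simulate the full radar data cube for a scenario
#'
#' Synthesizes the pulse-compressed L1 cube over all MIMO channels and
#' slow-time samples. The first-order reflectivity model is linear in
#' the radial excursion, so each channel factorizes exactly into a
#' static trace plus `cos(2 pi nu T)`-modulated traces (one per
#' pulsation frequency present); both are synthesized once per channel
#' through the full M-sequence sounding + compression chain.
#'
#' @param scenario an `mw_scenario`.
#' @param geom an `mw_array`.
#' @param acq acquisition list from [acquisition_config()].
#' @return a compressed `mw_cube`.
#' @export
simulate_cube <- function(scenario, geom, acq = acquisition_config()) {
  stopifnot(inherits(scenario, "mw_scenario"), inherits(geom, "mw_array"))
  if (!is.numeric(acq$duration) || acq$duration <= 0)
    stop("observation duration TI must be positive")
  nus <- unique(vapply(scenario$arteries, function(a) a$nu, 0))
  if (any(acq$slow_rate < 2 * nus))
    warning("slow-time rate below 2*nu: pulsation will alias")
  m <- generate_msequence(acq$mseq_order, chip_rate = acq$fs)
  irf <- system_irf(acq$irf_samples, fs = acq$fs)
  n_fast <- m$length
  n_slow <- round(acq$duration * acq$slow_rate)
  slow_t <- (seq_len(n_slow) - 1) / acq$slow_rate
  scat <- scenario_scatterers(scenario, dz = acq$scatterer_dz,
                              clutter = acq$clutter)
  medium <- scenario$phantom
  # static part: all scatterers at their rest reflectivity
  scat_static <- scat
  scat_static$delta_d <- 0
  # one modulation group per distinct pulsation frequency
  mod_groups <- list()
  for (nu in unique(scat$nu[scat$pulsating & scat$delta_d > 0])) {
    g <- scat[scat$pulsating & scat$delta_d > 0 & scat$nu == nu, ]
    g$lambda0 <- g$delta_d * g$pi_amp  # amplitude of the cos(2 pi nu T) term
    g$delta_d <- 0
    mod_groups[[length(mod_groups) + 1L]] <- list(nu = nu, scat = g)
  }
  chans <- geom$channels
  n_chan <- nrow(chans)
  data <- array(0, dim = c(n_fast, n_slow, n_chan))
  ones <- rep(1, n_slow)
  for (ch in seq_len(n_chan)) {
    tx_pos <- geom$antennas[chans$tx[ch], ]
    rx_pos <- geom$antennas[chans$rx[ch], ]
    g_static <- channel_response(scat_static, tx_pos, rx_pos, 0,
                                 medium, irf, m)
    slice <- g_static %o% ones
    for (grp in mod_groups) {
      g_mod <- channel_response(grp$scat, tx_pos, rx_pos, 0, medium, irf, m)
      slice <- slice + g_mod %o% cos(2 * pi * grp$nu * slow_t)
    }
    data[, , ch] <- slice
  }
  if (is.finite(acq$snr_db)) {
    if (is.null(acq$seed))
      stop("a seed is required when additive noise is enabled")
    p_sig <- mean(data^2)
    sd_n <- sqrt(p_sig / 10^(acq$snr_db / 10))
    set.seed(acq$seed)
    data <- data + stats::rnorm(length(data), sd = sd_n)
  }
  radar_data_cube(
    data = data,
    fast_time_s = (seq_len(n_fast) - 1) / acq$fs,
    slow_time_s = slow_t,
    channel_tx = chans$tx, channel_rx = chans$rx,
    meta = list(permittivity = medium$rel_permittivity,
                pulsation_hz = if (length(nus)) max(nus) else NA_real_,
                seed = acq$seed, compressed = TRUE,
                fs = acq$fs, slow_rate = acq$slow_rate,
                duration = acq$duration, snr_db = acq$snr_db,
                system_delay_samples = .system_delay_samples(irf, m),
                scenario_id = scenario$id,
                background_removed = FALSE,
                array = unclass(geom)))
}
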