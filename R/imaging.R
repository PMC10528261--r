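# Dynamic imaging, pipeline stages L3-L6: slow-time FFT, extraction of
# the pulsation-frequency channel matrix, delay-and-sum beamforming
# (coherent and incoherent) with gating and spreading-loss
# compensation, and adaptive post-filtering.

#' Slow-time FFT of a data cube (range-Doppler cube)
#'
#' Discrete Fourier transform along the slow-time axis of every
#' (fast-time bin, channel) pair, with forward `1/n_slow` scaling so a
#' unit-amplitude cosine at a bin frequency yields magnitude 1/2 at its
#' +/- bins. Frequency resolution is `1/TI`. Static scatterers land in
#' the DC bin; periodic pulsation concentrates at its frequency bin.
#'
#' @param cube an `mw_cube` (background-removed or raw; statics occupy
#'   DC either way).
#' @return object of class `mw_rdcube`: complex `data`
#'   `[n_fast, n_freq, n_channel]`, `freq_hz`, `fast_time_s`, `meta`.
#' @export
slow_time_fft <- function(cube) {
  stopifnot(inherits(cube, "mw_cube"))
  d <- dim(cube$data)
  if (d[2] < 2) stop("need at least 2 slow-time samples")
  n_slow <- d[2]
  out <- array(complex(real = 0), dim = d)
  for (ch in seq_len(d[3]))
    out[, , ch] <- t(stats::mvfft(t(cube$data[, , ch]))) / n_slow
  ti <- n_slow * diff(cube$slow_time_s[1:2])
  structure(list(data = out,
                 freq_hz = (seq_len(n_slow) - 1) / ti,
                 fast_time_s = cube$fast_time_s,
                 channel_tx = cube$channel_tx,
                 channel_rx = cube$channel_rx,
                 meta = c(cube$meta, list(ti_s = ti))),
            class = "mw_rdcube")
}

#' Extract the pulsation-frequency channel matrix
#'
#' Reduces the range-Doppler cube to the complex fast-time x channel
#' matrix at the slow-frequency bin nearest the pulsation frequency
#' `Fp` (stage L4). DC is refused: the static background lives there.
#' A warning is issued if `Fp` falls more than half a bin from the
#' nearest bin (spectral leakage).
#'
#' @param rd an `mw_rdcube`.
#' @param fp pulsation frequency in Hz, `0 < fp <` slow-time Nyquist.
#' @return object of class `mw_slice`: complex `data`
#'   `[n_fast, n_channel]`, `fp_hz`, `selected_bin`, `bin_freq_hz`.
#' @export
extract_pulsation_slice <- function(rd, fp) {
  stopifnot(inherits(rd, "mw_rdcube"))
  n_freq <- length(rd$freq_hz)
  df <- rd$freq_hz[2] - rd$freq_hz[1]
  nyq <- df * n_freq / 2
  if (fp <= 0)
    stop("Fp must be positive: the static background lies in the DC bin")
  if (fp >= nyq) stop("Fp at or above the slow-time Nyquist frequency")
  pos <- which(rd$freq_hz > 0 & rd$freq_hz <= nyq)
  bin <- pos[which.min(abs(rd$freq_hz[pos] - fp))]
  if (abs(rd$freq_hz[bin] - fp) > df / 2 + 1e-12)
    warning("Fp more than half a bin from the nearest FFT bin (leakage)")
  structure(list(data = matrix(rd$data[, bin, ], dim(rd$data)[1],
                               dim(rd$data)[3]),
                 fp_hz = fp,
                 selected_bin = bin, bin_freq_hz = rd$freq_hz[bin],
                 fast_time_s = rd$fast_time_s,
                 channel_tx = rd$channel_tx, channel_rx = rd$channel_rx,
                 meta = rd$meta),
            class = "mw_slice")
}

#' Define a voxel grid for image reconstruction
#'
#' Lateral plane (`z = const`, axes x-y) or longitudinal plane
#' (`y = const`, axes x-z). Voxel size defaults to 2 mm (1 mm remains
#' configurable).
#'
#' @param plane `"lateral"` or `"longitudinal"`.
#' @param at the fixed coordinate of the plane (z for lateral, y for
#'   longitudinal), metres.
#' @param voxel voxel edge length, metres.
#' @param lim1,lim2 ranges of the two in-plane axes, metres.
#' @return object of class `mw_grid`: `points` (n x 3), `ax1`, `ax2`,
#'   `dims`, `plane`, `at`, `voxel`.
#' @export
voxel_grid <- function(plane = c("lateral", "longitudinal"), at,
                       voxel = 0.002,
                       lim1 = c(-0.06, 0.06),
                       lim2 = if (plane[1] == "lateral") c(-0.06, 0.06)
                              else c(-0.09, -0.01)) {
  plane <- match.arg(plane)
  ax1 <- seq(lim1[1], lim1[2], by = voxel)
  ax2 <- seq(lim2[1], lim2[2], by = voxel)
  g <- as.matrix(expand.grid(a1 = ax1, a2 = ax2))
  pts <- if (plane == "lateral") cbind(g[, 1], g[, 2], at)
         else cbind(g[, 1], at, g[, 2])
  colnames(pts) <- c("x", "y", "z")
  structure(list(points = pts, ax1 = ax1, ax2 = ax2,
                 dims = c(length(ax1), length(ax2)),
                 plane = plane, at = at, voxel = voxel),
            class = "mw_grid")
}

#' Per-voxel, per-channel delays and attenuation gains
#'
#' Round-trip delay `tau_v = (|ri - rv| + |rj - rv|) / c` and
#' spreading-loss compensation gain `ga = |ri - rv| * |rj - rv|` for
#' every (voxel, channel) pair. Symmetric under swapping transmitter
#' and receiver.
#'
#' @param grid an `mw_grid`.
#' @param geom an `mw_array`.
#' @param medium an `mw_phantom` (supplies the wave speed).
#' @return object of class `mw_delays`: `tau_s` and `gain`
#'   (`n_vox x n_channel` matrices), plus the `grid`.
#' @export
delay_table <- function(grid, geom, medium) {
  stopifnot(inherits(grid, "mw_grid"), inherits(geom, "mw_array"))
  cc <- propagation_speed(medium$rel_permittivity)
  n_ant <- nrow(geom$antennas)
  # distances antenna x voxel
  D <- matrix(0, n_ant, nrow(grid$points))
  for (a in seq_len(n_ant))
    D[a, ] <- sqrt(colSums((t(grid$points) - geom$antennas[a, ])^2))
  if (any(D < 1e-6)) stop("voxel coincident with an antenna")
  ch <- geom$channels
  tau <- t(D[ch$tx, , drop = FALSE] + D[ch$rx, , drop = FALSE]) / cc
  gain <- t(D[ch$tx, , drop = FALSE] * D[ch$rx, , drop = FALSE])
  structure(list(tau_s = tau, gain = gain, grid = grid, c_mps = cc),
            class = "mw_delays")
}

#' Beamformer configuration
#'
#' @param window_samples rectangular fast-time gating window length in
#'   samples (default 4, about half a wavelength at the 3.25 GHz center
#'   frequency in the gel; 4-10 give visually indistinguishable images).
#' @param mode `"coherent"` (complex sum, higher resolution) or
#'   `"incoherent"` (magnitude sum, more robust to phase errors).
#' @return object of class `mw_bfcfg`.
#' @export
beamformer_config <- function(window_samples = 4,
                              mode = c("coherent", "incoherent")) {
  stopifnot(window_samples >= 1)
  structure(list(window_samples = as.integer(window_samples),
                 mode = match.arg(mode)),
            class = "mw_bfcfg")
}

# linear interpolation of a (possibly complex) trace at fractional
# 0-based sample positions; zero outside the record
.interp_trace <- function(trace, pos) {
  n <- length(trace)
  i0 <- floor(pos)
  w <- pos - i0
  lo <- i0 + 1
  hi <- i0 + 2
  v <- rep(if (is.complex(trace)) 0+0i else 0, length(pos))
  ok <- lo >= 1 & lo <= n
  v[ok] <- trace[lo[ok]] * (1 - w[ok])
  ok <- hi >= 1 & hi <= n
  v[ok] <- v[ok] + trace[hi[ok]] * w[ok]
  v
}

# gating-window sample offsets centered on the zero-residual-delay
# sample; exact half-sample ties round toward earlier time
.window_offsets <- function(w) (0:(w - 1)) - ceiling((w - 1) / 2)

# shared delay-and-sum kernel over the L4 channel matrix
.das_core <- function(slice, table, cfg) {
  fs <- slice$meta$fs
  sysdel <- slice$meta$system_delay_samples
  if (is.null(sysdel)) sysdel <- 0
  n_fast <- length(slice$fast_time_s)
  if (cfg$window_samples > n_fast)
    stop("gating window longer than the fast-time record")
  n_vox <- nrow(table$tau_s)
  n_chan <- ncol(table$tau_s)
  incoh <- cfg$mode == "incoherent"
  img <- numeric(n_vox)
  base_pos <- table$tau_s * fs + sysdel
  for (off in .window_offsets(cfg$window_samples)) {
    acc <- if (incoh) numeric(n_vox) else complex(n_vox)
    for (ch in seq_len(n_chan)) {
      tr <- slice$data[, ch]
      if (incoh) tr <- Mod(tr)
      v <- .interp_trace(tr, base_pos[, ch] + off)
      if (incoh) v <- Mod(v)
      acc <- acc + table$gain[, ch] * v
    }
    img <- img + Mod(acc)^2
  }
  img * (1 / fs)
}

.as_image <- function(values, grid, meta = list()) {
  structure(list(values = matrix(values, grid$dims[1], grid$dims[2]),
                 ax1 = grid$ax1, ax2 = grid$ax2,
                 plane = grid$plane, at = grid$at, voxel = grid$voxel,
                 meta = meta),
            class = "mw_image")
}

#' @export
print.mw_image <- function(x, ...) {
  cat(sprintf("%s image at %s = %.3f m: %d x %d voxels (%.0f mm), peak %.3g\n",
              x$plane, if (x$plane == "lateral") "z" else "y", x$at,
              length(x$ax1), length(x$ax2), 1e3 * x$voxel, max(x$values)))
  invisible(x)
}

#' Coherent delay-and-sum at the pulsation frequency
#'
#' For every voxel, each channel's complex fast-time trace of the L4
#' matrix is shifted by the voxel's round-trip delay (fractional delays
#' linearly interpolated), scaled by the spreading-loss gain, summed
#' over all channels, squared in magnitude, and integrated over the
#' rectangular gating window centered on the zero-residual-delay
#' sample.
#'
#' @param slice an `mw_slice` (L4 matrix).
#' @param table an `mw_delays`.
#' @param cfg an `mw_bfcfg` with `mode = "coherent"`.
#' @return an `mw_image` (non-negative values on the grid).
#' @export
das_coherent <- function(slice, table, cfg = beamformer_config()) {
  stopifnot(inherits(slice, "mw_slice"), inherits(table, "mw_delays"))
  cfg$mode <- "coherent"
  .as_image(.das_core(slice, table, cfg), table$grid,
            meta = list(mode = "coherent", fp_hz = slice$fp_hz,
                        window_samples = cfg$window_samples))
}

#' Incoherent (approximated) delay-and-sum
#'
#' Identical to [das_coherent()] except that channel magnitudes are
#' summed instead of complex values. More robust to channel phase
#' errors (no destructive cancellation) at the cost of resolution; for
#' a single channel it equals the coherent image exactly.
#'
#' @inheritParams das_coherent
#' @return an `mw_image`.
#' @export
das_incoherent <- function(slice, table, cfg = beamformer_config()) {
  stopifnot(inherits(slice, "mw_slice"), inherits(table, "mw_delays"))
  cfg$mode <- "incoherent"
  .as_image(.das_core(slice, table, cfg), table$grid,
            meta = list(mode = "incoherent", fp_hz = slice$fp_hz,
                        window_samples = cfg$window_samples))
}

#' Reference ordering: beamform per slow-time sample, then FFT
#'
#' The alternative pipeline ordering, kept as a test oracle: the
#' complex (gain-weighted, delay-aligned) channel sum is computed at
#' every slow-time sample, Fourier-transformed over observation time,
#' evaluated at the pulsation frequency, and only then squared and
#' gated. Both the beamformer and the DFT are linear, so this equals
#' the FFT-first main path to numerical precision; it is merely
#' `n_slow` times more expensive. Use on small grids only.
#'
#' @param cube an `mw_cube` (same input the main path would FFT).
#' @param grid an `mw_grid`.
#' @param geom an `mw_array`.
#' @param medium an `mw_phantom`.
#' @param fp pulsation frequency, Hz.
#' @param cfg an `mw_bfcfg`.
#' @return an `mw_image`.
#' @export
beamform_then_fft_reference <- function(cube, grid, geom, medium, fp,
                                        cfg = beamformer_config()) {
  stopifnot(inherits(cube, "mw_cube"))
  table <- delay_table(grid, geom, medium)
  fs <- cube$meta$fs
  sysdel <- cube$meta$system_delay_samples
  if (is.null(sysdel)) sysdel <- 0
  n_slow <- dim(cube$data)[2]
  n_vox <- nrow(table$tau_s)
  offs <- .window_offsets(cfg$window_samples)
  base_pos <- table$tau_s * fs + sysdel
  if (n_slow == 1) {
    img <- numeric(n_vox)
    for (off in offs) {
      acc <- numeric(n_vox)
      for (ch in seq_len(ncol(table$tau_s)))
        acc <- acc + table$gain[, ch] *
          .interp_trace(cube$data[, 1, ch], base_pos[, ch] + off)
      img <- img + Mod(acc)^2
    }
    return(.as_image(img / fs, grid, meta = list(mode = "reference")))
  }
  ti <- n_slow * diff(cube$slow_time_s[1:2])
  freq <- (seq_len(n_slow) - 1) / ti
  nyq <- n_slow / (2 * ti)
  pos_bins <- which(freq > 0 & freq <= nyq)
  bin <- pos_bins[which.min(abs(freq[pos_bins] - fp))]
  img <- numeric(n_vox)
  for (off in offs) {
    # beamformed sum per voxel per slow-time sample
    S <- matrix(0, n_vox, n_slow)
    for (ch in seq_len(ncol(table$tau_s))) {
      pos <- base_pos[, ch] + off
      for (s in seq_len(n_slow))
        S[, s] <- S[, s] + table$gain[, ch] *
          .interp_trace(cube$data[, s, ch], pos)
    }
    C <- stats::mvfft(t(S))[bin, ] / n_slow
    img <- img + Mod(C)^2
  }
  .as_image(img / fs, grid,
            meta = list(mode = "reference", fp_hz = fp,
                        window_samples = cfg$window_samples))
}

# local mean / variance over an n1 x n2 neighborhood with edge
# replication (keeps constant images exactly constant at the border)
.local_stats <- function(x, nb) {
  n1 <- nrow(x); n2 <- ncol(x)
  h1 <- (nb[1] - 1) %/% 2; h2 <- (nb[2] - 1) %/% 2
  ri <- pmin(pmax(seq_len(n1 + 2 * h1) - h1, 1), n1)
  ci <- pmin(pmax(seq_len(n2 + 2 * h2) - h2, 1), n2)
  P <- x[ri, ci, drop = FALSE]
  P2 <- P^2
  s <- matrix(0, n1, n2); s2 <- matrix(0, n1, n2)
  for (di in seq_len(nb[1]) - 1)
    for (dj in seq_len(nb[2]) - 1) {
      s <- s + P[di + seq_len(n1), dj + seq_len(n2)]
      s2 <- s2 + P2[di + seq_len(n1), dj + seq_len(n2)]
    }
  np <- nb[1] * nb[2]
  mu <- s / np
  list(mean = mu, var = pmax(s2 / np - mu^2, 0))
}

#' Adaptive noise post-filter
#'
#' Locally adaptive linear minimum mean-square-error (Wiener-type)
#' smoothing: per-pixel local mean and variance over the neighborhood
#' (noise power estimated as the mean of all local variances), then the
#' smoothed image is min-max normalized to [0, 1] and raised to the 3rd
#' power to emphasize the strongest responses. A constant image has
#' zero variance everywhere and degenerates to an all-zero output.
#'
#' @param image an `mw_image` (or a plain numeric matrix).
#' @param neighborhood odd neighborhood sizes, default `c(5, 5)`.
#' @param normalize apply the min-max normalization and power-of-3
#'   emphasis after smoothing (default); `FALSE` returns the adaptive
#'   smoothing stage alone.
#' @return filtered image of the same class as the input.
#' @export
postfilter <- function(image, neighborhood = c(5, 5), normalize = TRUE) {
  if (length(neighborhood) == 1) neighborhood <- rep(neighborhood, 2)
  if (any(neighborhood %% 2 == 0)) stop("neighborhood sizes must be odd")
  x <- if (inherits(image, "mw_image")) image$values else image
  st <- .local_stats(x, neighborhood)
  noise <- mean(st$var)
  gain <- ifelse(st$var > noise & st$var > 0,
                 (st$var - noise) / st$var, 0)
  y <- st$mean + gain * (x - st$mean)
  if (normalize) {
    rng <- range(y)
    y <- if (rng[2] > rng[1]) ((y - rng[1]) / (rng[2] - rng[1]))^3
         else matrix(0, nrow(y), ncol(y))
  }
  if (inherits(image, "mw_image")) {
    out <- image
    out$values <- y
    out$meta$postfiltered <- TRUE
    out
  } else y
}
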