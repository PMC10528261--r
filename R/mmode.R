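# M-mode time series and spectra at chosen points, plus peak detection
# and detection-count scoring against ground-truth artery positions.

#' M-mode time series at a point
#'
#' Motion-mode series of one spatial point over observation time: at
#' every slow-time sample, the gated, gain-compensated delay-and-sum of
#' the background-removed channel signals at the point's round-trip
#' delays (the real time-domain analogue of the beamformer, without the
#' slow-time FFT). A pulsating artery at the point shows up as a
#' sinusoid at the pulsation frequency; points free of artery stay
#' near zero.
#'
#' @param cube a background-removed `mw_cube` (the slow-time residual);
#'   an error is raised otherwise, since static returns would swamp the
#'   pulsation.
#' @param point position (x, y, z) in metres; must lie inside the
#'   phantom cylinder.
#' @param geom an `mw_array`.
#' @param medium an `mw_phantom`.
#' @param cfg an `mw_bfcfg` (gating window).
#' @return object of class `mw_mmode`: `series`, `time_s`, `spectrum`
#'   (magnitudes, `1/n` forward scaling), `freq_hz`, `point`.
#' @export
mmode <- function(cube, point, geom, medium, cfg = beamformer_config()) {
  stopifnot(inherits(cube, "mw_cube"), inherits(geom, "mw_array"))
  if (!isTRUE(cube$meta$background_removed))
    stop("M-mode requires a background-removed cube (stage L2)")
  point <- as.numeric(point)
  if (sqrt(sum(point[1:2]^2)) > medium$radius)
    stop("point outside the phantom")
  fs <- cube$meta$fs
  sysdel <- cube$meta$system_delay_samples
  if (is.null(sysdel)) sysdel <- 0
  cc <- propagation_speed(medium$rel_permittivity)
  ch <- geom$channels
  n_slow <- dim(cube$data)[2]
  n_fast <- dim(cube$data)[1]
  series <- numeric(n_slow)
  for (k in seq_len(nrow(ch))) {
    ri <- sqrt(sum((geom$antennas[ch$tx[k], ] - point)^2))
    rj <- sqrt(sum((geom$antennas[ch$rx[k], ] - point)^2))
    base <- (ri + rj) / cc * fs + sysdel
    for (off in .window_offsets(cfg$window_samples)) {
      pos <- base + off
      i0 <- floor(pos); w <- pos - i0
      lo <- i0 + 1; hi <- i0 + 2
      contrib <- numeric(n_slow)
      if (lo >= 1 && lo <= n_fast)
        contrib <- contrib + (1 - w) * cube$data[lo, , k]
      if (hi >= 1 && hi <= n_fast)
        contrib <- contrib + w * cube$data[hi, , k]
      series <- series + (ri * rj) * contrib
    }
  }
  series <- series / fs
  n <- length(series)
  spec <- Mod(stats::fft(series)) / n
  ti <- n * diff(cube$slow_time_s[1:2])
  structure(list(point = point, series = series,
                 time_s = cube$slow_time_s,
                 spectrum = spec, freq_hz = (seq_len(n) - 1) / ti),
            class = "mw_mmode")
}

#' @export
print.mw_mmode <- function(x, ...) {
  cat(sprintf("M-mode at (%.3f, %.3f, %.3f) m: %d samples, peak-to-peak %.3g\n",
              x$point[1], x$point[2], x$point[3], length(x$series),
              diff(range(x$series))))
  invisible(x)
}

#' Dominant non-DC frequency of an M-mode series
#'
#' Frequency of the largest spectral magnitude among the positive
#' frequencies up to Nyquist (DC excluded). Ties resolve to the lower
#' frequency.
#'
#' @param mm an `mw_mmode` (or a plain numeric series with attribute-free
#'   sampling given via `slow_rate`).
#' @param slow_rate slow-time rate in Hz, only for plain vectors.
#' @return frequency in Hz.
#' @export
dominant_frequency <- function(mm, slow_rate = NULL) {
  if (inherits(mm, "mw_mmode")) {
    spec <- mm$spectrum
    freq <- mm$freq_hz
  } else {
    stopifnot(!is.null(slow_rate))
    n <- length(mm)
    spec <- Mod(stats::fft(mm)) / n
    freq <- (seq_len(n) - 1) * slow_rate / n
  }
  series <- if (inherits(mm, "mw_mmode")) mm$series else mm
  if (diff(range(series)) == 0) stop("constant series has no dominant frequency")
  n <- length(spec)
  keep <- 2:(n %/% 2 + 1)
  # which.max returns the first maximum, i.e. the lower frequency on ties
  freq[keep[which.max(spec[keep])]]
}

# strict local maxima of a matrix over the 8-neighborhood
.local_maxima <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  P <- matrix(-Inf, n1 + 2, n2 + 2)
  P[1 + seq_len(n1), 1 + seq_len(n2)] <- x
  is_max <- matrix(TRUE, n1, n2)
  for (di in -1:1)
    for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      is_max <- is_max & (x > P[1 + di + seq_len(n1), 1 + dj + seq_len(n2)])
    }
  which(is_max, arr.ind = TRUE)
}

#' Detect image peaks and match them to ground-truth artery positions
#'
#' Local maxima of a 2D lateral image above a prominence threshold
#' (fraction of the global maximum) are greedily matched to the nearest
#' ground-truth lateral position within a tolerance; each truth is
#' matched at most once. The default 10 mm tolerance is about half a
#' wavelength in the gel plus grid slack.
#'
#' @param image an `mw_image` (lateral plane).
#' @param truth matrix (n x 2) of lateral artery coordinates, metres.
#' @param tolerance match radius in metres.
#' @param min_prominence minimum peak value as a fraction of the global
#'   maximum.
#' @return object of class `mw_detection`: `peaks` (data.frame x, y,
#'   value), `matches` (data.frame truth_idx, peak_idx, dist_m),
#'   `matched`, `n_truth`, `tolerance`.
#' @export
detect_and_match <- function(image, truth, tolerance = 0.010,
                             min_prominence = 0.1) {
  stopifnot(inherits(image, "mw_image"))
  truth <- matrix(as.numeric(truth), ncol = 2)
  if (nrow(truth) == 0) stop("empty ground-truth list")
  x <- image$values
  peaks <- data.frame(x = numeric(0), y = numeric(0), value = numeric(0))
  if (max(x) > 0) {
    lm <- .local_maxima(x)
    if (nrow(lm) > 0) {
      vals <- x[lm]
      keep <- vals >= min_prominence * max(x)
      lm <- lm[keep, , drop = FALSE]
      vals <- vals[keep]
      peaks <- data.frame(x = image$ax1[lm[, 1]], y = image$ax2[lm[, 2]],
                          value = vals)
      peaks <- peaks[order(-peaks$value), ]
      rownames(peaks) <- NULL
    }
  }
  # greedy globally-nearest assignment within tolerance
  matches <- data.frame(truth_idx = integer(0), peak_idx = integer(0),
                        dist_m = numeric(0))
  if (nrow(peaks) > 0) {
    D <- outer(seq_len(nrow(truth)), seq_len(nrow(peaks)),
               Vectorize(function(i, j)
                 sqrt((truth[i, 1] - peaks$x[j])^2 +
                      (truth[i, 2] - peaks$y[j])^2)))
    D <- matrix(D, nrow(truth), nrow(peaks))
    repeat {
      best <- which(D == min(D), arr.ind = TRUE)[1, , drop = FALSE]
      if (!is.finite(D[best]) || D[best] > tolerance) break
      matches <- rbind(matches,
                       data.frame(truth_idx = best[1], peak_idx = best[2],
                                  dist_m = D[best]))
      D[best[1], ] <- Inf
      D[, best[2]] <- Inf
      if (all(!is.finite(D))) break
    }
  }
  structure(list(peaks = peaks, matches = matches,
                 matched = nrow(matches), n_truth = nrow(truth),
                 tolerance = tolerance, min_prominence = min_prominence),
            class = "mw_detection")
}

#' @export
print.mw_detection <- function(x, ...) {
  cat(sprintf("detection report: %d/%d arteries matched within %.0f mm (%d peaks)\n",
              x$matched, x$n_truth, 1e3 * x$tolerance, nrow(x$peaks)))
  invisible(x)
}
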