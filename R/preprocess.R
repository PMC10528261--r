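# Background removal by slow-time average subtraction (pipeline stage
# L1 -> L2): static scatterers are constant along slow time, so the
# slow-time mean captures them while the zero-mean pulsation survives.

#' Estimate the static background of a data cube
#'
#' Per-channel, per-fast-time arithmetic mean over a slow-time window.
#' The mean of a cosine over a whole number of periods is zero, so when
#' the window spans an integer number of pulsations the mean isolates
#' the static scene exactly. If the pulsation frequency is known and the
#' requested window is not a whole number of periods, the window is
#' truncated to the largest whole number of periods, with a warning.
#'
#' @param cube an `mw_cube`.
#' @param window optional slow-time interval `c(start_s, end_s)`;
#'   defaults to the full record.
#' @return object of class `mw_background`: `mean_trace` (fast x
#'   channel matrix), `window_idx` (slow-time sample indices used).
#' @export
estimate_background <- function(cube, window = NULL) {
  stopifnot(inherits(cube, "mw_cube"))
  ts <- cube$slow_time_s
  idx <- seq_along(ts)
  if (!is.null(window)) {
    stopifnot(length(window) == 2, window[1] < window[2])
    idx <- which(ts >= window[1] & ts <= window[2])
    if (length(idx) == 0) stop("empty slow-time averaging window")
  }
  nu <- cube$meta$pulsation_hz
  if (!is.null(nu) && is.finite(nu) && nu > 0 && length(idx) > 1) {
    dt <- ts[2] - ts[1]
    per_samples <- 1 / (nu * dt)     # slow-time samples per pulsation
    n_keep <- floor(length(idx) / per_samples) * per_samples
    n_keep <- round(n_keep)
    if (n_keep >= 1 && n_keep < length(idx)) {
      warning(sprintf(
        "averaging window truncated from %d to %d samples (whole pulsation periods)",
        length(idx), n_keep))
      idx <- idx[seq_len(n_keep)]
    }
  }
  mt <- apply(cube$data[, idx, , drop = FALSE], c(1, 3), mean)
  structure(list(mean_trace = mt, window_idx = idx),
            class = "mw_background")
}

#' Subtract the static background from a data cube
#'
#' `y_tilde(t, T) = y(t, T) - ybar(t)` per channel. The slow-time mean
#' of the residual over the averaging window is zero by construction;
#' for a purely static scene the residual vanishes entirely.
#'
#' @param cube an `mw_cube`.
#' @param bg an `mw_background` from [estimate_background()]; computed
#'   from `cube` itself when omitted.
#' @return the background-removed `mw_cube`.
#' @export
remove_background <- function(cube, bg = NULL) {
  stopifnot(inherits(cube, "mw_cube"))
  if (is.null(bg)) bg <- estimate_background(cube)
  stopifnot(inherits(bg, "mw_background"))
  d <- dim(cube$data)
  if (!all(dim(bg$mean_trace) == d[c(1, 3)]))
    stop("background/cube axis mismatch")
  out <- cube
  for (ch in seq_len(d[3]))
    out$data[, , ch] <- cube$data[, , ch] - bg$mean_trace[, ch]
  out$meta$background_removed <- TRUE
  out
}
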