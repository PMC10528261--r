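# Maximal-length sequences for UWB sounding and pulse compression.

# known primitive feedback taps per register order (Fibonacci LFSR)
.MSEQ_TAPS <- list(
  `2` = c(2, 1),  `3` = c(3, 2),   `4` = c(4, 3),   `5` = c(5, 3),
  `6` = c(6, 5),  `7` = c(7, 6),   `8` = c(8, 6, 5, 4), `9` = c(9, 5),
  `10` = c(10, 7), `11` = c(11, 9), `12` = c(12, 6, 4, 1),
  `13` = c(13, 4, 3, 1), `14` = c(14, 5, 3, 1), `15` = c(15, 14),
  `16` = c(16, 15, 13, 4))

#' Generate a maximal-length (M-) sequence
#'
#' Binary maximal-length sequence of period `2^order - 1` from a linear
#' feedback shift register with a primitive feedback polynomial, mapped
#' to chips in {+1, -1}. Its circular autocorrelation is `N` at lag 0
#' and exactly -1 at every other lag, which is what makes pulse
#' compression recover the radar path impulse response.
#'
#' @param order register order, 2..16.
#' @param taps optional feedback tap positions (defaults to a known
#'   primitive polynomial for `order`). Non-primitive taps, which do not
#'   reach the full period, raise an error.
#' @param chip_rate chip rate in Hz (fast-time sampling rate).
#' @return object of class `mw_mseq`: `chips` (+/-1 vector of length
#'   `2^order - 1`), `order`, `chip_rate`.
#' @export
generate_msequence <- function(order, taps = NULL, chip_rate = 13e9) {
  if (!(is.numeric(order) && length(order) == 1 && order == round(order) &&
        order >= 2 && order <= 16))
    stop("order must be an integer in 2..16")
  order <- as.integer(order)
  if (is.null(taps)) taps <- .MSEQ_TAPS[[as.character(order)]]
  taps <- as.integer(taps)
  if (any(taps < 1 | taps > order) || !(order %in% taps))
    stop("taps must lie in 1..order and include the order itself")
  n <- 2L^order - 1L
  seed_state <- rep(1L, order)
  reg <- seed_state
  bits <- integer(n)
  for (i in seq_len(n)) {
    bits[i] <- reg[order]
    fb <- Reduce(bitwXor, reg[taps])
    reg <- c(fb, reg[-order])
    # with the order-th tap present the LFSR is invertible, so the state
    # cycles; a primitive polynomial first returns to the seed after
    # exactly n = 2^order - 1 shifts
    if (i < n && all(reg == seed_state))
      stop("supplied taps are not primitive: sequence period < 2^order - 1")
  }
  if (!all(reg == seed_state))
    stop("supplied taps are not primitive: sequence period < 2^order - 1")
  chips <- 1 - 2 * bits  # bit 0 -> +1, bit 1 -> -1
  acf0 <- sum(chips * chips)
  stopifnot(acf0 == n)
  structure(list(order = order, chips = chips, length = n,
                 chip_rate = chip_rate, taps = taps),
            class = "mw_mseq")
}

#' @export
print.mw_mseq <- function(x, ...) {
  cat(sprintf("M-sequence: order %d, length %d, chip rate %.3g Hz\n",
              x$order, x$length, x$chip_rate))
  invisible(x)
}

# circular convolution / correlation via FFT, real output
.circ_conv <- function(a, b) {
  n <- length(a)
  stopifnot(length(b) == n)
  Re(stats::fft(stats::fft(a) * stats::fft(b), inverse = TRUE)) / n
}

.circ_corr <- function(a, b) {
  n <- length(a)
  stopifnot(length(b) == n)
  Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE)) / n
}

#' Pulse-compress a raw data cube
#'
#' Circular correlation of every fast-time trace with the sounding
#' M-sequence, `y = b (*) m(-t)`. Because the M-sequence autocorrelation
#' is close to a Dirac impulse, the compressed trace is proportional to
#' the radar path impulse response. Linear in the input.
#'
#' @param raw an uncompressed [radar_data_cube()] whose fast-time length
#'   equals the sequence length, or a bare numeric vector (one trace).
#' @param m an `mw_mseq`.
#' @return the compressed cube (or vector), marked `compressed`.
#' @export
pulse_compress <- function(raw, m) {
  stopifnot(inherits(m, "mw_mseq"))
  if (is.numeric(raw) && is.null(dim(raw))) {
    if (length(raw) != m$length)
      stop("fast-time length must equal the M-sequence length")
    return(.circ_corr(raw, m$chips))
  }
  stopifnot(inherits(raw, "mw_cube"))
  if (isTRUE(raw$meta$compressed)) stop("cube is already compressed")
  if (dim(raw$data)[1] != m$length)
    stop("fast-time length must equal the M-sequence length")
  d <- raw$data
  for (ch in seq_len(dim(d)[3]))
    for (s in seq_len(dim(d)[2]))
      d[, s, ch] <- .circ_corr(d[, s, ch], m$chips)
  out <- raw
  out$data <- d
  out$meta$compressed <- TRUE
  out
}
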