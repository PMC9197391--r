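# Zero-phase filtering helpers.
#
# The slow baseline used for EPSP detection and voltage correlation is a
# <= few-Hz signal riding under millisecond-scale events, so it is computed
# on a block-mean decimated copy of the trace (default 10 ms blocks, i.e.
# 100 Hz) smoothed with a symmetric Gaussian kernel, then interpolated back
# to the full sampling grid.  Every step is symmetric in time, hence zero
# phase; the decimation makes the whole operation O(n) instead of an
# n-point FFT per trace.

#' Zero-phase low-pass baseline of a trace
#'
#' @param x numeric vector of samples.
#' @param dt_ms sampling interval in ms.
#' @param cutoff_hz -3 dB cutoff of the Gaussian smoother in Hz (default 1).
#' @param block_ms decimation block length in ms (default 10; must keep the
#'   decimated rate well above `cutoff_hz`).
#' @return numeric vector, same length as `x`: the slow baseline.
#' @export
lowpass_baseline <- function(x, dt_ms, cutoff_hz = 1, block_ms = 10) {
  n <- length(x)
  nyq_dec <- 1000 / (2 * block_ms)
  if (cutoff_hz >= nyq_dec)
    stop("lowpass_baseline: cutoff at or above decimated Nyquist frequency")
  bl <- max(1L, round(block_ms / dt_ms))
  nb <- floor(n / bl)
  if (nb < 8L) stop("lowpass_baseline: trace too short for baseline estimation")
  # block means (trailing partial block folded into the last mean)
  xm <- colMeans(matrix(x[seq_len(nb * bl)], nrow = bl))
  if (nb * bl < n) xm[nb] <- mean(x[((nb - 1) * bl + 1):n])
  # Gaussian kernel: -3 dB at cutoff_hz  =>  sigma_t = sqrt(ln 2)/(2*pi*fc)
  sigma_s <- sqrt(log(2)) / (2 * pi * cutoff_hz) * 1000 / (bl * dt_ms)
  hw <- max(1L, ceiling(4 * sigma_s))
  k <- exp(-0.5 * ((-hw:hw) / sigma_s)^2)
  k <- k / sum(k)
  padded <- c(rev(xm[seq_len(min(hw, nb))]),
              xm,
              rev(xm[seq.int(nb, by = -1, length.out = min(hw, nb))]))
  # reflect-pad may be shorter than hw for very short traces; extend by edge
  need <- 2 * hw + nb
  if (length(padded) < need) {
    lpad <- hw - min(hw, nb); rpad <- need - length(padded) - lpad
    padded <- c(rep(padded[1], lpad), padded, rep(padded[length(padded)], rpad))
  }
  sm <- stats::filter(padded, k, sides = 2)
  sm <- as.numeric(sm[(hw + 1):(hw + nb)])
  # interpolate block centers back to the sample grid
  centers <- (seq_len(nb) - 0.5) * bl
  stats::approx(x = centers, y = sm, xout = seq_len(n), rule = 2)$y
}

# Short boxcar smoother (zero phase, edge-replicated), used to suppress
# sample-level noise before peak picking.  width_ms rounded to an odd number
# of samples.
boxcar_smooth <- function(x, dt_ms, width_ms) {
  w <- max(1L, round(width_ms / dt_ms))
  if (w %% 2L == 0L) w <- w + 1L
  if (w == 1L) return(x)
  n <- length(x)
  hw <- (w - 1L) %/% 2L
  padded <- c(rep(x[1], hw), x, rep(x[n], hw))
  as.numeric(stats::filter(padded, rep(1 / w, w), sides = 2))[(hw + 1):(hw + n)]
}

# Smoothed derivative in mV/ms: 3-point smoothing followed by central
# differences.  Endpoints use one-sided differences.
smoothed_derivative <- function(x, dt_ms) {
  n <- length(x)
  if (n < 5L) stop("smoothed_derivative: trace shorter than derivative kernel")
  s <- c(x[1], as.numeric(stats::filter(x, rep(1 / 3, 3), sides = 2))[2:(n - 1)],
         x[n])
  d <- numeric(n)
  d[2:(n - 1)] <- (s[3:n] - s[1:(n - 2)]) / (2 * dt_ms)
  d[1] <- (s[2] - s[1]) / dt_ms
  d[n] <- (s[n] - s[n - 1]) / dt_ms
  d
}
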