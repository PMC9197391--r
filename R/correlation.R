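# Pairwise correlation of spontaneous activity.

#' Correlation of spontaneous activity within a recorded pair
#'
#' `filtered_voltage` (default): both voltage traces are baseline-
#' subtracted with the same zero-phase low-pass rule as EPSP detection and
#' the product-moment correlation of the residuals over the first
#' `window_min` minutes is returned.  `binned_spikes`: spikes are detected
#' in both traces, binned at `bin_ms`, and the counts correlated.
#'
#' @param pair an `ephys_pair` whose first sweeps are zero-command
#'   spontaneous segments of at least `window_min` minutes.
#' @param window_min correlation window, minutes (>= 1); the window is the
#'   half-open interval `[0, window_min)` of the segment.
#' @param method `"filtered_voltage"` or `"binned_spikes"`.
#' @param baseline_hz baseline cutoff for the voltage method, Hz.
#' @param bin_ms bin width for the spike method, ms.
#' @return A list of class `correlation_result`: `coefficient`, `method`,
#'   `window_s`, `pair_id`.
#' @export
pair_correlation <- function(pair, window_min = 3,
                             method = c("filtered_voltage", "binned_spikes"),
                             baseline_hz = 1, bin_ms = 100) {
  stopifnot(inherits(pair, "ephys_pair"))
  method <- match.arg(method)
  if (window_min < 1) stop("pair_correlation: window must be >= 1 min")
  win_ms <- window_min * 60000
  get_seg <- function(rec, off) {
    sw <- rec$sweeps[[1]]
    tr <- sw$signal
    if (trace_duration(tr) + 1e-9 < win_ms)
      stop("pair_correlation: window exceeds available data")
    extract_window(tr, tr$t0 + off, tr$t0 + off + win_ms)
  }
  x <- get_seg(pair$pre, 0)
  y <- get_seg(pair$post, pair$alignment_offset)
  if (method == "filtered_voltage") {
    rx <- x$samples - lowpass_baseline(x$samples, x$dt, cutoff_hz = baseline_hz)
    ry <- y$samples - lowpass_baseline(y$samples, y$dt, cutoff_hz = baseline_hz)
    if (sd(rx) == 0 || sd(ry) == 0)
      stop("pair_correlation: dead channel (zero variance); undefined")
    r <- cor(rx, ry)
  } else {
    sx <- detect_spikes(x)$spike_times
    sy <- detect_spikes(y)$spike_times
    breaks <- seq(0, win_ms, by = bin_ms)
    cx <- tabulate(findInterval(sx - x$t0, breaks,
                                rightmost.closed = FALSE),
                   nbins = length(breaks) - 1)
    cy <- tabulate(findInterval(sy - y$t0, breaks,
                                rightmost.closed = FALSE),
                   nbins = length(breaks) - 1)
    if (sd(cx) == 0 || sd(cy) == 0)
      stop("pair_correlation: no spike-count variance; undefined")
    r <- cor(cx, cy)
  }
  if (abs(r) > 1) {
    stopifnot(abs(r) - 1 < 1e-9)
    r <- sign(r)                      # clamp numerical excess
  }
  structure(list(coefficient = r, method = method,
                 window_s = win_ms / 1000, pair_id = pair$pair_id),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %s: r = %.3f (%s, %g s window)\n",
              x$pair_id, x$coefficient, x$method, x$window_s))
  invisible(x)
}

#' Group contrast of pair correlations
#'
#' Unpaired grouping (e.g. connected vs unconnected) uses the Mann-Whitney
#' test; paired grouping (before vs after in the same pairs) uses the
#' Wilcoxon signed-rank test.  Group summaries are median +/- SEM.
#'
#' @param coefficients numeric vector of correlation coefficients.
#' @param group factor/character of group labels (exactly two levels).
#' @param paired if `TRUE`, observations are matched by position within
#'   group (equal group sizes required).
#' @return A [group_comparison()] object.
#' @export
correlation_contrast <- function(coefficients, group, paired = FALSE) {
  group <- as.character(group)
  levs <- unique(group)
  if (length(levs) != 2) stop("correlation_contrast: need exactly 2 groups")
  a <- coefficients[group == levs[1]]
  b <- coefficients[group == levs[2]]
  if (length(a) < 2 || length(b) < 2)
    stop("correlation_contrast: group size < 2")
  group_comparison(a, b, labels = levs, paired = paired)
}
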