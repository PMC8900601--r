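#' Power spectrum of a simulated trajectory
#'
#' Discards the transient, removes the mean of the retained `r_E` segment,
#' applies a Hann window (the near-sinusoidal limit cycles of the model
#' leak badly under a rectangular window), and returns the one-sided
#' periodogram. Scaling preserves energy: the sum of the returned power
#' equals the windowed-signal energy (Parseval). The spectral peak is the
#' non-DC maximum, refined by parabolic interpolation over the three bins
#' around it.
#'
#' @param ts A `wc_timeseries`.
#' @param settle_fraction Fraction of samples discarded as transient; the
#'   retained segment must be at least 1 s long (1 Hz resolution).
#' @return A `wc_spectrum`: list with `freq` (Hz, ascending from 0),
#'   `power`, `peak_freq` (Hz, interpolated), `peak_power`, and
#'   `resolution` (Hz per bin).
#' @examples
#' ts <- make_sinusoid(f0 = 40, fs = 1000, duration = 4)
#' power_spectrum(ts)$peak_freq  # 40 within a fraction of a bin
#' @export
power_spectrum <- function(ts, settle_fraction = 0.5) {
  idx <- .retained_idx(ts, settle_fraction)
  x <- ts$r_E[idx]
  n <- length(x)
  if (n * ts$dt < 1)
    stop("retained segment shorter than 1 s; frequency resolution would be ",
         "worse than 1 Hz")
  w <- 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))  # Hann
  xw <- (x - mean(x)) * w
  X <- fft(xw)
  p2 <- Mod(X)^2 / n                       # two-sided, sum(p2) = sum(xw^2)
  nh <- floor(n / 2) + 1L
  power <- p2[seq_len(nh)]
  if (n %% 2 == 0) {
    power[2:(nh - 1L)] <- power[2:(nh - 1L)] + p2[n:(nh + 1L)]
  } else {
    power[2:nh] <- power[2:nh] + p2[n:(nh + 1L)]
  }
  df <- 1 / (n * ts$dt)
  freq <- (seq_len(nh) - 1L) * df
  k <- which.max(power[-1L]) + 1L          # exclude DC
  peak <- .parabolic_peak(freq, power, k)
  structure(list(freq = freq, power = power,
                 peak_freq = peak$freq, peak_power = peak$power,
                 resolution = df),
            class = "wc_spectrum")
}

# Refine a spectral peak by fitting a parabola to log-power at bins
# (k-1, k, k+1). Falls back to the bin centre at the edges.
.parabolic_peak <- function(freq, power, k) {
  if (k <= 2L || k >= length(power) || any(power[(k - 1L):(k + 1L)] <= 0))
    return(list(freq = freq[k], power = power[k]))
  y <- log(power[(k - 1L):(k + 1L)])
  denom <- y[1] - 2 * y[2] + y[3]
  if (abs(denom) < .Machine$double.eps)
    return(list(freq = freq[k], power = power[k]))
  delta <- 0.5 * (y[1] - y[3]) / denom
  delta <- max(-0.5, min(0.5, delta))
  list(freq = freq[k] + delta * (freq[2] - freq[1]),
       power = exp(y[2] - 0.25 * (y[1] - y[3]) * delta))
}

#' @export
print.wc_spectrum <- function(x, ...) {
  cat(sprintf("power spectrum: %d bins, resolution %.3f Hz, peak %.1f Hz\n",
              length(x$freq), x$resolution, x$peak_freq))
  invisible(x)
}

#' Dominant oscillation frequency of the model
#'
#' Runs the standard protocol: simulate from a zero initial condition,
#' test for sustained oscillation, and read the dominant frequency off the
#' spectrum. Near a Hopf point the amplitude settles slowly (critical
#' slowing down); when the 4 s run has not stabilized, the run is retried
#' once at `retry_duration`.
#'
#' @param params A [wc_params()] object.
#' @param duration,dt Simulation length and step, seconds.
#' @param settle_fraction,amp_threshold Passed to [detect_oscillation()].
#' @param retry_duration Extended duration for the near-Hopf retry; set to
#'   `NULL` to disable.
#' @param ic Initial condition (zero by default, the standard protocol).
#' @return The dominant frequency in Hz, or `NA_real_` when the model does
#'   not oscillate at these parameters.
#' @examples
#' dominant_frequency(wc_params())            # gamma-band value
#' dominant_frequency(wc_params(W_II = 3))    # NA: stable fixed point
#' @export
dominant_frequency <- function(params, duration = 4, dt = 1e-3,
                               settle_fraction = 0.5, amp_threshold = 1e-4,
                               retry_duration = 16, ic = c(0, 0)) {
  ts <- wc_simulate(params, ic = ic, duration = duration, dt = dt)
  if (!is.null(retry_duration) && retry_duration > duration &&
      .needs_retry(ts, settle_fraction, amp_threshold)) {
    ts <- wc_simulate(params, ic = ic, duration = retry_duration, dt = dt)
  }
  v <- detect_oscillation(ts, settle_fraction, amp_threshold)
  if (!v$oscillating) return(NA_real_)
  power_spectrum(ts, settle_fraction)$peak_freq
}

# TRUE when the retained amplitude trend has not settled to within 5%
# per cycle-span (either still growing from small amplitude or decaying).
.needs_retry <- function(ts, settle_fraction, amp_threshold) {
  idx <- .retained_idx(ts, settle_fraction)
  cyc <- .cycle_amplitudes(ts$r_E[idx])
  if (length(cyc) < 2L) return(FALSE)
  ratio <- cyc[length(cyc)] / cyc[1L]
  amp <- max(ts$r_E[idx]) - min(ts$r_E[idx])
  (amp > amp_threshold / 10) && (ratio < 0.95 || ratio > 1.05)
}

#' Oscillation frequency along a one-parameter sweep
#'
#' [dominant_frequency()] at each grid value of one parameter, all others
#' held fixed. Along the default sweeps the curve is monotone: frequency
#' is non-decreasing in `W_II` and non-increasing in `W_EE`.
#'
#' @param params Base parameter set.
#' @param pname One of `W_EE`, `W_II`, `W_EI`, `W_IE`, `i_E`, `i_I`.
#' @param values Numeric grid of parameter values.
#' @param ... Passed to [dominant_frequency()].
#' @return Numeric vector of frequencies (Hz), `NA` where the model does
#'   not oscillate, named by the grid values.
#' @export
frequency_curve <- function(params, pname, values, ...) {
  .check_pname(pname)
  out <- vapply(values, function(v)
    dominant_frequency(set_param(params, pname, v), ...), numeric(1))
  names(out) <- format(values)
  out
}

#' Oscillation frequency over a two-parameter plane
#'
#' Grid of [dominant_frequency()] over the plane spanned by two
#' parameters. Cells outside the oscillatory region hold `NA` (the
#' non-oscillation sentinel); `mask` records the oscillation verdicts.
#'
#' @param params Base parameter set.
#' @param p1,p2 Distinct parameter names (rows and columns).
#' @param values1,values2 Grids for `p1` and `p2`.
#' @param ... Passed to [dominant_frequency()].
#' @return A `wc_freqmap`: list with `p1`, `p2`, `values1`, `values2`,
#'   `frequency` (matrix, rows follow `values1`), and `mask` (logical
#'   matrix, `TRUE` where oscillating).
#' @export
frequency_map <- function(params, p1, values1, p2, values2, ...) {
  .check_pname(p1); .check_pname(p2)
  if (identical(p1, p2)) stop("p1 and p2 must be distinct parameters")
  fmat <- matrix(NA_real_, length(values1), length(values2),
                 dimnames = list(format(values1), format(values2)))
  for (i in seq_along(values1)) {
    pi_ <- set_param(params, p1, values1[i])
    for (j in seq_along(values2))
      fmat[i, j] <- dominant_frequency(set_param(pi_, p2, values2[j]), ...)
  }
  structure(list(p1 = p1, p2 = p2, values1 = values1, values2 = values2,
                 frequency = fmat, mask = !is.na(fmat)),
            class = "wc_freqmap")
}

#' @export
print.wc_freqmap <- function(x, ...) {
  cat(sprintf("frequency map %s x %s: %d x %d cells, %d oscillating\n",
              x$p1, x$p2, nrow(x$frequency), ncol(x$frequency),
              sum(x$mask)))
  if (any(x$mask))
    cat(sprintf("  frequency range: %.1f - %.1f Hz\n",
                min(x$frequency, na.rm = TRUE),
                max(x$frequency, na.rm = TRUE)))
  invisible(x)
}

#' Export a frequency map
#'
#' Writes a long-format CSV (`p1`, `p2`, `frequency`, `oscillating`; empty
#' frequency cells are the non-oscillation sentinel) and a JSON file with
#' grid metadata (`null` sentinel).
#'
#' @param fm A `wc_freqmap`.
#' @param csv_path,json_path Output paths; either may be `NULL` to skip.
#' @export
write_frequency_map <- function(fm, csv_path = NULL, json_path = NULL) {
  long <- data.frame(
    p1 = rep(fm$values1, times = length(fm$values2)),
    p2 = rep(fm$values2, each = length(fm$values1)),
    frequency = as.vector(fm$frequency),
    oscillating = as.vector(fm$mask))
  names(long)[1:2] <- c(fm$p1, fm$p2)
  if (!is.null(csv_path))
    write.csv(long, csv_path, row.names = FALSE, quote = FALSE, na = "")
  if (!is.null(json_path))
    jsonlite::write_json(
      list(axis1 = list(name = fm$p1, values = fm$values1),
           axis2 = list(name = fm$p2, values = fm$values2),
           frequency = fm$frequency, oscillating = fm$mask),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(fm)
}
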