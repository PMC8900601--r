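#' Simulate the Wilson-Cowan model with fixed-step RK4
#'
#' Classical 4th-order Runge-Kutta integration at a fixed step, the
#' protocol under which the model's gamma oscillations are studied:
#' step `dt = 0.001` s and a zero initial condition by default. The
#' integration is deterministic; identical inputs give bit-identical
#' trajectories.
#'
#' @param params A [wc_params()] object.
#' @param ic Initial condition `c(r_E, r_I)`; default `c(0, 0)`.
#' @param duration Total simulated time in seconds.
#' @param dt Time step in seconds; `duration >= dt > 0`.
#' @return A `wc_timeseries`: list with `t` (seconds), `r_E`, `r_I`
#'   (each of length `floor(duration/dt) + 1`) and `dt`.
#' @examples
#' ts <- wc_simulate(wc_params(), duration = 1)
#' range(ts$r_E)
#' @export
wc_simulate <- function(params, ic = c(0, 0), duration = 4, dt = 1e-3) {
  validate_params(params)
  .check_state(ic)
  if (!(duration >= dt && dt > 0))
    stop("need duration >= dt > 0")
  n <- floor(duration / dt)
  path <- .wc_rk4_cpp(.pack_params(params), as.numeric(ic), as.integer(n), dt)
  .make_timeseries(t = seq(0, by = dt, length.out = n + 1),
                   r_E = path[, 1], r_I = path[, 2], dt = dt)
}

.make_timeseries <- function(t, r_E, r_I, dt) {
  structure(list(t = t, r_E = r_E, r_I = r_I, dt = dt),
            class = "wc_timeseries")
}

#' @export
print.wc_timeseries <- function(x, ...) {
  cat(sprintf("Wilson-Cowan time series: %d samples, dt = %g s, %.3f s total\n",
              length(x$t), x$dt, x$t[length(x$t)]))
  cat(sprintf("  r_E in [%.4f, %.4f], r_I in [%.4f, %.4f]\n",
              min(x$r_E), max(x$r_E), min(x$r_I), max(x$r_I)))
  invisible(x)
}

#' Generic fixed-step RK4 path for an arbitrary planar field
#'
#' Pure-R companion of [wc_simulate()] used for the fixture systems
#' (damped oscillator, Hopf normal form) and as an independent
#' implementation to cross-check the compiled Wilson-Cowan integrator.
#'
#' @param f Function `f(state)` returning the two time-derivatives.
#' @param ic Initial condition, length-2 numeric.
#' @param duration,dt Total time and step, seconds.
#' @return A `wc_timeseries` (components named `r_E`, `r_I` for uniformity
#'   with the model trajectories).
#' @export
rk4_path <- function(f, ic, duration, dt) {
  if (!(duration >= dt && dt > 0)) stop("need duration >= dt > 0")
  n <- floor(duration / dt)
  out <- matrix(NA_real_, n + 1, 2)
  r <- as.numeric(ic)
  out[1, ] <- r
  for (i in seq_len(n)) {
    k1 <- f(r)
    k2 <- f(r + dt / 2 * k1)
    k3 <- f(r + dt / 2 * k2)
    k4 <- f(r + dt * k3)
    r <- r + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(r)))
      stop("integration blew up at step ", i, " (t = ", i * dt, " s)")
    out[i + 1, ] <- r
  }
  .make_timeseries(t = seq(0, by = dt, length.out = n + 1),
                   r_E = out[, 1], r_I = out[, 2], dt = dt)
}

# Retained (post-transient) sample indices.
.retained_idx <- function(ts, settle_fraction) {
  n <- length(ts$t)
  from <- floor(n * settle_fraction) + 1L
  if (n - from + 1L < 8L)
    stop("time series too short after discarding the transient")
  from:n
}

# Peak-to-trough amplitude of each cycle of x, cycles delimited by upward
# zero crossings of the mean-removed signal.
.cycle_amplitudes <- function(x) {
  xc <- x - mean(x)
  up <- which(xc[-length(xc)] < 0 & xc[-1] >= 0)
  if (length(up) < 3L) return(numeric(0))
  vapply(seq_len(length(up) - 1L), function(k) {
    seg <- x[up[k]:up[k + 1L]]
    max(seg) - min(seg)
  }, numeric(1))
}

#' Decide whether a trajectory is a sustained oscillation
#'
#' Discards the first `settle_fraction` of the samples, then calls the
#' trajectory oscillating when the retained `r_E` peak-to-peak amplitude
#' exceeds `amp_threshold` *and* the cycle amplitudes are not decaying
#' (amplitude of the last retained cycle at least 0.9 of the first): a
#' slowly dying spiral toward a stable focus is not an oscillation.
#'
#' @param ts A `wc_timeseries`.
#' @param settle_fraction Fraction of samples treated as transient.
#' @param amp_threshold Peak-to-peak amplitude of `r_E` below which the
#'   trajectory counts as settled.
#' @param frequency Optional dominant frequency (Hz) to attach when
#'   oscillating; [dominant_frequency()] fills this from the spectrum.
#' @return A `wc_verdict`: list with `oscillating` (logical), `amplitude`
#'   (retained peak-to-peak of `r_E`) and `frequency` (Hz, `NA` unless
#'   oscillating).
#' @export
detect_oscillation <- function(ts, settle_fraction = 0.5,
                               amp_threshold = 1e-4, frequency = NULL) {
  idx <- .retained_idx(ts, settle_fraction)
  x <- ts$r_E[idx]
  amp <- max(x) - min(x)
  osc <- amp > amp_threshold
  if (osc) {
    cyc <- .cycle_amplitudes(x)
    if (length(cyc) < 2L) {
      osc <- FALSE         # not even two full cycles survive the transient
    } else {
      osc <- cyc[length(cyc)] > 0.9 * cyc[1L]
    }
  }
  structure(list(oscillating = osc,
                 amplitude = amp,
                 frequency = if (osc && !is.null(frequency)) frequency
                             else NA_real_),
            class = "wc_verdict")
}

#' @export
print.wc_verdict <- function(x, ...) {
  if (x$oscillating)
    cat(sprintf("sustained oscillation: amplitude %.4g%s\n", x$amplitude,
                if (is.na(x$frequency)) ""
                else sprintf(", frequency %.1f Hz", x$frequency)))
  else
    cat(sprintf("no sustained oscillation (amplitude %.4g)\n", x$amplitude))
  invisible(x)
}

#' Time-series CSV round-trip
#'
#' Three-column CSV `t, r_E, r_I` with header, written at 17 significant
#' digits so values round-trip exactly.
#'
#' @param ts A `wc_timeseries`.
#' @param path File path.
#' @export
write_timeseries <- function(ts, path) {
  df <- data.frame(t = sprintf("%.17g", ts$t),
                   r_E = sprintf("%.17g", ts$r_E),
                   r_I = sprintf("%.17g", ts$r_I))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  df <- read.csv(path)
  dt <- median(diff(df$t))
  .make_timeseries(t = df$t, r_E = df$r_E, r_I = df$r_I, dt = dt)
}
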