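# Synthetic fixture signals and planar oracle systems. Every fixture
# carries closed-form "known facts" so the generic machinery (integrator,
# spectral stage, Hopf location, first Lyapunov coefficient) can be tested
# against answers that do not come from the machinery itself.

#' Synthetic sinusoidal time series
#'
#' Deterministic (given `seed`) sum of sinusoids with optional Gaussian
#' noise, shaped like a model trajectory so it feeds straight into
#' [power_spectrum()] and [detect_oscillation()]. `r_I` mirrors `r_E`
#' with a fixed phase lag.
#'
#' @param f0 Component frequencies, Hz. Must satisfy `fs > 2 * max(f0)`.
#' @param fs Sampling rate, samples/s.
#' @param duration Length in seconds.
#' @param amplitude Component amplitudes, recycled against `f0`.
#' @param noise_sd Gaussian noise standard deviation (default 0).
#' @param seed Integer seed for the noise.
#' @param phase_lag Phase lag of `r_I` behind `r_E`, radians.
#' @return A `wc_timeseries` with a `provenance` attribute recording the
#'   generator arguments (including the seed).
#' @export
make_sinusoid <- function(f0, fs, duration, amplitude = 1, noise_sd = 0,
                          seed = 1L, phase_lag = pi / 2) {
  if (fs <= 2 * max(f0))
    stop("Nyquist violation: need fs > 2 * max(f0)")
  amplitude <- rep_len(amplitude, length(f0))
  t <- seq(0, duration, by = 1 / fs)
  base <- function(phi) {
    x <- numeric(length(t))
    for (k in seq_along(f0))
      x <- x + amplitude[k] * sin(2 * pi * f0[k] * t - phi)
    x
  }
  noise <- if (noise_sd > 0)
    matrix(withr_seed_rnorm(2L * length(t), noise_sd, seed), ncol = 2)
  else matrix(0, length(t), 2)
  ts <- .make_timeseries(t = t,
                         r_E = base(0) + noise[, 1],
                         r_I = base(phase_lag) + noise[, 2],
                         dt = 1 / fs)
  attr(ts, "provenance") <- list(generator = "make_sinusoid", f0 = f0,
                                 fs = fs, duration = duration,
                                 amplitude = amplitude,
                                 noise_sd = noise_sd, seed = seed,
                                 phase_lag = phase_lag)
  ts
}

withr_seed_rnorm <- function(n, sd, seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  rnorm(n, 0, sd)
}

# ---------------------------------------------------------------------------
# Planar oracle systems

.new_planar_system <- function(name, field, jacobian, tensors_origin,
                               par, facts) {
  sys <- structure(list(name = name, field = field, jacobian = jacobian,
                        tensors_origin = tensors_origin, par = par,
                        facts = facts),
                   class = "planar_system")
  # construction-time consistency of the stated facts with the definition
  if (!is.null(facts$eigenvalues)) {
    ev <- eigen(jacobian(c(0, 0), par), only.values = TRUE)$values
    stopifnot(max(Mod(sort(ev) - sort(facts$eigenvalues))) < 1e-10)
  }
  if (!is.null(facts$onset_omega)) {
    par0 <- par; par0[facts$hopf_parameter] <- facts$hopf_at
    J <- jacobian(c(0, 0), par0)
    stopifnot(abs(J[1, 1] + J[2, 2]) < 1e-12,
              abs(sqrt(J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]) -
                    facts$onset_omega) < 1e-10)
  }
  sys
}

#' @export
print.planar_system <- function(x, ...) {
  cat(sprintf("planar fixture system '%s'\n", x$name))
  cat("  parameters:", paste(sprintf("%s = %g", names(x$par), x$par),
                             collapse = ", "), "\n")
  if (length(x$facts))
    cat("  known facts:", paste(names(x$facts), collapse = ", "), "\n")
  invisible(x)
}

#' Damped harmonic oscillator fixture
#'
#' The linear focus `dx/dt = lambda x - omega y`,
#' `dy/dt = omega x + lambda y` with eigenvalues `lambda +/- i omega` and
#' the closed-form solution
#' `x(t) = e^(lambda t) (x0 cos(omega t) - y0 sin(omega t))` (and the
#' rotated counterpart for `y`). Used as the integrator oracle: RK4 output
#' can be compared against `sys$closed_form(ic, t)` exactly.
#'
#' @param lambda Decay rate (1/s); negative for a stable focus.
#' @param omega Angular frequency (rad/s), positive.
#' @return A `planar_system` whose `facts` hold the eigenvalues and
#'   rotation frequency, plus a `closed_form(ic, t)` function.
#' @export
make_damped_oscillator <- function(lambda = -1, omega = 2 * pi * 10) {
  if (omega <= 0) stop("omega must be positive")
  par <- c(lambda = lambda, omega = omega)
  sys <- .new_planar_system(
    name = "damped-oscillator",
    field = function(state, par)
      c(par[["lambda"]] * state[1] - par[["omega"]] * state[2],
        par[["omega"]] * state[1] + par[["lambda"]] * state[2]),
    jacobian = function(state, par)
      matrix(c(par[["lambda"]], -par[["omega"]],
               par[["omega"]], par[["lambda"]]), 2, byrow = TRUE),
    tensors_origin = function(par)
      list(B2 = array(0, c(2, 2, 2)), B3 = array(0, c(2, 2, 2, 2))),
    par = par,
    facts = list(eigenvalues = c(lambda + 1i * omega, lambda - 1i * omega),
                 frequency = omega / (2 * pi)))
  sys$closed_form <- function(ic, t) {
    ex <- exp(lambda * t)
    cbind(x = ex * (ic[1] * cos(omega * t) - ic[2] * sin(omega * t)),
          y = ex * (ic[1] * sin(omega * t) + ic[2] * cos(omega * t)))
  }
  sys
}

#' Hopf normal form fixture
#'
#' \deqn{\dot x = \beta x - \omega y + s\, x (x^2+y^2) - c\, x (x^2+y^2)^2}
#' \deqn{\dot y = \omega x + \beta y + s\, y (x^2+y^2) - c\, y (x^2+y^2)^2}
#' with `c = 1` when `saturation` is on, else 0. Known facts: Hopf at
#' `beta = 0` with onset frequency `omega/(2 pi)`; first Lyapunov
#' coefficient of sign `sign(s)`; for `s = -1` (supercritical, no
#' saturation) a stable cycle of radius `sqrt(beta)` for `beta > 0`; for
#' `s = +1` with saturation, a subcritical Hopf with a fold of cycles at
#' `beta = -1/4` and bistability for `-1/4 < beta < 0`.
#'
#' @param beta Bifurcation parameter.
#' @param omega Rotation rate, rad/s; positive.
#' @param s Cubic coefficient; its sign is the Hopf criticality.
#' @param saturation Add the stabilizing quintic term.
#' @return A `planar_system`.
#' @export
make_hopf_normal_form <- function(beta = 0, omega = 2 * pi * 10, s = -1,
                                  saturation = FALSE) {
  if (omega <= 0) stop("omega must be positive")
  cq <- if (saturation) 1 else 0
  par <- c(beta = beta, omega = omega, s = s, cq = cq)
  facts <- list(hopf_parameter = "beta", hopf_at = 0,
                onset_omega = omega, onset_frequency = omega / (2 * pi),
                l1_sign = sign(s))
  if (s < 0 && !saturation)
    facts$stable_radius <- function(beta) ifelse(beta > 0, sqrt(beta), 0)
  if (s > 0 && saturation) {
    facts$cycle_fold_at <- -s^2 / 4
    facts$bistable_window <- c(-s^2 / 4, 0)
  }
  .new_planar_system(
    name = "hopf-normal-form",
    field = function(state, par) {
      x <- state[1]; y <- state[2]
      rho <- x^2 + y^2
      c(par[["beta"]] * x - par[["omega"]] * y + par[["s"]] * x * rho -
          par[["cq"]] * x * rho^2,
        par[["omega"]] * x + par[["beta"]] * y + par[["s"]] * y * rho -
          par[["cq"]] * y * rho^2)
    },
    jacobian = function(state, par) {
      x <- state[1]; y <- state[2]
      rho <- x^2 + y^2
      s_ <- par[["s"]]; c_ <- par[["cq"]]
      matrix(c(
        par[["beta"]] + s_ * (3 * x^2 + y^2) - c_ * (rho^2 + 4 * x^2 * rho),
        -par[["omega"]] + s_ * 2 * x * y - c_ * 4 * x * y * rho,
        par[["omega"]] + s_ * 2 * x * y - c_ * 4 * x * y * rho,
        par[["beta"]] + s_ * (x^2 + 3 * y^2) - c_ * (rho^2 + 4 * y^2 * rho)),
        2, byrow = TRUE)
    },
    tensors_origin = function(par) {
      s_ <- par[["s"]]
      B3 <- array(0, c(2, 2, 2, 2))
      B3[1, 1, 1, 1] <- 6 * s_
      B3[1, 1, 2, 2] <- B3[1, 2, 1, 2] <- B3[1, 2, 2, 1] <- 2 * s_
      B3[2, 2, 2, 2] <- 6 * s_
      B3[2, 1, 1, 2] <- B3[2, 1, 2, 1] <- B3[2, 2, 1, 1] <- 2 * s_
      list(B2 = array(0, c(2, 2, 2)), B3 = B3)
    },
    par = par, facts = facts)
}

#' Simulate a fixture system
#'
#' Fixed-step RK4 (pure R path of [rk4_path()]) on a `planar_system`.
#'
#' @param sys A `planar_system`.
#' @param ic Initial condition.
#' @param duration,dt Total time and step, seconds.
#' @param par Optional parameter override (defaults to `sys$par`).
#' @return A `wc_timeseries`.
#' @export
simulate_planar <- function(sys, ic, duration, dt, par = sys$par) {
  rk4_path(function(r) sys$field(r, par), ic, duration, dt)
}

#' Radial-equation oracle for the normal-form cycles
#'
#' In polar coordinates the normal form reduces to
#' `dr/dt = beta r + s r^3 - c r^5`; limit cycles are the positive roots
#' of `beta + s r^2 - c r^4`, found here by brute-force polynomial root
#' solving, with stability from the sign of the radial derivative. This
#' is the independent oracle for cycle radii and the fold of cycles.
#'
#' @param sys A normal-form `planar_system`.
#' @param beta Bifurcation parameter value.
#' @return Data frame with columns `radius` and `stable`.
#' @export
radial_cycles <- function(sys, beta) {
  s <- sys$par[["s"]]; cq <- sys$par[["cq"]]
  roots <- polyroot(c(beta, s, -cq)[seq_len(if (cq != 0) 3 else 2)])
  u <- Re(roots[abs(Im(roots)) < 1e-9 & Re(roots) > 1e-12])
  if (!length(u)) return(data.frame(radius = numeric(0), stable = logical(0)))
  r <- sqrt(u)
  dd <- beta + 3 * s * r^2 - 5 * cq * r^4   # d/dr of the radial field
  data.frame(radius = sort(r), stable = dd[order(r)] < 0)
}

#' Locate the Hopf point of a fixture system
#'
#' Generic planar Hopf bisection on a `planar_system`: continues the
#' equilibrium in `pname` by damped Newton, bisects the Jacobian trace to
#' zero, and evaluates omega and the first Lyapunov coefficient from the
#' system's analytic tensors. Used to close the self-consistency loop:
#' the package machinery must recover each fixture's known facts.
#'
#' @param sys A `planar_system`.
#' @param pname Parameter name in `sys$par`.
#' @param bracket Length-2 search interval.
#' @return List with `value`, `omega`, `frequency`, `l1`, `criticality`.
#' @export
planar_hopf_locate <- function(sys, pname, bracket) {
  eq_at <- function(v, warm = c(0, 0)) {
    par <- sys$par; par[pname] <- v
    r <- warm
    for (it in 1:100) {
      f <- sys$field(r, par)
      J <- sys$jacobian(r, par)
      dr <- tryCatch(solve(J, -f), error = function(e) NULL)
      if (is.null(dr)) break
      r <- r + dr
      if (sqrt(sum(sys$field(r, par)^2)) < 1e-12) break
    }
    list(r = r, J = sys$jacobian(r, par))
  }
  tr_at <- function(v) { e <- eq_at(v); e$J[1, 1] + e$J[2, 2] }
  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- tr_at(lo); f_hi <- tr_at(hi)
  if (f_lo * f_hi > 0) stop("no trace sign change in the bracket")
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    f_mid <- tr_at(mid)
    if (abs(f_mid) < 1e-12 || (hi - lo) < 1e-14) break
    if (sign(f_mid) == sign(f_lo)) { lo <- mid; f_lo <- f_mid } else hi <- mid
  }
  v <- (lo + hi) / 2
  e <- eq_at(v)
  det_ <- det(e$J)
  if (det_ <= 0) stop("determinant not positive at the trace zero")
  par <- sys$par; par[pname] <- v
  tens <- sys$tensors_origin(par)
  l1 <- .planar_l1(e$J, tens$B2, tens$B3)
  list(value = v, omega = sqrt(det_), frequency = sqrt(det_) / (2 * pi),
       l1 = l1, criticality = .criticality(l1))
}

#' Default Wilson-Cowan parameter set
#'
#' The standard gamma-band operating point (see [wc_params()]); provided
#' under this name for symmetry with the other fixture constructors.
#'
#' @return A `wc_params` object with the default values.
#' @export
default_parameters <- function() wc_params()
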