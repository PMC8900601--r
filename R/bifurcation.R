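#' Planar Hopf condition at the continued equilibrium
#'
#' In a planar system a Hopf bifurcation occurs where the Jacobian trace
#' crosses zero while the determinant stays positive; the emergent angular
#' frequency is `sqrt(det)`. This returns both quantities at the reference
#' equilibrium (warm-started from `warm` when supplied, otherwise solved
#' cold with the nearest-to-(0.5, 0.5) tie-break).
#'
#' @param params A [wc_params()] object.
#' @param warm Optional warm-start state or `wc_equilibrium` for the
#'   continued branch.
#' @return List with `trace`, `determinant` and the `wc_equilibrium`.
#' @export
hopf_condition <- function(params, warm = NULL) {
  eq <- .reference_equilibrium(params, warm)
  list(trace = eq$trace, determinant = eq$determinant, equilibrium = eq)
}

# trace/det along a parameter, continuing the equilibrium; used by the
# 1-D locator and branch continuation. `state` is carried by reference
# through an environment so successive calls stay on one branch.
.branch_tracker <- function(params, pname) {
  env <- new.env(parent = emptyenv())
  env$warm <- NULL
  function(value) {
    hc <- hopf_condition(set_param(params, pname, value), warm = env$warm)
    env$warm <- hc$equilibrium
    hc
  }
}

#' Locate a Hopf point along one parameter
#'
#' Marches the continued equilibrium across `bracket` looking for a sign
#' change of the Jacobian trace (with positive determinant), then bisects
#' to `|trace| < 1e-8`. The returned point carries the onset angular
#' frequency `omega = sqrt(det)`, the frequency in Hz, the first Lyapunov
#' coefficient and its criticality.
#'
#' @param params A [wc_params()] object.
#' @param pname Parameter to vary (see [frequency_curve()] for names).
#' @param bracket Length-2 interval to search.
#' @param n_scan Number of scan points used to find the sign change.
#' @return A `wc_hopf_point`: list with `pname`, `value`, `equilibrium`,
#'   `omega` (rad/s), `frequency` (Hz), `l1` and `criticality`
#'   (`"supercritical"`, `"subcritical"` or `"degenerate"`).
#' @examples
#' \donttest{
#' locate_hopf_1d(wc_params(), "W_II", c(0.5, 4))   # W_II = 2.019
#' }
#' @export
locate_hopf_1d <- function(params, pname, bracket, n_scan = 24L) {
  .check_pname(pname)
  if (length(bracket) != 2L || bracket[1] >= bracket[2])
    stop("bracket must be an increasing length-2 interval")
  tr_at <- .branch_tracker(params, pname)
  grid <- seq(bracket[1], bracket[2], length.out = n_scan)
  hcs <- lapply(grid, tr_at)
  tr <- vapply(hcs, `[[`, numeric(1), "trace")
  dt_ <- vapply(hcs, `[[`, numeric(1), "determinant")
  flips <- which(tr[-1] * tr[-length(tr)] < 0)
  flips <- flips[dt_[flips] > 0 & dt_[flips + 1L] > 0]
  if (!length(flips)) {
    if (any(dt_ <= 0))
      stop("no trace sign change with positive determinant in the bracket; ",
           "determinant changes sign (possible Bogdanov-Takens interference)")
    stop("no Hopf point in the bracket: trace does not change sign")
  }
  k <- flips[1L]
  lo <- grid[k]; hi <- grid[k + 1L]
  f_lo <- tr[k]
  tracker <- .branch_tracker(params, pname)
  for (v in grid[seq_len(k)]) tracker(v)  # walk onto the branch at lo
  hc_mid <- NULL
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    hc_mid <- tracker(mid)
    if (abs(hc_mid$trace) < .wc_tol$hopf_trace || (hi - lo) < 1e-14) break
    if (sign(hc_mid$trace) == sign(f_lo)) lo <- mid else hi <- mid
  }
  .make_hopf_point(params, pname, (lo + hi) / 2, hc_mid)
}

.make_hopf_point <- function(params, pname, value, hc) {
  if (hc$determinant <= 0)
    stop("determinant non-positive at the located trace zero: this is a ",
         "Bogdanov-Takens-type point, not a Hopf point")
  omega <- sqrt(hc$determinant)
  p_at <- set_param(params, pname, value)
  l1 <- first_lyapunov(p_at, hc$equilibrium)
  structure(list(pname = pname, value = value,
                 equilibrium = hc$equilibrium,
                 trace = hc$trace, determinant = hc$determinant,
                 omega = omega, frequency = omega / (2 * pi),
                 l1 = l1, criticality = .criticality(l1)),
            class = "wc_hopf_point")
}

.criticality <- function(l1) {
  if (abs(l1) < .wc_tol$l1_degenerate) "degenerate"
  else if (l1 < 0) "supercritical" else "subcritical"
}

#' @export
print.wc_hopf_point <- function(x, ...) {
  cat(sprintf("Hopf point: %s = %.6g\n", x$pname, x$value))
  cat(sprintf("  equilibrium (%.5f, %.5f), |trace| = %.2g, det = %.4g\n",
              x$equilibrium$state[1], x$equilibrium$state[2],
              abs(x$trace), x$determinant))
  cat(sprintf("  onset frequency %.2f Hz (omega = %.2f rad/s), l1 = %.4g (%s)\n",
              x$frequency, x$omega, x$l1, x$criticality))
  invisible(x)
}

# ---------------------------------------------------------------------------
# First Lyapunov coefficient (planar)

# Guckenheimer-Holmes planar formula for a system with linear part
# [[0, -omega], [omega, 0]]: the sign of
#   16 a = fxxx + fxyy + gxxy + gyyy
#        + (1/omega) [ fxy (fxx + fyy) - gxy (gxx + gyy) - fxx gxx + fyy gyy ]
# decides criticality (a < 0: supercritical).
# B2[i, j, k] and B3[i, j, k, l] are the second/third partial-derivative
# tensors of the field at the equilibrium; J its Jacobian with trace ~ 0.
.planar_l1 <- function(J, B2, B3) {
  det_ <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  if (det_ <= 0) stop("first Lyapunov coefficient needs determinant > 0")
  omega <- sqrt(det_)
  # eigenvector for +i*omega; with v = u + i w, columns T = [w, u] give
  # T^-1 J T = [[0, -omega], [omega, 0]]
  # Solve (J - i omega I) v = 0 analytically: v = (J[1,2], i omega - J[1,1])
  v <- c(J[1, 2], 1i * omega - J[1, 1])
  if (abs(J[1, 2]) < 1e-12 * max(abs(J)))
    v <- c(1i * omega - J[2, 2], J[2, 1])
  v <- v / sqrt(sum(Mod(v)^2))   # scale-free basis; l1 sign is the contract
  Tm <- cbind(Im(v), Re(v))
  if (abs(det(Tm)) < 1e-12 * max(abs(Tm))^2)
    stop("degenerate eigenbasis at the Hopf point")
  Ti <- solve(Tm)
  # transformed tensors: g_i,ab = Ti[i,p] B2[p,j,k] Tm[j,a] Tm[k,b]
  G2 <- array(0, c(2, 2, 2))
  for (p in 1:2) for (j in 1:2) for (k in 1:2) {
    if (B2[p, j, k] == 0) next
    for (i in 1:2) for (a in 1:2) for (b in 1:2)
      G2[i, a, b] <- G2[i, a, b] + Ti[i, p] * B2[p, j, k] * Tm[j, a] * Tm[k, b]
  }
  G3 <- array(0, c(2, 2, 2, 2))
  for (p in 1:2) for (j in 1:2) for (k in 1:2) for (l in 1:2) {
    if (B3[p, j, k, l] == 0) next
    for (i in 1:2) for (a in 1:2) for (b in 1:2) for (cc in 1:2)
      G3[i, a, b, cc] <- G3[i, a, b, cc] +
        Ti[i, p] * B3[p, j, k, l] * Tm[j, a] * Tm[k, b] * Tm[l, cc]
  }
  fxxx <- G3[1, 1, 1, 1]; fxyy <- G3[1, 1, 2, 2]
  gxxy <- G3[2, 1, 1, 2]; gyyy <- G3[2, 2, 2, 2]
  fxx <- G2[1, 1, 1]; fxy <- G2[1, 1, 2]; fyy <- G2[1, 2, 2]
  gxx <- G2[2, 1, 1]; gxy <- G2[2, 1, 2]; gyy <- G2[2, 2, 2]
  (fxxx + fxyy + gxxy + gyyy +
    (fxy * (fxx + fyy) - gxy * (gxx + gyy) - fxx * gxx + fyy * gyy) / omega) / 16
}

# Second/third derivative tensors of the Wilson-Cowan field at a state.
# Each component is G applied to a linear form, so the tensors are outer
# products of the coupling rows with the closed-form sigmoid derivatives.
.wc_tensors <- function(state, params) {
  cE <- params$W_EE * state[1] - params$W_EI * state[2] + params$i_E
  cI <- params$W_IE * state[1] - params$W_II * state[2] + params$i_I
  aE <- c(params$W_EE, -params$W_EI)
  aI <- c(params$W_IE, -params$W_II)
  d2E <- .sigmoid_d2(cE, params$m_E, params$theta_E) / params$tau_E
  d2I <- .sigmoid_d2(cI, params$m_I, params$theta_I) / params$tau_I
  d3E <- .sigmoid_d3(cE, params$m_E, params$theta_E) / params$tau_E
  d3I <- .sigmoid_d3(cI, params$m_I, params$theta_I) / params$tau_I
  B2 <- array(0, c(2, 2, 2))
  B3 <- array(0, c(2, 2, 2, 2))
  for (j in 1:2) for (k in 1:2) {
    B2[1, j, k] <- d2E * aE[j] * aE[k]
    B2[2, j, k] <- d2I * aI[j] * aI[k]
    for (l in 1:2) {
      B3[1, j, k, l] <- d3E * aE[j] * aE[k] * aE[l]
      B3[2, j, k, l] <- d3I * aI[j] * aI[k] * aI[l]
    }
  }
  list(B2 = B2, B3 = B3)
}

#' First Lyapunov coefficient at a Hopf equilibrium
#'
#' Transforms the system to the eigenbasis of the Hopf equilibrium and
#' evaluates the standard planar formula from the second and third partial
#' derivatives of the vector field. For the Wilson-Cowan model the
#' derivatives are closed-form (sigmoid derivatives), so the sign of the
#' result is robust. Negative values mean a supercritical Hopf (a small
#' stable cycle is born), positive subcritical.
#'
#' @param params A [wc_params()] object at the Hopf parameter value.
#' @param equilibrium The `wc_equilibrium` at the Hopf point (trace near 0,
#'   determinant positive).
#' @return The first Lyapunov coefficient (scalar).
#' @export
first_lyapunov <- function(params, equilibrium) {
  st <- as.numeric(equilibrium$state)
  tens <- .wc_tensors(st, params)
  .planar_l1(wc_jacobian(st, params), tens$B2, tens$B3)
}

# ---------------------------------------------------------------------------
# One-parameter branch continuation

#' Continue the equilibrium branch along one parameter
#'
#' Natural-parameter continuation with the previous solution as warm
#' start. Per grid point the equilibrium state, trace, determinant and
#' stability label are recorded; trace sign changes (with positive
#' determinant) are refined into Hopf points; determinant sign changes are
#' refined into a fold (limit point) of equilibria. Optionally the
#' attractor is swept by simulation with state carry-over in both
#' directions, exposing the cycle amplitude envelope and any hysteretic
#' loss of the carried-over oscillation away from a Hopf point.
#'
#' @param params A [wc_params()] object.
#' @param pname Parameter to continue in.
#' @param range Length-2 interval.
#' @param step Grid step.
#' @param envelope Run the simulation sweeps (slower).
#' @param sim_duration,sim_dt,settle_fraction,amp_threshold Simulation
#'   protocol for the envelope sweeps.
#' @return A `wc_bif1d`: list with `pname`, `values`, `states` (matrix),
#'   `trace`, `determinant`, `stability`, `hopf_points` (list of
#'   `wc_hopf_point`), `fold` (parameter value of the det-zero fold of
#'   equilibria, or `NA`), and when `envelope = TRUE` the upward/downward
#'   envelopes (`env_up`, `env_down`: min/max of retained `r_E`),
#'   oscillation masks and `cycle_loss_up` / `cycle_loss_down` (first
#'   parameter value at which the carried-over oscillation is lost away
#'   from any Hopf point, or `NA`).
#' @export
continue_branch <- function(params, pname, range, step,
                            envelope = TRUE,
                            sim_duration = 4, sim_dt = 1e-3,
                            settle_fraction = 0.5, amp_threshold = 1e-4) {
  .check_pname(pname)
  values <- seq(range[1], range[2], by = step)
  tr_at <- .branch_tracker(params, pname)
  n <- length(values)
  states <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("r_E", "r_I")))
  tr <- det_ <- rep(NA_real_, n)
  stab <- character(n)
  for (i in seq_len(n)) {
    hc <- tr_at(values[i])
    states[i, ] <- hc$equilibrium$state
    tr[i] <- hc$trace
    det_[i] <- hc$determinant
    stab[i] <- hc$equilibrium$stability
  }
  # Hopf refinement at trace sign changes
  hopf <- list()
  flips <- which(tr[-1] * tr[-n] < 0 & det_[-1] > 0 & det_[-n] > 0)
  for (k in flips) {
    hp <- tryCatch(
      locate_hopf_1d(params, pname, c(values[k], values[k + 1L]), n_scan = 2L),
      error = function(e) NULL)
    if (!is.null(hp)) hopf[[length(hopf) + 1L]] <- hp
  }
  # Fold of equilibria (limit point): along the branch either the
  # determinant changes sign, or the branch terminates and the
  # warm-started Newton jumps to a different equilibrium. Both patterns
  # are detected and refined by bisection on branch continuity.
  fold <- NA_real_
  jump <- c(FALSE, sqrt(rowSums((states[-1, , drop = FALSE] -
                                   states[-n, , drop = FALSE])^2)) > 0.1)
  dflip <- c(FALSE, det_[-1] * det_[-n] < 0)
  k <- which(jump | dflip)
  if (length(k)) {
    k <- k[1L] - 1L                      # last point still on the branch
    lo <- values[k]; hi <- values[k + 1L]
    r_lo <- states[k, ]
    d_lo <- det_[k]
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      r_mid <- .newton_eq(set_param(params, pname, mid), r_lo)
      on_branch <- !is.null(r_mid) &&
        sqrt(sum((r_mid - r_lo)^2)) < 0.1 &&
        {
          J <- wc_jacobian(r_mid, set_param(params, pname, mid))
          sign(J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]) == sign(d_lo)
        }
      if (on_branch) { lo <- mid; r_lo <- r_mid } else hi <- mid
      if ((hi - lo) < 1e-6) break
    }
    fold <- (lo + hi) / 2
  }
  out <- list(pname = pname, values = values, states = states,
              trace = tr, determinant = det_, stability = stab,
              hopf_points = hopf, fold = fold)
  if (envelope) {
    sweep <- function(vals) {
      ic <- c(0, 0)
      env <- matrix(NA_real_, length(vals), 2,
                    dimnames = list(NULL, c("min", "max")))
      osc <- logical(length(vals))
      for (i in seq_along(vals)) {
        ts <- wc_simulate(set_param(params, pname, vals[i]), ic = ic,
                          duration = sim_duration, dt = sim_dt)
        ic <- c(ts$r_E[length(ts$r_E)], ts$r_I[length(ts$r_I)])
        idx <- .retained_idx(ts, settle_fraction)
        env[i, ] <- range(ts$r_E[idx])
        osc[i] <- detect_oscillation(ts, settle_fraction,
                                     amp_threshold)$oscillating
      }
      list(env = env, osc = osc)
    }
    up <- sweep(values)
    down <- sweep(rev(values))
    out$env_up <- up$env
    out$osc_up <- up$osc
    out$env_down <- down$env[n:1, , drop = FALSE]
    out$osc_down <- down$osc[n:1]
    out$cycle_loss_up <- .cycle_loss(values, up$osc, hopf, step)
    out$cycle_loss_down <- .cycle_loss(rev(values), down$osc, hopf, step)
  }
  structure(out, class = "wc_bif1d")
}

# First sweep value (in sweep order) where a previously sustained
# oscillation is lost at least 2 steps away from every Hopf point.
.cycle_loss <- function(vals, osc, hopf_points, step) {
  if (length(vals) < 2L) return(NA_real_)
  hvals <- vapply(hopf_points, `[[`, numeric(1), "value")
  for (i in seq_along(vals)[-1L]) {
    if (osc[i - 1L] && !osc[i]) {
      if (!length(hvals) || min(abs(vals[i] - hvals)) > 2 * abs(step))
        return(vals[i])
    }
  }
  NA_real_
}

#' @export
print.wc_bif1d <- function(x, ...) {
  cat(sprintf("equilibrium branch in %s over [%g, %g] (%d points)\n",
              x$pname, min(x$values), max(x$values), length(x$values)))
  for (hp in x$hopf_points)
    cat(sprintf("  Hopf at %s = %.4f (%.1f Hz, %s)\n", x$pname, hp$value,
                hp$frequency, hp$criticality))
  if (!is.na(x$fold))
    cat(sprintf("  fold of equilibria (LP) at %s = %.4f\n", x$pname, x$fold))
  if (!is.null(x$cycle_loss_up) && !is.na(x$cycle_loss_up))
    cat(sprintf("  upward sweep loses the cycle at %s = %.4f\n",
                x$pname, x$cycle_loss_up))
  invisible(x)
}

#' Export a one-parameter bifurcation diagram
#'
#' Tidy CSV with one row per grid point: parameter value, equilibrium
#' state, trace, determinant, stability, and (when computed) the
#' simulation envelopes and oscillation flags. Hopf/fold metadata goes to
#' a JSON sidecar.
#'
#' @param bif A `wc_bif1d`.
#' @param csv_path,json_path Output paths; either may be `NULL`.
#' @export
write_bif1d <- function(bif, csv_path = NULL, json_path = NULL) {
  df <- data.frame(value = bif$values,
                   r_E = bif$states[, 1], r_I = bif$states[, 2],
                   trace = bif$trace, determinant = bif$determinant,
                   stability = bif$stability)
  if (!is.null(bif$env_up)) {
    df$env_up_min <- bif$env_up[, 1];   df$env_up_max <- bif$env_up[, 2]
    df$env_down_min <- bif$env_down[, 1]; df$env_down_max <- bif$env_down[, 2]
    df$osc_up <- bif$osc_up; df$osc_down <- bif$osc_down
  }
  names(df)[1] <- bif$pname
  if (!is.null(csv_path)) write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    meta <- list(
      pname = bif$pname,
      hopf_points = lapply(bif$hopf_points, function(h)
        list(value = h$value, frequency = h$frequency, l1 = h$l1,
             criticality = h$criticality)),
      fold = bif$fold,
      cycle_loss_up = bif$cycle_loss_up,
      cycle_loss_down = bif$cycle_loss_down)
    jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }
  invisible(bif)
}
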