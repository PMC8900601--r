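# Two-parameter Hopf-curve tracing by pseudo-arclength continuation.
#
# The curve is the solution set of the 3-equation system
#   F_E(r, p) = 0, F_I(r, p) = 0, trace J(r, p) = 0
# in the 4 unknowns z = (r_E, r_I, p1, p2). Special points flagged along
# the way: Bogdanov-Takens (determinant of the equilibrium Jacobian
# crosses zero; refined by a full 4-equation Newton solve) and
# generalized Hopf (first Lyapunov coefficient crosses zero).

# residual and per-point diagnostics at z
.hopf_sys <- function(params, p1, p2) {
  fn <- function(z) {
    p <- set_param(set_param(params, p1, z[3]), p2, z[4])
    st <- z[1:2]
    J <- wc_jacobian(st, p)
    c(wc_field(st, p), J[1, 1] + J[2, 2])
  }
  diag_fn <- function(z) {
    p <- set_param(set_param(params, p1, z[3]), p2, z[4])
    st <- z[1:2]
    J <- wc_jacobian(st, p)
    det_ <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
    l1 <- if (det_ > 0) {
      tens <- .wc_tensors(st, p)
      tryCatch(.planar_l1(J, tens$B2, tens$B3), error = function(e) NA_real_)
    } else NA_real_
    list(det = det_, l1 = l1)
  }
  list(fn = fn, diag = diag_fn)
}

# central-difference Jacobian of vector function fn at z (m x length(z))
.num_jac <- function(fn, z, m, eps = 1e-6) {
  J <- matrix(0, m, length(z))
  for (j in seq_along(z)) {
    h <- eps * max(1, abs(z[j]))
    zp <- z; zp[j] <- z[j] + h
    zm <- z; zm[j] <- z[j] - h
    J[, j] <- (fn(zp) - fn(zm)) / (2 * h)
  }
  J
}

# Newton corrector for the bordered system {H(z) = 0, (z - z_pred) . tang = 0}
.plc_correct <- function(fn, z_pred, tang, tol = 1e-9, max_iter = 12L) {
  z <- z_pred
  for (it in seq_len(max_iter)) {
    r <- c(fn(z), sum((z - z_pred) * tang))
    if (all(abs(r[1:3]) < c(tol, tol, 1e-6)) && it > 1L) return(z)
    A <- rbind(.num_jac(fn, z, 3L), tang)
    dz <- tryCatch(solve(A, -r), error = function(e) NULL)
    if (is.null(dz)) return(NULL)
    z <- z + dz
    if (any(!is.finite(z))) return(NULL)
  }
  r <- fn(z)
  if (all(abs(r) < 1e-6)) z else NULL
}

# unit tangent of the curve at z (null vector of the 3x4 Jacobian)
.plc_tangent <- function(fn, z) {
  A <- .num_jac(fn, z, 3L)
  v <- svd(A, nu = 0, nv = 4)$v[, 4]
  v / sqrt(sum(v^2))
}

#' Trace a Hopf bifurcation curve in a two-parameter plane
#'
#' Pseudo-arclength continuation of the planar Hopf condition (equilibrium
#' equations plus zero trace) in the plane spanned by `p1` and `p2`,
#' started from a point obtained with [locate_hopf_1d()]. The trace runs
#' in both directions until it leaves `bounds` or exhausts `max_steps`
#' half-steps. Bogdanov-Takens points (determinant zero: the Hopf curve
#' meets a saddle-node curve) are refined by a 4-equation Newton solve;
#' generalized Hopf points (first Lyapunov coefficient zero: criticality
#' flips) are located by interpolation between curve points. The side of
#' the curve that oscillates is determined by simulating one probe point
#' on each side of the curve midpoint.
#'
#' @param params A [wc_params()] object (values of `p1`, `p2` are
#'   overridden along the curve). Curves typically close through negative
#'   parameter values, so pass `biological_mode = FALSE` parameters when a
#'   full curve is wanted.
#' @param p1,p2 Distinct parameter names spanning the plane.
#' @param seed_hopf A `wc_hopf_point` located in `p1` or `p2`, or a
#'   length-2 numeric `c(v1, v2)` satisfying the Hopf condition.
#' @param step Arclength step in (scaled) parameter units.
#' @param bounds List with elements `p1` and `p2`, each a length-2
#'   interval; the trace stops on leaving the box.
#' @param max_steps Maximum accepted points per direction.
#' @return A `wc_hopf_curve`: list with `points` (data.frame: `p1`, `p2`,
#'   `r_E`, `r_I`, `det`, `omega`, `frequency`, `l1`), `bt_points`,
#'   `gh_points` (data.frames), `oscillating_side` (`+1`/`-1`: sign of the
#'   Jacobian trace on the oscillatory side — positive trace side
#'   oscillates), and `probe` (the two probe verdicts).
#' @export
trace_hopf_curve <- function(params, p1, p2, seed_hopf, step = 0.05,
                             bounds = NULL, max_steps = 400L) {
  .check_pname(p1); .check_pname(p2)
  if (identical(p1, p2)) stop("p1 and p2 must be distinct")
  params$biological_mode <- FALSE   # curves close through negative values
  sys <- .hopf_sys(params, p1, p2)

  if (inherits(seed_hopf, "wc_hopf_point")) {
    pv <- c(if (seed_hopf$pname == p1) seed_hopf$value else params[[p1]],
            if (seed_hopf$pname == p2) seed_hopf$value else params[[p2]])
    z0 <- c(as.numeric(seed_hopf$equilibrium$state), pv)
  } else {
    pv <- as.numeric(seed_hopf)
    p_seed <- set_param(set_param(params, p1, pv[1]), p2, pv[2])
    eq <- .reference_equilibrium(p_seed)
    z0 <- c(as.numeric(eq$state), pv)
  }
  if (any(abs(sys$fn(z0)) > c(1e-6, 1e-6, 1e-4))) {
    # polish the seed onto the curve (free the second parameter)
    tang <- .plc_tangent(sys$fn, z0)
    z0 <- .plc_correct(sys$fn, z0, tang)
    if (is.null(z0)) stop("seed point does not satisfy the Hopf condition")
  }
  if (is.null(bounds)) {
    bounds <- list(c(z0[3] - 10, z0[3] + 10), c(z0[4] - 10, z0[4] + 10))
  } else {
    bounds <- list(bounds[[1]], bounds[[2]])
  }
  in_box <- function(z) z[3] >= bounds[[1]][1] && z[3] <= bounds[[1]][2] &&
                        z[4] >= bounds[[2]][1] && z[4] <= bounds[[2]][2]

  run_dir <- function(dir) {
    pts <- list()
    z <- z0
    tang <- .plc_tangent(sys$fn, z) * dir
    h <- step
    fails <- 0L
    while (length(pts) < max_steps) {
      z_new <- .plc_correct(sys$fn, z + h * tang, tang)
      if (is.null(z_new)) {
        h <- h / 2; fails <- fails + 1L
        if (fails > 8L) break
        next
      }
      fails <- 0L
      h <- min(step, h * 2)
      t_new <- .plc_tangent(sys$fn, z_new)
      if (sum(t_new * tang) < 0) t_new <- -t_new
      tang <- t_new
      z <- z_new
      if (!in_box(z)) break
      pts[[length(pts) + 1L]] <- z
    }
    pts
  }
  fwd <- run_dir(+1)
  bwd <- run_dir(-1)
  zs <- c(rev(bwd), list(z0), fwd)
  d <- lapply(zs, sys$diag)
  pts <- data.frame(
    p1 = vapply(zs, `[`, numeric(1), 3L),
    p2 = vapply(zs, `[`, numeric(1), 4L),
    r_E = vapply(zs, `[`, numeric(1), 1L),
    r_I = vapply(zs, `[`, numeric(1), 2L),
    det = vapply(d, `[[`, numeric(1), "det"),
    l1 = vapply(d, `[[`, numeric(1), "l1"))
  pts$omega <- ifelse(pts$det > 0, sqrt(pmax(pts$det, 0)), NA_real_)
  pts$frequency <- pts$omega / (2 * pi)
  names(pts)[1:2] <- c(p1, p2)

  bt <- .find_bt(sys, zs, pts)
  gh <- .find_gh(zs, pts)
  probe <- .curve_polarity(params, p1, p2, sys, zs, step)

  structure(list(p1 = p1, p2 = p2, points = pts,
                 bt_points = bt, gh_points = gh,
                 oscillating_side = probe$side, probe = probe,
                 step = step, bounds = bounds),
            class = "wc_hopf_curve")
}

# refine BT points: det crosses zero between consecutive curve points;
# solve {field = 0, trace = 0, det = 0} (4 eq, 4 unknowns) by Newton.
.find_bt <- function(sys, zs, pts) {
  out <- data.frame()
  if (nrow(pts) < 2L) return(out)
  det_ <- pts$det
  for (k in which(det_[-1] * det_[-length(det_)] < 0)) {
    fn4 <- function(z) c(sys$fn(z), sys$diag(z)$det)
    z <- (zs[[k]] + zs[[k + 1L]]) / 2
    ok <- FALSE
    for (it in 1:30) {
      r <- fn4(z)
      if (all(abs(r) < 1e-7)) { ok <- TRUE; break }
      A <- .num_jac(fn4, z, 4L)
      dz <- tryCatch(solve(A, -r), error = function(e) NULL)
      if (is.null(dz) || any(!is.finite(dz))) break
      if (sqrt(sum(dz^2)) > 1) dz <- dz / sqrt(sum(dz^2))
      z <- z + dz
    }
    if (ok)
      out <- rbind(out, data.frame(p1 = z[3], p2 = z[4],
                                   r_E = z[1], r_I = z[2]))
  }
  if (nrow(out)) names(out)[1:2] <- names(pts)[1:2]
  out
}

# GH points: l1 sign change along the curve, linear interpolation.
.find_gh <- function(zs, pts) {
  out <- data.frame()
  l1 <- pts$l1
  for (k in seq_len(nrow(pts) - 1L)) {
    a <- l1[k]; b <- l1[k + 1L]
    if (is.na(a) || is.na(b) || a * b >= 0) next
    w <- a / (a - b)
    z <- (1 - w) * zs[[k]] + w * zs[[k + 1L]]
    out <- rbind(out, data.frame(p1 = z[3], p2 = z[4],
                                 r_E = z[1], r_I = z[2]))
  }
  if (nrow(out)) names(out)[1:2] <- names(pts)[1:2]
  out
}

# Which side of the curve oscillates: probe one off-curve point on each
# side of the curve midpoint with the simulation verdict.
.curve_polarity <- function(params, p1, p2, sys, zs, step) {
  k <- max(1L, length(zs) %/% 2L)
  z <- zs[[k]]
  tang <- .plc_tangent(sys$fn, z)
  nrm <- c(-tang[4], tang[3])          # normal in the parameter plane
  nn <- sqrt(sum(nrm^2))
  if (nn < 1e-10) nrm <- c(1, 0) else nrm <- nrm / nn
  delta <- 10 * step
  res <- lapply(c(+1, -1), function(s) {
    pv <- c(z[3], z[4]) + s * delta * nrm
    p <- set_param(set_param(params, p1, pv[1]), p2, pv[2])
    eq <- tryCatch(.reference_equilibrium(p, warm = z[1:2]),
                   error = function(e) NULL)
    ts <- wc_simulate(p, duration = 4)
    v <- detect_oscillation(ts)
    list(side = s, params = pv, oscillating = v$oscillating,
         trace = if (is.null(eq)) NA_real_ else eq$trace)
  })
  osc <- vapply(res, `[[`, logical(1), "oscillating")
  trs <- vapply(res, `[[`, numeric(1), "trace")
  side <- if (any(osc) && !all(osc)) sign(trs[which(osc)]) else NA_real_
  list(side = side, probes = res)
}

#' @export
print.wc_hopf_curve <- function(x, ...) {
  cat(sprintf("Hopf curve in (%s, %s): %d points\n", x$p1, x$p2,
              nrow(x$points)))
  cat(sprintf("  %s in [%.3f, %.3f], %s in [%.3f, %.3f]\n",
              x$p1, min(x$points[[1]]), max(x$points[[1]]),
              x$p2, min(x$points[[2]]), max(x$points[[2]])))
  if (nrow(x$bt_points))
    for (i in seq_len(nrow(x$bt_points)))
      cat(sprintf("  BT at (%.4f, %.4f)\n", x$bt_points[i, 1],
                  x$bt_points[i, 2]))
  if (nrow(x$gh_points))
    for (i in seq_len(nrow(x$gh_points)))
      cat(sprintf("  GH at (%.4f, %.4f)\n", x$gh_points[i, 1],
                  x$gh_points[i, 2]))
  if (!is.na(x$oscillating_side))
    cat(sprintf("  oscillatory side: trace %s 0\n",
                if (x$oscillating_side > 0) ">" else "<"))
  invisible(x)
}

#' Classify a parameter grid into oscillatory and fixed-point regions
#'
#' Labels every cell of a two-parameter grid by the planar linear
#' criterion on the continued equilibrium — oscillatory where the Jacobian
#' trace is positive with positive determinant (the side of the Hopf curve
#' the probe simulation found oscillating). Cells within one arclength
#' step of a Bogdanov-Takens or generalized-Hopf point are flagged
#' uncertain: the local bifurcation there is not a plain supercritical
#' Hopf and the linear criterion may mislabel.
#'
#' @param curve A `wc_hopf_curve`.
#' @param params Base parameters (plane values overridden per cell).
#' @param values1,values2 Grids for the two plane parameters.
#' @return List with logical matrices `oscillating` and `uncertain`
#'   (rows follow `values1`).
#' @export
classify_regions <- function(curve, params, values1, values2) {
  params$biological_mode <- FALSE
  side <- curve$oscillating_side
  if (is.na(side)) side <- +1   # trace > 0 side oscillates in this model
  osc <- unc <- matrix(FALSE, length(values1), length(values2),
                       dimnames = list(format(values1), format(values2)))
  special <- rbind(
    if (nrow(curve$bt_points)) curve$bt_points[, 1:2],
    if (nrow(curve$gh_points)) curve$gh_points[, 1:2])
  for (i in seq_along(values1)) {
    warm <- NULL
    for (j in seq_along(values2)) {
      p <- set_param(set_param(params, curve$p1, values1[i]),
                     curve$p2, values2[j])
      hc <- tryCatch(hopf_condition(p, warm = warm), error = function(e) NULL)
      if (is.null(hc)) next
      warm <- hc$equilibrium
      osc[i, j] <- (sign(hc$trace) == side) && hc$determinant > 0
      if (!is.null(special) && nrow(special)) {
        dmin <- min(sqrt((special[, 1] - values1[i])^2 +
                         (special[, 2] - values2[j])^2))
        unc[i, j] <- dmin < curve$step
      }
    }
  }
  list(oscillating = osc, uncertain = unc)
}

#' Export a Hopf curve
#'
#' Tidy CSV of the curve points plus a JSON sidecar with BT/GH points and
#' the oscillatory-side polarity.
#'
#' @param curve A `wc_hopf_curve`.
#' @param csv_path,json_path Output paths; either may be `NULL`.
#' @export
write_hopf_curve <- function(curve, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    write.csv(curve$points, csv_path, row.names = FALSE, na = "")
  if (!is.null(json_path))
    jsonlite::write_json(
      list(p1 = curve$p1, p2 = curve$p2,
           bt_points = curve$bt_points, gh_points = curve$gh_points,
           oscillating_side = curve$oscillating_side, step = curve$step),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(curve)
}
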