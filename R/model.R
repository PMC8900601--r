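#' Wilson-Cowan vector field
#'
#' Right-hand side of the two-population model
#' \deqn{\tau_E \dot r_E = -r_E + G_E(W_{EE} r_E - W_{EI} r_I + i_E)}
#' \deqn{\tau_I \dot r_I = -r_I + G_I(W_{IE} r_E - W_{II} r_I + i_I)}
#' where `G_E`, `G_I` are the shifted logistic responses of
#' [sigmoid_response()].
#'
#' @param state Numeric vector `c(r_E, r_I)` of population firing rates.
#' @param params A [wc_params()] object.
#' @return Numeric vector `c(dr_E/dt, dr_I/dt)` in rate units per second.
#' @export
wc_field <- function(state, params) {
  .check_state(state)
  cE <- params$W_EE * state[1] - params$W_EI * state[2] + params$i_E
  cI <- params$W_IE * state[1] - params$W_II * state[2] + params$i_I
  c((-state[1] + sigmoid_response(cE, params$m_E, params$theta_E)) / params$tau_E,
    (-state[2] + sigmoid_response(cI, params$m_I, params$theta_I)) / params$tau_I)
}

#' Analytic Jacobian of the Wilson-Cowan field
#'
#' @inheritParams wc_field
#' @return A 2x2 matrix; rows are the E and I equations, columns the
#'   derivatives with respect to `r_E` and `r_I`. For non-negative weights
#'   the (E, I) entry is non-positive and the (I, E) entry non-negative.
#' @export
wc_jacobian <- function(state, params) {
  .check_state(state)
  cE <- params$W_EE * state[1] - params$W_EI * state[2] + params$i_E
  cI <- params$W_IE * state[1] - params$W_II * state[2] + params$i_I
  gE <- sigmoid_slope(cE, params$m_E, params$theta_E)
  gI <- sigmoid_slope(cI, params$m_I, params$theta_I)
  matrix(c((-1 + params$W_EE * gE) / params$tau_E,
           (-params$W_EI * gE) / params$tau_E,
           (params$W_IE * gI) / params$tau_I,
           (-1 - params$W_II * gI) / params$tau_I),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("E", "I"), c("r_E", "r_I")))
}

.check_state <- function(state) {
  if (!is.numeric(state) || length(state) != 2L || any(!is.finite(state)))
    stop("state must be a finite numeric vector c(r_E, r_I)")
}

# Damped Newton on the fixed-point equations from one start.
# Returns the state, or NULL when no convergence.
.newton_eq <- function(params, r0, tol = .wc_tol$equilibrium,
                       max_iter = 200L) {
  r <- r0
  f <- wc_field(r, params)
  for (it in seq_len(max_iter)) {
    J <- wc_jacobian(r, params)
    dr <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(dr)) return(NULL)
    lambda <- 1
    repeat {
      rn <- r + lambda * dr
      fn <- wc_field(rn, params)
      if (sum(fn^2) < sum(f^2) || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    if (lambda < 1e-8 && sum(fn^2) >= sum(f^2)) return(NULL)
    r <- rn
    f <- fn
    if (sqrt(sum(f^2)) < tol) return(r)
  }
  NULL
}

#' Classify the stability of a planar Jacobian
#'
#' @param J A 2x2 Jacobian matrix.
#' @param tol Threshold on `|Re(lambda)|` below which the point is declared
#'   non-hyperbolic rather than guessed stable/unstable.
#' @return One of `"stable-node"`, `"stable-focus"`, `"unstable-node"`,
#'   `"unstable-focus"`, `"saddle"`, `"non-hyperbolic"`.
#' @export
classify_stability <- function(J, tol = .wc_tol$hyperbolic) {
  ev <- eigen(J, only.values = TRUE)$values
  re <- Re(ev)
  if (max(abs(re)) < tol) return("non-hyperbolic")
  complex_pair <- is.complex(ev) && any(abs(Im(ev)) > tol)
  if (all(re < 0)) return(if (complex_pair) "stable-focus" else "stable-node")
  if (all(re > 0)) return(if (complex_pair) "unstable-focus" else "unstable-node")
  "saddle"
}

# Build the Equilibrium record for a solved state.
.make_equilibrium <- function(state, params) {
  J <- wc_jacobian(state, params)
  ev <- eigen(J, only.values = TRUE)$values
  structure(list(state = setNames(state, c("r_E", "r_I")),
                 jacobian = J,
                 trace = sum(diag(J)),
                 determinant = J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1],
                 eigenvalues = ev,
                 stability = classify_stability(J),
                 residual = sqrt(sum(wc_field(state, params)^2))),
            class = "wc_equilibrium")
}

#' @export
print.wc_equilibrium <- function(x, ...) {
  cat(sprintf("Wilson-Cowan equilibrium (r_E = %.6f, r_I = %.6f)\n",
              x$state[1], x$state[2]))
  cat(sprintf("  trace = %.4f, det = %.4f, stability: %s\n",
              x$trace, x$determinant, x$stability))
  cat("  eigenvalues:", paste(format(x$eigenvalues, digits = 6),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Find the equilibria of the model
#'
#' Multi-start damped Newton iteration on the planar fixed-point equations.
#' Starting points are `(0, 0)`, `(0.5, 0.5)`, and `n_starts` seeded uniform
#' draws from the square `[-0.1, 1.1]^2` (firing rates live near `[0, 1]`).
#' Solutions closer than `1e-6` are merged. The result is deterministic
#' given `seed`.
#'
#' @param params A [wc_params()] object.
#' @param n_starts Number of random starting points (>= 1).
#' @param seed Integer seed for the start draws.
#' @return A list of `wc_equilibrium` objects, ordered by `r_E`. An empty
#'   list (with a warning) when no start converges.
#' @examples
#' eq <- find_equilibria(wc_params())
#' length(eq)        # 1 at the defaults
#' eq[[1]]$stability # "unstable-focus": inside the oscillation region
#' @export
find_equilibria <- function(params, n_starts = 40L, seed = 1L) {
  validate_params(params)
  if (n_starts < 1L) stop("n_starts must be >= 1")
  starts <- rbind(c(0, 0), c(0.5, 0.5),
                  matrix(withr_seed_runif(2L * n_starts, -0.1, 1.1, seed),
                         ncol = 2))
  sols <- list()
  for (i in seq_len(nrow(starts))) {
    r <- .newton_eq(params, starts[i, ])
    if (is.null(r)) next
    dup <- any(vapply(sols, function(s) sqrt(sum((s - r)^2)) < .wc_tol$dedup,
                      logical(1)))
    if (!dup) sols[[length(sols) + 1L]] <- r
  }
  if (!length(sols)) {
    warning("no equilibrium found from any starting point")
    return(list())
  }
  sols <- sols[order(vapply(sols, `[`, numeric(1), 1L))]
  lapply(sols, .make_equilibrium, params = params)
}

# Seeded uniform draws that do not disturb the caller's RNG state.
withr_seed_runif <- function(n, lo, hi, seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  runif(n, lo, hi)
}

# Continue the reference equilibrium: warm-start Newton from `warm`
# (or cold-start near (0.5, 0.5) then fall back to multi-start).
# Returns a wc_equilibrium or errors when nothing converges.
.reference_equilibrium <- function(params, warm = NULL) {
  if (!is.null(warm)) {
    st <- if (inherits(warm, "wc_equilibrium")) warm$state else warm
    r <- .newton_eq(params, as.numeric(st))
    if (!is.null(r)) return(.make_equilibrium(r, params))
  }
  r <- .newton_eq(params, c(0.5, 0.5))
  if (!is.null(r)) return(.make_equilibrium(r, params))
  eqs <- find_equilibria(params)
  if (!length(eqs)) stop("no equilibrium found for these parameters")
  # nearest to (0.5, 0.5): the explicit cold-start tie-break rule
  d <- vapply(eqs, function(e) sum((e$state - 0.5)^2), numeric(1))
  eqs[[which.min(d)]]
}
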