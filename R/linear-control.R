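# Linear-control view of the model: each population linearized about the
# operating point is a first-order low-pass block K/(tau s + 1); closing a
# population's self-feedback loop rescales its gain and time constant.

#' First-order transfer function
#'
#' The pair `(K, tau)` representing `phi(s) = K / (tau s + 1)`, the
#' linearized single-population block.
#'
#' @param K Equivalent gain (dimensionless).
#' @param tau Equivalent time constant, seconds; must be positive.
#' @return A `wc_tf` object.
#' @export
first_order_tf <- function(K, tau) {
  if (!is.finite(K)) stop("gain K must be finite")
  if (!is.finite(tau) || tau <= 0)
    stop("time constant tau must be positive for a physical population")
  structure(list(K = K, tau = tau), class = "wc_tf")
}

#' @export
print.wc_tf <- function(x, ...) {
  cat(sprintf("first-order block: K = %.6g, tau = %.6g s  [%.6g/(%.6gs+1)]\n",
              x$K, x$tau, x$K, x$tau))
  invisible(x)
}

#' Linearized population gains at an operating point
#'
#' First-order Taylor expansion of the sigmoid responses about the
#' operating point: `K_E` and `K_I` are the sigmoid slopes at the net
#' excitatory and inhibitory inputs. The natural operating point is the
#' model's equilibrium (the expansion is about the fixed point); supply
#' `operating_point` to expand elsewhere.
#'
#' @param params A [wc_params()] object.
#' @param operating_point State `c(r_E, r_I)`; defaults to the continued
#'   equilibrium.
#' @return Named vector `c(K_E, K_I)`.
#' @export
linear_gains <- function(params, operating_point = NULL) {
  if (is.null(operating_point))
    operating_point <- .reference_equilibrium(params)$state
  st <- as.numeric(operating_point)
  .check_state(st)
  cE <- params$W_EE * st[1] - params$W_EI * st[2] + params$i_E
  cI <- params$W_IE * st[1] - params$W_II * st[2] + params$i_I
  c(K_E = sigmoid_slope(cE, params$m_E, params$theta_E),
    K_I = sigmoid_slope(cI, params$m_I, params$theta_I))
}

#' Closed-loop transform of the inhibitory population
#'
#' Closing the inhibitory self-feedback loop of strength `W_II` around the
#' open-loop block `K/(tau s + 1)` gives another first-order block with
#' \deqn{K' = K / (1 + W_{II} K), \quad \tau' = \tau / (1 + W_{II} K).}
#' For any positive gain and feedback strength both the equivalent gain
#' and the equivalent time constant shrink — the mechanism by which
#' inhibitory self-feedback opposes oscillation onset and raises the
#' oscillation frequency.
#'
#' @param tf A [first_order_tf()].
#' @param W_II Inhibitory self-feedback strength.
#' @return The closed-loop `wc_tf`.
#' @export
closed_loop_inhibitory <- function(tf, W_II) {
  stopifnot(inherits(tf, "wc_tf"))
  d <- 1 + W_II * tf$K
  if (d <= 0)
    stop("singular feedback: 1 + W_II * K must be positive")
  first_order_tf(tf$K / d, tf$tau / d)
}

#' Closed-loop transform of the excitatory population
#'
#' Closing the excitatory self-feedback loop of strength `W_EE` gives
#' \deqn{K' = K / (1 - W_{EE} K), \quad \tau' = \tau / (1 - W_{EE} K),}
#' valid while `1 - W_EE * K > 0`. In that region both the equivalent
#' gain and time constant grow — excitatory self-feedback promotes
#' oscillation and lowers its frequency. At `W_EE * K >= 1` the linearized
#' loop is unstable and the first-order reduction stops being meaningful;
#' this is reported as an error rather than interpreted.
#'
#' @param tf A [first_order_tf()].
#' @param W_EE Excitatory self-feedback strength.
#' @return The closed-loop `wc_tf`.
#' @export
closed_loop_excitatory <- function(tf, W_EE) {
  stopifnot(inherits(tf, "wc_tf"))
  d <- 1 - W_EE * tf$K
  if (d <= 0)
    stop("linearized excitatory loop unstable: requires 1 - W_EE * K > 0 ",
         "(the increased-gain/time-constant conclusion holds only below ",
         "this threshold)")
  first_order_tf(tf$K / d, tf$tau / d)
}

#' Hopf frequency predicted by the linearization
#'
#' At a Hopf point of a planar system the emergent angular frequency is
#' the square root of the Jacobian determinant; `sqrt(det J)/(2 pi)`
#' evaluated at the continued equilibrium predicts the oscillation
#' frequency near onset.
#'
#' @param params A [wc_params()] object.
#' @param warm Optional warm start for the equilibrium continuation.
#' @return Predicted frequency in Hz.
#' @export
predicted_hopf_frequency <- function(params, warm = NULL) {
  hc <- hopf_condition(params, warm = warm)
  if (hc$determinant <= 0)
    stop("no oscillatory linearization: Jacobian determinant is not positive")
  sqrt(hc$determinant) / (2 * pi)
}

#' Full linearization report
#'
#' Computes, at the operating point (default: the equilibrium), the
#' linearized gains, the open-loop first-order blocks of both
#' populations, their closed-loop transforms under the self-feedback
#' strengths in `params`, and the linear Hopf-frequency prediction.
#' The excitatory closed loop is `NULL` (with a note) when
#' `1 - W_EE * K_E <= 0`, i.e. when the first-order reduction of that
#' loop is outside its validity region.
#'
#' @param params A [wc_params()] object.
#' @param operating_point Optional state `c(r_E, r_I)`.
#' @return A `wc_linearization` with fields `operating_point`, `K_E`,
#'   `K_I`, `open_loop` (list `E`, `I` of `wc_tf`), `closed_loop` (same
#'   shape; `E` may be `NULL`), `notes`, `predicted_hopf_frequency` (Hz or
#'   `NA` when the determinant is not positive).
#' @export
linearization_report <- function(params, operating_point = NULL) {
  if (is.null(operating_point))
    operating_point <- .reference_equilibrium(params)$state
  gains <- linear_gains(params, operating_point)
  open_E <- first_order_tf(gains[["K_E"]], params$tau_E)
  open_I <- first_order_tf(gains[["K_I"]], params$tau_I)
  notes <- character(0)
  closed_I <- closed_loop_inhibitory(open_I, params$W_II)
  closed_E <- tryCatch(closed_loop_excitatory(open_E, params$W_EE),
                       error = function(e) {
                         notes <<- c(notes, conditionMessage(e))
                         NULL
                       })
  pf <- tryCatch(predicted_hopf_frequency(params, warm = operating_point),
                 error = function(e) NA_real_)
  structure(list(operating_point = setNames(as.numeric(operating_point),
                                            c("r_E", "r_I")),
                 K_E = gains[["K_E"]], K_I = gains[["K_I"]],
                 open_loop = list(E = open_E, I = open_I),
                 closed_loop = list(E = closed_E, I = closed_I),
                 predicted_hopf_frequency = pf,
                 notes = notes),
            class = "wc_linearization")
}

#' @export
print.wc_linearization <- function(x, ...) {
  cat("Linearization about operating point ",
      sprintf("(r_E = %.5f, r_I = %.5f)\n", x$operating_point[1],
              x$operating_point[2]))
  fmt <- function(tf) if (is.null(tf)) "outside validity region"
                      else sprintf("K = %.5g, tau = %.5g s", tf$K, tf$tau)
  cat(sprintf("  E population: open  %s\n", fmt(x$open_loop$E)))
  cat(sprintf("                closed %s\n", fmt(x$closed_loop$E)))
  cat(sprintf("  I population: open  %s\n", fmt(x$open_loop$I)))
  cat(sprintf("                closed %s\n", fmt(x$closed_loop$I)))
  if (!is.na(x$predicted_hopf_frequency))
    cat(sprintf("  linear Hopf-frequency prediction: %.2f Hz\n",
                x$predicted_hopf_frequency))
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' @rdname linearization_report
#' @param report A `wc_linearization`.
#' @param path Output JSON path.
#' @export
write_linearization <- function(report, path) {
  tf_list <- function(tf) if (is.null(tf)) NULL else list(K = tf$K, tau = tf$tau)
  jsonlite::write_json(
    list(operating_point = as.list(report$operating_point),
         K_E = report$K_E, K_I = report$K_I,
         open_loop = lapply(report$open_loop, tf_list),
         closed_loop = lapply(report$closed_loop, tf_list),
         predicted_hopf_frequency = report$predicted_hopf_frequency,
         notes = report$notes),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
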