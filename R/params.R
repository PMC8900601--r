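#' Wilson-Cowan model parameters
#'
#' Constructs the parameter set of the two-population Wilson-Cowan model
#' with excitatory and inhibitory self-feedback loops. The defaults are the
#' standard gamma-oscillation operating point of the model: external inputs
#' `i_E = 2`, `i_I = 7`, inter-population couplings `W_IE = 20` (E to I) and
#' `W_EI = 26` (I to E), self-feedback strengths `W_EE = 16` and `W_II = 1`,
#' synaptic time constants `tau_E = 0.020` s and `tau_I = 0.010` s, and
#' sigmoid shape `m_E = m_I = 1`, `theta_E = 5`, `theta_I = 20`.
#'
#' Time constants are held in seconds (not milliseconds) so that simulated
#' time is in seconds and spectral output is directly in Hz.
#'
#' @param tau_E,tau_I Synaptic time constants of the excitatory and
#'   inhibitory populations, in seconds. Must be positive.
#' @param W_EE,W_II Excitatory and inhibitory self-feedback strengths
#'   (dimensionless).
#' @param W_EI Strength of the inhibitory-to-excitatory coupling.
#' @param W_IE Strength of the excitatory-to-inhibitory coupling.
#' @param i_E,i_I External inputs to the excitatory and inhibitory
#'   populations.
#' @param m_E,m_I Sigmoid slopes; must be positive.
#' @param theta_E,theta_I Sigmoid thresholds.
#' @param biological_mode Logical; when `TRUE` (default) all weights and
#'   inputs must be non-negative. Negative values are mathematically valid
#'   (and needed to close some bifurcation curves) but have no biological
#'   meaning; set this to `FALSE` to allow them.
#' @return An object of class `wc_params`: a named list of the above fields.
#' @examples
#' p <- wc_params()
#' p$W_II <- 2
#' p <- wc_params(W_II = 2)  # equivalent, with validation
#' @export
wc_params <- function(tau_E = 0.020, tau_I = 0.010,
                      W_EE = 16, W_II = 1, W_EI = 26, W_IE = 20,
                      i_E = 2, i_I = 7,
                      m_E = 1, m_I = 1, theta_E = 5, theta_I = 20,
                      biological_mode = TRUE) {
  p <- list(tau_E = tau_E, tau_I = tau_I,
            W_EE = W_EE, W_II = W_II, W_EI = W_EI, W_IE = W_IE,
            i_E = i_E, i_I = i_I,
            m_E = m_E, m_I = m_I, theta_E = theta_E, theta_I = theta_I,
            biological_mode = isTRUE(biological_mode))
  class(p) <- "wc_params"
  validate_params(p)
  p
}

#' @rdname wc_params
#' @param p A `wc_params` object to validate.
#' @export
validate_params <- function(p) {
  num <- .wc_param_names()
  for (nm in num) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number")
  }
  if (p$tau_E <= 0 || p$tau_I <= 0)
    stop("time constants tau_E and tau_I must be positive")
  if (p$m_E <= 0 || p$m_I <= 0)
    stop("sigmoid slopes m_E and m_I must be positive")
  if (isTRUE(p$biological_mode)) {
    signed <- c("W_EE", "W_II", "W_EI", "W_IE", "i_E", "i_I")
    bad <- signed[vapply(signed, function(nm) p[[nm]] < 0, logical(1))]
    if (length(bad))
      stop("negative values for ", paste(bad, collapse = ", "),
           " require biological_mode = FALSE (they are a mathematical ",
           "description only, with no biological significance)")
  }
  invisible(p)
}

.wc_param_names <- function() {
  c("tau_E", "tau_I", "W_EE", "W_II", "W_EI", "W_IE",
    "i_E", "i_I", "m_E", "m_I", "theta_E", "theta_I")
}

# Names that make sense as one-parameter bifurcation / sweep axes.
.wc_sweepable <- function() {
  c("W_EE", "W_II", "W_EI", "W_IE", "i_E", "i_I")
}

.check_pname <- function(pname) {
  ok <- .wc_sweepable()
  if (!is.character(pname) || length(pname) != 1L || !(pname %in% ok))
    stop("unknown sweep parameter '", paste(pname, collapse = ","),
         "'; valid names: ", paste(ok, collapse = ", "))
  pname
}

# Set one parameter, re-validating (biological_mode respected).
set_param <- function(p, pname, value) {
  p[[.check_pname(pname)]] <- value
  validate_params(p)
  p
}

# Packed numeric vector in the order the C++ integrator expects.
.pack_params <- function(p) {
  unlist(p[.wc_param_names()], use.names = FALSE)
}

#' @export
print.wc_params <- function(x, ...) {
  cat("Wilson-Cowan model parameters\n")
  cat(sprintf("  tau_E = %g s, tau_I = %g s\n", x$tau_E, x$tau_I))
  cat(sprintf("  W_EE = %g, W_II = %g, W_EI = %g, W_IE = %g\n",
              x$W_EE, x$W_II, x$W_EI, x$W_IE))
  cat(sprintf("  i_E = %g, i_I = %g\n", x$i_E, x$i_I))
  cat(sprintf("  sigmoid: m_E = %g, m_I = %g, theta_E = %g, theta_I = %g\n",
              x$m_E, x$m_I, x$theta_E, x$theta_I))
  cat(sprintf("  biological_mode: %s\n", x$biological_mode))
  invisible(x)
}

#' Read or write a parameter set as a flat JSON config
#'
#' The config is a flat `key: value` JSON object whose keys are the model
#' symbols (`tau_E` in seconds, `tau_I` in seconds, `W_EE`, `W_II`, `W_EI`,
#' `W_IE`, `i_E`, `i_I`, `m_E`, `m_I`, `theta_E`, `theta_I`, and optionally
#' `biological_mode`). Keys absent from the file keep their defaults.
#'
#' @param path File path.
#' @param p A `wc_params` object.
#' @return `read_params` returns a `wc_params`; `write_params` returns
#'   `path` invisibly.
#' @export
read_params <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  params_from_list(raw)
}

#' @rdname read_params
#' @export
write_params <- function(p, path) {
  validate_params(p)
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname read_params
#' @param x A named list of parameter overrides.
#' @export
params_from_list <- function(x) {
  known <- c(.wc_param_names(), "biological_mode")
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop("unknown parameter key(s): ", paste(bad, collapse = ", "),
         "; valid keys: ", paste(known, collapse = ", "))
  do.call(wc_params, x[intersect(names(x), known)])
}
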