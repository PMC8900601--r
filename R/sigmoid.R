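#' Sigmoid response function of the Wilson-Cowan populations
#'
#' The population response function
#' \deqn{G(x) = \frac{1}{1 + e^{-m(x-\theta)}} - \frac{1}{1 + e^{m\theta}}}
#' a logistic curve shifted so that `G(0) = 0`: a population with zero net
#' input is silent. Because of the shift, `G` is slightly negative for
#' negative inputs, with infimum `-1/(1 + exp(m*theta))`, and saturates at
#' `1 - 1/(1 + exp(m*theta))` for large inputs.
#'
#' @param x Net input (activation); any finite numeric vector.
#' @param m Sigmoid slope, must be positive.
#' @param theta Sigmoid threshold.
#' @return `sigmoid_response`: the firing-rate response, same shape as `x`.
#' @examples
#' sigmoid_response(0, 1, 5)        # exactly 0
#' sigmoid_slope(5, 1, 5)           # maximum slope m/4 = 0.25
#' @export
sigmoid_response <- function(x, m, theta) {
  .check_sigmoid_pars(m)
  1 / (1 + exp(-m * (x - theta))) - 1 / (1 + exp(m * theta))
}

#' @rdname sigmoid_response
#' @return `sigmoid_slope`: the derivative dG/dx, strictly positive with
#'   maximum `m/4` at `x = theta`.
#' @export
sigmoid_slope <- function(x, m, theta) {
  .check_sigmoid_pars(m)
  # symmetric form: s(1-s) = q/(1+q)^2 with q = exp(-|m (x - theta)|);
  # avoids the saturated side rounding 1 - s to zero
  q <- exp(-abs(m * (x - theta)))
  m * q / (1 + q)^2
}

.check_sigmoid_pars <- function(m) {
  if (any(!is.finite(m)) || any(m <= 0))
    stop("sigmoid slope m must be positive and finite")
}

# Higher derivatives of G, needed for the first Lyapunov coefficient.
# With s = logistic(m (x - theta)):
#   G''  = m^2 s (1 - s) (1 - 2 s)
#   G''' = m^3 s (1 - s) (1 - 6 s + 6 s^2)
.sigmoid_d2 <- function(x, m, theta) {
  s <- 1 / (1 + exp(-m * (x - theta)))
  m^2 * s * (1 - s) * (1 - 2 * s)
}

.sigmoid_d3 <- function(x, m, theta) {
  s <- 1 / (1 + exp(-m * (x - theta)))
  m^3 * s * (1 - s) * (1 - 6 * s + 6 * s^2)
}
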