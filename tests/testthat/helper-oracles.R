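# Shared oracles and frozen reference values.
#
# Frozen constants were computed with independent tools (30-digit
# arbitrary-precision arithmetic for the sigmoid values; a nested
# Brent-bisection solver, independent of the package's Newton path, for
# the equilibrium coordinates) and are asserted at tight tolerances.

# G(2, 1, 5) = 1/(1+e^3) - 1/(1+e^5), arbitrary-precision
G_2_1_5 <- 0.040733022253281925
# G(7, 1, 20), arbitrary-precision
G_7_1_20 <- 2.2582631442853843e-06
# G(3, 2, 1), arbitrary-precision
G_3_2_1 <- 0.86281086801579089

# Equilibrium coordinates at the Table-of-defaults parameter set and at
# W_II = 3, from the independent nested-bisection solver.
EQ_DEFAULTS <- c(0.6040453802191493, 0.23901191107790923)
EQ_WII3     <- c(0.6335317384793648, 0.2523141829709837)

# central finite difference of a scalar/vector function
num_deriv <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)

# upward-zero-crossing cycle-count frequency oracle for a time series
zero_crossing_freq <- function(ts, settle_fraction = 0.5) {
  n <- length(ts$t)
  idx <- (floor(n * settle_fraction) + 1L):n
  x <- ts$r_E[idx]
  xc <- x - mean(x)
  up <- sum(xc[-length(xc)] < 0 & xc[-1] >= 0)
  up / (length(x) * ts$dt)
}

# random parameter draw around the default operating point
random_params <- function() {
  wc_params(W_II = runif(1, 0.2, 3.5),
            W_EE = runif(1, 12, 20),
            i_I = runif(1, 5, 9),
            i_E = runif(1, 1, 3))
}

last_state <- function(ts) c(ts$r_E[length(ts$r_E)], ts$r_I[length(ts$r_I)])

# Prescribed upward sweep for the upper oscillation boundary: W_EE from
# 20 to 45 in steps of 0.25, 4 s at dt = 1 ms per step, state carried
# over, zero initial condition at the first step.
upward_cycle_loss_W_EE <- function() {
  continue_branch(wc_params(), "W_EE", c(20, 45), step = 0.25,
                  envelope = TRUE)$cycle_loss_up
}
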