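# Model core: sigmoid response, vector field, Jacobian, equilibria.

test_that("sigmoid response matches its closed form and limits", {
  # G(0) = 0 exactly, for random shape parameters
  set.seed(42)
  for (i in 1:25) {
    m <- runif(1, 0.1, 5); th <- runif(1, -10, 30)
    expect_identical(sigmoid_response(0, m, th), 0)
  }
  # frozen arbitrary-precision values
  expect_equal(sigmoid_response(2, 1, 5), G_2_1_5, tolerance = 1e-14)
  expect_equal(sigmoid_response(3, 2, 1), G_3_2_1, tolerance = 1e-14)
  # saturation limit and range; no overflow out to +/- 700
  expect_equal(sigmoid_response(700, 1, 5), 1 - 1 / (1 + exp(5)),
               tolerance = 1e-12)
  expect_equal(sigmoid_response(-700, 1, 5), -1 / (1 + exp(5)),
               tolerance = 1e-12)
  x <- seq(-700, 700, length.out = 401)
  y <- sigmoid_response(x, 2, 10)
  expect_true(all(is.finite(y)))
  expect_true(all(diff(y) >= 0))                       # strictly increasing
  expect_true(all(y > -1 / (1 + exp(20)) - 1e-15))
  expect_true(all(y < 1 - 1 / (1 + exp(20)) + 1e-15))
  expect_error(sigmoid_response(1, -1, 5), "positive")
})

test_that("sigmoid slope is the derivative of the response", {
  expect_equal(sigmoid_slope(5, 1, 5), 0.25)           # m/4 at threshold
  expect_equal(sigmoid_slope(-2, 3, -2), 0.75)
  set.seed(7)
  for (i in 1:30) {
    m <- runif(1, 0.2, 4); th <- runif(1, -5, 25)
    x <- th + runif(1, -10, 10) / m     # keep the slope above underflow
    fd <- num_deriv(function(z) sigmoid_response(z, m, th), x)
    an <- sigmoid_slope(x, m, th)
    expect_lt(abs(an - fd), 1e-6 * max(abs(fd), 1e-3))
    expect_gt(an, 0)
    expect_lte(an, m / 4 + 1e-12)
  }
  expect_error(sigmoid_slope(1, 0, 5), "positive")
})

test_that("vector field matches the model equations", {
  p0 <- wc_params(W_EE = 0, W_II = 0, W_EI = 0, W_IE = 0, i_E = 0, i_I = 0)
  expect_equal(wc_field(c(0, 0), p0), c(0, 0))
  # frozen high-precision value at the defaults, zero state
  f <- wc_field(c(0, 0), wc_params())
  expect_equal(f, c(G_2_1_5 / 0.020, G_7_1_20 / 0.010), tolerance = 1e-13)
  # structural decoupling when the cross-couplings vanish
  pd <- wc_params(W_EI = 0, W_IE = 0)
  set.seed(3)
  for (i in 1:10) {
    rE <- runif(1); a <- wc_field(c(rE, runif(1)), pd)
    b <- wc_field(c(rE, runif(1)), pd)
    expect_equal(a[1], b[1])                    # dr_E/dt independent of r_I
  }
})

test_that("analytic Jacobian agrees with finite differences", {
  set.seed(11)
  for (i in 1:100) {
    p <- random_params()
    st <- runif(2, -0.1, 1.1)
    J <- wc_jacobian(st, p)
    expect_lte(J[1, 2], 0)                      # I inhibits E
    expect_gte(J[2, 1], 0)                      # E excites I
    for (j in 1:2) {
      fd <- num_deriv(function(h) {
        s <- st; s[j] <- st[j] + h
        wc_field(s, p)
      }, 0)
      expect_equal(unname(J[, j]), unname(fd), tolerance = 1e-5)
    }
  }
  p <- wc_params(W_EE = 0, W_II = 0)
  J <- wc_jacobian(c(0.3, 0.4), p)
  expect_equal(unname(diag(J)), c(-1 / p$tau_E, -1 / p$tau_I))
})

test_that("equilibria are found, classified and reproducible", {
  p0 <- wc_params(W_EE = 0, W_II = 0, W_EI = 0, W_IE = 0, i_E = 0, i_I = 0)
  eq0 <- find_equilibria(p0)
  expect_length(eq0, 1L)
  expect_equal(unname(eq0[[1]]$state), c(0, 0), tolerance = 1e-9)

  # defaults: unique unstable focus, coordinates vs the independent solver
  eq <- find_equilibria(wc_params())
  expect_length(eq, 1L)
  expect_equal(unname(eq[[1]]$state), EQ_DEFAULTS, tolerance = 1e-8)
  expect_identical(eq[[1]]$stability, "unstable-focus")
  expect_lt(eq[[1]]$residual, 1e-9)
  J <- eq[[1]]$jacobian
  expect_equal(eq[[1]]$trace, sum(diag(J)))
  expect_equal(eq[[1]]$determinant, det(J))

  # W_II = 3: unique stable equilibrium (resting state)
  eq3 <- find_equilibria(wc_params(W_II = 3))
  expect_length(eq3, 1L)
  expect_equal(unname(eq3[[1]]$state), EQ_WII3, tolerance = 1e-8)
  expect_match(eq3[[1]]$stability, "^stable")

  # determinism given the seed
  a <- find_equilibria(wc_params(), n_starts = 20, seed = 9)
  b <- find_equilibria(wc_params(), n_starts = 20, seed = 9)
  expect_identical(a, b)

  # idempotency: re-solving from a found equilibrium returns it unchanged
  hc <- hopf_condition(wc_params(), warm = eq[[1]])
  expect_equal(unname(hc$equilibrium$state), unname(eq[[1]]$state),
               tolerance = 1e-9)
})

test_that("parameter validation and serialization behave", {
  expect_error(wc_params(tau_E = 0), "positive")
  expect_error(wc_params(m_I = -1), "positive")
  expect_error(wc_params(W_II = -0.5), "biological_mode")
  expect_silent(wc_params(W_II = -0.5, biological_mode = FALSE))
  expect_error(params_from_list(list(W_ZZ = 1)), "valid keys")

  p <- wc_params(W_II = 1.75, i_I = 6.5)
  path <- withr::local_tempfile(fileext = ".json")
  write_params(p, path)
  expect_equal(read_params(path), p)
  # Table-of-defaults round trip is the identity
  path2 <- withr::local_tempfile(fileext = ".json")
  write_params(default_parameters(), path2)
  expect_equal(read_params(path2), wc_params())
})
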