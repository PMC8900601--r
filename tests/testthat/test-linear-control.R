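# Closed-loop transfer-function analysis.

test_that("closed-loop formulas reduce to identity at zero feedback", {
  set.seed(5)
  for (i in 1:20) {
    tf <- first_order_tf(runif(1, 0.01, 2), runif(1, 0.001, 0.1))
    expect_equal(closed_loop_inhibitory(tf, 0), tf)
    expect_equal(closed_loop_excitatory(tf, 0), tf)
  }
})

test_that("closed-loop substitution values are exact", {
  tfI <- closed_loop_inhibitory(first_order_tf(0.5, 0.010), 2)
  expect_equal(tfI$K, 0.25)
  expect_equal(tfI$tau, 0.005)
  tfE <- closed_loop_excitatory(first_order_tf(0.02, 0.020), 16)
  expect_equal(tfE$K, 0.02 / 0.68)
  expect_equal(tfE$tau, 0.020 / 0.68)
})

test_that("feedback loops shift gain and time constant as predicted", {
  set.seed(17)
  for (i in 1:50) {
    K <- runif(1, 0.01, 1); tau <- runif(1, 0.001, 0.1)
    tf <- first_order_tf(K, tau)
    # inhibitory loop always shrinks both quantities
    W_II <- runif(1, 0.01, 10)
    cl <- closed_loop_inhibitory(tf, W_II)
    expect_lt(cl$K, K)
    expect_lt(cl$tau, tau)
    # excitatory loop grows both, inside its validity region W_EE K < 1
    W_EE <- runif(1, 0.01, 0.99) / K
    ce <- closed_loop_excitatory(tf, W_EE)
    expect_gt(ce$K, K)
    expect_gt(ce$tau, tau)
    # and the shifts are monotone in the feedback strength
    cl2 <- closed_loop_inhibitory(tf, W_II * 1.5)
    expect_lt(cl2$K, cl$K); expect_lt(cl2$tau, cl$tau)
    ce2 <- closed_loop_excitatory(tf, W_EE * 0.5)
    expect_lt(ce2$K, ce$K); expect_lt(ce2$tau, ce$tau)
  }
  expect_error(closed_loop_excitatory(first_order_tf(0.5, 0.02), 16),
               "unstable")
  expect_error(closed_loop_inhibitory(first_order_tf(-2, 0.02), 1),
               "singular")
})

test_that("linear gains delegate to the sigmoid slope and the Jacobian", {
  p <- wc_params()
  # an operating point that puts the inhibitory net input at threshold
  g_thr <- linear_gains(p, c(0.5, (20 * 0.5 + 7 - p$theta_I) / p$W_II))
  expect_equal(unname(g_thr["K_I"]), 0.25)
  set.seed(8)
  for (i in 1:100) {
    st <- runif(2, 0, 1)
    g <- linear_gains(p, st)
    cE <- p$W_EE * st[1] - p$W_EI * st[2] + p$i_E
    cI <- p$W_IE * st[1] - p$W_II * st[2] + p$i_I
    expect_identical(unname(g["K_E"]), sigmoid_slope(cE, p$m_E, p$theta_E))
    expect_identical(unname(g["K_I"]), sigmoid_slope(cI, p$m_I, p$theta_I))
  }
  # algebraic cross-check against the Jacobian at the equilibrium
  eq <- find_equilibria(p)[[1]]
  g <- linear_gains(p)
  J <- eq$jacobian
  expect_equal(unname(g["K_E"]), (J[1, 1] * p$tau_E + 1) / p$W_EE,
               tolerance = 1e-9)
  expect_equal(unname(g["K_I"]), -(J[2, 2] * p$tau_I + 1) / p$W_II,
               tolerance = 1e-9)
})

test_that("linear frequency prediction matches Hopf and simulation", {
  # exactly the HopfPoint frequency at the Hopf parameter
  hp <- locate_hopf_1d(wc_params(), "W_II", c(0.5, 4))
  p_hb <- wc_params(W_II = hp$value)
  expect_equal(predicted_hopf_frequency(p_hb), hp$frequency,
               tolerance = 1e-6)
  # on the normal-form fixture at onset: omega/(2 pi) exactly
  sys <- make_hopf_normal_form(beta = 0, omega = 2 * pi * 25, s = -1)
  J <- sys$jacobian(c(0, 0), sys$par)
  expect_equal(sqrt(det(J)) / (2 * pi), 25)
  # within 10% of simulation just inside the oscillation region
  f_sim <- dominant_frequency(wc_params(W_II = 1.9))
  f_lin <- predicted_hopf_frequency(wc_params(W_II = 1.9))
  expect_lt(abs(f_sim - f_lin) / f_lin, 0.1)
  # at the saddle that coexists with the focus near the upper fold the
  # determinant is negative: no oscillatory linearization there
  expect_error(predicted_hopf_frequency(wc_params(W_EE = 34.8),
                                        warm = c(0.8547, 0.9584)),
               "determinant")
})

test_that("the linearization report is internally consistent", {
  p <- wc_params()
  rep_ <- linearization_report(p)
  expect_equal(unname(rep_$operating_point), EQ_DEFAULTS, tolerance = 1e-7)
  # closed-loop I block satisfies the formula given the open-loop block
  expect_equal(rep_$closed_loop$I$K,
               rep_$open_loop$I$K / (1 + p$W_II * rep_$open_loop$I$K))
  # at the default equilibrium W_EE * K_E > 1: excitatory reduction is
  # outside its validity region and must be flagged, not fabricated
  expect_null(rep_$closed_loop$E)
  expect_true(length(rep_$notes) > 0)
  expect_gt(rep_$predicted_hopf_frequency, 30)
  path <- withr::local_tempfile(fileext = ".json")
  write_linearization(rep_, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$K_E, rep_$K_E)

  # a low-gain operating point keeps the excitatory block valid
  rep2 <- linearization_report(p, operating_point = c(0.05, 0.6))
  expect_false(is.null(rep2$closed_loop$E))
  expect_gt(rep2$closed_loop$E$tau, rep2$open_loop$E$tau)
})
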