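# Bifurcation engine: Hopf condition, 1-D location, branch continuation,
# first Lyapunov coefficient, two-parameter curve tracing.

test_that("hopf_condition reports trace and determinant on the branch", {
  hc <- hopf_condition(wc_params())
  expect_gt(hc$trace, 0)                      # unstable focus at defaults
  expect_gt(hc$determinant, 0)
  hc3 <- hopf_condition(wc_params(W_II = 3))
  expect_lt(hc3$trace, 0)
  # values equal the Jacobian invariants at the continued equilibrium
  J <- hc$equilibrium$jacobian
  expect_equal(hc$trace, sum(diag(J)))
  expect_equal(hc$determinant, det(J))
})

test_that("located Hopf points satisfy the planar Hopf invariants", {
  for (spec in list(list("W_II", c(0.5, 4)), list("W_EE", c(10, 20)))) {
    hp <- locate_hopf_1d(wc_params(), spec[[1]], spec[[2]])
    expect_lt(abs(hp$trace), 1e-8)
    expect_gt(hp$determinant, 0)
    expect_equal(hp$omega, sqrt(hp$determinant))
    expect_equal(hp$frequency, hp$omega / (2 * pi))
    expect_lt(hp$l1, 0)                       # supercritical on both axes
    expect_identical(hp$criticality, "supercritical")
  }
  expect_error(locate_hopf_1d(wc_params(), "W_II", c(2.5, 4)),
               "does not change sign")
})

test_that("normal-form fixture closes the self-consistency loop", {
  # location, onset frequency and l1 sign are closed-form for the fixture
  for (s in c(-1, 1)) {
    sys <- make_hopf_normal_form(beta = -0.5, omega = 2 * pi * 12, s = s)
    h <- planar_hopf_locate(sys, "beta", c(-1, 1))
    expect_lt(abs(h$value - sys$facts$hopf_at), 1e-8)
    expect_equal(h$frequency, sys$facts$onset_frequency, tolerance = 1e-10)
    expect_identical(sign(h$l1), sys$facts$l1_sign)
  }
  # trace of the fixture Jacobian is 2*beta: zero exactly at the Hopf
  sys <- make_hopf_normal_form(beta = 0.3, omega = 5, s = -1)
  J <- sys$jacobian(c(0, 0), sys$par)
  expect_equal(sum(diag(J)), 0.6)
  expect_equal(det(J), 0.3^2 + 25)
})

test_that("supercritical cycle amplitude follows the square-root law", {
  # fixture: radius sqrt(beta), via both the radial oracle and simulation
  sys <- make_hopf_normal_form(beta = 0.25, omega = 2 * pi * 10, s = -1)
  rc <- radial_cycles(sys, 0.25)
  expect_equal(rc$radius, 0.5)
  expect_true(rc$stable)
  ts <- simulate_planar(sys, c(0.1, 0), duration = 24, dt = 1e-3)
  r_end <- sqrt(ts$r_E[length(ts$r_E)]^2 + ts$r_I[length(ts$r_I)]^2)
  expect_equal(r_end, 0.5, tolerance = 1e-3)

  # model: amplitude ratio sqrt(0.1/0.4) = 0.5 just inside the W_II Hopf
  hb <- 2.019423
  amp <- vapply(c(0.4, 0.1), function(d) {
    ts <- wc_simulate(wc_params(W_II = hb - d), duration = 16)
    detect_oscillation(ts)$amplitude
  }, numeric(1))
  expect_equal(amp[2] / amp[1], 0.5, tolerance = 0.08)
})

test_that("subcritical fixture shows hysteresis bracketing the cycle fold", {
  sys <- make_hopf_normal_form(beta = 0, omega = 2 * pi * 10, s = 1,
                               saturation = TRUE)
  fold <- sys$facts$cycle_fold_at            # -1/4
  # radial oracle: two cycles (unstable inner, stable outer) inside the
  # bistable window, none below the fold
  rc <- radial_cycles(sys, -0.2)
  expect_identical(rc$stable, c(FALSE, TRUE))
  expect_length(radial_cycles(sys, -0.3)$radius, 0L)

  betas <- seq(-0.35, 0.30, by = 0.05)
  par <- sys$par
  osc_at <- function(beta, ic) {
    par["beta"] <- beta
    ts <- simulate_planar(sys, ic, duration = 10, dt = 1e-3, par = par)
    list(osc = detect_oscillation(ts)$oscillating, end = last_state(ts))
  }
  # upward sweep from rest: no cycle while beta is negative
  # a noise-floor kick keeps the carried state from underflowing to the
  # exact equilibrium during the long stable stretch
  ic <- c(1e-4, 0); up <- logical(length(betas))
  for (i in seq_along(betas)) {
    r <- osc_at(betas[i], ic); up[i] <- r$osc; ic <- r$end
    if (sqrt(sum(ic^2)) < 1e-4) ic <- c(1e-4, 0)
  }
  expect_false(any(up[betas < -0.001]))
  expect_true(up[length(up)])
  # downward sweep riding the large cycle: persists until the fold
  ic <- c(1.2, 0); down <- logical(length(betas))
  for (i in rev(seq_along(betas))) {
    r <- osc_at(betas[i], ic); down[i] <- r$osc; ic <- r$end
  }
  expect_true(all(down[betas > fold + 0.051]))
  expect_false(any(down[betas < fold - 0.051]))
})

test_that("branch continuation tracks stability and refines Hopf points", {
  bif <- continue_branch(wc_params(), "W_II", c(0.5, 3), step = 0.05,
                         envelope = TRUE)
  expect_length(bif$hopf_points, 1L)
  hb <- bif$hopf_points[[1]]$value
  # stability flips only at the detected Hopf value (within the grid)
  unstable <- grepl("^unstable", bif$stability)
  flips <- which(diff(unstable) != 0)
  expect_length(flips, 1L)
  expect_lt(abs(bif$values[flips] - hb), 2 * 0.05)
  # envelope collapses onto the branch outside the oscillation region,
  # opens inside it
  expect_true(all(bif$env_up[, 2] - bif$env_up[, 1] >= 0))
  inside <- bif$values < hb - 0.1
  outside <- bif$values > hb + 0.1
  expect_true(all((bif$env_up[, 2] - bif$env_up[, 1])[inside] > 0.01))
  expect_true(all((bif$env_up[, 2] - bif$env_up[, 1])[outside] < 1e-3))
  expect_true(all(bif$osc_up[bif$values < hb - 0.1]))
  expect_false(any(bif$osc_up[bif$values > hb + 0.1]))
  # no fold of equilibria on this stretch
  expect_true(is.na(bif$fold))
})

test_that("eigenvalue boundary matches brute-force onset within one step", {
  # near-boundary runs need long horizons (critical slowing down)
  onset <- function(pname, bracket, hopf) {
    vals <- seq(bracket[1], bracket[2], by = 0.01)
    osc <- vapply(vals, function(v) {
      f <- dominant_frequency(set_param(wc_params(), pname, v),
                              duration = 128, retry_duration = NULL)
      !is.na(f)
    }, logical(1))
    expect_identical(length(unique(osc)), 2L)
    flip <- which(diff(osc) != 0)
    expect_length(flip, 1L)
    mean(vals[flip + 0:1])
  }
  hb_ii <- locate_hopf_1d(wc_params(), "W_II", c(0.5, 4))$value
  expect_lt(abs(onset("W_II", c(1.99, 2.05), hb_ii) - hb_ii), 0.01)
  hb_ee <- locate_hopf_1d(wc_params(), "W_EE", c(10, 20))$value
  expect_lt(abs(onset("W_EE", c(13.53, 13.60), hb_ee) - hb_ee), 0.01)
})

test_that("Hopf curves satisfy their invariants and match the 1-D points", {
  p <- wc_params()
  hp <- locate_hopf_1d(p, "W_II", c(0.5, 4))
  cv <- trace_hopf_curve(p, "i_I", "W_II", hp, step = 0.05,
                         bounds = list(c(0, 14), c(0, 3)))
  pts <- cv$points
  expect_gt(nrow(pts), 20)
  # every stored point satisfies the Hopf condition
  for (k in seq(1, nrow(pts), length.out = 12)) {
    z <- as.numeric(pts[round(k), c("r_E", "r_I", "i_I", "W_II")])
    pz <- wc_params(i_I = z[3], W_II = z[4], biological_mode = FALSE)
    expect_lt(max(abs(wc_field(z[1:2], pz))), 1e-5)
    J <- wc_jacobian(z[1:2], pz)
    expect_lt(abs(sum(diag(J))), 1e-5)
  }
  # consecutive points are no further apart than ~2 arclength steps
  gaps <- sqrt(diff(pts$i_I)^2 + diff(pts$W_II)^2)
  expect_lt(max(gaps), 2 * cv$step + 1e-9)
  # consistency with the 1-D Hopf point at i_I = 7
  near <- which.min(abs(pts$i_I - 7))
  expect_lt(abs(pts$W_II[near] - hp$value), 0.05)
  expect_identical(cv$oscillating_side, 1)

  # the (W_II, W_EE) curve crosses W_EE = 13.57 at W_II = 1
  hp2 <- locate_hopf_1d(p, "W_EE", c(10, 20))
  cv2 <- trace_hopf_curve(p, "W_II", "W_EE", hp2, step = 0.05,
                          bounds = list(c(-2, 3.5), c(5, 45)),
                          max_steps = 2000)
  near2 <- which.min(abs(cv2$points$W_II - 1))
  expect_lt(abs(cv2$points$W_EE[near2] - 13.566), 0.05)
  # Bogdanov-Takens flagged where the determinant crosses zero
  expect_gte(nrow(cv2$bt_points), 1L)
  k_bt <- which(cv2$points$det[-1] * cv2$points$det[-nrow(cv2$points)] < 0)
  expect_gte(length(k_bt), 1L)
})

test_that("probe simulations agree with the curve's side labels", {
  p <- wc_params()
  hp <- locate_hopf_1d(p, "W_II", c(0.5, 4))
  cv <- trace_hopf_curve(p, "i_I", "W_II", hp, step = 0.05,
                         bounds = list(c(4, 10), c(0.2, 2.8)))
  set.seed(31)
  n_ok <- 0L
  for (i in 1:20) {
    ii <- runif(1, 4.5, 9.5); wii <- runif(1, 0.3, 2.7)
    pz <- wc_params(i_I = ii, W_II = wii)
    hc <- hopf_condition(pz)
    if (abs(hc$trace) < 2 || hc$determinant < 0) next  # skip boundary band
    sim_osc <- !is.na(dominant_frequency(pz, duration = 8))
    lab_osc <- (sign(hc$trace) == cv$oscillating_side)
    expect_identical(sim_osc, lab_osc)
    n_ok <- n_ok + 1L
  }
  expect_gte(n_ok, 10L)
})

test_that("region classification responds to the self-feedback strengths", {
  p <- wc_params()
  v_iI <- seq(2, 12, length.out = 9)
  v_iE <- seq(0.5, 3.5, length.out = 7)
  masks <- lapply(c(0.5, 1), function(wii) {
    pz <- wc_params(W_II = wii)
    hp <- locate_hopf_1d(pz, "i_I", c(1, 25))
    cv <- trace_hopf_curve(pz, "i_I", "i_E", hp, step = 0.05,
                           bounds = list(c(0, 14), c(0, 4)))
    classify_regions(cv, pz, v_iI, v_iE)$oscillating
  })
  # stronger inhibitory self-feedback shrinks the oscillatory region
  expect_lt(sum(masks[[2]]), sum(masks[[1]]))

  masks_ee <- lapply(c(15, 16), function(wee) {
    pz <- wc_params(W_EE = wee)
    hp <- locate_hopf_1d(pz, "i_I", c(1, 25))
    cv <- trace_hopf_curve(pz, "i_I", "i_E", hp, step = 0.05,
                           bounds = list(c(0, 14), c(0, 4)))
    classify_regions(cv, pz, v_iI, v_iE)$oscillating
  })
  # stronger excitatory self-feedback grows it
  expect_gt(sum(masks_ee[[2]]), sum(masks_ee[[1]]))

  # BT and GH flags appear on the full input-plane curve
  pz <- wc_params(W_II = 0.5)
  hp <- locate_hopf_1d(pz, "i_I", c(1, 25))
  cv_wide <- trace_hopf_curve(pz, "i_I", "i_E", hp, step = 0.1,
                              bounds = list(c(-10, 60), c(-10, 30)),
                              max_steps = 2000)
  expect_gte(nrow(cv_wide$bt_points), 1L)
  expect_gte(nrow(cv_wide$gh_points), 1L)
})
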