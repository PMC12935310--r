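ref <- reference_params()

test_that("single-step increment matches hand arithmetic at reference values", {
  # state --, x1 = 1, x2 = 0, cos-theta 1:
  # dx1 = 2.05 * (0.041 - 0.022 * (1 - 0 - 0.808) - 0.009 * 1) = 0.0569408
  d <- step_increment(1, 0, state_index("--"), 1, ref$params, dt = 2.05)
  expect_equal(d[1], 0.0569408, tolerance = 1e-10)
  # sister 2 in pulling state carries +v-:
  # dx2 = 2.05 * (-0.041 - 0.022 * (0 - 1 + 0.808) - 0) = -0.0754352
  expect_equal(d[2], 2.05 * (-0.041 - 0.022 * (-0.192)), tolerance = 1e-10)
})

test_that("sister-equal asymmetric parameters reduce exactly to the symmetric step", {
  pa <- asym_mech_params(tau = 673.7, kappa = 0.022, alpha = 0.009,
                         v_minus = -0.041, v_plus = 0.010, L = 0.808)
  for (s in 1:4) {
    for (x in list(c(0.5, -0.5), c(1.2, 0.1), c(-0.3, -0.9))) {
      expect_identical(
        step_increment(x[1], x[2], s, 0.97, pa, t = 5, dt = 2.05, c(0.3, -1.1)),
        step_increment(x[1], x[2], s, 0.97, ref$params, t = 5, dt = 2.05, c(0.3, -1.1)))
    }
  }
})

test_that("zero time rates reduce exactly to the time-invariant step", {
  ptd <- timedep_params(ref$params, rates = list(v_minus = 0, kappa = 0, tau = 0))
  for (s in 1:4) {
    expect_identical(
      step_increment(0.4, -0.2, s, 1, ptd, t = 123, dt = 2.05, c(1, 2)),
      step_increment(0.4, -0.2, s, 1, ref$params, t = 123, dt = 2.05, c(1, 2)))
  }
})

test_that("combined set-point model reduces to the plain exponential law", {
  # with set points at zero, v(t) = v0 exp(v1 t): identical to the
  # time-dependent parameterisation at every state and time
  pc <- combined_params(tau = 600, kappa = 0.02, alpha = 0.01,
                        v_minus = -0.05, v_plus = 0.012, L = 0.8,
                        v_minus_star = 0, v_plus_star = 0,
                        rates = list(v_minus = -0.002, v_plus = -0.001))
  pt <- timedep_params(mech_params(600, 0.02, 0.01, -0.05, 0.012, 0.8),
                       rates = list(v_minus = -0.002, v_plus = -0.001))
  for (s in 1:4) {
    expect_equal(
      step_increment(0.6, -0.3, s, 1, pc, t = 200, dt = 2.05, c(1, -1)),
      step_increment(0.6, -0.3, s, 1, pt, t = 200, dt = 2.05, c(1, -1)),
      tolerance = 1e-14)
  }
  # nonzero set point: the pulling speed relaxes toward it
  pc2 <- combined_params(tau = 600, kappa = 0.02, alpha = 0.01,
                         v_minus = -0.05, v_plus = 0.012, L = 0.8,
                         v_minus_star = -0.033,
                         rates = list(v_minus = -0.004))
  vm_late <- params_at_time(pc2, 1000, sister = 1)$v_minus
  expect_lt(abs(vm_late - -0.033), abs(-0.05 - -0.033) / 10)
})

test_that("zero-noise forceless dynamics converge to the spring fixed point", {
  p0 <- mech_params(tau = 1e6, kappa = 0.022, alpha = 0.009,
                    v_minus = 0, v_plus = 0, L = 0.808)
  tr <- simulate_pair(p0, switch_params(1, 1), T = 4000, x0 = c(2, -1),
                      noise = FALSE, states = rep(1L, 4000))
  xstar <- 0.022 * 0.808 / (0.009 + 2 * 0.022)
  expect_equal(tail(tr$x1_um, 1), xstar, tolerance = 1e-6)
  expect_equal(tail(tr$x2_um, 1), -xstar, tolerance = 1e-6)
  expect_equal(pair_fixed_point(1, p0), c(xstar, -xstar), tolerance = 1e-12)
})

test_that("reference-parameter trajectories oscillate (negative ACF lobe)", {
  depths <- sapply(1:3, function(i) {
    tr <- simulate_pair(ref$params, ref$sp, T = 300, seed = i)
    oscillation_summary(tr)$depth
  })
  expect_true(all(depths < -0.1))
})

test_that("identical seeds give bitwise-identical trajectories", {
  a <- simulate_pair(ref$params, ref$sp, T = 100, seed = 9)
  b <- simulate_pair(ref$params, ref$sp, T = 100, seed = 9)
  expect_identical(a, b)
})

test_that("non-finite initial condition is rejected", {
  expect_error(simulate_pair(ref$params, ref$sp, T = 10, x0 = c(NA, 0)),
               "finite")
})

test_that("increment moments match drift and noise scaling", {
  set.seed(5)
  n <- 1e4
  x1 <- 0.7; x2 <- -0.4; s <- 2
  dr <- pair_drift(x1, x2, s, 1, ref$params)
  dt <- 2.05
  inc <- replicate(n, step_increment(x1, x2, s, 1, ref$params, dt = dt,
                                     noise_pair = rnorm(2)))
  for (k in 1:2) {
    se_mean <- sqrt(dt / 673.7) / sqrt(n)
    expect_lt(abs(mean(inc[k, ]) - dr[k] * dt), 4 * se_mean)
    se_var <- (dt / 673.7) * sqrt(2 / (n - 1))
    expect_lt(abs(var(inc[k, ]) - dt / 673.7), 4 * se_var)
  }
})

test_that("drag scaling is the stated reparameterisation", {
  expect_equal(apply_drag_scaling(ref$params, 1), ref$params)
  p2 <- apply_drag_scaling(ref$params, 2)
  expect_equal(p2$v_minus, c(-0.0205, -0.0205))
  expect_equal(p2$kappa, 0.011)
  expect_equal(p2$alpha, 0.0045)
  expect_equal(p2$tau, c(2694.8, 2694.8))
  expect_error(apply_drag_scaling(ref$params, 0), "gamma")
})

test_that("trajectories are invariant under the drag reparameterisation", {
  p2 <- apply_drag_scaling(ref$params, 2)
  a <- simulate_pair(ref$params, ref$sp, T = 200, seed = 3, gamma = 2)
  b <- simulate_pair(p2, ref$sp, T = 200, seed = 3)
  expect_equal(a$x1_um, b$x1_um, tolerance = 1e-12)
  expect_equal(a$x2_um, b$x2_um, tolerance = 1e-12)
})

test_that("tuning closed form: fixed point, initial condition, RK4 agreement", {
  law <- tuning_law(a = 0.1, b = 0.0033)
  expect_equal(law$fixed_point, -0.033)
  expect_equal(tuning_solution(-0.033, law, c(0, 50, 1e4)), rep(-0.033, 3))
  expect_equal(tuning_solution(-0.06, law, 0), -0.06)
  for (v0 in c(-0.06, -0.02)) {
    for (tt in c(10, 100, 300)) {
      expect_equal(tuning_solution(v0, law, tt),
                   rk4_tuning(v0, 0.1, 0.0033, tt), tolerance = 1e-6)
    }
  }
  expect_error(tuning_solution(0.01, law, 1), "v0")
  expect_error(tuning_law(-0.1, 0.01), "a > 0")
})

test_that("parameter YAML serialisation round-trips", {
  p <- timedep_params(asym_mech_params(c(600, 700), 0.02, 0.01,
                                       c(-0.05, -0.03), c(0.004, 0.012), 0.8),
                      rates = list(v_minus = 0.002, tau = -0.001))
  f <- tempfile(fileext = ".yaml")
  write_params_yaml(p, f, sp = switch_params(0.95, 0.76))
  back <- read_params_yaml(f)
  expect_equal(back$params$v_minus, p$v_minus)
  expect_equal(back$params$rate$v_minus, p$rate$v_minus)
  expect_equal(back$sp$p_coh, 0.95)
  unlink(f)
})
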