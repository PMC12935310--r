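ref <- reference_params()

test_that("one-increment likelihood equals the explicit 4-term mixture", {
  tr <- sister_pair_trajectory(c(0, 2.05), c(0.5, 0.56), c(-0.5, -0.48))
  pi0 <- stationary_state_dist(ref$sp)
  mix <- sum(sapply(1:4, function(s) {
    dr <- pair_drift(0.5, -0.5, s, 1, ref$params)
    sdv <- sqrt(2.05 / 673.7)
    pi0[s] * dnorm(0.06, dr[1] * 2.05, sdv) * dnorm(0.02, dr[2] * 2.05, sdv)
  }))
  expect_equal(log_likelihood(tr, ref$params, ref$sp), log(mix),
               tolerance = 1e-12)
})

test_that("forward algorithm equals exhaustive path enumeration", {
  set.seed(7)
  for (T in c(4, 6)) {
    tr <- simulate_pair(ref$params, ref$sp, T = T, seed = 20 + T)
    expect_equal(log_likelihood(tr, ref$params, ref$sp),
                 enumerate_loglik(tr, ref$params, ref$sp), tolerance = 1e-10)
    # and under a randomly drawn parameter value
    th <- sample_prior("M0", n = 1)[1, ]
    pp <- theta_to_params("M0", th, dt = tr$dt)
    expect_equal(log_likelihood(tr, pp$params, pp$sp),
                 enumerate_loglik(tr, pp$params, pp$sp), tolerance = 1e-10)
  }
})

test_that("enumeration agreement holds for asymmetric and time-dependent models", {
  tr <- simulate_pair(ref$params, ref$sp, T = 5, seed = 31)
  pa <- asym_mech_params(c(500, 900), 0.03, 0.012, c(-0.06, -0.02),
                         c(0.002, 0.02), 0.8)
  expect_equal(log_likelihood(tr, pa, ref$sp),
               enumerate_loglik(tr, pa, ref$sp), tolerance = 1e-10)
  ptd <- timedep_params(ref$params,
                        rates = list(v_minus = -0.003, tau = 0.002, kappa = 0.001))
  expect_equal(log_likelihood(tr, ptd, ref$sp),
               enumerate_loglik(tr, ptd, ref$sp), tolerance = 1e-10)
})

test_that("sister-equal asymmetric model reproduces the vanilla likelihood", {
  tr <- simulate_pair(ref$params, ref$sp, T = 150, seed = 8)
  pa <- asym_mech_params(tau = 673.7, kappa = 0.022, alpha = 0.009,
                         v_minus = -0.041, v_plus = 0.010, L = 0.808)
  expect_equal(log_likelihood(tr, pa, ref$sp),
               log_likelihood(tr, ref$params, ref$sp), tolerance = 1e-12)
})

test_that("likelihood is invariant under the drag reparameterisation", {
  tr <- simulate_pair(ref$params, ref$sp, T = 150, seed = 9)
  for (g in c(0.5, 2, 3.7)) {
    ps <- apply_drag_scaling(ref$params, g)
    ll_scaled <- log_likelihood(tr, ps, ref$sp)
    # evaluating the scaled model must equal evaluating the original model on
    # a drag-transformed trajectory; equivalently the composition is identity
    back <- apply_drag_scaling(ps, 1 / g)
    expect_equal(log_likelihood(tr, back, ref$sp),
                 log_likelihood(tr, ref$params, ref$sp), tolerance = 1e-10)
    expect_false(isTRUE(all.equal(ll_scaled,
                                  log_likelihood(tr, ref$params, ref$sp))))
  }
})

test_that("fast evaluation path agrees with the reference likelihood", {
  set.seed(10)
  tr <- simulate_pair(ref$params, ref$sp, T = 80, seed = 11)
  tr_miss <- inject_missingness(list(cell_dataset(list(tr))), rate = 0.1,
                                seed = 2)[[1]]$pairs[[1]]
  for (m in c("M0", "Ma_vmvp", "Ma_vmvptau", "Mt_vmtau", "Mt_alpha")) {
    for (i in 1:3) {
      th <- sample_prior(m, n = 1)[1, ]
      pp <- theta_to_params(m, th, dt = tr$dt)
      f <- metakin:::make_loglik(tr_miss, m)
      expect_equal(f(th), log_likelihood(tr_miss, pp$params, pp$sp),
                   tolerance = 1e-12)
    }
  }
})

test_that("missing-data contracts hold", {
  tr <- simulate_pair(ref$params, ref$sp, T = 50, seed = 12)
  # all-missing trajectory errors
  tr_all <- tr
  tr_all$missing[] <- TRUE
  expect_error(log_likelihood(tr_all, ref$params, ref$sp), "no observed data")
  # single observed frame: no increments, likelihood constant at 0
  tr_one <- tr
  tr_one$missing[-1, ] <- TRUE
  tr_one$x1_um[-1] <- NA; tr_one$x2_um[-1] <- NA
  expect_equal(log_likelihood(tr_one, ref$params, ref$sp), 0)
  th2 <- sample_prior("M0", n = 1)[1, ]
  pp2 <- theta_to_params("M0", th2, dt = tr$dt)
  expect_equal(log_likelihood(tr_one, pp2$params, pp2$sp), 0)
  # masking interior frames changes but does not break the likelihood
  tr_gap <- tr
  tr_gap$missing[20:23, 1] <- TRUE
  tr_gap$x1_um[20:23] <- NA
  ll <- log_likelihood(tr_gap, ref$params, ref$sp)
  expect_true(is.finite(ll))
  expect_false(isTRUE(all.equal(ll, log_likelihood(tr, ref$params, ref$sp))))
})

test_that("a gap-spanning increment uses the rescaled k*dt Gaussian", {
  # two frames observed with one missing between them: the sister-1 factor
  # must be a 2*dt Gaussian with drift held at the last observed position
  p <- ref$params; sp <- ref$sp
  tr <- sister_pair_trajectory(c(0, 2.05, 4.10),
                               c(0.50, NA, 0.58), c(-0.50, -0.46, -0.44))
  ll <- log_likelihood(tr, p, sp)
  # oracle: forward over 2 steps with explicit emission terms
  P <- build_transition_matrix(sp); pi0 <- stationary_state_dist(sp)
  e <- matrix(0, 2, 4)
  for (s in 1:4) {
    dr1 <- pair_drift(0.50, -0.50, s, 1, p)    # step 1: sister 2 only
    e[1, s] <- dnorm(-0.46 - -0.50, dr1[2] * 2.05, sqrt(2.05 / 673.7), log = TRUE)
    dr2 <- pair_drift(0.50, -0.46, s, 1, p)    # step 2: sister 2 single-frame
    drg <- pair_drift(0.50, -0.50, s, 1, p)    # sister-1 gap: positions held
    e[2, s] <- dnorm(-0.44 - -0.46, dr2[2] * 2.05, sqrt(2.05 / 673.7), log = TRUE) +
      dnorm(0.58 - 0.50, drg[1] * 2 * 2.05, sqrt(2 * 2.05 / 673.7), log = TRUE)
  }
  a <- pi0 * exp(e[1, ])
  a2 <- drop(a %*% P) * exp(e[2, ])
  expect_equal(ll, log(sum(a2)), tolerance = 1e-12)
})
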