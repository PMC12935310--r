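# Shared fixtures and independent oracles used across the suite.

ref_pop_params <- function() reference_params()

# Brute-force marginal likelihood by exhaustive enumeration over all 4^(T-1)
# hidden paths (complete data only). Independent of the forward recursion.
enumerate_loglik <- function(traj, params, sp) {
  P <- build_transition_matrix(sp)
  pi0 <- stationary_state_dist(sp)
  T <- length(traj$time_s)
  dt <- traj$dt
  paths <- as.matrix(expand.grid(rep(list(1:4), T - 1)))
  lp_all <- apply(paths, 1, function(s) {
    lp <- log(pi0[s[1]])
    if (T > 2) for (t in 2:(T - 1)) lp <- lp + log(P[s[t - 1], s[t]])
    for (t in 1:(T - 1)) {
      tt <- (t - 1) * dt
      dr <- pair_drift(traj$x1_um[t], traj$x2_um[t], s[t],
                       traj$cos_theta[t], params, tt)
      tau1 <- params_at_time(params, tt, 1)$tau
      tau2 <- params_at_time(params, tt, 2)$tau
      lp <- lp +
        dnorm(traj$x1_um[t + 1] - traj$x1_um[t], dr[1] * dt, sqrt(dt / tau1), log = TRUE) +
        dnorm(traj$x2_um[t + 1] - traj$x2_um[t], dr[2] * dt, sqrt(dt / tau2), log = TRUE)
    }
    lp
  })
  m <- max(lp_all)
  m + log(sum(exp(lp_all - m)))
}

# Exact conditional path probabilities P(path | data) on a tiny trajectory,
# by enumeration.
enumerate_path_posterior <- function(traj, params, sp) {
  P <- build_transition_matrix(sp)
  pi0 <- stationary_state_dist(sp)
  T <- length(traj$time_s)
  dt <- traj$dt
  paths <- as.matrix(expand.grid(rep(list(1:4), T - 1)))
  lp_all <- apply(paths, 1, function(s) {
    lp <- log(pi0[s[1]])
    if (T > 2) for (t in 2:(T - 1)) lp <- lp + log(P[s[t - 1], s[t]])
    for (t in 1:(T - 1)) {
      dr <- pair_drift(traj$x1_um[t], traj$x2_um[t], s[t],
                       traj$cos_theta[t], params, (t - 1) * dt)
      sdv <- sqrt(dt / params$tau)
      lp <- lp +
        dnorm(traj$x1_um[t + 1] - traj$x1_um[t], dr[1] * dt, sdv[1], log = TRUE) +
        dnorm(traj$x2_um[t + 1] - traj$x2_um[t], dr[2] * dt, sdv[2], log = TRUE)
    }
    lp
  })
  w <- exp(lp_all - max(lp_all))
  list(paths = paths, prob = w / sum(w))
}

# Naive O(n * lag) mean-removed ACF with per-lag normalisation.
naive_acf <- function(x, max_lag) {
  x <- x - mean(x, na.rm = TRUE)
  n <- length(x)
  cc <- sapply(0:max_lag, function(l) {
    mean(x[1:(n - l)] * x[(1 + l):n], na.rm = TRUE)
  })
  cc / cc[1]
}

# Classical 4th-order Runge-Kutta integration of dv/dt = (a v + b) v.
rk4_tuning <- function(v0, a, b, t_end, h = 0.01) {
  f <- function(v) (a * v + b) * v
  v <- v0
  n <- ceiling(t_end / h)
  h <- t_end / n
  for (i in seq_len(n)) {
    k1 <- f(v); k2 <- f(v + h / 2 * k1); k3 <- f(v + h / 2 * k2)
    k4 <- f(v + h * k3)
    v <- v + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  v
}
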