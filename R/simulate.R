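state_speed <- function(params, state, sister, t) {
  pt <- params_at_time(params, t, sister)
  sig <- if (sister == 1) SIGMA1[state] else SIGMA2[state]
  ifelse(sig > 0, pt$v_plus, pt$v_minus)
}

#' Deterministic drift of the paired force-balance model
#'
#' Drift (um/s) on each sister at positions `(x1, x2)` in joint state
#' `state`: sister 1 carries `-v(sigma1)`, sister 2 `+v(sigma2)`, both feel
#' the centromeric spring and the linear centralising force.
#'
#' @param x1,x2 sister positions (um).
#' @param state joint state index in 1..4.
#' @param cos_theta sister axis projection factor.
#' @param params a `kt_params` object.
#' @param t time (s) used to evaluate time-dependent parameters.
#' @return numeric length-2 vector of drifts (sister 1, sister 2).
#' @export
pair_drift <- function(x1, x2, state, cos_theta, params, t = 0) {
  p1 <- params_at_time(params, t, 1)
  p2 <- params_at_time(params, t, 2)
  v1 <- if (SIGMA1[state] > 0) p1$v_plus else p1$v_minus
  v2 <- if (SIGMA2[state] > 0) p2$v_plus else p2$v_minus
  spring <- x1 - x2 - params$L * cos_theta
  c(-v1 - p1$kappa * spring - p1$alpha * x1,
    +v2 - p2$kappa * (-spring) - p2$alpha * x2)
}

#' One Euler-Maruyama step of the paired model
#'
#' Deterministic given the supplied unit-variance noise pair; the noise is
#' scaled by `sqrt(dt / tau_k(t))` per sister.
#'
#' @inheritParams pair_drift
#' @param dt step length (s), > 0.
#' @param noise_pair length-2 vector of unit-variance draws (0 for noise off).
#' @return length-2 vector of increments `(dx1, dx2)` in um.
#' @export
step_increment <- function(x1, x2, state, cos_theta, params, t = 0, dt = 2.05,
                           noise_pair = c(0, 0)) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  dr <- pair_drift(x1, x2, state, cos_theta, params, t)
  tau1 <- params_at_time(params, t, 1)$tau
  tau2 <- params_at_time(params, t, 2)$tau
  dr * dt + sqrt(dt / c(tau1, tau2)) * noise_pair
}

#' Deterministic fixed point of the drift in a given state
#'
#' Solves the 2x2 linear system of zero drift at fixed `state` and
#' `cos_theta`; with forces off and `cos_theta = 1` this is
#' `x1* = kappa L / (alpha + 2 kappa)`, `x2* = -x1*`.
#'
#' @inheritParams pair_drift
#' @return length-2 vector `(x1*, x2*)`.
#' @export
pair_fixed_point <- function(state, params, cos_theta = 1, t = 0) {
  p1 <- params_at_time(params, t, 1)
  p2 <- params_at_time(params, t, 2)
  v1 <- if (SIGMA1[state] > 0) p1$v_plus else p1$v_minus
  v2 <- if (SIGMA2[state] > 0) p2$v_plus else p2$v_minus
  Lc <- params$L * cos_theta
  A <- matrix(c(p1$kappa + p1$alpha, -p2$kappa,
                -p1$kappa, p2$kappa + p2$alpha), 2, 2, byrow = TRUE)
  b <- c(-v1 + p1$kappa * Lc, v2 - p2$kappa * Lc)
  as.numeric(solve(A, b))
}

#' Simulate a sister-pair trajectory
#'
#' Simulates the hidden directional chain and the Euler-Maruyama dynamics of
#' both sisters under any model variant, recording the ground-truth states.
#'
#' @param params a `kt_params` object.
#' @param sp a `switch_params` object.
#' @param T number of frames (>= 2).
#' @param dt frame interval (s); defaults to `sp$dt`.
#' @param cos_theta constant value or length-`T` series (default 1).
#' @param x0 initial positions; defaults to the fixed point of the initial
#'   state.
#' @param init initial state distribution (default stationary).
#' @param seed optional integer seed.
#' @param noise logical; FALSE gives the zero-noise (deterministic) limit.
#' @param states optional pre-specified state sequence of length `T`.
#' @param gamma optional drag scale applied inside the step (default 1).
#' @param cell_id,pair_id,r_um trajectory metadata.
#' @return a [sister_pair_trajectory()].
#' @export
simulate_pair <- function(params, sp, T = 300, dt = sp$dt, cos_theta = 1,
                          x0 = NULL, init = NULL, seed = NULL, noise = TRUE,
                          states = NULL, gamma = 1,
                          cell_id = "cell1", pair_id = "pair1", r_um = NA_real_) {
  if (T < 2) stop("T must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  if (length(cos_theta) == 1) cos_theta <- rep(cos_theta, T)
  stopifnot(length(cos_theta) == T)
  if (is.null(states)) states <- simulate_hidden_chain(sp, T, init = init)
  if (is.null(x0)) x0 <- pair_fixed_point(states[1], params, cos_theta[1])
  if (any(!is.finite(x0))) stop("initial condition must be finite")
  eff <- if (gamma != 1) apply_drag_scaling(params, gamma) else params
  x1 <- numeric(T); x2 <- numeric(T)
  x1[1] <- x0[1]; x2[1] <- x0[2]
  z <- if (noise) matrix(rnorm(2 * (T - 1)), ncol = 2) else matrix(0, T - 1, 2)
  tgrid <- (seq_len(T) - 1) * dt
  for (t in 1:(T - 1)) {
    d <- step_increment(x1[t], x2[t], states[t], cos_theta[t], eff,
                        t = tgrid[t], dt = dt, noise_pair = z[t, ])
    x1[t + 1] <- x1[t] + d[1]
    x2[t + 1] <- x2[t] + d[2]
  }
  sister_pair_trajectory(tgrid, x1, x2, cos_theta = cos_theta, r_um = r_um,
                         cell_id = cell_id, pair_id = pair_id,
                         hidden_states = states)
}
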