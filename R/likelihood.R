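fill_forward <- function(x) {
  ok <- is.finite(x)
  idx <- cumsum(ok)
  out <- x[ok][pmax(idx, 1)]
  out[idx == 0] <- NA_real_
  out
}

# Per-step log emission weights (T-1 x 4) for a trajectory under the model.
# Each observed increment of sister k contributes a Gaussian factor attached
# to the joint state in force over the step that completes the increment.
# An increment spanning g missing frames is rescaled to a g*dt Gaussian with
# drift evaluated at the last observed positions (first-order hold); frames
# with no completing observation contribute no factor, so the hidden chain
# propagates through the transition matrix across gaps.
build_log_emissions <- function(traj, params) {
  T <- n_frames(traj)
  dt <- traj$dt
  logE <- matrix(0, T - 1, 4)
  h1 <- fill_forward(ifelse(traj$missing[, 1], NA_real_, traj$x1_um))
  h2 <- fill_forward(ifelse(traj$missing[, 2], NA_real_, traj$x2_um))
  hc <- fill_forward(traj$cos_theta)
  t0 <- traj$time_s - traj$time_s[1]
  for (k in 1:2) {
    x <- if (k == 1) traj$x1_um else traj$x2_um
    obs <- which(!traj$missing[, k] & is.finite(x))
    if (length(obs) < 2) next
    j <- obs[-1]; s <- obs[-length(obs)]
    g <- j - s
    delta <- x[j] - x[s]
    ts <- t0[s]
    pk <- params_at_time(params, ts, k)
    spring <- h1[s] - h2[s] - params$L * hc[s]
    own <- if (k == 1) h1[s] else h2[s]
    sgn <- if (k == 1) -1 else 1
    base <- sgn * pk$kappa * spring - pk$alpha * own
    drift_plus <- sgn * pk$v_plus + base
    drift_minus <- sgn * pk$v_minus + base
    sdv <- sqrt(g * dt / pk$tau)
    e_plus <- dnorm(delta, drift_plus * g * dt, sdv, log = TRUE)
    e_minus <- dnorm(delta, drift_minus * g * dt, sdv, log = TRUE)
    sig <- if (k == 1) SIGMA1 else SIGMA2
    for (st in 1:4) {
      logE[j - 1, st] <- logE[j - 1, st] + (if (sig[st] > 0) e_plus else e_minus)
    }
  }
  logE
}

#' Marginal log-likelihood of a trajectory under a model
#'
#' Exact marginalisation over hidden directional-state paths by the forward
#' algorithm on the 4 joint states, with independent per-sister Gaussian
#' increment emissions given the state. Missing frames contribute no emission
#' factor while the chain propagates; increments spanning gaps are rescaled
#' (see the methods vignette).
#'
#' @param traj a [sister_pair_trajectory()].
#' @param params a `kt_params` object (any model variant).
#' @param sp a [switch_params()] object; `sp$dt` must match the trajectory.
#' @param init initial state distribution (default: stationary distribution
#'   of the switching chain).
#' @param pair_level use the pair-level transition-matrix variant.
#' @return log-likelihood (scalar).
#' @export
log_likelihood <- function(traj, params, sp, init = NULL, pair_level = FALSE) {
  forward_filter(traj, params, sp, init = init, pair_level = pair_level)$loglik
}

#' @rdname log_likelihood
#' @return `forward_filter` additionally returns the normalised filtered
#'   state probabilities (`alpha`, (T-1) x 4) and the transition matrix used.
#' @export
forward_filter <- function(traj, params, sp, init = NULL, pair_level = FALSE) {
  if (all(traj$missing)) stop("trajectory has no observed data")
  if (abs(sp$dt - traj$dt) > 1e-9) stop("sp$dt does not match the trajectory time grid")
  P <- build_transition_matrix(sp, pair_level = pair_level)
  if (is.null(init)) init <- stationary_state_dist(sp, pair_level = pair_level)
  logE <- build_log_emissions(traj, params)
  out <- forward_filter_cpp(logE, P, init)
  out$P <- P
  out
}
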