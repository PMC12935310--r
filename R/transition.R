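#' Transition matrix of the joint sister directional state
#'
#' Product-form construction: over one frame each sister independently keeps
#' its direction with probability `p_coh` when the pair is currently in a
#' coherent state (+-, -+) and `p_incoh` when incoherent (++, --). Rows and
#' columns follow the fixed ordering (++, +-, -+, --); rows sum to 1.
#'
#' With `pair_level = TRUE` an alternative reading is used for sensitivity
#' checks: the pair as a whole stays in its current joint state with the
#' relevant stay probability, and the complement is split between a
#' leading-sister and a trailing-sister single switch plus a joint switch via
#' the per-sister product form renormalised off the diagonal.
#'
#' @param sp a [switch_params()] object.
#' @param pair_level logical; use the pair-level stay variant (default FALSE).
#' @return 4x4 row-stochastic matrix with dimnames (++, +-, -+, --).
#' @export
build_transition_matrix <- function(sp, pair_level = FALSE) {
  stopifnot(inherits(sp, "switch_params"))
  stay <- ifelse(is_coherent(1:4), sp$p_coh, sp$p_incoh)
  keep1 <- outer(SIGMA1, SIGMA1, "==")
  keep2 <- outer(SIGMA2, SIGMA2, "==")
  P <- ifelse(keep1, stay, 1 - stay) * ifelse(keep2, stay, 1 - stay)
  dimnames(P) <- list(STATE_LABELS, STATE_LABELS)
  if (pair_level) {
    for (s in 1:4) {
      off <- P[s, -s]
      P[s, ] <- 0
      P[s, s] <- stay[s]
      if (sum(off) > 0) P[s, -s] <- (1 - stay[s]) * off / sum(off)
      else P[s, s] <- 1
    }
  }
  P
}

#' Stationary distribution of the hidden chain
#'
#' @inheritParams build_transition_matrix
#' @return probability vector of length 4 in the (++, +-, -+, --) ordering.
#' @export
stationary_state_dist <- function(sp, pair_level = FALSE) {
  if (!pair_level) {
    # detailed-balance-style closed form of the product chain:
    # pi(incoh)/pi(coh) = p_coh q_coh / (p_incoh q_incoh)
    wi <- sp$p_coh * (1 - sp$p_coh)
    wc <- sp$p_incoh * (1 - sp$p_incoh)
    if (wi + wc > 0) {
      v <- c(wi, wc, wc, wi) / (2 * (wi + wc))
      return(stats::setNames(v, STATE_LABELS))
    }
  }
  P <- build_transition_matrix(sp, pair_level)
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- abs(Re(e$vectors[, i]))
  stats::setNames(v / sum(v), STATE_LABELS)
}

#' Simulate the hidden directional-state chain
#'
#' @inheritParams build_transition_matrix
#' @param T number of frames (>= 1).
#' @param init initial distribution over the 4 states; defaults to the
#'   stationary distribution.
#' @param seed optional integer seed for reproducibility.
#' @return integer vector of length `T` with values in 1..4.
#' @export
simulate_hidden_chain <- function(sp, T, init = NULL, seed = NULL) {
  if (!is.numeric(T) || T < 1) stop("T must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init)) init <- stationary_state_dist(sp)
  if (length(init) != 4 || any(init < 0) || abs(sum(init) - 1) > 1e-8) {
    stop("init must be a probability vector over 4 states")
  }
  P <- build_transition_matrix(sp)
  s <- integer(T)
  s[1] <- sample.int(4, 1, prob = init)
  if (T > 1) {
    u <- runif(T - 1)
    cum <- t(apply(P, 1, cumsum))
    for (t in 2:T) {
      s[t] <- findInterval(u[t - 1], cum[s[t - 1], ], left.open = TRUE) + 1L
    }
  }
  s
}
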