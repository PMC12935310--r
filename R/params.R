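#' @useDynLib metakin, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats dnorm rnorm runif median quantile sd var optim plogis qlogis
NULL

# Hidden-state ordering convention, fixed globally: 1 = ++, 2 = +-, 3 = -+, 4 = --.
# "+" is a pushing (polymerising) K-fiber, "-" pulling (depolymerising).
# States 2 and 3 are coherent (sisters move in the same direction), 1 and 4 incoherent.
STATE_LABELS <- c("++", "+-", "-+", "--")
SIGMA1 <- c(+1, +1, -1, -1)
SIGMA2 <- c(+1, -1, +1, -1)
COHERENT_STATES <- c(2L, 3L)

#' Hidden-state labels
#'
#' The four joint polymerisation states of a sister pair in the fixed ordering
#' (++, +-, -+, --). Coherent states (+-, -+) move both sisters in the same
#' direction; incoherent states (++, --) compress, respectively stretch, the
#' centromeric spring.
#'
#' @param state integer vector in 1..4 or character vector of labels.
#' @return `state_label` returns labels; `state_index` returns 1-based indices.
#' @export
state_label <- function(state) {
  stopifnot(all(state %in% 1:4))
  STATE_LABELS[state]
}

#' @rdname state_label
#' @export
state_index <- function(state) {
  i <- match(state, STATE_LABELS)
  if (anyNA(i)) stop("unknown state label(s): ", paste(state[is.na(i)], collapse = ", "))
  i
}

#' Is a state coherent?
#' @param state integer state index in 1..4.
#' @return logical vector.
#' @export
is_coherent <- function(state) state %in% COHERENT_STATES

#' Directional switching probabilities
#'
#' Per-frame probabilities that a kinetochore keeps its direction, conditional
#' on the pair being in a coherent (`p_coh`) or incoherent (`p_incoh`) state.
#'
#' @param p_coh,p_incoh stay probabilities in \[0, 1\].
#' @param dt frame interval in seconds (default 2.05 s).
#' @return an object of class `switch_params`.
#' @export
switch_params <- function(p_coh, p_incoh, dt = 2.05) {
  for (p in c(p_coh, p_incoh)) {
    if (!is.finite(p) || p < 0 || p > 1) {
      stop("stay probabilities must lie in [0, 1]; got ", format(p))
    }
  }
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  structure(list(p_coh = p_coh, p_incoh = p_incoh, dt = dt),
            class = "switch_params")
}

check_sign <- function(x, name, sign) {
  if (any(!is.finite(x))) stop(name, " must be finite")
  if (sign > 0 && any(x < 0)) stop(name, " must be >= 0")
  if (sign < 0 && any(x > 0)) stop(name, " must be <= 0")
  if (sign == 2 && any(x <= 0)) stop(name, " must be > 0")
  invisible(x)
}

new_kt_params <- function(tau, kappa, alpha, v_minus, v_plus, L,
                          rate = NULL, set_point = NULL) {
  rate0 <- list(v_minus = c(0, 0), v_plus = c(0, 0), tau = c(0, 0),
                kappa = 0, alpha = 0)
  if (!is.null(rate)) {
    for (nm in names(rate)) {
      want <- length(rate0[[nm]])
      rate0[[nm]] <- rep(rate[[nm]], length.out = want)
    }
  }
  structure(list(
    tau = rep(tau, length.out = 2),
    kappa = kappa, alpha = alpha,
    v_minus = rep(v_minus, length.out = 2),
    v_plus = rep(v_plus, length.out = 2),
    L = L,
    rate = rate0,
    set_point = set_point), class = "kt_params")
}

#' Mechanical parameters of the force-balance model
#'
#' Symmetric (vanilla) parameterisation: all forces divided by drag, so
#' `kappa` and `alpha` carry units of s^-1 and `v_minus`/`v_plus` are speeds.
#'
#' @param tau noise precision (um^-2 s).
#' @param kappa centromeric spring rate (s^-1).
#' @param alpha centralising rate (s^-1).
#' @param v_minus pulling speed, <= 0 (um/s).
#' @param v_plus pushing speed, >= 0 (um/s).
#' @param L spring natural length (um).
#' @return an object of class `kt_params`.
#' @export
mech_params <- function(tau, kappa, alpha, v_minus, v_plus, L) {
  check_sign(tau, "tau", 2); check_sign(kappa, "kappa", 2)
  check_sign(alpha, "alpha", 2); check_sign(L, "L", 2)
  check_sign(v_minus, "v_minus", -1); check_sign(v_plus, "v_plus", +1)
  stopifnot(length(tau) == 1, length(v_minus) == 1, length(v_plus) == 1)
  new_kt_params(tau, kappa, alpha, v_minus, v_plus, L)
}

#' Sister-asymmetric mechanical parameters
#'
#' Per-sister K-fiber forces and noise precisions; the spring (`kappa`, `L`)
#' and centralising rate (`alpha`) are shared. Collapsing both sisters to the
#' same values reproduces [mech_params()] semantics exactly.
#'
#' @param tau,v_minus,v_plus length-1 or length-2 (per sister) values.
#' @inheritParams mech_params
#' @return an object of class `kt_params`.
#' @export
asym_mech_params <- function(tau, kappa, alpha, v_minus, v_plus, L) {
  check_sign(tau, "tau", 2); check_sign(kappa, "kappa", 2)
  check_sign(alpha, "alpha", 2); check_sign(L, "L", 2)
  check_sign(v_minus, "v_minus", -1); check_sign(v_plus, "v_plus", +1)
  new_kt_params(tau, kappa, alpha, v_minus, v_plus, L)
}

#' Time-dependent mechanical parameters
#'
#' Exponential time dependence: a flagged parameter takes value
#' `p0 * exp(p1 * t)` at time `t` (seconds from the first fitted frame);
#' the noise precision evolves as `tau0 * exp(tau1 * t)`, i.e. the increment
#' variance is `dt / tau0 * exp(-tau1 * t)`. All rates zero reduces exactly
#' to the time-invariant model.
#'
#' @param base a `kt_params` object holding the initial values.
#' @param rates named list with any of `v_minus`, `v_plus`, `tau`, `kappa`,
#'   `alpha`; log-rates in s^-1 (length 1, or 2 for per-sister entries).
#' @return an object of class `kt_params`.
#' @export
timedep_params <- function(base, rates = list()) {
  stopifnot(inherits(base, "kt_params"))
  bad <- setdiff(names(rates), c("v_minus", "v_plus", "tau", "kappa", "alpha"))
  if (length(bad)) stop("unknown rate entries: ", paste(bad, collapse = ", "))
  p <- base
  for (nm in names(rates)) {
    want <- length(p$rate[[nm]])
    p$rate[[nm]] <- rep(rates[[nm]], length.out = want)
  }
  p
}

#' Combined asymmetric + temporal parameters with an anaphase-ready set point
#'
#' Per-sister forces relax exponentially toward shared set points:
#' `v(t) = v_star + (v0 - v_star) * exp(v1 * t)` (per sister), with
#' per-sister precision `tau0 * exp(tau1 * t)`; `kappa`, `alpha`, `L` shared.
#'
#' @param tau,v_minus,v_plus per-sister (length 1 or 2) initial values.
#' @param v_minus_star,v_plus_star shared set points (um/s).
#' @param rates named list of per-sister log-rates for `v_minus`, `v_plus`, `tau`.
#' @inheritParams mech_params
#' @return an object of class `kt_params`.
#' @export
combined_params <- function(tau, kappa, alpha, v_minus, v_plus, L,
                            v_minus_star = 0, v_plus_star = 0, rates = list()) {
  p <- asym_mech_params(tau, kappa, alpha, v_minus, v_plus, L)
  p <- timedep_params(p, rates)
  check_sign(v_minus_star, "v_minus_star", -1)
  check_sign(v_plus_star, "v_plus_star", +1)
  p$set_point <- c(v_minus = v_minus_star, v_plus = v_plus_star)
  p
}

#' Parameter values at a given time
#'
#' Evaluates the (possibly time-dependent) parameters at times `t`, applying
#' the exponential laws of the time-dependent and combined models.
#'
#' @param params a `kt_params` object.
#' @param t numeric vector of times (s from the first frame).
#' @param sister 1 or 2.
#' @return list with numeric vectors `v_minus`, `v_plus`, `tau` (per `t`),
#'   and `kappa`, `alpha` (per `t`), `L` (scalar).
#' @export
params_at_time <- function(params, t, sister = 1) {
  k <- sister
  vm <- params$v_minus[k]; vp <- params$v_plus[k]
  if (!is.null(params$set_point)) {
    vm_t <- params$set_point[["v_minus"]] +
      (vm - params$set_point[["v_minus"]]) * exp(params$rate$v_minus[k] * t)
    vp_t <- params$set_point[["v_plus"]] +
      (vp - params$set_point[["v_plus"]]) * exp(params$rate$v_plus[k] * t)
  } else {
    vm_t <- vm * exp(params$rate$v_minus[k] * t)
    vp_t <- vp * exp(params$rate$v_plus[k] * t)
  }
  list(
    v_minus = vm_t,
    v_plus  = vp_t,
    tau     = params$tau[k] * exp(params$rate$tau[k] * t),
    kappa   = params$kappa * exp(params$rate$kappa * t),
    alpha   = params$alpha * exp(params$rate$alpha * t),
    L       = params$L)
}

#' Rescale parameters for a position-dependent drag factor
#'
#' A drag scale gamma(r) > 1 slows all deterministic terms by gamma and
#' scales the noise variance by gamma^-2: speeds and rates are divided by
#' gamma and the precision multiplied by gamma^2. gamma = 1 is the identity.
#' This is an exact reparameterisation: simulating with the scaled parameters
#' equals simulating the original model with the drag factor in the step.
#'
#' @param params a `kt_params` object.
#' @param gamma positive drag scale factor.
#' @return a rescaled `kt_params` object.
#' @export
apply_drag_scaling <- function(params, gamma) {
  if (!is.finite(gamma) || gamma <= 0) stop("gamma must be > 0")
  p <- params
  p$v_minus <- p$v_minus / gamma
  p$v_plus <- p$v_plus / gamma
  p$kappa <- p$kappa / gamma
  p$alpha <- p$alpha / gamma
  p$tau <- p$tau * gamma^2
  if (!is.null(p$set_point)) p$set_point <- p$set_point / gamma
  p
}

#' Force-tuning law toward the anaphase-ready state
#'
#' The pulling speed obeys dv/dt = (a v + b) v with a, b > 0, which focuses
#' v toward the stable fixed point -b/a. `tuning_solution` evaluates the
#' closed-form solution 1/v(t) = -a/b + exp(-b t) (1/v0 + a/b).
#'
#' @param a coefficient ((um/s)^-1 s^-1), > 0.
#' @param b coefficient (s^-1), > 0.
#' @return `tuning_law` returns a `tuning_law` object with fixed point -b/a.
#' @export
tuning_law <- function(a, b) {
  if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0) {
    stop("tuning_law requires a > 0 and b > 0")
  }
  structure(list(a = a, b = b, fixed_point = -b / a), class = "tuning_law")
}

#' @rdname tuning_law
#' @param v0 initial pulling speed, < 0 (um/s).
#' @param law a `tuning_law` object.
#' @param t numeric vector of times (s).
#' @return `tuning_solution` returns v(t) for each `t`.
#' @export
tuning_solution <- function(v0, law, t) {
  stopifnot(inherits(law, "tuning_law"))
  if (!is.finite(v0) || v0 >= 0) stop("tuning law applies to pulling speeds v0 < 0")
  a <- law$a; b <- law$b
  inv <- -a / b + exp(-b * t) * (1 / v0 + a / b)
  1 / inv
}

#' Serialise parameters to a flat YAML file
#'
#' @param params a `kt_params` object.
#' @param sp optional `switch_params` appended under `p_coh`, `p_incoh`, `dt`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_params_yaml <- function(params, path, sp = NULL) {
  out <- list(
    tau = params$tau, kappa = params$kappa, alpha = params$alpha,
    v_minus = params$v_minus, v_plus = params$v_plus, L = params$L,
    rate = params$rate)
  if (!is.null(params$set_point)) out$set_point <- as.list(params$set_point)
  if (!is.null(sp)) out <- c(out, list(p_coh = sp$p_coh, p_incoh = sp$p_incoh, dt = sp$dt))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_params_yaml
#' @return `read_params_yaml` returns a list with elements `params`
#'   (`kt_params`) and, when present, `sp` (`switch_params`).
#' @export
read_params_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  p <- new_kt_params(y$tau, y$kappa, y$alpha, y$v_minus, y$v_plus, y$L,
                     rate = y$rate,
                     set_point = if (!is.null(y$set_point)) unlist(y$set_point))
  sp <- NULL
  if (!is.null(y$p_coh)) sp <- switch_params(y$p_coh, y$p_incoh, y$dt)
  list(params = p, sp = sp)
}
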