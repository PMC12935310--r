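#' Default prior specification
#'
#' Weakly-informative priors whose supports match the sign constraints:
#' gamma on precisions, half-normal on `kappa`, `alpha` and `v_plus`,
#' negative half-normal on `v_minus`, uniform (beta) on the stay
#' probabilities, normal on time rates, and an informative truncated normal
#' on the natural length `L` centred on the accessory nocodazole measurement
#' of 0.78 um. The `L` prior is deliberately tight enough that the prior,
#' not the trajectory, pins `L` (it is practically unidentifiable from the
#' dynamics alone).
#'
#' @param ... named overrides, each a list with a `type` field (`gamma`,
#'   `halfnormal`, `neghalfnormal`, `truncnormal`, `beta`, `normal`) and its
#'   hyperparameters.
#' @return named list of prior specifications, class `prior_spec`.
#' @export
default_priors <- function(...) {
  pr <- list(
    tau = list(type = "gamma", shape = 2, rate = 0.002),
    kappa = list(type = "halfnormal", scale = 0.1),
    alpha = list(type = "halfnormal", scale = 0.1),
    v_minus = list(type = "neghalfnormal", scale = 0.1),
    v_plus = list(type = "halfnormal", scale = 0.1),
    L = list(type = "truncnormal", mean = 0.78, sd = 0.1225),
    p_coh = list(type = "beta", a = 1, b = 1),
    p_incoh = list(type = "beta", a = 1, b = 1),
    rate = list(type = "normal", mean = 0, sd = 0.01))
  over <- list(...)
  for (nm in names(over)) pr[[nm]] <- over[[nm]]
  structure(pr, class = "prior_spec")
}

prior_basename <- function(par) {
  ifelse(grepl("_rate$", par), "rate", sub("_[12]$", "", par))
}

log_prior_one <- function(x, spec) {
  switch(spec$type,
    gamma = stats::dgamma(x, shape = spec$shape, rate = spec$rate, log = TRUE),
    halfnormal = if (x < 0) -Inf else log(2) + dnorm(x, 0, spec$scale, log = TRUE),
    neghalfnormal = if (x > 0) -Inf else log(2) + dnorm(x, 0, spec$scale, log = TRUE),
    truncnormal = if (x <= 0) -Inf else
      dnorm(x, spec$mean, spec$sd, log = TRUE) -
        stats::pnorm(0, spec$mean, spec$sd, lower.tail = FALSE, log.p = TRUE),
    beta = stats::dbeta(x, spec$a, spec$b, log = TRUE),
    normal = dnorm(x, spec$mean, spec$sd, log = TRUE),
    stop("unknown prior type: ", spec$type))
}

rprior_one <- function(n, spec) {
  switch(spec$type,
    gamma = stats::rgamma(n, shape = spec$shape, rate = spec$rate),
    halfnormal = abs(rnorm(n, 0, spec$scale)),
    neghalfnormal = -abs(rnorm(n, 0, spec$scale)),
    truncnormal = {
      x <- rnorm(2 * n + 20, spec$mean, spec$sd)
      x <- x[x > 0]
      while (length(x) < n) x <- c(x, abs(rnorm(n, spec$mean, spec$sd)))
      x[seq_len(n)]
    },
    beta = stats::rbeta(n, spec$a, spec$b),
    normal = rnorm(n, spec$mean, spec$sd),
    stop("unknown prior type: ", spec$type))
}

#' Log prior density of a named parameter vector
#'
#' @param theta named parameter vector on the constrained scale.
#' @param priors a [default_priors()] specification.
#' @return scalar log density (parameters treated as independent a priori).
#' @export
log_prior <- function(theta, priors = default_priors()) {
  bn <- prior_basename(names(theta))
  sum(vapply(seq_along(theta),
             function(i) log_prior_one(theta[[i]], priors[[bn[i]]]), 0))
}

#' Draw a parameter vector from the prior
#'
#' @param model_id model id defining the parameter set.
#' @param priors a [default_priors()] specification.
#' @param n number of draws.
#' @return n x p matrix of draws with parameter columns.
#' @export
sample_prior <- function(model_id, priors = default_priors(), n = 1) {
  nm <- par_names(model_id)
  bn <- prior_basename(nm)
  out <- vapply(seq_along(nm), function(i) rprior_one(n, priors[[bn[i]]]),
                numeric(n))
  matrix(out, nrow = n, dimnames = list(NULL, nm))
}
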