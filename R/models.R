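# Model family registry. Ids:
#   "M0"                      symmetric, time-invariant (vanilla)
#   "Ma_<subset>"             sister-asymmetric in subset of {vm, vp, tau}
#   "Mt_<subset>"             time-dependent in subset of {alpha, kappa, vm, vp, tau}
# 7 asymmetric + 9 time-dependent + vanilla = 17 models.

ASYM_SETS <- list("tau", "vm", "vp", c("vm", "vp"), c("vm", "tau"),
                  c("vp", "tau"), c("vm", "vp", "tau"))
TD_SETS <- list("alpha", "kappa", "vm", "vp", "tau", c("vm", "vp"),
                c("vm", "tau"), c("vp", "tau"), c("vm", "vp", "tau"))

short2par <- c(vm = "v_minus", vp = "v_plus", tau = "tau",
               kappa = "kappa", alpha = "alpha")

#' The 17-model family
#'
#' @return character vector of model ids: the vanilla model `M0`, the 7
#'   sister-asymmetric variants `Ma_*` and the 9 time-dependent variants
#'   `Mt_*`.
#' @export
model_ids <- function() {
  c("M0",
    paste0("Ma_", vapply(ASYM_SETS, paste, "", collapse = "")),
    paste0("Mt_", vapply(TD_SETS, paste, "", collapse = "")))
}

#' Structure of one model variant
#'
#' @param model_id a model id from [model_ids()].
#' @return list with `id`, `family`, `asym` (parameters asymmetric between
#'   sisters) and `td` (parameters with exponential time dependence), both as
#'   full parameter names.
#' @export
model_spec <- function(model_id) {
  ids <- model_ids()
  if (!model_id %in% ids) stop("unknown model id: ", model_id)
  asym <- character(0); td <- character(0)
  if (startsWith(model_id, "Ma_")) {
    asym <- short2par[ASYM_SETS[[match(model_id, ids) - 1L]]]
  } else if (startsWith(model_id, "Mt_")) {
    td <- short2par[TD_SETS[[match(model_id, ids) - 8L]]]
  }
  list(id = model_id,
       family = if (length(asym)) "asymmetric" else if (length(td)) "timedep" else "vanilla",
       asym = unname(asym), td = unname(td))
}

#' Free-parameter names of a model
#'
#' Base parameters are (tau, kappa, alpha, v_minus, v_plus, L, p_coh,
#' p_incoh); asymmetric parameters split into `_1`/`_2` per sister and
#' time-dependent parameters add a `_rate` entry.
#'
#' @inheritParams model_spec
#' @return character vector of parameter names, in canonical order.
#' @export
par_names <- function(model_id) {
  ms <- model_spec(model_id)
  base <- c("tau", "kappa", "alpha", "v_minus", "v_plus", "L", "p_coh", "p_incoh")
  out <- unlist(lapply(base, function(p) {
    if (p %in% ms$asym) paste0(p, c("_1", "_2")) else p
  }))
  c(out, if (length(ms$td)) paste0(ms$td, "_rate"))
}

#' Build model parameters from a named parameter vector
#'
#' @inheritParams model_spec
#' @param theta named numeric vector over [par_names()].
#' @param dt frame interval (s) for the returned `switch_params`.
#' @return list with `params` (`kt_params`) and `sp` (`switch_params`).
#' @export
theta_to_params <- function(model_id, theta, dt = 2.05) {
  nm <- par_names(model_id)
  if (!all(nm %in% names(theta))) {
    stop("theta is missing: ", paste(setdiff(nm, names(theta)), collapse = ", "))
  }
  get2 <- function(p) {
    if (paste0(p, "_1") %in% names(theta)) {
      unname(theta[paste0(p, c("_1", "_2"))])
    } else rep(unname(theta[p]), 2)
  }
  rates <- list()
  for (p in c("v_minus", "v_plus", "tau", "kappa", "alpha")) {
    rn <- paste0(p, "_rate")
    if (rn %in% names(theta)) rates[[p]] <- unname(theta[rn])
  }
  params <- new_kt_params(get2("tau"), unname(theta["kappa"]),
                          unname(theta["alpha"]), get2("v_minus"),
                          get2("v_plus"), unname(theta["L"]), rate = rates)
  list(params = params,
       sp = switch_params(unname(theta["p_coh"]), unname(theta["p_incoh"]), dt))
}

#' @rdname theta_to_params
#' @param params a `kt_params` object.
#' @param sp a `switch_params` object.
#' @return `params_to_theta` returns the named vector for `model_id`.
#' @export
params_to_theta <- function(model_id, params, sp) {
  nm <- par_names(model_id)
  val <- function(n) {
    if (grepl("_rate$", n)) {
      p <- sub("_rate$", "", n)
      return(params$rate[[p]][1])
    }
    if (grepl("_[12]$", n)) {
      p <- sub("_[12]$", "", n)
      k <- as.integer(sub(".*_", "", n))
      return(params[[p]][k])
    }
    switch(n, p_coh = sp$p_coh, p_incoh = sp$p_incoh,
           tau = params$tau[1], v_minus = params$v_minus[1],
           v_plus = params$v_plus[1], params[[n]])
  }
  stats::setNames(vapply(nm, val, 0), nm)
}

# Unconstrained reparameterisation used by the sampler and bridge estimator.
transform_kind <- function(names) {
  ifelse(grepl("^tau|^kappa|^alpha|^L|^v_plus", names) & !grepl("_rate$", names), "log",
  ifelse(grepl("^v_minus", names) & !grepl("_rate$", names), "neglog",
  ifelse(grepl("^p_", names), "logit", "identity")))
}

to_unconstrained <- function(theta) {
  kind <- transform_kind(names(theta))
  out <- theta
  out[kind == "log"] <- log(theta[kind == "log"])
  out[kind == "neglog"] <- log(-theta[kind == "neglog"])
  out[kind == "logit"] <- qlogis(theta[kind == "logit"])
  out
}

from_unconstrained <- function(z) {
  kind <- transform_kind(names(z))
  out <- z
  out[kind == "log"] <- exp(z[kind == "log"])
  out[kind == "neglog"] <- -exp(z[kind == "neglog"])
  out[kind == "logit"] <- plogis(z[kind == "logit"])
  out
}

# log |d theta / d z|, the Jacobian of from_unconstrained.
log_jacobian <- function(z) {
  kind <- transform_kind(names(z))
  lj <- numeric(length(z))
  lj[kind %in% c("log", "neglog")] <- z[kind %in% c("log", "neglog")]
  li <- kind == "logit"
  lj[li] <- z[li] - 2 * log1p(exp(z[li]))
  sum(lj)
}
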