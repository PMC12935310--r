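# Internal fast path for repeated likelihood evaluation on one trajectory.
# Precomputes the observation design (gaps, held positions, spring geometry)
# once, then evaluates the forward likelihood from a named theta vector with
# minimal allocation. Semantics are identical to log_likelihood(); the tests
# assert agreement.

transition_matrix_fast <- function(pc, pic) {
  qc <- 1 - pc; qi <- 1 - pic
  matrix(c(pic * pic, pic * qi, qi * pic, qi * qi,
           pc * qc,  pc * pc,  qc * qc,  qc * pc,
           qc * pc,  qc * qc,  pc * pc,  pc * qc,
           qi * qi,  qi * pic, pic * qi, pic * pic),
         4, 4, byrow = TRUE)
}

stationary_fast <- function(pc, pic) {
  wi <- pc * (1 - pc); wc <- pic * (1 - pic)
  if (wi + wc <= 0) return(rep(0.25, 4))
  c(wi, wc, wc, wi) / (2 * (wi + wc))
}

emission_design <- function(traj) {
  T <- n_frames(traj)
  h1 <- fill_forward(ifelse(traj$missing[, 1], NA_real_, traj$x1_um))
  h2 <- fill_forward(ifelse(traj$missing[, 2], NA_real_, traj$x2_um))
  hc <- fill_forward(traj$cos_theta)
  t0 <- traj$time_s - traj$time_s[1]
  sisters <- lapply(1:2, function(k) {
    x <- if (k == 1) traj$x1_um else traj$x2_um
    obs <- which(!traj$missing[, k] & is.finite(x))
    if (length(obs) < 2) return(NULL)
    j <- obs[-1]; s <- obs[-length(obs)]
    list(rows = j - 1L, gdt = (j - s) * traj$dt, delta = x[j] - x[s],
         ts = t0[s], d12 = h1[s] - h2[s], hc = hc[s],
         own = if (k == 1) h1[s] else h2[s], sgn = if (k == 1) -1 else 1)
  })
  list(sisters = sisters, Tm1 = T - 1L, dt = traj$dt)
}

# theta layout helper: resolves per-sister values and rates from a named
# vector without string matching at evaluation time.
theta_layout <- function(model_id) {
  nm <- par_names(model_id)
  idx <- function(x) match(x, nm)
  per_sister <- function(p) {
    if (paste0(p, "_1") %in% nm) c(idx(paste0(p, "_1")), idx(paste0(p, "_2")))
    else c(idx(p), idx(p))
  }
  list(nm = nm,
       vm = per_sister("v_minus"), vp = per_sister("v_plus"),
       tau = per_sister("tau"), kappa = idx("kappa"), alpha = idx("alpha"),
       L = idx("L"), pcoh = idx("p_coh"), pincoh = idx("p_incoh"),
       r_vm = idx("v_minus_rate"), r_vp = idx("v_plus_rate"),
       r_tau = idx("tau_rate"), r_kappa = idx("kappa_rate"),
       r_alpha = idx("alpha_rate"))
}

make_loglik <- function(traj, model_id) {
  des <- emission_design(traj)
  lay <- theta_layout(model_id)
  rate_of <- function(theta, i) if (is.na(i)) 0 else theta[[i]]
  function(theta) {
    logE <- matrix(0, des$Tm1, 4)
    kap <- theta[[lay$kappa]]; alp <- theta[[lay$alpha]]; L <- theta[[lay$L]]
    r_kap <- rate_of(theta, lay$r_kappa)
    r_alp <- rate_of(theta, lay$r_alpha)
    r_vm <- rate_of(theta, lay$r_vm); r_vp <- rate_of(theta, lay$r_vp)
    r_tau <- rate_of(theta, lay$r_tau)
    for (k in 1:2) {
      d <- des$sisters[[k]]
      if (is.null(d)) next
      vm <- theta[[lay$vm[k]]]; vp <- theta[[lay$vp[k]]]
      tau <- theta[[lay$tau[k]]]
      if (r_vm != 0) vm <- vm * exp(r_vm * d$ts)
      if (r_vp != 0) vp <- vp * exp(r_vp * d$ts)
      if (r_tau != 0) tau <- tau * exp(r_tau * d$ts)
      kap_t <- if (r_kap != 0) kap * exp(r_kap * d$ts) else kap
      alp_t <- if (r_alp != 0) alp * exp(r_alp * d$ts) else alp
      base <- d$sgn * kap_t * (d$d12 - L * d$hc) - alp_t * d$own
      mu_p <- (d$sgn * vp + base) * d$gdt
      mu_m <- (d$sgn * vm + base) * d$gdt
      sdv <- sqrt(d$gdt / tau)
      ep <- dnorm(d$delta, mu_p, sdv, log = TRUE)
      em <- dnorm(d$delta, mu_m, sdv, log = TRUE)
      if (k == 1) {
        logE[d$rows, 1L] <- logE[d$rows, 1L] + ep
        logE[d$rows, 2L] <- logE[d$rows, 2L] + ep
        logE[d$rows, 3L] <- logE[d$rows, 3L] + em
        logE[d$rows, 4L] <- logE[d$rows, 4L] + em
      } else {
        logE[d$rows, 1L] <- logE[d$rows, 1L] + ep
        logE[d$rows, 3L] <- logE[d$rows, 3L] + ep
        logE[d$rows, 2L] <- logE[d$rows, 2L] + em
        logE[d$rows, 4L] <- logE[d$rows, 4L] + em
      }
    }
    pc <- theta[[lay$pcoh]]; pic <- theta[[lay$pincoh]]
    P <- transition_matrix_fast(pc, pic)
    forward_filter_cpp(logE, P, stationary_fast(pc, pic))$loglik
  }
}

# Vectorised prior evaluator for a fixed parameter layout.
make_log_prior <- function(nm, priors) {
  bn <- prior_basename(nm)
  specs <- priors[bn]
  function(theta) {
    s <- 0
    for (i in seq_along(theta)) {
      s <- s + log_prior_one(theta[[i]], specs[[i]])
      if (!is.finite(s)) return(-Inf)
    }
    s
  }
}

# Precomputed unconstrained transform for a fixed layout.
make_transform <- function(nm) {
  kind <- transform_kind(nm)
  i_log <- which(kind == "log"); i_neg <- which(kind == "neglog")
  i_logit <- which(kind == "logit")
  list(
    from_z = function(z) {
      th <- z
      th[i_log] <- exp(z[i_log])
      th[i_neg] <- -exp(z[i_neg])
      th[i_logit] <- plogis(z[i_logit])
      th
    },
    to_z = function(theta) {
      z <- theta
      z[i_log] <- log(theta[i_log])
      z[i_neg] <- log(-theta[i_neg])
      z[i_logit] <- qlogis(theta[i_logit])
      z
    },
    log_jac = function(z) {
      s <- sum(z[i_log]) + sum(z[i_neg])
      zl <- z[i_logit]
      s + sum(zl - 2 * log1p(exp(zl)))
    })
}

# Full unnormalised log posterior in unconstrained space, plus the loglik.
make_logpost <- function(traj, model_id, priors) {
  nm <- par_names(model_id)
  ll_fn <- make_loglik(traj, model_id)
  pr_fn <- make_log_prior(nm, priors)
  tr <- make_transform(nm)
  function(z) {
    theta <- tr$from_z(z)
    lp <- pr_fn(theta)
    if (!is.finite(lp)) return(list(lp = -Inf, ll = -Inf))
    ll <- ll_fn(theta)
    if (!is.finite(ll)) return(list(lp = -Inf, ll = -Inf))
    list(lp = ll + lp + tr$log_jac(z), ll = ll)
  }
}
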