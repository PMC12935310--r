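#' Sampler configuration
#'
#' Settings for the MAP-initialised adaptive Metropolis sampler operating in
#' unconstrained parameter space (positives log-transformed, probabilities
#' logit-transformed).
#'
#' @param chains number of chains (>= 2).
#' @param warmup adaptation iterations per chain (discarded).
#' @param draws retained iterations per chain.
#' @param target_accept target acceptance rate of the random-walk kernel.
#' @param rhat_threshold split-R-hat convergence flag threshold.
#' @param init_jitter s.d. of the unconstrained jitter applied to chain
#'   starting points around the posterior mode.
#' @return list of class `sampler_config`.
#' @export
sampler_config <- function(chains = 2, warmup = 1500, draws = 1500,
                           target_accept = 0.3, rhat_threshold = 1.01,
                           init_jitter = 0.3) {
  if (chains < 2) stop("at least 2 chains are required for diagnostics")
  structure(list(chains = chains, warmup = warmup, draws = draws,
                 target_accept = target_accept,
                 rhat_threshold = rhat_threshold, init_jitter = init_jitter),
            class = "sampler_config")
}

# Heuristic moment-based starting point on the constrained scale.
init_theta <- function(traj, model_id) {
  nm <- par_names(model_id)
  dx <- c(diff(traj$x1_um), diff(traj$x2_um))
  dx <- dx[is.finite(dx)]
  v <- if (length(dx) > 10) stats::var(dx) else 0.01
  tau0 <- max(traj$dt / v, 50)
  base <- c(tau = tau0, kappa = 0.02, alpha = 0.01, v_minus = -0.03,
            v_plus = 0.01, L = 0.78, p_coh = 0.9, p_incoh = 0.7)
  val <- function(n) {
    if (grepl("_rate$", n)) return(0)
    base[[sub("_[12]$", "", n)]]
  }
  stats::setNames(vapply(nm, val, 0), nm)
}

split_rhat <- function(draws_by_chain) {
  halves <- do.call(cbind, lapply(draws_by_chain, function(x) {
    n <- floor(length(x) / 2)
    cbind(x[seq_len(n)], x[(length(x) - n + 1):length(x)])
  }))
  m <- ncol(halves); n <- nrow(halves)
  mu <- colMeans(halves); s2 <- apply(halves, 2, stats::var)
  W <- mean(s2); B <- n * stats::var(mu)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Sample the joint posterior of a model's parameters
#'
#' Marginalises the hidden chain analytically (forward algorithm) and samples
#' the continuous parameters with a MAP-initialised adaptive random-walk
#' Metropolis kernel in unconstrained space. Reproducible under `seed`.
#'
#' @param traj a [sister_pair_trajectory()].
#' @param model_id one of [model_ids()].
#' @param priors a [default_priors()] specification.
#' @param config a [sampler_config()].
#' @param seed integer seed.
#' @param retry_on_nonconvergence retry once with doubled draws if split-R-hat
#'   exceeds the threshold.
#' @return an object of class `posterior_fit`: draws matrix, posterior
#'   medians, posterior interquartile ranges (PIR), log-likelihood and
#'   log-posterior draws, diagnostics (split-R-hat per parameter, acceptance
#'   rate, `converged`, `excluded`), and the data/model references.
#' @export
sample_posterior <- function(traj, model_id = "M0", priors = default_priors(),
                             config = sampler_config(), seed = 1,
                             retry_on_nonconvergence = TRUE) {
  fit <- sample_posterior_once(traj, model_id, priors, config, seed)
  if (retry_on_nonconvergence && !fit$diagnostics$converged) {
    config2 <- config
    config2$warmup <- 2 * config$warmup
    config2$draws <- 2 * config$draws
    fit <- sample_posterior_once(traj, model_id, priors, config2, seed + 1L)
    fit$diagnostics$retried <- TRUE
  }
  fit$diagnostics$excluded <- !fit$diagnostics$converged
  fit
}

sample_posterior_once <- function(traj, model_id, priors, config, seed) {
  set.seed(seed)
  nm <- par_names(model_id)
  d <- length(nm)
  logpost_z <- make_logpost(traj, model_id, priors)

  z0 <- unname(to_unconstrained(init_theta(traj, model_id)))
  opt <- tryCatch(
    optim(z0, function(z) -logpost_z(z)$lp, method = "BFGS",
          control = list(maxit = 150), hessian = TRUE),
    error = function(e) NULL)
  if (!is.null(opt) && is.finite(opt$value)) {
    zmap <- opt$par
    Sig <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  } else {
    zmap <- z0; Sig <- NULL
  }
  if (is.null(Sig) || any(!is.finite(Sig)) ||
      inherits(tryCatch(chol(Sig), error = function(e) e), "error")) {
    Sig <- diag(0.05, d)
  }

  # Mixture kernel: adaptive independence proposals from a multivariate-t
  # approximation of the posterior (refitted during warmup), combined with
  # adaptive random-walk moves for local robustness.
  t_df <- 6
  run_chain <- function(chain_id) {
    n_tot <- config$warmup + config$draws
    Z <- matrix(NA_real_, n_tot, d)
    ll_vec <- numeric(n_tot); lp_vec <- numeric(n_tot)
    z <- zmap + rnorm(d, 0, config$init_jitter)
    cur <- logpost_z(z)
    tries <- 0
    while (!is.finite(cur$lp) && tries < 50) {
      z <- zmap + rnorm(d, 0, config$init_jitter / 2)
      cur <- logpost_z(z); tries <- tries + 1
    }
    if (!is.finite(cur$lp)) { z <- zmap; cur <- logpost_z(z) }
    ind_mu <- zmap
    ind_chol <- chol(Sig * 1.3)
    logt <- function(zz) {
      b <- backsolve(ind_chol, zz - ind_mu, transpose = TRUE)
      -0.5 * (t_df + d) * log1p(sum(b^2) / t_df)
    }
    rt_draw <- function() {
      g <- stats::rchisq(1, t_df) / t_df
      ind_mu + drop(rnorm(d) %*% ind_chol) / sqrt(g)
    }
    cur_logt <- logt(z)
    log_scale <- log(2.38^2 / d)
    C <- Sig
    cholC <- chol(C)
    run_mean <- z; run_m2 <- matrix(0, d, d); n_seen <- 1
    acc <- 0
    for (i in seq_len(n_tot)) {
      if (runif(1) < 0.7) { # independence move
        prop <- rt_draw()
        cand <- logpost_z(prop)
        prop_logt <- logt(prop)
        accept <- is.finite(cand$lp) &&
          log(runif(1)) < (cand$lp - prop_logt) - (cur$lp - cur_logt)
        if (accept) { z <- prop; cur <- cand; cur_logt <- prop_logt; acc <- acc + 1 }
      } else {              # random-walk move
        prop <- z + exp(log_scale / 2) * drop(rnorm(d) %*% cholC)
        cand <- logpost_z(prop)
        accept <- is.finite(cand$lp) && log(runif(1)) < cand$lp - cur$lp
        if (accept) { z <- prop; cur <- cand; cur_logt <- logt(z); acc <- acc + 1 }
        if (i <= config$warmup) {
          log_scale <- log_scale +
            i^(-0.6) * ((if (accept) 1 else 0) - config$target_accept)
        }
      }
      if (i <= config$warmup) {
        n_seen <- n_seen + 1
        dz <- z - run_mean
        run_mean <- run_mean + dz / n_seen
        run_m2 <- run_m2 + tcrossprod(dz, z - run_mean)
        if (i >= 500 && i %% 250 == 0) {
          Ct <- run_m2 / (n_seen - 1) + diag(1e-8, d)
          ch <- tryCatch(chol(Ct), error = function(e) NULL)
          if (!is.null(ch)) {
            C <- Ct; cholC <- ch
            ind_mu <- run_mean
            ind_chol <- tryCatch(chol(Ct * 1.3), error = function(e) ind_chol)
            cur_logt <- logt(z)
          }
        }
      }
      Z[i, ] <- z; ll_vec[i] <- cur$ll; lp_vec[i] <- cur$lp
    }
    keep <- (config$warmup + 1):n_tot
    list(Z = Z[keep, , drop = FALSE], ll = ll_vec[keep], lp = lp_vec[keep],
         acc = acc / n_tot)
  }

  chains <- lapply(seq_len(config$chains), run_chain)
  Zall <- do.call(rbind, lapply(chains, `[[`, "Z"))
  colnames(Zall) <- nm
  draws <- t(apply(Zall, 1, function(z) from_unconstrained(stats::setNames(z, nm))))
  colnames(draws) <- nm
  rhat <- vapply(seq_len(d), function(j) {
    split_rhat(lapply(chains, function(ch) ch$Z[, j]))
  }, 0)
  names(rhat) <- nm
  medians <- apply(draws, 2, median)
  pir <- apply(draws, 2, function(x) diff(quantile(x, c(0.25, 0.75))))
  structure(list(
    model_id = model_id,
    draws = draws,
    unconstrained_draws = Zall,
    medians = medians,
    pir = pir,
    loglik_draws = do.call(c, lapply(chains, `[[`, "ll")),
    logpost_draws = do.call(c, lapply(chains, `[[`, "lp")),
    diagnostics = list(
      rhat = rhat,
      max_rhat = max(rhat),
      accept_rate = mean(vapply(chains, `[[`, 0, "acc")),
      converged = max(rhat) < config$rhat_threshold,
      retried = FALSE),
    priors = priors,
    config = config,
    dt = dt,
    n_chains = config$chains,
    traj_id = paste(traj$cell_id, traj$pair_id, sep = "/")),
    class = "posterior_fit")
}

#' @export
print.posterior_fit <- function(x, ...) {
  cat(sprintf("<posterior_fit %s on %s: %d draws, max split-Rhat %.3f%s>\n",
              x$model_id, x$traj_id, nrow(x$draws), x$diagnostics$max_rhat,
              if (x$diagnostics$converged) "" else " (not converged)"))
  print(round(rbind(median = x$medians, PIR = x$pir), 4))
  invisible(x)
}

#' Summarise a posterior fit as a data frame
#'
#' @param object a `posterior_fit`.
#' @param ... unused.
#' @return data frame with one row per parameter: median, PIR, central 80%
#'   interval, split-R-hat.
#' @export
summary.posterior_fit <- function(object, ...) {
  q <- t(apply(object$draws, 2, quantile, c(0.1, 0.5, 0.9)))
  data.frame(parameter = colnames(object$draws),
             median = object$medians, pir = object$pir,
             q10 = q[, 1], q90 = q[, 3],
             rhat = object$diagnostics$rhat, row.names = NULL)
}

#' Serialise a posterior fit
#'
#' Writes the draws to CSV and a YAML summary (medians, PIR, diagnostics).
#'
#' @param fit a `posterior_fit`.
#' @param prefix output path prefix; writes `<prefix>_draws.csv` and
#'   `<prefix>_summary.yaml`.
#' @return the two paths, invisibly.
#' @export
write_posterior_fit <- function(fit, prefix) {
  p1 <- paste0(prefix, "_draws.csv")
  p2 <- paste0(prefix, "_summary.yaml")
  utils::write.csv(as.data.frame(fit$draws), p1, row.names = FALSE)
  yaml::write_yaml(list(
    model_id = fit$model_id, traj = fit$traj_id,
    medians = as.list(fit$medians), pir = as.list(fit$pir),
    max_rhat = fit$diagnostics$max_rhat,
    converged = fit$diagnostics$converged), p2)
  invisible(c(p1, p2))
}
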