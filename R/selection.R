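logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Bridge-sampling estimate of a log normalising constant
#'
#' Iterative optimal bridge between an unnormalised density `log_q` and a
#' moment-matched Gaussian proposal fitted to the supplied draws (assumed to
#' come from the normalised density q/m). Returns log m with a Monte-Carlo
#' standard error. Falls back to plain Gaussian importance sampling, with a
#' flag, if the bridge iteration fails to converge.
#'
#' @param draws matrix of (approximate) posterior draws, one row per draw, in
#'   the space where `log_q` is evaluated.
#' @param log_q function mapping a parameter vector to its unnormalised log
#'   density.
#' @param log_q_draws optional precomputed `log_q` values for `draws`.
#' @param n_proposal number of proposal draws (default 1000).
#' @param tol convergence tolerance on the bridge identity (default 1e-6).
#' @param maxit maximum bridge iterations.
#' @param seed integer seed.
#' @return list with `logml`, `se`, `n_iter`, `converged`, `method`.
#' @export
bridge_sampling <- function(draws, log_q, log_q_draws = NULL,
                            n_proposal = 1000, tol = 1e-6, maxit = 200,
                            seed = 1) {
  set.seed(seed)
  draws <- as.matrix(draws)
  n1 <- nrow(draws); d <- ncol(draws)
  mu <- colMeans(draws)
  Sig <- stats::cov(draws) + diag(1e-10, d)
  ch <- chol(Sig)
  ldet <- 2 * sum(log(diag(ch)))
  log_g <- function(Z) {
    B <- backsolve(ch, t(Z) - mu, transpose = TRUE)
    -0.5 * colSums(B^2) - 0.5 * d * log(2 * pi) - 0.5 * ldet
  }
  Z2 <- matrix(rnorm(n_proposal * d), n_proposal, d) %*% ch +
    matrix(mu, n_proposal, d, byrow = TRUE)
  if (is.null(log_q_draws)) {
    log_q_draws <- apply(draws, 1, log_q)
  }
  lq2 <- apply(Z2, 1, log_q)
  l1 <- log_q_draws - log_g(draws)   # at posterior draws
  l2 <- lq2 - log_g(Z2)              # at proposal draws
  ok2 <- is.finite(l2)
  if (sum(ok2) < 10 || !any(is.finite(l1))) {
    return(list(logml = NA_real_, se = NA_real_, n_iter = 0,
                converged = FALSE, method = "failed"))
  }
  n2 <- sum(ok2); l2 <- l2[ok2]
  ok1 <- is.finite(l1); l1 <- l1[ok1]; n1 <- length(l1)
  s1 <- n1 / (n1 + n2); s2 <- n2 / (n1 + n2)
  lstar <- median(l1)  # stabilising shift
  logr <- logsumexp(l2) - log(n2) # importance-sampling start
  converged <- FALSE
  for (it in seq_len(maxit)) {
    num <- logsumexp((l2 - lstar) -
                       apply(cbind(log(s1) + l2 - lstar, log(s2) + logr - lstar), 1, logsumexp)) - log(n2)
    den <- logsumexp(-apply(cbind(log(s1) + l1 - lstar, log(s2) + logr - lstar), 1, logsumexp)) - log(n1)
    logr_new <- lstar + num - den
    if (!is.finite(logr_new)) break
    if (abs(logr_new - logr) < tol) { logr <- logr_new; converged <- TRUE; break }
    logr <- logr_new
  }
  if (!converged || !is.finite(logr)) {
    # stabilised fallback: importance sampling under the Gaussian proposal
    logml <- logsumexp(l2) - log(n2)
    w <- exp(l2 - logsumexp(l2))
    se <- sqrt(sum(w^2) - 1 / n2)
    return(list(logml = logml, se = se, n_iter = maxit,
                converged = FALSE, method = "importance"))
  }
  # relative-MSE standard error of the bridge estimate
  f2 <- exp(l2 - apply(cbind(log(s1) + l2, log(s2) + logr), 1, logsumexp))
  f1 <- exp(-apply(cbind(log(s1) + l1, log(s2) + logr), 1, logsumexp))
  rho1 <- if (n1 > 10) {
    a <- stats::acf(f1, lag.max = 1, plot = FALSE)$acf[2]
    if (!is.finite(a)) 0 else max(0, a)
  } else 0
  ess1 <- n1 * (1 - rho1) / (1 + rho1)
  re2 <- var(f2) / (n2 * mean(f2)^2) + var(f1) / (max(ess1, 2) * mean(f1)^2)
  list(logml = logr, se = sqrt(max(re2, 0)), n_iter = it, converged = TRUE,
       method = "bridge")
}

#' Log marginal likelihood of a fitted model
#'
#' Bridge-sampling estimate of the model evidence from a converged
#' [sample_posterior()] fit, computed in unconstrained space against a
#' moment-matched Gaussian proposal.
#'
#' @param fit a `posterior_fit`.
#' @param traj the trajectory the fit was run on.
#' @param priors prior specification (defaults to the fit's).
#' @param n_proposal,seed see [bridge_sampling()].
#' @param max_draws posterior draws used (thinned evenly).
#' @return list with `logml`, `se`, `converged`, `method`, `model_id`.
#' @export
log_marginal_likelihood <- function(fit, traj, priors = fit$priors,
                                    n_proposal = 1000, max_draws = 1000,
                                    seed = 1) {
  lpfun <- make_logpost(traj, fit$model_id, priors)
  log_q <- function(z) lpfun(as.numeric(z))$lp
  idx <- unique(round(seq(1, nrow(fit$unconstrained_draws),
                          length.out = min(max_draws, nrow(fit$unconstrained_draws)))))
  out <- bridge_sampling(fit$unconstrained_draws[idx, , drop = FALSE], log_q,
                         log_q_draws = fit$logpost_draws[idx],
                         n_proposal = n_proposal, seed = seed)
  out$model_id <- fit$model_id
  out
}

#' Bayes factor and evidence category
#'
#' BF = exp(logml_complex - logml_simple), categorised on the standard
#' evidence scale: below 3.2 not worth more than a bare mention, 3.2 up to 10
#' substantial, 10 up to 100 strong, 100 and above decisive.
#'
#' @param logml_complex,logml_simple log marginal likelihoods.
#' @return list with `bf`, `log_bf`, `category`.
#' @export
bayes_factor <- function(logml_complex, logml_simple) {
  stopifnot(is.finite(logml_complex), is.finite(logml_simple))
  lb <- logml_complex - logml_simple
  bf <- exp(lb)
  list(bf = bf, log_bf = lb, category = evidence_category(bf))
}

#' @rdname bayes_factor
#' @param bf a Bayes factor (>= 0).
#' @export
evidence_category <- function(bf) {
  cut(bf, breaks = c(-Inf, 3.2, 10, 100, Inf), right = FALSE,
      labels = c("bare_mention", "substantial", "strong", "decisive")) |>
    as.character()
}

model_subset_size <- function(model_id) {
  ms <- model_spec(model_id)
  length(ms$asym) + length(ms$td)
}

is_nested_in <- function(simple, complex) {
  if (simple == complex) return(FALSE)
  if (simple == "M0") return(TRUE)
  if (complex == "M0") return(FALSE)
  ss <- model_spec(simple); cs <- model_spec(complex)
  if (ss$family != cs$family) return(FALSE)
  s_set <- c(ss$asym, ss$td); c_set <- c(cs$asym, cs$td)
  all(s_set %in% c_set) && length(s_set) < length(c_set)
}

#' Nesting edges of the model family
#'
#' Directed simple-to-complex edges between the supplied candidate models:
#' the vanilla model nests in every other model, and within each family an
#' edge joins models whose varying-parameter sets differ by one element.
#'
#' @param candidates character vector of model ids.
#' @return data frame with columns `from` (simple) and `to` (complex).
#' @export
model_network_edges <- function(candidates = model_ids()) {
  stopifnot(all(candidates %in% model_ids()))
  edges <- expand.grid(from = candidates, to = candidates,
                       stringsAsFactors = FALSE)
  direct <- mapply(function(f, t) {
    is_nested_in(f, t) &&
      model_subset_size(t) - model_subset_size(f) == 1
  }, edges$from, edges$to)
  out <- edges[direct, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Navigate the nested model network to the preferred model
#'
#' Selection rule: (1) keep models with Bayes factor above `threshold`
#' against vanilla; (2) within the kept set, prune any model lacking a Bayes
#' factor above `threshold` over each of its kept nested submodels (checked
#' against all kept ancestors); (3) of the survivors pick the one with the
#' highest Bayes factor against vanilla, resolving ties within one combined
#' standard error toward the simpler model. An empty kept set returns
#' vanilla.
#'
#' @param logml named vector of log marginal likelihoods including `"M0"`.
#' @param se optional named vector of standard errors (default 0).
#' @param threshold Bayes-factor threshold (default 3.2).
#' @return list with `preferred`, `kept`, and the BF-vs-vanilla `table`.
#' @export
select_preferred_model <- function(logml, se = NULL, threshold = 3.2) {
  if (!"M0" %in% names(logml)) stop("logml must include the vanilla model M0")
  if (anyNA(logml)) {
    stop("missing marginal likelihood for model(s): ",
         paste(names(logml)[is.na(logml)], collapse = ", "))
  }
  if (is.null(se)) se <- stats::setNames(rep(0, length(logml)), names(logml))
  se <- se[names(logml)]
  names(se) <- names(logml)
  se[!is.finite(se)] <- 0
  ids <- setdiff(names(logml), "M0")
  ids <- ids[order(vapply(ids, model_subset_size, 0L), match(ids, model_ids()))]
  bf0 <- exp(logml[ids] - logml[["M0"]])
  kept <- ids[bf0 > threshold]
  surviving <- character(0)
  for (m in kept) {
    parents <- surviving[vapply(surviving, is_nested_in, TRUE, complex = m)]
    ok <- all(vapply(parents, function(p) {
      exp(logml[[m]] - logml[[p]]) > threshold
    }, TRUE))
    if (ok) surviving <- c(surviving, m)
  }
  if (!length(surviving)) {
    preferred <- "M0"
  } else {
    lbf <- logml[surviving] - logml[["M0"]]
    best <- max(lbf)
    comb_se <- sqrt(se[surviving]^2 + se[["M0"]]^2)
    near <- surviving[lbf >= best - comb_se[which.max(lbf)]]
    preferred <- near[which.min(vapply(near, model_subset_size, 0L))]
  }
  table <- data.frame(model_id = names(logml), logml = as.numeric(logml),
                      se = as.numeric(se[names(logml)]),
                      log_bf_vs_vanilla = as.numeric(logml - logml[["M0"]]),
                      row.names = NULL)
  table$category <- evidence_category(exp(table$log_bf_vs_vanilla))
  list(preferred = preferred, kept = surviving, table = table)
}

#' Default asymmetric candidate model set
#'
#' The five asymmetric-family models reported in the population analysis;
#' `full = TRUE` returns all eight.
#'
#' @param full include all 7 asymmetric variants plus vanilla.
#' @return character vector of model ids.
#' @export
asym_candidates <- function(full = FALSE) {
  if (full) c("M0", model_ids()[2:8])
  else c("M0", "Ma_vm", "Ma_vp", "Ma_vmvp", "Ma_vmvptau")
}

#' Fit a candidate model set to one pair and select the preferred model
#'
#' @param traj a [sister_pair_trajectory()].
#' @param candidates model ids (must include "M0").
#' @param priors,config,seed passed to [sample_posterior()] and
#'   [log_marginal_likelihood()].
#' @param threshold Bayes-factor selection threshold.
#' @return list with `preferred`, `logml`, `se`, `fits`, `selection`.
#' @export
select_for_pair <- function(traj, candidates = asym_candidates(),
                            priors = default_priors(),
                            config = sampler_config(), seed = 1,
                            threshold = 3.2, retry_on_nonconvergence = TRUE,
                            n_proposal = 1000) {
  stopifnot("M0" %in% candidates)
  fits <- list(); logml <- c(); se <- c()
  for (i in seq_along(candidates)) {
    m <- candidates[i]
    fit <- sample_posterior(traj, m, priors = priors, config = config,
                            seed = seed + 1000L * i,
                            retry_on_nonconvergence = retry_on_nonconvergence)
    ml <- log_marginal_likelihood(fit, traj, priors = priors,
                                  n_proposal = n_proposal,
                                  seed = seed + 1000L * i + 1L)
    if (!is.finite(ml$logml)) {  # one retry with a larger proposal sample
      ml <- log_marginal_likelihood(fit, traj, priors = priors,
                                    n_proposal = 4L * n_proposal,
                                    seed = seed + 1000L * i + 2L)
    }
    fits[[m]] <- fit
    logml[m] <- ml$logml
    se[m] <- ml$se
  }
  sel <- select_preferred_model(logml, se, threshold = threshold)
  list(preferred = sel$preferred, logml = logml, se = se, fits = fits,
       selection = sel)
}

#' Per-cell model-selection report
#'
#' @param selections named list of [select_for_pair()] results (names =
#'   pair ids).
#' @param path optional CSV path to write the report.
#' @return data frame with one row per pair x model.
#' @export
selection_report <- function(selections, path = NULL) {
  out <- do.call(rbind, lapply(names(selections), function(pid) {
    s <- selections[[pid]]
    tb <- s$selection$table
    tb$pair_id <- pid
    tb$preferred <- s$preferred
    tb
  }))
  out <- out[, c("pair_id", "model_id", "logml", "se", "log_bf_vs_vanilla",
                 "category", "preferred")]
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
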