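# Self-contained simulation-and-recovery experiments. These drive the
# analysis scripts, the acceptance checks and parts of the test suite, so
# their study conditions (pair counts, trajectory length, generating values)
# are fixed here in one place.

#' Vanilla-model parameter-recovery experiment
#'
#' Simulates sister pairs from the symmetric model at the reference
#' population medians (T frames at 2.05 s), fits the vanilla model to each
#' by MCMC, and summarises the median over pairs of the posterior medians
#' together with the median posterior interquartile range per parameter.
#'
#' @param n_pairs number of pairs (default 10).
#' @param T frames per trajectory (default 300).
#' @param seed integer seed controlling simulation and fitting.
#' @param config a [sampler_config()].
#' @return list with `medians` (pair x parameter matrix), `pir` (likewise),
#'   `recovered` (median of posterior medians), `pir_med` (median PIR),
#'   `truth` (generating values), `rhat` (per-fit max split-R-hat).
#' @export
recovery_experiment_vanilla <- function(n_pairs = 10, T = 300, seed = 1,
                                        config = sampler_config()) {
  ref <- reference_params()
  truth <- params_to_theta("M0", ref$params, ref$sp)
  meds <- NULL; pirs <- NULL; rhat <- numeric(n_pairs)
  for (i in seq_len(n_pairs)) {
    tr <- simulate_pair(ref$params, ref$sp, T = T,
                        seed = seed * 1000L + i, pair_id = sprintf("pair%02d", i))
    fit <- sample_posterior(tr, "M0", config = config, seed = seed * 2000L + i)
    meds <- rbind(meds, fit$medians)
    pirs <- rbind(pirs, fit$pir)
    rhat[i] <- fit$diagnostics$max_rhat
  }
  list(medians = meds, pir = pirs,
       recovered = apply(meds, 2, median),
       pir_med = apply(pirs, 2, median),
       truth = truth, rhat = rhat)
}

#' Table 2 generating values for the asymmetric recovery experiment
#'
#' Population medians of significantly asymmetric pairs under the
#' v+/v- asymmetric model; sister 1 is the stronger puller.
#'
#' @return list with `params` (`kt_params`) and `sp` (`switch_params`).
#' @export
asym_reference_params <- function() {
  list(params = asym_mech_params(tau = 700, kappa = 0.023, alpha = 0.013,
                                 v_minus = c(-0.060, -0.032),
                                 v_plus = c(0.004, 0.015), L = 0.839),
       sp = switch_params(p_coh = 0.952, p_incoh = 0.766, dt = 2.05))
}

#' Asymmetric-model recovery experiment
#'
#' Simulates pairs from the v+/v- asymmetric model at the asymmetric-column
#' reference medians and fits the same model; reports the recovered pulling
#' parameter of the stronger sister (identified per fit by the larger
#' posterior-median pulling magnitude).
#'
#' @inheritParams recovery_experiment_vanilla
#' @return list with `vm_strong` (per-pair posterior medians of the stronger
#'   sister's v-), `recovered` (their median), `pir_med`, `truth`, `rhat`.
#' @export
recovery_experiment_asym <- function(n_pairs = 10, T = 300, seed = 1,
                                     config = sampler_config()) {
  gen <- asym_reference_params()
  vm_strong <- numeric(n_pairs); pir_strong <- numeric(n_pairs)
  rhat <- numeric(n_pairs)
  for (i in seq_len(n_pairs)) {
    tr <- simulate_pair(gen$params, gen$sp, T = T, seed = seed * 3000L + i,
                        pair_id = sprintf("pair%02d", i))
    fit <- sample_posterior(tr, "Ma_vmvp", config = config,
                            seed = seed * 4000L + i)
    k <- which.max(abs(fit$medians[c("v_minus_1", "v_minus_2")]))
    vm_strong[i] <- fit$medians[c("v_minus_1", "v_minus_2")][k]
    pir_strong[i] <- fit$pir[c("v_minus_1", "v_minus_2")][k]
    rhat[i] <- fit$diagnostics$max_rhat
  }
  list(vm_strong = vm_strong, recovered = median(vm_strong),
       pir_med = median(pir_strong),
       truth = gen$params$v_minus[1], rhat = rhat)
}

#' Tuning set-point recovery experiment
#'
#' Simulates pairs whose pulling-force log-rates lie on the tuning line
#' v1 = a (v0 - v*) with the anaphase-ready x-intercept v* = -0.033 um/s,
#' fits the time-dependent v+/v-/tau model to each, and regresses the
#' posterior-median rate on the posterior-median initial value to recover
#' the set point.
#'
#' @param n_pairs number of pairs (default 20).
#' @param a tuning slope ((um/s)^-1 s^-1, default 0.1).
#' @param set_point generating x-intercept (default -0.033 um/s).
#' @inheritParams recovery_experiment_vanilla
#' @return list with `regression` (from [tuning_regression()]), per-pair
#'   `v0_hat`, `v1_hat`, generating `v0`, `v1`, and `set_point`.
#' @export
tuning_recovery_experiment <- function(n_pairs = 20, T = 300, seed = 1,
                                       a = 0.1, set_point = -0.033,
                                       config = sampler_config()) {
  ref <- reference_params()
  v0 <- seq(-0.065, -0.025, length.out = n_pairs)
  v1 <- a * (v0 - set_point)
  v0_hat <- numeric(n_pairs); v1_hat <- numeric(n_pairs)
  for (i in seq_len(n_pairs)) {
    p <- timedep_params(
      mech_params(tau = 673.7, kappa = 0.022, alpha = 0.009,
                  v_minus = v0[i], v_plus = 0.010, L = 0.808),
      rates = list(v_minus = v1[i],
                   v_plus = -0.3 * (0.010 - 0.003),
                   tau = 5e-4))
    tr <- simulate_pair(p, ref$sp, T = T, seed = seed * 5000L + i,
                        pair_id = sprintf("pair%02d", i))
    fit <- sample_posterior(tr, "Mt_vmvptau", config = config,
                            seed = seed * 6000L + i)
    v0_hat[i] <- fit$medians[["v_minus"]]
    v1_hat[i] <- fit$medians[["v_minus_rate"]]
  }
  list(regression = tuning_regression(v0_hat, v1_hat),
       v0_hat = v0_hat, v1_hat = v1_hat, v0 = v0, v1 = v1,
       set_point = set_point)
}

#' Model-selection sanity experiment
#'
#' Generates pairs either from the vanilla model (false-complexity control)
#' or from a strongly v- asymmetric model, runs Bayes-factor selection over
#' the asymmetric candidate set for each pair, and reports the selection
#' outcomes.
#'
#' @param kind `"vanilla"` or `"asym"`.
#' @param n_pairs number of pairs (default 20).
#' @param delta_vm sister pulling-force difference for the asymmetric
#'   generation (um/s, default 0.03).
#' @inheritParams recovery_experiment_vanilla
#' @param candidates candidate model ids (must include "M0").
#' @return list with `picks` (preferred model per pair), `complex_fraction`,
#'   `vm_detect_fraction` (fraction preferring a model with v- asymmetry).
#' @export
selection_experiment <- function(kind = c("vanilla", "asym"), n_pairs = 20,
                                 delta_vm = 0.03, T = 300, seed = 1,
                                 config = sampler_config(chains = 2,
                                                         warmup = 800,
                                                         draws = 800),
                                 candidates = asym_candidates()) {
  kind <- match.arg(kind)
  ref <- reference_params()
  params <- if (kind == "vanilla") ref$params else
    asym_mech_params(tau = 673.7, kappa = 0.022, alpha = 0.009,
                     v_minus = c(-0.041 - delta_vm / 2, -0.041 + delta_vm / 2),
                     v_plus = 0.010, L = 0.808)
  picks <- character(n_pairs)
  for (i in seq_len(n_pairs)) {
    tr <- simulate_pair(params, ref$sp, T = T, seed = seed * 7000L + i,
                        pair_id = sprintf("pair%02d", i))
    sel <- select_for_pair(tr, candidates = candidates, config = config,
                           seed = seed * 8000L + i,
                           retry_on_nonconvergence = FALSE, n_proposal = 600)
    picks[i] <- sel$preferred
  }
  vm_models <- c("Ma_vm", "Ma_vmvp", "Ma_vmvptau", "Ma_vmtau")
  list(picks = picks,
       complex_fraction = mean(picks != "M0"),
       vm_detect_fraction = mean(picks %in% vm_models))
}

#' Planted-archetype clustering experiment
#'
#' Simulates pairs from each of the five oscillation archetype presets,
#' computes mid-point ACFs sampled on a geometric lag grid (dense at short
#' lags, extending to 150 s), and clusters them with the DTW hierarchical
#' machinery at k = 5; scores label agreement against the planted classes.
#' Because the archetypes differ by their decay time scales, warping is
#' disabled for this test (band 0) and Ward linkage is used — see the
#' methods vignette for why a warping band would erase exactly the feature
#' separating the planted classes.
#'
#' @param n_per pairs per archetype (default 50).
#' @param T frames (default 1200).
#' @param seed integer seed.
#' @param band DTW band passed to [dtw_cluster()] (default 0).
#' @param method linkage (default "ward.D2").
#' @return list with `accuracy` (Hungarian-matched), `assignment`
#'   (`cluster_assignment`), `truth` labels, `acfs`, `lag_s`.
#' @export
archetype_clustering_experiment <- function(n_per = 50, T = 1200, seed = 1,
                                            band = 0, method = "ward.D2") {
  kinds <- c("strong_short", "strong_long", "weak_long", "weak_noisy", "poor")
  lag_s <- c(2.05 * 1:5, 14, 20, 28, 40, 56, 78, 110, 150, 210)
  idx <- round(lag_s / 2.05) + 1
  acfs <- NULL; truth <- integer(0)
  for (k in seq_along(kinds)) {
    for (i in seq_len(n_per)) {
      tr <- archetype_pair(kinds[k], T = T, seed = seed * 10000L + 100L * k + i)
      os <- oscillation_summary(tr, max_lag_s = 220)
      acfs <- rbind(acfs, os$acf[idx])
      truth <- c(truth, k)
    }
  }
  cl <- dtw_cluster(acfs, k = 5, band = band, method = method, refine = 3)
  list(accuracy = matched_accuracy(truth, cl$labels), assignment = cl,
       truth = truth, acfs = acfs, lag_s = lag_s, kinds = kinds)
}
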