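#' Reference parameter set for untreated RPE1-like populations
#'
#' Population medians of the vanilla-model parameters used as the
#' generator's base values.
#'
#' @return named list with `params` (`kt_params`) and `sp` (`switch_params`).
#' @export
reference_params <- function() {
  list(params = mech_params(tau = 673.7, kappa = 0.022, alpha = 0.009,
                            v_minus = -0.041, v_plus = 0.010, L = 0.808),
       sp = switch_params(p_coh = 0.949, p_incoh = 0.760, dt = 2.05))
}

#' Synthetic population generator configuration
#'
#' Defaults emulate the study conditions of the tracked metaphase
#' populations: cells of on average 40 sister pairs, 300 frames at 2.05 s,
#' base parameters at the reference medians, multiplicative radial trends
#' with centre-to-periphery drops of 38% (v-), 25% (v+), 53% (kappa), 9%
#' (alpha) and a 10% rise of tau^(-1/2), per-kinetochore force variation
#' with anti-correlated pulling and pushing strengths, a tuned fraction of
#' pairs relaxing toward the anaphase-ready set points, and geometric-gap
#' missing data.
#'
#' @param n_cells number of cells.
#' @param pairs_per_cell mean pairs per cell (Poisson, floored at 1).
#' @param T frames per trajectory.
#' @param dt frame interval (s).
#' @param base named list overriding entries of [reference_params()].
#' @param spatial_drop named vector of centre-to-periphery fractional drops
#'   for `v_minus`, `v_plus`, `kappa`, `alpha`; `tau_inv_sqrt_rise` the rise
#'   of the reciprocal root precision. Set all to 0 for a spatially flat
#'   population.
#' @param asym_sd log-scale per-kinetochore s.d. of `v_minus` and `v_plus`
#'   (0 = symmetric sisters).
#' @param asym_cor correlation of per-KT log pulling and log pushing
#'   strengths (negative: stronger pullers are weaker pushers).
#' @param cell_sd log-scale between-cell s.d. applied to the mechanical
#'   parameters.
#' @param switch_logit_sd per-pair jitter of the stay probabilities on the
#'   logit scale.
#' @param tuned_fraction fraction of pairs with time-dependent forces.
#' @param set_point anaphase-ready set points (um/s).
#' @param rate_slope regression slopes of the rate on the initial value for
#'   `v_minus` and `v_plus` ((um/s)^-1 s^-1).
#' @param rate_noise_sd s.d. of the rate residuals (s^-1).
#' @param missing_rate target missing-data fraction.
#' @param missing_gap mean missing-gap length (frames).
#' @param onset_mean_s,onset_cell_sd_s,onset_pair_sd_s anaphase-onset
#'   distribution (cell mean, between-cell s.d., within-cell pair s.d.).
#' @param plate_radius_um radius of the metaphase-plate disc (um).
#' @param treatment `"DMSO"` or `"nocodazole"`; the latter applies the
#'   washout shifts (v+ -37.5%, |v-| -5.8%, tau +20%, alpha +15%,
#'   kappa -40%).
#' @param seed integer seed.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_cells = 3, pairs_per_cell = 40, T = 300,
                             dt = 2.05, base = list(),
                             spatial_drop = c(v_minus = 0.38, v_plus = 0.25,
                                              kappa = 0.53, alpha = 0.09),
                             tau_inv_sqrt_rise = 0.10,
                             asym_sd = c(v_minus = 0.25, v_plus = 0.40),
                             asym_cor = -0.5, cell_sd = 0.10,
                             switch_logit_sd = 0.15,
                             tuned_fraction = 0.466,
                             set_point = c(v_minus = -0.033, v_plus = 0.003),
                             rate_slope = c(v_minus = 0.1, v_plus = 0.3),
                             rate_noise_sd = 5e-4,
                             missing_rate = 0.05, missing_gap = 3,
                             onset_mean_s = 650, onset_cell_sd_s = 60,
                             onset_pair_sd_s = 15,
                             plate_radius_um = 5,
                             treatment = c("DMSO", "nocodazole"),
                             seed = 1) {
  treatment <- match.arg(treatment)
  ref <- reference_params()
  basev <- list(tau = ref$params$tau[1], kappa = ref$params$kappa,
                alpha = ref$params$alpha, v_minus = ref$params$v_minus[1],
                v_plus = ref$params$v_plus[1], L = ref$params$L,
                p_coh = ref$sp$p_coh, p_incoh = ref$sp$p_incoh)
  for (nm in names(base)) {
    if (!nm %in% names(basev)) stop("unknown base parameter: ", nm)
    basev[[nm]] <- base[[nm]]
  }
  if (treatment == "nocodazole") {
    basev$v_plus <- basev$v_plus * (1 - 0.375)
    basev$v_minus <- basev$v_minus * (1 - 0.058)
    basev$tau <- basev$tau * 1.20
    basev$alpha <- basev$alpha * 1.15
    basev$kappa <- basev$kappa * 0.60
  }
  cfg <- list(n_cells = n_cells, pairs_per_cell = pairs_per_cell, T = T,
              dt = dt, base = basev, spatial_drop = spatial_drop,
              tau_inv_sqrt_rise = tau_inv_sqrt_rise, asym_sd = asym_sd,
              asym_cor = asym_cor, cell_sd = cell_sd,
              switch_logit_sd = switch_logit_sd,
              tuned_fraction = tuned_fraction, set_point = set_point,
              rate_slope = rate_slope, rate_noise_sd = rate_noise_sd,
              missing_rate = missing_rate, missing_gap = missing_gap,
              onset_mean_s = onset_mean_s, onset_cell_sd_s = onset_cell_sd_s,
              onset_pair_sd_s = onset_pair_sd_s,
              plate_radius_um = plate_radius_um, treatment = treatment,
              seed = seed)
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  with(cfg, {
    if (n_cells < 1 || pairs_per_cell < 1) stop("n_cells and pairs_per_cell must be >= 1")
    if (T < 2) stop("T must be >= 2")
    if (dt <= 0) stop("dt must be > 0")
    if (base$v_minus > 0) stop("base v_minus must be <= 0")
    if (base$v_plus < 0) stop("base v_plus must be >= 0")
    if (any(c(base$tau, base$kappa, base$alpha, base$L) <= 0)) {
      stop("tau, kappa, alpha, L must be > 0")
    }
    if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
    if (tuned_fraction < 0 || tuned_fraction > 1) stop("tuned_fraction must be in [0, 1]")
  })
  invisible(cfg)
}

#' @rdname generator_config
#' @param cfg a `generator_config`.
#' @param path YAML file path.
#' @export
write_generator_config <- function(cfg, path) {
  yaml::write_yaml(lapply(unclass(cfg), function(x) {
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x
  }), path)
  invisible(path)
}

#' @rdname generator_config
#' @export
read_generator_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (nm in c("spatial_drop", "asym_sd", "set_point", "rate_slope")) {
    y[[nm]] <- unlist(y[[nm]])
  }
  # base is stored post-treatment-shift; avoid applying the shifts twice
  treat <- y$treatment
  y$treatment <- "DMSO"
  cfg <- do.call(generator_config, y)
  cfg$treatment <- treat
  cfg
}

# Spatial scale at radial quantile u for one parameter: 1 at the median of
# the innermost quintile (u = 0.1), 1 - drop at the outermost (u = 0.9).
spatial_scale <- function(u, drop) 1 - drop * (u - 0.1) / 0.8

#' Generate a synthetic sister-pair population
#'
#' Simulates cells of paired trajectories under the force-balance model with
#' per-pair parameters drawn per the configuration, radial positions within
#' a disc, and a full ground-truth record sufficient to score every recovery
#' analysis without re-simulation.
#'
#' @param cfg a [generator_config()].
#' @return list with `cells` (list of [cell_dataset()]), `truth` (one row
#'   per pair with all generating values and flags) and `cfg`.
#' @export
generate_population <- function(cfg) {
  set.seed(cfg$seed)
  cells <- vector("list", cfg$n_cells)
  truth <- list()
  for (ci in seq_len(cfg$n_cells)) {
    cell_id <- sprintf("cell%02d", ci)
    n_pairs <- max(1L, stats::rpois(1, cfg$pairs_per_cell))
    cell_eff <- exp(rnorm(5, 0, cfg$cell_sd))  # v-, v+, kappa, alpha, tau
    onset_cell <- rnorm(1, cfg$onset_mean_s, cfg$onset_cell_sd_s)
    pairs <- vector("list", n_pairs)
    for (pi in seq_len(n_pairs)) {
      pair_id <- sprintf("pair%03d", pi)
      u <- runif(1)
      r <- cfg$plate_radius_um * sqrt(u)
      s_vm <- spatial_scale(u, cfg$spatial_drop[["v_minus"]])
      s_vp <- spatial_scale(u, cfg$spatial_drop[["v_plus"]])
      s_ka <- spatial_scale(u, cfg$spatial_drop[["kappa"]])
      s_al <- spatial_scale(u, cfg$spatial_drop[["alpha"]])
      s_tau <- (1 + cfg$tau_inv_sqrt_rise * (u - 0.1) / 0.8)^(-2)
      # per-KT log-normal force variation, pulling and pushing anti-correlated
      z <- matrix(rnorm(4), 2, 2)
      z[, 2] <- cfg$asym_cor * z[, 1] + sqrt(1 - cfg$asym_cor^2) * z[, 2]
      vm <- cfg$base$v_minus * cell_eff[1] * s_vm *
        exp(cfg$asym_sd[["v_minus"]] * z[, 1])
      vp <- cfg$base$v_plus * cell_eff[2] * s_vp *
        exp(cfg$asym_sd[["v_plus"]] * z[, 2])
      kap <- cfg$base$kappa * cell_eff[3] * s_ka
      alp <- cfg$base$alpha * cell_eff[4] * s_al
      tau <- cfg$base$tau * cell_eff[5] * s_tau
      pc <- plogis(qlogis(cfg$base$p_coh) + rnorm(1, 0, cfg$switch_logit_sd))
      pic <- plogis(qlogis(cfg$base$p_incoh) + rnorm(1, 0, cfg$switch_logit_sd))
      tuned <- runif(1) < cfg$tuned_fraction
      rates <- list()
      if (tuned) {
        # rates point toward the set point: negative for forces above it
        r_vm <- cfg$rate_slope[["v_minus"]] *
          (mean(vm) - cfg$set_point[["v_minus"]]) + rnorm(1, 0, cfg$rate_noise_sd)
        r_vp <- -cfg$rate_slope[["v_plus"]] *
          (mean(vp) - cfg$set_point[["v_plus"]]) + rnorm(1, 0, cfg$rate_noise_sd)
        r_tau <- abs(rnorm(1, 5e-4, 2e-4))  # precision rises toward anaphase
        rates <- list(v_minus = r_vm, v_plus = r_vp, tau = r_tau)
      }
      params <- asym_mech_params(tau = tau, kappa = kap, alpha = alp,
                                 v_minus = vm, v_plus = vp, L = cfg$base$L)
      if (tuned) params <- timedep_params(params, rates)
      sp <- switch_params(pc, pic, cfg$dt)
      traj <- simulate_pair(params, sp, T = cfg$T, dt = cfg$dt,
                            cos_theta = pmin(1, 1 - abs(rnorm(cfg$T, 0.02, 0.01))),
                            cell_id = cell_id, pair_id = pair_id, r_um = r)
      traj$anaphase_onset_s <- rnorm(1, onset_cell, cfg$onset_pair_sd_s)
      pairs[[pi]] <- traj
      truth[[length(truth) + 1]] <- data.frame(
        cell_id = cell_id, pair_id = pair_id, r_um = r, u = u,
        v_minus_1 = vm[1], v_minus_2 = vm[2],
        v_plus_1 = vp[1], v_plus_2 = vp[2],
        tau = tau, kappa = kap, alpha = alp, L = cfg$base$L,
        p_coh = pc, p_incoh = pic,
        tuned = tuned,
        v_minus_rate = if (tuned) rates$v_minus else 0,
        v_plus_rate = if (tuned) rates$v_plus else 0,
        tau_rate = if (tuned) rates$tau else 0,
        anaphase_onset_s = traj$anaphase_onset_s,
        missing_fraction = 0, qc_fail = FALSE)
    }
    cells[[ci]] <- cell_dataset(pairs, cell_id = cell_id,
                                treatment = cfg$treatment)
  }
  truth <- do.call(rbind, truth)
  pop <- list(cells = cells, truth = truth, cfg = cfg)
  if (cfg$missing_rate > 0) {
    pop <- inject_missingness(pop, rate = cfg$missing_rate,
                              mean_gap = cfg$missing_gap,
                              seed = cfg$seed + 104729L)
  }
  pop
}

#' Inject tracking-gap missingness into a population
#'
#' Geometric-gap model: per sister, an observed frame opens a gap with a
#' rate chosen so the long-run missing fraction matches `rate`; gap lengths
#' are geometric with mean `mean_gap`. Realised per-pair missing fractions
#' and quality-control violations (>= 20%) are recorded in the truth table.
#'
#' @param pop a population from [generate_population()], or a list of
#'   [cell_dataset()] (then returned without a truth update).
#' @param rate target long-run missing fraction (0 leaves data unchanged).
#' @param mean_gap mean gap length in frames.
#' @param seed integer seed.
#' @return the population with masked observations.
#' @export
inject_missingness <- function(pop, rate, mean_gap = 3, seed = 1) {
  if (rate == 0) return(pop)
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  set.seed(seed)
  q <- rate / (mean_gap * (1 - rate))  # gap-opening probability per frame
  cells <- if (!is.null(pop$cells)) pop$cells else pop
  mask_one <- function(T) {
    m <- logical(T)
    t <- 1
    while (t <= T) {
      if (runif(1) < q) {
        len <- stats::rgeom(1, 1 / mean_gap) + 1
        m[t:min(T, t + len - 1)] <- TRUE
        t <- t + len
      }
      t <- t + 1
    }
    m
  }
  for (ci in seq_along(cells)) {
    for (pi in seq_along(cells[[ci]]$pairs)) {
      p <- cells[[ci]]$pairs[[pi]]
      T <- n_frames(p)
      miss <- cbind(mask_one(T), mask_one(T))
      miss[1, ] <- FALSE  # keep the first frame anchored
      p$missing <- p$missing | miss
      p$x1_um[p$missing[, 1]] <- NA_real_
      p$x2_um[p$missing[, 2]] <- NA_real_
      cells[[ci]]$pairs[[pi]] <- p
      if (!is.null(pop$truth)) {
        row <- pop$truth$cell_id == p$cell_id & pop$truth$pair_id == p$pair_id
        pop$truth$missing_fraction[row] <- mean(p$missing)
        pop$truth$qc_fail[row] <- mean(p$missing) >= 0.20
      }
    }
  }
  if (!is.null(pop$cells)) { pop$cells <- cells; pop } else cells
}

ARCHETYPES <- c("strong_short", "strong_long", "weak_long", "weak_noisy", "poor")

#' Archetype sister pairs spanning the oscillation-quality taxonomy
#'
#' Parameter presets realising five distinct mid-point ACF phenotypes as a
#' ladder of directional-persistence times. Under the constant-probability
#' switching chain the achievable single-pair ACFs are monotone mixtures of
#' decays (see the methods vignette), so oscillation quality maps onto how
#' rapidly direction decorrelates: `strong_short` pairs alternate direction
#' fastest (deep, fast-dropping ACF), through `strong_long`, `weak_long` and
#' `weak_noisy`, to `poor` pairs whose weak, slowly-switching dynamics leave
#' a flat featureless ACF. Force magnitudes decrease from the strong to the
#' poor presets, mirroring the weaker pulling of poor oscillators.
#'
#' @param kind one of "strong_short", "strong_long", "weak_long",
#'   "weak_noisy", "poor".
#' @param T frames (default 1200; long recordings stabilise the per-pair ACF
#'   estimate).
#' @param seed integer seed.
#' @return a [sister_pair_trajectory()] with attribute `"archetype"`.
#' @export
archetype_pair <- function(kind = ARCHETYPES, T = 1200, seed = 1) {
  kind <- match.arg(kind)
  dt <- 2.05
  preset <- switch(kind,
    strong_short = list(p = mech_params(2500, 0.06, 0.060, -0.09, 0.030, 0.808),
                        sp = switch_params(0.450, 0.28, dt)),
    strong_long  = list(p = mech_params(2500, 0.05, 0.030, -0.08, 0.030, 0.808),
                        sp = switch_params(0.780, 0.42, dt)),
    weak_long    = list(p = mech_params(2500, 0.04, 0.015, -0.06, 0.020, 0.808),
                        sp = switch_params(0.920, 0.58, dt)),
    weak_noisy   = list(p = mech_params(2000, 0.03, 0.0070, -0.05, 0.018, 0.808),
                        sp = switch_params(0.987, 0.84, dt)),
    poor         = list(p = mech_params(1500, 0.02, 0.0030, -0.045, 0.015, 0.808),
                        sp = switch_params(0.997, 0.94, dt)))
  traj <- simulate_pair(preset$p, preset$sp, T = T, seed = seed, pair_id = kind)
  attr(traj, "archetype") <- kind
  traj
}

#' Write a generated population to disk
#'
#' Emits the long-format trajectory CSV, the ground-truth CSV and the
#' configuration YAML.
#'
#' @param pop a population from [generate_population()].
#' @param dir output directory (created if needed).
#' @return named character vector of the three paths, invisibly.
#' @export
write_population <- function(pop, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "trajectories.csv")
  p2 <- file.path(dir, "ground_truth.csv")
  p3 <- file.path(dir, "config.yaml")
  write_trajectories(do.call(c, lapply(pop$cells, `[[`, "pairs")), p1)
  utils::write.csv(pop$truth, p2, row.names = FALSE)
  write_generator_config(pop$cfg, p3)
  invisible(c(trajectories = p1, truth = p2, config = p3))
}
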