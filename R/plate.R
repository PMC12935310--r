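#' Autocorrelation function with pairwise-complete missing handling
#'
#' Mean-removed ACF with per-lag normalisation: lag-l covariance is averaged
#' over the index pairs where both points are observed, then divided by the
#' lag-0 value. `acf(0) = 1`; values are clamped to \[-1, 1\].
#'
#' @param series numeric vector, NA where missing.
#' @param max_lag maximum lag in samples.
#' @param min_obs minimum non-missing points required (default 30).
#' @return list with `lag` (0..max_lag), `acf`, and `ok` (FALSE when the
#'   series has too few observations, in which case `acf` is NA).
#' @export
acf_series <- function(series, max_lag = 60, min_obs = 30) {
  x <- as.numeric(series)
  n <- length(x)
  max_lag <- min(max_lag, n - 2)
  if (sum(is.finite(x)) < min_obs) {
    return(list(lag = 0:max_lag, acf = rep(NA_real_, max_lag + 1), ok = FALSE))
  }
  x <- x - mean(x, na.rm = TRUE)
  cc <- vapply(0:max_lag, function(l) {
    a <- x[seq_len(n - l)]
    b <- x[seq_len(n - l) + l]
    mean(a * b, na.rm = TRUE)
  }, 0)
  r <- cc / cc[1]
  list(lag = 0:max_lag, acf = pmin(1, pmax(-1, r)), ok = TRUE)
}

#' Sister mid-point oscillation summary
#'
#' ACF of the sister mid-point signal, its depth (global ACF minimum) and the
#' oscillation period read off as the lag of the first local maximum after
#' the minimum; also summarises the sister-sister (KK) distance.
#'
#' @param traj a [sister_pair_trajectory()].
#' @param max_lag_s maximum ACF lag in seconds (default 250 s).
#' @return list of class `oscillation_summary` with `lag_s`, `acf`, `depth`,
#'   `period_s` (NA if no local maximum), `kk_median`, `kk_iqr`, `ok`.
#' @export
oscillation_summary <- function(traj, max_lag_s = 250) {
  mid <- (traj$x1_um + traj$x2_um) / 2
  mid[traj$missing[, 1] | traj$missing[, 2]] <- NA
  max_lag <- floor(max_lag_s / traj$dt)
  a <- acf_series(mid, max_lag = max_lag)
  kk <- traj$x1_um - traj$x2_um
  kk <- kk[is.finite(kk)]
  out <- list(lag_s = a$lag * traj$dt, acf = a$acf, ok = a$ok,
              depth = NA_real_, period_s = NA_real_,
              kk_median = median(kk), kk_iqr = stats::IQR(kk))
  if (a$ok) {
    r <- a$acf
    out$depth <- min(r)
    minima <- which(diff(sign(diff(r))) > 0) + 1
    maxima <- which(diff(sign(diff(r))) < 0) + 1
    if (length(minima)) {
      cand <- maxima[maxima > minima[1]]
      if (length(cand)) out$period_s <- out$lag_s[cand[1]]
    }
  }
  class(out) <- "oscillation_summary"
  out
}

#' Metaphase-plate width from a point cloud
#'
#' Square root of the smallest eigenvalue of the covariance matrix of the
#' supplied points (e.g. kinetochore mid-points at one frame).
#'
#' @param points n x d numeric matrix.
#' @return width (same units as the points).
#' @export
plate_width <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2) stop("need at least 2 points")
  ev <- eigen(stats::cov(points), symmetric = TRUE, only.values = TRUE)$values
  sqrt(max(min(ev), 0))
}

#' Align a cell's trajectories to its median anaphase onset
#'
#' @param cell a [cell_dataset()]; every pair must carry `anaphase_onset_s`.
#' @return the cell with an `onset_s` field (the median pair onset) and each
#'   pair gaining `aligned_time_s = time_s - onset_s` (t = 0 at onset).
#' @export
align_to_anaphase <- function(cell) {
  onsets <- vapply(cell$pairs, function(p) p$anaphase_onset_s, 0)
  if (all(is.na(onsets))) stop("cell has no anaphase onsets; excluded from time-aligned analyses")
  onset <- median(onsets, na.rm = TRUE)
  cell$onset_s <- onset
  cell$pairs <- lapply(cell$pairs, function(p) {
    p$aligned_time_s <- p$time_s - onset
    p
  })
  cell
}

#' Named metaphase windows relative to anaphase onset
#'
#' Mid-metaphase covers 330-230 s before onset, late metaphase 130-30 s
#' before onset.
#'
#' @param aligned_time_s times relative to the cell median onset (s).
#' @param which `"mid"` or `"late"`.
#' @return logical selection vector.
#' @export
metaphase_window <- function(aligned_time_s, which = c("mid", "late")) {
  which <- match.arg(which)
  rng <- if (which == "mid") c(-330, -230) else c(-130, -30)
  aligned_time_s >= rng[1] & aligned_time_s <= rng[2]
}

#' Equal-count radial partition of sister pairs
#'
#' Orders pairs by mean in-plate radial position (ties broken by stable pair
#' id order) and splits them into `k` groups of equal count (+/- 1, extras to
#' the innermost groups).
#'
#' @param pairs list of trajectories, or a numeric vector of radial positions.
#' @param k number of groups (default 5).
#' @param pair_ids optional ids used for tie-breaking and labelling.
#' @return object of class `radial_partition`: `group` (integer per pair, 1 =
#'   innermost), `boundaries` (k+1 edges), `r`, `pair_ids`.
#' @export
radial_partition <- function(pairs, k = 5, pair_ids = NULL) {
  r <- if (is.numeric(pairs)) pairs else vapply(pairs, function(p) p$r_um, 0)
  if (is.null(pair_ids)) {
    pair_ids <- if (is.numeric(pairs)) as.character(seq_along(r))
                else vapply(pairs, function(p) p$pair_id, "")
  }
  n <- length(r)
  if (k > n) stop("more groups than pairs")
  ord <- order(r, pair_ids)
  sizes <- rep(floor(n / k), k)
  if (n %% k) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1
  grp <- integer(n)
  grp[ord] <- rep(seq_len(k), times = sizes)
  bounds <- c(min(r), vapply(seq_len(k), function(g) max(r[grp == g]), 0))
  structure(list(group = grp, boundaries = bounds, r = r, pair_ids = pair_ids,
                 k = k), class = "radial_partition")
}

#' Check spatial parameter trends against a single drag profile
#'
#' Under a pure position-dependent drag scale, the speeds, spring and
#' centralising rates and the reciprocal square-root precision all scale
#' identically with radial position. Given per-group medians (innermost to
#' outermost), reports the relative centre-to-periphery change of each
#' tracked quantity and flags inconsistency when the changes differ by more
#' than `tol`.
#'
#' @param group_medians data frame or matrix, rows = radial groups ordered
#'   innermost to outermost, with columns among `v_minus`, `v_plus`,
#'   `kappa`, `alpha`, `tau`.
#' @param tol tolerance on the spread of relative changes (default 0.1).
#' @return list with `changes` (named relative centre-to-periphery change per
#'   tracked quantity, precision entering as tau^(-1/2)), `spread`, and
#'   `consistent`.
#' @export
drag_consistency_check <- function(group_medians, tol = 0.1) {
  gm <- as.data.frame(group_medians)
  tracked <- intersect(c("v_minus", "v_plus", "kappa", "alpha", "tau"),
                       names(gm))
  if (!length(tracked)) stop("no tracked parameter columns found")
  changes <- vapply(tracked, function(p) {
    inner <- gm[[p]][1]; outer <- gm[[p]][nrow(gm)]
    if (p == "tau") {
      (outer^(-0.5) - inner^(-0.5)) / inner^(-0.5)
    } else {
      (abs(outer) - abs(inner)) / abs(inner)
    }
  }, 0)
  names(changes)[names(changes) == "tau"] <- "tau_inv_sqrt"
  spread <- max(changes) - min(changes)
  list(changes = changes, spread = spread, consistent = spread <= tol)
}

#' Tuning regression toward the anaphase-ready set point
#'
#' Least-squares regression of the posterior-median exponential rate `p1` on
#' the initial value `p0` across pairs; under the tuning law
#' dv/dt = (a v + b) v the slope estimates `a`, the intercept `b`, and the
#' x-intercept -b/a is the anaphase-ready set point. The set-point standard
#' error comes from the delta method.
#'
#' @param p0 initial parameter values (posterior medians), one per pair.
#' @param p1 log-rates (s^-1), one per pair.
#' @return list with `a`, `b`, `set_point`, `se_set_point`, `degenerate`
#'   (TRUE when the slope is indistinguishable from zero, in which case the
#'   set point is NA), and the underlying `fit`.
#' @export
tuning_regression <- function(p0, p1) {
  ok <- is.finite(p0) & is.finite(p1)
  fit <- stats::lm(p1 ~ p0, data = data.frame(p0 = p0[ok], p1 = p1[ok]))
  cf <- stats::coef(fit)
  b <- cf[[1]]; a <- cf[[2]]
  V <- stats::vcov(fit)
  se_a <- sqrt(V[2, 2])
  degenerate <- !is.finite(a) || abs(a) < 2 * se_a
  if (degenerate || a == 0) {
    return(list(a = a, b = b, set_point = NA_real_, se_set_point = NA_real_,
                degenerate = TRUE, fit = fit))
  }
  sp <- -b / a
  grad <- c(-1 / a, b / a^2)
  se_sp <- sqrt(drop(t(grad) %*% V %*% grad))
  list(a = a, b = b, set_point = sp, se_set_point = se_sp,
       degenerate = FALSE, fit = fit)
}

#' Randomised-pairing null for sister force differences
#'
#' Shuffles the sister pairing within each radial group and compares the
#' real sister difference distribution with the randomised one by rank
#' (Mann-Whitney) and distribution (Kolmogorov-Smirnov) tests on absolute
#' differences.
#'
#' @param v1,v2 per-sister force estimates (same length, paired).
#' @param group radial group label per pair.
#' @param n_perm number of pairing randomisations (default 200).
#' @param seed integer seed.
#' @return list with `delta_real`, `delta_null` (pooled over permutations),
#'   `p_mw`, `p_ks`.
#' @export
randomized_pairing_null <- function(v1, v2, group, n_perm = 200, seed = 1) {
  stopifnot(length(v1) == length(v2), length(group) == length(v1))
  set.seed(seed)
  delta_real <- v1 - v2
  nulls <- vector("list", n_perm)
  for (b in seq_len(n_perm)) {
    d <- unlist(lapply(unique(group), function(g) {
      pool <- c(v1[group == g], v2[group == g])
      pool <- sample(pool)
      half <- length(pool) %/% 2
      pool[seq_len(half)] - pool[half + seq_len(half)]
    }))
    nulls[[b]] <- d
  }
  delta_null <- unlist(nulls)
  p_mw <- stats::wilcox.test(abs(delta_real), abs(delta_null))$p.value
  p_ks <- suppressWarnings(stats::ks.test(abs(delta_real), abs(delta_null))$p.value)
  list(delta_real = delta_real, delta_null = delta_null,
       p_mw = p_mw, p_ks = p_ks)
}

#' Two-factor variance decomposition of per-pair parameter estimates
#'
#' Additive cell + radial-location decomposition without interaction:
#' significance from a two-way ANOVA, variance components from a
#' random-intercept model. Cells must contribute at least `min_per_group`
#' pairs to each radial group they appear in.
#'
#' @param values per-pair estimates (e.g. posterior medians).
#' @param cell cell label per pair.
#' @param group radial group per pair.
#' @param min_per_group minimum pairs per cell x group combination kept
#'   (default 3); cells with any under-filled group are dropped.
#' @return list with `components` (between_cell, between_location, residual),
#'   `ratio` (cell / location), `total_sd_over_mean`, `anova` (the aov
#'   summary), `n_used`, `n_cells`.
#' @export
variance_decomposition <- function(values, cell, group, min_per_group = 3) {
  df <- data.frame(y = values, cell = factor(cell), group = factor(group))
  df <- df[is.finite(df$y), ]
  tab <- table(df$cell, df$group)
  keep_cells <- rownames(tab)[apply(tab, 1, function(r) all(r[r > 0] >= min_per_group) && sum(r > 0) >= 2)]
  df <- df[df$cell %in% keep_cells, ]
  df$cell <- droplevels(df$cell)
  if (nlevels(df$cell) < 2) stop("variance decomposition needs at least 2 cells after filtering")
  av <- stats::aov(y ~ cell + group, data = df)
  fit <- lme4::lmer(y ~ 1 + (1 | cell) + (1 | group), data = df,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  comp <- stats::setNames(vc$vcov, vc$grp)
  components <- c(between_cell = unname(comp["cell"]),
                  between_location = unname(comp["group"]),
                  residual = unname(comp["Residual"]))
  list(components = components,
       ratio = components[["between_cell"]] / components[["between_location"]],
       total_sd_over_mean = stats::sd(df$y) / abs(mean(df$y)),
       anova = summary(av), n_used = nrow(df), n_cells = nlevels(df$cell))
}

#' Transverse organisation of kinetochores by pulling-force asymmetry
#'
#' Classifies each kinetochore as the stronger or weaker sister of a
#' significantly asymmetric pair, or as part of a symmetric pair, and
#' computes its mean signed displacement toward its own pole relative to the
#' mean position of its poleward (anaphase) cluster. Sister 1's pole lies in
#' the positive normal direction, sister 2's in the negative.
#'
#' @param pairs list of trajectories.
#' @param asym_calls data frame with `pair_id`, `asymmetric` (logical) and
#'   `stronger` (1 or 2, which sister pulls harder; ignored for symmetric
#'   pairs).
#' @return list with `kt` (one row per kinetochore: pair_id, sister, class,
#'   displacement toward own pole) and `medians` per class, plus rank-test
#'   p-values of stronger and weaker classes against the symmetric class.
#' @export
transverse_organisation <- function(pairs, asym_calls) {
  mean_pos <- function(p, k) {
    x <- if (k == 1) p$x1_um else p$x2_um
    mean(x[!p$missing[, k]], na.rm = TRUE)
  }
  rows <- do.call(rbind, lapply(pairs, function(p) {
    data.frame(pair_id = p$pair_id, sister = 1:2,
               mpos = c(mean_pos(p, 1), mean_pos(p, 2)))
  }))
  cl1 <- mean(rows$mpos[rows$sister == 1])  # pole-positive cluster
  cl2 <- mean(rows$mpos[rows$sister == 2])  # pole-negative cluster
  rows$toward_pole <- ifelse(rows$sister == 1,
                             rows$mpos - cl1, -(rows$mpos - cl2))
  m <- match(rows$pair_id, asym_calls$pair_id)
  rows$class <- ifelse(!asym_calls$asymmetric[m], "symmetric",
                       ifelse(rows$sister == asym_calls$stronger[m],
                              "stronger", "weaker"))
  meds <- tapply(rows$toward_pole, rows$class, median)
  pv <- function(a, b) {
    if (!length(a) || !length(b)) return(NA_real_)
    stats::wilcox.test(a, b)$p.value
  }
  list(kt = rows, medians = meds,
       p_stronger_vs_symmetric = pv(rows$toward_pole[rows$class == "stronger"],
                                    rows$toward_pole[rows$class == "symmetric"]),
       p_weaker_vs_symmetric = pv(rows$toward_pole[rows$class == "weaker"],
                                  rows$toward_pole[rows$class == "symmetric"]))
}
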