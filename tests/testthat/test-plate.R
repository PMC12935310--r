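ref <- reference_params()

test_that("ACF of a pure cosine peaks at the oscillation period", {
  dt <- 2.05
  t <- seq(0, 800, by = dt)
  x <- cos(2 * pi * t / 84)
  a <- acf_series(x, max_lag = 60)
  expect_equal(a$acf[1], 1)
  expect_true(all(abs(a$acf) <= 1))
  # first local maximum after the minimum sits at 84 s within one lag
  tr <- sister_pair_trajectory(t, x + 0.52, x - 0.52)
  os <- oscillation_summary(tr)
  expect_lt(abs(os$period_s - 84), dt + 1e-9)
})

test_that("white-noise ACF stays within sampling bounds", {
  set.seed(1)
  x <- rnorm(1e4)
  a <- acf_series(x, max_lag = 100)
  expect_gt(mean(abs(a$acf[-1]) < 4 / sqrt(1e4)), 0.99)
})

test_that("vectorised ACF equals the naive direct-sum oracle", {
  set.seed(2)
  x <- cumsum(rnorm(400)) + seq(0, 3, length.out = 400)
  x <- stats::residuals(stats::lm(x ~ seq_along(x)))  # trend removed
  expect_equal(acf_series(x, 50)$acf, naive_acf(x, 50), tolerance = 1e-12)
  # pairwise-complete handling: missing points are simply skipped per lag
  xm <- x; xm[c(5, 60, 61, 200)] <- NA
  expect_equal(acf_series(xm, 30)$acf, naive_acf(xm, 30), tolerance = 1e-12)
})

test_that("too-few observations flag an undefined ACF", {
  a <- acf_series(rnorm(20), max_lag = 5)
  expect_false(a$ok)
  expect_true(all(is.na(a$acf)))
})

test_that("plate width is the root smallest covariance eigenvalue", {
  set.seed(3)
  # isotropic cloud: width approaches the generating s.d.
  pts <- matrix(rnorm(3 * 4000, sd = 0.7), ncol = 3)
  expect_lt(abs(plate_width(pts) - 0.7), 0.05)
  # coplanar points have zero width
  flat <- cbind(rnorm(100), rnorm(100), 0)
  expect_equal(plate_width(flat), 0, tolerance = 1e-12)
  # 5-point hand computation: diagonal covariance diag(0.5, 2)
  five <- rbind(c(1, 0), c(-1, 0), c(0, 2), c(0, -2), c(0, 0))
  expect_equal(plate_width(five), sqrt(0.5), tolerance = 1e-12)
  # rotation invariance
  th <- 0.83; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(plate_width(five %*% R), plate_width(five), tolerance = 1e-10)
})

test_that("anaphase alignment recovers onsets, windows and equivariance", {
  mk <- function(onset) {
    tr <- simulate_pair(ref$params, ref$sp, T = 250, seed = 4)
    tr$anaphase_onset_s <- onset
    tr
  }
  cell <- cell_dataset(lapply(c(500, 520, 540), mk))
  al <- align_to_anaphase(cell)
  expect_equal(al$onset_s, 520)
  at <- al$pairs[[1]]$aligned_time_s
  sel <- metaphase_window(at, "mid")
  expect_true(all(at[sel] >= -330 & at[sel] <= -230))
  expect_true(any(sel))
  # shifting all onsets by c shifts aligned times by -c
  cell2 <- cell_dataset(lapply(c(500, 520, 540) + 37, mk))
  al2 <- align_to_anaphase(cell2)
  expect_equal(al2$pairs[[1]]$aligned_time_s, at - 37)
  noon <- cell_dataset(list(mk(NA_real_)))
  expect_error(align_to_anaphase(noon), "onset")
})

test_that("radial partition gives equal counts, quantile boundaries, stable ties", {
  rp <- radial_partition(runif(10, 0, 5), k = 5)
  expect_equal(as.integer(table(rp$group)), rep(2L, 5))
  set.seed(5)
  r <- runif(1000, 0, 5)
  rp2 <- radial_partition(r, k = 5)
  expect_lt(max(abs(rp2$boundaries[2:5] - c(1, 2, 3, 4))), 0.2)
  # ties broken by stable pair id order
  rt <- c(1, 1, 1, 1)
  g <- radial_partition(rt, k = 2, pair_ids = c("a", "b", "c", "d"))$group
  expect_equal(g, c(1L, 1L, 2L, 2L))
})

test_that("drag-consistency check separates a pure drag profile from free trends", {
  base <- c(v_minus = -0.041, v_plus = 0.010, kappa = 0.022, alpha = 0.009,
            tau = 673.7)
  gammas <- seq(1, 1.6, length.out = 5)
  pure <- t(sapply(gammas, function(g) {
    c(v_minus = base[["v_minus"]] / g, v_plus = base[["v_plus"]] / g,
      kappa = base[["kappa"]] / g, alpha = base[["alpha"]] / g,
      tau = base[["tau"]] * g^2)
  }))
  chk <- drag_consistency_check(pure, tol = 1e-9)
  expect_true(chk$consistent)
  expect_equal(unname(chk$changes), rep(1 / 1.6 - 1, 5), tolerance = 1e-9)
  # independent trends break the single-drag explanation
  free <- pure
  free[, "kappa"] <- base[["kappa"]] * seq(1, 0.4, length.out = 5)
  expect_false(drag_consistency_check(free, tol = 0.1)$consistent)
  flat <- pure[rep(1, 5), ]
  expect_equal(max(abs(drag_consistency_check(flat)$changes)), 0)
})

test_that("tuning regression recovers exact and simulated set points", {
  p0 <- seq(-0.06, -0.02, length.out = 12)
  p1 <- 0.1 * (p0 - -0.033)  # exact line through (-0.033, 0)
  tr <- suppressWarnings(tuning_regression(p0, p1))  # perfect-fit warning
  expect_false(tr$degenerate)
  expect_equal(tr$set_point, -0.033, tolerance = 1e-12)
  # zero-slope cloud is flagged degenerate
  set.seed(6)
  tr0 <- tuning_regression(rnorm(40, -0.04, 0.01), rnorm(40, 0, 1e-3))
  expect_true(tr0$degenerate)
  expect_true(is.na(tr0$set_point))
  # noisy generation: set point recovered within 2 s.e.
  set.seed(7)
  p0n <- runif(60, -0.07, -0.02)
  p1n <- 0.1 * (p0n - -0.033) + rnorm(60, 0, 5e-4)
  trn <- tuning_regression(p0n, p1n)
  expect_lt(abs(trn$set_point - -0.033), 2 * trn$se_set_point)
})

test_that("randomised pairing null detects correlated sisters only", {
  set.seed(8)
  n <- 150
  grp <- sample(1:5, n, replace = TRUE)
  # independent sisters: indistinguishable from the null
  v1 <- rnorm(n, -0.04, 0.01); v2 <- rnorm(n, -0.04, 0.01)
  ind <- randomized_pairing_null(v1, v2, grp, n_perm = 100, seed = 9)
  expect_gt(ind$p_mw, 0.01)
  # strongly correlated sisters: real differences are narrower than the null
  base <- rnorm(n, -0.04, 0.01)
  v1c <- base + rnorm(n, 0, 0.002); v2c <- base + rnorm(n, 0, 0.002)
  cor_ <- randomized_pairing_null(v1c, v2c, grp, n_perm = 100, seed = 10)
  expect_lt(cor_$p_mw, 0.001)
  expect_lt(median(abs(cor_$delta_real)), median(abs(cor_$delta_null)))
  # fixed seed reproduces the null
  again <- randomized_pairing_null(v1c, v2c, grp, n_perm = 100, seed = 10)
  expect_identical(again$delta_null, cor_$delta_null)
})

test_that("variance decomposition recovers known components", {
  set.seed(11)
  n_cell <- 8; n_grp <- 5; n_rep <- 6
  sd_cell <- 0.3; sd_loc <- 0.2; sd_res <- 0.1
  cell_eff <- rnorm(n_cell, 0, sd_cell)
  loc_eff <- rnorm(n_grp, 0, sd_loc)
  df <- expand.grid(cell = 1:n_cell, grp = 1:n_grp, rep = 1:n_rep)
  df$y <- 1 + cell_eff[df$cell] + loc_eff[df$grp] + rnorm(nrow(df), 0, sd_res)
  vd <- variance_decomposition(df$y, df$cell, df$grp)
  expect_lt(abs(vd$components[["residual"]] - sd_res^2) / sd_res^2, 0.15)
  expect_gt(vd$components[["between_cell"]], vd$components[["residual"]])
  # cell-effect-only data: location component collapses to ~0
  df$y2 <- 1 + cell_eff[df$cell] + rnorm(nrow(df), 0, sd_res)
  vd2 <- variance_decomposition(df$y2, df$cell, df$grp)
  expect_lt(vd2$components[["between_location"]],
            0.1 * vd2$components[["between_cell"]])
  # a single cell is degenerate
  one <- df[df$cell == 1, ]
  expect_error(variance_decomposition(one$y, one$cell, one$grp), "2 cells")
})

test_that("stronger pulling sisters sit toward their pole; symmetric pairs centre", {
  sp <- ref$sp
  mk_pair <- function(dv, id, seed) {
    p <- asym_mech_params(673.7, 0.022, 0.009,
                          v_minus = c(-0.041 - dv / 2, -0.041 + dv / 2),
                          v_plus = 0.010, L = 0.808)
    simulate_pair(p, sp, T = 300, seed = seed, pair_id = id)
  }
  pairs <- c(lapply(1:12, function(i) mk_pair(0.03, paste0("a", i), i)),
             lapply(1:12, function(i) mk_pair(0, paste0("s", i), 100 + i)))
  calls <- data.frame(pair_id = sapply(pairs, function(p) p$pair_id),
                      asymmetric = rep(c(TRUE, FALSE), each = 12),
                      stronger = 1)
  org <- transverse_organisation(pairs, calls)
  expect_gt(org$medians[["stronger"]], org$medians[["weaker"]])
  expect_gt(org$medians[["stronger"]], 0)
  expect_lt(org$medians[["weaker"]], 0)
  expect_lt(abs(org$medians[["symmetric"]]), 0.15)
  # flipping the plate normal flips displacements exactly
  flipped <- lapply(pairs, function(p) {
    q <- p
    q$x1_um <- -p$x2_um; q$x2_um <- -p$x1_um
    q$missing <- p$missing[, 2:1]
    q
  })
  calls2 <- calls; calls2$stronger <- 2
  org2 <- transverse_organisation(flipped, calls2)
  expect_equal(sort(unname(org2$medians)), sort(unname(org$medians)),
               tolerance = 1e-9)
})

test_that("sister-centre offset grows with pulling-force asymmetry", {
  sp <- ref$sp
  offs <- sapply(c(0.01, 0.03, 0.05), function(dv) {
    p <- asym_mech_params(673.7, 0.022, 0.009,
                          v_minus = c(-0.041 - dv / 2, -0.041 + dv / 2),
                          v_plus = 0.010, L = 0.808)
    mean(sapply(1:8, function(i) {
      tr <- simulate_pair(p, sp, T = 300, seed = 300 + i)
      mean((tr$x1_um + tr$x2_um) / 2)
    }))
  })
  expect_true(all(diff(offs) > 0))
})
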