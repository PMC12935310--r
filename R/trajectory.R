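#' Paired sister-kinetochore trajectory
#'
#' Container for one sister pair's 1D displacements normal to the metaphase
#' plate, sampled on a constant-interval time grid, together with the
#' per-frame sister-sister angle cosine, missing-data mask, mean in-plate
#' radial position and (for synthetic data) the ground-truth hidden states.
#'
#' @param time_s increasing time grid with constant spacing (s).
#' @param x1_um,x2_um per-sister displacement normal to the plate (um); NA
#'   where missing.
#' @param cos_theta per-frame projection factor in (0, 1]; defaults to 1.
#' @param missing T x 2 logical matrix; defaults to `is.na(cbind(x1, x2))`.
#' @param r_um mean in-plate radial position (um).
#' @param cell_id,pair_id identifiers.
#' @param anaphase_onset_s optional anaphase onset time (s).
#' @param hidden_states optional integer ground-truth state sequence (1..4).
#' @return an object of class `sister_pair_trajectory`.
#' @export
sister_pair_trajectory <- function(time_s, x1_um, x2_um, cos_theta = NULL,
                                   missing = NULL, r_um = NA_real_,
                                   cell_id = "cell1", pair_id = "pair1",
                                   anaphase_onset_s = NA_real_,
                                   hidden_states = NULL) {
  T <- length(time_s)
  stopifnot(length(x1_um) == T, length(x2_um) == T)
  if (T >= 2) {
    dts <- diff(time_s)
    if (any(abs(dts - dts[1]) > 1e-9)) stop("time grid must have constant spacing")
    if (dts[1] <= 0) stop("time grid must be increasing")
  }
  if (is.null(cos_theta)) cos_theta <- rep(1, T)
  stopifnot(length(cos_theta) == T)
  if (is.null(missing)) missing <- cbind(is.na(x1_um), is.na(x2_um))
  missing <- matrix(as.logical(missing), ncol = 2)
  stopifnot(nrow(missing) == T)
  obs <- !missing[, 1] & !missing[, 2]
  if (any(obs & !is.finite(cos_theta))) {
    stop("cos_theta must be defined whenever both sisters are observed")
  }
  if (any(cos_theta[is.finite(cos_theta)] <= 0 | cos_theta[is.finite(cos_theta)] > 1)) {
    stop("cos_theta must lie in (0, 1]")
  }
  if (!is.null(hidden_states)) stopifnot(length(hidden_states) == T)
  structure(list(
    time_s = as.numeric(time_s), x1_um = as.numeric(x1_um),
    x2_um = as.numeric(x2_um), cos_theta = as.numeric(cos_theta),
    missing = missing, r_um = r_um, cell_id = cell_id, pair_id = pair_id,
    anaphase_onset_s = anaphase_onset_s, hidden_states = hidden_states,
    dt = if (T >= 2) diff(time_s)[1] else NA_real_),
    class = "sister_pair_trajectory")
}

#' @export
print.sister_pair_trajectory <- function(x, ...) {
  cat(sprintf("<sister_pair_trajectory %s/%s: %d frames, dt = %.3g s, %.1f%% missing>\n",
              x$cell_id, x$pair_id, length(x$time_s), x$dt,
              100 * mean(x$missing)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `sister_pair_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) length(traj$time_s)

#' Fraction of sister-frame observations missing
#' @param traj a `sister_pair_trajectory`.
#' @return fraction in \[0, 1\].
#' @export
missing_fraction <- function(traj) mean(traj$missing)

traj_to_long <- function(traj) {
  T <- n_frames(traj)
  st <- if (is.null(traj$hidden_states)) rep(NA_character_, T)
        else state_label(traj$hidden_states)
  do.call(rbind, lapply(1:2, function(k) {
    x <- if (k == 1) traj$x1_um else traj$x2_um
    data.frame(cell_id = traj$cell_id, pair_id = traj$pair_id, sister = k,
               frame = 0:(T - 1), time_s = traj$time_s, x_um = x,
               cos_theta = traj$cos_theta, r_um = traj$r_um,
               missing = as.integer(traj$missing[, k]), state = st)
  }))
}

#' Read and write trajectories as long-format CSV
#'
#' One row per (cell, pair, sister, frame) with columns `cell_id`, `pair_id`,
#' `sister` (1|2), `frame` (0-based), `time_s`, `x_um`, `cos_theta`, `r_um`,
#' `missing` (0|1) and optional `state` (one of ++/+-/-+/--).
#'
#' @param trajs a list of `sister_pair_trajectory` objects (or a single one).
#' @param path CSV file path.
#' @return `write_trajectories` returns `path` invisibly; `read_trajectories`
#'   returns a list of `sister_pair_trajectory` objects.
#' @export
write_trajectories <- function(trajs, path) {
  if (inherits(trajs, "sister_pair_trajectory")) trajs <- list(trajs)
  long <- do.call(rbind, lapply(trajs, traj_to_long))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  keys <- unique(long[, c("cell_id", "pair_id")])
  lapply(seq_len(nrow(keys)), function(i) {
    d <- long[long$cell_id == keys$cell_id[i] & long$pair_id == keys$pair_id[i], ]
    d1 <- d[d$sister == 1, ][order(d[d$sister == 1, "frame"]), ]
    d2 <- d[d$sister == 2, ][order(d[d$sister == 2, "frame"]), ]
    hs <- NULL
    if ("state" %in% names(d1) && !all(is.na(d1$state)) && !all(d1$state == "")) {
      hs <- state_index(d1$state)
    }
    sister_pair_trajectory(
      time_s = d1$time_s,
      x1_um = ifelse(d1$missing == 1, NA_real_, d1$x_um),
      x2_um = ifelse(d2$missing == 1, NA_real_, d2$x_um),
      cos_theta = d1$cos_theta,
      missing = cbind(d1$missing == 1, d2$missing == 1),
      r_um = d1$r_um[1], cell_id = keys$cell_id[i], pair_id = keys$pair_id[i],
      hidden_states = hs)
  })
}
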