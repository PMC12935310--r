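#' Sample hidden directional-state paths
#'
#' Conditional on a parameter value (or averaging over posterior draws),
#' samples exact hidden-state paths via backward sampling from the forward
#' filter, and reports per-step marginal state probabilities.
#'
#' @param traj a [sister_pair_trajectory()].
#' @param fit either a `posterior_fit` (paths are sampled under parameter
#'   draws taken evenly from the posterior) or a list with `params`
#'   (`kt_params`) and `sp` (`switch_params`).
#' @param n_paths total number of sampled paths.
#' @param seed integer seed.
#' @return object of class `state_annotation`: `prob` ((T-1) x 4 matrix of
#'   per-step state probabilities, rows summing to 1) and `paths`
#'   (n_paths x (T-1) integer matrix).
#' @export
sample_hidden_states <- function(traj, fit, n_paths = 200, seed = 1) {
  set.seed(seed)
  draws_list <- if (inherits(fit, "posterior_fit")) {
    idx <- unique(round(seq(1, nrow(fit$draws), length.out = min(50, n_paths))))
    lapply(idx, function(i) {
      theta <- fit$draws[i, ]
      theta_to_params(fit$model_id, theta, dt = traj$dt)
    })
  } else list(fit)
  per <- ceiling(n_paths / length(draws_list))
  paths <- do.call(rbind, lapply(draws_list, function(pp) {
    ff <- forward_filter(traj, pp$params, pp$sp)
    backward_sample_cpp(ff$alpha, ff$P, per)
  }))
  paths <- paths[seq_len(min(nrow(paths), n_paths)), , drop = FALSE]
  prob <- t(vapply(seq_len(ncol(paths)), function(t) {
    tabulate(paths[, t], nbins = 4) / nrow(paths)
  }, numeric(4)))
  colnames(prob) <- STATE_LABELS
  structure(list(prob = prob, paths = paths,
                 time_s = traj$time_s[-length(traj$time_s)]),
            class = "state_annotation")
}

#' @export
print.state_annotation <- function(x, ...) {
  cat(sprintf("<state_annotation: %d steps, %d sampled paths>\n",
              nrow(x$prob), nrow(x$paths)))
  invisible(x)
}

#' Write a state annotation to CSV
#' @param ann a `state_annotation`.
#' @param path CSV path; columns time_s then the 4 state probabilities.
#' @return `path`, invisibly.
#' @export
write_state_annotation <- function(ann, path) {
  df <- data.frame(time_s = ann$time_s, ann$prob, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Classify the directional-switch events on one state path. A directional
# switch moves the pair from one coherent state to the opposite coherent
# state either directly (a joint switch) or through a run of a single
# incoherent state. The leading sister of a coherent state is the pulling
# one; if the first sister to switch is the leader the event is a LIDS,
# otherwise a TIDS.
classify_path_switches <- function(path) {
  runs <- rle(path)
  v <- runs$values
  start <- cumsum(c(1, runs$lengths))[seq_along(v)]
  out <- list()
  for (i in seq_along(v)[-1]) {
    prev <- v[i - 1]; cur <- v[i]
    if (is_coherent(prev) && is_coherent(cur) && prev != cur) {
      out[[length(out) + 1]] <- list(time_index = start[i], type = "joint")
    } else if (is_coherent(prev) && !is_coherent(cur) &&
               i < length(v) && is_coherent(v[i + 1]) && v[i + 1] != prev) {
      # leader is the sister in the pulling (-) state
      leader <- if (SIGMA1[prev] < 0) 1L else 2L
      changed1 <- SIGMA1[cur] != SIGMA1[prev]
      first <- if (changed1) 1L else 2L
      out[[length(out) + 1]] <- list(time_index = start[i],
                                     type = if (first == leader) "LIDS" else "TIDS")
    }
  }
  out
}

#' Classify directional-switch events from sampled state paths
#'
#' For every sampled hidden path, directional switches (coherent state to the
#' opposite coherent state) are located and classified as lead-initiated
#' (LIDS), trail-initiated (TIDS) or joint; events are aggregated by the
#' frame index at which the pair leaves its coherent state, and per-event
#' type probabilities are the fractions of sampled paths carrying a matching
#' event there.
#'
#' @param annotation a `state_annotation` from [sample_hidden_states()].
#' @param min_prob drop aggregated events whose total switch probability is
#'   below this (default 0.05).
#' @return object of class `switch_events`: data frame with `time_index`,
#'   `p_lids`, `p_tids`, `p_joint`, `p_any`; plus overall type proportions
#'   in attribute `totals`.
#' @export
classify_switches <- function(annotation, min_prob = 0.05) {
  n <- nrow(annotation$paths)
  counts <- list()
  for (d in seq_len(n)) {
    for (ev in classify_path_switches(annotation$paths[d, ])) {
      key <- as.character(ev$time_index)
      if (is.null(counts[[key]])) counts[[key]] <- c(LIDS = 0, TIDS = 0, joint = 0)
      counts[[key]][ev$type] <- counts[[key]][ev$type] + 1
    }
  }
  if (!length(counts)) {
    events <- data.frame(time_index = integer(0), p_lids = numeric(0),
                         p_tids = numeric(0), p_joint = numeric(0),
                         p_any = numeric(0))
  } else {
    events <- do.call(rbind, lapply(names(counts), function(k) {
      ct <- counts[[k]] / n
      data.frame(time_index = as.integer(k), p_lids = ct[["LIDS"]],
                 p_tids = ct[["TIDS"]], p_joint = ct[["joint"]],
                 p_any = sum(ct))
    }))
    events <- events[order(events$time_index), ]
    events <- events[events$p_any >= min_prob, ]
    rownames(events) <- NULL
  }
  tot <- colSums(events[, c("p_lids", "p_tids", "p_joint")])
  totals <- if (sum(tot) > 0) tot / sum(tot) else tot
  structure(events, totals = stats::setNames(totals, c("LIDS", "TIDS", "joint")),
            class = c("switch_events", "data.frame"))
}
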