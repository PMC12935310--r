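#' A cell's collection of sister-pair trajectories
#'
#' @param pairs list of [sister_pair_trajectory()] objects sharing the cell's
#'   time grid.
#' @param cell_id identifier; defaults to the pairs' common cell_id.
#' @param treatment label, e.g. "DMSO" or "nocodazole".
#' @param ground_truth optional per-pair generating record (synthetic data).
#' @return an object of class `cell_dataset`.
#' @export
cell_dataset <- function(pairs, cell_id = NULL, treatment = "DMSO",
                         ground_truth = NULL) {
  stopifnot(length(pairs) >= 1)
  if (is.null(cell_id)) cell_id <- pairs[[1]]$cell_id
  dts <- vapply(pairs, function(p) p$dt, 0)
  if (any(abs(dts - dts[1]) > 1e-9)) stop("pairs must share the cell time grid")
  structure(list(pairs = pairs, cell_id = cell_id, treatment = treatment,
                 ground_truth = ground_truth, dt = dts[1]),
            class = "cell_dataset")
}

#' @export
print.cell_dataset <- function(x, ...) {
  cat(sprintf("<cell_dataset %s (%s): %d pairs, dt = %.3g s>\n",
              x$cell_id, x$treatment, length(x$pairs), x$dt))
  invisible(x)
}

#' Quality-control filter for cells and trajectories
#'
#' Drops trajectories shorter than `min_frames` frames or with at least
#' `max_missing` missing data, then drops cells left with fewer than
#' `min_pairs` qualifying pairs.
#'
#' @param cells list of [cell_dataset()] objects.
#' @param min_frames minimum frame count per trajectory (default 120).
#' @param max_missing maximum tolerated missing fraction, exclusive bound
#'   (default 0.20).
#' @param min_pairs minimum qualifying pairs per retained cell (default 30).
#' @return list with `cells` (retained, containing only qualifying pairs) and
#'   `report` (data frame of per-cell counts and retention).
#' @export
qc_filter <- function(cells, min_frames = 120, max_missing = 0.20,
                      min_pairs = 30) {
  report <- do.call(rbind, lapply(cells, function(cell) {
    ok <- vapply(cell$pairs, function(p) {
      n_frames(p) >= min_frames && missing_fraction(p) < max_missing
    }, TRUE)
    data.frame(cell_id = cell$cell_id, n_pairs = length(cell$pairs),
               n_qualifying = sum(ok), retained = sum(ok) >= min_pairs)
  }))
  kept <- lapply(cells[report$retained], function(cell) {
    ok <- vapply(cell$pairs, function(p) {
      n_frames(p) >= min_frames && missing_fraction(p) < max_missing
    }, TRUE)
    cell$pairs <- cell$pairs[ok]
    cell
  })
  list(cells = kept, report = report)
}
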