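#' Select a decision threshold by F1 maximisation
#'
#' Pools scored residues from all targets (unknown labels excluded), sweeps
#' candidate thresholds, and returns the one maximising pooled F1 with the
#' `score >= threshold` call rule. The default grid is every distinct
#' observed score plus 0 and 1, which contains the exact optimum; a
#' fixed-step grid can be supplied for parity with assessments that
#' discretise. Ties are broken toward the smallest threshold (favours
#' sensitivity and is deterministic).
#'
#' @param scores Numeric vector of pooled per-residue scores.
#' @param labels Integer vector of pooled labels (0/1, `NA` = unknown,
#'   excluded before pooling).
#' @param grid Optional numeric vector of candidate thresholds.
#' @return A `threshold_calibration` object with `best_threshold`,
#'   `best_metric` and the per-threshold metric `curve`.
#' @examples
#' optimize_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
#' @export
optimize_threshold <- function(scores, labels, grid = NULL) {
  keep <- !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (length(scores) == 0L) abort("no labelled residues to calibrate on.")
  if (sum(labels == 1L) == 0L || sum(labels == 0L) == 0L) {
    abort("degenerate input: calibration needs both positive and negative labels.")
  }
  curve <- if (is.null(grid)) {
    f1_curve(scores, labels)[, c("threshold", "precision", "recall", "f1")]
  } else {
    purrr::map_dfr(sort(unique(grid)), function(t) {
      cc <- confusion_counts(scores, labels, t)
      tibble::tibble(threshold = t,
                     precision = if (cc$tp + cc$fp == 0) 0 else cc$tp / (cc$tp + cc$fp),
                     recall = if (cc$tp + cc$fn == 0) 0 else cc$tp / (cc$tp + cc$fn),
                     f1 = f1_score(cc))
    })
  }
  best <- which(curve$f1 == max(curve$f1))[1L]  # curve ascends in threshold
  structure(
    list(
      best_threshold = curve$threshold[best],
      best_metric = curve$f1[best],
      metric = "f1",
      curve = curve
    ),
    class = c("threshold_calibration", "disorder_calibration")
  )
}

#' Select the RSA smoothing window by grid search
#'
#' For each candidate window width the RSA profiles are re-smoothed, residues
#' pooled against the reference, and the maximum F1 over thresholds (Fmax)
#' recorded; the window with the highest Fmax wins, ties toward the smaller
#' window. Even widths are skipped with a warning (a centred window of
#' +/- h residues is necessarily odd). The F1 at a fixed threshold is
#' recorded alongside, since a flat Fmax plateau is the expected shape of
#' this search.
#'
#' @param profiles Tibble with `target_id`, `position` and raw (unsmoothed)
#'   `rsa` per residue.
#' @param ref Reference tibble (`target_id`, `position`, `label`).
#' @param windows Integer vector of candidate widths (default `seq(1, 49, 2)`,
#'   covering the conventional 1-50 search range).
#' @param fixed_threshold Threshold for the secondary per-window F1 column
#'   (default 0.581).
#' @param mirror Terminus convention passed to [windowed_mean()].
#' @return A `window_calibration` object with `best_window`, `best_metric`
#'   and the per-window `curve` (`window`, `fmax`, `fmax_threshold`,
#'   `f1_fixed`).
#' @export
window_grid_search <- function(profiles, ref, windows = seq(1L, 49L, 2L),
                               fixed_threshold = 0.581,
                               mirror = c("reflect", "duplicate")) {
  mirror <- match.arg(mirror)
  stopifnot(all(c("target_id", "position", "rsa") %in% names(profiles)))
  if (length(windows) == 0L) abort("empty window range.")
  even <- windows %% 2L == 0L
  if (any(even)) {
    warn(sprintf("skipping even window width(s): %s",
                 paste(windows[even], collapse = ", ")))
    windows <- windows[!even]
  }
  if (length(windows) == 0L) abort("no odd window widths to search.")
  joined <- dplyr::inner_join(
    profiles[, c("target_id", "position", "rsa")],
    ref[, c("target_id", "position", "label")],
    by = c("target_id", "position")
  )
  if (nrow(joined) == 0L) abort("no overlap between profiles and reference.")
  curve <- purrr::map_dfr(sort(unique(as.integer(windows))), function(w) {
    sm <- joined |>
      dplyr::group_by(.data$target_id) |>
      dplyr::mutate(score = windowed_mean(.data$rsa, w, mirror = mirror)) |>
      dplyr::ungroup()
    known <- sm[!is.na(sm$label), , drop = FALSE]
    fm <- fmax_score(known$score, known$label)
    tibble::tibble(
      window = w,
      fmax = fm$fmax,
      fmax_threshold = fm$threshold,
      f1_fixed = f1_score(confusion_counts(known$score, known$label,
                                           fixed_threshold))
    )
  })
  best <- which(curve$fmax == max(curve$fmax))[1L]  # ascending windows
  structure(
    list(
      best_window = curve$window[best],
      best_metric = curve$fmax[best],
      metric = "fmax",
      fixed_threshold = fixed_threshold,
      curve = curve
    ),
    class = c("window_calibration", "disorder_calibration")
  )
}

#' @export
print.threshold_calibration <- function(x, ...) {
  cat("<threshold_calibration>\n")
  cat(sprintf("  best threshold : %.4f (pooled F1 = %.4f)\n",
              x$best_threshold, x$best_metric))
  cat(sprintf("  curve          : %d candidate thresholds\n", nrow(x$curve)))
  invisible(x)
}

#' @export
print.window_calibration <- function(x, ...) {
  cat("<window_calibration>\n")
  cat(sprintf("  best window : %d residues (pooled Fmax = %.4f)\n",
              x$best_window, x$best_metric))
  cat(sprintf("  curve       : windows %d-%d\n",
              min(x$curve$window), max(x$curve$window)))
  invisible(x)
}
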