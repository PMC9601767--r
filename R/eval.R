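#' Pooled confusion counts at a threshold
#'
#' Residues from all targets are pooled into a single confusion matrix
#' (the CAID convention for headline metrics). Residues with unknown
#' reference label (`NA`) are excluded. A residue is called positive when
#' `score >= threshold`.
#'
#' @param scores Numeric vector of prediction scores.
#' @param labels Integer vector of reference labels (0/1, `NA` = unknown).
#' @param threshold Decision threshold.
#' @return One-row tibble with `tp`, `fp`, `tn`, `fn`.
#' @examples
#' confusion_counts(c(0.9, 0.1), c(1, 0), 0.5)
#' @export
confusion_counts <- function(scores, labels, threshold) {
  if (length(scores) != length(labels)) {
    abort("`scores` and `labels` lengths differ.")
  }
  keep <- !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  call <- scores >= threshold
  tibble::tibble(
    tp = sum(call & labels == 1L),
    fp = sum(call & labels == 0L),
    tn = sum(!call & labels == 0L),
    fn = sum(!call & labels == 1L)
  )
}

#' F1 score from confusion counts
#'
#' `precision = tp/(tp+fp)`, `recall = tp/(tp+fn)`, F1 their harmonic mean.
#' Degenerate conventions: precision is 0 when no residue is called,
#' recall is 0 when there are no positives, and F1 is 0 when
#' `precision + recall = 0`.
#'
#' @param counts One-row tibble (or list) with `tp`, `fp`, `fn`.
#' @return F1 in `[0, 1]`.
#' @examples
#' f1_score(confusion_counts(c(0.9, 0.6, 0.1), c(1, 0, 1), 0.5))
#' @export
f1_score <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

# precision/recall/F1 at every effective cut, vectorised over the sorted
# score sequence; thresholds are the distinct observed scores plus 0 and 1.
f1_curve <- function(scores, labels) {
  keep <- !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  npos <- sum(labels == 1L)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  ctp <- cumsum(l == 1L)
  cfp <- cumsum(l == 0L)
  last <- !duplicated(s, fromLast = TRUE)  # last index of each distinct score
  thr <- s[last]; tp <- ctp[last]; fp <- cfp[last]
  # add cuts above the max (nothing called) and at 0 (everything called)
  extra_thr <- setdiff(c(1, 0), thr)
  for (t in extra_thr) {
    called <- sum(s >= t)
    thr <- c(thr, t)
    tp <- c(tp, if (called) ctp[called] else 0L)
    fp <- c(fp, if (called) cfp[called] else 0L)
  }
  o <- order(thr)
  thr <- thr[o]; tp <- tp[o]; fp <- fp[o]
  fn <- npos - tp
  prec <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  rec <- if (npos == 0) rep(0, length(tp)) else tp / npos
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  tibble::tibble(threshold = thr, tp = tp, fp = fp, fn = fn,
                 precision = prec, recall = rec, f1 = f1)
}

#' Maximum F1 over all thresholds (Fmax)
#'
#' Evaluates pooled F1 at every distinct score value (plus the trivial cuts
#' 0 and 1) and returns the maximum; threshold ties are broken toward the
#' smallest threshold.
#'
#' @inheritParams confusion_counts
#' @return List with `fmax`, `threshold` and the precision-recall `curve`
#'   tibble.
#' @examples
#' fmax_score(c(0.2, 0.4, 0.6, 0.8), c(0, 1, 0, 1))$fmax
#' @export
fmax_score <- function(scores, labels) {
  keep <- !is.na(labels)
  if (!any(keep)) abort("empty evaluation: all reference labels unknown.")
  if (sum(labels[keep] == 1L) == 0L) {
    abort("degenerate evaluation: no positive reference residues.")
  }
  curve <- f1_curve(scores, labels)
  best <- which(curve$f1 == max(curve$f1))[1L]  # curve sorted by threshold
  list(fmax = curve$f1[best], threshold = curve$threshold[best], curve = curve)
}

#' ROC AUC on pooled residues
#'
#' Computed by the rank (Wilcoxon) formulation: the probability that a
#' random positive residue outscores a random negative one, with ties
#' counting one half. Equivalent to trapezoidal integration of the ROC curve.
#'
#' @inheritParams confusion_counts
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0))
#' @export
roc_auc <- function(scores, labels) {
  keep <- !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  npos <- sum(labels == 1L)
  nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L) {
    abort("AUC undefined: need at least one positive and one negative residue.")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' ROC curve points
#'
#' False/true positive rates at every distinct score cut (descending), with
#' the trivial endpoints (0,0) and (1,1).
#'
#' @inheritParams confusion_counts
#' @return Tibble with `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  keep <- !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  last <- !duplicated(s, fromLast = TRUE)
  tp <- cumsum(l == 1L)[last]
  fp <- cumsum(l == 0L)[last]
  tibble::tibble(
    threshold = c(Inf, s[last], -Inf),
    fpr = c(0, fp / max(1L, nneg), 1),
    tpr = c(0, tp / max(1L, npos), 1)
  )
}

#' Benchmark coverage
#'
#' Fraction of reference targets for which predictions are available:
#' `|predicted intersect reference| / |reference|`. Reported to 2 decimals in
#' summaries; the full-precision value is returned.
#'
#' @param pred_ids Character vector of predicted target ids.
#' @param ref_ids Character vector of reference target ids.
#' @return Coverage in `[0, 1]` at full precision.
#' @examples
#' round(coverage(paste0("T", 1:489), paste0("T", 1:645)), 2)
#' @export
coverage <- function(pred_ids, ref_ids) {
  ref <- unique(ref_ids)
  if (length(ref) == 0L) abort("empty reference target set.")
  length(intersect(unique(pred_ids), ref)) / length(ref)
}

#' Fully-disordered protein calls
#'
#' A protein is called fully disordered when the fraction of its residues
#' with a positive binary call reaches `fraction_threshold` (default 0.95,
#' with the `>=` rule). The criterion is a documented dialect of this
#' implementation; near-total thresholds are conventional for this
#' classification.
#'
#' @param data Tibble with `target_id` and a binary call column.
#' @param call Name of the call column (default `"call"`).
#' @param fraction_threshold Fraction in `(0, 1]` (default 0.95).
#' @return Tibble with `target_id`, `n_residues`, `fraction_called`,
#'   `fully_disordered` (logical).
#' @export
fully_disordered <- function(data, call = "call", fraction_threshold = 0.95) {
  if (nrow(data) == 0L) abort("empty prediction track.")
  if (!call %in% names(data)) {
    abort(sprintf("call column '%s' not found.", call))
  }
  data |>
    dplyr::group_by(.data$target_id) |>
    dplyr::summarise(
      n_residues = dplyr::n(),
      fraction_called = mean(.data[[call]] == 1L),
      .groups = "drop"
    ) |>
    dplyr::mutate(fully_disordered = .data$fraction_called >= fraction_threshold)
}

#' CAID-style evaluation of a prediction set
#'
#' Matches predictions to references by target id, pools residues with known
#' labels into one confusion matrix, and computes Fmax (maximum F1 over all
#' thresholds), ROC AUC, the precision-recall and ROC curves, and target
#' coverage. Reference targets without predictions are excluded from residue
#' pooling and only lower the coverage (the CAID convention); per-target
#' metrics are available with `per_target = TRUE`.
#'
#' @param pred Tibble of predictions with `target_id`, `position`, `score`
#'   (e.g. one variant of [prediction_tracks()]).
#' @param ref Reference tibble from [read_caid_reference()] (`target_id`,
#'   `position`, `label` with `NA` for unknown).
#' @param variant Optional tag for the dataset variant (e.g. `"DisProt"`,
#'   `"DisProt-PDB"`, `"DisProt-binding"`).
#' @param per_target Also compute per-target F1-at-Fmax-threshold summaries.
#' @return A `caid_evaluation` object; see [glance.caid_evaluation()] and
#'   [tidy.caid_evaluation()].
#' @export
caid_evaluate <- function(pred, ref, variant = NULL, per_target = FALSE) {
  stopifnot(all(c("target_id", "position", "score") %in% names(pred)),
            all(c("target_id", "position", "label") %in% names(ref)))
  cov <- coverage(pred$target_id, ref$target_id)
  matched <- intersect(unique(pred$target_id), unique(ref$target_id))
  if (length(matched) == 0L) {
    abort("empty evaluation: no overlap between predicted and reference targets.")
  }
  # length consistency per matched target
  np <- table(pred$target_id[pred$target_id %in% matched])
  nr <- table(ref$target_id[ref$target_id %in% matched])
  bad <- matched[as.integer(np[matched]) != as.integer(nr[matched])]
  if (length(bad)) {
    abort(sprintf("prediction/reference length mismatch for target '%s'", bad[1L]))
  }
  joined <- dplyr::inner_join(
    pred[pred$target_id %in% matched, c("target_id", "position", "score")],
    ref[, c("target_id", "position", "label")],
    by = c("target_id", "position")
  )
  known <- joined[!is.na(joined$label), , drop = FALSE]
  fm <- fmax_score(known$score, known$label)
  auc <- roc_auc(known$score, known$label)
  per_tgt <- NULL
  if (per_target) {
    per_tgt <- known |>
      dplyr::group_by(.data$target_id) |>
      dplyr::summarise(
        f1 = f1_score(confusion_counts(.data$score, .data$label, fm$threshold)),
        auc = tryCatch(roc_auc(.data$score, .data$label),
                       error = function(e) NA_real_),
        .groups = "drop"
      )
  }
  structure(
    list(
      variant = variant,
      fmax = fm$fmax,
      fmax_threshold = fm$threshold,
      auc = auc,
      pr_curve = fm$curve,
      roc_curve = roc_curve(known$score, known$label),
      coverage = cov,
      n_targets = length(matched),
      n_reference_targets = length(unique(ref$target_id)),
      n_residues = nrow(known),
      n_unknown = nrow(joined) - nrow(known),
      per_target = per_tgt
    ),
    class = "caid_evaluation"
  )
}

#' @export
print.caid_evaluation <- function(x, ...) {
  cat(sprintf("<caid_evaluation>%s\n",
              if (is.null(x$variant)) "" else paste0(" [", x$variant, "]")))
  cat(sprintf("  Fmax     : %.3f (threshold %.3f)\n", x$fmax, x$fmax_threshold))
  cat(sprintf("  AUC      : %.3f\n", x$auc))
  cat(sprintf("  coverage : %.2f (%d of %d targets)\n", x$coverage,
              x$n_targets, x$n_reference_targets))
  cat(sprintf("  residues : %d evaluated, %d unknown excluded\n",
              x$n_residues, x$n_unknown))
  invisible(x)
}
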