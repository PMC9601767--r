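#' pLDDT-based disorder score
#'
#' Low model confidence tracks intrinsic disorder, so the score is simply
#' `1 - pLDDT/100`. At the default decision threshold 0.312 a residue is
#' called disordered exactly when its pLDDT is below 68.8%.
#'
#' @param plddt_percent Numeric vector of pLDDT values on the 0-100 scale.
#' @return Numeric vector of disorder scores in `[0, 1]`.
#' @examples
#' plddt_disorder(c(100, 68.8, 0))
#' @export
plddt_disorder <- function(plddt_percent) {
  if (any(!is.finite(plddt_percent)) ||
      any(plddt_percent < 0 | plddt_percent > 100)) {
    abort("`plddt_percent` must lie in [0, 100].")
  }
  1 - plddt_percent / 100
}

#' Sliding-window mean with mirrored termini
#'
#' Smooths a per-residue profile with a centred window of odd width. Near the
#' termini the window is completed by mirroring: with the default `"reflect"`
#' convention the profile is reflected about the terminal element without
#' duplicating it (0-based index `-k` maps to `+k`, and `N-1+k` to `N-1-k`);
#' for windows wider than the sequence the reflection repeats. The
#' `"duplicate"` convention (edge element repeated: `-k` maps to `k-1`) is
#' available for parity with other implementations.
#'
#' @param values Numeric vector (length >= 1).
#' @param window Odd positive integer window width.
#' @param mirror `"reflect"` (default) or `"duplicate"`.
#' @return Numeric vector of the same length.
#' @examples
#' windowed_mean(c(1, 0, 0, 0, 0), 3)  # first element: mean(v[2], v[1], v[2])
#' @export
windowed_mean <- function(values, window, mirror = c("reflect", "duplicate")) {
  mirror <- match.arg(mirror)
  check_window(window)
  n <- length(values)
  if (n == 0L) return(numeric(0))
  if (n == 1L || window == 1L) return(values)
  h <- (window - 1L) %/% 2L
  offsets <- -h:h
  # closed-form reflected index (0-based); handles any window width
  idx <- outer(seq_len(n) - 1L, offsets, `+`)
  idx <- if (mirror == "reflect") {
    p <- 2L * (n - 1L)
    m <- idx %% p
    ifelse(m < n, m, p - m)
  } else {
    p <- 2L * n
    m <- idx %% p
    ifelse(m < n, m, p - 1L - m)
  }
  rowMeans(matrix(values[idx + 1L], nrow = n))
}

#' Windowed RSA disorder score
#'
#' The RSA-based disorder score of a residue is the mean relative solvent
#' accessibility over a local window centred on it (default 25 residues,
#' i.e. +/- 12), with mirrored termini.
#'
#' @param data Residue tibble carrying an `rsa` column (see
#'   [add_accessibility()]).
#' @param config A [score_config()].
#' @return `data` with a `score_RSA` column appended.
#' @export
rsa_disorder <- function(data, config = score_config()) {
  if (!"rsa" %in% names(data) || anyNA(data$rsa)) {
    abort("`data` must carry a complete `rsa` column; run add_accessibility() first.")
  }
  data |>
    dplyr::group_by(.data$target_id) |>
    dplyr::mutate(score_RSA = windowed_mean(.data$rsa, config$window,
                                            mirror = config$mirror)) |>
    dplyr::ungroup()
}

#' Conditional-folding (disordered binding) score
#'
#' Combines accessibility and confidence: regions that are simultaneously
#' solvent exposed (high windowed RSA) and confidently modelled (high pLDDT)
#' are candidate disordered binding / conditional-folding regions. The score
#' is piecewise in the windowed RSA score `s` with pivot `T`:
#' \deqn{Bind = s \quad (s \le T), \qquad Bind = T + p\,(1 - T) \quad (s > T),}
#' where `p = pLDDT/100`. Rescaling the pLDDT term by `1 - T` keeps the score
#' in `[0, 1]`; at `s = T` the `<=` branch applies. The pLDDT operand is the
#' raw per-residue value (only RSA is window-smoothed).
#'
#' @param rsa_score Numeric vector of windowed RSA scores in `[0, 1]`.
#' @param plddt_percent Numeric vector of pLDDT values in `[0, 100]`.
#' @param config A [score_config()]; supplies the pivot `T` (default 0.581).
#' @return Numeric vector of binding scores in `[0, 1]`.
#' @examples
#' bind_score(0.70, 50)  # 0.581 + 0.5 * 0.419
#' @export
bind_score <- function(rsa_score, plddt_percent, config = score_config()) {
  T <- config$T
  if (!is.numeric(T) || T <= 0 || T >= 1) {
    abort("bind pivot `T` must lie strictly inside (0, 1).")
  }
  p <- plddt_percent / 100
  ifelse(rsa_score <= T, rsa_score, T + p * (1 - T))
}

#' Per-residue disorder and conditional-folding prediction
#'
#' Full pipeline: residue table, solvent accessibility, the three scores and
#' their binary calls (a residue is called positive when its score is greater
#' than or equal to the variant's threshold).
#'
#' @param x A `structure_model` from [read_structure()], or a path to a
#'   PDB/mmCIF file.
#' @param config A [score_config()].
#' @param chain Chain identifier; default the first chain.
#' @return Tibble with one row per residue and columns `target_id`,
#'   `position`, `aa`, `plddt_percent`, `score_pLDDT`, `rsa_raw`, `score_RSA`,
#'   `score_Bind`, `call_pLDDT`, `call_RSA`, `call_Bind`.
#' @examples
#' pdb <- system.file("extdata", "tiny_model.pdb", package = "afdisorder")
#' predict_disorder(pdb, score_config(n_points = 120))
#' @export
predict_disorder <- function(x, config = score_config(), chain = NULL) {
  model <- if (inherits(x, "structure_model")) x else read_structure(x)
  res <- residue_table(model, chain = chain)
  res <- add_accessibility(res, model, config = config, chain = chain)
  res <- rsa_disorder(res, config = config)
  res |>
    dplyr::mutate(
      score_pLDDT = plddt_disorder(.data$plddt_percent),
      score_Bind = bind_score(.data$score_RSA, .data$plddt_percent, config),
      rsa_raw = .data$rsa,
      call_pLDDT = as.integer(.data$score_pLDDT >= config$thr_plddt),
      call_RSA = as.integer(.data$score_RSA >= config$thr_rsa),
      call_Bind = as.integer(.data$score_Bind >= config$thr_bind)
    ) |>
    dplyr::select("target_id", "position", "aa", "plddt_percent",
                  "score_pLDDT", "rsa_raw", "score_RSA", "score_Bind",
                  "call_pLDDT", "call_RSA", "call_Bind")
}

#' Long-format prediction tracks
#'
#' Reshapes a wide prediction table (one column pair per score variant) into
#' one row per residue and variant, convenient for evaluation and plotting.
#'
#' @param data Prediction tibble from [predict_disorder()].
#' @return Tibble with `target_id`, `position`, `aa`, `variant`
#'   (`"pLDDT"`, `"RSA"`, `"Bind"`), `score`, `call`.
#' @export
prediction_tracks <- function(data) {
  scores <- data |>
    dplyr::select("target_id", "position", "aa",
                  pLDDT = "score_pLDDT", RSA = "score_RSA",
                  Bind = "score_Bind") |>
    tidyr::pivot_longer(c("pLDDT", "RSA", "Bind"),
                        names_to = "variant", values_to = "score")
  calls <- data |>
    dplyr::select("target_id", "position",
                  pLDDT = "call_pLDDT", RSA = "call_RSA",
                  Bind = "call_Bind") |>
    tidyr::pivot_longer(c("pLDDT", "RSA", "Bind"),
                        names_to = "variant", values_to = "call")
  dplyr::left_join(scores, calls, by = c("target_id", "position", "variant"))
}
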