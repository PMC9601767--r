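#' Method configuration
#'
#' Bundles every tunable constant of the disorder/conditional-folding method:
#' the RSA smoothing window, the three decision thresholds, the pivot `T` of
#' the binding score, and the solvent-accessibility dialect (probe radius,
#' sphere sample count, van der Waals radii, maximum-ASA table, mirroring
#' convention).
#'
#' Defaults are the published operating point of the method: a 25-residue
#' window (centre +/- 12), decision thresholds 0.312 (pLDDT score, i.e.
#' pLDDT < 68.8%), 0.581 (RSA score) and 0.773 (binding score), with the
#' binding pivot `T` equal to the RSA threshold.
#'
#' @param window Odd positive integer; width of the local RSA averaging
#'   window in residues. Default 25.
#' @param thr_plddt,thr_rsa,thr_bind Decision thresholds in `[0, 1]` for the
#'   pLDDT, RSA and binding scores (binary call is `score >= threshold`).
#' @param T Pivot of the piecewise binding score, in `(0, 1)`. Defaults to
#'   `thr_rsa`.
#' @param probe_radius Solvent probe radius in Angstrom. Default 1.4.
#' @param n_points Number of sphere sample points per atom for the
#'   Shrake-Rupley engine. Default 960.
#' @param radii Named numeric vector of van der Waals radii (Angstrom) by
#'   element symbol; see [vdw_radii()].
#' @param radius_default Radius (Angstrom) used for elements absent from
#'   `radii`. Default 1.8.
#' @param max_asa_dialect Which Gly-X-Gly maximum-accessibility table
#'   normalises residue ASA to RSA: `"sander"` (Sander & Rost empirical
#'   values, the default) or `"tien"` (theoretical values).
#' @param mirror Terminus handling of the sliding window: `"reflect"`
#'   (default; reflection about the terminal residue without duplicating it)
#'   or `"duplicate"` (edge-duplicating reflection), kept as a switchable
#'   dialect for parity experiments.
#'
#' @return An object of class `score_config` (a named list).
#' @examples
#' cfg <- score_config()
#' cfg$thr_rsa
#' score_config(window = 15, max_asa_dialect = "tien")
#' @export
score_config <- function(window = 25,
                         thr_plddt = 0.312,
                         thr_rsa = 0.581,
                         thr_bind = 0.773,
                         T = thr_rsa,
                         probe_radius = 1.4,
                         n_points = 960,
                         radii = vdw_radii(),
                         radius_default = 1.8,
                         max_asa_dialect = c("sander", "tien"),
                         mirror = c("reflect", "duplicate")) {
  max_asa_dialect <- match.arg(max_asa_dialect)
  mirror <- match.arg(mirror)
  check_window(window)
  for (nm in c("thr_plddt", "thr_rsa", "thr_bind")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      abort(sprintf("`%s` must be a single number in [0, 1].", nm))
    }
  }
  if (!is.numeric(T) || length(T) != 1L || is.na(T) || T <= 0 || T >= 1) {
    abort("`T` must be a single number strictly inside (0, 1).")
  }
  if (!is.numeric(probe_radius) || probe_radius < 0) {
    abort("`probe_radius` must be a non-negative number.")
  }
  if (!is.numeric(n_points) || n_points < 2) {
    abort("`n_points` must be an integer >= 2.")
  }
  if (any(radii <= 0) || radius_default <= 0) {
    abort("van der Waals radii must all be positive.")
  }
  structure(
    list(
      window = as.integer(window),
      thr_plddt = thr_plddt,
      thr_rsa = thr_rsa,
      thr_bind = thr_bind,
      T = T,
      probe_radius = probe_radius,
      n_points = as.integer(n_points),
      radii = radii,
      radius_default = radius_default,
      max_asa_dialect = max_asa_dialect,
      mirror = mirror
    ),
    class = "score_config"
  )
}

check_window <- function(window) {
  if (!is.numeric(window) || length(window) != 1L || is.na(window) ||
      window < 1 || window != as.integer(window) || window %% 2 == 0) {
    abort("`window` must be an odd positive integer.")
  }
  invisible(as.integer(window))
}

#' @export
print.score_config <- function(x, ...) {
  cat("<score_config>\n")
  cat(sprintf("  window        : %d residues (+/- %d)\n", x$window, (x$window - 1L) %/% 2L))
  cat(sprintf("  thresholds    : pLDDT %.3f | RSA %.3f | Bind %.3f (call rule: score >= thr)\n",
              x$thr_plddt, x$thr_rsa, x$thr_bind))
  cat(sprintf("  bind pivot T  : %.3f\n", x$T))
  cat(sprintf("  SASA          : probe %.2f A, %d points/atom, max-ASA '%s', mirror '%s'\n",
              x$probe_radius, x$n_points, x$max_asa_dialect, x$mirror))
  invisible(x)
}

#' Van der Waals radii for protein heavy atoms
#'
#' A compact protein vdW set: C 1.70, N 1.55, O 1.52, S 1.80 Angstrom.
#' Elements not listed fall back to the configured default (1.8 Angstrom).
#'
#' @return Named numeric vector of radii in Angstrom.
#' @export
vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
}

# Maximum accessibility (A^2) of residue X in an extended Gly-X-Gly
# tripeptide. "sander": Sander & Rost empirical values; "tien": theoretical
# values. Both cover the 20 standard amino acids; 'X' uses the Gly value
# (conservative: smallest denominator short of Gly itself is irrelevant
# for backbone-only synthetic chains, and unknown residues are rare).
.max_asa_tables <- list(
  sander = c(
    A = 106, R = 248, N = 157, D = 163, C = 135, Q = 198, E = 194,
    G = 84, H = 184, I = 169, L = 164, K = 205, M = 188, F = 197,
    P = 136, S = 130, T = 142, W = 227, Y = 222, V = 142
  ),
  tien = c(
    A = 129, R = 274, N = 195, D = 193, C = 167, Q = 225, E = 223,
    G = 104, H = 224, I = 197, L = 201, K = 236, M = 224, F = 240,
    P = 159, S = 155, T = 172, W = 285, Y = 263, V = 174
  )
)

#' Maximum-accessibility (Gly-X-Gly) normalisation table
#'
#' Per-residue maximum solvent accessibility of X in a fully extended
#' Gly-X-Gly tripeptide, used to normalise absolute ASA to relative solvent
#' accessibility (RSA). Two dialects are shipped: the Sander-Rost empirical
#' values (default) and the theoretical Tien values. Unknown residues
#' (one-letter code `X`) normalise by the glycine value.
#'
#' @param dialect `"sander"` or `"tien"`.
#' @return Named numeric vector (one-letter amino-acid code to max ASA in
#'   square Angstrom), including an `X` entry.
#' @examples
#' max_asa_table()[["G"]]
#' @export
max_asa_table <- function(dialect = c("sander", "tien")) {
  dialect <- match.arg(dialect)
  tab <- .max_asa_tables[[dialect]]
  if (any(tab <= 0)) abort("max-ASA table contains a non-positive value.")
  c(tab, X = unname(tab[["G"]]))
}

#' Read a key = value configuration file
#'
#' Parses a plain-text file of `key = value` lines (lines starting with `#`
#' and blank lines ignored) and materialises a [score_config()] with those
#' fields overridden. Recognised keys are the arguments of [score_config()]
#' except `radii`.
#'
#' @param path Path to the configuration file.
#' @param base A `score_config` supplying defaults for keys not present.
#' @return A `score_config`.
#' @export
read_score_config <- function(path, base = score_config()) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) abort(sprintf("malformed config line: %s", lines[bad][1]))
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  allowed <- c("window", "thr_plddt", "thr_rsa", "thr_bind", "T",
               "probe_radius", "n_points", "radius_default",
               "max_asa_dialect", "mirror")
  unknown <- setdiff(keys, allowed)
  if (length(unknown)) abort(sprintf("unknown config key: %s", unknown[1]))
  args <- unclass(base)
  for (i in seq_along(keys)) {
    v <- vals[i]
    args[[keys[i]]] <- if (keys[i] %in% c("max_asa_dialect", "mirror")) v else as.numeric(v)
  }
  do.call(score_config, args)
}
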