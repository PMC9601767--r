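#' Shrake-Rupley solvent accessible surface area
#'
#' Per-atom SASA by sphere sampling: each atom's solvent-expanded sphere
#' (van der Waals radius + probe radius) is covered with a quasi-uniform
#' golden-spiral point lattice; a point is exposed when it lies outside every
#' other atom's expanded sphere, and
#' `SASA = exposed fraction * 4 * pi * (r_vdw + r_probe)^2`.
#' The neighbour search is restricted to atoms within
#' `r_i + r_j + 2 * probe` of each other.
#'
#' @param xyz Numeric matrix (n x 3) of atom coordinates in Angstrom.
#' @param elements Character vector of element symbols (length n).
#' @param radii Named vector of van der Waals radii; see [vdw_radii()].
#' @param radius_default Radius for elements absent from `radii` (1.8 A).
#' @param probe_radius Solvent probe radius in Angstrom (default 1.4).
#' @param n_points Sphere sample points per atom (default 960; must be >= 2).
#' @return Numeric vector of per-atom SASA in square Angstrom.
#' @examples
#' # an isolated carbon atom: SASA = 4 * pi * (1.7 + 1.4)^2
#' shrake_rupley(matrix(0, 1, 3), "C")
#' @export
shrake_rupley <- function(xyz, elements,
                          radii = vdw_radii(), radius_default = 1.8,
                          probe_radius = 1.4, n_points = 960) {
  if (is.data.frame(xyz)) xyz <- as.matrix(xyz)
  if (!is.matrix(xyz) || ncol(xyz) != 3L || nrow(xyz) == 0L) {
    abort("`xyz` must be a non-empty n x 3 coordinate matrix.")
  }
  if (!all(is.finite(xyz))) abort("coordinates must be finite (no NA/NaN/Inf).")
  if (length(elements) != nrow(xyz)) {
    abort("`elements` must have one symbol per atom.")
  }
  if (n_points < 2) abort("`n_points` must be >= 2.")
  n <- nrow(xyz)
  r <- unname(radii[toupper(elements)])
  r[is.na(r)] <- radius_default
  R <- r + probe_radius  # expanded radii
  pts <- golden_spiral_points(as.integer(n_points))

  # candidate neighbours: pairwise centre distance < R_i + R_j
  d2 <- as.matrix(stats::dist(xyz))^2
  out <- numeric(n)
  for (i in seq_len(n)) {
    cutoff2 <- (R[i] + R[-i])^2
    nb <- which(d2[i, -i] < cutoff2)
    nb <- setdiff(seq_len(n)[-i][nb], i)
    area <- 4 * pi * R[i]^2
    if (length(nb) == 0L) {
      out[i] <- area
      next
    }
    p <- sweep(pts * R[i], 2L, xyz[i, ], "+")  # sample points on sphere i
    exposed <- rep(TRUE, nrow(p))
    # squared distance from each sample point to each neighbour centre
    nb_xyz <- xyz[nb, , drop = FALSE]
    pd2 <- outer(rowSums(p^2), rep(1, length(nb))) +
      outer(rep(1, nrow(p)), rowSums(nb_xyz^2)) -
      2 * p %*% t(nb_xyz)
    exposed <- rowSums(pd2 < rep(R[nb]^2, each = nrow(p))) == 0L
    out[i] <- mean(exposed) * area
  }
  out
}

# quasi-uniform points on the unit sphere (Fibonacci / golden-spiral lattice)
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (3 - sqrt(5)) * (i - 0.5)
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(x = s * cos(phi), y = s * sin(phi), z = z)
}

#' Add per-residue accessibility to a residue table
#'
#' Runs the Shrake-Rupley engine over the model's heavy atoms, sums atom SASA
#' within each residue (`asa`), and normalises by the Gly-X-Gly maximum
#' accessibility of the residue type to give relative solvent accessibility
#' (`rsa`), clamped to `[0, 1]`. Hydrogens, if present, are excluded.
#'
#' @param data Residue tibble from [residue_table()].
#' @param model The `structure_model` the residues came from.
#' @param config A [score_config()] supplying probe radius, sample count,
#'   radii and the max-ASA dialect.
#' @param chain Chain identifier; default the first chain.
#' @return `data` with columns `asa` (square Angstrom) and `rsa` appended.
#' @export
add_accessibility <- function(data, model, config = score_config(),
                              chain = NULL) {
  stopifnot(inherits(model, "structure_model"))
  atoms <- model$atoms
  chain <- chain %||% unique(atoms$chain)[1L]
  atoms <- atoms[atoms$chain == chain & atoms$elesy != "H", , drop = FALSE]
  sasa <- shrake_rupley(
    as.matrix(atoms[, c("x", "y", "z")]), atoms$elesy,
    radii = config$radii, radius_default = config$radius_default,
    probe_radius = config$probe_radius, n_points = config$n_points
  )
  per_res <- tibble::tibble(position = atoms$resno, sasa = sasa) |>
    dplyr::group_by(.data$position) |>
    dplyr::summarise(asa = sum(.data$sasa), .groups = "drop")
  out <- dplyr::left_join(data, per_res, by = "position")
  if (anyNA(out$asa)) abort("residues without atoms encountered in SASA step")
  out$rsa <- relative_accessibility(out$asa, out$aa,
                                    table = max_asa_table(config$max_asa_dialect))
  out
}

#' Relative solvent accessibility
#'
#' `RSA = min(1, ASA / maxASA(aa))`. The clamp at 1 keeps downstream scores
#' inside `[0, 1]`; absolute ASA can exceed the tabulated Gly-X-Gly maximum
#' for unusual conformations. Unknown residues (`X`) normalise by the glycine
#' value.
#'
#' @param asa Numeric vector of residue ASA in square Angstrom (>= 0).
#' @param aa Character vector of one-letter amino-acid codes.
#' @param table Named max-ASA vector; see [max_asa_table()].
#' @return Numeric vector of RSA values in `[0, 1]`.
#' @examples
#' relative_accessibility(c(0, 84, 120), c("G", "G", "G"))
#' @export
relative_accessibility <- function(asa, aa, table = max_asa_table()) {
  if (any(table <= 0)) abort("max-ASA table must be strictly positive.")
  aa <- toupper(aa)
  aa[!aa %in% names(table)] <- "X"
  mx <- unname(table[aa])
  pmin(1, pmax(0, asa / mx))
}
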