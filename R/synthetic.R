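#' Segment specification for a synthetic structure
#'
#' Describes a single-chain synthetic model as an ordered list of segments.
#' Geometries: `"helix"` (ideal alpha-helical backbone: 1.5 A rise, 100
#' degrees twist per residue), `"extended"` (straight chain, 3.5 A per
#' residue — solvent exposed), `"core"` (residues packed on a compact 3.8 A
#' lattice so interior residues are occluded). Ground-truth labels:
#' `"order"`, `"disorder"`, `"binding"` (the conditional-folding case:
#' exposed geometry with high pLDDT).
#'
#' @param length Integer vector of segment lengths (>= 1).
#' @param geometry Character vector in `{"helix", "extended", "core"}`.
#' @param plddt Numeric vector of per-segment pLDDT values in `[0, 100]`.
#' @param label Character vector in `{"order", "disorder", "binding"}`.
#' @return A tibble with one row per segment (class `synthetic_spec`).
#' @examples
#' synthetic_spec(c(27, 15), c("core", "extended"), c(95, 30),
#'                c("order", "disorder"))
#' @export
synthetic_spec <- function(length, geometry, plddt, label) {
  geometry <- match.arg(geometry, c("helix", "extended", "core"),
                        several.ok = TRUE)
  label <- match.arg(label, c("order", "disorder", "binding"),
                     several.ok = TRUE)
  if (any(length < 1)) abort("segment lengths must be >= 1.")
  if (any(plddt < 0 | plddt > 100)) abort("segment pLDDT must lie in [0, 100].")
  spec <- tibble::tibble(length = as.integer(length), geometry = geometry,
                         plddt = plddt, label = label)
  class(spec) <- c("synthetic_spec", class(spec))
  spec
}

#' Build a synthetic structure model with known ground truth
#'
#' Deterministically (given `seed`) generates backbone coordinates (N, CA, C,
#' O; all-glycine sequence) for the segments of a [synthetic_spec()], sets
#' every atom's B-factor to its segment's pLDDT, and returns the model
#' together with per-residue reference labels. Coordinates receive a small
#' seeded jitter (+/- 0.1 A) to avoid degenerate exact-contact geometry; if
#' any two atoms still fall closer than 1 A the model is regenerated with a
#' fresh jitter (construction error after repeated failures).
#'
#' @param spec A [synthetic_spec()].
#' @param target_id Identifier for the generated model.
#' @param seed Integer seed controlling the jitter.
#' @return List with `model` (a `structure_model`) and `reference`, a tibble
#'   with `target_id`, `position`, `aa`, `label` (segment label),
#'   `label_disorder` (1 for disorder and binding segments, 0 for order) and
#'   `label_binding` (1 for binding segments only).
#' @examples
#' spec <- synthetic_spec(27, "core", 95, "order")
#' build_model(spec, "demo", seed = 1)$model
#' @export
build_model <- function(spec, target_id = "synthetic", seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  for (attempt in 1:5) {
    atoms <- withr::with_seed(seed + (attempt - 1L) * 997L,
                              generate_backbone(spec))
    d <- stats::dist(as.matrix(atoms[, c("x", "y", "z")]))
    if (min(d) >= 1.0) {
      model <- structure(
        list(target_id = target_id, atoms = atoms),
        class = "structure_model"
      )
      n <- sum(spec$length)
      lab <- rep(spec$label, spec$length)
      reference <- tibble::tibble(
        target_id = target_id,
        position = seq_len(n),
        aa = "G",
        label = lab,
        label_disorder = as.integer(lab %in% c("disorder", "binding")),
        label_binding = as.integer(lab == "binding")
      )
      return(list(model = model, reference = reference))
    }
  }
  abort("construction error: atoms overlap (< 1 A) after repeated jitter.")
}

# backbone generator: CA trace per segment geometry, then N/C/O placed in a
# local frame along the chain direction
generate_backbone <- function(spec) {
  ca <- matrix(numeric(0), ncol = 3)
  radial <- matrix(numeric(0), ncol = 3)  # outward normal for helix residues
  cursor <- 0
  for (k in seq_len(nrow(spec))) {
    len <- spec$length[k]
    seg <- switch(spec$geometry[k],
      extended = cbind(cursor + 3.5 * (seq_len(len) - 1), 0, 0),
      helix = {
        th <- (seq_len(len) - 1) * 100 * pi / 180
        cbind(cursor + 1.5 * (seq_len(len) - 1), 2.3 * cos(th), 2.3 * sin(th))
      },
      core = {
        m <- ceiling(len^(1 / 3))
        idx <- seq_len(len) - 1L
        a <- idx %% m
        b <- (idx %/% m) %% m
        cc <- idx %/% (m * m)
        # serpentine fill keeps consecutive residues on adjacent sites
        a <- ifelse(b %% 2L == 1L, m - 1L - a, a)
        b <- ifelse(cc %% 2L == 1L, m - 1L - b, b)
        cbind(cursor + a * 3.8, (b - (m - 1) / 2) * 3.8, (cc - (m - 1) / 2) * 3.8)
      }
    )
    ca <- rbind(ca, seg)
    radial <- rbind(radial, if (spec$geometry[k] == "helix") {
      th <- (seq_len(len) - 1) * 100 * pi / 180
      cbind(0, cos(th), sin(th))
    } else {
      matrix(NA_real_, nrow = len, ncol = 3)
    })
    cursor <- max(seg[, 1]) + 5.5
  }
  n <- nrow(ca)
  ca <- ca + matrix(runif(3 * n, -0.1, 0.1), ncol = 3)
  # chain direction per residue; last residue reuses the previous direction
  d <- rbind(diff(ca), if (n > 1) diff(ca)[n - 1L, , drop = FALSE] else c(1, 0, 0))
  d <- d / sqrt(rowSums(d^2))
  # perpendicular from a fixed oblique reference vector: u varies smoothly
  # along the chain and never flips sign at lattice turns
  g <- c(0.3, 0.5, 0.81)
  g <- g / sqrt(sum(g^2))
  u <- matrix(g, nrow = n, ncol = 3, byrow = TRUE) - (d %*% g)[, 1] * d
  len_u <- sqrt(rowSums(u^2))
  bad <- len_u < 1e-6
  u[bad, ] <- matrix(rep(c(0, 1, 0), sum(bad)), ncol = 3, byrow = TRUE)
  # helix residues use the outward radial normal instead: carbonyls splay
  # away from the axis, keeping consecutive O atoms apart despite the twist
  hel <- !is.na(radial[, 1])
  u[hel, ] <- radial[hel, ]
  u <- u - (rowSums(u * d)) * d  # re-orthogonalise against the chain direction
  u <- u / pmax(sqrt(rowSums(u^2)), 1e-12)
  plddt <- rep(spec$plddt, spec$length)
  per_res <- function(name, pos) {
    tibble::tibble(
      chain = "A", resno = seq_len(n), resid = "GLY", elety = name,
      elesy = substr(name, 1, 1),
      x = pos[, 1], y = pos[, 2], z = pos[, 3],
      b = plddt, o = 1
    )
  }
  # staggered offsets keep nominal inter-atom distances >= 1.25 A, so the
  # +/- 0.1 A jitter cannot push any pair below the 1 A contact floor
  atoms <- dplyr::bind_rows(
    per_res("N", ca - 1.2 * d - 0.4 * u),
    per_res("CA", ca),
    per_res("C", ca + 1.2 * d + 0.4 * u),
    per_res("O", ca + 1.2 * d + 1.63 * u)
  ) |>
    dplyr::arrange(.data$resno, factor(.data$elety, c("N", "CA", "C", "O")))
  atoms
}

#' Write a structure model as a PDB file
#'
#' Fixed-format ATOM records (wwPDB v3.3 columns) with the model's B-factor
#' column intact; output is deterministic, so identical models yield
#' byte-identical files.
#'
#' @param model A `structure_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  lines <- sprintf(
    "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)), a$elety, a$resid, a$chain, a$resno,
    a$x, a$y, a$z, a$o, a$b, a$elesy
  )
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(lines, "TER", "END"), con)
  invisible(path)
}

#' Write reference labels in CAID format
#'
#' One record per target: `>` header, amino-acid sequence line, and a
#' same-length state line over `{0, 1, -}` (`-` for unknown labels).
#'
#' @param ref Tibble with `target_id`, `position`, `aa` and a 0/1/`NA` label
#'   column.
#' @param path Output path.
#' @param label Name of the label column (default `"label"`).
#' @return `path`, invisibly.
#' @export
write_caid_reference <- function(ref, path, label = "label") {
  stopifnot(all(c("target_id", "position", "aa", label) %in% names(ref)))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (id in unique(ref$target_id)) {
    block <- ref[ref$target_id == id, ]
    block <- block[order(block$position), ]
    states <- ifelse(is.na(block[[label]]), "-",
                     as.character(as.integer(block[[label]])))
    writeLines(c(paste0(">", id),
                 paste(block$aa, collapse = ""),
                 paste(states, collapse = "")), con)
  }
  invisible(path)
}

# archetype mixtures emulating the input regime: compact folded cores with
# exposed low-confidence tails/linkers, plus exposed-but-confident
# ("conditional folding") segments
suite_spec <- function(archetype) {
  j <- function(mu, s) max(5L, as.integer(round(mu + runif(1, -s, s))))
  p <- function(mu) min(100, max(0, mu + runif(1, -4, 4)))
  switch(archetype,
    ordered = synthetic_spec(j(48, 10), "core", p(92), "order"),
    tailed = synthetic_spec(
      c(j(18, 5), j(40, 8), j(18, 5)),
      c("extended", "core", "extended"),
      c(p(30), p(90), p(30)),
      c("disorder", "order", "disorder")
    ),
    linkered = synthetic_spec(
      c(j(30, 6), j(22, 5), j(30, 6)),
      c("core", "extended", "core"),
      c(p(88), p(32), p(88)),
      c("order", "disorder", "order")
    ),
    conditional = synthetic_spec(
      c(j(35, 6), j(20, 4), j(14, 4)),
      c("core", "extended", "extended"),
      c(p(90), p(88), p(28)),
      c("order", "binding", "disorder")
    )
  )
}

#' Generate a synthetic benchmark suite
#'
#' Writes `n_targets` synthetic models (PDB) plus two CAID-format references
#' — a disorder reference (disorder and binding residues positive) and a
#' binding reference (binding residues positive) — and a ground-truth
#' manifest. Targets cycle through four archetypes: fully ordered cores,
#' cores with disordered tails, two cores joined by a disordered linker, and
#' targets carrying an exposed high-confidence (conditional-folding) segment.
#' Fully deterministic given `seed`.
#'
#' @param dir Output directory (created if needed); models go to
#'   `dir/models/`, references to `dir/references/`.
#' @param n_targets Number of targets (default 20).
#' @param seed Integer seed.
#' @return Invisibly, a list with `manifest` (tibble), `reference`
#'   (per-residue tibble) and the written `paths`.
#' @export
benchmark_suite <- function(dir, n_targets = 20L, seed = 1L) {
  model_dir <- file.path(dir, "models")
  ref_dir <- file.path(dir, "references")
  dir.create(model_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(ref_dir, recursive = TRUE, showWarnings = FALSE)
  archetypes <- rep(c("ordered", "tailed", "linkered", "conditional"),
                    length.out = n_targets)
  refs <- vector("list", n_targets)
  manifest <- vector("list", n_targets)
  for (i in seq_len(n_targets)) {
    id <- sprintf("T%04d", i)
    spec <- withr::with_seed(seed * 1000L + i, suite_spec(archetypes[i]))
    built <- build_model(spec, target_id = id, seed = seed * 1000L + i)
    write_pdb(built$model, file.path(model_dir, paste0(id, ".pdb")))
    refs[[i]] <- built$reference
    manifest[[i]] <- tibble::tibble(
      target_id = id, archetype = archetypes[i],
      n_residues = nrow(built$reference),
      n_disorder = sum(built$reference$label_disorder),
      n_binding = sum(built$reference$label_binding)
    )
  }
  reference <- dplyr::bind_rows(refs)
  manifest <- dplyr::bind_rows(manifest)
  disorder_path <- file.path(ref_dir, "disorder.txt")
  binding_path <- file.path(ref_dir, "binding.txt")
  write_caid_reference(reference, disorder_path, label = "label_disorder")
  write_caid_reference(reference, binding_path, label = "label_binding")
  manifest_path <- file.path(dir, "manifest.tsv")
  readr::write_tsv(manifest, manifest_path, progress = FALSE)
  invisible(list(
    manifest = manifest,
    reference = reference,
    paths = list(models = model_dir, disorder = disorder_path,
                 binding = binding_path, manifest = manifest_path)
  ))
}

#' Simulate labelled RSA profiles for window calibration
#'
#' Score-level synthetic dataset for exercising [window_grid_search()]:
#' each target is a domains-and-linkers architecture alternating ordered
#' blocks (about `order_length` residues, emulating folded domains whose
#' surface residues keep per-residue RSA well above zero) with contiguous
#' disordered blocks (about `disorder_length` residues, emulating exposed
#' linkers). The per-residue raw RSA is the block's base level plus Gaussian
#' noise, clamped to `[0, 1]`. The default base levels (0.40 ordered, 0.55
#' disordered) are the typical per-residue accessibility contrast between
#' ordered regions -- a mix of buried and exposed residues -- and disordered
#' ones; with noise of the same order the per-residue signal is weak, so
#' recovering the labels genuinely requires window averaging.
#' Deterministic given `seed`.
#'
#' @param n_targets Number of targets (default 20).
#' @param n_repeats Ordered-disordered block pairs per target (default 5).
#' @param order_length Mean ordered-block length in residues (default 45;
#'   individual blocks vary by +/- 8).
#' @param disorder_length Mean disordered-block length (default 20; varies
#'   by +/- 4).
#' @param rsa_order,rsa_disorder Base RSA levels (defaults 0.40 and 0.55).
#' @param noise_sd Standard deviation of the additive noise (default 0.15).
#' @param seed Integer seed.
#' @return List with `profiles` (`target_id`, `position`, `rsa`) and `ref`
#'   (`target_id`, `position`, `aa`, `label`).
#' @export
simulate_rsa_profiles <- function(n_targets = 20L, n_repeats = 5L,
                                  order_length = 45L, disorder_length = 20L,
                                  rsa_order = 0.40, rsa_disorder = 0.55,
                                  noise_sd = 0.15, seed = 1L) {
  withr::with_seed(seed, {
    out <- purrr::map(seq_len(n_targets), function(i) {
      lens <- integer(0)
      for (b in seq_len(n_repeats)) {
        lens <- c(lens,
                  max(10L, order_length + sample(-8:8, 1L)),
                  max(8L, disorder_length + sample(-4:4, 1L)))
      }
      lab <- rep(rep(c(0L, 1L), n_repeats), lens)
      base <- ifelse(lab == 1L, rsa_disorder, rsa_order)
      rsa <- pmin(1, pmax(0, base + stats::rnorm(length(base), 0, noise_sd)))
      tibble::tibble(
        target_id = sprintf("S%03d", i),
        position = seq_along(lab),
        aa = "G",
        label = lab,
        rsa = rsa
      )
    })
    all <- dplyr::bind_rows(out)
    list(
      profiles = all[, c("target_id", "position", "rsa")],
      ref = all[, c("target_id", "position", "aa", "label")]
    )
  })
}
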