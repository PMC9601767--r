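#' Read an AlphaFold-style structure model
#'
#' Parses a PDB or mmCIF file into a `structure_model`: a per-atom tibble plus
#' a target identifier. Per-residue pLDDT confidence is expected in the
#' B-factor / isotropic-displacement column on the 0-100 scale, as written by
#' AlphaFoldDB. Hetero and water records are excluded; alternate locations are
#' resolved to the highest-occupancy conformer (ties broken by alternate
#' location identifier order).
#'
#' @param path Path to a `.pdb` or `.cif` file.
#' @param format `"pdb"`, `"cif"` or `"auto"` (default: by file extension,
#'   then content sniffing).
#' @param target_id Target identifier; defaults to the file name stem.
#' @return A `structure_model`: list with `target_id` and `atoms`, a tibble
#'   with columns `chain`, `resno`, `resid`, `elety` (atom name), `elesy`
#'   (element symbol), `x`, `y`, `z` (Angstrom), `b` (B-factor / pLDDT) and
#'   `o` (occupancy).
#' @examples
#' pdb <- system.file("extdata", "tiny_model.pdb", package = "afdisorder")
#' model <- read_structure(pdb)
#' model
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           target_id = NULL) {
  format <- match.arg(format)
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    abort(sprintf("cannot read structure: file not found: %s", path))
  }
  if (format == "auto") format <- sniff_format(path)
  raw <- tryCatch(
    suppressWarnings(switch(format,
      pdb = bio3d::read.pdb(path, rm.alt = FALSE),
      cif = bio3d::read.cif(path, rm.alt = FALSE)
    )),
    error = function(e) {
      abort(sprintf("failed to parse '%s' as %s: %s",
                    path, format, conditionMessage(e)))
    }
  )
  atoms <- tibble::as_tibble(raw$atom)
  # protein records only: drop hetero/water and anything without residue info
  atoms <- atoms[atoms$type == "ATOM" & !is.na(atoms$resno), , drop = FALSE]
  if (nrow(atoms) == 0L) {
    abort(sprintf("empty model: no protein (ATOM) residues in %s", path))
  }
  if (all(is.na(atoms$b))) {
    abort("missing B-factor column: per-residue pLDDT is mandatory input")
  }
  atoms$o[is.na(atoms$o)] <- 1
  atoms <- resolve_altloc(atoms)
  atoms$chain[is.na(atoms$chain)] <- "A"
  atoms$elesy <- infer_element(atoms$elesy, atoms$elety)
  structure(
    list(
      target_id = target_id %||% tools::file_path_sans_ext(basename(path)),
      atoms = tibble::as_tibble(atoms[, c("chain", "resno", "resid", "elety",
                                          "elesy", "x", "y", "z", "b", "o")])
    ),
    class = "structure_model"
  )
}

sniff_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("pdb", "ent")) return("pdb")
  if (ext %in% c("cif", "mmcif")) return("cif")
  head_lines <- readLines(path, n = 50L, warn = FALSE)
  if (any(grepl("^(data_|loop_|_atom_site\\.)", head_lines))) "cif" else "pdb"
}

# keep, per (chain, resno, atom name), the highest-occupancy conformer;
# ties resolved by altloc identifier order
resolve_altloc <- function(atoms) {
  if (all(is.na(atoms$alt))) return(atoms)
  atoms$alt[is.na(atoms$alt)] <- ""
  atoms |>
    dplyr::group_by(.data$chain, .data$resno, .data$elety) |>
    dplyr::arrange(dplyr::desc(.data$o), .data$alt, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chain, .data$resno)
}

infer_element <- function(elesy, elety) {
  missing <- is.na(elesy) | !nzchar(elesy)
  if (any(missing)) {
    # first alphabetic character of the atom name (H-stripped names like 1HB
    # do not occur in heavy-atom predicted models, but handle them anyway)
    guess <- toupper(sub("^[^A-Za-z]*([A-Za-z]).*$", "\\1", elety[missing]))
    elesy[missing] <- guess
  }
  toupper(trimws(elesy))
}

#' @export
print.structure_model <- function(x, ...) {
  res <- unique(paste(x$atoms$chain, x$atoms$resno))
  cat(sprintf("<structure_model> %s: %d chain(s), %d residues, %d atoms\n",
              x$target_id, length(unique(x$atoms$chain)), length(res),
              nrow(x$atoms)))
  invisible(x)
}

# three-letter to one-letter amino-acid codes; anything else becomes 'X'
aa_three_to_one <- function(resid) {
  out <- suppressWarnings(bio3d::aa321(resid))
  out[is.na(out) | !out %in% c(LETTERS)] <- "X"
  out[!out %in% names(max_asa_table())] <- "X"
  out
}

#' Per-residue table of a structure model
#'
#' Collapses a parsed model to one row per residue: position, one-letter
#' amino acid and pLDDT. pLDDT is taken from the CA atom's B-factor, falling
#' back to the mean over the residue's atoms when CA is absent (AlphaFoldDB
#' writes identical per-atom values, so the two agree on real inputs).
#' Non-standard residues map to `'X'`.
#'
#' @param model A `structure_model` from [read_structure()].
#' @param chain Chain identifier; default the first chain in the file
#'   (AlphaFoldDB models are single-chain).
#' @return Tibble with columns `target_id`, `position` (residue number,
#'   strictly increasing), `aa`, `plddt_percent`.
#' @examples
#' pdb <- system.file("extdata", "tiny_model.pdb", package = "afdisorder")
#' residue_table(read_structure(pdb))
#' @export
residue_table <- function(model, chain = NULL) {
  stopifnot(inherits(model, "structure_model"))
  atoms <- model$atoms
  chains <- unique(atoms$chain)
  chain <- chain %||% chains[1L]
  if (!chain %in% chains) {
    abort(sprintf("chain '%s' not present in model '%s' (chains: %s)",
                  chain, model$target_id, paste(chains, collapse = ", ")))
  }
  atoms <- atoms[atoms$chain == chain, , drop = FALSE]
  res <- atoms |>
    dplyr::group_by(.data$resno) |>
    dplyr::summarise(
      aa = aa_three_to_one(.data$resid[1L]),
      plddt_percent = if (any(.data$elety == "CA")) {
        .data$b[.data$elety == "CA"][1L]
      } else {
        mean(.data$b)
      },
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$resno)
  if (any(res$plddt_percent < 0 | res$plddt_percent > 100, na.rm = TRUE)) {
    abort("B-factor values outside [0, 100]: not a pLDDT-bearing model")
  }
  tibble::tibble(
    target_id = model$target_id,
    position = res$resno,
    aa = res$aa,
    plddt_percent = res$plddt_percent
  )
}

#' Write the per-residue prediction table as TSV
#'
#' One row per residue with all three scores and binary calls. Scores are
#' rendered with 3 decimals (round-half-even). The file is tab-separated,
#' UTF-8, with a terminating newline.
#'
#' @param data Prediction tibble as returned by [predict_disorder()], with
#'   columns `target_id`, `position`, `aa`, `plddt_percent`, `score_pLDDT`,
#'   `rsa_raw`, `score_RSA`, `score_Bind`, `call_pLDDT`, `call_RSA`,
#'   `call_Bind`.
#' @param path Output file path.
#' @return `data`, invisibly.
#' @export
write_prediction_tsv <- function(data, path) {
  cols <- c("target_id", "position", "aa", "plddt_percent", "score_pLDDT",
            "rsa_raw", "score_RSA", "score_Bind", "call_pLDDT", "call_RSA",
            "call_Bind")
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(sprintf("prediction table lacks column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  out <- data[, cols]
  for (col in c("score_pLDDT", "rsa_raw", "score_RSA", "score_Bind")) {
    out[[col]] <- format_score3(out[[col]])
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(data)
}

# fixed 3-decimal rendering with round-half-even, e.g. 0.5817 -> "0.582"
format_score3 <- function(x) {
  sprintf("%.3f", round(x, 3))
}

#' Read CAID-style reference annotations
#'
#' The reference dialect is FASTA-like: a `>` header carrying the target id,
#' the amino-acid sequence on the next line, then a same-length state string
#' over `{0, 1, -}` where `-` marks residues with unknown annotation.
#'
#' @param path Path to the reference file.
#' @return Tibble with one row per residue: `target_id`, `position` (1-based),
#'   `aa`, `label` (integer 0/1, `NA` for unknown).
#' @examples
#' tf <- tempfile()
#' writeLines(c(">T1", "MKV", "0-1"), tf)
#' read_caid_reference(tf)
#' @export
read_caid_reference <- function(path) {
  if (!file.exists(path)) abort(sprintf("reference file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  starts <- which(startsWith(lines, ">"))
  if (length(starts) == 0L) abort("no '>' records in reference file")
  blocks <- purrr::map(seq_along(starts), function(i) {
    from <- starts[i]
    to <- if (i < length(starts)) starts[i + 1L] - 1L else length(lines)
    block <- lines[from:to]
    if (length(block) != 3L) {
      abort(sprintf("record '%s': expected sequence and state lines",
                    sub("^>", "", block[1L])))
    }
    id <- trimws(sub("^>", "", block[1L]))
    seq <- trimws(block[2L])
    states <- trimws(block[3L])
    if (nchar(states) != nchar(seq)) {
      abort(sprintf("record '%s': state string length (%d) != sequence length (%d)",
                    id, nchar(states), nchar(seq)))
    }
    st <- strsplit(states, "")[[1L]]
    if (!all(st %in% c("0", "1", "-"))) {
      abort(sprintf("record '%s': state characters must be 0, 1 or -", id))
    }
    tibble::tibble(
      target_id = id,
      position = seq_len(nchar(seq)),
      aa = strsplit(seq, "")[[1L]],
      label = {
        lab <- rep(NA_integer_, length(st))
        lab[st != "-"] <- as.integer(st[st != "-"])
        lab
      }
    )
  })
  dplyr::bind_rows(blocks)
}

#' Write a prediction track in CAID submission format
#'
#' A `>` header with the target id, then one tab-separated line per residue:
#' 1-based position, amino acid, score with 3 decimals, and the binary call.
#' A score exactly at the decision threshold is called positive (`>=` rule).
#'
#' @param data Tibble with columns `position`, `aa`, `score`, `call` for one
#'   target (e.g. a variant slice of [prediction_tracks()]).
#' @param target_id Target identifier for the header line.
#' @param path Output file; opened in append mode if `append = TRUE` so
#'   multiple targets can share one file.
#' @param append Append to an existing file (default `FALSE`).
#' @return `data`, invisibly.
#' @export
write_caid_prediction <- function(data, target_id, path, append = FALSE) {
  stopifnot(all(c("position", "aa", "score", "call") %in% names(data)))
  if (anyNA(data$score)) abort("prediction scores contain NA")
  if (nrow(data) && length(data$aa) != length(data$score)) {
    abort("sequence and score lengths differ")
  }
  lines <- c(
    paste0(">", target_id),
    if (nrow(data)) {
      sprintf("%d\t%s\t%s\t%d", data$position, data$aa,
              format_score3(data$score), as.integer(data$call))
    }
  )
  con <- file(path, open = if (append) "a" else "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(data)
}

#' Read a CAID-format prediction file
#'
#' Inverse of [write_caid_prediction()]; mainly used for round-trip checks
#' and for evaluating externally produced CAID submissions.
#'
#' @param path Path to a CAID prediction file (may hold several targets).
#' @return Tibble with `target_id`, `position`, `aa`, `score`, `call`.
#' @export
read_caid_prediction <- function(path) {
  if (!file.exists(path)) abort(sprintf("prediction file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  starts <- which(startsWith(lines, ">"))
  if (length(starts) == 0L) abort("no '>' records in prediction file")
  purrr::map_dfr(seq_along(starts), function(i) {
    from <- starts[i]
    to <- if (i < length(starts)) starts[i + 1L] - 1L else length(lines)
    id <- trimws(sub("^>", "", lines[from]))
    body <- if (to > from) lines[(from + 1L):to] else character()
    if (length(body) == 0L) {
      return(tibble::tibble(target_id = character(), position = integer(),
                            aa = character(), score = double(),
                            call = integer()))
    }
    parts <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(parts) != 4L)) {
      abort(sprintf("record '%s': expected 4 tab-separated fields per line", id))
    }
    m <- do.call(rbind, parts)
    tibble::tibble(
      target_id = id,
      position = as.integer(m[, 1L]),
      aa = m[, 2L],
      score = as.numeric(m[, 3L]),
      call = as.integer(m[, 4L])
    )
  })
}

#' Read per-residue accessibility from a DSSP output file
#'
#' Adapter for parity studies: extracts the `ACC` column (absolute solvent
#' accessibility in square Angstrom) from a classic DSSP output so that RSA
#' can be computed from an external accessibility source instead of the
#' built-in Shrake-Rupley engine.
#'
#' @param path Path to a DSSP output file.
#' @return Tibble with `chain`, `position`, `aa`, `asa`.
#' @export
read_dssp_acc <- function(path) {
  if (!file.exists(path)) abort(sprintf("DSSP file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) != 1L) abort("not a DSSP output: missing '  #  RESIDUE' header")
  body <- lines[seq.int(hdr + 1L, length(lines))]
  body <- body[nchar(body) >= 38]
  aa <- substr(body, 14, 14)
  keep <- aa != "!"  # chain breaks
  body <- body[keep]
  tibble::tibble(
    chain = trimws(substr(body, 12, 12)),
    position = as.integer(substr(body, 6, 10)),
    aa = substr(body, 14, 14),
    asa = as.numeric(substr(body, 35, 38))
  )
}
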