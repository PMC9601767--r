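test_that("PDB B-factors round-trip into the residue table as pLDDT", {
  model <- read_structure(tiny_pdb_path())
  res <- residue_table(model)
  expect_equal(res$position, 1:3)
  expect_equal(res$aa, c("M", "K", "V"))
  expect_equal(res$plddt_percent, c(90, 50, 30))
})

test_that("mmCIF and PDB encodings of the same model give identical residue tables", {
  res_pdb <- residue_table(read_structure(tiny_pdb_path(), target_id = "t"))
  res_cif <- residue_table(read_structure(tiny_cif_path(), target_id = "t"))
  expect_equal(res_pdb, res_cif)
})

test_that("format auto-detection sniffs content when the extension is unhelpful", {
  tf <- tempfile(fileext = ".txt")
  file.copy(tiny_cif_path(), tf)
  res <- residue_table(read_structure(tf, target_id = "t"))
  expect_equal(res$plddt_percent, c(90, 50, 30))
})

test_that("hetero/water-only files raise an empty-model error", {
  tf <- tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  O   HOH A 401      10.000  10.000  10.000  1.00 20.00           O",
    "HETATM    2  O   HOH A 402      13.000  10.000  10.000  1.00 20.00           O",
    "END"
  ), tf)
  expect_error(read_structure(tf), "empty model")
})

test_that("missing files and absent chains raise informative errors", {
  expect_error(read_structure(tempfile(fileext = ".pdb")), "not found")
  model <- read_structure(tiny_pdb_path())
  expect_error(residue_table(model, chain = "Z"), "chain 'Z' not present")
})

test_that("pLDDT falls back to the atom mean when CA is absent", {
  tf <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   GLY A   1      10.000  10.000  10.000  1.00 60.00           N",
    "ATOM      2  C   GLY A   1      12.000  10.000  10.000  1.00 70.00           C",
    "END"
  ), tf)
  res <- residue_table(read_structure(tf))
  expect_equal(res$plddt_percent, 65)
})

test_that("alternate locations resolve to the highest-occupancy conformer", {
  tf <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AGLY A   1      10.000  10.000  10.000  0.40 50.00           C",
    "ATOM      2  CA BGLY A   1      10.500  10.000  10.000  0.60 80.00           C",
    "END"
  ), tf)
  res <- residue_table(read_structure(tf))
  expect_equal(nrow(res), 1L)
  expect_equal(res$plddt_percent, 80)
})

test_that("non-standard residues map to 'X'", {
  tf <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  FOO A   1      10.000  10.000  10.000  1.00 50.00           C",
    "END"
  ), tf)
  res <- residue_table(read_structure(tf))
  expect_equal(res$aa, "X")
})

test_that("CAID references parse 0/1/- states and reject malformed records", {
  ref <- read_caid_reference(system.file("extdata", "tiny_reference.txt",
                                         package = "afdisorder"))
  t1 <- ref[ref$target_id == "T1", ]
  t2 <- ref[ref$target_id == "T2", ]
  expect_equal(t1$label, c(0L, 1L, 0L))
  expect_equal(t2$label, c(0L, NA_integer_, 1L))
  expect_equal(t2$aa, c("M", "K", "V"))

  bad_len <- tempfile(); writeLines(c(">T3", "MKV", "01"), bad_len)
  expect_error(read_caid_reference(bad_len), "length")
  bad_chr <- tempfile(); writeLines(c(">T4", "MKV", "012"), bad_chr)
  expect_error(read_caid_reference(bad_chr), "0, 1 or -")
})

test_that("prediction TSV has header plus one row per residue, 3-decimal scores", {
  pred <- tibble::tibble(
    target_id = "t", position = 1:3, aa = c("M", "K", "V"),
    plddt_percent = c(90, 50, 30),
    score_pLDDT = c(0.1, 0.5, 0.7), rsa_raw = c(0.5817, 0.25, 1),
    score_RSA = c(0.5, 0.5, 0.5), score_Bind = c(0.5, 0.5, 0.5),
    call_pLDDT = c(0L, 1L, 1L), call_RSA = c(0L, 0L, 0L),
    call_Bind = c(0L, 0L, 0L)
  )
  tf <- tempfile(fileext = ".tsv")
  write_prediction_tsv(pred, tf)
  lines <- readLines(tf)
  expect_length(lines, 4L)
  expect_match(lines[1], "^target_id\tposition\taa\tplddt_percent")
  expect_match(lines[2], "\t0\\.582\t", all = FALSE)  # 0.5817 -> "0.582"
  expect_error(write_prediction_tsv(pred[, -5], tf), "lacks column")
})

test_that("empty prediction tables yield a header-only TSV", {
  pred <- tibble::tibble(
    target_id = character(), position = integer(), aa = character(),
    plddt_percent = double(), score_pLDDT = double(), rsa_raw = double(),
    score_RSA = double(), score_Bind = double(), call_pLDDT = integer(),
    call_RSA = integer(), call_Bind = integer()
  )
  tf <- tempfile(fileext = ".tsv")
  write_prediction_tsv(pred, tf)
  expect_length(readLines(tf), 1L)
})

test_that("CAID prediction files round-trip positions, 3-decimal scores and calls", {
  track <- tibble::tibble(
    position = 1:2, aa = c("M", "K"),
    score = c(0.1, 0.9), call = c(0L, 1L)
  )
  tf <- tempfile()
  write_caid_prediction(track, "T1", tf)
  lines <- readLines(tf)
  expect_equal(lines, c(">T1", "1\tM\t0.100\t0", "2\tK\t0.900\t1"))
  back <- read_caid_prediction(tf)
  expect_equal(back$position, track$position)
  expect_equal(back$score, as.numeric(format_score3(track$score)))
  expect_equal(back$call, track$call)

  # empty track: header-only record
  empty <- track[0, ]
  write_caid_prediction(empty, "T9", tf)
  expect_equal(readLines(tf), ">T9")
})

test_that("a score exactly at threshold is called positive in written tracks", {
  cfg <- score_config()
  track <- tibble::tibble(position = 1L, aa = "M", score = cfg$thr_rsa,
                          call = as.integer(cfg$thr_rsa >= cfg$thr_rsa))
  tf <- tempfile()
  write_caid_prediction(track, "T1", tf)
  expect_match(readLines(tf)[2], "\t1$")
})

test_that("DSSP accessibility adapter extracts the ACC column", {
  tf <- tempfile()
  writeLines(c(
    "==== Secondary Structure Definition by the program DSSP ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N",
    "    1    1 A M              0   0  155      0, 0.0   2,-0.3",
    "    2    2 A K  H  >  S+    0   0   82      1,-0.1   4,-2.4",
    "    3        !              0   0    0      0, 0.0   0, 0.0",
    "    4    3 A V  H  > S+     0   0   12      1,-0.2   4,-2.2"
  ), tf)
  acc <- read_dssp_acc(tf)
  expect_equal(acc$position, c(1L, 2L, 3L))
  expect_equal(acc$asa, c(155, 82, 12))
  expect_equal(acc$aa, c("M", "K", "V"))
})

test_that("residue ordering matches file order with strictly increasing positions", {
  model <- read_structure(tiny_pdb_path())
  res <- residue_table(model)
  expect_true(all(diff(res$position) > 0))
})
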