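test_that("a plain two-chain PDB parses with the expected chains and residues", {
  path <- write_tmp_pdb(two_chain_pdb_lines(n = 10))
  s <- read_structure(path)
  ch <- chain_table(s)
  expect_equal(ch$chain, c("A", "B"))
  expect_equal(ch$n_res, c(10L, 10L))
  expect_equal(nrow(s$atoms), 2 * 10 * 5)
  expect_equal(unique(residue_table(s)$aa), "A")
})

test_that("altloc duplicates resolve to the highest-occupancy atom", {
  plain <- read_structure(write_tmp_pdb(two_chain_pdb_lines(n = 6)))
  dup <- read_structure(write_tmp_pdb(two_chain_pdb_lines(n = 6, with_altloc = TRUE)))
  expect_equal(dup$atoms$x, plain$atoms$x, tolerance = 1e-12)
  expect_equal(dup$atoms$occ, rep(0.6, nrow(dup$atoms)))
  expect_equal(nrow(dup$atoms), nrow(plain$atoms))
})

test_that("CASP TS header lines are skipped and coordinates match a fixed-column read", {
  body <- two_chain_pdb_lines(n = 8)
  ts <- c("PFRMAT TS", "TARGET T1170", "MODEL  1", "PARENT N/A", body)
  path <- write_tmp_pdb(ts)
  s <- read_structure(path, dialect = "casp_ts")
  expected <- oracle_parse_coords(path)
  got <- as.matrix(s$atoms[c("x", "y", "z")])
  dimnames(got) <- dimnames(expected)
  expect_equal(got, expected, tolerance = 1e-12)
  expect_equal(nrow(chain_table(s)), 2L)
})

test_that("HETATM, waters and CA-less residues are excluded; only first MODEL read", {
  lines <- c(
    "MODEL     1",
    pdb_atom_line(1, "N", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.5, 0, 0),
    pdb_atom_line(3, "C", "ALA", "A", 1, 2, 1.4, 0),
    pdb_atom_line(4, "N", "GLY", "A", 2, 3, 2, 0), # no CA -> dropped
    pdb_atom_line(5, "CA", "VAL", "A", 3, 4, 3, 0),
    pdb_atom_line(6, "CA", "LEU", "A", 4, 6, 4, 0),
    sub("^ATOM  ", "HETATM", pdb_atom_line(7, "CA", "HOH", "A", 90, 9, 9, 9)),
    "ENDMDL",
    "MODEL     2",
    pdb_atom_line(8, "CA", "ALA", "A", 1, 50, 50, 50),
    "ENDMDL",
    "END"
  )
  s <- read_structure(write_tmp_pdb(lines))
  res <- residue_table(s)
  expect_equal(res$aa, c("A", "V", "L"))
  expect_equal(res$res_index, 1:3)       # re-indexed after the drop
  expect_equal(res$resno, c(1L, 3L, 4L)) # author numbering preserved
  expect_equal(s$atoms$x[s$atoms$atom == "CA" & s$atoms$resno == 1], 1.5)
})

test_that("unreadable input raises parse errors", {
  expect_error(read_structure(tempfile()), "not found")
  nocoord <- write_tmp_pdb(c("REMARK nothing here", "END"))
  expect_error(read_structure(nocoord), "ATOM|parse")
})

test_that("parse -> write -> parse is idempotent on coordinates to 3 decimals", {
  s1 <- make_idealized_multimer("A2B1", 12, seed = 5)
  p1 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s1, p1)
  s2 <- read_structure(p1)
  expect_equal(s2$atoms$x, round(s1$atoms$x, 3), tolerance = 1e-9)
  p2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s2, p2)
  s3 <- read_structure(p2)
  expect_identical(s2$atoms[c("x", "y", "z")], s3$atoms[c("x", "y", "z")])
  expect_identical(chain_table(s2), chain_table(s1))
})

test_that("B-factor writing applies the fixed transform and round-trips", {
  s <- make_idealized_multimer("A2", 8, seed = 3)
  res <- residue_table(s)

  all_one <- tibble::tibble(chain = res$chain, res_index = res$res_index, score = 1)
  p <- withr::local_tempfile(fileext = ".pdb")
  write_structure_with_bfactor(s, all_one, p)
  expect_true(all(grepl("1\\.00100\\.00", grep("^ATOM", readLines(p), value = TRUE))))

  one <- all_one[1, ]
  one$score <- 0.799
  write_structure_with_bfactor(s, one, p)
  s2 <- read_structure(p)
  expect_equal(unique(s2$atoms$b[s2$atoms$chain == one$chain &
                                   s2$atoms$res_index == one$res_index]), 79.9)
  # unscored residues take the sentinel
  expect_equal(unique(s2$atoms$b[s2$atoms$chain != one$chain]), 0)

  withr::with_seed(42, {
    rnd <- tibble::tibble(chain = res$chain, res_index = res$res_index,
                          score = runif(nrow(res)))
    write_structure_with_bfactor(s, rnd, p)
    back <- read_bfactor_scores(p)
    merged <- merge(rnd, back, by = c("chain", "res_index"))
    expect_lte(max(abs(merged$score.x - merged$score.y)), 0.005)
  })

  bad <- all_one
  bad$score[1] <- 1.2
  expect_error(write_structure_with_bfactor(s, bad, p), "\\[0, 1\\]")
})

test_that("QMODE2 output round-trips through the package's QA reader", {
  ref <- make_idealized_multimer("A2", 6, seed = 1)
  models <- lapply(1:3, function(i) {
    perturb(ref, decoy_spec(noise_sigma = 0.3, seed = i),
            model_name = sprintf("m%02d", i))
  })
  ens <- validate_ensemble(models, "A2")
  jr <- jury_assess(ens)
  p <- withr::local_tempfile(fileext = ".qa")
  write_qa_qmode2(jr, "T0999", p)

  qa <- read_qa(p)
  expect_equal(qa$target_id, "T0999")
  expect_equal(qa$n_models, 3L)
  expect_setequal(qa$models$model, jr$scores$model)
  for (i in seq_len(3)) {
    m <- qa$models$model[i]
    expect_equal(qa$models$global[i],
                 round(jr$scores$combined_linear[jr$scores$model == m], 3),
                 tolerance = 1e-9)
    loc <- jr$local$score[jr$local$model == m]
    expect_equal(qa$models$local[[i]], round(loc, 3), tolerance = 1e-9)
  }
  # layout: header lines and wrapping at 20 scores per line
  lines <- readLines(p)
  expect_equal(lines[1:4], c("PFRMAT QA", "TARGET T0999", "MODEL 3", "QMODE 2"))
  expect_equal(lines[length(lines)], "END")
  body <- lines[-(1:4)]
  expect_true(all(lengths(strsplit(body[grepl("^[0-9]", body)], " ")) <= 20))

  # a global score of exactly 1 prints as 1.000
  jr2 <- jr
  jr2$scores$combined_linear[] <- 1
  write_qa_qmode2(jr2, "T0999", p)
  expect_true(all(grepl(" 1\\.000$", grep("^m0", readLines(p), value = TRUE))))

  jr3 <- jr
  jr3$local <- jr3$local[0, ]
  expect_error(write_qa_qmode2(jr3, "T0999", p), "local scores")
})
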