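write_ensemble_pdbs <- function(dir, stoich = "A2", n = 3, len = 10,
                                sigma = 0.5, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- make_idealized_multimer(stoich, len, seed = seed)
  paths <- character(n)
  for (i in seq_len(n)) {
    d <- perturb(ref, decoy_spec(noise_sigma = sigma, seed = seed * 100 + i),
                 model_name = sprintf("m%02d", i))
    paths[i] <- file.path(dir, sprintf("m%02d.pdb", i))
    write_structure(d, paths[i])
  }
  list(ref = ref, paths = paths)
}

test_that("run_jury writes a consistent ranking table, QA file and local PDBs", {
  dir <- withr::local_tempdir()
  fix <- write_ensemble_pdbs(file.path(dir, "models"), n = 4)
  out <- file.path(dir, "out")
  cfg <- run_config("jury_rank", "A2", as.list(fix$paths),
                    target_id = "T0101", out_dir = out, quiet = TRUE)
  res <- run_jury(cfg)

  # the TSV ordering equals rank_models on the jury object
  tsv <- read.delim(res$files[["ranking"]], comment.char = "#")
  want <- rank_models(res$jury, "modfolddockr")
  expect_equal(tsv$model, want$model)
  expect_equal(tsv$rank, want$rank)
  expect_equal(tsv$rank_score, round(want$rank_score, 10), tolerance = 1e-6)

  # QA file round-trips and every local PDB re-parses to the local scores
  qa <- read_qa(res$files[["qa"]])
  expect_equal(qa$target_id, "T0101")
  expect_equal(qa$n_models, 4L)
  m1 <- tsv$model[1]
  back <- read_bfactor_scores(res$files[[paste0("model_", m1)]])
  loc <- res$jury$local[res$jury$local$model == m1, ]
  merged <- merge(loc, back, by = c("chain", "res_index"))
  expect_lte(max(abs(merged$score.x - merged$score.y)), 0.005)

  # reruns with identical config and inputs are byte-identical
  out2 <- file.path(dir, "out2")
  cfg2 <- run_config("jury_rank", "A2", as.list(fix$paths),
                     target_id = "T0101", out_dir = out2, quiet = TRUE)
  res2 <- run_jury(cfg2)
  expect_identical(readLines(res$files[["ranking"]]),
                   readLines(res2$files[["ranking"]]))
  expect_identical(readLines(res$files[["qa"]]),
                   readLines(res2$files[["qa"]]))
})

test_that("identical models tie at 1.000 and rank by name", {
  dir <- withr::local_tempdir()
  ref <- make_idealized_multimer("A2", 8, seed = 2)
  paths <- vapply(c("zeta", "alpha", "mid"), function(nm) {
    s <- ref
    s$model_name <- nm
    p <- file.path(dir, paste0(nm, ".pdb"))
    write_structure(s, p)
    p
  }, "")
  res <- run_jury(run_config("jury", "A2", as.list(paths),
                             out_dir = file.path(dir, "o"), quiet = TRUE))
  expect_true(all(abs(res$ranking$combined_linear - 1) < 1e-9))
  expect_equal(res$ranking$model, c("alpha", "mid", "zeta"))
})

test_that("configuration errors are usage errors", {
  expect_error(run_config("jury", NULL, list()), class = "dockjury_usage")
  expect_error(run_config("compare", "A2", list("x.pdb")),
               class = "dockjury_usage")
  cfg <- run_config("jury", "A2", list())
  expect_error(run_jury(cfg), class = "dockjury_usage")
})

test_that("run_compare reports self-comparison optima and label invariance", {
  dir <- withr::local_tempdir()
  ref <- make_idealized_multimer("A2", 10, seed = 3)
  rp <- file.path(dir, "ref.pdb")
  write_structure(ref, rp)

  res <- run_compare(run_config("compare", "A2", list(rp), references = list(rp),
                                out_dir = file.path(dir, "cmp"), quiet = TRUE))
  g <- res$comparison$global
  expect_equal(as.numeric(g), c(1, 1, 1), tolerance = 1e-6)
  expect_equal(res$comparison$per_chain$gdt_ts, c(100, 100), tolerance = 1e-9)

  # swapped chain labels give the identical report
  swapped <- perturb(ref, decoy_spec(label_permutation = c(A = "B", B = "A")),
                     model_name = "swapped")
  sp <- file.path(dir, "swapped.pdb")
  write_structure(swapped, sp)
  res2 <- run_compare(run_config("compare", "A2", list(sp), references = list(rp),
                                 quiet = TRUE))
  expect_equal(res2$comparison$global, res$comparison$global, tolerance = 1e-9)

  # a graded decoy reproduces direct module calls
  dec <- perturb(ref, decoy_spec(noise_sigma = 1, seed = 44), "dec")
  dp <- file.path(dir, "dec.pdb")
  write_structure(dec, dp)
  res3 <- run_compare(run_config("compare", "A2", list(dp), references = list(rp),
                                 quiet = TRUE))
  dec_read <- read_structure(dp)
  ref_read <- read_structure(rp)
  expect_equal(res3$comparison$global$oligo_lddt,
               oligo_lddt(dec_read, ref_read)$global, tolerance = 1e-9)
  expect_equal(res3$comparison$global$qs,
               qs_score(dec_read, ref_read)$global, tolerance = 1e-9)
})

test_that("run_single scores models against a reference set", {
  dir <- withr::local_tempdir()
  fix <- write_ensemble_pdbs(file.path(dir, "refs"), n = 3, seed = 5)
  ref <- make_idealized_multimer("A2", 10, seed = 5)
  q <- perturb(ref, decoy_spec(noise_sigma = 0.8, seed = 77), "query")
  qp <- file.path(dir, "query.pdb")
  write_structure(q, qp)
  res <- run_single(run_config("single", "A2", list(qp),
                               references = as.list(fix$paths),
                               out_dir = file.path(dir, "s"), quiet = TRUE))
  expect_equal(nrow(res$scores), 1L)
  expect_true(all(res$scores$combined_linear > 0 &
                    res$scores$combined_linear < 1))
  expect_true(file.exists(res$files[["tsv"]]))
})

test_that("the CLI drives a jury run end to end", {
  cli <- system.file("cli", "dockjury.R", package = "dockjury")
  expect_true(nzchar(cli))
  dir <- withr::local_tempdir()
  fix <- write_ensemble_pdbs(file.path(dir, "models"), n = 3, len = 8)
  out <- file.path(dir, "cli_out")
  status <- system2("Rscript",
                    c(cli, "rank", "--stoichiometry", "A2", "--out", out,
                      "--quiet", fix$paths),
                    stdout = FALSE, stderr = FALSE)
  expect_equal(status, 0L)
  expect_true(file.exists(file.path(out, "ranking.tsv")))

  # missing stoichiometry is a usage error with exit code 2
  status2 <- system2("Rscript", c(cli, "jury", fix$paths),
                     stdout = FALSE, stderr = FALSE)
  expect_equal(status2, 2L)
})
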