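# End-to-end runs binding I/O, metrics and the jury together; the CLI in
# inst/cli/dockjury.R is a thin wrapper over these.

#' Configuration for an end-to-end run
#'
#' @param mode `"jury"` (linear variant governs), `"jury_rank"` (rank
#'   score governs), `"single"` (one model vs a reference set) or
#'   `"compare"` (one model vs one reference).
#' @param stoichiometry Stoichiometry string, e.g. `"A2B2"`.
#' @param models Character vector of model PDB paths (or a list of
#'   [structure3d()] objects).
#' @param references Reference paths/structures (required for `single` and
#'   `compare`).
#' @param fasta Optional FASTA file; when given, every model's chain
#'   sequences must be drawn from it (mismatches are rejected).
#' @param weights Component weights (see [jury_assess()]).
#' @param target_id Target identifier used in output files.
#' @param seed Integer seed recorded in provenance.
#' @param out_dir Output directory (created if needed); `NULL` writes no
#'   files.
#' @param quiet Suppress progress messages.
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("jury", "jury_rank", "single", "compare"),
                       stoichiometry, models, references = NULL,
                       fasta = NULL, weights = NULL, target_id = "T0000",
                       seed = 1L, out_dir = NULL, quiet = FALSE) {
  mode <- match.arg(mode)
  if (missing(stoichiometry) || is.null(stoichiometry)) {
    abort("a stoichiometry is required (e.g. \"A2\")", class = "dockjury_usage")
  }
  if (mode %in% c("single", "compare") &&
      (is.null(references) || length(references) == 0L)) {
    abort(paste0("mode '", mode, "' requires reference structure(s)"),
          class = "dockjury_usage")
  }
  structure(list(mode = mode, stoichiometry = stoichiometry, models = models,
                 references = references, fasta = fasta, weights = weights,
                 target_id = target_id, seed = as.integer(seed),
                 out_dir = out_dir, quiet = quiet),
            class = "run_config")
}

load_structures <- function(x) {
  if (inherits(x, "structure3d")) return(list(x))
  lapply(x, function(el) {
    if (inherits(el, "structure3d")) el else read_structure(el)
  })
}

check_fasta <- function(structures, fasta) {
  if (!requireNamespace("seqinr", quietly = TRUE)) {
    warn("seqinr not available; skipping FASTA sequence check")
    return(invisible(NULL))
  }
  fa <- toupper(vapply(seqinr::read.fasta(fasta, seqtype = "AA", as.string = TRUE),
                       `[[`, "", 1))
  for (s in structures) {
    bad <- setdiff(unname(chain_sequences(s)), fa)
    if (length(bad)) {
      abort(sprintf("model '%s': chain sequence not found in FASTA input",
                    s$model_name),
            class = "dockjury_validation")
    }
  }
  invisible(NULL)
}

say <- function(config, ...) {
  if (!isTRUE(config$quiet)) message(sprintf(...))
}

tsv_header <- function(config, extra = character(0)) {
  c(sprintf("# dockjury %s", as.character(utils::packageVersion("dockjury"))),
    sprintf("# mode=%s stoichiometry=%s target=%s seed=%d",
            config$mode, config$stoichiometry, config$target_id, config$seed),
    extra)
}

write_tsv_with_comments <- function(df, path, comments) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(comments, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the consensus jury on a set of models
#'
#' Reads and validates the models, runs [jury_assess()], and (when
#' `out_dir` is set) writes a ranking table (`ranking.tsv`), a
#' QMODE2-style QA file (`<target>.qa`) and one PDB per model with local
#' scores in the B-factor column.
#'
#' @param config A [run_config()] with mode `"jury"` or `"jury_rank"`.
#' @return A list of class `run_result`: `jury`, `ranking`, `ensemble`,
#'   `files` (paths written).
#' @export
run_jury <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!config$mode %in% c("jury", "jury_rank")) {
    abort("run_jury needs mode 'jury' or 'jury_rank'", class = "dockjury_usage")
  }
  structures <- load_structures(config$models)
  if (length(structures) < 2L) {
    abort("jury mode requires >= 2 models", class = "dockjury_usage")
  }
  if (!is.null(config$fasta)) check_fasta(structures, config$fasta)
  ens <- validate_ensemble(structures, config$stoichiometry,
                           target_id = config$target_id)
  if (length(ens) < 2L) {
    abort("fewer than 2 models survived validation",
          class = "dockjury_validation")
  }
  say(config, "scoring %d models (stoichiometry %s)", length(ens),
      config$stoichiometry)
  jury <- jury_assess(ens, weights = config$weights)
  variant <- if (config$mode == "jury") "modfolddock" else "modfolddockr"
  ranking <- rank_models(jury, variant)

  files <- character(0)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    tsv <- file.path(config$out_dir, "ranking.tsv")
    write_tsv_with_comments(
      ranking[c("model", "dockq_jury", "qs_jury", "lddt_jury",
                "combined_linear", "rank_score", "rank")],
      tsv,
      tsv_header(config, sprintf("# variant=%s weights=%s", variant,
                                 paste(sprintf("%.4f", jury$provenance$weights),
                                       collapse = ","))))
    qa <- file.path(config$out_dir, paste0(config$target_id, ".qa"))
    write_qa_qmode2(jury, config$target_id, qa,
                    governing = if (variant == "modfolddock")
                      "combined_linear" else "rank_score")
    files <- c(ranking = tsv, qa = qa)
    for (m in names(ens$structures)) {
      loc <- jury$local[jury$local$model == m, c("chain", "res_index", "score")]
      p <- file.path(config$out_dir, paste0(m, "_local.pdb"))
      write_structure_with_bfactor(ens$structures[[m]], loc, p)
      files[paste0("model_", m)] <- p
    }
  }
  structure(list(jury = jury, ranking = ranking, ensemble = ens,
                 files = files, config = config),
            class = "run_result")
}

#' Compare one model against one reference structure
#'
#' Emits every pairwise metric (oligo-lDDT global and per residue, QS
#' global and per interface, DockQ with its Fnat/iRMS/LRMS terms,
#' per-chain GDT_TS and CA RMSD) under the solved chain mapping.
#'
#' @param config A [run_config()] with mode `"compare"`, one model and one
#'   reference.
#' @return A list of class `run_result` with `comparison` and `files`
#'   (`compare.tsv`, `compare.txt` when `out_dir` is set).
#' @export
run_compare <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (config$mode != "compare") {
    abort("run_compare needs mode 'compare'", class = "dockjury_usage")
  }
  model <- load_structures(config$models)[[1]]
  reference <- load_structures(config$references)[[1]]
  if (!is.null(config$fasta)) check_fasta(list(model, reference), config$fasta)
  ens <- validate_ensemble(list(model, reference), config$stoichiometry,
                           target_id = config$target_id)
  if (length(ens) < 2L) {
    abort("model and reference must both match the stoichiometry",
          class = "dockjury_validation")
  }
  cmp <- compare_structures(model, reference)

  files <- character(0)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    g <- cmp$global
    long <- bind_rows(
      tibble(section = "global", item = names(g),
             value = as.numeric(g[1, ])),
      tibble(section = "per_chain",
             item = paste0("gdt_ts_", cmp$per_chain$model_chain),
             value = cmp$per_chain$gdt_ts),
      tibble(section = "per_chain",
             item = paste0("rmsd_ca_", cmp$per_chain$model_chain),
             value = cmp$per_chain$rmsd_ca),
      tibble(section = "per_interface",
             item = paste0("dockq_", cmp$per_interface$chain_i,
                           cmp$per_interface$chain_j),
             value = cmp$per_interface$dockq)
    )
    tsv <- file.path(config$out_dir, "compare.tsv")
    write_tsv_with_comments(long, tsv, tsv_header(config))
    txt <- file.path(config$out_dir, "compare.txt")
    writeLines(c(
      sprintf("model:     %s", model$model_name),
      sprintf("reference: %s", reference$model_name),
      sprintf("mapping:   %s",
              paste(names(cmp$mapping), cmp$mapping, sep = "->", collapse = " ")),
      sprintf("oligo-lDDT = %.3f  QS = %.3f  DockQ = %.3f",
              g$oligo_lddt, g$qs, g$dockq),
      sprintf("chain %s: GDT_TS = %.2f, CA RMSD = %.3f A",
              cmp$per_chain$model_chain, cmp$per_chain$gdt_ts,
              cmp$per_chain$rmsd_ca)
    ), txt)
    files <- c(tsv = tsv, txt = txt)
  }
  structure(list(comparison = cmp, files = files, config = config),
            class = "run_result")
}

#' Score single models against a reference set
#'
#' @param config A [run_config()] with mode `"single"`; `references` hold
#'   the reference ensemble.
#' @return A list of class `run_result` with `scores` (one row per model)
#'   and `files`.
#' @export
run_single <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (config$mode != "single") {
    abort("run_single needs mode 'single'", class = "dockjury_usage")
  }
  models <- load_structures(config$models)
  refs <- load_structures(config$references)
  if (!is.null(config$fasta)) check_fasta(c(models, refs), config$fasta)
  ref_ens <- validate_ensemble(refs, config$stoichiometry,
                               target_id = config$target_id)
  results <- lapply(models, function(m) {
    validate_ensemble(list(m), config$stoichiometry)
    score_single_model(m, ref_ens, weights = config$weights)
  })
  scores <- list_rbind(lapply(results, function(r) r$scores))
  files <- character(0)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    tsv <- file.path(config$out_dir, "single.tsv")
    write_tsv_with_comments(scores, tsv, tsv_header(config))
    files <- c(tsv = tsv)
  }
  structure(list(scores = scores, results = results, files = files,
                 config = config),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result> mode = %s\n", x$config$mode))
  if (!is.null(x$ranking)) print(head(x$ranking, 5))
  if (!is.null(x$comparison)) print(x$comparison)
  if (!is.null(x$scores)) print(x$scores)
  if (length(x$files)) cat("files:", paste(x$files, collapse = ", "), "\n")
  invisible(x)
}
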