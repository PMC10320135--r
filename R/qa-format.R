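# CASP QA (QMODE2-style) output: global score plus per-residue local
# scores for every model. Layout written here (and parsed back by
# read_qa):
#   PFRMAT QA
#   TARGET <id>
#   MODEL <n models>
#   QMODE 2
#   <model name> <global score, 3 decimals>
#   <local scores, 3 decimals, 20 per line>
#   ...
#   END

#' Write a jury result in CASP QMODE2-style QA format
#'
#' @param jury A [jury_assess()] result (global and per-residue scores for
#'   every model are required).
#' @param target_id Target identifier for the TARGET header line.
#' @param path Output path.
#' @param governing `"combined_linear"` or `"rank_score"`: which global
#'   score to print.
#' @param per_line Local scores per continuation line (default 20).
#' @return `path`, invisibly.
#' @export
write_qa_qmode2 <- function(jury, target_id, path,
                            governing = c("combined_linear", "rank_score"),
                            per_line = 20L) {
  governing <- match.arg(governing)
  if (!inherits(jury, "jury_result") || nrow(jury$scores) == 0L) {
    abort("QMODE2 emission requires a non-empty jury result")
  }
  if (is.null(jury$local) || nrow(jury$local) == 0L) {
    abort("QMODE2 requires per-residue local scores")
  }
  lines <- c("PFRMAT QA",
             paste("TARGET", target_id),
             paste("MODEL", nrow(jury$scores)),
             "QMODE 2")
  for (i in seq_len(nrow(jury$scores))) {
    m <- jury$scores$model[i]
    loc <- jury$local[jury$local$model == m, ]
    if (nrow(loc) == 0L) abort(paste0("no local scores for model '", m, "'"))
    lines <- c(lines, sprintf("%s %.3f", m, jury$scores[[governing]][i]))
    vals <- sprintf("%.3f", loc$score)
    idx <- split(vals, ceiling(seq_along(vals) / per_line))
    lines <- c(lines, vapply(idx, paste, "", collapse = " "))
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

#' Read a QMODE2-style QA file
#'
#' Inverse of [write_qa_qmode2()].
#'
#' @param path Path to the QA file.
#' @return A list with `target_id`, `n_models`, and `models`: a tibble
#'   `model`, `global`, `local` (list column of numeric vectors).
#' @export
read_qa <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) < 5L || lines[1] != "PFRMAT QA") {
    abort(paste0("not a QA file: ", path))
  }
  target_id <- sub("^TARGET ", "", lines[grepl("^TARGET ", lines)][1])
  n_models <- as.integer(sub("^MODEL ", "", lines[grepl("^MODEL ", lines)][1]))
  body <- lines[-(1:4)]
  body <- body[body != "END"]

  models <- list()
  cur <- NULL
  for (ln in body) {
    toks <- strsplit(ln, " +")[[1]]
    if (suppressWarnings(is.na(as.numeric(toks[1])))) {
      cur <- toks[1]
      models[[cur]] <- list(global = as.numeric(toks[2]), local = numeric(0))
    } else {
      if (is.null(cur)) abort("malformed QA file: scores before any model name")
      models[[cur]]$local <- c(models[[cur]]$local, as.numeric(toks))
    }
  }
  list(
    target_id = target_id,
    n_models = n_models,
    models = tibble(
      model = names(models),
      global = unname(vapply(models, function(m) m$global, 0)),
      local = unname(lapply(models, function(m) m$local))
    )
  )
}
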