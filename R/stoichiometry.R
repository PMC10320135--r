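#' Parse a stoichiometry string
#'
#' A stoichiometry such as `"A2B2"` gives the copy number of each distinct
#' chain type in a complex: letters label distinct sequences, digits give
#' copy counts (an omitted count means 1). `"A6"` is a homo-hexamer,
#' `"A1B1"` a heterodimer.
#'
#' @param spec Character scalar, e.g. `"A2"`, `"A2B2"`, `"A1B1C1"`, `"AB"`.
#' @return An object of class `stoichiometry`: a tibble with columns
#'   `label` and `copies`, plus attribute `total` (total chain count).
#' @examples
#' parse_stoichiometry("A2B1")
#' @export
parse_stoichiometry <- function(spec) {
  if (!is.character(spec) || length(spec) != 1L || !nzchar(spec)) {
    abort("stoichiometry must be a non-empty string such as \"A2B2\"")
  }
  if (!grepl("^([A-Za-z][0-9]*)+$", spec)) {
    bad <- regmatches(spec, regexpr("[^A-Za-z0-9]+|^[0-9]+", spec))
    abort(paste0("malformed stoichiometry '", spec, "'",
                 if (length(bad)) paste0(" near '", bad, "'")))
  }
  m <- gregexpr("[A-Za-z][0-9]*", spec)[[1]]
  tokens <- regmatches(spec, list(m))[[1]]
  labels <- substr(tokens, 1, 1)
  copies <- as.integer(sub("^[A-Za-z]", "", tokens))
  copies[is.na(copies)] <- 1L
  if (any(copies < 1L)) {
    abort(paste0("copy count must be >= 1 in '", spec, "'"))
  }
  if (anyDuplicated(labels)) {
    abort(paste0("duplicate group label in '", spec, "'"))
  }
  out <- tibble(label = labels, copies = copies)
  attr(out, "total") <- sum(copies)
  class(out) <- c("stoichiometry", class(out))
  out
}

#' @export
print.stoichiometry <- function(x, ...) {
  cat(sprintf("<stoichiometry> %s (%d chains)\n",
              paste0(x$label, x$copies, collapse = ""), attr(x, "total")))
  invisible(x)
}

as_stoichiometry <- function(x) {
  if (inherits(x, "stoichiometry")) x else parse_stoichiometry(x)
}

# Group the chains of one structure by exact sequence identity.
# Returns a tibble chain, sequence, group (integer id in order of first
# appearance), sorted by file order.
sequence_groups <- function(s) {
  ch <- chain_table(s)
  ch$group <- match(ch$sequence, unique(ch$sequence))
  ch[c("chain", "sequence", "group")]
}

#' Validate a set of models against a target stoichiometry
#'
#' Groups each model's chains by exact sequence identity and checks the
#' multiset of copy numbers against the stoichiometry. All models must also
#' share the same multiset of chain sequences (they model the same target).
#'
#' @param structures A list of [structure3d()] objects (>= 1).
#' @param stoichiometry A `stoichiometry` or a string parseable by
#'   [parse_stoichiometry()].
#' @param target_id Identifier for the modelled target.
#' @return An object of class `ensemble`: a list with `target_id`,
#'   `structures` (named by model), `stoichiometry` and `sequence_groups`
#'   (tibble `chain`, `sequence`, `group` for the common chain composition).
#' @export
validate_ensemble <- function(structures, stoichiometry, target_id = "T0000") {
  if (inherits(structures, "structure3d")) structures <- list(structures)
  if (length(structures) < 1L) abort("at least one structure is required")
  stoich <- as_stoichiometry(stoichiometry)

  names(structures) <- vapply(structures, function(s) s$model_name, "")
  if (anyDuplicated(names(structures))) {
    nm <- names(structures)
    names(structures) <- make.unique(nm, sep = "_")
    for (i in seq_along(structures)) structures[[i]]$model_name <- names(structures)[i]
  }

  report <- character(0)
  ref_counts <- NULL
  groups <- NULL
  keep <- logical(length(structures))
  for (i in seq_along(structures)) {
    sg <- sequence_groups(structures[[i]])
    counts <- sort(as.integer(table(sg$group)), decreasing = TRUE)
    want <- sort(stoich$copies, decreasing = TRUE)
    if (!identical(counts, want)) {
      report <- c(report, sprintf(
        "model '%s': expected copy numbers {%s}, found {%s}",
        names(structures)[i], paste(want, collapse = ","),
        paste(counts, collapse = ",")))
      next
    }
    seq_multiset <- sort(sg$sequence)
    if (is.null(ref_counts)) {
      ref_counts <- seq_multiset
      groups <- sg
    } else if (!identical(seq_multiset, ref_counts)) {
      report <- c(report, sprintf(
        "model '%s': chain sequences differ from the other models",
        names(structures)[i]))
      next
    }
    keep[i] <- TRUE
  }
  if (!any(keep)) {
    abort(paste0("no model matches stoichiometry ",
                 paste0(stoich$label, stoich$copies, collapse = ""), ":\n",
                 paste(report, collapse = "\n")))
  }
  if (length(report)) {
    warn(paste0("rejected ", sum(!keep), " model(s):\n",
                paste(report, collapse = "\n")))
  }
  structure(
    list(target_id = target_id,
         structures = structures[keep],
         stoichiometry = stoich,
         sequence_groups = groups,
         rejected = report),
    class = "ensemble"
  )
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble> %s: %d model(s), stoichiometry %s\n",
              x$target_id, length(x$structures),
              paste0(x$stoichiometry$label, x$stoichiometry$copies, collapse = "")))
  invisible(x)
}

#' @export
length.ensemble <- function(x) length(x$structures)
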