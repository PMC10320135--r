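# PDB / CASP TS reading and writing. Parsing is delegated to bio3d; the
# filtering rules applied on top are:
#   * ATOM records only (no HETATM, no waters, no ligands)
#   * first MODEL block only
#   * altloc duplicates resolved by highest occupancy (ties: first seen)
#   * residues without a CA atom dropped

AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)
AA1TO3 <- setNames(names(AA3TO1), AA3TO1)

#' Read a protein structure from a PDB or CASP TS file
#'
#' Accepts standard PDB and the CASP TS dialect (PFRMAT/TARGET/MODEL header
#' lines are tolerated and skipped). Only the first MODEL block is read.
#' HETATM records, waters and non-polymer residues are excluded; for altloc
#' duplicates the highest-occupancy atom is kept (ties: first encountered);
#' residues lacking a CA atom are dropped.
#'
#' @param path Path to the file.
#' @param dialect `"pdb"` or `"casp_ts"` (parsed identically; the argument
#'   documents intent and is recorded as the model's provenance).
#' @param model_name Name for the model; defaults to the file name without
#'   extension.
#' @return A [structure3d()] object.
#' @export
read_structure <- function(path, dialect = c("pdb", "casp_ts"),
                           model_name = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE,
                                     hex = FALSE, rm.alt = FALSE)),
    error = function(e) {
      abort(paste0("cannot parse PDB file '", path, "': ", conditionMessage(e)))
    }
  )
  at <- pdb$atom
  at <- at[at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (nrow(at) == 0L) abort(paste0("no ATOM records in '", path, "'"))

  tb <- tibble(
    chain = ifelse(is.na(at$chain), " ", at$chain),
    resno = as.integer(at$resno),
    ins = ifelse(is.na(at$insert), "", at$insert),
    res3 = at$resid,
    atom = at$elety,
    alt = ifelse(is.na(at$alt), "", at$alt),
    element = ifelse(is.na(at$elesy), "", at$elesy),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, at$b)
  )
  if (any(!is.finite(tb$x) | !is.finite(tb$y) | !is.finite(tb$z))) {
    bad <- which(!is.finite(tb$x) | !is.finite(tb$y) | !is.finite(tb$z))[1]
    abort(paste0("non-finite coordinates at atom record ", bad, " of '", path, "'"))
  }

  # altloc: keep highest occupancy per (chain, resno, ins, atom); ties first.
  tb <- tb |>
    mutate(.row = row_number()) |>
    group_by(.data$chain, .data$resno, .data$ins, .data$atom) |>
    filter(.data$.row == .data$.row[which.max(.data$occ)]) |>
    ungroup() |>
    arrange(.data$.row) |>
    select(-".row", -"alt")

  tb$aa <- unname(AA3TO1[tb$res3])
  tb$aa[is.na(tb$aa)] <- "X"

  # drop residues without CA, then assign per-chain ordinals in file order
  tb <- tb |>
    group_by(.data$chain, .data$resno, .data$ins) |>
    filter(any(.data$atom == "CA")) |>
    ungroup()
  if (nrow(tb) == 0L) abort(paste0("no residues with CA atoms in '", path, "'"))

  reskey <- paste(tb$chain, tb$resno, tb$ins, sep = "\r")
  tb$res_index <- NA_integer_
  for (ch in unique(tb$chain)) {
    sel <- tb$chain == ch
    tb$res_index[sel] <- match(reskey[sel], unique(reskey[sel]))
  }

  if (is.null(model_name)) {
    model_name <- sub("\\.[^.]*$", "", basename(path))
  }
  s <- structure3d(tb[c("chain", "res_index", "resno", "ins", "aa", "atom",
                        "element", "x", "y", "z", "occ", "b")],
                   model_name = model_name)
  attr(s, "dialect") <- dialect
  s
}

# Shared ATOM-record writer.
format_pdb_atoms <- function(s, bvals = NULL) {
  at <- s$atoms
  if (is.null(bvals)) bvals <- at$b
  res3 <- unname(AA1TO3[at$aa])
  res3[is.na(res3)] <- "UNK"
  # atom-name column: names < 4 chars start in column 14
  aname <- ifelse(nchar(at$atom) >= 4, at$atom, sprintf(" %-3s", at$atom))
  elem <- ifelse(at$element == "", substr(trimws(at$atom), 1, 1), at$element)
  lines <- character(0)
  serial <- 0L
  for (ch in unique(at$chain)) {
    idx <- which(at$chain == ch)
    for (i in idx) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial %% 100000L, aname[i], res3[i], at$chain[i], at$resno[i],
        ifelse(at$ins[i] == "", " ", at$ins[i]),
        at$x[i], at$y[i], at$z[i], at$occ[i], bvals[i], elem[i]
      ))
    }
    last <- idx[length(idx)]
    serial <- serial + 1L
    lines <- c(lines, sprintf("TER   %5d      %3s %1s%4d",
                              serial %% 100000L, res3[last], at$chain[last],
                              at$resno[last]))
  }
  c(lines, "END")
}

#' Write a structure as a PDB file
#'
#' @param s A [structure3d()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "structure3d"))
  writeLines(format_pdb_atoms(s), path)
  invisible(path)
}

#' Write a structure with per-residue quality scores in the B-factor column
#'
#' Every atom of residue r is given B-factor `round(score(r) * 100, 2)`.
#' Residues without a score take the sentinel 0.00. Re-reading the file
#' recovers the scores to 2 decimals (<= 0.005 absolute error).
#'
#' @param s A [structure3d()].
#' @param per_residue_scores A data frame with columns `chain`, `res_index`
#'   and `score` (each score in `[0, 1]`), or a numeric vector named
#'   `"<chain>:<res_index>"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_with_bfactor <- function(s, per_residue_scores, path) {
  stopifnot(inherits(s, "structure3d"))
  if (is.numeric(per_residue_scores)) {
    nm <- strsplit(names(per_residue_scores), ":", fixed = TRUE)
    per_residue_scores <- tibble(
      chain = vapply(nm, `[`, "", 1),
      res_index = as.integer(vapply(nm, `[`, "", 2)),
      score = unname(per_residue_scores)
    )
  }
  sc <- as_tibble(per_residue_scores)
  stopifnot(all(c("chain", "res_index", "score") %in% names(sc)))
  if (any(!is.finite(sc$score)) || any(sc$score < 0 | sc$score > 1)) {
    abort("per-residue scores must lie in [0, 1]")
  }
  key <- paste(s$atoms$chain, s$atoms$res_index)
  sk <- paste(sc$chain, sc$res_index)
  b <- round(sc$score[match(key, sk)] * 100, 2)
  b[is.na(b)] <- 0
  writeLines(format_pdb_atoms(s, bvals = b), path)
  invisible(path)
}

#' Recover per-residue scores from a B-factor-annotated PDB file
#'
#' Inverse of [write_structure_with_bfactor()]: reads the file and converts
#' each residue's B-factor back to a score in `[0, 1]`.
#'
#' @param path Path to the PDB file.
#' @return A tibble `chain`, `res_index`, `score`.
#' @export
read_bfactor_scores <- function(path) {
  s <- read_structure(path)
  s$atoms |>
    group_by(.data$chain, .data$res_index) |>
    summarise(score = .data$b[.data$atom == "CA"][1] / 100, .groups = "drop")
}
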