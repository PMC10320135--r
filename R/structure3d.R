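#' In-memory representation of a (multi-chain) protein structure
#'
#' A `structure3d` is a light wrapper around a tibble of atoms — one row per
#' atom with columns `chain`, `res_index` (1-based ordinal position within
#' the chain after parsing), `resno` (author residue number), `ins`
#' (insertion code, `""` if none), `aa` (one-letter amino-acid code, `X` for
#' non-standard), `atom` (PDB atom name), `element`, `x`, `y`, `z`
#' (Angstrom), `occ` and `b`. Every residue is guaranteed to carry a CA
#' atom; chain identifiers are unique and chains keep file order.
#'
#' @param atoms A data frame with the columns above.
#' @param model_name Character scalar naming the model.
#' @return An object of class `structure3d`.
#' @export
structure3d <- function(atoms, model_name = "model") {
  atoms <- as_tibble(atoms)
  needed <- c("chain", "res_index", "resno", "ins", "aa", "atom",
              "element", "x", "y", "z", "occ", "b")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols)) {
    abort(paste0("atom table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(atoms) == 0L) abort("structure has no atoms")
  if (!all(is.finite(atoms$x)) || !all(is.finite(atoms$y)) || !all(is.finite(atoms$z))) {
    abort("atom coordinates must be finite")
  }
  has_ca <- atoms |>
    group_by(.data$chain, .data$res_index) |>
    summarise(ok = any(.data$atom == "CA"), .groups = "drop")
  if (!all(has_ca$ok)) abort("every residue must retain a CA atom")
  structure(list(model_name = model_name, atoms = atoms[needed]),
            class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  ch <- chain_table(x)
  cat(sprintf("<structure3d> %s: %d chain(s), %d residues, %d atoms\n",
              x$model_name, nrow(ch), sum(ch$n_res), nrow(x$atoms)))
  for (i in seq_len(nrow(ch))) {
    sq <- ch$sequence[i]
    if (nchar(sq) > 40) sq <- paste0(substr(sq, 1, 40), "...")
    cat(sprintf("  chain %s (%d res): %s\n", ch$chain[i], ch$n_res[i], sq))
  }
  invisible(x)
}

#' Per-chain summary of a structure
#'
#' @param s A `structure3d`.
#' @return A tibble with columns `chain`, `n_res` and `sequence`
#'   (one-letter), one row per chain in file order.
#' @export
chain_table <- function(s) {
  stopifnot(inherits(s, "structure3d"))
  res <- residue_table(s)
  res |>
    group_by(.data$chain) |>
    summarise(n_res = n(),
              sequence = paste(.data$aa, collapse = ""),
              .groups = "drop") |>
    arrange(match(.data$chain, unique(s$atoms$chain)))
}

#' Residue-level view of a structure
#'
#' @param s A `structure3d`.
#' @return A tibble with one row per residue: `chain`, `res_index`, `resno`,
#'   `ins`, `aa`, in chain/file order.
#' @export
residue_table <- function(s) {
  stopifnot(inherits(s, "structure3d"))
  s$atoms |>
    distinct(.data$chain, .data$res_index, .data$resno, .data$ins, .data$aa) |>
    arrange(match(.data$chain, unique(s$atoms$chain)), .data$res_index)
}

chain_ids <- function(s) unique(s$atoms$chain)

# Named chain -> sequence vector.
chain_sequences <- function(s) {
  ch <- chain_table(s)
  setNames(ch$sequence, ch$chain)
}

#' Apply a rigid transform (or arbitrary coordinate function) to a structure
#'
#' @param s A `structure3d`.
#' @param rotation 3 x 3 rotation matrix (row-vector convention).
#' @param translation Length-3 translation (Angstrom).
#' @param chains Chains to transform; default all.
#' @return The transformed `structure3d`.
#' @export
transform_structure <- function(s, rotation = diag(3), translation = c(0, 0, 0),
                                chains = NULL) {
  stopifnot(inherits(s, "structure3d"))
  sel <- if (is.null(chains)) rep(TRUE, nrow(s$atoms)) else s$atoms$chain %in% chains
  xyz <- as.matrix(s$atoms[sel, c("x", "y", "z")])
  xyz <- sweep(xyz %*% rotation, 2, translation, "+")
  s$atoms$x[sel] <- xyz[, 1]
  s$atoms$y[sel] <- xyz[, 2]
  s$atoms$z[sel] <- xyz[, 3]
  s
}

# ---------------------------------------------------------------------------
# Feature cache: everything the metrics need, precomputed once per structure.
# rid is a global residue index 1..R in chain/file order.

structure_features <- function(s) {
  if (!is.null(attr(s, "dockjury_features"))) return(attr(s, "dockjury_features"))
  stopifnot(inherits(s, "structure3d"))
  at <- s$atoms
  res <- residue_table(s)
  res$rid <- seq_len(nrow(res))
  rid <- res$rid[match(paste(at$chain, at$res_index), paste(res$chain, res$res_index))]
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rownames(xyz) <- NULL
  akey <- paste(at$chain, at$res_index, at$atom, sep = "|")

  ca_i <- which(at$atom == "CA")
  ca <- xyz[ca_i[match(res$rid, rid[ca_i])], , drop = FALSE]

  # CB with CA fallback (glycine and any residue lacking CB)
  cb_i <- which(at$atom == "CB")
  cb_row <- cb_i[match(res$rid, rid[cb_i])]
  cb <- ca
  ok <- !is.na(cb_row)
  cb[ok, ] <- xyz[cb_row[ok], , drop = FALSE]

  list(
    s = s,
    atoms = at, res = res, rid = rid, xyz = xyz, akey = akey,
    atom_reskey = paste(at$chain, at$res_index),
    res_key = paste(res$chain, res$res_index),
    ca = ca, cb = cb,
    chains = unique(at$chain),
    seqs = chain_sequences(s),
    backbone = at$atom %in% c("N", "CA", "C", "O")
  )
}

# Attach the feature cache so repeated metric calls on the same object are
# cheap (used heavily by the jury layer).
with_features <- function(s) {
  if (inherits(s, "structure3d") && is.null(attr(s, "dockjury_features"))) {
    attr(s, "dockjury_features") <- structure_features(s)
  }
  s
}

as_features <- function(x) {
  if (is.list(x) && !inherits(x, "structure3d") && !is.null(x$akey)) return(x)
  structure_features(x)
}
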