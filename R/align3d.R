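# Superposition-based per-chain comparison: GDT_TS and the two RMSD terms
# of DockQ (interface RMSD and ligand RMSD after receptor fit).

BACKBONE <- c("N", "CA", "C", "O")

# CA coordinate matrices for a chain pair, matched by residue ordinal.
matched_ca <- function(fm, fr, model_chain, ref_chain) {
  mr <- fm$res[fm$res$chain == model_chain, ]
  rr <- fr$res[fr$res$chain == ref_chain, ]
  common <- intersect(mr$res_index, rr$res_index)
  if (length(common) < 3L) abort("fewer than 3 paired residues")
  list(
    model = fm$ca[mr$rid[match(common, mr$res_index)], , drop = FALSE],
    ref = fr$ca[rr$rid[match(common, rr$res_index)], , drop = FALSE],
    res_index = common
  )
}

# Exhaustive continuous-seed GDT search for one threshold: every contiguous
# window of the given lengths seeds a superposition that is iteratively
# re-fit on the within-threshold subset until fixed point.
gdt_fraction <- function(mca, rca, threshold, seed_lengths = c(3, 5, 7),
                         max_iter = 10) {
  n <- nrow(mca)
  best <- 0
  seeds <- list(seq_len(n)) # full-set fit as an extra seed
  for (L in seed_lengths) {
    if (L > n) next
    for (s in seq_len(n - L + 1L)) {
      seeds[[length(seeds) + 1L]] <- s:(s + L - 1L)
    }
  }
  for (seed in seeds) {
    cur <- seed
    frac <- 0
    for (it in seq_len(max_iter)) {
      sp <- tryCatch(kabsch_superpose(mca[cur, , drop = FALSE],
                                      rca[cur, , drop = FALSE]),
                     error = function(e) NULL)
      if (is.null(sp)) break
      d <- row_dist(apply_superposition(sp, mca), rca)
      within <- which(d <= threshold)
      frac <- length(within) / n
      if (length(within) < 3L || identical(within, cur)) break
      cur <- within
    }
    if (frac > best) best <- frac
    if (best >= 1) return(1)
  }
  best
}

#' GDT_TS between a model chain and a reference chain
#'
#' Global Distance Test Total Score: the average over thresholds 1, 2, 4
#' and 8 Angstrom of the maximal fraction of paired CA atoms that can be
#' placed within the threshold by a rigid superposition. The maximal
#' fraction is approximated by a deterministic exhaustive-seed search:
#' every contiguous window of lengths 3, 5 and 7 (plus the full chain)
#' seeds a superposition that is re-fit on its within-threshold subset
#' until a fixed point.
#'
#' @param model,reference [structure3d()] objects sharing sequences.
#' @param model_chain,ref_chain Chain ids to compare (default: the first
#'   chain of each). Residues are paired by their ordinal index.
#' @return A list of class `tertiary_score`: `gdt_ts` in `[0, 100]`,
#'   `rmsd_ca` (Angstrom, all paired CAs), `per_threshold` (named
#'   fractions at 1/2/4/8 A).
#' @export
gdt_ts <- function(model, reference, model_chain = NULL, ref_chain = NULL) {
  fm <- as_features(model)
  fr <- as_features(reference)
  model_chain <- model_chain %||% fm$chains[1]
  ref_chain <- ref_chain %||% fr$chains[1]
  m <- matched_ca(fm, fr, model_chain, ref_chain)

  thresholds <- c(1, 2, 4, 8)
  fracs <- vapply(thresholds, function(t) gdt_fraction(m$model, m$ref, t), 0)
  names(fracs) <- paste0("frac_", thresholds, "A")
  structure(
    list(gdt_ts = 25 * sum(fracs),
         rmsd_ca = kabsch_superpose(m$model, m$ref)$rmsd,
         per_threshold = fracs,
         n_pairs = nrow(m$model)),
    class = "tertiary_score"
  )
}

#' @export
print.tertiary_score <- function(x, ...) {
  cat(sprintf("<tertiary_score> GDT_TS = %.2f, CA RMSD = %.3f A (%d residues)\n",
              x$gdt_ts, x$rmsd_ca, x$n_pairs))
  invisible(x)
}

# Matched backbone coordinates for a set of (ref chain, res_index) residues.
# Returns model and reference matrices over atoms present in both. `mkey`
# may carry precomputed model atom keys translated into reference labels.
matched_backbone <- function(fm, fr, map, residues, mkey = NULL) {
  rsel <- fr$backbone &
    fr$atom_reskey %in% paste(residues$chain, residues$res_index)
  rkeys <- fr$akey[rsel]
  if (is.null(mkey)) {
    mkey <- paste(unname(map[fm$atoms$chain]), fm$atoms$res_index,
                  fm$atoms$atom, sep = "|")
  }
  idx <- match(rkeys, mkey)
  ok <- !is.na(idx)
  list(model = fm$xyz[idx[ok], , drop = FALSE],
       ref = fr$xyz[which(rsel)[ok], , drop = FALSE])
}

#' Ligand RMSD after receptor superposition (LRMS)
#'
#' Backbone atoms (N, CA, C, O; a missing O is tolerated) of the model are
#' superposed onto the reference over the receptor chains; the RMSD of the
#' ligand-chain backbone is then reported without re-fitting. The receptor
#' is the side with more residues (ties: lexicographically first chain
#' set).
#'
#' @param model,reference [structure3d()] objects.
#' @param mapping A [map_chains()] result or named vector; solved when
#'   `NULL`.
#' @param receptor,ligand Character vectors of reference chain ids
#'   partitioning the interface's two sides.
#' @return RMSD in Angstrom.
#' @export
lrms <- function(model, reference, mapping = NULL, receptor, ligand) {
  fm <- as_features(model)
  fr <- as_features(reference)
  if (is.null(mapping)) mapping <- map_chains_features(fm, fr)
  map <- as_mapping_vector(mapping)
  if (length(receptor) == 0L || length(ligand) == 0L) {
    abort("receptor and ligand chain sets must be non-empty")
  }
  rec_res <- fr$res[fr$res$chain %in% receptor, c("chain", "res_index")]
  lig_res <- fr$res[fr$res$chain %in% ligand, c("chain", "res_index")]
  rec <- matched_backbone(fm, fr, map, rec_res)
  lig <- matched_backbone(fm, fr, map, lig_res)
  sp <- kabsch_superpose(rec$model, rec$ref)
  sqrt(mean(rowSums((apply_superposition(sp, lig$model) - lig$ref)^2)))
}

#' Interface RMSD (iRMS)
#'
#' Backbone RMSD over the interface residues only, after superposing the
#' model onto the reference on those same atoms.
#'
#' @inheritParams lrms
#' @param interface A tibble `chain`, `res_index` of reference interface
#'   residues (see [interface_residues()]).
#' @return RMSD in Angstrom.
#' @export
irms <- function(model, reference, mapping = NULL, interface) {
  fm <- as_features(model)
  fr <- as_features(reference)
  if (is.null(mapping)) mapping <- map_chains_features(fm, fr)
  map <- as_mapping_vector(mapping)
  if (nrow(interface) < 3L) abort("fewer than 3 interface residues")
  bb <- matched_backbone(fm, fr, map, interface)
  kabsch_superpose(bb$model, bb$ref)$rmsd
}
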