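# One pairwise comparison = the kernel the jury consumes: chain mapping +
# oligo-lDDT (with per-residue vector) + QS + DockQ, computed on cached
# per-structure features.

# fm, fr: features (ideally from features_with_contacts). mapping optional.
compare_pair <- function(fm, fr, mapping = NULL) {
  if (is.null(mapping)) mapping <- map_chains_features(fm, fr)
  map <- as_mapping_vector(mapping)
  mkey <- paste(unname(map[fm$atoms$chain]), fm$atoms$res_index, fm$atoms$atom,
                sep = "|")
  ld <- lddt_core(fm, fr, map, mkey = mkey)
  qs <- qs_core(fm, fr, map)
  dq <- dockq_core(fm, fr, map, mkey = mkey)
  list(mapping = map,
       oligo_lddt = ld$global, lddt_per_residue = ld$per_residue,
       qs = qs$global, qs_per_interface = qs$per_interface,
       dockq = dq$global, dockq_per_interface = dq$per_interface)
}

#' Full pairwise comparison of two complexes
#'
#' Solves the chain mapping, then reports every metric of one model scored
#' against one reference: oligo-lDDT (global and per residue), QS-score
#' (global and per interface), DockQ (aggregate and per interface) and
#' per-chain GDT_TS / CA RMSD.
#'
#' @param model,reference [structure3d()] objects with the same
#'   stoichiometry.
#' @return A list of class `comparison`: `mapping`, `global` (one-row
#'   tibble `oligo_lddt`, `qs`, `dockq`), `per_residue`, `per_interface`,
#'   `per_chain` (tibble `model_chain`, `ref_chain`, `gdt_ts`, `rmsd_ca`).
#' @export
compare_structures <- function(model, reference) {
  fm <- features_with_contacts(model)
  fr <- features_with_contacts(reference)
  cmp <- compare_pair(fm, fr)

  chains <- names(cmp$mapping)
  per_chain <- list_rbind(lapply(chains, function(ch) {
    ts <- gdt_ts(fm, fr, model_chain = ch, ref_chain = cmp$mapping[[ch]])
    tibble(model_chain = ch, ref_chain = unname(cmp$mapping[[ch]]),
           gdt_ts = ts$gdt_ts, rmsd_ca = ts$rmsd_ca)
  }))

  structure(
    list(mapping = cmp$mapping,
         global = tibble(oligo_lddt = cmp$oligo_lddt, qs = cmp$qs,
                         dockq = cmp$dockq),
         per_residue = cmp$lddt_per_residue,
         per_interface = left_join(cmp$qs_per_interface,
                                   cmp$dockq_per_interface,
                                   by = c("chain_i", "chain_j")),
         per_chain = per_chain),
    class = "comparison"
  )
}

#' @export
print.comparison <- function(x, ...) {
  g <- x$global
  cat(sprintf("<comparison> oligo-lDDT = %.3f, QS = %.3f, DockQ = %.3f\n",
              g$oligo_lddt, g$qs, g$dockq))
  cat(sprintf("  mapping: %s\n",
              paste(names(x$mapping), x$mapping, sep = "->", collapse = ", ")))
  invisible(x)
}
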