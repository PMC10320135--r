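# QS-score: agreement of inter-chain residue contacts between two
# complexes. Contacts use CB (CA for glycine) at a 12 A cutoff on both
# structures. A contact shared by model and reference contributes
# w = max(0, 1 - |d_model - d_ref| / 12); the score normalises by the union
# of contacts:
#   QS = sum_shared w / (N_shared + N_model_only + N_ref_only)

#' QS-score between a model and a reference complex
#'
#' @inheritParams oligo_lddt
#' @return An object of class `metric_result` with `metric = "qs"`,
#'   `global` in `[0, 1]` and `per_interface` (tibble `chain_i`, `chain_j`
#'   in reference labels, `qs` restricted to that chain pair's contacts).
#' @export
qs_score <- function(model, reference, mapping = NULL) {
  fm <- as_features(model)
  fr <- as_features(reference)
  if (is.null(mapping)) mapping <- map_chains_features(fm, fr)
  map <- as_mapping_vector(mapping)
  out <- qs_core(fm, fr, map)
  structure(list(metric = "qs", global = out$global,
                 per_interface = out$per_interface),
            class = "metric_result")
}

qs_core <- function(fm, fr, map) {
  mc <- cached_cb12(fm)
  rc <- cached_cb12(fr)
  if (nrow(mc) + nrow(rc) == 0L) {
    abort("QS-score undefined: no inter-chain contacts in either structure")
  }
  mk <- relabel_contact_keys(mc, map)
  rk <- ref_contact_keys(rc)
  global <- qs_from_keys(mk, mc$dist, rk, rc$dist)

  # per-interface breakdown in reference chain labels
  m_ci <- unname(map[mc$chain_i]); m_cj <- unname(map[mc$chain_j])
  m_pair <- ifelse(m_ci < m_cj, paste(m_ci, m_cj), paste(m_cj, m_ci))
  r_pair <- paste(rc$chain_i, rc$chain_j)
  pairs <- sort(unique(c(m_pair, r_pair)))
  per <- lapply(pairs, function(p) {
    ms <- m_pair == p
    rs <- r_pair == p
    tibble(chain_i = strsplit(p, " ")[[1]][1],
           chain_j = strsplit(p, " ")[[1]][2],
           qs = qs_from_keys(mk[ms], mc$dist[ms], rk[rs], rc$dist[rs]))
  })
  list(global = global, per_interface = list_rbind(per))
}
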