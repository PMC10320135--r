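# Oligomeric local Distance Difference Test: superposition-free, all heavy
# atoms, all residue pairs (intra- and inter-chain) within the inclusion
# radius on the reference. Per-residue score = mean over thresholds of the
# preserved fraction of that residue's pairs; global = mean over residues.

#' Oligo-lDDT between a model and a reference complex
#'
#' For every reference atom pair in different residues (including
#' inter-chain pairs under the chain mapping) within `inclusion_radius`,
#' the model distance is compared against the reference distance at each
#' threshold. A pair is preserved at threshold t when the absolute distance
#' difference is <= t. Atoms are matched by (mapped chain, residue ordinal,
#' atom name); only atoms present in both structures are scored.
#'
#' @param model,reference [structure3d()] objects.
#' @param mapping A [map_chains()] result or named vector model chain ->
#'   reference chain; solved automatically when `NULL`.
#' @param inclusion_radius Reference distance cutoff in Angstrom
#'   (default 15).
#' @param thresholds Distance-difference tolerances in Angstrom
#'   (default 0.5, 1, 2, 4).
#' @return An object of class `metric_result`: a list with `metric`
#'   (`"oligo_lddt"`), `global` in `[0, 1]` and `per_residue` (tibble
#'   `chain`, `res_index`, `score` on the model's residues; `NA` for
#'   residues with no scorable pair).
#' @export
oligo_lddt <- function(model, reference, mapping = NULL,
                       inclusion_radius = 15, thresholds = c(0.5, 1, 2, 4)) {
  fm <- as_features(model)
  fr <- as_features(reference)
  if (is.null(mapping)) mapping <- map_chains_features(fm, fr)
  map <- as_mapping_vector(mapping)
  out <- lddt_core(fm, fr, map, inclusion_radius, thresholds)
  structure(list(metric = "oligo_lddt", global = out$global,
                 per_residue = out$per_residue),
            class = "metric_result")
}

lddt_core <- function(fm, fr, map, inclusion_radius = 15,
                      thresholds = c(0.5, 1, 2, 4), mkey = NULL) {
  # model atom keys translated into reference chain labels
  if (is.null(mkey)) {
    mkey <- paste(unname(map[fm$atoms$chain]), fm$atoms$res_index, fm$atoms$atom,
                  sep = "|")
  }
  idx <- match(fr$akey, mkey) # for each ref atom, the matching model atom
  keep <- which(!is.na(idx))
  if (length(keep) < 2L) abort("no common atoms to score")

  ar <- fr$xyz[keep, , drop = FALSE]
  am <- fm$xyz[idx[keep], , drop = FALSE]
  rid <- fr$rid[keep]

  dr <- dist_mat(ar, ar)
  dm <- dist_mat(am, am)
  k <- length(keep)
  sel <- upper.tri(dr) & dr <= inclusion_radius &
    outer(rid, rid, "!=")
  pr <- which(sel, arr.ind = TRUE)
  if (nrow(pr) == 0L) abort("no scorable atom pairs within the inclusion radius")

  adiff <- abs(dm[sel] - dr[sel])
  w <- numeric(length(adiff))
  for (t in thresholds) w <- w + (adiff <= t)
  w <- w / length(thresholds)

  ri <- rid[pr[, 1]]
  rj <- rid[pr[, 2]]
  acc <- rowsum(c(w, w), c(ri, rj))
  cnt <- rowsum(rep(1, 2 * length(w)), c(ri, rj))
  scored_rid <- as.integer(rownames(acc))
  score <- as.numeric(acc / cnt)

  # express per-residue scores on the model's residues (model order)
  score_by_rid <- rep(NA_real_, nrow(fr$res))
  score_by_rid[scored_rid] <- score
  mres_refkey <- paste(unname(map[fm$res$chain]), fm$res$res_index)
  ridx <- match(mres_refkey, fr$res_key)
  per <- tibble::new_tibble(
    list(chain = fm$res$chain, res_index = fm$res$res_index,
         score = score_by_rid[ridx]),
    nrow = nrow(fm$res)
  )

  list(global = mean(score), per_residue = per)
}

#' @export
print.metric_result <- function(x, ...) {
  cat(sprintf("<metric_result> %s: global = %.4f\n", x$metric, x$global))
  invisible(x)
}
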