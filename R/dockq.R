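# DockQ: composite interface quality score
#   DockQ = ( Fnat + 1/(1+(iRMS/1.5)^2) + 1/(1+(LRMS/8.5)^2) ) / 3
# per reference interface; the multimer aggregate is the unweighted mean
# over all reference interfaces under the chain mapping.

#' Fraction of native contacts (Fnat)
#'
#' The fraction of the reference's inter-chain residue contacts (minimum
#' heavy-atom distance <= 5 Angstrom) across the chain pair that are also
#' contacts in the model under the chain mapping.
#'
#' @inheritParams lrms
#' @param chain_pair Two reference chain ids.
#' @return Fraction in `[0, 1]`.
#' @export
fnat <- function(model, reference, mapping = NULL, chain_pair) {
  fm <- as_features(model)
  fr <- as_features(reference)
  if (is.null(mapping)) mapping <- map_chains_features(fm, fr)
  map <- as_mapping_vector(mapping)
  fnat_core(fm, fr, map, chain_pair)
}

fnat_core <- function(fm, fr, map, chain_pair) {
  rc <- contacts_between(fr, chain_pair[1], chain_pair[2], 5)
  if (nrow(rc) == 0L) {
    abort(sprintf("Fnat undefined: no native contacts across %s-%s",
                  chain_pair[1], chain_pair[2]))
  }
  inv <- setNames(names(map), unname(map))
  mc <- contacts_between(fm, inv[chain_pair[1]], inv[chain_pair[2]], 5)
  if (nrow(mc) == 0L) return(0)
  mk <- relabel_contact_keys(mc, map)
  rk <- ref_contact_keys(rc)
  mean(rk %in% mk)
}

#' DockQ score of a model against a reference complex
#'
#' Combines Fnat, the interface RMSD (10 Angstrom heavy-atom interface on
#' the reference) and the ligand RMSD after receptor superposition:
#' `DockQ = (Fnat + 1/(1+(iRMS/1.5)^2) + 1/(1+(LRMS/8.5)^2)) / 3`.
#' With `chain_pair = NULL` the multimer aggregate is returned: the
#' unweighted mean of DockQ over every reference interface (chain pairs
#' with at least one native heavy-atom contact at 5 Angstrom).
#'
#' @inheritParams lrms
#' @param chain_pair Two reference chain ids, or `NULL` for all reference
#'   interfaces.
#' @return An object of class `metric_result` with `metric = "dockq"`,
#'   `global` in `[0, 1]` and `per_interface` (tibble `chain_i`, `chain_j`,
#'   `fnat`, `irms`, `lrms`, `dockq`).
#' @export
dockq <- function(model, reference, mapping = NULL, chain_pair = NULL) {
  fm <- as_features(model)
  fr <- as_features(reference)
  if (is.null(mapping)) mapping <- map_chains_features(fm, fr)
  map <- as_mapping_vector(mapping)
  out <- dockq_core(fm, fr, map, chain_pair)
  structure(list(metric = "dockq", global = out$global,
                 per_interface = out$per_interface),
            class = "metric_result")
}

dockq_formula <- function(fnat, irms, lrms) {
  (fnat + 1 / (1 + (irms / 1.5)^2) + 1 / (1 + (lrms / 8.5)^2)) / 3
}

dockq_core <- function(fm, fr, map, chain_pair = NULL, mkey = NULL) {
  hc <- cached_heavy12(fr)
  native <- hc[hc$dist <= 5, , drop = FALSE]
  pairs <- if (is.null(chain_pair)) {
    unique(native[c("chain_i", "chain_j")])
  } else {
    p <- sort(chain_pair)
    data.frame(chain_i = p[1], chain_j = p[2])
  }
  if (nrow(pairs) == 0L) {
    abort("DockQ undefined: the reference has no inter-chain interface")
  }
  if (is.null(mkey)) {
    mkey <- paste(unname(map[fm$atoms$chain]), fm$atoms$res_index,
                  fm$atoms$atom, sep = "|")
  }

  rows <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    cp <- c(pairs$chain_i[k], pairs$chain_j[k])
    fn <- fnat_core(fm, fr, map, cp)

    iface <- interface_residues(fr, cp, cutoff = 10)
    if (nrow(iface) < 3L) abort("fewer than 3 interface residues")
    bb <- matched_backbone(fm, fr, map, iface, mkey = mkey)
    ir <- kabsch_superpose(bb$model, bb$ref)$rmsd

    # receptor = chain with more residues; tie -> lexicographically first
    n1 <- sum(fr$res$chain == cp[1])
    n2 <- sum(fr$res$chain == cp[2])
    receptor <- if (n1 > n2 || (n1 == n2 && cp[1] < cp[2])) cp[1] else cp[2]
    ligand <- setdiff(cp, receptor)
    rec <- matched_backbone(fm, fr, map,
                            fr$res[fr$res$chain == receptor,
                                   c("chain", "res_index")], mkey = mkey)
    lig <- matched_backbone(fm, fr, map,
                            fr$res[fr$res$chain == ligand,
                                   c("chain", "res_index")], mkey = mkey)
    sp <- kabsch_superpose(rec$model, rec$ref)
    lr <- sqrt(mean(rowSums((apply_superposition(sp, lig$model) - lig$ref)^2)))

    rows[[k]] <- data.frame(chain_i = cp[1], chain_j = cp[2], fnat = fn,
                            irms = ir, lrms = lr,
                            dockq = dockq_formula(fn, ir, lr))
  }
  per <- as_tibble(do.call(rbind, rows))
  list(global = mean(per$dockq), per_interface = per)
}
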