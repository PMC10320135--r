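# Inter-chain residue contacts. Two schemes:
#   cb    — CB-CB distance (CA for glycine), the QS-score substrate
#   heavy — minimum heavy-atom distance between residues (Fnat, interfaces)
# Pairs are canonical: each unordered residue pair stored once with
# chain_i < chain_j (file order of chains), never intra-chain.

#' Inter-chain residue contact map
#'
#' @param s A [structure3d()].
#' @param scheme `"cb"` (CB-CB, CA for glycine) or `"heavy"` (minimum
#'   heavy-atom distance).
#' @param cutoff Distance cutoff in Angstrom (> 0).
#' @return A tibble of class `contact_map` with columns `chain_i`, `res_i`,
#'   `chain_j`, `res_j`, `dist`, and attributes `scheme` and `cutoff`.
#'   Empty when no residue pair is within the cutoff.
#' @export
inter_chain_contacts <- function(s, scheme = c("cb", "heavy"), cutoff = 12) {
  scheme <- match.arg(scheme)
  if (cutoff <= 0) abort("cutoff must be > 0")
  f <- as_features(s)
  out <- if (scheme == "cb") cb_contacts(f, cutoff) else heavy_contacts(f, cutoff)
  attr(out, "scheme") <- scheme
  attr(out, "cutoff") <- cutoff
  class(out) <- c("contact_map", class(out))
  out
}

cb_contacts <- function(f, cutoff) {
  res <- f$res
  d <- dist_mat(f$cb, f$cb)
  chain_rank <- match(res$chain, f$chains)
  inter <- outer(chain_rank, chain_rank, "<") # upper block triangle, once
  hit <- which(inter & d <= cutoff, arr.ind = TRUE)
  tibble(
    chain_i = res$chain[hit[, 1]], res_i = res$res_index[hit[, 1]],
    chain_j = res$chain[hit[, 2]], res_j = res$res_index[hit[, 2]],
    dist = d[hit]
  )
}

heavy_contacts <- function(f, cutoff) {
  chains <- f$chains
  rows <- list()
  for (a in seq_along(chains)) {
    for (b in seq_along(chains)) {
      if (b <= a) next
      ia <- which(f$atoms$chain == chains[a])
      ib <- which(f$atoms$chain == chains[b])
      d <- dist_mat(f$xyz[ia, , drop = FALSE], f$xyz[ib, , drop = FALSE])
      ra <- f$atoms$res_index[ia]
      rb <- f$atoms$res_index[ib]
      # min over atoms, residue by residue
      m1 <- do.call(rbind, lapply(split(seq_along(ia), ra), function(ix) {
        if (length(ix) == 1L) d[ix, ] else do.call(pmin, asplit(d[ix, , drop = FALSE], 1))
      }))
      m2 <- do.call(rbind, lapply(split(seq_along(ib), rb), function(ix) {
        if (length(ix) == 1L) m1[, ix] else do.call(pmin, asplit(m1[, ix, drop = FALSE], 2))
      }))
      # m2: rows = residues of b (split order), cols = residues of a
      res_a <- as.integer(rownames(m1))
      res_b <- as.integer(rownames(m2))
      hit <- which(t(m2) <= cutoff, arr.ind = TRUE)
      if (nrow(hit)) {
        rows[[length(rows) + 1L]] <- tibble(
          chain_i = chains[a], res_i = res_a[hit[, 1]],
          chain_j = chains[b], res_j = res_b[hit[, 2]],
          dist = t(m2)[hit]
        )
      }
    }
  }
  if (length(rows)) list_rbind(rows) else {
    tibble(chain_i = character(), res_i = integer(),
           chain_j = character(), res_j = integer(), dist = numeric())
  }
}

#' Interface residues of a chain pair
#'
#' Residues of either chain having any heavy atom within `cutoff` of the
#' other chain, measured on `reference`.
#'
#' @param reference A [structure3d()].
#' @param chain_pair Character vector of two chain ids.
#' @param cutoff Heavy-atom distance cutoff in Angstrom (default 10).
#' @return A tibble `chain`, `res_index` (possibly empty).
#' @export
interface_residues <- function(reference, chain_pair, cutoff = 10) {
  f <- as_features(reference)
  if (!all(chain_pair %in% f$chains)) {
    abort("chain_pair must name two chains of the structure")
  }
  cts <- contacts_between(f, chain_pair[1], chain_pair[2], cutoff)
  if (nrow(cts) == 0L) {
    return(tibble(chain = character(), res_index = integer()))
  }
  ch <- c(cts$chain_i, cts$chain_j)
  ri <- c(cts$res_i, cts$res_j)
  keep <- !duplicated(paste(ch, ri))
  ord <- order(ch[keep], ri[keep])
  tibble::new_tibble(list(chain = ch[keep][ord], res_index = ri[keep][ord]),
                     nrow = sum(keep))
}

# Heavy contacts restricted to one chain pair, from the cached <=12 A map.
contacts_between <- function(f, ca_, cb_, cutoff) {
  stopifnot(cutoff <= 12)
  hc <- cached_heavy12(f)
  sel <- ((hc$chain_i == ca_ & hc$chain_j == cb_) |
            (hc$chain_i == cb_ & hc$chain_j == ca_)) & hc$dist <= cutoff
  hc[sel, , drop = FALSE]
}

# Lazily attach the 12 A maps to a features list (environment-free caching:
# the jury layer holds on to the returned features).
cached_cb12 <- function(f) {
  if (is.null(f$cb12)) f$cb12 <- cb_contacts(f, 12) # nolint: assigned to local copy
  f$cb12
}
cached_heavy12 <- function(f) {
  if (is.null(f$heavy12)) f$heavy12 <- heavy_contacts(f, 12)
  f$heavy12
}

# Precompute both contact maps into the features list (jury fast path).
# Plain data frames: repeated row subsetting is cheaper than on tibbles.
features_with_contacts <- function(s) {
  f <- as_features(s)
  f$cb12 <- as.data.frame(cb_contacts(f, 12))
  f$heavy12 <- as.data.frame(heavy_contacts(f, 12))
  f
}
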