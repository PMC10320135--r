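# Chain mapping between two complexes. A mapping is a named character
# vector model_chain -> reference_chain, a bijection restricted to
# identical-sequence groups, chosen to maximise the QS-style shared-contact
# objective. Exhaustive over within-group permutations when the largest
# group has <= 6 copies, otherwise greedy with one round of pairwise-swap
# hill climbing.

# Canonical contact keys after relabelling model chains into reference ids.
relabel_contact_keys <- function(cts, map) {
  ci <- unname(map[cts$chain_i])
  cj <- unname(map[cts$chain_j])
  swap <- ci > cj
  k1 <- ifelse(swap, cj, ci)
  r1 <- ifelse(swap, cts$res_j, cts$res_i)
  k2 <- ifelse(swap, ci, cj)
  r2 <- ifelse(swap, cts$res_i, cts$res_j)
  paste(k1, r1, k2, r2)
}

ref_contact_keys <- function(cts) paste(cts$chain_i, cts$res_i, cts$chain_j, cts$res_j)

# QS from two canonical contact key/dist sets.
qs_from_keys <- function(mk, md, rk, rd) {
  n_m <- length(mk)
  n_r <- length(rk)
  if (n_m + n_r == 0L) return(NA_real_)
  im <- match(mk, rk)
  shared <- which(!is.na(im))
  w <- if (length(shared)) {
    pmax(0, 1 - abs(md[shared] - rd[im[shared]]) / 12)
  } else numeric(0)
  denom <- length(shared) + (n_m - length(shared)) + (n_r - length(shared))
  sum(w) / denom
}

# All sequence-group-respecting candidate mappings (list of named vectors).
group_permutations <- function(model_groups, ref_groups) {
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  per_group <- lapply(seq_along(model_groups), function(g) {
    lapply(perms(ref_groups[[g]]), function(p) setNames(p, model_groups[[g]]))
  })
  out <- list(setNames(character(0), character(0)))
  for (g in per_group) {
    out <- unlist(lapply(out, function(acc) lapply(g, function(p) c(acc, p))),
                  recursive = FALSE)
  }
  out
}

#' Optimal chain mapping between two complexes
#'
#' Finds the bijection from model chains to reference chains (restricted to
#' identical-sequence groups) that maximises the QS-style shared-contact
#' objective. Groups with at most 6 copies are searched exhaustively;
#' larger groups fall back to a greedy assignment by contact-profile
#' similarity followed by one round of pairwise-swap hill climbing.
#'
#' @param model,reference [structure3d()] objects with the same
#'   stoichiometry (same multiset of chain sequences).
#' @param groups Optional precomputed sequence grouping (unused unless you
#'   need to override exact-sequence grouping; default derives groups from
#'   the sequences).
#' @return An object of class `chain_mapping`: a list with `pairs` (named
#'   character vector model chain -> reference chain) and `score` (the QS
#'   objective achieved).
#' @export
map_chains <- function(model, reference, groups = NULL) {
  fm <- as_features(model)
  fr <- as_features(reference)
  map_chains_features(fm, fr)
}

map_chains_features <- function(fm, fr) {
  mseq <- fm$seqs
  rseq <- fr$seqs
  if (!identical(sort(unname(mseq)), sort(unname(rseq)))) {
    abort("chain mapping requires identical stoichiometry (same multiset of chain sequences)")
  }
  useq <- unique(unname(rseq))
  model_groups <- lapply(useq, function(sq) sort(names(mseq)[mseq == sq]))
  ref_groups <- lapply(useq, function(sq) sort(names(rseq)[rseq == sq]))

  mc <- cached_cb12(fm)
  rc <- cached_cb12(fr)
  rk <- ref_contact_keys(rc)

  objective <- function(map) {
    v <- qs_from_keys(relabel_contact_keys(mc, map), mc$dist, rk, rc$dist)
    if (is.na(v)) 0 else v
  }

  max_copies <- max(vapply(model_groups, length, 0L))
  if (max_copies <= 6L) {
    cands <- group_permutations(model_groups, ref_groups)
    scores <- vapply(cands, objective, 0)
    best <- which.max(scores) # first maximum: deterministic tie-break
    map <- cands[[best]]
    score <- scores[best]
  } else {
    map <- greedy_mapping(fm, fr, model_groups, ref_groups)
    score <- objective(map)
    # one round of within-group pairwise-swap hill climbing
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      for (g in seq_along(model_groups)) {
        mg <- model_groups[[g]]
        if (length(mg) < 2L) next
        for (i in seq_len(length(mg) - 1L)) {
          for (j in seq((i + 1L), length(mg))) {
            cand <- map
            cand[c(mg[i], mg[j])] <- cand[c(mg[j], mg[i])]
            sc <- objective(cand)
            if (sc > score + 1e-12) {
              map <- cand; score <- sc; improved <- TRUE
            }
          }
        }
      }
      break # single round
    }
  }
  structure(list(pairs = map[order(names(map))], score = score),
            class = "chain_mapping")
}

# Greedy seed for large groups: match chains by similarity of their
# inter-chain contact-degree profiles, ties broken lexicographically.
greedy_mapping <- function(fm, fr, model_groups, ref_groups) {
  degree_profile <- function(f, ch) {
    cts <- cached_cb12(f)
    n <- sum(cts$chain_i == ch) + sum(cts$chain_j == ch)
    md <- c(cts$dist[cts$chain_i == ch], cts$dist[cts$chain_j == ch])
    c(n, if (n) mean(md) else 0)
  }
  map <- character(0)
  for (g in seq_along(model_groups)) {
    mg <- model_groups[[g]]
    rg <- ref_groups[[g]]
    pm <- vapply(mg, function(ch) degree_profile(fm, ch), numeric(2))
    pr <- vapply(rg, function(ch) degree_profile(fr, ch), numeric(2))
    cost <- outer(seq_along(mg), seq_along(rg),
                  Vectorize(function(i, j) sum(abs(pm[, i] - pr[, j]))))
    taken <- logical(length(rg))
    for (i in order(apply(cost, 1, min))) {
      j <- order(cost[i, ] + ifelse(taken, Inf, 0))[1]
      map[mg[i]] <- rg[j]
      taken[j] <- TRUE
    }
  }
  map
}

#' @export
print.chain_mapping <- function(x, ...) {
  cat(sprintf("<chain_mapping> %s (objective %.4f)\n",
              paste(names(x$pairs), x$pairs, sep = "->", collapse = ", "),
              x$score))
  invisible(x)
}

as_mapping_vector <- function(mapping) {
  if (inherits(mapping, "chain_mapping")) mapping$pairs else mapping
}
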