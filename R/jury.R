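# The consensus ("jury") layer: all-vs-all pairwise metrics -> per-model
# global and local quality estimates, in three variants:
#   * linear combination of the component jury means (correlation-oriented)
#   * Borda rank aggregation of the components (ranking-oriented)
#   * single-model mode against a user-supplied reference set

#' All-vs-all pairwise comparisons of an ensemble
#'
#' Computes, for every ordered pair (i, j) of models, the oligo-lDDT,
#' QS-score and DockQ of model i scored against model j as reference
#' (chain mappings solved once per unordered pair; QS is symmetric under
#' the mapping and is shared). Matrices are not symmetrized: oligo-lDDT
#' and DockQ are direction-sensitive.
#'
#' @param ensemble An [validate_ensemble()] result with >= 2 models.
#' @return An object of class `pairwise_comparisons`: list with `models`,
#'   matrices `oligo_lddt`, `qs`, `dockq` (diagonal `NA`), and `local`
#'   (per model, a residues x models matrix of per-residue oligo-lDDT).
#' @export
all_vs_all <- function(ensemble) {
  stopifnot(inherits(ensemble, "ensemble"))
  n <- length(ensemble$structures)
  if (n < 2L) abort("jury scoring requires an ensemble of >= 2 models")
  models <- names(ensemble$structures)
  feats <- lapply(ensemble$structures, features_with_contacts)

  mk <- function() {
    m <- matrix(NA_real_, n, n, dimnames = list(models, models))
    m
  }
  L <- mk(); Q <- mk(); D <- mk()
  local <- lapply(feats, function(f) {
    r <- f$res
    m <- matrix(NA_real_, nrow(r), n,
                dimnames = list(paste(r$chain, r$res_index), models))
    m
  })

  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      map_ij <- tryCatch(map_chains_features(feats[[i]], feats[[j]]),
                         error = function(e) NULL)
      if (is.null(map_ij)) next
      fwd <- as_mapping_vector(map_ij)
      rev <- setNames(names(fwd), unname(fwd))

      cij <- tryCatch(compare_pair(feats[[i]], feats[[j]], fwd),
                      error = function(e) NULL)
      if (!is.null(cij)) {
        L[i, j] <- cij$oligo_lddt
        Q[i, j] <- Q[j, i] <- cij$qs
        D[i, j] <- cij$dockq
        local[[i]][, j] <- cij$lddt_per_residue$score[
          match(rownames(local[[i]]),
                paste(cij$lddt_per_residue$chain, cij$lddt_per_residue$res_index))]
      }
      cji <- tryCatch(compare_pair(feats[[j]], feats[[i]], rev),
                      error = function(e) NULL)
      if (!is.null(cji)) {
        L[j, i] <- cji$oligo_lddt
        if (is.na(Q[j, i])) Q[j, i] <- Q[i, j] <- cji$qs
        D[j, i] <- cji$dockq
        local[[j]][, i] <- cji$lddt_per_residue$score[
          match(rownames(local[[j]]),
                paste(cji$lddt_per_residue$chain, cji$lddt_per_residue$res_index))]
      }
    }
  }
  structure(list(models = models, oligo_lddt = L, qs = Q, dockq = D,
                 local = local, ensemble = ensemble),
            class = "pairwise_comparisons")
}

#' Pairwise metric matrix over an ensemble
#'
#' Entry (i, j) is the metric of model i scored against model j as
#' reference; the diagonal is undefined (`NA`). Undefined pairwise scores
#' are recorded as `NA` and later excluded from jury means.
#'
#' @param x An `ensemble` or a precomputed [all_vs_all()] result.
#' @param metric `"oligo_lddt"`, `"qs"` or `"dockq"`.
#' @return A numeric n x n matrix of class `pairwise_matrix` with model
#'   names as dimnames and attribute `metric`.
#' @export
pairwise_matrix <- function(x, metric = c("oligo_lddt", "qs", "dockq")) {
  metric <- match.arg(metric)
  cmp <- if (inherits(x, "pairwise_comparisons")) x else all_vs_all(x)
  m <- cmp[[metric]]
  attr(m, "metric") <- metric
  class(m) <- c("pairwise_matrix", class(m))
  m
}

#' Jury global scores from a pairwise matrix
#'
#' The jury score of model i is the mean of row i over all other models
#' (the mean similarity of model i to every other model of the ensemble),
#' skipping undefined entries.
#'
#' @param matrix A [pairwise_matrix()] (or plain matrix with `NA`
#'   diagonal).
#' @return A tibble `model`, `score`.
#' @export
jury_global <- function(matrix) {
  n <- nrow(matrix)
  if (is.null(n) || n < 2L) abort("jury scoring requires >= 2 models")
  vals <- matrix
  diag(vals) <- NA_real_
  defined <- rowSums(!is.na(vals))
  if (any(defined == 0L)) {
    abort(paste0("jury score undefined for model(s): ",
                 paste(rownames(vals)[defined == 0L], collapse = ", ")))
  }
  tibble(model = rownames(vals) %||% as.character(seq_len(n)),
         score = unname(rowMeans(vals, na.rm = TRUE)))
}

#' Linear combination of component jury scores
#'
#' The correlation-oriented variant: a weighted arithmetic mean of the
#' component jury scores (equal weights by default). Weights are
#' normalised to sum to 1 (with a message when renormalisation was
#' needed) and recorded in the result's attributes.
#'
#' @param components A data frame with a `model` column plus one numeric
#'   column per component score.
#' @param weights Numeric weights, one per component column (optionally
#'   named by component); `NULL` for equal weights.
#' @return The input tibble with a `combined` column appended; attribute
#'   `weights` carries the normalised weights.
#' @export
combine_linear <- function(components, weights = NULL) {
  components <- as_tibble(components)
  comp_cols <- setdiff(names(components), "model")
  stopifnot(length(comp_cols) >= 1L)
  x <- as.matrix(components[comp_cols])
  if (anyNA(x)) abort("all components must be defined for all models")
  if (is.null(weights)) weights <- rep(1 / length(comp_cols), length(comp_cols))
  if (!is.null(names(weights))) weights <- weights[comp_cols]
  if (length(weights) != length(comp_cols) || anyNA(weights)) {
    abort("need one weight per component column")
  }
  if (abs(sum(weights) - 1) > 1e-12) {
    inform("normalising component weights to sum to 1")
    weights <- weights / sum(weights)
  }
  out <- components
  out$combined <- as.numeric(x %*% weights)
  attr(out, "weights") <- setNames(weights, comp_cols)
  out
}

#' Borda rank aggregation of component jury scores
#'
#' The ranking-oriented variant: each component contributes its
#' within-ensemble ranks (best = 1; ties share the mean of the tied
#' ranks); the rank score is `1 - (mean_rank - 1)/(n - 1)`, in `[0, 1]`.
#' The final ranking sorts by rank score, breaking ties by the
#' equal-weight linear combination and then by model name.
#'
#' @inheritParams combine_linear
#' @return A tibble `model`, component columns, `rank_score`, `rank`.
#' @export
combine_for_ranking <- function(components) {
  components <- as_tibble(components)
  comp_cols <- setdiff(names(components), "model")
  n <- nrow(components)
  if (n < 2L) abort("ranking requires >= 2 models")
  x <- as.matrix(components[comp_cols])
  if (anyNA(x)) abort("all components must be defined for all models")
  ranks <- apply(x, 2, function(v) rank(-v, ties.method = "average"))
  mean_rank <- rowMeans(ranks)
  out <- components
  out$rank_score <- 1 - (mean_rank - 1) / (n - 1)
  tie_break <- combine_linear(components)$combined
  ord <- order(-out$rank_score, -tie_break, out$model)
  out$rank <- integer(n)
  out$rank[ord] <- seq_len(n)
  out
}

#' Per-residue local consensus scores
#'
#' The local score of residue r in model i is the mean over the other
#' models j of the per-residue oligo-lDDT of r in the comparison of model
#' i against model j. Every residue receives a score (sentinel 0 with a
#' message when a residue was never scorable); interface residues of the
#' model itself (any heavy atom within 10 Angstrom of another chain) are
#' flagged.
#'
#' @param x An `ensemble` or a precomputed [all_vs_all()] result.
#' @return A tibble `model`, `chain`, `res_index`, `score`, `interface`.
#' @export
local_scores <- function(x) {
  cmp <- if (inherits(x, "pairwise_comparisons")) x else all_vs_all(x)
  rows <- vector("list", length(cmp$models))
  for (i in seq_along(cmp$models)) {
    m <- cmp$local[[i]]
    sc <- rowMeans(m, na.rm = TRUE)
    never <- !is.finite(sc)
    if (any(never)) {
      inform(sprintf("model '%s': %d residue(s) unscored in every comparison; using 0",
                     cmp$models[i], sum(never)))
      sc[never] <- 0
    }
    f <- features_with_contacts(cmp$ensemble$structures[[i]])
    iface <- cached_heavy12(f)
    iface <- iface[iface$dist <= 10, , drop = FALSE]
    iface_keys <- unique(c(paste(iface$chain_i, iface$res_i),
                           paste(iface$chain_j, iface$res_j)))
    key <- rownames(m)
    parts <- strsplit(key, " ", fixed = TRUE)
    rows[[i]] <- tibble(
      model = cmp$models[i],
      chain = vapply(parts, `[`, "", 1),
      res_index = as.integer(vapply(parts, `[`, "", 2)),
      score = unname(sc),
      interface = key %in% iface_keys
    )
  }
  list_rbind(rows)
}

#' Consensus quality estimation for an ensemble of complex models
#'
#' Runs the full jury: all-vs-all pairwise oligo-lDDT / QS / DockQ, the
#' three component jury means, the linear combination, the Borda rank
#' score, and per-residue local consensus scores.
#'
#' @param ensemble An [validate_ensemble()] result with >= 2 models.
#' @param weights Component weights for the linear combination, named by
#'   `dockq_jury`, `qs_jury`, `lddt_jury` (default equal).
#' @return An object of class `jury_result`: list with `scores` (tibble
#'   `model`, `dockq_jury`, `qs_jury`, `lddt_jury`, `combined_linear`,
#'   `rank_score`, `rank_linear`, `rank_ranking`), `local` (tibble from
#'   [local_scores()]), and `provenance` (weights, ensemble size).
#' @export
jury_assess <- function(ensemble, weights = NULL) {
  cmp <- all_vs_all(ensemble)
  comp <- tibble(
    model = cmp$models,
    dockq_jury = jury_global(pairwise_matrix(cmp, "dockq"))$score,
    qs_jury = jury_global(pairwise_matrix(cmp, "qs"))$score,
    lddt_jury = jury_global(pairwise_matrix(cmp, "oligo_lddt"))$score
  )
  lin <- combine_linear(comp, weights)
  rk <- combine_for_ranking(comp)
  scores <- comp
  scores$combined_linear <- lin$combined
  scores$rank_score <- rk$rank_score
  ord_lin <- order(-scores$combined_linear, scores$model)
  scores$rank_linear <- integer(nrow(scores))
  scores$rank_linear[ord_lin] <- seq_len(nrow(scores))
  scores$rank_ranking <- rk$rank

  structure(
    list(scores = scores,
         local = local_scores(cmp),
         provenance = list(weights = attr(lin, "weights"),
                           n_models = length(cmp$models),
                           components = c("dockq_jury", "qs_jury", "lddt_jury"))),
    class = "jury_result"
  )
}

#' Score a single model against a reference set
#'
#' The single-model variant: each component score is the mean of the
#' metric of the model against every reference structure; components are
#' combined as in [combine_linear()]; local scores are the mean
#' per-residue oligo-lDDT over the references.
#'
#' @param model A [structure3d()].
#' @param references An `ensemble` (or list of structures) of reference
#'   models with the model's stoichiometry.
#' @param weights As in [jury_assess()].
#' @return A list of class `single_model_result` with `scores` (one-row
#'   tibble) and `local`.
#' @export
score_single_model <- function(model, references, weights = NULL) {
  refs <- if (inherits(references, "ensemble")) references$structures else references
  if (length(refs) < 1L) abort("the reference set is empty")
  fm <- features_with_contacts(model)
  res_key <- paste(fm$res$chain, fm$res$res_index)
  lmat <- matrix(NA_real_, length(res_key), length(refs))
  l <- q <- d <- numeric(length(refs))
  for (k in seq_along(refs)) {
    cmp <- compare_pair(fm, features_with_contacts(refs[[k]]))
    l[k] <- cmp$oligo_lddt; q[k] <- cmp$qs; d[k] <- cmp$dockq
    lmat[, k] <- cmp$lddt_per_residue$score[
      match(res_key, paste(cmp$lddt_per_residue$chain,
                           cmp$lddt_per_residue$res_index))]
  }
  comp <- tibble(model = model$model_name,
                 dockq_jury = mean(d), qs_jury = mean(q), lddt_jury = mean(l))
  lin <- combine_linear(comp, weights)
  sc <- rowMeans(lmat, na.rm = TRUE)
  sc[!is.finite(sc)] <- 0
  structure(
    list(scores = mutate(comp, combined_linear = lin$combined),
         local = tibble(model = model$model_name,
                        chain = fm$res$chain, res_index = fm$res$res_index,
                        score = sc),
         provenance = list(weights = attr(lin, "weights"),
                           n_references = length(refs))),
    class = "single_model_result"
  )
}

#' Rank the models of a jury result
#'
#' Descending order of the variant's governing score: `combined_linear`
#' for the linear variant, `rank_score` for the ranking variant. Ties are
#' broken by the linear combination and then by model name.
#'
#' @param jury A [jury_assess()] result.
#' @param variant `"modfolddock"` (linear) or `"modfolddockr"` (ranking).
#' @param top_k Optionally keep only the first `top_k` models.
#' @return The `scores` tibble ordered by rank, with a `rank` column for
#'   the chosen variant.
#' @export
rank_models <- function(jury, variant = c("modfolddock", "modfolddockr"),
                        top_k = NULL) {
  variant <- match.arg(variant)
  sc <- jury$scores
  governing <- if (variant == "modfolddock") sc$combined_linear else sc$rank_score
  ord <- order(-governing, -sc$combined_linear, sc$model)
  out <- sc[ord, ]
  out$rank <- seq_len(nrow(out))
  if (!is.null(top_k)) out <- head(out, top_k)
  out
}

#' @export
print.jury_result <- function(x, ...) {
  cat(sprintf("<jury_result> %d models (weights: %s)\n",
              x$provenance$n_models,
              paste(names(x$provenance$weights),
                    sprintf("%.2f", x$provenance$weights),
                    sep = "=", collapse = ", ")))
  print(rank_models(x, "modfolddockr"), n = 5)
  invisible(x)
}

#' @export
print.single_model_result <- function(x, ...) {
  cat(sprintf("<single_model_result> vs %d reference(s)\n",
              x$provenance$n_references))
  print(x$scores)
  invisible(x)
}
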