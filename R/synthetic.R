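# Synthetic multimers and decoy ensembles with known true quality.
# Geometry is deliberately minimal: parametric alpha-helices placed on a
# ring so that adjacent chains form interfaces. The metrics need contacts,
# not physical realism.

GROUP_MARKERS <- c("V", "L", "I", "F", "M", "T", "S", "K", "E", "R", "D", "Q")

# Backbone + CB coordinates for one ideal helix of `len` residues, axis
# along z through the origin. Returns a tibble of atoms (chain unset).
helix_chain_atoms <- function(len, sequence) {
  stopifnot(nchar(sequence) == len)
  i <- seq_len(len)
  theta <- (i - 1) * 100 * pi / 180
  rad <- 2.3
  ca <- cbind(rad * cos(theta), rad * sin(theta), 1.5 * (i - 1))
  # local frame: tangent along the helix, outward radial, and their normal
  tang <- rbind(ca[2, ] - ca[1, ],
                if (len > 2) ca[3:len, , drop = FALSE] - ca[1:(len - 2), , drop = FALSE],
                ca[len, ] - ca[len - 1, ])
  tang <- tang / sqrt(rowSums(tang^2))
  radial <- cbind(cos(theta), sin(theta), 0)
  nrm <- cbind(tang[, 2] * radial[, 3] - tang[, 3] * radial[, 2],
               tang[, 3] * radial[, 1] - tang[, 1] * radial[, 3],
               tang[, 1] * radial[, 2] - tang[, 2] * radial[, 1])

  aa <- strsplit(sequence, "")[[1]]
  rows <- vector("list", len)
  for (k in i) {
    atoms <- rbind(
      N = ca[k, ] - 1.2 * tang[k, ] - 0.6 * radial[k, ],
      CA = ca[k, ],
      C = ca[k, ] + 1.2 * tang[k, ] - 0.4 * radial[k, ],
      O = ca[k, ] + 1.6 * tang[k, ] - 0.4 * radial[k, ] + 1.1 * nrm[k, ]
    )
    if (aa[k] != "G") {
      atoms <- rbind(atoms, CB = ca[k, ] + 1.5 * radial[k, ] + 0.4 * nrm[k, ])
    }
    rows[[k]] <- tibble(
      res_index = k, resno = k, ins = "", aa = aa[k],
      atom = rownames(atoms),
      element = substr(rownames(atoms), 1, 1),
      x = unname(atoms[, 1]), y = unname(atoms[, 2]), z = unname(atoms[, 3]),
      occ = 1, b = 0
    )
  }
  list_rbind(rows)
}

#' Generate an idealized synthetic multimer
#'
#' Each chain is a parametric alpha-helix (1.5 Angstrom rise, 100 degree
#' twist per residue; backbone N/CA/C/O plus CB except at glycines) and
#' chains sit on a ring whose spacing guarantees inter-chain CB contacts
#' between ring neighbours. Sequences are poly-alanine with one
#' group-specific marker residue (position 2) so distinct stoichiometry
#' groups have distinct sequences, and a glycine at position 4 so the
#' CA-for-glycine rule is always exercised. A small seeded coordinate
#' jitter (sigma 0.05 Angstrom) makes structures differ across seeds while
#' remaining bit-reproducible for a fixed seed.
#'
#' @param stoich A stoichiometry string or [parse_stoichiometry()] result;
#'   total chains <= 12.
#' @param chain_length Residues per chain, in `[5, 200]`.
#' @param seed Integer seed fixing all randomness.
#' @param model_name Name for the structure.
#' @return A [structure3d()].
#' @examples
#' ref <- make_idealized_multimer("A2", 20, seed = 1)
#' @export
make_idealized_multimer <- function(stoich, chain_length, seed = 1,
                                    model_name = NULL) {
  stoich <- as_stoichiometry(stoich)
  total <- attr(stoich, "total")
  if (total > 12L) abort("stoichiometry total must be <= 12 chains")
  if (chain_length < 5L || chain_length > 200L) {
    abort("chain_length must be in [5, 200]")
  }
  if (nrow(stoich) > length(GROUP_MARKERS)) abort("too many sequence groups")

  seqs <- vapply(seq_len(nrow(stoich)), function(g) {
    aa <- rep("A", chain_length)
    aa[2] <- GROUP_MARKERS[g]
    aa[4] <- "G"
    paste(aa, collapse = "")
  }, "")

  chain_ids <- LETTERS[seq_len(total)]
  group_of <- rep(seq_len(nrow(stoich)), stoich$copies)

  # ring placement: adjacent helix axes 9 A apart
  sep <- 9
  ring_r <- if (total == 1) 0 else sep / (2 * sin(pi / max(total, 2)))
  phi <- 2 * pi * (seq_len(total) - 1) / max(total, 1)

  parts <- vector("list", total)
  for (k in seq_len(total)) {
    at <- helix_chain_atoms(chain_length, seqs[group_of[k]])
    at$chain <- chain_ids[k]
    at$x <- at$x + ring_r * cos(phi[k])
    at$y <- at$y + ring_r * sin(phi[k])
    parts[[k]] <- at
  }
  at <- list_rbind(parts)

  set.seed(as.integer(seed))
  jit <- matrix(rnorm(3L * nrow(at), sd = 0.05), ncol = 3)
  at$x <- at$x + jit[, 1]
  at$y <- at$y + jit[, 2]
  at$z <- at$z + jit[, 3]

  if (is.null(model_name)) {
    model_name <- sprintf("ideal_%s_s%d",
                          paste0(stoich$label, stoich$copies, collapse = ""),
                          as.integer(seed))
  }
  structure3d(at[c("chain", "res_index", "resno", "ins", "aa", "atom",
                   "element", "x", "y", "z", "occ", "b")],
              model_name = model_name)
}

#' Specify a decoy perturbation
#'
#' @param noise_sigma Gaussian coordinate noise sigma in Angstrom (>= 0),
#'   applied i.i.d. to every atom.
#' @param shift_chain Chain id receiving an additional rigid shift, or
#'   `NULL` for none.
#' @param shift_translation Length-3 translation (Angstrom) for
#'   `shift_chain`.
#' @param shift_rotation_deg Rotation (degrees, about the z axis through the
#'   chain centroid) for `shift_chain`.
#' @param label_permutation Named character vector `old_chain -> new_chain`
#'   permuting chain identifiers; must stay within identical-sequence
#'   groups. `NULL` for identity.
#' @param seed Integer seed fixing the noise.
#' @return A list of class `decoy_spec`.
#' @export
decoy_spec <- function(noise_sigma = 0, shift_chain = NULL,
                       shift_translation = c(0, 0, 0),
                       shift_rotation_deg = 0,
                       label_permutation = NULL, seed = 1) {
  if (noise_sigma < 0) abort("noise_sigma must be >= 0")
  structure(list(noise_sigma = noise_sigma, shift_chain = shift_chain,
                 shift_translation = shift_translation,
                 shift_rotation_deg = shift_rotation_deg,
                 label_permutation = label_permutation,
                 seed = as.integer(seed)),
            class = "decoy_spec")
}

#' Perturb a reference structure into a decoy
#'
#' Adds i.i.d. Gaussian noise to every atom, then applies the rigid shift to
#' the designated chain, then relabels chains by the label permutation.
#' Fully determined by the spec's seed.
#'
#' @param reference A [structure3d()].
#' @param spec A [decoy_spec()].
#' @param model_name Name for the decoy.
#' @return A [structure3d()].
#' @export
perturb <- function(reference, spec, model_name = NULL) {
  stopifnot(inherits(reference, "structure3d"), inherits(spec, "decoy_spec"))
  s <- reference
  s$model_name <- model_name %||% paste0(reference$model_name, "_decoy")

  if (spec$noise_sigma > 0) {
    set.seed(spec$seed)
    noise <- matrix(rnorm(3L * nrow(s$atoms), sd = spec$noise_sigma), ncol = 3)
    s$atoms$x <- s$atoms$x + noise[, 1]
    s$atoms$y <- s$atoms$y + noise[, 2]
    s$atoms$z <- s$atoms$z + noise[, 3]
  }

  if (!is.null(spec$shift_chain)) {
    if (!spec$shift_chain %in% chain_ids(s)) {
      abort(paste0("shift_chain '", spec$shift_chain, "' not in structure"))
    }
    sel <- s$atoms$chain == spec$shift_chain
    xyz <- as.matrix(s$atoms[sel, c("x", "y", "z")])
    ctr <- colMeans(xyz)
    rot <- rotation_about_axis(c(0, 0, 1), spec$shift_rotation_deg)
    xyz <- sweep(sweep(xyz, 2, ctr) %*% rot, 2, ctr + spec$shift_translation, "+")
    s$atoms$x[sel] <- xyz[, 1]
    s$atoms$y[sel] <- xyz[, 2]
    s$atoms$z[sel] <- xyz[, 3]
  }

  if (!is.null(spec$label_permutation)) {
    perm <- spec$label_permutation
    ids <- chain_ids(s)
    if (!setequal(names(perm), ids) || !setequal(perm, ids)) {
      abort("label_permutation must be a bijection over the chain ids")
    }
    seqs <- chain_sequences(s)
    if (!all(seqs[names(perm)] == seqs[unname(perm)])) {
      abort("label_permutation must stay within identical-sequence groups")
    }
    s$atoms$chain <- unname(perm[s$atoms$chain])
    # restore file order A, B, C ... for determinism
    s$atoms <- s$atoms[order(match(s$atoms$chain, sort(unique(s$atoms$chain)))), ]
  }
  s
}

#' Generate a graded decoy ensemble with known true quality
#'
#' Produces `n` decoys of `reference` with noise sigmas evenly spaced over
#' `sigma_range`, and attaches each decoy's true oligo-lDDT, QS-score and
#' DockQ against the unperturbed reference (computed with this package's
#' own metrics).
#'
#' @param reference A [structure3d()].
#' @param n Number of decoys (>= 2).
#' @param sigma_range Length-2 numeric `(lo, hi)` in Angstrom.
#' @param seed Integer seed; fixes decoy noise draws.
#' @param stoichiometry Stoichiometry string for ensemble validation;
#'   inferred from the reference when `NULL`.
#' @return A list of class `labeled_ensemble` with elements `ensemble`
#'   (an [validate_ensemble()] result), `reference` and `true_scores`
#'   (tibble `model`, `sigma`, `oligo_lddt`, `qs`, `dockq`).
#' @export
make_labeled_ensemble <- function(reference, n = 20, sigma_range = c(0.1, 4),
                                  seed = 1, stoichiometry = NULL) {
  stopifnot(inherits(reference, "structure3d"))
  if (n < 2L) abort("a labeled ensemble needs n >= 2 decoys")
  sigmas <- seq(sigma_range[1], sigma_range[2], length.out = n)
  set.seed(as.integer(seed))
  decoy_seeds <- sample.int(.Machine$integer.max - 1L, n)

  decoys <- vector("list", n)
  for (i in seq_len(n)) {
    decoys[[i]] <- perturb(
      reference,
      decoy_spec(noise_sigma = sigmas[i], seed = decoy_seeds[i]),
      model_name = sprintf("decoy_%02d", i)
    )
  }

  if (is.null(stoichiometry)) stoichiometry <- infer_stoichiometry(reference)
  ens <- validate_ensemble(decoys, stoichiometry,
                           target_id = reference$model_name)

  fr <- structure_features(reference)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cmp <- compare_pair(structure_features(decoys[[i]]), fr)
    rows[[i]] <- tibble(model = decoys[[i]]$model_name, sigma = sigmas[i],
                        oligo_lddt = cmp$oligo_lddt, qs = cmp$qs,
                        dockq = cmp$dockq)
  }
  structure(list(ensemble = ens, reference = reference,
                 true_scores = list_rbind(rows)),
            class = "labeled_ensemble")
}

# Stoichiometry string implied by a structure's sequence groups.
infer_stoichiometry <- function(s) {
  sg <- sequence_groups(s)
  counts <- table(factor(sg$group, levels = unique(sg$group)))
  paste0(LETTERS[seq_along(counts)], as.integer(counts), collapse = "")
}

#' @export
print.labeled_ensemble <- function(x, ...) {
  cat(sprintf("<labeled_ensemble> %d decoys, sigma %.2f..%.2f A\n",
              nrow(x$true_scores), min(x$true_scores$sigma),
              max(x$true_scores$sigma)))
  invisible(x)
}
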