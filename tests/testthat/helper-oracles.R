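# Fixture builders and independent oracles used across the suite.
# Oracles are deliberately naive (double loops, closed forms, external
# superposition) and never share code with the implementation they check.

# ---- builders -------------------------------------------------------------

# Minimal structure from a data frame with chain, res_index, aa, atom, x, y, z.
build_structure <- function(df, model_name = "toy") {
  df$resno <- df$res_index
  df$ins <- ""
  df$element <- substr(df$atom, 1, 1)
  df$occ <- 1
  df$b <- 0
  structure3d(df[c("chain", "res_index", "resno", "ins", "aa", "atom",
                   "element", "x", "y", "z", "occ", "b")], model_name)
}

# A chain of CA-only glycines at the given positions (n x 3 matrix).
ca_chain <- function(chain, pos, aa = "G") {
  data.frame(chain = chain, res_index = seq_len(nrow(pos)), aa = aa,
             atom = "CA", x = pos[, 1], y = pos[, 2], z = pos[, 3])
}

# Fixed-column PDB ATOM line (independent of the package's writer).
pdb_atom_line <- function(serial, name, resn, chain, resno, x, y, z,
                          occ = 1, b = 0, alt = " ", elem = NULL) {
  if (is.null(elem)) elem <- substr(name, 1, 1)
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, sprintf(" %-3s", name), alt, resn, chain, resno,
          x, y, z, occ, b, elem)
}

# Two-chain helix-free test PDB text: n residues per chain, N/CA/C/O(/CB).
two_chain_pdb_lines <- function(n = 10, with_altloc = FALSE) {
  lines <- character(0)
  serial <- 0
  for (ch in c("A", "B")) {
    off <- if (ch == "A") 0 else 8
    for (r in seq_len(n)) {
      for (at in c("N", "CA", "C", "O", "CB")) {
        serial <- serial + 1
        dx <- switch(at, N = -0.5, CA = 0, C = 0.5, O = 0.9, CB = 0.2)
        dz <- switch(at, N = 0, CA = 0, C = 0, O = 0.6, CB = -1.2)
        x <- off + dx; y <- 3 * r; z <- dz
        if (with_altloc) {
          lines <- c(lines,
                     pdb_atom_line(serial, at, "ALA", ch, r, x, y, z,
                                   occ = 0.6, alt = "A"),
                     pdb_atom_line(serial, at, "ALA", ch, r,
                                   x + 5, y + 5, z + 5, occ = 0.4, alt = "B"))
        } else {
          lines <- c(lines, pdb_atom_line(serial, at, "ALA", ch, r, x, y, z))
        }
      }
    }
    lines <- c(lines, "TER")
  }
  c(lines, "END")
}

write_tmp_pdb <- function(lines) {
  path <- withr::local_tempfile(fileext = ".pdb",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# ---- oracles --------------------------------------------------------------

# Independent fixed-column coordinate reader (columns per the PDB spec).
oracle_parse_coords <- function(path) {
  lines <- readLines(path)
  lines <- lines[startsWith(lines, "ATOM")]
  cbind(
    x = as.numeric(substr(lines, 31, 38)),
    y = as.numeric(substr(lines, 39, 46)),
    z = as.numeric(substr(lines, 47, 54))
  )
}

# Closed-form minimal RMSD via the quaternion characteristic polynomial
# (largest eigenvalue of the Horn K matrix); no SVD, no iteration.
oracle_quat_rmsd <- function(a, b) {
  n <- nrow(a)
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  m <- crossprod(ac, bc)
  sxx <- m[1, 1]; sxy <- m[1, 2]; sxz <- m[1, 3]
  syx <- m[2, 1]; syy <- m[2, 2]; syz <- m[2, 3]
  szx <- m[3, 1]; szy <- m[3, 2]; szz <- m[3, 3]
  k <- matrix(c(
    sxx + syy + szz, syz - szy, szx - sxz, sxy - syx,
    syz - szy, sxx - syy - szz, sxy + syx, szx + sxz,
    szx - sxz, sxy + syx, -sxx + syy - szz, syz + szy,
    sxy - syx, szx + sxz, syz + szy, -sxx - syy + szz
  ), 4, 4, byrow = TRUE)
  lam <- max(eigen(k, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, (sum(ac^2) + sum(bc^2) - 2 * lam) / n))
}

# Brute-force inter-chain contacts by double loop over residues.
oracle_contacts <- function(s, scheme, cutoff) {
  at <- s$atoms
  res <- unique(at[c("chain", "res_index")])
  out <- NULL
  for (i in seq_len(nrow(res))) {
    for (j in seq_len(nrow(res))) {
      if (j <= i) next
      ci <- res$chain[i]; cj <- res$chain[j]
      if (ci == cj) next
      ai <- at[at$chain == ci & at$res_index == res$res_index[i], ]
      aj <- at[at$chain == cj & at$res_index == res$res_index[j], ]
      if (scheme == "cb") {
        pick <- function(a) {
          r <- a[a$atom == "CB", ]
          if (nrow(r) == 0) r <- a[a$atom == "CA", ]
          r
        }
        ai <- pick(ai); aj <- pick(aj)
      }
      d <- Inf
      for (p in seq_len(nrow(ai))) {
        for (q in seq_len(nrow(aj))) {
          d <- min(d, sqrt((ai$x[p] - aj$x[q])^2 + (ai$y[p] - aj$y[q])^2 +
                             (ai$z[p] - aj$z[q])^2))
        }
      }
      if (d <= cutoff) {
        first <- ci < cj
        out <- rbind(out, data.frame(
          chain_i = if (first) ci else cj,
          res_i = if (first) res$res_index[i] else res$res_index[j],
          chain_j = if (first) cj else ci,
          res_j = if (first) res$res_index[j] else res$res_index[i],
          dist = d))
      }
    }
  }
  out
}

# Brute-force oligo-lDDT by full double loop over matched atoms.
oracle_oligo_lddt <- function(model, ref, map, radius = 15,
                              thresholds = c(0.5, 1, 2, 4)) {
  ma <- model$atoms
  ra <- ref$atoms
  ma$mapped <- unname(map[ma$chain])
  key <- function(a, ch) paste(ch, a$res_index, a$atom)
  idx <- match(key(ra, ra$chain), key(ma, ma$mapped))
  keep <- which(!is.na(idx))
  rxyz <- as.matrix(ra[keep, c("x", "y", "z")])
  mxyz <- as.matrix(ma[idx[keep], c("x", "y", "z")])
  rres <- paste(ra$chain[keep], ra$res_index[keep])
  scores <- numeric(0)
  for (r in unique(rres)) {
    tot <- 0; pres <- 0
    for (p in which(rres == r)) {
      for (q in seq_along(keep)) {
        if (rres[q] == rres[p]) next # no intra-residue pairs
        dr <- sqrt(sum((rxyz[p, ] - rxyz[q, ])^2))
        if (dr > radius) next
        dm <- sqrt(sum((mxyz[p, ] - mxyz[q, ])^2))
        tot <- tot + 1
        pres <- pres + mean(abs(dm - dr) <= thresholds)
      }
    }
    if (tot > 0) scores[r] <- pres / tot
  }
  list(global = mean(scores), per_residue = scores)
}

# Direct QS formula from two brute-force contact tables (model contacts
# already expressed in reference chain labels).
oracle_qs <- function(model_cts, ref_cts) {
  key <- function(d) paste(d$chain_i, d$res_i, d$chain_j, d$res_j)
  mk <- key(model_cts); rk <- key(ref_cts)
  shared <- intersect(mk, rk)
  w <- 0
  for (k in shared) {
    w <- w + max(0, 1 - abs(model_cts$dist[mk == k] - ref_cts$dist[rk == k]) / 12)
  }
  w / (length(shared) + sum(!mk %in% rk) + sum(!rk %in% mk))
}

# All bijections model chains -> ref chains respecting sequence groups.
oracle_all_mappings <- function(model, ref) {
  ms <- dockjury::chain_table(model)
  rs <- dockjury::chain_table(ref)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  maps <- list(character(0))
  for (sq in unique(rs$sequence)) {
    mg <- sort(ms$chain[ms$sequence == sq])
    rg <- sort(rs$chain[rs$sequence == sq])
    maps <- unlist(lapply(maps, function(acc) {
      lapply(perms(rg), function(p) c(acc, setNames(p, mg)))
    }), recursive = FALSE)
  }
  maps
}

# Exhaustive-permutation chain mapping oracle: best QS over all
# group-respecting bijections, QS evaluated from brute-force contacts.
oracle_map_chains <- function(model, ref) {
  rc <- oracle_contacts(ref, "cb", 12)
  best <- NULL; best_score <- -Inf
  for (map in oracle_all_mappings(model, ref)) {
    mc <- oracle_contacts(model, "cb", 12)
    if (!is.null(mc)) {
      ci <- unname(map[mc$chain_i]); cj <- unname(map[mc$chain_j])
      swap <- ci > cj
      mc2 <- data.frame(
        chain_i = ifelse(swap, cj, ci),
        res_i = ifelse(swap, mc$res_j, mc$res_i),
        chain_j = ifelse(swap, ci, cj),
        res_j = ifelse(swap, mc$res_i, mc$res_j),
        dist = mc$dist)
    } else mc2 <- data.frame(chain_i = character(0), res_i = integer(0),
                             chain_j = character(0), res_j = integer(0),
                             dist = numeric(0))
    sc <- oracle_qs(mc2, rc)
    if (is.nan(sc)) sc <- 0
    if (sc > best_score + 1e-12) {
      best_score <- sc
      best <- map[order(names(map))]
    }
  }
  list(pairs = best, score = best_score)
}

# GDT fraction oracle: all contiguous seeds of every length >= 3, iterated
# to convergence; superpositions via bio3d (independent of the package's
# Kabsch).
oracle_gdt_fraction <- function(mca, rca, threshold) {
  n <- nrow(mca)
  fit_dist <- function(idx) {
    xyz <- bio3d::fit.xyz(fixed = as.vector(t(rca)),
                          mobile = as.vector(t(mca)),
                          fixed.inds = as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx)),
                          mobile.inds = as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx)))
    m <- matrix(xyz, ncol = 3, byrow = TRUE)
    sqrt(rowSums((m - rca)^2))
  }
  best <- 0
  for (L in 3:n) {
    for (s in seq_len(n - L + 1)) {
      cur <- s:(s + L - 1)
      repeat {
        d <- fit_dist(cur)
        within <- which(d <= threshold)
        if (length(within) < 3 || identical(within, cur)) {
          best <- max(best, length(within) / n)
          break
        }
        cur <- within
      }
    }
  }
  best
}

# Random rigid motion applied to a whole structure (seeded by caller).
random_isometry <- function(s) {
  rot <- dockjury:::random_rotation()
  tr <- rnorm(3, sd = 20)
  transform_structure(s, rotation = rot, translation = tr)
}

spearman <- function(a, b) suppressWarnings(stats::cor(a, b, method = "spearman"))
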