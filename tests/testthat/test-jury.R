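make_test_ensemble <- function(n = 4, stoich = "A2", len = 10, sigma = 0.6,
                               seed = 1) {
  ref <- make_idealized_multimer(stoich, len, seed = seed)
  decoys <- lapply(seq_len(n), function(i) {
    perturb(ref, decoy_spec(noise_sigma = sigma, seed = seed * 1000 + i),
            model_name = sprintf("m%02d", i))
  })
  validate_ensemble(decoys, stoich)
}

test_that("identical models give an all-ones pairwise matrix and unit jury scores", {
  ref <- make_idealized_multimer("A2", 10, seed = 6)
  ens <- validate_ensemble(
    lapply(1:3, function(i) {
      s <- ref
      s$model_name <- sprintf("copy%d", i)
      s
    }), "A2")
  cmp <- all_vs_all(ens)
  for (metric in c("oligo_lddt", "qs", "dockq")) {
    m <- pairwise_matrix(cmp, metric)
    expect_true(all(abs(m[upper.tri(m) | lower.tri(m)] - 1) < 1e-12))
    expect_true(all(is.na(diag(m))))
    expect_equal(jury_global(m)$score, rep(1, 3), tolerance = 1e-12)
  }
  jr <- jury_assess(ens)
  expect_true(all(abs(jr$scores$combined_linear - 1) < 1e-12))
  expect_true(all(jr$local$score == 1))
})

test_that("the pairwise matrix equals element-by-element direct metric calls", {
  ens <- make_test_ensemble(n = 4)
  cmp <- all_vs_all(ens)
  L <- pairwise_matrix(cmp, "oligo_lddt")
  Q <- pairwise_matrix(cmp, "qs")
  D <- pairwise_matrix(cmp, "dockq")
  models <- ens$structures
  for (i in 1:4) {
    for (j in 1:4) {
      if (i == j) next
      expect_equal(L[i, j], oligo_lddt(models[[i]], models[[j]])$global,
                   tolerance = 1e-9)
      expect_equal(Q[i, j], qs_score(models[[i]], models[[j]])$global,
                   tolerance = 1e-9)
      expect_equal(D[i, j], dockq(models[[i]], models[[j]])$global,
                   tolerance = 1e-9)
    }
  }
  # n = 2: exactly two defined entries
  two <- make_test_ensemble(n = 2, seed = 3)
  m2 <- pairwise_matrix(two, "qs")
  expect_equal(sum(!is.na(m2)), 2L)
  js <- jury_global(m2)
  expect_equal(js$score, c(m2[1, 2], m2[2, 1]))
})

test_that("jury means are row means excluding the diagonal", {
  m <- matrix(c(NA, 0.2, 0.4,
                0.6, NA, 0.8,
                0.1, 0.3, NA), 3, 3, byrow = TRUE,
              dimnames = list(paste0("m", 1:3), paste0("m", 1:3)))
  js <- jury_global(m)
  expect_equal(js$score, c(0.3, 0.7, 0.2), tolerance = 1e-12)

  # a missing entry is skipped, an all-missing row errors
  m[1, 2] <- NA
  expect_equal(jury_global(m)$score[1], 0.4)
  m[1, 3] <- NA
  expect_error(jury_global(m), "m1")
})

test_that("an extreme outlier gets the strictly lowest QS jury score", {
  ens <- make_test_ensemble(n = 5, sigma = 0.4, seed = 8)
  out <- perturb(ens$structures[[1]],
                 decoy_spec(shift_chain = "B", shift_translation = c(100, 0, 0)),
                 model_name = "outlier")
  ens2 <- validate_ensemble(c(ens$structures, list(out)), "A2")
  js <- jury_global(pairwise_matrix(ens2, "qs"))
  expect_equal(js$model[which.min(js$score)], "outlier")
  expect_lt(max(js$score[js$model == "outlier"]),
            min(js$score[js$model != "outlier"]))
})

test_that("linear combination respects weights and bounds", {
  comp <- tibble::tibble(model = c("a", "b", "c"),
                         x = c(0.9, 0.5, 0.1),
                         y = c(0.8, 0.6, 0.2),
                         z = c(0.7, 0.4, 0.3))
  eq <- combine_linear(comp)
  expect_equal(eq$combined, rowMeans(as.matrix(comp[c("x", "y", "z")])),
               tolerance = 1e-12)
  expect_true(all(eq$combined <= pmax(comp$x, comp$y, comp$z) + 1e-12))
  expect_true(all(eq$combined >= pmin(comp$x, comp$y, comp$z) - 1e-12))

  first_only <- combine_linear(comp, c(1, 0, 0))
  expect_equal(first_only$combined, comp$x)

  expect_message(combine_linear(comp, c(2, 1, 1)), "normalis")
  w <- combine_linear(comp, c(2, 1, 1))
  expect_equal(w$combined,
               as.numeric(as.matrix(comp[c("x", "y", "z")]) %*% c(0.5, 0.25, 0.25)),
               tolerance = 1e-12)

  same <- tibble::tibble(model = c("a", "b"), x = c(0.4, 0.9), y = c(0.4, 0.9))
  expect_equal(combine_linear(same)$combined, same$x)
})

test_that("Borda aggregation matches a hand-computed table with a Condorcet split", {
  # components disagree: ranks per column are hand-enumerated
  comp <- tibble::tibble(
    model = c("a", "b", "c"),
    x = c(0.9, 0.6, 0.3), # ranks 1, 2, 3
    y = c(0.2, 0.8, 0.5), # ranks 3, 1, 2
    z = c(0.5, 0.1, 0.9)  # ranks 2, 3, 1
  )
  rk <- combine_for_ranking(comp)
  mean_ranks <- c(2, 2, 2)
  expect_equal(rk$rank_score, 1 - (mean_ranks - 1) / 2, tolerance = 1e-12)
  # rank_score ties broken by the equal-weight linear mean:
  # a = 0.533..., b = 0.5, c = 0.566... -> order c, a, b
  expect_equal(rk$rank, c(2L, 3L, 1L))

  dominant <- tibble::tibble(model = c("good", "bad"),
                             x = c(0.9, 0.1), y = c(0.8, 0.2))
  rk2 <- combine_for_ranking(dominant)
  expect_equal(rk2$rank_score, c(1, 0))
  expect_equal(rk2$rank, c(1L, 2L))

  # ties share the mean of the tied ranks
  tied <- tibble::tibble(model = c("a", "b", "c"),
                         x = c(0.5, 0.5, 0.1), y = c(0.7, 0.7, 0.2))
  rk3 <- combine_for_ranking(tied)
  expect_equal(rk3$rank_score, c(0.75, 0.75, 0))
})

test_that("jury scores are equivariant under model relabelling", {
  ens <- make_test_ensemble(n = 4, seed = 12)
  jr1 <- jury_assess(ens)
  perm <- c(3, 1, 4, 2)
  ens2 <- validate_ensemble(unname(ens$structures)[perm], "A2")
  jr2 <- jury_assess(ens2)
  s1 <- jr1$scores[match(jr2$scores$model, jr1$scores$model), ]
  expect_equal(jr2$scores$combined_linear, s1$combined_linear, tolerance = 1e-9)
  expect_equal(jr2$scores$rank_score, s1$rank_score, tolerance = 1e-9)
})

test_that("local consensus flags interfaces and pinpoints a displaced residue", {
  ref <- make_idealized_multimer("A2", 10, seed = 15)
  decoys <- lapply(1:4, function(i) {
    perturb(ref, decoy_spec(noise_sigma = 0.1, seed = 300 + i),
            model_name = sprintf("m%02d", i))
  })
  # displace one interface residue of model 1 only
  iface <- interface_residues(decoys[[1]], c("A", "B"), 10)
  tgt <- iface[1, ]
  sel <- decoys[[1]]$atoms$chain == tgt$chain &
    decoys[[1]]$atoms$res_index == tgt$res_index
  decoys[[1]]$atoms$x[sel] <- decoys[[1]]$atoms$x[sel] + 12

  ens <- validate_ensemble(decoys, "A2")
  loc <- local_scores(ens)
  expect_true(all(loc$score >= 0 & loc$score <= 1))
  m1 <- loc[loc$model == "m01", ]
  worst <- m1[which.min(m1$score), ]
  expect_equal(worst$chain, tgt$chain)
  expect_equal(worst$res_index, tgt$res_index)
  expect_true(any(loc$interface))
  # the flag reflects each model's own interface: in an undisplaced decoy
  # the same residue is still at the interface
  m2 <- loc[loc$model == "m02", ]
  expect_true(m2$interface[m2$chain == tgt$chain & m2$res_index == tgt$res_index])
})

test_that("single-model mode averages pairwise calls against the reference set", {
  ref <- make_idealized_multimer("A2", 10, seed = 20)
  model <- perturb(ref, decoy_spec(noise_sigma = 0.5, seed = 99), "query")
  refs <- lapply(1:3, function(i) {
    perturb(ref, decoy_spec(noise_sigma = 0.2, seed = 400 + i),
            model_name = sprintf("r%d", i))
  })

  # model identical to the sole reference: every component is 1
  self <- score_single_model(ref, list(ref))
  expect_equal(as.numeric(self$scores[c("dockq_jury", "qs_jury", "lddt_jury",
                                        "combined_linear")]),
               rep(1, 4), tolerance = 1e-12)

  one <- score_single_model(model, refs[1])
  expect_equal(one$scores$lddt_jury, oligo_lddt(model, refs[[1]])$global,
               tolerance = 1e-9)

  three <- score_single_model(model, refs)
  expect_equal(three$scores$qs_jury,
               mean(vapply(refs, function(r) qs_score(model, r)$global, 0)),
               tolerance = 1e-9)
  expect_equal(three$scores$dockq_jury,
               mean(vapply(refs, function(r) dockq(model, r)$global, 0)),
               tolerance = 1e-9)
  expect_error(score_single_model(model, list()), "empty")
})

test_that("rank_models orders by the governing score with deterministic ties", {
  ens <- make_test_ensemble(n = 5, seed = 31)
  jr <- jury_assess(ens)
  rk <- rank_models(jr, "modfolddockr")
  expect_equal(rk$rank, 1:5)
  expect_true(all(diff(rk$rank_score) <= 1e-12))
  lin <- rank_models(jr, "modfolddock")
  expect_true(all(diff(lin$combined_linear) <= 1e-12))
  expect_equal(nrow(rank_models(jr, "modfolddockr", top_k = 2)), 2L)

  # exact tie on the governing score is broken by model name
  jr2 <- jr
  jr2$scores$combined_linear[] <- 0.5
  jr2$scores$rank_score[] <- 0.5
  rk2 <- rank_models(jr2, "modfolddock")
  expect_equal(rk2$model, sort(jr$scores$model))
})

test_that("tidiers and plots expose the jury result", {
  ens <- make_test_ensemble(n = 3, seed = 40)
  jr <- jury_assess(ens)
  td <- tidy(jr)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("model", "dockq_jury", "qs_jury", "lddt_jury",
                    "combined_linear", "rank_score") %in% names(td)))
  gl <- glance(jr)
  expect_equal(gl$n_models, 3L)
  expect_true(gl$best_model %in% td$model)
  p1 <- autoplot(jr)
  expect_s3_class(p1, "ggplot")
  p2 <- plot_local_quality(jr)
  expect_s3_class(p2, "ggplot")
})
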