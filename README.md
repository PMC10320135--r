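# dockjury

Consensus ("jury") quality estimation for models of protein quaternary
structure, without a native reference.

Predictors of protein complexes produce ensembles of candidate models;
the practical questions are which model to trust, how good it is, and
which interface residues are reliable. `dockjury` answers them by
all-vs-all comparison: every model is scored against every other model
of the same target with three quaternary-structure metrics —
**oligo-lDDT** (superposition-free preserved-distance test, radius 15 Å,
tolerances 0.5/1/2/4 Å), **QS-score** (shared inter-chain CB contacts at
12 Å, weighted by `max(0, 1 − |Δd|/12)` and normalised by the contact
union) and **DockQ**

    DockQ = ( Fnat + 1/(1+(iRMS/1.5)²) + 1/(1+(LRMS/8.5)²) ) / 3

— and a model's predicted quality is its mean similarity to the rest of
the ensemble. Chain mapping between complexes (which copy of a chain
corresponds to which) is solved by permutation search within
identical-sequence groups. Per-chain tertiary quality is reported as
GDT_TS and CA RMSD.

Three combination variants cover the three facets of the problem:

| variant | governing score | for |
|---|---|---|
| linear | `combined_linear` — weighted mean of the component jury scores | absolute quality estimates |
| ranking | `rank_score` — Borda rank aggregation of the components | picking the top-k models |
| single-model | mean metrics against a user-supplied reference set | scoring one model alone |

Local (per-residue) quality is the consensus per-residue oligo-lDDT,
written to the B-factor column of output PDBs (`B = 100·score`) and to a
CASP QMODE2-style QA file. A seeded synthetic generator (idealized
helix-ring multimers plus graded decoys with known true quality) makes
the whole pipeline testable without any external data.

## Worked example

```r
library(dockjury)

ref  <- make_idealized_multimer("A2", 20, seed = 1)   # homodimer reference
le   <- make_labeled_ensemble(ref, n = 10, sigma_range = c(0.2, 3), seed = 2)
jury <- jury_assess(le$ensemble)
rank_models(jury, "modfolddockr", top_k = 5)
```

```
# A tibble: 5 × 7
  model    dockq_jury qs_jury lddt_jury combined_linear rank_score  rank
  <chr>         <dbl>   <dbl>     <dbl>           <dbl>      <dbl> <int>
1 decoy_01      0.512   0.582     0.535           0.543      0.852     1
2 decoy_03      0.512   0.557     0.499           0.523      0.741     2
3 decoy_02      0.505   0.564     0.523           0.531      0.704     3
4 decoy_04      0.517   0.507     0.469           0.498      0.704     4
5 decoy_06      0.537   0.476     0.408           0.474      0.667     5
```

The ensemble holds decoys with noise from 0.2 Å (`decoy_01`, true
oligo-lDDT 0.989 against the reference) to 3 Å (`decoy_10`, 0.306). The
jury sees no reference, yet ranks the truest model first: `dockq_jury`,
`qs_jury` and `lddt_jury` are the model's mean DockQ/QS/oligo-lDDT
against the other nine models, `combined_linear` their equal-weight mean,
and `rank_score` the Borda aggregate in [0, 1] that governs this
ranking.

```r
glance(jury)
#   n_models best_model best_rank_score mean_combined sd_combined
# 1       10 decoy_01             0.852         0.463      0.0649

tidy(jury)                 # full per-model score table
autoplot(jury)             # component scores per model
plot_local_quality(jury)   # per-residue profiles, interface residues marked
```

End-to-end runs (`run_jury()`, `run_single()`, `run_compare()` via
`run_config()`) additionally write `ranking.tsv`, a `<target>.qa` QMODE2
file and per-model `*_local.pdb` files with local scores in the B-factor
column. The same operations are available from a shell:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "dockjury.R", package = "dockjury"))') \
    rank --stoichiometry A2 --out results/ model1.pdb model2.pdb model3.pdb
```

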