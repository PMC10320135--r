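---
title: "Consensus quality estimation for protein complex models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus quality estimation for protein complex models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dockjury)
```

## The problem

Structure predictors for protein complexes emit many candidate models of
the same target, and the native structure is unknown at prediction time.
Estimation of model accuracy (EMA/QA) asks: without a reference, which
model is best, how good is it globally, and which interface residues can
be trusted? `dockjury` answers this with a *consensus (jury)* approach:
every model of an ensemble is compared against every other model, and a
model's predicted quality is its mean similarity to the rest of the
ensemble. The intuition is that errors are idiosyncratic while signal is
shared — a model that agrees with many alternatives is likely close to
the truth, and a residue placed consistently across models is likely
placed correctly.

## Pairwise metrics

Three established quaternary-structure similarity metrics form the
pairwise kernel. All are computed after solving the *chain mapping* — the
bijection between chains of the two complexes, restricted to
identical-sequence groups, that maximises a shared-contact objective
(exhaustive over within-group permutations up to 6 copies per group,
greedy with pairwise-swap refinement beyond).

**Oligo-lDDT.** The local Distance Difference Test, extended across
chains: for every reference atom pair in different residues (intra- *and*
inter-chain) within an inclusion radius $R_0 = 15$ Å, the model must
reproduce the reference distance within tolerances
$t \in \{0.5, 1, 2, 4\}$ Å. A residue's score is the mean over
tolerances of the preserved fraction of its pairs; the global score is
the mean over residues. lDDT is superposition-free, which makes it
robust to domain and chain motions.

**QS-score.** Quaternary similarity via inter-chain residue contacts
(CB–CB, CA for glycine, 12 Å cutoff). With $S$ the contacts shared by
model and reference under the mapping,

$$\mathrm{QS} = \frac{\sum_{c \in S} \max\!\left(0,\; 1 - \frac{|d^{model}_c - d^{ref}_c|}{12}\right)}
  {|S| + N_{model\ only} + N_{ref\ only}}.$$

The cited QS-score literature fixes the idea but not an implementable
kernel; the linear-decay weight above is this package's declared,
testable stand-in, isolated in one function (`qs_from_keys`) so an
alternative kernel can be swapped in. Both the in-house and
"official-style" jury roles are served by this one implementation.

**DockQ.** The composite interface score

$$\mathrm{DockQ} = \tfrac{1}{3}\left( F_{nat}
  + \frac{1}{1+(\mathrm{iRMS}/1.5)^2}
  + \frac{1}{1+(\mathrm{LRMS}/8.5)^2} \right)$$

per reference interface, where $F_{nat}$ is the fraction of native
residue–residue contacts (heavy atoms, 5 Å) preserved by the model, iRMS
is the backbone RMSD over interface residues (defined at 10 Å on the
reference) after superposing on those same atoms, and LRMS is the
ligand-chain backbone RMSD after superposing on the receptor (the larger
chain; ties broken lexicographically). A multimer's DockQ is the
unweighted mean over all reference interfaces — the aggregation is not
fixed by the original two-chain definition, and the unweighted mean is
deterministic and symmetric across interfaces.

Per-chain tertiary quality is reported as GDT_TS (thresholds 1/2/4/8 Å)
and CA RMSD. The exact GDT optimisation is not published as an
algorithm; the search here is a deterministic exhaustive-seed heuristic:
every contiguous window of lengths 3, 5, 7 (plus the full chain) seeds a
Kabsch superposition which is re-fit on its within-threshold subset
until a fixed point (at most 10 iterations), and the best fraction per
threshold is kept. On small cases this matches a full
all-seeds-to-convergence search within 1 GDT unit (see the test suite).

## The jury and its three variants

For an ensemble of $n \ge 2$ validated models, each ordered pair
$(i, j)$ is scored with model $i$ against model $j$ as reference.
Matrices are *not* symmetrised — lDDT and DockQ are direction-sensitive —
and the jury score of model $i$ is the mean of row $i$:
$\mathrm{jury}_i = \frac{1}{n-1}\sum_{j \ne i} M_{ij}$ for each of the
three component metrics (QS is symmetric under the solved mapping and is
shared between directions).

The components are combined in three ways, mirroring the three facets of
the QA problem:

* **Linear variant** (`combined_linear`): a weighted arithmetic mean of
  the component jury scores, by default equal weights. Intended for
  absolute quality estimates that correlate linearly with observed
  quality. The published method trained these combinations on CASP
  data; the trained weights are not public, so equal weights are the
  package default and the weight vector is exposed (`weights` argument,
  recorded in provenance) so fitted weights can be dropped in.
* **Ranking variant** (`rank_score`): Borda rank aggregation. Each
  component contributes its within-ensemble ranks (ties share the mean
  rank); the rank score is $1 - (\bar r_i - 1)/(n - 1) \in [0, 1]$.
  Rank aggregation discards calibration and keeps order information,
  which is what a top-1/top-5 selection needs. Ties are broken by the
  linear combination, then by model name, so rankings are deterministic.
* **Single-model variant** (`score_single_model()`): when only one model
  is to be scored, a user-supplied set of reference models plays the
  role of the ensemble and the model's components are its mean metric
  against that set. Generating the reference set (production QA servers
  do this with their own structure predictors) is outside this package's
  scope; references are an explicit input.

**Local scores.** The per-residue estimate of model $i$ is the mean,
over the other models, of the per-residue oligo-lDDT of that residue.
Per-residue lDDT is defined for every residue (not only interface
residues), which is what the QA output format requires; residues at an
interface of the model itself (any heavy atom within 10 Å of another
chain) are flagged so interface quality can be read off directly. The
local score is a [0, 1] similarity, not an error in Å — the output
format does not fix the convention, and a bounded similarity composes
cleanly with the B-factor transform below.

## Input and output formats

Models are read from PDB files, including the CASP TS dialect
(PFRMAT/TARGET/MODEL headers are skipped). Only the first MODEL block is
used (one model, one score); altloc duplicates resolve to the highest
occupancy; residues without a CA atom are dropped rather than rejected,
because submitted models are frequently backbone-incomplete; waters,
HETATM records and non-polymer residues are excluded. Chains are grouped
by *exact* sequence identity when checking a stoichiometry such as
`"A2B2"` — point mutants count as distinct groups, a documented
limitation in exchange for deterministic grouping.

Outputs are: a ranking table (TSV with parameter provenance in `#`
comments), a QMODE2-style QA file (global score plus per-residue local
scores to 3 decimals, 20 per line), and per-model PDB files with the
local score written to the B-factor column as
$B = \mathrm{round}(100 \cdot s, 2)$ — unscored residues take the
sentinel 0.00 because the fixed-width column must hold a number.
Re-reading recovers scores to ±0.005 (column precision). Every writer
has a matching reader and the round trips are tested.

## The synthetic generator

All tests run on synthetic complexes with known construction:

* each chain is a parametric α-helix (rise 1.5 Å, 100° twist per
  residue, backbone N/CA/C/O plus CB except at glycines);
* chains sit on a ring with adjacent helix axes 9 Å apart, which
  guarantees CB-level interfaces between ring neighbours without any
  physics;
* sequences are poly-alanine with a group-specific marker residue at
  position 2 (so stoichiometry groups are distinguishable by sequence)
  and a glycine at position 4 (so the CA-for-glycine rule is always
  exercised);
* a seeded 0.05 Å coordinate jitter makes structures differ across
  seeds while remaining bit-reproducible for a fixed seed.

Decoys are derived from a reference by i.i.d. Gaussian coordinate noise,
an optional rigid shift of one chain (to create docking failures), and
an optional relabelling of same-sequence chains (to exercise the chain
mapping). `make_labeled_ensemble()` draws noise levels evenly from a
sigma range — default 20 decoys over [0.1, 4] Å, spanning near-native
to badly wrong — and attaches each decoy's true oligo-lDDT/QS/DockQ
against the unperturbed reference.

What this does *not* emulate: real decoys err in correlated,
physically structured ways (domain shifts, register errors, clashes),
have side chains beyond CB, and differ in sequence coverage. Passing
tests therefore demonstrate correctness of the metrics and the
machinery, and recovery of a *known* quality gradient — not predictive
performance on real predictor outputs.

## Numerical choices and degenerate inputs

* Superpositions use the Kabsch algorithm via SVD with the reflection
  guard; (near-)collinear point sets are rejected as ill-conditioned
  (second singular value below 1e-10 of scale) rather than returning an
  arbitrary rotation.
* lDDT threshold tests use ≤, and contact cutoffs use ≤; with
  continuous coordinates boundary ties have measure zero.
* Chain-mapping ties (e.g. perfectly symmetric complexes) resolve to the
  first optimum in a deterministic enumeration order; greedy mapping
  breaks ties by lexicographic chain id.
* Undefined pairwise scores (a metric can refuse, e.g. QS without any
  contacts) are recorded as missing and excluded from jury means; a
  model with no defined comparison at all is an error, not a silent 0.
* Residues never scorable in any comparison receive local sentinel 0
  with a message.
* All randomness is seed-controlled; equal inputs and configuration give
  byte-identical output files.

## Problem sizes used in the tests

The test-suite and the acceptance script exercise desk-scale problems
chosen to make every property checkable in seconds to a few minutes:
chains of 8–34 residues, stoichiometries A2, A3, A2B2, A6, ensembles of
up to 20 models, 20–50 seeded trials per property. These sizes are the
package's own test conditions; the implementation itself is limited only
by memory (distance matrices are dense).

## Known limitations

* The QS-score kernel is a stand-in for the cited formulation; absolute
  QS values may differ from other implementations, although ordering
  behaviour (shared-contact agreement weighted by distance error) is
  preserved.
* Equal-weight combinations replace the method's trained score
  combinations; users with fitted weights should pass them explicitly.
* Nucleic-acid chains, ligands and mmCIF input are out of scope.
* Exact-sequence chain grouping treats point mutants as different
  groups.
* GDT_TS uses a heuristic (though deterministic and exhaustive-seeded)
  search; it can in principle undershoot the true optimum on adversarial
  cases.

## A complete example

```{r example, eval = FALSE}
ref <- make_idealized_multimer("A2B2", 20, seed = 1)
le <- make_labeled_ensemble(ref, n = 10, sigma_range = c(0.2, 3), seed = 2)

jury <- jury_assess(le$ensemble)
tidy(jury)                      # per-model component + combined scores
rank_models(jury, "modfolddockr", top_k = 5)
glance(jury)

autoplot(jury)                  # jury score overview
plot_local_quality(jury)        # per-residue profiles, interfaces marked

out <- tempdir()
cfg <- run_config("jury_rank", "A2B2",
                  models = le$ensemble$structures,
                  target_id = "T0001", out_dir = out, quiet = TRUE)
res <- run_jury(cfg)
res$files                       # ranking.tsv, T0001.qa, *_local.pdb
```
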