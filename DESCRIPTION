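Package: dockjury
Title: Consensus Quality Estimation for Protein Complex Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reference-free quality estimation for models of protein
    quaternary structure. Implements all-vs-all pairwise comparison of
    multimer models with self-contained oligo-lDDT, QS-score and DockQ
    metrics (plus per-chain GDT_TS), chain mapping by permutation search,
    and three consensus ("jury") score-combination variants: a linear
    combination for correlation with observed quality, a Borda rank
    aggregation for model ranking, and a single-model mode against a
    user-supplied reference set. Reads PDB and CASP TS model files, writes
    per-residue local quality to the B-factor column and emits CASP
    QMODE2-style QA files. Includes a seeded synthetic decoy generator so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
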