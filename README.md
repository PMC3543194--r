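# vecsite

Transcription factor binding site (TFBS) search in vector spaces.

A transcription factor binds short DNA segments of a fixed length *l*.
Given its known binding sites, the search problem is to rank candidate
*l*-mers — and windows of longer sequences — so that unseen binding sites
come out on top.  `vecsite` embeds every *l*-mer **s** as a sparse
indicator vector: four weighted variables *w<sub>i</sub> I<sub>u</sub>(s<sub>i</sub>)*
per position and sixteen *w<sub>i,j</sub> I<sub>uv</sub>(s<sub>i</sub>s<sub>j</sub>)*
per nucleotide pair with *j − i* ∈ {1, 2}, and scores candidates against a
query vector **t** by the dot product Score(*s*) = **s**ᵀ**t**.  Search
runs in one of three nested subspaces — `mono` (4*l*), `markov`
(16*l* − 12, first position plus adjacent pairs) and `full` (36*l* − 48) —
with uniform or information-content weights, chosen per TF by nested
cross-validation.

Two query constructions are provided, plus two baselines:

* **NPV** — the vector from the centroid of embedded non-sites to the
  centroid of embedded sites, **t** = **μ**₊ − **μ**₋.
* **ODV** — the direction β solving the class-weighted soft-margin
  quadratic program min ½‖β‖² + (C/n₊)Σξᵢ + (C/n₋)Σξᵢ subject to
  βᵀ**s** ≥ b + 1 − ξ for sites and βᵀ**s** ≤ b − 1 + ξ for non-sites
  (default C = 2⁻⁶), solved by a sequential-minimal-optimization dual
  solver verified against an independent soft-margin implementation.
* **kNPV / kODV** — two-subtype variants: k-means (k = 2) clusters the
  embedded sites, and scoring takes the best branch,
  e.g. max<sub>m</sub> **s**ᵀ(**μ**₊ₘ − **μ**₋).
* **PSSM** (Σ log₂ f<sub>i</sub>(s<sub>i</sub>)) and **ULPB** (positional
  first-order Markov chain against a background chain,
  log₂ f₁(s₁) + Σ log₂ [f<sub>i</sub>(s<sub>i+1</sub>|s<sub>i</sub>) /
  f(s<sub>i+1</sub>|s<sub>i</sub>)]) for comparison.

Evaluation follows a ν-fold cross-validation protocol (ν = 10): training
negatives are all embedding-sequence windows minus each site and its two
neighboring windows, sampled at 10:1; an inner (ν−1)-fold CV picks the
weight/subspace combination on training data only; test positives and
negatives are scored on both strands; each positive's rank among the test
negatives is 1 + #{negatives ≥ it}; AUC, partial AUC at FPR ≤ 0.01 and
ChIP-seq-style peak containment matching summarize performance.  A
synthetic-data module generates Markov backgrounds and PWM-planted motifs
(optionally two subtypes) with recorded coordinates, so the whole pipeline
is testable without downloads.

## Worked example

```r
library(vecsite)

# a weak planted motif: 40 sites, ~0.7 bits/column, 40-base flanks
spec <- motif_spec("TGACGTCATTAG", ic_per_column = 0.7)
ds <- plant_motif(spec, n_sites = 40, flank_length = 40, seed = 101)
positives <- site_set(ds$sites, coords = ds$coords)
test_negs <- sample_background(400, 12, seed = 202)

for (m in c("pssm", "ulpb", "npv", "odv")) {
  print(run_cv(positives, ds$seqs, test_negs, m,
               cv_config(nu = 10, seed = 303)))
}
```

```
eval_result: method = pssm, 40 positives vs 400 test negatives
  AUC = 0.9996 (median rank 1)
eval_result: method = ulpb, 40 positives vs 400 test negatives
  AUC = 0.9941 (median rank 1)
eval_result: method = npv, 40 positives vs 400 test negatives
  AUC = 0.9998 (median rank 1)
  chosen combos: uniform full x 2, uniform mono x 8
eval_result: method = odv, 40 positives vs 400 test negatives
  AUC = 0.9998 (median rank 1)
  chosen combos: uniform full x 2, uniform mono x 8
```

Each `eval_result` reports the cross-validated AUC of the method against
the 400 test negatives, the median rank of a held-out site, and (for the
vector-space methods) which weight/subspace combination the inner CV chose
per fold.  Training a final query and scanning a fresh sequence:

```r
pool <- build_training_negatives(ds$seqs, ds$coords, 12)
q <- odv_fit(ds$sites, sample_negatives(pool, 40, seed = 9),
             embedding_config(12, "uniform", "full"))
target <- paste0(sample_background(1, 25, seed = 7), "TGACGTCATTAG",
                 sample_background(1, 25, seed = 8))
score_sequence(target, q, seq_id = "chrTest")
```

```
   seq_id start end strand     score n_skipped
1 chrTest    25  37      + 0.2715625         0
```

The best window is the planted site (0-based interval [25, 37) on the
forward strand).  A command-line wrapper with `simulate`, `train`, `scan`,
`cv` and `compare` subcommands is installed under `inst/cli/vecsite`.

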