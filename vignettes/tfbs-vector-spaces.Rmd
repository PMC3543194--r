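---
title: "Searching for transcription factor binding sites in vector spaces"
author: "vecsite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Searching for transcription factor binding sites in vector spaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vecsite)
```

## The model

A transcription factor (TF) binds short, similar DNA segments of a fixed
length $l$.  Given a set of known binding sites of one TF, the search
problem is to rank unseen $l$-mers (and windows of longer sequences) so
that true binding sites come out on top.

`vecsite` casts this as retrieval in a Euclidean space.  Every $l$-mer $s$
is embedded as a sparse indicator vector $\mathbf{s}$: position $i$
contributes four variables $w_i I_u(s_i)$, $u \in \{A, C, G, T\}$, and
each nucleotide pair $(s_i, s_j)$ with $j - i \in \{1, 2\}$ contributes
sixteen variables $w_{i,j} I_{uv}(s_i s_j)$.  Pairs further apart are not
encoded; short-range dependence is where most of the positional
correlation in binding sites lives, and restricting to adjacent and
one-gap pairs keeps the dimension linear in $l$.  A candidate is scored
against a query vector $\mathbf{t}$ by the dot product
$\mathrm{Score}(s) = \mathbf{s}^\top \mathbf{t}$; with unit weights and a
query that is itself an embedded $l$-mer this counts shared nucleotides
and nucleotide pairs.

Three nested subspaces are searched, selected per TF by cross-validation:

| subspace | features | dimension |
|---|---|---|
| `mono`   | single nucleotides                    | $4l$      |
| `markov` | first position + adjacent pairs       | $16l-12$  |
| `full`   | nucleotides + adjacent and gap-1 pairs | $36l-48$  |

The `markov` subspace mirrors a first-order Markov chain.  Because the
subspaces are nested coordinate blocks of the `full` layout, restricting
the search is just a matter of zeroing (or dropping) coordinates.  The
`full` subspace is defined for $l \ge 2$: the gap-1 block is then empty
and $36l-48$ still equals $4l + 16(l-1)$.

Two weight schemes are supported.  Uniform weights set $w_i = w_{i,j} = 1$.
Information-content (IC) weights set $w_i = IC_i \in [0, 2]$ and
$w_{i,j} = IC_{i,j} \in [0, 4]$, where $IC_i = 2 + \sum_u f_i(u) \log_2
f_i(u)$ and the pair analogue starts from 4 bits.  IC weighting
de-emphasizes uninformative columns.  Note that the IC enters the weights
literally (not as $\sqrt{IC}$), so when both the candidate and a
mean-based query are weighted, IC contributes quadratically to the score;
this is the documented behavior, and rankings — the only thing the
evaluation uses — are unaffected by any monotone rescaling of a fixed
weight vector.

## Query construction

**NPV (negative-to-positive vector).**  With embedded positives $P$ and
negatives $N$, the query is $\mathbf{t} = \boldsymbol\mu_+ -
\boldsymbol\mu_-$, the vector from the negative centroid to the positive
centroid.  Scores decompose as
$\mathbf{s}^\top\boldsymbol\mu_+ - \mathbf{s}^\top\boldsymbol\mu_-$.

**ODV (optimal discriminating vector).**  The query direction
$\boldsymbol\beta$ and threshold $b$ solve the class-weighted soft-margin
quadratic program

$$\min_{\beta, b, \xi}\ \tfrac12\lVert\beta\rVert^2
  + \frac{C}{n_+}\sum_{i \le n_+}\xi_i
  + \frac{C}{n_-}\sum_{i > n_+}\xi_i$$

subject to $\beta^\top \mathbf{s}_{(i)} \ge b + 1 - \xi_i$ for binding
sites, $\beta^\top \mathbf{s}_{(i)} \le b - 1 + \xi_i$ for non-sites, and
$\xi_i \ge 0$.  The per-class costs $C/n_+$ and $C/n_-$ make the solution
invariant to duplicating the training data and balance the 10:1
negative:positive sampling.  The default $C = 2^{-6}$ is deliberately
small — on these low-dimensional indicator embeddings a soft margin with
many support vectors generalizes better than a hard fit, and the value
works across TFs; it is exposed as a parameter.

The solver works on the dual (a box-constrained QP with one equality
constraint) by sequential minimal optimization with maximal-violating-pair
working-set selection, run to a Karush–Kuhn–Tucker gap of $10^{-8}$
(`tol`).  $\boldsymbol\beta$ is recovered from the dual variables, $b$
from the free support vectors (mid-point of the feasible interval when
none are free), and the slacks from $(\boldsymbol\beta, b)$, so the
returned primal solution is feasible by construction; the reported primal
and dual objective values agree at optimality and both are stored.  The
test suite cross-checks objective values, directions and intercepts
against an independent class-weighted soft-margin implementation (libsvm
via `e1071`) on randomized instances.

**Motif subtypes (kNPV / kODV).**  Some TFs bind two distinct sequence
patterns.  Training positives are clustered in the embedded space by
k-means with $k = 2$; the package keeps $k$ fixed at 2 (automatic
selection of $k$ is out of scope).  kNPV scores by
$\max_m \mathbf{s}^\top(\boldsymbol\mu_{+m} - \boldsymbol\mu_-)$ with a
single shared negative centroid (recomputing $\boldsymbol\mu_-$ per
subtype would change nothing but cost, since the same negative sample is
used).  kODV fits one ODV per cluster against the same sampled negative
set — keeping the comparison with plain ODV matched — and scores by
$\max_m \mathbf{s}^\top \boldsymbol\beta_{+m} / \lVert\boldsymbol\beta_{+m}\rVert$;
the directions are unit-normalized because the per-cluster margins are not
commensurate, and the per-cluster intercepts are discarded.  k-means uses
10 seeded Lloyd restarts from distinct embedded points, keeping the best
within-cluster sum of squares; restarts yielding an empty cluster are
discarded, with up to 5 additional rounds before erroring.

## Baselines

**PSSM** scores $\sum_i \log_2 f_i(s_i)$ from the positional
mononucleotide probabilities alone — no pairs, no background.

**ULPB** models a site by a position-specific first-order Markov chain and
the background by a homogeneous one:
$\log_2 f_1(s_1) + \sum_{i=1}^{l-1} \log_2 \left[ f_i(s_{i+1} \mid s_i)
/ f(s_{i+1} \mid s_i) \right]$.  The first term carries no background
correction; the score is approximately a log-likelihood ratio.  The
background transition matrix is estimated from user-supplied sequences
(the embedding sequences during cross-validation), not from a hard-coded
genome.

All frequency estimates use an additive pseudocount $\alpha = 1$ by
default (configurable; $\alpha = 0$ reproduces textbook counts) so that
the log scores stay finite; logs are base 2 throughout, which matches the
IC definitions and does not affect rankings.  A degenerate model with
$\alpha = 0$ is accepted, but scoring a word that touches a
zero-probability cell raises an error rather than returning $-\infty$.

## Evaluation protocol

Performance on one TF is measured by $\nu$-fold cross-validation
($\nu = 10$):

1. **Training negatives** are all $l$-windows of the sequences embedding
   the binding sites, minus each site's own window and the two windows
   starting one position to either side (near-duplicates of the
   positives).  Windows containing non-ACGT characters are skipped and
   counted.
2. **Test negatives** are binding sites of *other* TFs, with entries
   identical to a positive on either strand removed and entries shorter
   than $l$ dropped; longer entries are kept whole and scored by their
   best window.
3. Positives are split into $\nu$ folds (seeded permutation, round-robin,
   sizes $\lfloor n_+/\nu \rfloor$ or $\lfloor n_+/\nu \rfloor + 1$).  In
   each iteration the scorer is fitted on the training folds plus
   negatives sampled at ratio 10:1 from the training pool.
4. For NPV/ODV-family methods, the weight scheme and subspace are chosen
   per fold by an inner $(\nu-1)$-fold CV over the six combinations
   $\{\text{uniform}, \text{IC}\} \times \{\text{mono}, \text{markov},
   \text{full}\}$, using only training-fold positives and held-out
   training negatives (never the external test negatives, so selection
   cannot leak test information); ties break in fixed grid order.  IC
   weights are always estimated from the training positives of the fit at
   hand.  Baselines have no combination to select.
5. Test positives and test negatives are scored on both strands (best
   $l$-window).  Each positive's rank is $1 + \#\{\text{negatives scoring}
   \ge \text{it}\}$ — ties count against the positive, exactly as the rank
   is defined.  The overall AUC, however, uses the standard half-tie
   Mann–Whitney convention, computed from the ranks together with
   per-positive tie counts; both conventions are implemented and the test
   suite verifies their algebraic relationship.

For genome-scale validation against ChIP-seq peaks the package provides a
partial AUC restricted to FPR $\le 0.01$ (rescaled to $[0,1]$; the ROC is
piecewise linear between threshold vertices, so tied scores contribute
diagonal segments) and containment matching: a predicted site is a true
positive only if a peak fully contains it, and a peak is recalled only if
it fully contains a predicted site.  Coordinates are 0-based half-open
(BED) everywhere.

Methods are compared across TFs by one-sided Wilcoxon signed-rank tests on
paired per-TF AUCs, one p-value per ordered method pair; this is the
standard paired nonparametric choice for such tables.  All-zero
differences report $p = 1$.

Every random choice — fold assignment, negative sampling, clustering
restarts, simulation — derives deterministically from one master seed, so
`run_cv()` is bit-reproducible.

## Synthetic data

The generator emulates the structure the search methods assume: a
first-order Markov background (default: uniform initial distribution,
transitions mildly favoring base repetition, so the ULPB background ratio
is non-trivial), sites drawn from per-column distributions placing
`fidelity` mass on a consensus base, an optional second subtype with its
own consensus, and an optional adjacent-copy dependence that leaves
mononucleotide columns uninformative while creating pair structure (used
to exercise subspace selection).  `fidelity_for_ic()` converts a target
per-column information content into the corresponding fidelity.  Sites
are planted on the forward strand with recorded 0-based coordinates;
strand handling is tested by planting reverse-complemented sites
explicitly.

What the generator does **not** emulate: CpG islands, repeats, copy-number
structure, variable site lengths, position-specific indels, or the
phylogenetic correlation between sites of homologous TFs.  Passing the
synthetic evaluation therefore demonstrates correctness of the machinery
and sensible behavior under the model's own assumptions, not performance
on real genomes.

The packaged evaluation scripts use $n_+ = 50$ sites of length $l = 12$ at
about 1.5 bits per column with 50-base flanks, 500 background test
negatives, $\nu = 10$, ratio 10, $C = 2^{-6}$; for the two-subtype
condition the consensi differ at 6 of 12 positions with fidelity 0.9.
These sizes give stable AUCs while keeping a full nested-CV run of all
methods in the low minutes on one core.

## Numerical choices and edge cases

* SMO convergence: KKT gap below $10^{-8}$ ($10^{-10}$ in the
  verification tests); non-convergence raises an error with diagnostics.
* Window scanning ties: smaller start first, then forward strand.
* Sequences shorter than $l$ cannot be scored and raise an error — there
  is no $l$-mer to pick, and silent padding would fabricate sequence.
* $0 \log 0 \equiv 0$ in entropy sums; IC values are clamped to their
  $[0, 2]$ / $[0, 4]$ ranges against rounding.
* Empty site sets, ragged site lengths and non-ACGT characters are
  rejected at construction with the offending entries named; negative
  *pools* silently skip invalid windows but log the count.
* `sample_negatives()` clamps to the pool when the request exceeds it and
  says so.

## Limitations

* Fixed $l$ per TF; variable-length sites would need alignment-free
  extensions.
* $k = 2$ subtypes only.
* Pair features stop at gap 1 by design.
* The plain window scan is linear in sequence length; no indexing is
  provided for genome-scale scans.
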