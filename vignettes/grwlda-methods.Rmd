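---
title: "GrwLDA: model, design choices and evaluation protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GrwLDA: model, design choices and evaluation protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GrwLDA)
```

## The prediction problem

Given a binary lncRNA–disease association matrix `AS` (`nl` rows,
`nd` columns), the task is to score every unknown pair so that true
but unobserved associations rank high. The model rests on one
assumption, used in both directions: functionally similar lncRNAs tend
to associate with semantically similar diseases. Everything else is
machinery for propagating the sparse association evidence through two
similarity networks.

## Disease semantic similarity

A disease is represented by the DAG of its MeSH-style tree positions
and all their ancestors, obtained by dot-segment prefix truncation
(`C04.588.274` has ancestors `C04.588` and `C04`); the DAG of a
disease with several codes is the union over the codes. The disease's
own positions contribute 1, and each ancestor contributes the decay
`Δ` times the maximum over its children, so a term reachable along
several paths keeps the strongest path's value. The pairwise
similarity divides the two-sided contribution mass of the shared terms
by the sum of the two total semantic values; it is symmetric, lies in
[0, 1], and is exactly 1 on the diagonal.

Two representational notes. First, the disease node is identified
with its full tree codes rather than carried as an extra pseudo-node:
this is what makes the two-disease chain example
(`C04.588` vs `C04`) come out at `(0.5 + 1) / (1.5 + 1) = 0.6`
exactly, with no double counting of the disease in its own semantic
value. Second, a code that is simultaneously a full position and an
ancestor of another code of the same disease keeps contribution 1
(the maximum rule).

`Δ` defaults to 0.5, the conventional value for this family of
DAG-decay measures; it is exposed everywhere (`decay =` /
`--delta`) because the measure's literature treats it as a tunable.
At `Δ = 0` only identical leaf positions match; at `Δ = 1` every
ancestor counts as much as the disease itself.

## lncRNA functional similarity

The functional similarity of two lncRNAs is the group-wise best-match
average of their associated disease sets: each disease of one group is
matched to its most similar disease of the other group, and the
matched scores of both directions are averaged over the two group
sizes. Identical groups give 1; disjoint groups with no cross
similarity give 0.

When a lncRNA's disease set is empty — which happens routinely under
novel-lncRNA masking — the formula's denominator vanishes. The
package defines the similarity (including the self-similarity) as 0 in
that case: an empty profile carries no functional evidence, and
encoding it as 0 keeps the downstream transfer matrix well defined
(its column is all-zero and stays all-zero under normalization).

The implementation is vectorized (a best-match matrix followed by two
matrix products); the test suite checks it against a literal
nested-loop evaluation of the defining formula on random small
instances, exhaustively over 100 cases of up to 5 entities per side.

## Propagation

The four transfer matrices `WL`, `WD`, `WA1`, `WA2` are the column
normalizations of `LL`, `DD`, `AS`, `ASᵀ`; a zero column stays zero.
For disease `j`, the seed of the lncRNA-side walk combines the image
of a smoothed disease-relevance vector with the disease's own
association column, then renormalizes; the walk
`p ← (1−γ)·WL·p + γ·p⁰` runs to its steady state. The disease-side
walk is symmetric. Final scores blend the two walks linearly with
weight `η`.

### The Laplacian smoothing form

The seed smoothing is stated as a product `(1−α)(I − α·WD)·d(j)`, but
evaluated literally that expression puts negative mass
(`−α·WD(i,j)`) on every neighbor of the query — the opposite of its
stated purpose of forcing connected diseases toward similar scores,
and incompatible with the subsequent probability normalization. The
package therefore defaults to the resolvent form
`(1−α)(I − α·WD)⁻¹·d(j)`, the standard graph-regularization smoother,
which is provably nonnegative for a column-stochastic matrix and
`α < 1` and reduces to the indicator as `α → 0` just as the literal
product does. The literal form is kept behind
`laplacianForm = "literal"` for fidelity experiments; the test suite
demonstrates the negative entries that motivate the default. The
resolvent is checked against a truncated Neumann series
`Σ αᵏ·Wᵏ·d` to `1e-10`.

The seed normalization is applied on both the disease-seeded and the
lncRNA-seeded side, for symmetry, even though it is spelled out only
once in the method's statement.

### Numerical choices

* Convergence is declared when the L1 change between successive
  vectors is at most `1e-6` (non-strict comparison); the iteration cap
  is 1000, after which an error carrying the last residual is raised.
  With `γ = 0.9` the contraction factor is `0.1` per step, so
  convergence takes under ten iterations.
* A closed-form engine (`engine = "solve"`,
  `γ(I − (1−γ)W)⁻¹p⁰`) is exposed as an alternative and serves as the
  oracle the iterative walk is tested against (agreement to `1e-8` on
  random 20×20 column-stochastic instances).
* All per-disease (and per-lncRNA) walks share one matrix iteration:
  seeds are columns of a seed matrix, which makes a full 78×113 score
  matrix a pair of small matrix iterations rather than 191 vector
  loops.
* An entity disconnected from everything (all-zero seed) keeps an
  all-zero score column/row instead of raising, so whole-matrix
  prediction never aborts; steady vectors of nonzero seeds sum to 1.
* Ranked outputs order by descending score and break ties by ascending
  identifier, so outputs are deterministic byte for byte.

## Evaluation protocol

Three leave-one-out modes mask, per evaluated known pair: only the
cell (overall), the lncRNA's entire row (novel lncRNA), or the
disease's entire column (isolated disease). The held-out pair's score
under the masked model is a positive.

**Negatives.** In overall mode the negatives are all unknown pairs
scored once under the full model: masking a single cell perturbs the
rest of the score matrix negligibly, and rescoring all ~8,600
negatives per left-out cell would cost a quadratic number of runs for
no benefit. In the novel and isolated modes, however, the masked
model is *systematically* differently calibrated from the full model —
an emptied column redistributes its entire seed mass over the
similarity neighborhood, inflating every score in that column —
so comparing masked positives against full-model negatives is not a
like-for-like comparison (it inverts the expected ordering of the
modes). Since each row/column-masked run rescores the entity's whole
row/column anyway, the negatives of that row/column are taken from
the same masked run, at zero extra cost. This keeps positives and
negatives on one calibration and is the package's deliberate
protocol choice.

**Similarity recomputation.** The lncRNA functional similarity is
derived from `AS`, so evaluating against a similarity computed from
the *unmasked* matrix leaks the held-out evidence. By default `LL` is
recomputed from the masked matrix in every fold. One consequence is
intentional and worth stating plainly: under leakage-free novel-lncRNA
masking, the masked lncRNA has an empty profile, its similarity row is
0, no mass can reach it from either walk, and every score in its row
is 0 — the pooled novel AUC is exactly 0.5. That is the honest answer
to "what does the model know about a lncRNA with no associations and
no other data source: nothing." The `staticLL = TRUE` variant keeps
the full-data similarity (as association-derived-similarity methods
in this literature implicitly do) and yields an informative novel-mode
evaluation; both variants are computed by the acceptance script and
reported side by side.

**k-fold.** Associations are partitioned at the cell level; per
repetition each fold is masked jointly, the held-out scores of all
folds are pooled into one per-repetition AUC, and the reported value
is the mean over repetitions (10 by default). The partition seed is
mandatory. AUPR uses the step-wise (non-interpolated) rule, the
conservative convention; ROC/AUC use the trapezoidal rule, equal to
the Mann–Whitney statistic with half credit for ties.

## The synthetic benchmark

The generator emulates the statistical shape of the curated benchmark
this method was developed on: 78 lncRNAs, 113 diseases, 210
associations — a sparse bipartite graph in which diseases cluster
into families sharing deep MeSH ancestors and lncRNAs associate
within disease families. Six co-modules are planted; each block's
diseases share a depth-4 ancestor chain and differ in a private leaf,
giving within-block semantic similarity near 0.5 against ~0.03
between blocks at `Δ = 0.5`. Each block receives 33 associations
(first a covering set so that every entity has at least one
association and the edge list alone reproduces the dimensions, then
uniform fill), plus 12 uniform off-block noise associations, for 210
total. A single integer seed drives per-phase substreams derived
deterministically, so adding an output never shifts earlier ones. A
label-permutation null (same count, uniformly random cells) is
provided for signal-vs-noise checks.

What the generator does **not** emulate: the heavy-tailed degree
distribution of real curated databases (a few hub lncRNAs with many
associations), disease families of uneven size, correlated curation
biases, or any biological signal beyond block co-membership. Passing
the planted-signal tests therefore shows that the pipeline recovers
structure of the kind the model assumes, at realistic size and
sparsity — not that it attains any particular accuracy on real
curated data.

## Problem sizes used by the checks

The test suite runs its full-size recovery checks on the 78×113
benchmark for five generator seeds (leave-one-out in all three modes
plus a permuted-label null), and everything else on small instances:
12×15 planted benchmarks for pipeline tests, ≤5-entity exhaustive
oracle comparisons for the similarity formula, 15–20-node random
stochastic matrices for the walk oracles. The acceptance script uses
the full 78×113 benchmark for every quantity it reports, with 10
repetitions of 5-fold cross-validation.

## Known limitations

* lncRNA similarity is derived from the association matrix itself, so
  predictions are biased toward well-annotated lncRNAs; orthogonal
  similarity sources (expression, interaction profiles) are out of
  scope.
* The leakage-free novel-lncRNA evaluation is degenerate by
  construction (see above); the informative variant necessarily leaks
  association-derived similarity.
* Parameters are taken as given (`γ = 0.9`, `α = β = 0.1`,
  `η = 0.7`); no tuning machinery is included.
* The method scores each disease's column as a probability vector;
  scores are comparable within a query entity's candidate list, and
  cross-entity pooling (as in the cross-validation protocols) relies
  on that shared normalization rather than on any probabilistic
  calibration of individual scores.
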