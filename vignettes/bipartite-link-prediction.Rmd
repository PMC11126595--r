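---
title: "Balanced link prediction in two-mode association networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Balanced link prediction in two-mode association networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biplink)
```

## The problem

Association databases in microbiology and pharmacology are naturally
*two-mode* (bipartite) networks: one part holds agents (probiotic strains,
drugs, microbes), the other holds conditions (diseases), and an edge records
a reported association.  Such catalogues are incomplete by construction --
absence of an edge usually means "not yet studied", not "no effect".  Link
prediction ranks the zero entries of the cross-part adjacency matrix by how
likely they are to be true-but-missing associations, so that laboratory
follow-up can be prioritized.

In an ordinary (one-mode) graph the classical neighbourhood scores compare
the direct neighbour sets of the two endpoints.  In a bipartite graph the two
endpoints of a candidate pair live in different parts, so their direct
neighbour sets are disjoint by construction and the classical formulas are
identically zero.  The repair used here is the *neighbour-of-neighbour* set:
for a node $x$, $\Gamma(x)$ is its neighbour set (in the opposite part) and
$\Gamma(\Gamma(x)) = \bigcup_{z \in \Gamma(x)} \Gamma(z)$ is the union of its
neighbours' neighbour sets, which lies back in $x$'s own part.  Overlaps of
the form $|\Gamma(x) \cap \Gamma(\Gamma(y))|$ are then well defined for a
cross-part pair, and each score is *balanced*: it averages the two one-sided
overlaps so that neither part dominates the ranking.

## The scores

For a candidate pair $(x, y)$ with $x$ in part A and $y$ in part B:

| method | formula |
|---|---|
| CN | $\tfrac12\left(|\Gamma(x)\cap\Gamma(\Gamma(y))| + |\Gamma(y)\cap\Gamma(\Gamma(x))|\right)$ |
| JC | CN divided by $|\Gamma(x)\cup\Gamma(y)| = |\Gamma(x)|+|\Gamma(y)|$ |
| AA | $\tfrac12\left(\sum_{z\in\Gamma(y)\cap\Gamma(\Gamma(x))}\frac{1}{\log|\Gamma(z)|} + \sum_{z\in\Gamma(x)\cap\Gamma(\Gamma(y))}\frac{1}{\log|\Gamma(z)|}\right)$ |
| PA | $|\Gamma(x)|\times|\Gamma(y)|$ |

Useful consequences, all asserted in the test suite: every score is
non-negative and symmetric in argument order; JC lies in $[0, 0.5]$ because
its numerator is at most $(|\Gamma(x)|+|\Gamma(y)|)/2$; CN is bounded by the
same quantity; PA is zero exactly when an endpoint is isolated.

### Numerical conventions

Decisions the formulas themselves leave open, fixed once here:

* **AA logarithm base.** Natural log by default (the usual Adamic/Adar
  convention); `logBase` is a knob on every scorer.
* **AA degree-1 contributors.** A contributing node $z$ with $|\Gamma(z)| \le 1$
  is skipped, since $1/\log 1$ is undefined.  Skipping (rather than smoothing
  with $1/\log(1+|\Gamma(z)|)$) is the least surprising choice and preserves
  non-negativity.
* **JC 0/0.** A pair of isolated endpoints scores 0 -- an isolated pair
  carries no evidence of affinity.
* **$\Gamma(\Gamma(x))$ retains $x$** when $x$ is reachable in two hops.
  Nothing in the formulas requires removing it: the overlaps intersect
  $\Gamma(\Gamma(x))$ with sets from the opposite part only, where $x$ cannot
  appear, so retention is harmless and keeps the operation a plain union.
* **Ties.** Wherever an order matters (ranked prediction lists, degree
  extremes), ties are broken lexicographically by node identifier, so every
  ranking is a deterministic function of the network.  Note that on very
  small networks several candidates can share the top score; the tie rule,
  not the score, then decides rank 1.
* **Score comparison.** AUC win/tie decisions use a relative tolerance of
  $10^{-9}$ so that floating-point noise in AA sums cannot turn a true tie
  into a spurious win.
* **Existing edges are scorable.** The evaluation protocol scores held-out
  true edges against the training network, so the scorers do not insist
  their input be a non-edge; only the candidate *ranking* refuses existing
  edges.

Two implementations of the scores ship in the package: `linkScore()` /
`rankCandidates()` (sparse-matrix products and cached two-hop sets; the
candidate enumeration streams over column blocks keeping only a running
top-$k$ pool) and `bruteForceScore()` (a literal set-by-set transcription
with no indexing), kept deliberately independent so each can check the
other.  The test suite compares them on more than $10^4$ random pairs.

## The evaluation protocol

`evaluateLinkPrediction()` runs $k$-fold *edge holdout* (default $k = 10$):
the edge set is randomly partitioned into $k$ disjoint folds of near-equal
size; in each round one fold is removed (nodes are never removed, so a node
stripped of all edges stays as an isolated node) and two metrics are
computed on the training network:

* **Sampled-pair AUC.**  $n$ independent comparisons are drawn, each pitting
  a uniform held-out edge against a uniform *true non-edge* -- a cross-part
  pair absent from the original network, i.e. from both training and test
  edges.  With $n'$ strict wins for the held-out edge and $n''$ ties,
  $\mathrm{AUC} = (n' + 0.5\,n'')/n$: 0.5 is chance, 1 is perfect
  separation.  Both draws are with replacement; $n$ defaults to
  $10\times$ the fold size (the protocol itself does not fix $n$).
* **Precision@L.**  All candidate non-edges of the training network are
  ranked; the precision is the fraction of the top $L$ that are held-out
  edges.  $L$ defaults to the fold size, which keeps the value comparable
  across folds; the prediction *report* (`cmdPredict`) instead defaults to a
  top-20 cut, the customary length of a literature-confirmation list.

Per-method results are reported per fold, as mean $\pm$ sd across folds, and
as pooled tallies (summing $n'$, $n''$, $n$, hits and $L$ over folds) --
published single-number summaries rarely state which aggregation they used,
so both are available.  The best method is chosen by mean AUC, ties broken
by mean precision, then method name.

One user-visible seed governs a run; fold assignment and each fold's AUC
sampling draw from separately derived substreams, so changing the AUC sample
count never changes the folds.  Two runs with the same inputs and seed
produce byte-identical reports.

## The synthetic generator

Real association databases of this kind are built by scraping curated
sources and cannot be redistributed here, so the package carries a seeded
generator that emulates their gross statistics.  Edges are drawn
independently with pair probability

$$ p_{ab} \;=\; d \cdot \frac{w_a\, w_b\, \beta_{ab}}{\overline{w w \beta}} $$

where $d$ is the target density, the node weights $w$ are log-normal with
log-scale standard deviation `skew` (all 1 when `skew = 0`), and
$\beta_{ab}$ multiplies same-block pairs by `withinBlockOdds` when planted
communities are requested.  The normalization makes the *expected* density
exactly $d$; a configuration whose normalized probabilities would exceed 1
is a hard error naming the offending parameters, never a silent truncation
(truncation would quietly bias the realized density below its target).

Two deliberate choices:

* **Winsorized tails.** The log-normal draw is winsorized at $3\sigma$ in
  log space.  Unbounded tails would make the maximum pair probability --
  and hence the feasibility of a configuration -- a lottery over seeds;
  bounding the tails keeps every preset valid for every seed while
  preserving the one-knob heavy-tail behaviour.
* **The planted-block preset is a testing device.**  `plantedBlockPreset()`
  (40 x 60 nodes, density 0.08899, 4 blocks, within-block odds 20) exists
  so that AUC and precision have a *recoverable* signal to find:
  within-block held-out edges share two-hop structure with surviving
  within-block edges, so neighbourhood scores beat the degree-product
  baseline.  It does not model any real database.

`probioLike()` presets the generator to the shape of a scraped
probiotic--disease catalogue: parts of 640 and 3884 nodes and density
0.08899 at full scale, and a reduced 64 x 388 instance at the same density
(the default) so that density-based checks transfer while routine runs stay
fast.  Its skew of 0.4 was fixed once, before any evaluation, as the largest
value at which the normalized pair probabilities are provably below 1 with
a comfortable margin for both scales; it yields many low-degree nodes on
the large part (a fifth of part B at degree $\le 2$ in typical draws) and
hubs at roughly 2--3 times the average degree.

### What the generator does not reproduce

A product-form (Chung--Lu style) edge model at density 0.089 *cannot* match
the extreme hub degrees of a real curated catalogue on both margins at
once: hub-hub pairs would need probability greater than 1.  The synthetic
hubs are therefore much milder than the real "powerhouse" nodes (real
top-degree ratios reach 4--5 times the average).  Nor does the generator
model curation artefacts: block-duplicated disease codes, correlated
annotation of related conditions, or the layered growth of a literature
database.  Passing tests on synthetic data therefore demonstrate the
*correctness of the machinery* -- scores, protocol, metrics -- and the
recoverability of planted structure, not the headline accuracy attainable
on any particular real network.

## Problem sizes used in the checks

The shipped checks run on sizes chosen to make their statistics sharp while
keeping a full suite run in well under a minute: exhaustive-versus-sampled
AUC agreement on a 40 x 50 instance with $10^5$ sampled comparisons
(binomial standard error $\approx 0.0016$); scorer cross-validation on
$10^4$ random (pair, method) cases over ten 12 x 14 networks; generator
calibration on the reduced 64 x 388 preset, where three binomial standard
errors of the density are $\approx 0.0054$.

## Known limitations

* Scoring is neighbourhood-based only; path-based, diffusion and supervised
  scorers are out of scope, as is within-part (agent--agent or
  disease--disease) prediction.
* `rankCandidates()` materializes one column block of scores at a time;
  with the default block size the full enumeration is comfortable up to a
  few million candidate pairs, beyond which `topK` plus a smaller
  `chunkSize` should be used.
* Precision@L on sparse holdouts is intrinsically noisy: with a fold of ~20
  edges among ~2000 candidates, one hit moves the value by 0.05.  AUC is
  the stabler comparison metric, which is why the best-method rule consults
  it first.
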