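---
title: "Consensus-based ranking of RNA 3D model ensembles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus-based ranking of RNA 3D model ensembles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaconsensus)
```

## The model

`rnaconsensus` assumes that when many independent 3D models are built for
the same RNA, the interactions they *agree* on are more likely to be real
than the interactions any single model invents. The unit of agreement is
a typed, symmetric interaction between two residues:

* `canonical_pair` — Watson-Crick AU and GC, plus the GU wobble. Identity
  is the residue pair alone.
* `noncanonical_pair` — any other base pair, classified into one of the
  12 Leontis-Westhof geometric families (cis/trans crossed with the
  unordered pair of edges Watson-Crick/Hoogsteen/Sugar). The family is
  part of the identity: `tWH` between residues 3 and 9 and `cSS` between
  the same residues are different interactions.
* `stacking` — face-to-face base contact; identity is the residue pair
  (stacking topology is deliberately not part of identity, keeping the
  noise simulator's payload space a simple pair space).

Across an ensemble of `N` models each distinct interaction key receives a
count `c` and a fuzzy membership `p = c/N`. This multiset is the *virtual
consensus structure*. Scoring a model against it uses either

* crisp confusion counts against the threshold subset `{c >= n}` for a
  confidence level `n`, or
* fuzzy confusion sums against the whole multiset: a consensus entry with
  membership `p` contributes `p` to `TPsum` and `1-p` to `FPsum` when the
  model contains it, and `p` to `FNsum` when it does not.

Both feed `INF = sqrt(precision * recall)` and
`F1 = 2TP/(2TP + FP + FN)`. The fuzzy update rules have a useful
provable property, exercised by the test suite: adding to a model a
consensus interaction with `p > 0.5` can never lower its F1, while
adding one with `p < 0.5` can never raise it. The weighted mode is
therefore a threshold-free compromise that rewards common interactions
continuously instead of through a hard cutoff.

### Assumptions and scope

The approach presumes the ensemble is *informative*: at least two models
(enforced), identical nucleotide composition (enforced after automatic
chain renaming and renumbering), and errors that are at least partly
independent between models. A systematically wrong ensemble produces a
confidently wrong consensus; the package can flag nothing in that case.
Consistency is defined on (chain count, per-chain length, per-chain base
sequence) only — coordinates never participate.

## Constraint semantics

Extended dot-bracket constraints state an *effect*, not a mechanism, so
the mechanism had to be designed. The package uses the smallest rule set
that makes a required pair favor the models containing it and an `x`
position penalize any model pairing it:

* a **required** pair is a consensus member with membership forced to 1.0
  (weighted mode) and is always retained in the threshold subset, even at
  count 0. A model lacking it pays `FNsum += 1`.
* an **x-forbidden** interaction (any canonical or non-canonical pair
  touching an `x` position) is removed from the consensus; a model
  containing it pays a full `FPsum += 1`. Stackings are never
  constraint-flagged, since dot-bracket describes pairing only.

Whether a required-but-never-observed pair should enter the *threshold*
consensus is genuinely open; the package says yes by default
(`required_override = TRUE` in `threshold_consensus()`) because a user
asserting a pair from experimental data presumably wants it enforced in
both modes, and exposes the switch for the other reading.

Bracket families `()`, `[]`, `{}`, `<>` are matched with independent
stacks, so crossing (pseudoknotted) constraints are expressible. The
consensus exporter inverts this: greedy selection by descending
membership (ties: lexicographic key, so the export is deterministic),
then first-fit family assignment over the pairwise-crossing conflict
graph. More than four mutually crossing families is an error rather than
silent truncation.

## The geometric annotator

Production annotation of base pairs is its own research field; the
package's fidelity path is the interaction-table import, which accepts
the output of any external annotation tool as CSV. The built-in
geometric detector exists so that the package is usable end-to-end on
raw coordinates, and its thresholds (all configurable via
`annotation_params()`) are conventional distance/angle criteria, in
Angstrom and degrees:

| parameter | default | meaning |
|---|---|---|
| `canonical_c1_range` | 8.0–12.0 | C1'–C1' distance of a canonical pair |
| `hbond_max` | 3.5 | every named donor–acceptor distance of the WC/wobble pattern |
| `pair_plane_max` | 65 | maximum inter-base plane angle for any pair |
| `pair_offset_max` | 2.0 | out-of-plane centroid offset below which bases are coplanar |
| `polar_max` | 3.5 | nearest polar contact qualifying a non-canonical pair |
| `stack_centroid_max` | 5.5 | centroid distance for stacking |
| `stack_plane_max` | 30 | plane angle for stacking |
| `stack_offset_range` | 2.0–5.5 | out-of-plane offset for stacking |

The coplanarity bound (`pair_offset_max`) doubles as the pair/stack
separator: a base directly above another (offset ≈ helical rise 2.8)
can have polar atoms within 3.5 Å, and without the bound it would be
misread as a non-canonical pair. Edge assignment uses nearest-atom edge
membership; cis/trans comes from the sidedness of the two glycosidic
bonds relative to the glycosidic-nitrogen axis, projected into the mean
base plane. At most one pair interaction is kept per residue pair, with
canonical classification taking precedence.

The test fixture for the detector is `synthetic_helix_model()`: planar
idealized bases (regular polygon rings) placed so that Watson-Crick and
wobble hydrogen-bond distances come out near 2.9 Å, stacked with A-form
rise and twist. It is geometry built to satisfy the documented
thresholds — not crystallographic truth — and the detector is checked
against an independently coded brute-force all-pairs oracle on jittered
copies of it.

Modified nucleotides are mapped to their parent base through a small
built-in table (e.g. pseudouridine to U, 1-methyladenosine to A);
residues that look like nucleotides (they carry a C1' atom) but cannot
be mapped are kept for consistency checking with base `N` and excluded
from interaction analysis with a warning, which avoids fabricating
pairings for chemistry the detector does not understand.

## Ranking-similarity statistics

Four metrics compare a noisy or alternative ranking to a reference:
Spearman's ρ, Kendall's τ, a top-fraction enrichment score
`ES = |top_k ∩ top_k| / (f^2 N)` with `k = max(1, floor(f N))`, and
extrapolated rank-biased overlap. Two parameters are conventions rather
than derivations and are exposed as arguments: the ES top fraction
(default `f = 0.25`, which for a 13-model ensemble compares the top
three positions) and the RBO persistence (default `p = 0.9`, the common
choice weighting the top of the list heavily while still reading the
whole ranking). Rankings are required to be strict permutations; score
ties are already broken deterministically upstream, so tie-aware metric
variants are unnecessary.

The null model (`null_model_ci()`) draws batches of independent uniform
random permutation pairs, takes each batch's mean per metric, and
reports the empirical 2.5/97.5 percentiles of the batch means (linear
interpolation, the default quantile definition). For Spearman's ρ with
`k` items the per-pair null variance is `1/(k-1)`, so the batch-mean
half-width is approximately `1.96/(sqrt(k-1) sqrt(pairs))` — an analytic
cross-check the tests apply. The implementation is vectorized over rank
matrices and processes batches in chunks of at most 250,000 pairs to
bound memory; chunking does not affect the random stream.

## Noise injection

`run_noise_simulation()` perturbs interaction tables cumulatively: each
iteration picks a model, an interaction kind, and add/remove uniformly,
resampling infeasible combinations (nothing of that kind to remove, or a
saturated payload space). An added pair is drawn uniformly from all
unordered residue pairs of the universe, with a uniform Leontis-Westhof
family for non-canonical pairs, redrawing until the interaction is absent
from the chosen model. Noise level `n` means `n` accumulated alterations
since the reference, and the ensemble is re-ranked after every single
alteration. One seeded generator drives the whole simulation with
per-run substreams (`seed + run_index`), so runs are independent and the
entire profile is reproducible. A model is allowed to become empty: the
scoring conventions (below) keep its scores defined.

`synth_ensemble()` generates desk-scale study ensembles: a shared random
interaction core present in every model plus per-model
`Poisson(noise_rate)` additions and deletions. It emulates exactly what
the consensus machinery consumes — recurrent signal plus idiosyncratic
noise at the interaction level. It does *not* emulate spatial coherence
(no geometry), correlated errors between models produced by the same
method, or annotation-tool disagreement; passing tests on it demonstrate
the correctness of the consensus/scoring algebra, not performance on
real prediction sets.

## Numerical choices

* **Degenerate scores**: all-zero confusion (empty model, empty
  consensus) scores 1.0 — two empty interaction networks agree
  perfectly; `TP = 0` with any `FP` or `FN` scores 0.0. These are the
  limits of the two formulas.
* **Tie-breaking**: rankings sort by the primary score descending, then
  lexicographically by model id. This makes every downstream ranking a
  strict permutation and all outputs byte-reproducible.
* **Out-of-ensemble interactions**: a scored model containing an
  interaction the multiset has never seen pays `FPsum += 1`, the
  `p -> 0` limit of the fuzzy rule (reachable only when scoring a model
  from outside the consensus ensemble, or under `x` constraints).
* **Weighted-mode dot-bracket export** uses membership `>= 0.5`: the
  fuzzy rules are neutral at exactly `p = 0.5`, and the export should
  show precisely the pairs whose inclusion the scoring rewards.
* **Leontis-Westhof codes**: all 18 orientation-edge-edge strings are
  accepted on input and normalized to the 12 geometric families by
  sorting the edge letters (W before H before S), since interactions are
  stored with residues in canonical order and a family, not an
  edge-per-residue assignment, is what identity needs.
* **CSV output** is fixed at six decimals, making repeated runs
  byte-identical.

## Problem sizes

The test suite and the acceptance script are sized for a laptop: the
full null model runs 10,000 batches of 100 ranking pairs (one million
permutation pairs, a few seconds vectorized), property suites use
ensembles of up to 6 models and about 30 interactions with hundreds of
randomized trials, and the robustness checks use 25 runs of 12
iterations on 5-model ensembles. These sizes give Monte-Carlo error well
inside the tolerances the tests assert while keeping the whole suite
under a minute.

## Known limitations

* The consensus is only as good as the ensemble; a homogeneous set of
  wrong models yields a confident wrong consensus (garbage in, consensus
  garbage out).
* The geometric detector is a pragmatic screen, not a replacement for
  dedicated annotation tools; for publication-grade annotation, import
  an external tool's output through the interaction table.
* Constraints address base pairing only; there is no way to require or
  forbid a stacking.
* PDB-format capacity limits (99,999 atoms; 9,999 residues; 62 chains)
  are checked and reported because the legacy format cannot express
  larger models, even though the internal pipeline is format-agnostic.
* The enrichment-score and RBO null distributions depend on their `f`
  and `p` conventions; comparisons across tools must hold these fixed.
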