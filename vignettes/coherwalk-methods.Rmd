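---
title: "Classifying tacit coordination from EEG coherence graphs with anonymous walk embeddings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying tacit coordination from EEG coherence graphs with anonymous walk embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coherwalk)
```

## The problem

In a tacit coordination game two players earn a reward only if they
independently pick the same option — say the same word out of four —
without communicating. Some option pairs "click": a salient focal point
draws both players to the same choice. The scientific question this
package operationalizes is whether successful coordination leaves a
measurable trace in the players' brain activity even when the players
were recorded *separately*: an offline form of hyper-scanning in which
each participant's EEG is recorded alone and pairs are compared after
the fact.

The working hypothesis is spatial: when two players converge on the same
answer, the spatial organization of their scalp synchronization networks
is more similar than when they diverge. The pipeline therefore turns
each player's 1-second task epoch into a graph of synchronized electrode
pairs, summarizes each graph by a label-free spatial fingerprint, and
classifies player pairs from the distance between their fingerprints.

## From raw epochs to synchronization graphs

Conditioning follows standard EEG practice: a zero-phase Butterworth
band-pass (default 1–32 Hz, order 4 applied forward and backward),
re-referencing to the common average, integer decimation from 512 Hz to
64 Hz, and per-channel epoch-mean baseline correction. One second from
task onset is kept, so a conditioned epoch is a 16 × 64 matrix. The
band-pass upper edge must not exceed half the target rate; the default
1–32 Hz fills the band representable at 64 Hz. We apply the baseline
after decimation so that both stated invariants — zero per-sample channel
mean and zero per-channel temporal mean — hold exactly on the output.
Artifact rejection by independent component analysis is deliberately out
of scope: selecting artifact components is a manual judgment, and the
synthetic data below is artifact-free. Users of real recordings should
clean epochs before `preprocess_epoch()`.

Synchronization between two electrodes is quantified by coherence, the
frequency-domain analogue of correlation, which is 1 for a signal paired
with itself. We estimate it with a Welch cross-spectral estimator (Hann
window, 32-sample segments, 16-sample overlap) and average the magnitude
of the complex coherency over the analysis band, giving one scalar in
[0, 1] per electrode pair. Two caveats are worth stating plainly:

* With 64-sample epochs the estimate averages only three segments, which
  biases coherence upward (independent noise averages about 0.5–0.6
  rather than near 0). This is intrinsic to 1-second epochs, affects all
  pairs roughly equally, and is why `segment_length`, `segment_overlap`
  and the epoch length are exposed; validation tests that need unbiased
  estimates use 10-second epochs.
* "Magnitude of complex coherency" and "magnitude-squared coherence" are
  both in common use; the magnitude is the default and the square is a
  configuration switch.

Thresholding at 0.5 (inclusive) yields an undirected simple graph on the
16 electrodes: at most 120 edges, degree at most 15. The threshold, the
estimator and the band are configurable because none of them is forced
by theory; raising the threshold can only remove edges.

## Anonymous walk embeddings

A random walk on the graph, recorded only by the order of first
appearances — (Fp1, F3, Fp1, C3) becomes (1, 2, 1, 3) — is an *anonymous
walk*. The distribution over all anonymous patterns of a fixed length l
is a graph fingerprint that is invariant under node relabeling and
captures spatial structure (branching, returns, hubs) without naming
electrodes. Throughout the package, walk *length counts edges*: a
length-l walk visits l + 1 node slots. With that convention the
vocabulary sizes are 1, 2, 5, 15, 52, 203, 877 for l = 1…7, so the
default l = 5 gives a 52-dimensional embedding.

Two estimators are provided:

* `exact_embedding()` accumulates the probability of every node walk
  (start uniform over nodes of degree ≥ 1, steps uniform over neighbors,
  immediate backtracking allowed) onto its pattern — the exact law, used
  as ground truth and for isomorphism-invariance checks. Cost grows as
  |V| · max-degree^l, comfortable for 16 electrodes up to l ≈ 6.
* `sample_embedding()` performs m independent seeded walks and returns
  empirical frequencies. The number of walks needed for the empirical
  law to stay within ε of the exact one (in L1) except with probability
  δ is m = ⌈(2/ε²)(ln(2^N − 2) − ln δ)⌉, where N is the vocabulary
  size; natural logarithms, rounded up because the bound is a minimum,
  and the first logarithm is evaluated as N ln 2 + log1p(−2^(1−N)) since
  2^N overflows long before N = 877. At ε = 0.1, δ = 0.01 and l = 5 this
  gives m = 8130.

Choices the underlying theory leaves open, fixed here and recorded so
that results are reproducible: walks restart independently (not one long
trajectory); the start distribution excludes isolated nodes; patterns
are indexed in lexicographic order so embedding coordinates mean the
same thing for every graph; an edgeless graph is a hard error rather
than a zero vector, because a zero vector would silently violate
normalization.

## Pair features and classification

For players a and b in one game, the feature vector is z = |e_a − e_b|,
the element-wise absolute difference of their embeddings; the label is 1
if they chose the same option. Ten players and twelve games give
choose(10, 2) × 12 = 540 labeled observations. Classification uses
gradient-boosted trees with a grid search over number of estimators
{50, 100, 200}, maximal depth {3, 5, 7} and learning rate {0.01, 0.1,
0.3}, evaluated by stratified 3-fold cross-validation (a 153/387 class
split stratifies to exactly 51 positives and 129 negatives per fold).
The trees use the exact greedy split finder: on datasets this small it
is fast, deterministic, and places split thresholds at midpoints between
training values rather than at histogram bin edges.

Grid selection on the same three folds that produce the reported
accuracy mildly flatters the estimate; this pooled protocol is the
default because it matches common practice for this design, and a
nested mode (`grid_search_cv(..., mode = "nested")`) re-runs the search
inside each training split for a methodologically cleaner number. Folds
stratify by class only; a given player contributes observations to
several folds, which can leak player identity. Both caveats apply
equally to the walk-length sweep.

`walk_length_sweep()` repeats the whole procedure across walk lengths
and selects the smallest l whose successor improves mean accuracy by
less than one percentage point (configurable): longer walks inflate the
vocabulary steeply, so marginal gains do not justify them. A flat curve
selects the smallest length in the range; a curve that keeps improving
selects the largest.

The comparison baseline, `bag_of_node_degree()`, is the normalized
degree histogram — entry d is the fraction of nodes with degree d. It is
the natural "how connected" summary that ignores *where* the
connectivity sits, which is exactly what the walk embedding adds.

## What the synthetic scenario emulates

No recordings ship with the package, so `scenario_config()` defines a
generative stand-in for the behavioral and neural design: 10 players, 12
games, 4 options per game.

* **Choices.** Each player draws independently from a per-game salience
  distribution. The default (0.40, 0.25, 0.20, 0.15) encodes a strong
  focal point; its implied coordination rate Σpᵢ² ≈ 28.5% matches the
  roughly 28% positive fraction (153 of 540) such tasks produce.
* **Graphs.** Each (game, option) has a fixed template graph; a player's
  graph is their chosen option's template with every edge indicator
  independently flipped with probability `flip_prob_same` (default
  0.05 — symmetric flips keep expected density stable). Players sharing
  an option thus differ by noise only; by default templates for
  different options are drawn independently (`flip_prob_diff = 0.5`),
  while smaller values couple a game's options to a common base graph.
  Templates are *not* homogeneous random graphs: each draws its overall
  density uniformly from `template_density ± density_spread` (default
  0.35 ± 0.15) and weights edge probabilities by random per-node hub
  strengths. Both features are deliberate: real coherence graphs vary
  widely in overall synchronization between brain states and have
  hub-dominated degree structure, and without them same-density
  homogeneous templates are nearly indistinguishable in walk space, so
  no classifier could separate the classes the generator is supposed to
  make separable.
* **Signals.** For full-pipeline exercises, each edge of a target graph
  is assigned an independent broadband source inside 1–31 Hz shared by
  the two channels it joins, scaled so shared-source power is `snr`
  (default 9) times the channel noise. Because a channel's power is
  split across incident edges, pairwise coherence falls with node
  degree: recovery by thresholding is faithful for sparse graphs and
  degrades for dense ones. Volume conduction, 1/f background spectra,
  and artifacts are not modeled.

Consequently, a passing synthetic run demonstrates that the pipeline
recovers controllable graph similarity end to end — it does not certify
performance on real EEG, where the similarity structure, its noise, and
confounds (shared reference, volume conduction, player identity) are all
richer.

## Numerical and protocol choices

* All randomness flows through explicit integer seeds; synthetic objects
  are deterministic functions of (scenario seed, indices), so any graph
  can be regenerated in isolation and reruns are byte-identical.
* Sampled embeddings store counts/m, so they sum to 1 exactly; the exact
  law sums to 1 within 1e−9 and permutation invariance holds to float
  summation order (~1e−13 relative).
* Thresholds are inclusive (≥); ties at exactly 0.5 produce edges.
* Degenerate inputs fail loudly with classed conditions: non-integer
  decimation factors, epochs shorter than the window, zero-variance
  channels inside the coherence estimator, edgeless graphs at embedding
  time, single-class datasets at training time.
* Default problem sizes (one 1-s epoch per player-game, l = 5,
  m = 8130, 27-point grid, 3 folds) run in well under a minute for the
  graph-level scenario on a single core; the signal-level path adds
  filtering and spectral estimation per epoch and is used at miniature
  scale in examples and tests.

## Known limitations

ICA artifact handling is a documented hook, not an implementation. The
Welch estimator's few-segment bias at 1-second epochs is reported, not
corrected; band-limited alternatives (multitaper) are out of scope. The
degree-split signal model cannot realize dense graphs at high coherence.
Fold stratification ignores player identity. And the synthetic
templates, however structured, remain far simpler than cortical
connectivity — conclusions about real inter-brain similarity require
real recordings.
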