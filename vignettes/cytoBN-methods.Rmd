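---
title: "Bayesian network analysis of flow cytometry data with cytoBN"
author: "cytoBN authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian network analysis of flow cytometry data with cytoBN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytoBN)
```

## The problem

Conventional flow cytometry analysis reduces cell-level fluorescence data
to manually gated population percentages and univariate comparisons. That
workflow discards most of the joint distributional information in a
multi-marker panel: higher-order marker interactions, full-distribution
location and shape differences, and marker combinations that jointly
predict a clinical phenotype. cytoBN implements a secondary-analysis
pipeline that works directly on the compensated intensity matrix (cells
x markers) exported from the acquisition software, with a clinical
response label attached per patient, and uses discrete Bayesian networks
(BNs) as the central modeling device.

The pipeline: (1) discretize each marker into equal-frequency bins;
(2) learn a BN over markers plus the response variable; (3) extract the
Markov neighborhood (MN) of the response node — the markers directly
linked to it; (4) tabulate the joint configurations of the MN markers
with their frequencies and conditional response probabilities; (5) sort
and truncate that table into a compact, human-readable rule set.
Separately, networks learned under different regimes (responders vs
nonresponders, before vs after treatment) are compared by pooling the
data and adding an indicator ("contrast") variable, and per-marker
distributional differences are quantified with the Earth Mover's
Distance (EMD) and the energy distance.

## Discretization

Markers are discretized marker-by-marker into *k* equal-frequency bins
(`discretizeCells()`, *k* in 2..8), with cut points computed on the full
pooled sample — all patients, all cells in scope — never per patient.
Bin *i* ends at the empirical type-1 (inverse-ECDF) quantile at *i/k*,
so each interior edge is the smallest data value strictly above that
quantile and the mapping rule `v >= edge` is tie-safe: identical raw
values can never straddle a bin boundary, which keeps configuration
tables interpretable. Duplicate edges produced by heavy ties are
collapsed, reducing the effective bin count. Labels run from 0 ("low")
to *k − 1* ("high").

The bin count is the main sensitivity/specificity dial: few bins (2–3)
give denser networks (higher sensitivity), many bins (4–8) give sparser
ones (higher specificity). The package defaults to *k* = 3 for
full-panel analyses and *k* = 8 for the stratified and contrast
analyses, both configurable.

## Scoring and structure search

Networks are scored with the BDeu marginal likelihood (equivalent
sample size `ess`, default 1.0): for each family, with $r$ child
states, $q$ parent configurations, counts $N_{jk}$ and hyperparameters
$\alpha_j = \mathrm{ess}/q$, $\alpha_{jk} = \mathrm{ess}/(qr)$,

$$\mathrm{score} = \sum_j\left[\ln\Gamma(\alpha_j) -
  \ln\Gamma(\alpha_j + N_j)\right] +
  \sum_{j,k}\left[\ln\Gamma(\alpha_{jk} + N_{jk}) -
  \ln\Gamma(\alpha_{jk})\right].$$

BDeu was chosen because it is the canonical marginal-likelihood score
with score equivalence: Markov-equivalent DAGs receive identical
totals, so the search cannot manufacture spurious orientation
preferences. The total score decomposes over families, which makes
single-edge move deltas local and cheap.

Search is hybrid: a sparse-candidates stage limits each node's
potential parents to the `kCandidates` (default 8) highest pairwise
mutual-information partners, then random-restart hill climbing
(default 20 restarts) explores add/delete/reverse moves inside those
pools. Reverse moves are included to escape equivalence-class plateaus.
A restart terminates when no move improves the score by more than
1e-9; the best local optimum across restarts is returned. The first
restart always starts from the empty graph; later restarts start from
random sparse DAGs. Determinism: all restart randomness derives from
`SearchConfig@seed`, move scanning follows lexicographic node order,
and only strictly better moves are accepted, so ties resolve to the
first candidate — the same data and seed always give the same network.
`maxParents` (default 4) bounds family sizes; at 8 bins a family with
4 parents already has 4096 parent configurations, which is the
practical ceiling for the cell counts involved.

CPTs are posterior means under the same BDeu prior (no zero rows), so
forward sampling from a learned network is always well-defined.

**Edge strengths.** The strength of an edge is the log
marginal-likelihood ratio between the network with and without it —
`familyScore(child, parents) − familyScore(child, parents \ parent)`.
Strengths are directly comparable within one network; the package
deliberately provides no cross-network strength comparison (they scale
with dataset size), steering users to the contrast-variable machinery
instead.

## Markov neighborhoods and configuration tables

The MN of the response node (parents and children) is the candidate
predictor set; the Markov blanket (plus children's other parents) is
also available for the cases where one extra degree of separation is
needed for conditional-independence reasoning. Members are partitioned
into strong and weak by a relative rule — strong iff strength ≥ 0.3 x
the MN maximum. The cut had to be relative: raw strengths scale with n,
and the figures the analysis emulates distinguish strong/weak visually.
The 0.3 default reproduces the "clearly weaker on average" reading; it
is exposed as a parameter. A weak member whose endpoint shares a much
stronger edge (3x by default) with a strong member is flagged
"possible artifact" in the MN report — advisory only, never removed,
mirroring the informal reasoning used to discount indirect edges.

Configuration tables enumerate observed joint label tuples of the MN
markers. `p_response` is the raw cell-level responder fraction given
the configuration: cells inherit their patient's label and patients are
pooled unweighted (patients contribute proportionally to their cell
counts). Raw counts were chosen over BN inference or smoothing because
they make the conservation identity exact — frequencies sum to 1 and
the frequency-weighted response probabilities equal the overall
responder-cell fraction — which the tests assert. Two sort modes:
`frequency_then_probability` (keep the top-n most frequent, re-sort by
response probability; robust, compact rules) and `probability_only`
(surfaces rare, extreme-probability configurations, akin to rare-cell
discovery). The table length is chosen by the first noticeable relative
frequency dropoff (default 15% within the first 40 rows); a ~0.020 to
~0.017 step qualifies at that default.

## Contrast variables

To compare networks across regimes, the package never compares raw
edge strengths across separately learned networks. Instead the regime
datasets are pooled and an indicator variable (the "contrast") with one
state per regime is added as an ordinary categorical node. If the joint
distribution of any variable pair differs between regimes — an edge
present in one regime only, or a pure location shift in one marker —
the contrast node cannot be independent of those variables, so the
search pulls it into their Markov blanket. Conditioning the pooled data
on one contrast state and relearning recovers the stratified network;
relearning (rather than CPT slicing) was chosen because it matches the
distribution-level argument and what a practitioner actually does.

One deliberate deviation from plain search: contrast nodes are forced
into every node's candidate pool. The marginal MI between a contrast
and a marker can be near zero even when a real conditional dependence
exists (e.g. an edge flip that leaves marginals unchanged), and the
entire purpose of the supergraph is contrast linkage — MI pruning must
not be allowed to mask it.

Cell-subset stratification for these analyses uses threshold gating on
CD4/CD8/CCR7/CD45RA with per-panel cutoffs and the standard 4-bit
membership patterns for naive/non-naive CD4/CD8 T cells. The boundary
convention is `>=` (a value at the cutoff is "high"); cells matching no
subset pattern (e.g. 1111, 0000) are excluded from stratified analyses.

## Distributional distances

`emd1d()` computes the 1-D first Wasserstein distance exactly as the
area between the two ECDFs over merged breakpoints (equal to the mean
absolute difference of order statistics at equal n). `energyDistance()`
computes $2E|X-Y| - E|X-X'| - E|Y-Y'|$ as V-statistics in
O(n log n); the rooted form is the default, the squared form (twice
the Cramér distance in 1-D) is a flag away. EMD is computed on raw
compensated intensities without normalization, so its units are
fluorescence units and magnitudes are comparable to published
per-marker tables. `pointBiserial()` (identical to Pearson correlation
with a 0/1 label) is included as the conventional univariate
association measure for comparison.

## The synthetic cohort generator

`simulateCohort()` emulates the study design the pipeline targets:
13 patients (4 responders, 9 nonresponders), a 14-marker panel,
1000 cells per patient at each of days 1 and 21. Latent per-cell marker
states follow a fixed random ground-truth network (3 levels,
concentrated monotone CPTs: each parent configuration puts 0.8 mass on
a dominant state that increases with the mean parent level — this keeps
every edge marginally detectable and the structure identifiable).
Continuous intensities are log-normal around state-dependent log-means
(location log 300, log-scale 0.6, one log-sd per latent level):
strictly positive with heavy right tails, the shape of compensated
cytometry intensities. Regime effects are the two kinds of differences
the contrast machinery is meant to detect: responders carry a +2 sd
location shift of one marker, and the responders' day-21 regime loses
one ground-truth edge (the child's CPT re-derived by exact
marginalization where the state space permits, otherwise from a large
fixed-seed forward sample).

What the generator does **not** emulate: spillover/compensation
artifacts, autofluorescence, batch effects, doublets or debris. Passing
tests therefore demonstrate correctness of the statistical machinery
under a faithful generative model, not robustness to instrument
artifacts — real data should still be inspected with the usual QC
upstream.

Validation problem sizes were chosen to make the checks decisive yet
desk-scale: structure recovery uses 8-node networks at n = 10,000 over
10 seeds (skeleton SHD ≤ 2 expected in ≥ 8); contrast detection uses
6 variables, one changed edge with 0.85-vs-marginal CPT contrast,
4000 cells per regime, 3 bins, 20 seeds for power and 20 for
specificity; the distance oracles use 100 random instances up to
n = 200.

## Numerical choices and edge cases

* Constant markers cannot be discretized and raise an error naming the
  marker; heavy ties collapse bins instead of erroring.
* Unseen parent configurations contribute exactly zero score terms.
* Cycle-creating moves are silently skipped during search, never
  raised.
* Equal-score moves and MI ties resolve by lexicographic variable
  order: determinism over convenience.
* The frequency-dropoff rule allows 1e-9 slack so drops numerically at
  the threshold qualify.
* Empty gating results return an empty object with a warning, not an
  error; an empty MN yields an empty partition.
* Negative post-compensation intensities are accepted and never
  clipped.

## Known limitations

* Edge strengths are not p-values; dependencies of interest should be
  followed up with conventional statistics (the distance functions and
  point-biserial correlation are provided for exactly that).
* The cell-level response probabilities treat cells as exchangeable
  within patients; with very few patients the tables can be dominated
  by individual patients. The study design this emulates pools all
  patients, and the package follows it; per-patient weighting is
  intentionally not offered.
* Only complete cases are supported; the FCS reader handles list-mode
  float/integer data in single datasets, not analysis segments or
  multi-dataset files.
* Exact edge-removal marginalization is limited to state spaces up to
  ~3x10^5 configurations; larger networks fall back to a fixed-seed
  sampling estimate.
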