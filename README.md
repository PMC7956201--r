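# cytoBN

Comparative Bayesian network analysis of cell-level flow cytometry data.

## What it is for

Flow cytometry (FACS) panels measure a dozen or more markers on
thousands of cells per patient. The conventional analysis — manual
gating and univariate comparisons of population percentages — discards
most of the joint information in that matrix, and can miss strong
predictive signals entirely. cytoBN is a secondary-analysis toolkit for
immunology/immuno-oncology studies that works directly on the
compensated intensity matrix plus per-patient clinical annotations
(response label, tumor-size change), and answers two questions:

1. **Which markers, and which marker combinations, predict the clinical
   response?** A discrete Bayesian network is learned over all markers
   plus the response variable; the Markov neighborhood of the response
   node is the compact predictor set; configuration tables turn it into
   readable rules.
2. **How do the immune networks differ between regimes** (responders vs
   nonresponders, before vs after treatment)? Regimes are pooled with
   an indicator ("contrast") variable; any regime-specific difference in
   a joint distribution pulls the contrast node into the affected
   variables' Markov blanket.

## The model in brief

Markers are discretized into *k* equal-frequency bins (cut points =
type-1 quantiles at *i/k* on the full pooled sample). Network families
are scored with the BDeu log marginal likelihood

score = Σ_j [lnΓ(α_j) − lnΓ(α_j + N_j)] + Σ_{j,k} [lnΓ(α_jk + N_jk) − lnΓ(α_jk)],
α_j = ess/q, α_jk = ess/(q·r),

which is decomposable and score-equivalent across Markov-equivalent
DAGs. Structure search is sparse candidates (top-k pairwise mutual
information) + hill climbing with add/delete/reverse moves and random
restarts; the strength of an edge is the log marginal-likelihood ratio
with vs without it. Per-marker distribution differences between cell
groups are quantified by the exact 1-D Earth Mover's (Wasserstein)
distance — the area between the two ECDFs — and the energy distance
2E|X−Y| − E|X−X′| − E|Y−Y′|.

A synthetic cohort generator (`simulateCohort()`) emulates the target
study design (13 patients, 4 responders, 14-marker panels, two
timepoints, log-normal intensities over a latent ground-truth network)
so every stage is testable without external data.

## Worked example

```r
library(cytoBN)

spec <- defaultCohortSpec()          # 13 patients, 14 markers, 2 days
spec@cellsPerPatient <- 400L
sim   <- simulateCohort(spec, seed = 42)
day1  <- sim$cells[, cellData(sim$cells)$day == 1]
day1
#> FlowCellSet: 14 markers x 5200 cells
#>   patients: 13  days: 1
#>   responder cells: 1600 / 5200

net <- learnNetwork(day1, kBins = 3,
                    config = SearchConfig(kCandidates = 6, restarts = 10,
                                          seed = 1, maxParents = 3),
                    extraVars = "response")
net
#> BayesianNetwork: 15 nodes, 19 edges, score -81073.599
#>   response -> M01  (833)
#>   M09 -> M05  (217)
#>   ...

markovNeighborhood(net, "response")
#> MarkovNeighborhood of response ( 1 members )
#>   M01               832.5  strong

head(markerDistanceTable(day1), 3)
#>   marker        emd    energy n_group1 n_group0
#> 1    M01 1706.42640 32.689605     1600     3600
#> 2    M12   42.54811  1.040650     1600     3600
#> 3    M10   36.89168  1.137805     1600     3600

round(binaryMarkerResponse(day1, "M01"), 4)
#> p_high  p_low
#> 0.5219 0.0935
```

Reading it: the ground truth plants a +2 sd responder shift on marker
M01, and the pipeline recovers exactly that — M01 is the single strong
member of the response node's Markov neighborhood, it dominates the
EMD ranking by a factor of ~40, and its two-bin split separates a 52%
from a 9% responder-cell fraction.

The same functions drive the regime comparison
(`poolWithContrast()` → `buildSupergraph()` → `contrastReport()` →
`conditionOnContrast()` → `diffNetworks()`) and the end-to-end modes of
`runPipeline()` (`panel_day1`, `stratified`, `contrast`, `distances`),
which write DOT/JSON networks, MN reports, configuration tables and a
reproducibility manifest. A thin CLI wrapper lives at
`inst/cli/cytobn.R`.

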