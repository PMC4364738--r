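---
title: "Weighted connectome analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted connectome analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

fcnet implements a complete group analysis of weighted functional brain
networks: individual network construction from regional BOLD time series,
efficiency-based topology with null-model normalization, spectral module
detection, and nonparametric group inference. Because suitable imaging data
cannot ship with a package, a synthetic-cohort generator with a fully known
ground truth stands in for the scanner: every downstream claim the package
makes can be checked against what was planted.

## The network model

Each subject contributes an N-by-N Pearson correlation matrix over N
regional time series. Edges are retained when their correlation is
significant at P < 0.05 Bonferroni-corrected over the N(N-1)/2 unique
pairs, and negative correlations are discarded, yielding a sparse,
positive, weighted graph G with N nodes and K edges. The length of an edge
is the reciprocal of its weight, so strong coupling means short functional
distance.

On G we compute:

* **Global efficiency** — the mean of 1/d_ij over ordered pairs, with
  1/Inf = 0 for disconnected pairs: parallel information transfer over the
  whole network.
* **Local efficiency** — the mean over nodes of the global efficiency of
  each node's neighbor-induced subgraph (original weights retained):
  fault tolerance of the node's neighborhood.
* **Nodal efficiency** — per node, the mean of 1/d_ij to all other nodes;
  its node-average equals global efficiency exactly, which the pipeline
  uses as an internal consistency check. High-efficiency nodes are hubs.
* **Modularity** — Q = sum_s [ w_s/W − (W_s/(2W))^2 ] with W the total
  weight (each edge once), w_s the intra-module weight and W_s the summed
  nodal strength of module s. This printed normalization is internally
  consistent exactly when W counts each edge once while strengths
  double-count; that reading reproduces the canonical value Q = 0.5 for
  two disconnected equal cliques, which is frozen in the tests.

Normalized efficiencies divide the real network's values by the mean over
100 degree-preserving random networks (Maslov–Sneppen double-edge swaps,
roughly 10K attempts, with the weight multiset randomly reassigned to the
rewired topology). A network is called small-world when normalized local
efficiency exceeds 1 while normalized global efficiency is near 1
(tolerance 0.25 by default).

How weights should travel under rewiring is genuinely underdetermined —
preserving per-edge weights, per-node strength, or only the multiset are
all defensible. We preserve the multiset, which keeps the weight
distribution exact while fully randomizing its placement; a
strength-preserving variant would be a straightforward extension.

## Spectral module detection

`spectral_partition()` maximizes Q by recursive leading-eigenvector
bisection of the weighted modularity matrix. After each candidate split a
greedy Kernighan–Lin-style refinement moves single nodes while any move
increases Q; recursion stops when no split yields a positive gain.
Determinism matters for a reference partition, so the eigenvector sign is
fixed by making its first nonzero component positive, and connected
components are handled independently. On planted four-block graphs the
procedure recovers the blocks exactly (adjusted Rand index 1), and its Q
never falls below random relabelings of its own solution.

The group backbone feeding the partition is extracted from the Fisher-z
average of the control group's matrices by a locally adaptive
sparsification: each node ranks its incident positive weights, and an edge
survives when it is an endpoint's strongest connection or ranks within the
top `local_alpha` fraction at either endpoint (an exchangeable-rank null:
the chance an edge ranks in the top t of k by luck is t/k). The OR rule
preserves structure at every weight scale — a weak bridge that is some
node's best edge survives next to strong cliques. The upstream method this
reconstructs is cited only by name in the source literature, so the filter
is documented here as a reconstruction with exactly this contract. If the
kept graph is connected on fewer than 95% of active nodes, `local_alpha`
doubles with a logged warning (up to 0.5); with the nearly disconnected
synthetic modules this relaxation is expected and visible in stage-3 logs.

## Statistics

Group differences use label-permutation tests: the observed difference of
group means is compared against 10,000 random reallocations preserving
group sizes, with the 95th percentile of the null as the one-tailed
critical value and the add-one p-value convention (p is never exactly 0).
Tail directions are declared per metric up front: raw efficiencies are
tested for decreases in patients, normalized local efficiency for an
increase. Head-motion summaries (mean, RMS and maximum frame-wise
displacement, Power-style with a 50 mm rotation radius) enter as
covariates by residualizing the metric before permuting.

Multiplicity is handled by Benjamini–Hochberg within three declared
families: all nodes (node-wise comparison), all 10 intra- plus
inter-module connectivity contrasts, and the metric-by-covariate partial
correlations. Flagged-node concentration in a module is assessed by
resampling: draw |flagged| nodes uniformly without replacement 10,000
times; the empirical tail agrees with the exact hypergeometric tail within
Monte-Carlo error, which the tests assert on fuzzed configurations.

Partial correlations are Pearson correlations of OLS residuals on the
covariates over complete cases, with df = n − n_cov − 2. The hub analysis
bins each subject's nodal efficiencies into 8 equal-width bins between
that subject's minimum and maximum (top bin right-closed; a constant
vector degenerates to bin 1 with a warning) and compares the percentage
per bin across groups. The binning statistic is nodal efficiency by
default with a strength option, since the two appear interchangeably in
descriptions of this analysis.

## The synthetic cohort

Each ROI signal is `intra * f_module + inter * g_global + noise`, where
the module factors and the global factor are independent unit-variance
series band-limited to 0.01–0.1 Hz by frequency-domain masking (exact band
control, no filter transients), and the noise is white. A factor model
guarantees a positive-definite covariance at any dimension and closed-form
correlations: within-module r = (a² + b²)/(a² + b² + σ²), between-module
r = b²/(a² + b² + σ²). Patients have the intra-module loading of one
designated module (the largest) multiplied by `patient_effect`; each
subject's hemoglobin value scales that subject's intra loadings through
`covariate_coupling`, standardized within group so the two groups differ
only through the planted effect.

Defaults mirror the emulated study design: 22 patients vs 29 controls,
160 volumes at TR = 3 s (5 discarded), 128 ROIs in modules of 40/31/36/21
(proportional to a published 317/250/289/168 four-module decomposition at
1,024 parcels — the full scale remains available by passing the original
sizes). Patient hemoglobin is drawn around 95.4 g/L (SD 22.6), the anemic
range typical of dialysis cohorts; controls around 131.6 g/L (SD 12).
Motion is a small-amplitude random walk (0.02 units per volume per
parameter), a free parameter the emulated study does not constrain.

The loadings were fixed once from the edge-detection arithmetic rather
than by trial: at 155 retained volumes the Bonferroni edge threshold is
r ≈ 0.48 (with the corrected df below) while band-limited sample
correlations fluctuate with SD ≈ 0.11. The defaults (intra 0.65, inter
0.07, noise SD 0.7) put controls' within-module correlation near 0.62 —
above threshold across the whole hemoglobin range — the patients' affected
module near 0.37, where most of its edges fall below detection (the
planted analogue of within-network decoupling), and between-module
correlations near 0.01, far below detection. With `covariate_coupling`
0.1, high-hemoglobin patients climb back over the threshold, making the
efficiency–hemoglobin association strong and recoverable at n = 22.

### Degrees of freedom for edge significance

`threshold_to_weighted_network()` defaults to df = timepoints − 2, the
textbook r-to-t test. After band-pass filtering to 0.01–0.1 Hz at TR 3 s,
however, only about 54% of Fourier components remain, so the effective
sample is ≈ 84, not 155, and the nominal test is anticonservative by
roughly one sd at the Bonferroni threshold. On the synthetic design that
inflation seeds every subject with a handful of spurious bridges between
otherwise disconnected modules, and because a single bridge reconnects
thousands of node pairs, whole-network global efficiency becomes dominated
by this lottery. `run_group_pipeline()` therefore defaults to the
band-corrected effective df (`effective_df()`, via the `df_override`
hook); `edge_df = "nominal"` restores the textbook behavior.

## What the synthetic data does and does not show

The generator reproduces the statistical skeleton of a resting-state
cohort — band-limited signals, modular correlation structure, motion
nuisance, a group effect and a covariate gradient — but not the physiology
around it: no hemodynamic response, no spatially structured artifacts, no
inter-module coupling beyond one global factor. Consequences worth
knowing:

* The planted modules are nearly disconnected, so normalized global
  efficiency sits around 0.4 rather than near 1, and the small-world
  check fails on its global arm by construction. Real connectomes have
  dense inter-module connectivity; passing the pipeline's recovery tests
  says nothing about small-worldness of real data.
* The planted effect removes coherence from one module wholesale, so the
  hub-bin analysis redistributes mass differently than a disease that
  preferentially targets high-degree nodes.
* Edge counts differ between groups here (the affected module loses most
  edges in patients), whereas matched edge counts are reported in real
  cohorts with distributed, subtler effects.

## Numerical choices

Zero-phase band-pass by DFT masking with a 2-bin raised-cosine roll-off
(no filter-order parameter); DC always removed. Detrending is exact OLS on
an intercept plus linear term. Collinear nuisance columns are dropped by
pivoted-QR rank with a warning. Fisher averaging clips off-diagonal
|r| ≥ 1 to 0.999999 with a warning. Disconnected pairs contribute 0 to
efficiencies (1/Inf = 0), keeping all metrics finite; isolated nodes count
in N. Ties in shortest paths cannot affect any reported quantity because
only path lengths, never paths, enter the metrics. All randomness flows
through explicit seeds; two runs at the same seed are numerically
identical, which the tests assert.

Problem sizes used by the shipped analyses: the 128-ROI cohort throughout;
50-network null ensembles per subject in the stage-4 driver and the
acceptance script with 10,000 permutations and draws (100-network
ensembles are exercised in the null-model validation tests); the
type-I-error study uses 1,000 replicates of 1,000 permutations.

## Known limitations

The backbone filter is a reconstruction, not the literature method it
stands in for; module-level normalized metrics inherit the null-model
ambiguity above; the permutation machinery residualizes covariates rather
than permuting within strata; and the effective-df correction is a
bandwidth argument, not an estimate from the data's empirical
autocorrelation.
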