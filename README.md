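# fcnet — weighted functional connectome analysis

fcnet is an R package for graph-based group analysis of resting-state
functional brain networks, aimed at researchers comparing a patient cohort
against matched controls with regional BOLD time series as input. It
covers the full chain: time-series conditioning (volume discard, detrend,
0.01–0.1 Hz band-pass, nuisance regression with the 24-parameter motion
expansion), individual network construction (Pearson correlation,
Bonferroni significance thresholding, positive weights only), efficiency
metrics with degree-preserving null-model normalization, spectral module
detection on a group backbone, and nonparametric inference (permutation
tests, FDR control, module-enrichment resampling, partial correlations
against clinical covariates). A factor-model cohort simulator with known
ground truth makes the whole pipeline testable end to end.

## The model in brief

For a weighted network *G* with *N* nodes, edge lengths are reciprocal
weights and *d*<sub>ij</sub> is the shortest path length. The package
computes

- global efficiency
  *E*<sub>glob</sub> = (1/(N(N−1))) Σ<sub>i≠j</sub> 1/d<sub>ij</sub>,
- local efficiency
  *E*<sub>loc</sub> = (1/N) Σ<sub>i</sub> E<sub>glob</sub>(G<sub>i</sub>)
  over neighbor-induced subgraphs G<sub>i</sub>,
- nodal efficiency
  *E*<sub>nodal</sub>(i) = (1/(N−1)) Σ<sub>j≠i</sub> 1/d<sub>ij</sub>,
- modularity
  *Q* = Σ<sub>s</sub> [ w<sub>s</sub>/W − (W<sub>s</sub>/2W)² ],
  maximized by recursive leading-eigenvector bisection with
  Kernighan–Lin refinement,

with Ẽ<sub>glob</sub>, Ẽ<sub>loc</sub> normalized against 100 random
networks preserving N, K, the degree sequence and the weight multiset.
Group differences use 10,000-permutation tests (one-tailed, 95th-percentile
critical values, add-one p), Benjamini–Hochberg FDR within declared
families, and uniform-resampling enrichment of flagged nodes over modules.

## Worked example

The `analysis/` directory holds the numbered study drivers. Stage 3 builds
the networks and the reference partition from a simulated 22-patient /
29-control cohort (128 ROIs, four planted modules):

```sh
$ Rscript analysis/03_networks.R
edges per subject: median 1815 (Bonferroni at 6.15e-06, df = 82)
backbone: 1476 edges on 128 nodes
modules: 4, Q = 0.725 (sizes 40/36/31/21)
        planted
detected  1  2  3  4
       1 40  0  0  0
       2  0  0 36  0
       3  0 31  0  0
       4  0  0  0 21
```

Every subject's 8,128 ROI pairs are tested at the Bonferroni-corrected
level 6.15e-06 (band-corrected df = 82); the control-group backbone
decomposes into exactly the four planted modules (the detected/planted
cross-table is a permutation matrix) with modularity Q = 0.725. Stage 5
then runs the inference battery:

```sh
$ Rscript analysis/05_group_stats.R
global permutation tests (one-tailed):
  e_glob       diff = -0.0312  p = 0.0001
  e_loc        diff = -0.0917  p = 0.0001
module-connectivity comparisons rejected (BH): intra_1
flagged ROIs: 40; enrichment p by module: 1e-04 / 1e+00 / 1e+00 / 1e+00
hemoglobin ~ E_glob partial r = 0.937 (p = 0.0000, n = 22)
```

Patients show decreased global and local efficiency; of the ten intra- and
inter-module connectivity contrasts only the affected module's internal
connectivity survives FDR; node-wise comparison flags exactly the 40 ROIs
of that module, whose enrichment p (10,000 draws) is at the resolution
floor; and global efficiency correlates positively with hemoglobin in the
patient group after controlling age, sex and head motion — the planted
disease-and-covariate pattern, recovered from raw simulated time series.

Stages 1, 2 and 4 write the cohort TSVs, the motion-QC table, and the
per-subject efficiency tables (stage 4 runs 50-network null ensembles per
subject and takes a few minutes).

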