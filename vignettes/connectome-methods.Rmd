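---
title: "Group analysis of FA-weighted structural connectomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group analysis of FA-weighted structural connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

sivconn implements a complete group-comparison workflow for
fractional-anisotropy (FA) weighted structural brain networks, of the kind
built from deterministic diffusion-tensor tractography over a 90-region
anatomical parcellation (45 regions per hemisphere): network construction,
weighted graph metrics summarised across a sparsity range, covariate-adjusted
permutation inference, the network-based statistic (NBS), brain–behaviour
correlation, and SVM classification under leave-one-out cross-validation
(LOOCV). Because cohorts of this kind are rarely shareable, the package
ships a seeded synthetic cohort generator that plants the group effects the
analysis is designed to detect; every stage is validated against that
planted truth.

## Network construction

Each subject contributes two symmetric 90×90 matrices: streamline counts and
mean FA along the connecting bundles. An edge exists when at least
`min_streamlines = 3` streamlines connect two regions; its weight is the
mean FA, so `w_ij ∈ (0, 1]` where connected and 0 elsewhere
(`build_connectome()`). Raw networks built this way have sparsity (fraction
of the $N(N-1)/2$ node pairs connected) in the 20–28% range.

Age, sex and education are then removed from every edge by ordinary least
squares across subjects (`deconfound_edges()`). We keep *residual + grand
mean* rather than the bare residual so weights stay on the FA scale; the
handful of adjusted weights that fall below zero are floored at zero and
counted (weighted metrics require nonnegative weights). Edges absent in a
subject remain absent: the regression is an adjustment of existing
connections, not an imputation.

To compare networks of equal edge count, each connectome is thresholded to
target sparsities 5%–14% in 1% steps (`threshold_series()`): the top
$k = \mathrm{round}(s \cdot N(N-1)/2)$ edges by weight are retained with
their weights. Ties at the cutoff are broken by lexicographic node order so
runs are bit-reproducible, and edge sets are nested across the grid. The
5–14% window is where networks of this density remain comparable without
becoming disconnected fragments; metrics are summarised over the window so
no single threshold is privileged.

## Weighted graph metrics

All metrics treat edge length as reciprocal weight, $L_{ij} = 1/w_{ij}$,
the standard map for FA-weighted connectomes (stronger tracts are shorter).
With $\hat w = w / \max(w)$ over the network:

- **Clustering coefficient** $C_p$: per node, the Onnela-style normalised
  triangle intensity
  $C_i = \frac{2}{k_i(k_i-1)} \sum_{j<k} (\hat w_{ij}\hat w_{jk}\hat w_{ki})^{1/3}$,
  averaged over nodes; nodes with degree < 2 contribute 0. The overbarred
  weights in the source formulation are read as max-normalised weights, the
  convention of the GRETNA/BCT toolbox tradition.
- **Characteristic path length** $L_p$: mean shortest path length over
  *connected* ordered pairs. Disconnected pairs are excluded (and counted in
  the verbose log) rather than contributing $\infty$; an all-infinite
  network returns $\infty$. The alternative (infinite $L_p$ as soon as one
  pair disconnects) is available by inspecting `shortest_path_lengths()`
  directly.
- **Global efficiency** $E_{glob} = \frac{1}{N(N-1)}\sum_{i \ne j} 1/L_{ij}$,
  with $1/\infty = 0$; robust to disconnection.
- **Nodal global efficiency** $E^i_{nodal} = \frac{1}{N-1}\sum_j 1/L_{ij}$;
  its mean is exactly $E_{glob}$ (asserted in tests).
- **Nodal local efficiency**: the global efficiency of the subgraph induced
  by a node's neighbours (the node itself excluded), with subgraph weights
  taken from the full network.
- **Local efficiency** $E_{loc}$: the summary of the nodal local
  efficiencies. The default `"printed"` mode divides their sum by $N(N-1)$,
  matching the formulation this pipeline reproduces; the fault-tolerance
  convention of the wider literature divides by $N$ (`mode = "mean"`). The
  two differ by the constant $N-1$, so group inference is identical under
  either; the default is flagged here because the printed normalisation is
  unusual.

Each metric is computed at every grid sparsity and summarised by the
trapezoidal area under the curve (`auc_trapz()`); a uniform grid makes the
trapezoid the continuous-limit-consistent choice. Shortest paths are
Dijkstra via igraph on large networks, with a dense Floyd–Warshall fast
path below 49 nodes and closed forms for 2–3-node neighbourhood subgraphs;
all routes are cross-checked against exhaustive path-enumeration oracles in
the test suite (agreement to 1e-9 on graphs up to 8 nodes).

## Group inference

**Permutation tests.** The group statistic is the difference of group
means. Age, sex and education are removed from the per-subject AUCs by the
same residual-plus-grand-mean regression before testing
(`deconfound_scalar()`); both the edge-level and AUC-level adjustments are
independently switchable because the upstream description applies
regression at both stages. Group labels are shuffled preserving group
sizes; the default p-value uses the add-one rule
$p = (1 + \#\{|\mathrm{null}| \ge |\mathrm{obs}|\})/(1 + n_{perm})$, which
is valid (never 0) and matches the permutation-test literature; the plain
proportion is available with `add_one = FALSE`. The four global metrics
form one Benjamini–Hochberg FDR family; each nodal metric forms a 90-region
family — mirroring how such results are reported (a figure for the global
metrics, a region table per nodal metric). Tests are two-tailed by default
since both decreases (Cp, Eglob) and increases (Lp) are expected.

**NBS.** Edgewise pooled two-sample t-tests (one-tailed, control > patient
by default, since the expected pathology is connection weakening) are
thresholded at uncorrected p < 0.005; connected components of surviving
edges are measured by *edge count* (the NBS extent convention). The null
distribution of the maximal component size is built by reshuffling group
labels — one shuffle per permutation reused across all edges, preserving
the edge dependence structure NBS requires. Corrected p for an observed
component of size $M$ is $(1 + \#\{\mathrm{null max} \ge M\})/(1+n_{perm})$;
the `>=` comparison gives a valid, conservative p (a strict `>` mode
exists). Components at corrected p < 0.01 are significant; hub nodes are
those whose degree on the significant-edge graph exceeds the mean by more
than one sample SD. NBS runs on the covariate-adjusted matrices, consistent
with adjustment happening at network construction time. Edges zero in all
subjects are excluded; zero-variance edges get p = 1.

**Brain–behaviour correlation.** Pearson correlation between each global
AUC and z-scored MMSE/MoCA within the patient group, two-sided p from the
t transform.

**Classification.** An RBF-kernel SVM on the four global AUCs under LOOCV.
Features are standardised *within each training fold* and the fold's
statistics applied to the held-out subject — with 27 subjects, whole-sample
scaling would leak the test subject into training. Hyperparameters are
deliberately fixed (cost 1, gamma = 1/p on standardised features): with
n = 27 an inner tuning loop would mostly fit noise; treating the defaults
as the model keeps the estimate honest. Accuracy, sensitivity (patients
correctly flagged) and specificity (controls correctly flagged) come from
exact count arithmetic, rounded to whole percent only for reporting, and
accuracy is referenced against a label-permutation null.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis
assumes, not diffusion MRI itself. Its defaults are the study conditions:
14 controls vs 13 patients, 90 nodes, every subject's raw sparsity inside
20–28%, and covariate distributions (age, sex, education ranges and
moments) and cognitive score moments matching the reference cohort summary
shipped in `extdata/`.

- **Backbone.** A cohort-level template propensity combines a
  ring-distance decay kernel (spatial smoothness: nearby regions connect
  more) with lognormal noise; each subject draws a target sparsity
  uniformly inside the interior of the density band and keeps the top-k
  pairs by propensity with subject-level lognormal perturbation. Direct
  top-k selection is what *guarantees* the hard density band; a marginal
  count model cannot. Selected pairs receive 3 + negative-binomial
  streamline counts; unselected pairs receive zero-inflated counts in
  {0, 1, 2}, so the 3-streamline rule has real candidates to filter.
- **FA weights.** Edge-level baseline FA is a rescaled Beta centred on
  `fa_mean`, increasing with tract-strength rank so that strong tracts
  carry high FA — this pins the network maximum (the $C_p$ normaliser) and
  keeps edge ranking stable under pathology, both properties of real
  connectomes that the planted effects rely on.
- **Planted pathology.** Each subject has a latent damage level
  $\delta_i = \max(0,\, 0.02 + \mathbb{1}[\mathrm{patient}]\cdot\texttt{global\_fa\_shift} + \mathcal{N}(0, \texttt{subject\_shift\_sd}))$;
  each edge's FA is multiplied by $1 - \delta_i \min(\mathrm{Exp}(1), 3)$.
  The *heterogeneity* is essential: some tracts are hit hard and some
  spared, so normalised weights (hence $C_p$) fall along with $E_{glob}$
  while $L_p$ rises — a uniform FA scaling would leave $C_p$ untouched.
  The default damage contrast (0.14) and spread (0.05) were chosen so the
  default cohort reproduces group differences of the strength implied by
  the reproduced study's permutation p-values (~0.001–0.003 at n = 27),
  i.e. standardised effects near 2. On top of this, patient FA on the
  `planted_edges` (a connected 6-edge fronto-subcortical/parieto-occipital
  set by default, forced into every subject's backbone) is multiplied by
  `1 - planted_attenuation`, giving NBS a ground-truth component.
- **Covariates and scores.** Age/sex/education act as small additive
  edge-weight slopes (FA declines ~0.002 per year of age), giving the
  deconfounding stages something real to remove. MMSE and MoCA are linear
  in the latent damage level plus the planted component's share of
  network-mean FA, with slopes fixed by the reference score gaps
  (35 = 4.9/0.14 points of MMSE per unit damage; 89 for MoCA) plus
  N(0, 1) noise, then rounded and clamped to 0–30.

**What passing tests do and do not show.** The generator plants group
effects, confounds and couplings with known truth, so the suite can verify
calibration (type-I error of the permutation and NBS machinery at nominal
rate under the null generator) and recovery (planted components found,
planted directions flagged, above-chance classification). It does not
emulate tractography failure modes, distance-dependent FA biases,
site/scanner effects, or anatomically faithful geometry — so passing these
tests says the *statistics* behave as designed, not that the pipeline is
robust to every artefact of real diffusion data. One honest limitation
surfaced by the planted-truth design: with 13 patients and realistic
between-subject topology variability (driven largely by the mandated
20–28% raw density band), the per-cohort power of the patient-group
metric–score correlation is modest — the planted positive Cp–MMSE and
Eglob–MMSE couplings show up as positive correlations in most cohorts but
reach p < 0.05 in only a minority, much as the reproduced study found only
one of eight metric–score pairs significant. The tests therefore assert
the direction consistently and significance in aggregate, not per cohort.

## Numerical and design choices

- Sparsity denominator is $N(N-1)/2$ (undirected pairs) everywhere.
- Thresholding tie-break: lexicographic (i, j); determinism over elegance.
- Degenerate curves (single grid point) get AUC 0 with a warning.
- All-zero networks: $C_p = 0$ with a warning, $E_{glob} = 0$, $L_p = \infty$.
- Every stochastic routine takes an explicit seed and restores the caller's
  RNG state; identical configurations give byte-identical pipeline output
  directories (asserted in tests).
- The pipeline configuration is a YAML-compatible nested list; constants
  (3-streamline rule, 5–14% grid, 0.005 primary alpha, 10,000 permutations,
  0.01 NBS report level, 0.05 FDR) live in `default_config()`, never
  hard-coded in stage code. Validation is a plain R checking function that
  names the offending field.
- Simulation problem sizes in the test suite are scaled deliberately:
  statistical calibration suites run the full replicate counts (1000 for
  metric test size, 500 for NBS familywise error) on 24-node cohorts —
  test validity is size-free — while planted-effect recovery runs at the
  full 90-node study scale over 100 seeds; the brute-force oracle suite
  uses 200 random graphs of up to 8 nodes, where exhaustive path
  enumeration is tractable.

## Known limitations

Deterministic-tractography inputs are taken as given; the upstream
provenance (FA < 0.2 and 45° curvature stopping rules, AAL warping) is a
documented constant of the data, not computation. The printed $E_{loc}$
normalisation is reproduced verbatim despite conflicting with the cited
fault-tolerance definition; both modes are exposed. Whether covariate
regression should apply at the edge level, the AUC level, or both is left
switchable because the source description applies it at both. Exact
reproduction of the original cohort's numbers (78/69/86 classification,
region tables) is out of reach without the unreleased scans; the package
reproduces the *procedure* and validates it on planted truth.
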