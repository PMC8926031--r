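---
title: "Individual metabolic connectomes from FDG-PET: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual metabolic connectomes from FDG-PET: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jsseconn)
```

## The problem

In refractory temporal lobe epilepsy, roughly half of surgical patients
remain seizure-free (Engel class I, here `SZF`); the others relapse
(`SZR`). Presurgical FDG-PET captures regional glucose metabolism, and the
hypothesis behind this package is that the *coupling structure* of
metabolism across brain regions — a subject-level metabolic connectome —
carries predictive signal for that binary outcome that regional averages
miss.

Classical metabolic covariance networks are group-level objects: one
network per cohort, built from across-subject correlations. The method
implemented here instead builds one network **per subject**, which is what
makes individual outcome prediction possible.

## The model

### From voxels to region distributions

Each subject's PET volume is assumed spatially aligned to a 90-region
AAL-style parcellation (45 regions per hemisphere, cerebellum excluded).
Intensities are globally normalized by proportional scaling — every
in-mask voxel is divided by the in-mask grand mean, so the normalized mean
is exactly 1 and raw scanner scaling cancels. The voxel intensities of
region $i$ form a sample whose probability density $\mathbb{P}_i$ is
estimated by Gaussian kernel density estimation with Silverman's
rule-of-thumb bandwidth.

### Jensen-Shannon similarity

For each unordered region pair $(i, j)$ both densities are evaluated on a
common grid and compared with the Jensen-Shannon divergence in log base 2,

$$D_{JS}(\mathbb{P} \| \mathbb{Q}) = \tfrac{1}{2}\!\left[
  D_{KL}(\mathbb{P} \| \bar{Q}) + D_{KL}(\mathbb{Q} \| \bar{Q})\right],
  \qquad \bar{Q} = \tfrac{1}{2}(\mathbb{P} + \mathbb{Q}),$$

where $D_{KL}$ is the Kullback-Leibler divergence. Unlike $D_{KL}$, the JS
divergence is symmetric and, in base 2, bounded in $[0, 1]$ — 0 for
identical distributions, 1 for disjoint supports — so
$w_{ij} = 1 - D_{JS}$ is a bounded similarity. The $90 \times 90$
symmetric matrix of these weights, with zero diagonal, is the subject's
metabolic network. A configuration switch
(`edge_weight = "divergence"`) stores $D_{JS}$ itself instead, since the
field uses both conventions; similarity is the default because
thresholding and hub analysis assume stronger = more connected.

### Graph features over a sparsity sweep

Each network is binarized at sparsity thresholds 0.02–0.50 in steps of
0.01 (49 thresholds), keeping exactly $\lfloor s \cdot 4005 \rfloor$
strongest edges. On each binary graph the package computes 11 global
metrics (clustering coefficient $C_p$, characteristic path length $L_p$,
their null-normalized versions $\gamma$, $\lambda$, small-worldness
$\sigma = \gamma/\lambda$, global and local efficiency, modularity $Q$,
assortativity, hierarchy, synchronization) and 5 nodal metrics per region
(degree, betweenness, nodal efficiency, shortest path length, nodal
clustering). Summing each metric over the 49 thresholds ("area under the
sweep") gives one feature per metric: 11 global features, 450 nodal
features, plus the 4005 raw connection weights.

Hubs are nodes whose degree (or betweenness) exceeds the mean plus one
standard deviation across the 90 nodes (population SD; a switch selects
the sample convention).

### Multi-kernel SVM and nested LOOCV

The three feature blocks $x^1$ (connections), $x^2$ (global), $x^3$
(nodal) enter a linear multi-kernel SVM: a C-SVC on the convex kernel
combination $K = \sum_m \beta_m K_m$ with $\beta_m \ge 0$,
$\sum_m \beta_m = 1$, linear kernels $k_m(x, x') = x^\top x'$. The dual

$$\max_\alpha \sum_i \alpha_i - \tfrac{1}{2} \sum_{i,j}
  \alpha_i \alpha_j y_i y_j \sum_m \beta_m k_m(x_i^m, x_j^m)
  \quad \text{s.t. } \textstyle\sum_i \alpha_i y_i = 0,\;
  0 \le \alpha_i \le C$$

is solved by a compiled maximal-violating-pair SMO with second-order
working-set selection (KKT-gap tolerance $10^{-9}$); at a simplex vertex
the model coincides exactly with a single-kernel SVM, which is a test
invariant.

Validation is nested leave-one-out: the outer loop holds out one subject;
within each outer training set, features are selected by pooled-variance
two-sample t-test ($p < 0.05$; connection and nodal blocks only — the
11-dimensional global block is always kept), z-scored with training
statistics, and an inner LOOCV grid search chooses
$C \in \{2^{-5}, \dots, 2^5\}$ and $\beta$ on a simplex lattice. Every
training-fold computation is a pure function of the training subjects;
this leakage-freedom is asserted by tests that corrupt the held-out
subject and demand bit-identical masks, scalings and grid choices.
*Consensus connections* are those passing the t-test in **every** outer
fold. Performance is summarized as accuracy, sensitivity (positive class
`SZF`), specificity, and the trapezoid AUC of the decision-value ROC;
correlated AUCs are compared with DeLong's test.

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `grid_points` | 256 | evaluation points of the pair-specific KDE grid; the grid spans the union of both samples' ranges padded by 3 bandwidths, guaranteeing shared support for the mixture |
| bandwidth | Silverman | per-region rule-of-thumb; zero-variance samples fall back to $10^{-6}\max(1, |\bar{x}|)$ |
| `edge_weight` | similarity | $1 - D_{JS}$ vs raw divergence |
| sparsity sweep | 0.02–0.50, step 0.01 | 49 thresholds; features are sums over the sweep |
| `n_nulls` | 100 | degree-preserving (Maslov-Sneppen, $10\,|E|$ attempted swaps) rewirings per threshold behind $\gamma, \lambda, \sigma$ |
| `C_grid` | $2^{-5} \dots 2^5$ | 11 powers of two |
| `beta_step` | 0.1 | simplex lattice of kernel weights (66 points; 0.25 gives 15) |
| `alpha` | 0.05 | t-test selection level |
| `positive` | SZF | class treated as positive in sensitivity/ROC |

## Numerical choices and degenerate inputs

- **KL/JS conventions.** Terms with $P(i) = 0$ contribute zero;
  $P(i) > 0, Q(i) = 0$ makes $D_{KL} = +\infty$. No epsilon flooring is
  applied inside JS: the mixture $\bar{Q} \ge P/2$ on $P$'s support keeps
  it finite by construction. Last-bit rounding outside $[0, 1]$ is clamped.
- **Binarization ties** are broken by lexicographic $(i, j)$ order, making
  edge sets reproducible even for degenerate all-equal weights; edge sets
  are nested across thresholds by construction.
- **Disconnected graphs** (routine at sparsity 0.02): $L_p$ and nodal path
  length average over connected pairs only; efficiencies use $1/d$ with 0
  for unreachable pairs; isolated nodes get clustering 0. This keeps every
  feature finite across the sweep.
- **Normalized metrics** $\gamma, \lambda, \sigma$ are `NA` at thresholds
  where the null ensemble is degenerate (e.g. triangle-free nulls give
  $\langle C_p^{null}\rangle = 0$); sweep sums skip undefined thresholds.
- **Modularity** is the value of the deterministic greedy-agglomeration
  partition. **Hierarchy** is the slope $\beta$ of
  $\log C(k) \sim -\beta \log k$ over nodes with $k > 1$, $C > 0$;
  **synchronization** is the Laplacian eigenratio $\lambda_2/\lambda_{max}$.
  No formula for the latter two is universal across toolboxes; the
  conventions above (shared with the GRETNA toolbox) are used throughout.
- **Grid-search ties** resolve to the smaller $C$, then the earlier
  $\beta$ row; `sign(0)` maps to the positive class. Both are documented
  so runs are bit-reproducible.
- **Standardization** uses training means/SDs; zero-variance features
  scale to 0 (they are excluded by the t-test in the selected blocks
  anyway).

## The synthetic cohort generator

No imaging data are distributed with the package, so a seeded generator
emulates the study conditions end to end, in two modes that are proven
equivalent by test: *direct* mode yields region samples, *phantom* mode
writes NIfTI volumes plus a label atlas and exercises the full imaging
path (read, normalize, extract).

Subject region $i$ draws `n_vox` (default 200) intensities from
$\mathcal{N}(\mu_i + o_s, \sigma^2)$ with region means $\mu_i$ evenly
spaced on $[0.8, 1.2]$, noise $\sigma = 0.1$ (10% of the normalized mean,
a realistic regional coefficient of variation), and a per-subject global
offset $o_s \sim \mathcal{N}(0, (0.5\sigma)^2)$ mimicking the uptake
variation that global normalization removes. In the `SZR` group the second
region of each *effect pair* (default: the ten homologous pairs
$(1,2), \dots, (19,20)$) is shifted by $\delta \cdot \sigma$ (default
$\delta = 3$), lowering that pair's JS similarity. The cohort default is
20 subjects per group.

What the generator does **not** emulate: anatomically shaped regions,
scanner point-spread and partial-volume effects, spatially correlated
noise, and hemisphere-lateralized pathology. Passing tests therefore
demonstrate that the pipeline recovers distributional coupling effects it
was designed to detect under clean conditions — not clinical performance
on patient data.

A note on the effect model: shifting region $j$ perturbs *every* pair
involving $j$, not only the injected pair, so consensus-connection lists
on synthetic cohorts legitimately contain neighbors of the shifted
regions; recovery is scored on the injected pairs being present.

## Problem sizes used in the checks

The test suite runs the full standard conditions — 40 subjects, 90
regions, 200 voxels per region, 49 thresholds — with a null-ensemble size
of 10 per threshold and a $\beta$ lattice step of 0.25 for the
cross-validated runs; these sizes keep a single-CPU run of the whole suite
in the tens of minutes while leaving every pipeline stage exercised at
full dimensionality. The null-ensemble default of 100 is recommended for
reported analyses. Exhaustive graph-metric verification enumerates all
graphs on up to 6 nodes against an adjacency-power oracle.

## Known limitations

- LOOCV on small balanced cohorts has a known pessimistic bias under the
  null (the training set is always slightly unbalanced against the
  held-out class); calibration checks use the binomial band around chance
  rather than a point value.
- The JS similarity is estimated from KDE on a pair-specific grid;
  extremely heavy-tailed intensity distributions would warrant a wider
  padding than the default 3 bandwidths.
- Betweenness, $L_p$ and efficiency conventions follow the
  efficiency-based treatment of disconnected graphs; toolboxes that drop
  disconnected nodes instead will differ at the sparsest thresholds.
- The $\beta$ simplex search is a lattice, not a continuous optimizer; the
  lattice step bounds the granularity of the kernel weighting.
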