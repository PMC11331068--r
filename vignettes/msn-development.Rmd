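---
title: "Modeling adolescent development of morphometric similarity networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling adolescent development of morphometric similarity networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msndev)
```

## The analysis this package implements

Morphometric similarity networks (MSNs) estimate a structural connectome
from a single anatomical scanning session. Each cortical region is described
by a vector of morphometric MRI features — here six: cortical thickness
(CT, mm), gray-matter volume (GM, mm³), surface area (SA, mm²),
magnetization transfer (MT, a myelination marker), fractional anisotropy
(FA) and mean diffusivity (MD) — and the MSN edge between two regions is the
Pearson correlation of their standardized feature vectors. Regions with
similar cytoarchitecture tend to be axonally connected ("like connects with
like"), which is what makes inter-regional morphometric similarity a proxy
for anatomical connectivity.

The package implements, end to end, the developmental analysis of such
networks in an accelerated longitudinal adolescent cohort:

1. **QC and MSN construction** — robust (median/MAD) outlier exclusion of
   subjects, exclusion of zero-variance (signal-dropout) regions, per-scan
   MAD standardization of features across regions, per-scan MSNs, weighted
   degree (hubness) `k` = mean edge weight per region, and
   cytoarchitectonic-zone block summaries.
2. **Longitudinal mixed models** — for every per-scan quantity (a feature,
   a region's degree, a coupling value, a graph metric) the model
   `value ~ age + sex + site + (1 | subject)`, fitted by REML, with age
   centered at 14 years so the intercept is the baseline at the start of
   adolescence; per-region maps are corrected by Benjamini–Hochberg FDR.
3. **Structure–function coupling** — FC edges are Fisher r-to-z transformed
   and residualized edgewise on mean framewise displacement; coupling is the
   Spearman correlation of corresponding MSN and FC edges, globally (upper
   triangle) and per region (the region's edge row).
4. **Functional graph metrics** — proportional thresholding of FC to a
   target edge density, then weighted degree, eigenvector centrality,
   Onnela clustering, efficiency, participation coefficient (PC) and
   within-module degree, each fed back through the same mixed model.
5. **Spin-test inference** — map–map correlations are tested against
   spatial-autocorrelation-preserving nulls built by random spherical
   rotation of parcel centroids (mirrored across hemispheres) with
   nearest-centroid reassignment.
6. **Robustness** — subject-level ablation, leave-10%-out bootstrap CIs,
   within-subject baseline→follow-up change validation, and between-visit
   rank stability as a test–retest proxy.

Because the cohort the original analyses were performed on is access
controlled, every stage is exercised against a synthetic cohort generator
with planted, recoverable effects; the package's claims are
parameter-recovery claims, checked by the test suite.

## The synthetic cohort and its planted biology

`make_parcellation()` places regions quasi-uniformly on the unit sphere,
mirrored across hemispheres, and assigns spatially contiguous
cytoarchitectonic zones (idiotypic, unimodal, heteromodal, paralimbic — the
first three jointly "isocortex") and functional modules via
capacity-balanced spherical Voronoi caps. Contiguity matters: it gives zone
labels and smooth maps genuine spatial autocorrelation, which is the
phenomenon the spin test exists to handle.

`default_ground_truth()` encodes the generative model. Per feature `f`,
region `i`, scan at age `a` (with `d = a - 14`):

```
value = mean_f + slope_{f,i} * d + sex + site + subject intercept
        + subject regional signature + struct_{i,f}(d) + noise
```

The structural term `struct` lives in units of each feature's cross-region
spread and has three parts:

* a **morphometric gradient** `v` (macrostructural features +, micro −)
  carried with loading `+g_i` by isocortical and `−g_i` by paralimbic
  regions — paralimbic cortex is the anticorrelated minority of the
  similarity network at baseline, as befits its agranular/dysgranular
  cytoarchitecture;
* a **zone profile**: one shared direction per zone, orthogonal to `v`,
  which gives within-zone similarity its positive baseline. The three
  isocortical profiles form a symmetric 120° configuration in a plane
  (equal norms, summing to zero per feature); the paralimbic profile takes
  the orthogonal third direction with a small norm;
* an **idiosyncratic profile** per region (orthogonal to `v`, equal norms,
  zero-sum within zone), fixed over age.

Age acts by decaying each zone's *characteristic shared component*.
Negative drift (isocortex, −0.05/yr) decays the shared zone profile:
regions lose their zone-shared structure and stand increasingly on their
individual morphometry, so within-zone similarity erodes and MSN degree
falls — differentiation. Positive drift (paralimbic, +0.07/yr) decays the
gradient anticorrelation: paralimbic similarity to the rest of the cortex
rises — convergence. Together these reproduce the full qualitative sign
structure of adolescent MSN development: within-zone similarity declines in
every zone, paralimbic–isocortex between-zone similarity rises, and the
degree age map is signed by zone.

Several design points were forced by analysis rather than chosen freely,
all traceable to one fact: cross-region standardization removes any
profile component shared by the majority of regions (the per-feature
median), so (i) naive "scale each region's deviation from the grand mean"
constructions plant nothing — for idiosyncratic deviations the expected
edge weight is zero regardless of scale; (ii) growing idiosyncratic
deviations is not a reliable differentiation mechanism either, because it
dilutes *all* of a region's edges toward zero, which raises degree for
regions whose baseline degree is negative — hence differentiation acts by
zone-profile decay, which lowers degree for every isocortical region
regardless of baseline sign; (iii) the zone geometry must be symmetric and
the idiosyncratic spread broad, or the removed median lands on one zone's
profile and silently deletes that zone's planted effect; and (iv)
idiosyncratic and zone directions are constructed orthogonal to the
gradient so no random gradient overlap contaminates a region's planted
trend.

Magnitudes were fixed once, before the test suite was written, so that (i)
global feature age t-statistics at the default cohort scale echo the
canonical adolescent pattern (strong CT/GM decline, moderate SA decline,
clear MT increase, near-null FA/MD), and (ii) the zone-signed degree change
is recoverable (>80% of regions with the correct t sign) at cohorts of 120+
subjects across seeds. The per-subject regional signature
(`subject_idio_sd`, stable across a subject's visits, centered across
regions) models morphometric individuality; it is what makes between-visit
rank stability positive and gives the motion-residualized FC edges a
subject-specific component, at the cost of a wider subject random intercept
in the regional models.

Functional connectomes (`simulate_fc()`) are built edgewise on a latent
z-scale as `lambda_ij(age)` times the normal-quantile rank transform of the
MSN edge plus `(1 − lambda_ij)` times modular noise, mapped through `tanh`
to the correlation scale. `lambda` declines with age (global
structure–function decoupling, −0.010/yr from a baseline 0.25), faster in
isocortex; within-module noise inflation fades with age in isocortex and
grows in paralimbic cortex, which plants rising isocortical and falling
paralimbic participation coefficients. Head motion (`mean_fd`) is
log-normal and independent of FC by default; `motion_coupling` injects a
planted motion–FC association for testing the residualization.

The cohort design mimics an accelerated longitudinal study: subjects are
allocated evenly to five age strata spanning 14–26 years, sex balanced
within stratum, scanned 1–3 times (probabilities 0.40/0.50/0.10) at 6–18
month intervals, across three sites with a 70/22/8 split.

### What the generator does not emulate

MRI physics, scanner drift, spatially correlated measurement noise, cortical
folding geometry (regions live on a sphere), nonlinear growth trajectories,
and drop-out correlated with age or motion. Passing tests therefore show
that the *pipeline* recovers what was planted under its own model class;
they do not certify effect sizes in real cohorts.

## Statistical and numerical choices

* **MAD standardization** uses the 1.4826 normal-consistency constant. The
  constant cancels in Pearson correlations, so MSN edges are insensitive to
  it (a property test asserts this). Standardization is across regions
  within each scan: inter-regional correlation requires cross-region spread
  per feature, and the per-scan choice keeps each network a function of one
  scan only.
* **Subject QC** applies the robust-z ≥ 5 rule to scan-wise global feature
  means and excludes at subject level (all scans of a flagged subject),
  since exclusion lists are subject lists. A zero MAD in the QC statistics
  is raised as a degenerate-feature error rather than silently excluding
  everyone.
* **Mixed models**: random-intercept-only — estimating subject-level slopes
  would need three or more scans for most subjects, which the design does
  not provide. Singular fits are kept at the boundary and flagged, never
  dropped, so maps keep full regional coverage; with one scan per subject
  the boundary fit equals OLS (tested to 1e-8). t-statistics use residual
  degrees of freedom (`n_obs − n_fixed`) by default; at 200+ scans the
  difference from Satterthwaite (available via `df_method`) is immaterial,
  and the measured type-I rate of the age test at nominal 5% is about 6%.
  Baseline predictions at age 14 average sex and site contributions over
  their observed frequencies rather than picking a reference level.
* **Coupling** uses average ranks for ties (ties are measure-zero in
  continuous data); regional coupling excludes only the self-edge.
  Motion residualization is a single pooled edgewise regression across all
  scans; when motion is constant it degenerates to subtracting the edge
  mean. Residualization removes each edge's cohort mean, so coupling values
  measure the alignment of a scan's *deviations* with its MSN — their
  absolute level is lower than raw-FC coupling, and the age trend is the
  modeled quantity.
* **Graph metrics** are computed on Fisher-z FC rather than the
  residualized edges: thresholded topology needs the connectome itself, and
  subtracting cohort means would destroy it. Negative edges are discarded
  at thresholding (path metrics need nonnegative weights); ties at the
  threshold break by stable edge index; weights are normalized by their
  maximum so efficiencies and clustering lie in [0, 1]. Eigenvector
  centrality iterates on `W + I` (same eigenvectors, no bipartite
  oscillation) to tolerance 1e-10, on the largest component with zeros
  elsewhere. The participation coefficient uses the Guimerà–Amaral
  quadratic form `1 − Σ_s (k_is/k_i)²`; module labels come from the
  parcellation's predefined functional modules, not per-scan community
  detection, so nodes correspond across scans. Default density 0.10,
  configurable; thresholded edge sets are nested across densities.
* **Spin test**: parcel-level spins (nearest-centroid reassignment after a
  Haar-uniform rotation, mirrored to the right hemisphere); only the first
  map is rotated; p-values are two-sided and permutation-inclusive,
  `(1 + #{|null| ≥ |obs|}) / (n_perm + 1)`, hence never exactly zero.
  Masked regions propagate their mask through the reassignment. On
  independent smooth null maps the measured rejection rate at α = 0.05 is
  near nominal while naive parametric correlation rejects several times
  more often.
* **Robustness** resamples subjects, never scans, preserving longitudinal
  dependence, and reuses the identical `degree_age_map()` code path as the
  main analysis. Bootstrap CIs are plain percentile intervals, matching the
  leave-N-out description they implement. Rank stability uses Spearman
  correlation, as "rank ... correlated" suggests.

## Problem sizes

The analysis scripts and the test suite run at 90 regions, 5 modules and
120–150 subjects (the package's default analysis scale), with 100-cohort
Monte-Carlo loops for recovery and calibration claims, 50 replicate cohorts
for planted-sign recovery, 200 replicates for spin calibration, and 500–1000
spins per colocation test. The atlas-scale region count (360 regions, two
planted dropout regions, 358 analyzed) is exercised in the QC tests. All
sizes are configuration, not constants.

## Known limitations

Zone identities of the synthetic parcellation are geometric caps, not
anatomical zones; the generator's age trajectories are linear by
construction, so the package's linear models are correctly specified for it
— misspecification robustness is untested; the FC generator couples to the
MSN through ranks only; and absolute coupling and stability levels are
generator-dependent, so only their signs and trends are asserted.
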