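---
title: "Methods: from gut microbiota to brain networks to cognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from gut microbiota to brain networks to cognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models and procedures the package implements,
the assumptions behind each numerical choice, and what the synthetic
cohort generator does and does not emulate.

## The analysis chain

The package operationalizes a common observational design in gut–brain
research: a cohort of healthy adults contributes a 16S genus count table,
a diffusion-tractography fiber-number (FN) matrix, a resting-state
functional connectivity (FC) matrix, and behavioral scores. The question
is whether microbial community structure (alpha diversity, enterotype)
relates to brain network topology, and whether topology mediates an
association with cognition. Inference proceeds in three gated stages:
microbiota → network screens, then network → cognition screens restricted
to stage-1 hits, then bootstrap mediation restricted to pairs surviving
both screens. The gating is implemented as a data dependency, not as a
p-value filter inside the mediation code, so each stage is independently
testable.

## Network construction

**Structural.** Two regions of the 90-region AAL parcellation are
connected when the streamline count between them is at least
`min_fibers = 3`. The threshold suppresses spurious single-streamline
connections; structural networks are analyzed at this single threshold,
with no sparsity sweep.

**Functional.** Pearson correlations of regional time series are Fisher
z-transformed (arctanh, with |r| clipped to 1 − 1e−7 so perfect
correlations stay finite). Binary graphs are formed over a sparsity sweep
of 0.10–0.34 in steps of 0.01 (25 graphs), at each sparsity retaining the
K = ⌊s·N(N−1)/2⌋ largest **positive** weights. Negative correlations
never become edges by default; whether the original analyses ranked
signed or absolute correlations is not recoverable, so positive-only is
the documented default with `include_negative` as an option. The floor in
the edge budget guarantees realized sparsity ≤ nominal; ties at the
cutoff break by node index so graphs are reproducible at any precision.
Because the ranking is fixed, the 25 graphs are nested, which also makes
global efficiency monotone along the sweep — a property the tests
exploit. Binarization operates on the correlation matrix; the Fisher
transform is monotone, so the graphs would be identical either way.

## Topological metrics

Per-node clustering is 2·triangles/(k(k−1)) with 0 for degree < 2; Cp is
the mean over all nodes. Lp averages hop distances over *reachable* pairs
only and carries a disconnection flag — the handling of disconnected
pairs is a genuine free choice, and the efficiency metrics (which sum
1/d with 1/∞ = 0) carry the disconnection information instead. Local
efficiency of a node is the global efficiency of its neighbor-induced
subgraph. Betweenness is reported unnormalized; group comparisons and
correlations are scale-invariant, so normalization cannot change any
downstream statistic.

Small-world normalization divides Cp and Lp by their means over
`n_random = 100` degree-preserving random networks produced by
Maslov–Sneppen double-edge swaps (10 × edge-count swap attempts per
null, seeded). Gamma = Cp/⟨Cp_null⟩, Lambda = Lp/⟨Lp_null⟩,
Sigma = Gamma/Lambda. A null whose Lp is undefined is excluded; if more
than 10% are excluded the computation errors rather than silently
averaging a biased ensemble. On a complete graph no swap is possible and
Gamma = Lambda = Sigma = 1 exactly, which the tests assert.

Functional metrics are summarized across the sweep by the trapezoidal
AUC. The quadrature rule behind published AUC summaries is typically
unstated; the trapezoid is exact for constant and linear curves and any
alternative differs only by a factor close to the step size for smooth
curves.

## SC–FC coupling

For region i, all edges incident to i with non-zero fiber count
contribute a pair (log FN, FC value); the coupling of region i is the
Pearson correlation over those pairs, giving exactly 90 values per
subject. The log uses base e — the base is an affine change in log space
and cannot alter r. The FC side uses Fisher-z values by default
(configurable), matching the transform applied at matrix construction.
Regions with fewer than `min_edges = 5` usable edges (keeping at least 3
residual degrees of freedom) are reported missing rather than numeric.

## Microbiome

Shannon entropy is reported in nats: the published cohort ranges this
package was designed around (roughly 1.6–4.0 for gut genera) are
consistent with natural logarithms. Simpson is the dominance form Σ pᵢ²,
which lies in (0, 1] and decreases with diversity. Neither index is
rarefied by default; rarefaction is a documented option rather than a
silent step.

Enterotyping follows the classical recipe: relative abundances →
Jensen–Shannon divergence (natural log) → √JSD distances (a metric) →
partitioning around medoids for k = 2…6 → Calinski–Harabasz selection of
k. The CH index is computed on a classical multidimensional scaling
embedding of the distance matrix with centroid-based between/within sums
of squares. When no candidate k beats the runner-up by more than 10% of
the best score, the assignment is flagged `weak_clustering` instead of
pretending a structure exists. Each cluster's driver taxon is the taxon
with the largest inside-minus-outside mean abundance contrast.

## Statistics

Partial correlation residualizes both variables on an intercept plus
covariates and correlates the residuals; the t test uses df = n − 2 − k.
Stage 1 adjusts for age, sex and BMI; stage 2 adds education; any metric
flagged FC-derived additionally gets frame-wise displacement. The FDR
family is one metric-type × exposure screen (e.g., the 7 global metrics,
or 90 nodal values of one metric); family composition is configurable
because published analyses rarely define it exactly. Enterotype group
differences use the classical one-way ANOVA F test followed by Bonferroni
post hoc pairwise pooled-variance t tests (p × number of pairs, capped at
1). The pooled variance is the two-group pooled estimate for each pair;
some software instead pools the ANOVA mean-square error across all
groups, which differs slightly when group variances are unequal.

Mediation fits three OLS models — m ~ x + Z, y ~ m + x + Z, y ~ x + Z —
and reports unstandardized a, b, c′, c with indirect effect a·b. The OLS
identity c = c′ + a·b holds to numerical precision on every complete-case
run and is asserted in the tests. The confidence interval is a percentile
bootstrap over subject resampling (10,000 draws by default, seeded); the
percentile variant is the simplest defensible default where the
bias-corrected variant is not documented in the sources a user may be
comparing against. A categorical exposure (enterotype) is indicator-coded
against its first level, yielding one relative indirect effect per
remaining level. A perfectly collinear direct path (noise-free mediator)
resolves, as in `lm()`, to c′ = 0 rather than an error; a bootstrap draw
whose design is rank-deficient is redrawn (at most 10 times) before
failing.

## The synthetic cohort generator

`sim_config()` freezes the study conditions the package is tested under:
157 subjects, 90 regions, 60 genera at depth 20,000, three equally
weighted Dirichlet-multinomial enterotype components driven by
Prevotella, Ruminococcaceae and Bacteroides (driver concentration 20
against a background of 0.7, with per-subject lognormal background
heterogeneity, sdlog 0.6, giving Shannon ≈ 2.9 ± 0.5 in nats — the
spread real cohorts show).

Structural networks are Watts–Strogatz graphs (ring lattice degree 14)
whose per-subject rewiring probability is
logistic(logit(0.095) + 0.05·z(Shannon)): the canonical one-parameter
dial for small-worldness, oriented so that higher diversity lowers Gamma
(the direction this design was built to detect). Backbone edges carry
log-normal fiber counts floored at 3, so FN ≥ 3 recovers the backbone
exactly. These settings give a cohort-mean Gamma close to 3 (SD ≈ 0.15)
and a diversity–Gamma association in the −0.3 to −0.5 range. The
functional matrix is
tanh of (standardized log FN + noise) on backbone edges — making the
coupling statistic's ground truth analytic — with N(0, 0.08) background
correlations elsewhere; designated regions receive enterotype-dependent
extra noise so coupling differs by group. The default edge-noise scale
1.8 puts mean regional coupling near 0.5.

One cognitive outcome follows Y = 0.32·M + 0.02·X + covariate terms +
N(0, 0.12), where M is the generator-side mediator: the clustering
coefficient of each subject's thresholded graph normalized by the mean
null-model clustering of a reference subject (a cohort-constant scale,
i.e. Gamma up to a few percent of between-subject null variation — a
deliberate shortcut that avoids a full null ensemble per subject at
generation time). The remaining six scores are effect-free noise with
cohort-realistic means. The effect sizes were calibrated once by
simulation so the full pipeline detects the planted chain in at least
80% of default cohorts (the acceptance test asserts this over 50 seeded
cohorts; observed rates sit above 90%), and then frozen.

What the generator does **not** emulate: read-level 16S error profiles,
compositional correlations between genera beyond the Dirichlet, realistic
BOLD dynamics (FC comes from a monotone transform of SC, not a dynamical
model), spatially structured tractography error, or non-linear
covariate–outcome relationships. Passing tests therefore demonstrate the
*machinery* — constructors, metrics, screens, gating, bootstrap — under
known truth, not robustness to every artifact of real data.

## Problem sizes and determinism

The test suite and the acceptance script scale simulations to remain
decisive but quick: oracle comparisons use 200 random graphs with up to
12 nodes; small-world simulations use 10–30 null networks where the
estimate's Monte-Carlo error is a fraction of a percent of the quantity
tested; multi-cohort power checks use 8 nulls and 400 bootstrap draws per
cohort; single-run analyses use the full defaults (100 nulls, 10,000
draws). Every random step — generators, null ensembles, bootstrap —
flows from explicit integer seeds, and rerunning any pipeline with the
same cohort, config and seed reproduces every table bit for bit.

## Known limitations

- Whole-brain (single-scalar) SC–FC coupling and communication-model
  couplings are out of scope; only the per-region statistic is provided.
- Weighted-graph topology, modularity, hubs and rich-club analyses are
  not implemented.
- Mediation supports a single mediator per model; structural-equation
  models, moderated mediation and Sobel tests are out of scope.
- The per-sparsity small-world normalization of functional sweeps is
  expensive (25 × n_random nulls per subject); `include_functional` in
  `pipeline_config()` is therefore opt-in.
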