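---
title: "Methods: statistics of a plate-based ionomic screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: statistics of a plate-based ionomic screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionoscreen)
```

# The measurement model

An ionomic screen quantifies element concentrations (ppm, by ICP-MS) for
thousands of mutant strains grown on 96-well plates. Each plate carries four
fixed control strains and up to 20 mutants; three plates are processed per
instrument day; each strain is measured in 4, 8 or 16 biological replicates.
Concentrations are positive and technical effects (day-to-day drift,
per-plate handling) act multiplicatively, so all correction is done on the
log scale. The package assumes, and its simulator realizes, the structure

log concentration = element baseline + gene effect + day effect
\+ plate-within-day effect + replicate noise, scaled by the well's OD600
(element content grows with biomass).

## Normalization

`od_normalize()` divides concentrations by OD600. `fit_plate_correction()`
then estimates, per element and from control wells only, fixed day offsets
and plate-within-day residuals on the log scale. Plate residuals are shrunken
toward zero by the empirical-Bayes factor

λ = s²_plate / (s²_plate + s²_within / n_c),

where s²_within is the pooled within-plate control variance, s²_plate a
method-of-moments between-plate variance component, and n_c the control
count per plate. With noise-free controls λ = 1 and the correction removes a
constant plate offset exactly; with few/noisy controls λ shrinks unreliable
estimates. The published analysis delegates this step to external
mixed-model software whose full specification is not part of the analysis
description; the shrinkage estimator above was chosen as a transparent
surrogate with the same intent (control-based removal of day and plate
effects) that is fully testable by simulation. `lme4` would fit the same
structure, but with 3 plates per day and 4 controls per plate such fits sit
routinely on the variance boundary; the closed-form moment estimator is
deterministic and never fails to converge.

Phenotypes are summarized on the *measurement* scale after log-domain
correction: `D_ge` is the mean and `σ̃_ge` the n−1 standard deviation of the
corrected replicate values. Whether the original analysis summarized on the
log or linear scale is not documented; the linear choice keeps `D` in
concentration-like units and is the package's documented convention. Strains
seen in a single replicate have no scale estimate; they are flagged and
excluded from testing.

# Significance

The moderated Z standardizes a gene's phenotype against the across-gene
median, with the scale estimated by 1.4826 × MAD (the consistency factor
that makes the MAD unbiased for the standard deviation under normality):

Z_ge = (D_ge − median_g D_ge) / (1.4826 · median_g |D_ge − median_g D_ge|).

Two algebraic identities follow immediately and are asserted to 1e-9 in the
tests: within each element the median of Z is 0 and the median of |Z| is
1/1.4826. If an element's MAD across genes is zero (degenerate input, e.g. a
noise-free simulation) its Z values are undefined and a warning is raised
rather than dividing by zero.

The mapping from Z to p-values is not part of the published description; the
conventional companion of a robust Z — the two-sided standard normal tail —
is used. Benjamini–Hochberg adjustment is applied **jointly over all
gene×element cells** of a dataset, because the screen reports one cutoff
pair per dataset rather than per element. The reported cutoffs are the
extreme observed significant Z per direction (largest significant negative,
smallest significant positive), which makes them data-dependent and slightly
asymmetric without any asymmetry in the test itself; empty sides report
∓∞ sentinels.

The annealing filter is a replicate-consistency quality control: a call
passes only if ≥75% (inclusive) of the strain's replicates deviate from the
element's pooled replicate median in the call's direction by at least
2 × MAD of all replicate values pooled across genes. The filter MAD is the
*raw* median absolute deviation: the 1.4826 factor is applied explicitly in
the Z statistic where intended, and the filter's description does not
rescale. Percent change uses the product σ̃_ge·D_ge as printed in the
source formula (its prose gloss reads as if σ̃ were absent; the formula was
followed), and its across-gene mean is zero by construction. Effect groups
are assigned from the most extreme perCh over a gene's *significant*
elements, with band boundaries inclusive toward the more extreme group
(exactly +20% is B, exactly +100% is C).

# Exhaustive significance clustering

Significant genes are partitioned by exact equality of their full sign
vector over the panel (14 elements for deletion screens, 17 for
over-expression), a space of 3^E patterns (`pattern_space_size()`).
Patterns with fewer than `min_size` (default 3) members are reported as
unclustered. Clusters are named `CLUSTER_k` in order of decreasing size with
lexicographic pattern-key tie-breaks — the original numbering scheme is
unexplained, so the package defines its own deterministic one. Median Z
profiles are computed over **all** elements, including non-significant ones,
so sub-threshold structure remains visible in the heatmap; row and column
orders come from complete-linkage hierarchical clustering of Euclidean
distances (`stats::hclust`), deterministic given input order.

# Enrichment and networks

`hypergeom_overlap()` computes the exact upper tail P(X ≥ k) by summing
`dhyper` terms in log space. `conditional_hypergeom_go()` walks the
ontology children-before-parents (Kahn topological order over is_a/part_of;
other relations are ignored, the standard practice); when testing a parent,
genes annotated to already-significant descendants (p ≤ `alpha_cond`,
default 0.05 — the conditioning threshold is not documented in the source
analysis and is exposed as a parameter) are removed from the term's gene
set *and* the universe counts. With no significant children the conditional
test equals the plain test exactly, which the suite asserts.

Subnetworks keep interactions with both endpoints in the tested gene set;
genes without any edge are excluded from the node list. A pair interacting
both physically and genetically contributes two typed edges but one node
pair. The inclusion rate is 100 × interacting/tested — the published figure
legend inverts the ratio, but its printed 36–54% values force this
orientation. Connectivity is edges/nodes. Edge correlations default to
Pearson over the two genes' moderated-Z vectors across all panel elements
(Spearman available); cells absent from supplementary-style tables are
imputed as 0, the null value of the moderated Z, since those tables blank
sub-threshold cells.

# The simulator, and what passing tests show

`sim_config()` fixes the screen layout (4 controls, ≤20 mutants/plate,
3 plates/day, 4/8/16 replicates) and exposes dispersions the published
screen does not state. Defaults were chosen once as realistic ICP-MS screen
values: replicate noise 0.10 (log scale, ≈10% CV), plate and day effects
0.05, gene-to-gene baseline heterogeneity 0.05, OD600 log-normal around 1.0
(sd 0.15), spikes log-uniform between 2- and 4-fold with random sign at
2% of gene×element cells. Per-element baselines are typical solution
concentrations of digested yeast samples (P ≈ 100 ppm down to Cd ≈ 5 ppb).
One master seed drives three documented substreams (truth, technical
effects, measurement noise), so stages can be regenerated independently.

The simulator emulates plate structure, multiplicative technical effects and
sparse large-effect perturbations. It does **not** emulate element–element
covariance beyond shared sign patterns, instrument drift within a run,
growth differences between mutants (OD is independent of genotype), or the
heavy-tailed contamination of real plates. Passing the recovery test
(sign-correct recall ≥80% at 4 replicates and ≥2-fold spikes, empirical FDR
≤10% over 20 screens of 100 mutants) therefore demonstrates the pipeline's
statistical machinery is correct under its stated model, not that real
screens achieve those operating characteristics.

# Problem sizes and determinism

The test suite runs simulated screens of 15–100 mutants with the 14-element
panel and 20 repeats for distributional properties; oracle comparisons use
1000 random p-vectors (BH), every hypergeometric instance with N ≤ 12, 500
random sign matrices (clustering) and brute-force agglomeration for ≤6
profiles — sizes at which exhaustive oracles are exact and the whole suite
completes in well under a minute. `run_pipeline()` writes a manifest (seeds,
configuration, per-stage counts) and reruns are byte-identical.

# Known limitations

- The plate-correction surrogate is not the original mixed model; on real
  data with strong control outliers a robust variant (median-based control
  summaries) would be preferable.
- The hypergeometric overlap test reproduces published overlap p-values only
  insofar as the published universe sizes are stated; at the stated
  N = 4940, K = 584, n = 233, k = 61 the exact upper tail is 4.8696e-10.
- No multiple-testing correction is applied across GO terms (raw conditional
  p-values are reported, as in the source analysis), and GAF qualifiers
  other than NOT are not interpreted.
- Published per-figure network edge counts depend on the interaction-database
  snapshot and are not reproducible from code alone; the network module is
  validated against planted simulated truth instead.
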