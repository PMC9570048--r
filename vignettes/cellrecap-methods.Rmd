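---
title: "Methods: cell-cycle-controlled phylostratum expression profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-cycle-controlled phylostratum expression profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the statistic

Phylostratigraphy assigns every gene an evolutionary age class — here 17
strata from cellular organisms (stratum 1) to Hominidae (stratum 17),
with strata 1–2 of unicellular (UC) and 3–17 of multicellular (MC)
origin.  If cell differentiation recapitulates phylogenesis, the
expression of old genes should fall and that of younger genes rise as a
stem-like population differentiates.  The confounder is proliferation:
stem-like cells cycle faster, and cell-cycle expression strongly
correlates with UC-gene expression, so a naive population comparison
mixes the differentiation effect with the proliferation effect.

`cellrecap` therefore compares two cell populations *at equal cell-cycle
activity*.  For a gene group \(G\) and cell \(j\):

1. the expression matrix is quantile-normalized across all cells;
2. the group signal is the back-transformed mean
   \(y_j = 2^{\frac{1}{|G|}\sum_{i \in G}\log_2(v_{ij}+o)} - o\)
   (pseudo-count \(o\), default 1);
3. the covariate \(x_j\) is the same statistic for a mitotic cell-cycle
   signature (the GO "mitotic cell cycle" category in real data);
4. the equal-slope ANCOVA model \(y = a + \Delta a\,g + b\,x\) is fitted
   over both populations, \(g\) indicating the contrast population.

\(\Delta a\) — the intercept difference at a common slope — is the
expression difference between the populations extrapolated to zero
cell-cycle activity.  The common slope is the pooled within-population
slope \(\hat b = (S_{xy}^{(c)}+S_{xy}^{(r)})/(S_{xx}^{(c)}+S_{xx}^{(r)})\),
and \(\Delta a = (\bar y_c - \bar y_r) - \hat b(\bar x_c - \bar x_r)\).
Its standard error uses the standard three-parameter linear-model
covariance with \(n-3\) residual degrees of freedom and the t
distribution, exact at small n and indistinguishable from the normal at
the hundreds of cells typical of single-cell data sets.

An *evolutionary profile* is the vector of \(\Delta a\) over the 17
strata for one population pair; a *slope profile* collects the
per-stratum slopes \(b\) within one population; an *ontogenetic profile*
contrasts one group (by default the UC genes) across developmental
stages against a fixed reference stage.  Qualitative per-stratum calls
(`down`/`up`/`null`) are made from the 95% confidence interval excluding
zero — no p-value thresholds and no multiple-testing correction across
the 17 strata, because the profile is read as a curve with per-stratum
intervals; correction is reserved for the enrichment module, where
hundreds of categories are scanned.

## Model assumptions and their check

The contrast is only meaningful for straight lines: intercepts of curved
fits are not comparable.  `adequacy_check()` fits the linear and the
order-2 polynomial model and reports both explained-variance fractions,
their ratio, and the p-value of the quadratic coefficient.  In regimes
where the method is trustworthy the line captures well above 90% of what
the quadratic captures.  Degenerate inputs (zero total variance) are
flagged and report a fraction of 0 rather than a 0/0.

Equal slopes are imposed by construction; the per-population fits from
`fit_group_regression()` serve as the diagnostic for populations whose
slopes genuinely differ, and are never used to form \(\Delta a\).

## Interactome neighborhood stratification

The interaction network is built from a confidence-scored edge list with
a strict threshold (default: confidence > 0.5, the top-half-confidence
convention of STRING-style scores), duplicate pairs collapsed to the
maximum confidence and self-loops dropped.  For every protein, the MC
fraction \(f\) of its one-step neighborhood is computed over *dated*
neighbors only — undated neighbors cannot be assigned an origin and are
excluded from the denominator.  Nodes with fewer than `min_neighbors`
(default 3) dated neighbors get an undefined fraction: below that, \(f\)
is too granular to bin.  UC genes are partitioned by \(f\) at cut points
0.25/0.5/0.75 with the lowest bin closed ("0.25 or a lesser fraction")
and each bin contrasted between the populations like any other gene
group; MC genes are binned symmetrically by the UC fraction.

## What the synthetic generator emulates

`simulate_expression()` draws, for cell \(j\) of population \(P\), a
latent cell-cycle activity \(c_j\) Gaussian on the log2 scale (log-normal
on the linear scale), and sets
\(\log_2 v_{ij} = \alpha + \delta_{s,P} + \beta_s c_j + \varepsilon\)
for a gene of stratum \(s\), with \(\varepsilon \sim N(0, \sigma)\).
Defaults encode the structure the analysis is designed to detect:

* **slope profile** \(\beta_s\) (log2 per log2 unit): +0.4 for the two
  UC strata, tapering through the early MC strata, −0.2 from Bilateria
  on — the positive-then-negative coupling of gene expression to
  proliferation;
* **shift profile** \(\delta_s\) (log2 units; contrast − reference):
  −0.15, −0.15 for strata 1–2, +0.08 for strata 3–9, 0 for strata 10–17
  — the three-phase recapitulation pattern (UC down, early-MC up,
  post-bony-vertebrate flat);
* a **cell-cycle signature** of 60 genes tracking \(c_j\) with unit
  slope, disjoint from the strata so overlap removal is testable both
  ways;
* 4000 **background genes** with no population shift and mildly
  heterogeneous slopes, so quantile normalization operates on a
  transcriptome-wide distribution.  Without them, the programmed shifts
  of the tested strata would dominate each cell's value distribution and
  normalization would visibly push the unshifted strata in the opposite
  direction;
* **activity parameters**: reference location 1.2, contrast 0.9, SD 0.4
  (log2 scale).  The reference (stem-like) population cycles faster, but
  the two populations overlap broadly in activity.  This is deliberate:
  the linear-scale signal is a power law in the covariate
  (\(y \propto x^{\beta}\)), and a line fitted at a common slope across
  two populations occupying nearly disjoint covariate ranges acquires a
  deterministic intercept bias.  With the default gap the measured bias
  on null strata is an order of magnitude below the per-stratum
  confidence radius, i.e. the generator stays in the regime where the
  linear model is adequate — the regime the method is built for;
* **noise** \(\sigma = 0.5\) log2 units of per-gene residual, a typical
  magnitude for normalized single-cell group-level analysis; 40 genes
  per stratum and 300 cells per population by default.

Per-stratum magnitudes of the real shifts are not published; the
defaults were chosen once for statistical detectability at the default
study size, not for biological realism, and the per-stratum false-call
rate then sits at the nominal ~5% of the 95% CIs (plus a small
normalization remnant), so a profile of 17 calls occasionally carries
one or two false calls — exactly what the CI semantics promise.

`simulate_network()` is a stochastic block model — one UC block, two MC
blocks, the UC block with the higher within/between edge-probability
ratio (the denser unicellular cluster) — with one addition: each UC node
carries a mixing propensity \(m_i \sim U(0.05, 0.95)\) that scales its
within-UC edge probabilities by \(4(1-m_i)(1-m_j)\) and its UC–MC
probabilities by \(2m_i\), preserving the block-level means while making
the node's expected neighborhood MC fraction equal \(m_i\).  A
homogeneous block model gives every UC node the *same* expected
composition, so the extreme composition bins would be populated only by
binomial sampling noise; real interactomes have genuine composition
heterogeneity (metabolic UC proteins in conserved UC-dense regions,
signaling UC proteins in evolved MC-dense ones), and the propensity term
reproduces it.  Edge confidences are drawn U(0.4, 1.0) so the strict 0.5
filter removes a nontrivial sixth of the edges.  When neighborhood
coupling is enabled, each network gene's expression shift is re-blended
as \((1-f_i)\,\delta_{UC} + f_i\,\delta_{MC}\) from its node's realized
MC fraction — the mechanism that produces the sign reversal of UC-gene
contrasts in MC-rich neighborhoods.

`simulate_ontology()` layers terms under a single root and draws each
non-root term's parent from the level above, so cycles are impossible by
construction; a planted leaf term annotated with a chosen gene set
provides a known enrichment signal.

What the generator does *not* emulate: count-level noise (dropout, UMI
sampling, library-size variation), gene–gene correlation beyond the
shared latent activity, batch structure, and any real phylostratum
assignment.  Passing recovery tests therefore shows the pipeline's
statistics are correct and calibrated for the generative structure they
assume — not that real data satisfy that structure.

## Enrichment

Annotations are propagated up the ontology (a gene belongs to a category
if annotated to it or any descendant) by a leaves-first sweep; the
hypergeometric test is exact, upper-tailed when observed/expected > 1
and lower-tailed when < 1, with the two-sided-minimum fallback (smaller
tail doubled, capped at 1) at the O/E = 1 boundary; categories with
fewer than 3 universe genes are skipped as untestable; correction is
Benjamini–Hochberg across all categories of one invocation (ontology
terms and pathway sets jointly — the conservative reading when the
original scope is unstated).  The universe is the genes that could have
entered the sample: present in the analyzed matrix, dated, annotated.
Pathway compendia are deduplicated by uniting entries with set-equal
membership (proper subsets are kept separate).

## Numerical and reproducibility choices

* log base 2, pseudo-count 1 by default (configurable, including 0 for
  strictly positive data); back-transformed means floored at zero.
* Quantile-normalization ties receive the mean of the reference
  quantiles their rank range spans — deterministic and
  permutation-invariant.
* Normalization is computed once on the full matrix, never per
  population: intercepts are only comparable on a shared scale.
* All generator randomness flows from one integer seed through
  deterministic per-component sub-seeds; repeated pipeline runs with the
  same configuration produce byte-identical TSV outputs, and every run
  writes a manifest (package version, seed, configuration hash).
* TSV numerics are formatted at 12 significant digits for byte-stable
  round-trips.

## Problem sizes

The bundled tests and the acceptance script run the full pipeline at the
default study size (17 × 40 stratum genes + 60 signature + 4000
background genes × 600 cells), 500-replicate calibration loops at
n = 200 per population, oracle sweeps of 200 random ANCOVA instances,
150 hypergeometric grids (N ≤ 30) and 100 random DAGs (≤ 50 terms) —
sizes at which every check completes in seconds while leaving the
Monte-Carlo error well inside the asserted tolerances.

## Known limitations

* The contrast extrapolates to zero cell-cycle activity; with strongly
  separated populations this is an extrapolation outside both clouds
  and inherits any curvature of the true relation (see the adequacy
  check).
* Cluster membership and gene dating are consumed as inputs; errors in
  either propagate silently into group definitions.
* The enrichment module assumes exchangeability of genes under the
  null; co-expression makes the hypergeometric p-values optimistic on
  real data.
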