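---
title: "Nitrogen metabolism profiling: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nitrogen metabolism profiling: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(azotrace)
```

## The measurement model

A stable-isotope tracing measurement reports, for each metabolite, the
intensities of its isotopologues M+0 … M+n, where n is the number of
tracer-element atoms (nitrogen, by default) in the molecular formula. Two
processes place mass at shifts above zero: genuine incorporation of
tracer-derived ¹⁵N, and the natural abundance of heavy isotopes. azotrace
models the observed vector as

$$ m = C\,x, $$

where $x$ is the true distribution over the number of labelled atoms
(summing to 1) and column $j$ of $C$ is the theoretical isotopologue
distribution of the species carrying exactly $j$ labels.

**Resolved mode (default).** Orbitrap and FT-ICR acquisitions at 60,000
FWHM and above separate ¹⁵N isotopologues from the ¹³C peaks of
neighbouring nominal mass, so only the $n-j$ *unlabelled* tracer positions
contribute natural heavy signal: column $j$ is
$\mathrm{Binomial}(n-j,\,a_{15\mathrm{N}})$ shifted by $j$, with
$a_{15\mathrm{N}} = 0.003663$. The matrix is square, lower triangular with
positive diagonal, hence invertible, and each column sums to 1.

**Unresolved mode.** For lower-resolution data the natural heavy-isotope
distributions of all non-tracer elements (C, H, O, S; deuterium and ¹⁷O are
kept despite their negligible size so the matrix agrees exactly with an
exhaustive convolution oracle) are convolved into every column, truncated
at shift $n$ so the matrix stays square. Truncation loses a little mass in
the last rows; columns then sum to at most 1.

Isotope abundances are standard IUPAC values shipped as an editable CSV
(`inst/extdata/isotope_abundances.csv`). A ³⁶S entry (abundance 1e-4) is
included so sulfur, like every element, sums to 1 within 1e-9. Mass shifts
are nominal integers; fine structure and exact masses are out of scope.

## Inverting the model

`correct_vector()` solves $\min_x \lVert Cx - m\rVert^2$ subject to
$x \ge 0$ and renormalizes $x$ to sum to 1. Non-negative least squares was
chosen over triangular back-substitution with clipping because it degrades
gracefully under noise and matches established correction practice. Since
the resolved-mode matrix is square and invertible, the implementation first
tries the exact solve and accepts it whenever all components are
$\ge -10^{-12}$ (a zero-residual non-negative solution is necessarily the
NNLS optimum); the active-set solver (`pracma::lsqnonneg`) handles the
rest. The relative residual is reported as a QC field. Noiseless forward
simulations are recovered to machine precision; the correction is exactly
scale invariant because the observed vector is normalized to unit total
before solving.

All-zero vectors are an error for single-vector correction but a *missing
value* for imaging grids (`correct_pixel_grid()`), where off-tissue pixels
are routine; a grid with fewer than 1% non-empty pixels triggers a warning,
not an error.

## From enrichments to platform outputs

- **Replicate aggregation** (`build_enrichment_table()`): the arithmetic
  mean of per-sample fractional enrichments, with s.e.m., not the FE of
  summed intensities — this matches per-replicate error bars and makes a
  dropped (all-zero) replicate an explicit decrement of n.
- **Filter cascade** (`apply_filter_cascade()`): five independent rules
  with reasons that accumulate. Thresholds (defaults: 2 samples, pool-size
  floor 1e5 intensity units with 2e6 as the documented alternative preset,
  1% / 3% / 500% labelling bounds) follow their published wording
  literally: "less than", "greater than" are strict, so boundary ties keep
  the metabolite. "Across all conditions" is read as the *sum* over
  (condition, tracer) pairs — the reading under which a 1% lower and 500%
  upper bound are coherent, since one condition's total labelling cannot
  exceed 100% — with a `summed_mode = "max"` switch for the alternative
  reading.
- **Differential labelling score** (`differential_labelling_score()`):
  $|\ln(FE_1/FE_2)| \times (FE_1 - FE_2)$ on total labelling
  ($\sum_{k\ge1}$ FE), with the log arguments clamped below at
  $\varepsilon = 10^{-6}$ so zero enrichments remain scoreable (the
  difference term is unclamped). The 1% labelling pre-filter makes the
  clamp a boundary case in practice. Waterfall ties break
  lexicographically by (tracer, metabolite) so reruns are byte-identical.
- **Sankey flows** (`build_sankey_flows()`): one edge per tracer →
  pathway-representative metabolite, weighted by total labelling, with
  metabolites below the 5% visualization threshold excluded and nodes
  ordered by total flow. Emitted as a CSV edge list and a nodes/links JSON
  consumable by standard Sankey renderers.
- **PQN** (`pqn_normalize()`): reference = per-metabolite median spectrum
  across all samples in the run (the cited method's default; whether the
  reference should be global or per-condition is genuinely open — global
  was chosen as the less assumption-laden option). Metabolites quantified
  in at most half the samples are excluded from quotient computation to
  guard against zero-inflated quotients. Note a subtlety: the quotient
  step is exactly scale invariant per sample *given* a reference, but the
  data-derived median reference itself moves (by at most one order
  statistic per metabolite) when a single sample is rescaled; for this
  reason `pqn_normalize()` accepts an explicit `reference` and the
  invariance property is stated conditionally on it. Pool-size filtering
  uses raw (pre-PQN) intensities by default — enrichment fractions are
  scale-free, so PQN placement affects only pool-size outputs.
- **Pool contrasts** (`pool_contrast()`): unpaired two-tailed t-test per
  metabolite, preceded by an F test of variance equality; Welch's
  correction is applied when the F test gives P < 0.05. No
  multiple-testing adjustment is applied, matching the platform's
  volcano-plot convention.
- **Precursor normalization** (`normalize_to_precursor()`) divides product
  labelling by the cognate precursor isotopologue's FE measured in the
  same condition (per-condition means; the per-sample pairing of
  precursor and product measurements is not generally available in the
  long peak table). Ratios above 1 are flagged, not clamped.
- **Time courses** (`timecourse_auc()`): trapezoidal area under FE(t), the
  comparator used for replete-vs-deprived labelling kinetics; sigmoidal
  dose–response fitting is deliberately out of scope.

## The synthetic-data generator

`ground_truth_model()` emulates the study conditions of a two-condition
profiling run of the full tracer library:

- **Registry**: 30 tracer stocks — the 20 proteinogenic amino acids,
  taurine, ornithine, citrulline, hypoxanthine, uridine, nitrate,
  ammonium, urea, urate, plus an amide-¹⁵N-glutamine positional variant
  (1 labelled atom, against 2 for uniformly labelled glutamine). Each
  entry records the labelled-atom count used for intact-moiety transfer.
- **Catalog**: 127 nitrogenous metabolites with molecular formulas,
  pathway classes and pathway-representative flags (UMP/UDP/UTP for
  pyrimidines, glutamate for amino acids, glutathione for redox, and so
  on). The catalog is a realistic synthetic manifest, not a published
  compound list.
- **Transfer model**: every tracer labels its own nutrient pool through
  the *intact* channel (mass at M+m) at `cognate_fe = 0.5` — tracer
  accumulation in the cognate pool is the platform's validation signal,
  and ~50% steady-state replacement after an 18 h medium exchange is a
  realistic magnitude. A diffuse background `background_fe = 0.02` places
  single nitrogens (M+1) from every tracer in every metabolite, mimicking
  exchange through transamination networks and ensuring unperturbed
  metabolites survive the 1% labelling filter so that ranking tests
  operate on the full pair set. Condition-specific biology is added with
  `plant_differential_flow()`, which records ground truth for analytic
  score computation. The two channels (intact vs single) mirror the
  salvage-type (M+2 from ¹⁵N₂-uridine) versus amide-transfer (M+1 from
  amide-glutamine) readouts of pyrimidine synthesis.
- **Noise**: multiplicative lognormal on intensities, mean 1, default CV
  10% (5% in most tests), applied independently per isotopologue — MS
  intensity error scales with signal, and independent per-peak noise is
  the conservative choice for fraction estimates (perfectly correlated
  noise would cancel in fractions entirely).
- **Design**: n = 1 per tracer per condition by default, matching
  profiling-scale experiments; replicates are configurable for tests that
  need s.e.m. or t-statistics. Pool-size means are lognormal
  (meanlog log(1e7), sdlog 0.5) so all metabolites clear the default
  pool filter; pool variation is not the object of the default model.
- Tracer-free control samples are generated with zero transfer; after
  correction their apparent labelling is attributable only to noise
  (< 0.5% in tests).

What the generator does *not* emulate: kinetic/ODE dynamics, medium
depletion, compartmentation, positional isotopomers, correlated
(batch/drift) noise, missing peaks, and detector saturation. Passing tests
therefore validate the computational pipeline — correction algebra, filter
semantics, score ranking — not instrument behaviour on real extracts.

## Problem sizes and statistical tolerances in the test-suite

The suite exercises the full pipeline at the sizes a desk-scale replication
supports: 1,000 Dirichlet round-trip trials over 20 catalog formulas;
100 seeded replicates each for the branched-chain-amino-acid/glutamine
rediscovery scenario and for top-10 recovery of ten planted flows among
3,810 tracer–metabolite pairs; five 3-replicate runs for end-to-end
transfer-fraction recovery; a 24 × 36 two-region imaging phantom. One
statistical note: at 5% intensity CV with n = 3, a single enrichment
estimate of a 0.5 fraction has sampling error of roughly 0.01 s.d., so
end-to-end recovery is asserted on the error distribution (median < 0.005,
RMSE < 0.02) and on seed-averaged planted flows, not on the maximum over
all ~7,600 estimates, which necessarily exceeds any fixed 2-s.d. bound.

## Known limitations

- Single tracer element per run; dual ¹³C+¹⁵N tracers are out of scope.
- Unresolved mode truncates at M+n rather than extending the matrix.
- "Quantified" is operationalized as intensity > 0; vendor software's
  notion of a detected peak may differ.
- The pixel-grid path starts at exported x/y/intensity tables; imzML and
  vendor formats are not parsed.
- The DLS is a ranking device; no significance is attached to individual
  scores (profiling runs have n = 1 per tracer).
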