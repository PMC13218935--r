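# azotrace

Analysis toolkit for **multiplexed nitrogen stable-isotope tracing**
("nitrogen metabolism profiling"): experiments in which a library of
culture-medium stocks — each replacing one nitrogenous nutrient with its
¹⁵N-labelled counterpart — is used to trace dozens of nitrogen donors in
parallel into the nitrogen-containing metabolome. The package takes the
integrated isotopologue peak tables produced by LC–MS (or per-pixel tables
exported from mass spectrometry imaging) and turns them into corrected
fractional enrichments, quality-filtered labelling matrices, differential
labelling scores, and Sankey flow sets. It is aimed at metabolomics
analysts who already have vendor-integrated peak tables and want the
downstream computation to be scripted, testable and reproducible.

## What it computes

**Natural-abundance correction.** For a metabolite whose formula contains
*n* tracer-element atoms, the observed isotopologue vector *m* (intensities
at M+0 … M+n) is modelled as *m = C x*, where column *j* of *C* is the
theoretical isotopologue distribution of the species with *j* labelled
atoms. At the resolving powers of modern orbitrap/FT-ICR acquisitions the
¹⁵N isotopologues separate from ¹³C interference, so column *j* is the
binomial distribution Binomial(n − j, a) of natural ¹⁵N (abundance
a = 0.003663) over the unlabelled positions, shifted by *j* (an
"unresolved" mode additionally convolves the natural distributions of C, H,
O, S). The true enrichment vector is recovered by non-negative least
squares, min ‖C x − m‖² s.t. x ≥ 0, renormalized to sum to 1. *Fractional
enrichment* (FE) of M+k is x_k; *total labelling* is 1 − x₀.

**Differential labelling score (DLS).** For each (tracer, metabolite) pair
quantified in two conditions,

```
DLS = |ln(FE₁ / FE₂)| × (FE₁ − FE₂)
```

a signed ranking statistic that is zero at equality, antisymmetric, and
grows with both the ratio and the absolute difference of labelling.

**Filter cascade.** Before scoring, metabolites are removed if they were
quantified in fewer than two samples, have a mean pool size below an
experiment-defined threshold, show summed total labelling across all tracer
conditions below 1%, show apparent labelling above 3% in any tracer-free
control sample, or exceed 500% summed labelling. Sankey diagrams
additionally drop metabolites below 5% total labelling.

**Supporting steps.** Probabilistic quotient normalization of pool
intensities, pool-size contrasts with an F-test-gated Student/Welch t-test,
precursor normalization (e.g. UMP labelling over intracellular glutamine
M+1 FE), row-max normalization for heat maps, trapezoidal AUC for labelling
time courses, and per-pixel correction of imaging grids.

**Synthetic data.** A generator (`ground_truth_model()`,
`simulate_peak_table()`, `simulate_pixel_grid()`, `simulate_timecourse()`)
emulates a 30-tracer plasma-like-medium library traced into a packaged
catalog of >100 nitrogenous metabolites, with planted condition-specific
flows and known ground truth, so every stage of the pipeline is testable
without instrument data.

## Worked example

Simulate a two-condition profiling run in which condition A routes
glutamate nitrogen from leucine and condition B from glutamine (the
classic branched-chain amino acid vs glutamine switch), then analyse it:

```r
library(azotrace)

model <- ground_truth_model(noise_cv = 0.05, seed = 42)
model <- plant_differential_flow(model, "leucine",   "glutamate", 0.30, 0.05)
model <- plant_differential_flow(model, "glutamine", "glutamate", 0.05, 0.30)

peaks <- simulate_peak_table(model)   # 27,466 peak records, 62 samples
res   <- run_profiling(peaks, model$catalog, model$registry)

res$filter_report
#> <filter_report> kept 127, removed 0 metabolite(s)

head(res$scores, 3)
#>   tracer    metabolite               fe1    fe2   score  rank
#> 1 leucine   glutamate             0.307  0.0490 0.474       1
#> 2 aspartate glutathione-disulfide 0.0291 0.0179 0.00550     2
#> 3 proline   proline               0.576  0.522  0.00548     3

tail(res$scores, 1)
#>   tracer    metabolite   fe1   fe2  score  rank
#> 1 glutamine glutamate  0.056 0.312 -0.441  3810

res$sankey[["A"]]
#> <sankey_flows> condition 'A': 5 edge(s), 5 tracer(s) -> 3 pathway(s) (threshold 5%)
```

The two planted flows sit at the opposite extremes of the 3,810-pair
waterfall (scores +0.474 and −0.441; the analytic ground-truth score for a
0.30 vs 0.05 contrast is |ln 6| × 0.25 ≈ 0.448), while every unperturbed
pair scores near zero.

The correction machinery is available directly:

```r
cm <- correction_matrix("C5H10N2O3")   # glutamine, 2 tracer atoms
round(cm, 6)
#>          M+0      M+1 M+2
#> M+0 0.992687 0.000000   0
#> M+1 0.007299 0.996337   0
#> M+2 0.000013 0.003663   1

obs <- forward_convolve(c(0.75, 0.20, 0.05), cm)  # generative model
correct_vector(obs, cm)                           # inverse problem
#> <enrichment_vector>
#>   FE: M+0 0.7500, M+1 0.2000, M+2 0.0500
#>   total labelling: 0.2500
```

A thin command-line dispatcher wraps the same functions
(`inst/cli/azotrace.R`, subcommands `simulate`, `correct`, `enrich`,
`filter`, `score`, `sankey`, `run`).

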