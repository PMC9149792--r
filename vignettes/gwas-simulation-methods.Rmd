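---
title: "Simulating and evaluating mixed-model GWAS in structured yeast panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and evaluating mixed-model GWAS in structured yeast panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`gwasim` is a simulation framework for asking a practical question: given a
panel of genotyped individuals — its size, its allele-frequency spectrum,
its relatedness structure — how well will a linear-mixed-model genome-wide
association study (GWAS) detect the variants that causally drive a
quantitative trait? The package grew out of the study design used for
*Saccharomyces cerevisiae* natural isolates, where strongly structured
subpopulations (clonal expansions, domestication lineages) make this
question acute, but every component is generic.

This vignette documents the models, the numerical choices, and the limits
of what the simulations can show.

## The population simulator

`simulate_panel()` draws a haploid (default) or diploid biallelic genotype
matrix under a hierarchical frequency model:

1. **Ancestral spectrum.** Each candidate site gets an ancestral minor
   allele frequency from a `Beta(shape1, shape2)` distribution folded onto
   (0, 0.5]. The default `(0.5, 5)` gives the rapid low-frequency decay
   typical of yeast panels. This is a summary-statistic emulation, not a
   coalescent: the study characterises panels by their singleton fraction
   and MAF spectrum, so those are the quantities the generator controls
   directly.
2. **Clade drift.** Under `structure_model = "clades"` each clade draws a
   drifted frequency from the Balding–Nichols distribution
   `Beta(p(1-F)/F, (1-p)(1-F)/F)`, with `F` the clade's fixation index
   (`clade_divergence`). `F` close to 0 means panmixia; 0.2–0.6 produce
   clearly separated clusters.
3. **Clonal subclade.** `recent_clone_fraction` carves out a group that
   shares a single haplotype per site, drawn once from a heavily drifted
   frequency (`clone_divergence`, default 0.8–0.9 in the presets). This is
   the degenerate limit of relatedness: a very recent common ancestor with
   essentially no within-group mutation. Sites where that haplotype
   carries an allele absent elsewhere segregate at exactly
   `n_clone / n_samples`, which is how a clonal group of ~49% of a panel
   manufactures an excess of markers at MAF ≈ 0.49 — the signature that
   makes sake-like panels pathological for GWAS.
4. **Singletons.** `singleton_rate` is the *realized* fraction of
   variants whose minor allele has exactly one carrier. Low-frequency
   candidates realize singletons naturally; the generator counts them,
   then adds explicit one-carrier variants or drops the excess so the
   realized fraction matches the target. Monomorphic realizations are
   discarded throughout, so a panel holds polymorphic sites only.
5. **Missingness** is missing-completely-at-random at `missing_rate`; no
   informative missingness mechanism is modelled.

Six presets (`panel_preset()`) encode published summary characteristics of
yeast panels: the full 1011-isolate collection, mixed-origin, mosaic,
sake, sampled-diversity and European-wine subsets, spanning n = 47–1011,
nucleotide diversity π = 0.0008–0.0049 and singleton fractions
2.8–54.2%. Marker counts are scaled down (default 10 000 candidate sites);
the genome length that divides π is rescaled analytically so the preset
hits its diversity target at any marker count: the expected per-site
diversity of a candidate is `2 E[p(1-p)] κ`, where `κ` discounts
within-clade pairs by their fixation index (clone pairs count as F = 1),
and each singleton contributes exactly `2/N`. Spectrum shapes and
divergences were calibrated once against the published summaries — e.g.
the sake-like preset uses three internal clades at F = 0.6 plus the 49%
clonal subclade, which reproduces simultaneously its 14.5% singleton
fraction, π = 0.0008, and ~13% of post-filter markers at MAF > 0.45.

What the presets do *not* reproduce: linkage disequilibrium (sites are
exchangeable, so "linked false positives" arise only through relatedness,
not through chromosomal proximity), mutation-rate heterogeneity, and the
absolute marker counts of the real matrices (14k–83k after filtering).
Conclusions about per-scan multiple-testing burden therefore transfer only
qualitatively.

## Trait simulation

`simulate_trait()` implements the standard additive model used by GCTA's
phenotype simulator. For causal set C with effects `b_j ~ N(0, 1)`:

* genetic value `g_i = Σ_{j∈C} w_ij b_j`, with `w` the standardized
  genotype — centered at `ploidy · p_j` and scaled by
  `sqrt(ploidy · p_j (1 - p_j))`;
* residuals `e_i ~ N(0, Var(g) (1 - h²) / h²)`, where `Var(g)` is the
  realized sample variance, so finite panels hit the target heritability
  in expectation (the package records `h2_realized` for every trait);
* `h² = 0` yields a pure standard-normal trait, used for null
  calibration; `h² = 1` returns the genetic values exactly.

Standardization makes the expected variance contribution of a causal
variant independent of its MAF; detection propensity is then governed by
the effect magnitude `|b_j|`, not the frequency — the property-style test
on effect exchangeability checks exactly this. Missing causal genotypes
are mean-imputed, the simplest unbiased choice.

## The mixed-model engine

The association model is `y = Xβ + g + e`, `g ~ N(0, σ²_g K)`,
`e ~ N(0, σ²_e I)`, with `K = W W' / m` the genomic relationship matrix
over the same standardized genotypes (mean diagonal ≈ 1, so
`h² = σ²_g / (σ²_g + σ²_e)` is on the phenotypic scale).

`fit_null_reml()` maximizes the restricted likelihood profiled over the
variance ratio `δ = σ²_e / σ²_g`, using the single-spectral-decomposition
device: with `K = U S U'`, rotating `y`, `X` (and later every genotype) by
`U'` turns the model into weighted least squares with diagonal weights
`1/(S_i + δ)`, so each likelihood evaluation is O(n) after the one-off
O(n³) eigendecomposition. The search is Brent's method on
`log δ ∈ [-10, 10]` with tolerance 1e-6; the profile likelihood is
unimodal on this axis in practice, and the bracket covers
`h² ∈ [5·10⁻⁵, 0.99995]`. An optimum at the bracket edge is flagged
(`boundary = TRUE`) and the heritability estimate clamped to [0, 1].
Eigenvalues are clipped at zero (the GRM is rank-deficient whenever
m < n or duplicated samples are present); the likelihood remains proper
because `δ > 0`.

`association_scan()` tests each variant by generalized least squares in
the rotated space with `δ` held fixed at the null-model estimate — the
"population parameters previously determined" approximation that EMMAX
and FaST-LMM use by default. Covariates (an intercept, by default) are
projected out via a QR decomposition; the per-variant slope then yields a
1-d.f. Wald statistic whose p-value is taken from its asymptotic
chi-square distribution. Two consequences worth knowing:

* **Proximal contamination.** The tested variant stays in the GRM (the
  same marker set builds `K` and is scanned, as in the reference
  single-GRM workflow). With small marker panels and strong single-SNP
  signals the polygenic term absorbs part of the causal signal, deflating
  the genome-wide statistic distribution (λ can sit well below 1 under a
  *signal-bearing* trait at m in the hundreds). This is a documented
  power cost, not a calibration defect — the null-trait λ stays at 1.
* **Finite-sample p-values.** The Wald statistic is exactly the squared
  t statistic of the weighted regression; using the chi-square rather
  than the t reference makes p-values slightly anti-conservative at small
  n. Every significance decision in the framework goes through the
  permutation threshold, which is invariant to any monotone transform of
  the statistic, so this choice cannot distort error rates.

## Permutation thresholds and evaluation

`permutation_threshold()` shuffles the phenotype across samples
`n_perm = 100` times, re-scans the genome for each shuffle, records each
genome-wide minimum p-value, and returns the `ceiling(fwer · n_perm)`-th
smallest — the fifth lowest of 100 at the 5% family-wise error target.
Permutations reuse the unpermuted fit's `δ` rather than refitting REML:
shuffling destroys the genetic covariance, per-permutation REML would
mostly land on the boundary, and reusing `δ` keeps the permuted and
observed statistics on the same scale (it is also what makes a
100-permutation scan affordable: all permuted scans are batched into one
matrix product against the pre-rotated genotypes). Significance is
`p ≤ threshold`, the boundary being attainable by construction.

`genomic_inflation()` divides the median observed statistic by the exact
chi-square(1) median `qchisq(0.5, 1) ≈ 0.45494` (conventionally printed
as 0.456; the difference is < 0.3% and the exact value is used).

`confusion_rates()` classifies every tested variant against the known
causal set: TPR = TP/(TP+FN), TNR = TN/(TN+FP), FPR = FP/(FP+TN),
FNR = FN/(FN+TP). By default a significant non-causal variant counts as a
false positive even if it is strongly correlated with a causal one —
matching the headline convention of the reference study, which inflates
FPR in the presence of linkage or clonal duplication. An optional
`linkage_window` (25 kb suggested) excludes significant non-causal
variants near a causal site from FP/TN and reports them separately, for
sensitivity analysis.

## Study orchestration and problem sizes

`run_study()` chains the per-run pipeline (draw causal set → simulate
trait → fit null REML → scan → 100-permutation threshold → confusion
summary) and aggregates medians and IQRs. The panel-level work — GRM,
eigendecomposition, genotype rotation — is shared across runs, which is
what makes desk-scale replication practical: the default scaled-down
study is 100 runs on ~10 000 markers with 100 permutations each, and the
largest configuration exercised by the acceptance checks (1011 samples ×
10 000 markers × 50 runs) completes in a few CPU-minutes. Reference
results were produced with 1000 runs per condition; 50–100 runs leave
Monte-Carlo error on median rates of roughly ±0.05, which the acceptance
bands account for. Per-run seeds derive from the master seed by a counter
scheme, so any single run can be replayed in isolation.

Known scaled-down biases, deliberately accepted: with 10 000 rather than
~80 000 markers the permutation threshold is less stringent, so absolute
power (TPR) runs higher than the full-scale reference — the complex-trait
TPR lands around 0.6 rather than 0.5 — while orderings between designs
(clonal sake-like worst, sampled-diversity and full-panel best) are
preserved and are what the framework is for.

## Open design choices, resolved

* **Ploidy of the GWAS matrix.** Isolate panels are treated as haploid
  {0,1} by default; diploid {0,1,2} mode shares all code paths (MAF, π,
  standardization use allele counts). The reference pipeline's PLINK
  encoding of haploids as homozygous diploids differs only by a constant
  per-variant scale, which cancels in every statistic.
* **MAF boundary.** A site at exactly the 5% threshold is kept; the
  exclusion rule is MAF strictly below the cutoff.
* **Wald vs likelihood-ratio scan.** The Wald form was chosen because it
  batches across permutations; the two are asymptotically equivalent and
  the permutation threshold removes any residual calibration difference.
* **Fifth-lowest boundary.** Whether the reference procedure used ≤ or <
  at the permutation order statistic is unknowable from its description;
  `p ≤ threshold` was chosen so the threshold itself is attainable.
* **Fresh permutations per run** (rather than a shared permutation set
  across runs), since per-run thresholds are trait-specific.

## Limitations

Beyond the absence of LD noted above: no dominance, epistasis or
gene–environment terms (the additive model is the reference design); no
low-rank speedups for n in the tens of thousands (one dense
eigendecomposition is assumed affordable); no Bonferroni/FDR alternatives
wired into the study loop — the permutation FWER procedure is the only
significance machinery the headline results use.
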