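---
title: "Methods: combinatorial case-control mining of rumen microbiome and host genotype cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combinatorial case-control mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Methane output and feed efficiency in dairy cattle co-vary with the
composition of the rumen microbial community, and a subset of that community
is itself under host genetic control. `rumenmine` implements an analysis
chain that connects the three layers: it labels animals as high or low
emitters from covariate-adjusted trait residuals, mines combinations of
taxon-abundance bins (and SNP genotypes) that discriminate the two groups,
summarises the mined combinations as co-occurrence networks and
differential-enrichment tables, estimates the narrow-sense heritability of
each taxon's abundance with genomic REML, and benchmarks the mined
combinations as classifiers against single-SNP association scans.

Because the cohorts this kind of study uses are not redistributable, the
package ships a synthetic-cohort generator with planted, known truth. Every
claim the pipeline makes is tested against that truth.

## Case/control construction

For each trait the covariates are screened by an L1-penalised linear model
(`select_covariates()`): categoricals are one-hot encoded, the design is
standardised, the penalty is chosen by 10-fold cross-validation with the
one-standard-error rule, and every covariate with a nonzero coefficient is
kept and refit by OLS. Trait residuals from the refit are z-scored using the
sample standard deviation (n − 1). Animals with z > +0.5 become cases,
z < −0.5 controls, and the central band is excluded; the boundary |z| = 0.5
counts as excluded, reading "±0.5 sd" as an exclusion band (`binarize_z()`).
Under a normal residual this excludes 2Φ(0.5) − 1 ≈ 38.3% of animals, which
the tests verify. A percentile variant (`binarize_percentile()`, type-7
quantiles, boundary-inclusive) is provided because both constructions are in
common use; the z form is the default because it retains more animals at
equal classification quality.

## Binning and core-taxon filtering

Relative abundances are binned per taxon into 10 equal-width intervals over
the observed range, following base R's `cut(x, breaks = 10)` convention
(range extended by 0.1% at both ends, right-closed intervals), so the
minimum always maps to bin 1 and the maximum to bin 10. Zeros participate
like any other value and anchor bin 1. An equal-frequency option and a
pooled-distribution option exist behind flags for sensitivity analysis;
per-taxon equal width is the default because it is the documented behaviour
of the utility this field uses.

A consequence worth knowing: on right-skewed (log-normal-like) abundances,
equal-width binning is dominated by the largest observed value. A single
extreme sample can stretch the range until 90–97% of animals sit in bin 1,
which compresses a planted case/control shift into a diluted bin-1 contrast.
In the package's planted-signal experiments (one taxon's latent mean shifted
by 1 sd in cases, 600 animals, 150 taxa, structural-zero rate 0.2), the
mining stage recovers the planted taxon as a validated layer-1 record in
roughly 85% of seeds — the misses are almost entirely seeds where one
outlier collapsed the binning — while false-discovery among the 149 null
taxa stays near 1%. This is a property of the binning convention itself, not
of the implementation; an equal-frequency binning flag exists precisely for
this sensitivity check.

The heritability stage first restricts to "core" taxa: nonzero in at least a
prevalence fraction (70% or 90%) of animals AND in at least a fixed animal
count, both clauses binding independently (`core_taxa_filter()`).

## The combinatorial engine

A combination is a conjunction of feature:bin pairs — an animal *carries* it
when its code equals the stated bin for every pair; missing codes never
match. Layer k combinations contain k pairs with distinct features.

`mine()` evaluates candidates layer by layer. Every candidate's 2×2 carriage
table (cases carrying / not, controls carrying / not) is tested with the
one-sided exact hypergeometric (Fisher) test in both directions; the better
direction is recorded. A two-proportion z statistic is recorded alongside.
P-values are corrected within each layer (Benjamini–Hochberg by default,
Bonferroni optional), and a layer *reports* the records whose adjusted p is
at or below alpha (0.05 default). A support floor (5 carriers by default)
removes untestable candidates.

Search proceeds by extending combinations with one new pair. Statistical
significance is not anti-monotone — a pair can be null marginally and
decisive jointly — so extension deliberately proceeds from the top
`beam_width` candidates of the previous layer ranked by adjusted p, not only
from the significant ones. With the beam disabled the search is exhaustive,
and the test suite proves the beam-disabled miner identical to brute-force
enumeration of all layer-1 and layer-2 candidates on random instances. The
purely epistatic benchmark (two SNPs whose effect exists only in a joint
genotype cell with exactly null additive marginals) is detectable only
because of this design: no layer-1 candidate involving the causal pair is
significant, yet the layer-2 conjunction is found in every tested seed.
Candidates are canonicalised as sorted pair sets so set-equal candidates are
evaluated once; ties in the beam ranking are broken deterministically.

The correction is applied per layer, not jointly across layers, and this
choice (plus the beam width, alpha, correction method and support floor) is
recorded in every result object.

## Networks and enrichment

`build_graph()` turns the records of one direction into a taxon
co-occurrence graph: each record of layer ≥ 2 increments the edge weight of
every unordered taxon pair it contains; layer-1 records contribute isolated
nodes. A node's `abundance_class` is "high" when its modal bin across
contributing records lies in bins 7–9, "low" for bins 1–3, otherwise
"other" (ties give "other"). Total edge weight always equals
Σ records C(layer, 2), which the tests assert.

`taxon_enrichment()` contrasts a taxon's representation between the
case-direction and control-direction outputs with the pooled two-proportion
z test, on either of two bases. The *records* basis compares the fraction of
records containing the taxon. The *animals* basis compares the fraction of
cases carrying at least one containing record against the same fraction of
controls. Both are first-class. Note a structural fact: when a single taxon
drives the signal, its low bins validate control-enriched and its high bins
case-enriched, so the records-basis proportions are near-equal by
construction and only the animals basis detects the shift; the end-to-end
power tests therefore use the animals basis.

## Genotype QC

The chain is: PCA outlier removal (first 5 components of the standardised,
mean-imputed genotype matrix; an animal is flagged when any score is more
than 3 sd from that component's mean — the 3-sd rule is this package's
documented choice), then per-SNP missingness (> 0.05 dropped), minor allele
frequency (< 0.05 dropped, boundary kept), the exact conditional
Hardy–Weinberg test (p < 0.001 dropped), and windowed LD thinning
(r² > 0.8 within sliding windows of 50 SNPs, step 5, dropping the
later-positioned SNP of a violating pair; passes repeat until stable, so the
filter is idempotent). The exact HWE test is used rather than the chi-square
because genotype classes are small near the MAF threshold; it matches full
enumeration to 10⁻¹² for all totals up to 40. MAF is computed after outlier
animals are removed, so the filter order matters and is recorded.

## Heritability and association

The genomic relationship matrix is the standard allele-frequency-scaled
cross-product (`compute_grm()`), G[i,j] = (1/m) Σ_k (x_ik − 2p_k)(x_jk −
2p_k) / (2p_k(1 − p_k)); its diagonal averages ≈ 1 under HWE.

`greml()` fits y = Xβ + g + e, g ~ N(0, G σ²g), e ~ N(0, I σ²e), by
restricted maximum likelihood. The model is rotated onto the eigenvectors of
G once; the total variance profiles out analytically, leaving a
one-dimensional REML deviance in h² = σ²g/(σ²g + σ²e) optimised on [0, 1).
This is exact for a single random effect and fully deterministic — no
iterative AI-REML is needed at this scale. The standard error comes from the
numerical curvature of the profile deviance at the optimum. A GRM
numerically proportional to the identity makes h² unidentifiable; the fit is
then flagged rather than returning an arbitrary number. On simulated traits
(n = 500 animals, 1,000 SNPs, 20 replicates per target), estimates cover the
target within 2 SE in ≈ 96% of replicates and the null-trait median estimate
is ≈ 0.

`heritable_taxa_screen()` runs `greml()` per taxon and keeps taxa with
h² ≥ 0.15 (boundary-inclusive). The trait scale matters for zero-inflated
abundances: a structural zero is non-genetic, so every observed-scale
estimate is attenuated relative to the latent heritability, and a log
transform with pseudocount is the most fragile choice (the zero spike
dominates the variance). The screen therefore exposes three scales — `log`
(default, appropriate for core taxa with few zeros), `int` (rank-based
inverse normal, robust to outliers), and `none` (raw abundance, the scale
reference GREML tooling is typically fed). The analysis scripts use `none`
when zeros are common and say so. A practical resolution limit is also worth
stating: the sampling SD of the REML h² under an HWE GRM is ≈ √(2m)/n
(≈ 0.06–0.09 at the cohort sizes used here), so a screen at a 0.15 threshold
cannot reliably separate a taxon at h² = 0.10 from one at 0.15; the
four-taxon separation experiment in the tests achieves the intended
keep/drop pattern in ≈ 65–75% of seeds for exactly this reason.

`gwas_linear()` is the standard per-SNP additive OLS with fixed covariates,
implemented by projecting the covariates out of both the trait and the
genotypes (Frisch–Waugh–Lovell), which reproduces the full-model t test to
10⁻¹⁰ and scans thousands of SNPs in one pass. Null-trait p-values are
uniform (KS-checked) with 5% below 0.05.

## Classifier evaluation

A combination predicts "case" for carriers; sensitivity, specificity and
Youden's J = sensitivity + specificity − 1 follow (`youden_j()`). A
control-enriched rule naturally has negative J under this convention;
inverting its prediction negates J, which the analysis scripts use to put
both directions on one positive scale. `bootstrap_null_j()` draws random
combinations (distinct features, bins uniform over observed codes) — the
reference is random *combinations*, not resampled animals, because the
question is whether mined combinations beat arbitrary ones.
`compare_top_features()` places the engine and a GWAS on the same scale by
converting each top-ranked SNP to its best single-genotype classifier (the
genotype value maximising J) — a construction of this package, needed
because an additive regression has no intrinsic J.

## The synthetic cohort generator

`simulate_genotypes()` draws per-SNP allele frequencies uniformly from a MAF
range and genotypes as Binomial(2, p) — HWE by construction, verified by the
exact test rejecting at the nominal rate. `simulate_taxa()` gives each
heritable taxon a latent value √h²·g + √(1 − h²)·e, where g is a
standardised polygenic score over a random 10% of SNPs with Gaussian
effects; the latent value plus a per-taxon baseline passes through an
exponential link (right-skewed, strictly positive, resembling 16S relative
abundances), structural zeros are inserted per taxon, and each sample is
closed to sum 1. Realised heritabilities are recorded next to the targets.
`simulate_phenotype()` adds planted taxon effects (in latent-sd units),
categorical and continuous covariate effects, and Gaussian noise.
`simulate_cohort()` optionally plants an engine signal by designating
prospective cases from the phenotype's non-covariate residual and shifting
one taxon's latent mean by δ in those animals — giving a known ground-truth
taxon:bin enrichment.

Defaults were fixed once to mirror a multi-country dairy cohort: 1,000
animals, 2,000 SNPs with MAF ∈ [0.05, 0.5], 150 order-level taxa,
structural-zero rate 0.2, four countries / ten farms / two breeds, unit
phenotype noise. What the generator deliberately does not emulate: taxon–
taxon ecological interactions, phylogenetic correlation among taxa, LD
between SNPs (each SNP is drawn independently, so the LD-thinning filter is
exercised by planted duplicates in tests rather than by the cohort),
sequencing-depth variation, and breed-stratified allele frequencies. Tests
passing on this cohort therefore demonstrate statistical correctness of the
machinery, not robustness to every failure mode of real 16S data.

## Problem sizes and numerical choices

The test-suite experiments use: exact-test enumeration to totals 30 (2×2)
and 40 (HWE); 50 random miner-oracle instances at 8 features × 30 samples;
100 end-to-end planted-signal cohorts at n = 600 × 150 taxa; 80 REML
recoveries at n = 500 × 1,000 SNPs; 20 screen cohorts at n = 1,000 × 2,000
SNPs; 50 epistasis cohorts at n = 600 × 100 SNPs; the analysis scripts run
one n = 600 cohort. Ties at the exclusion-band boundary are excluded;
ties in beam ranking break on the canonical pair string; the two-proportion
z is defined as 0 (p = 1) when the pooled proportion is degenerate;
constant taxa bin to 1 with a warning; monomorphic SNPs are skipped by the
GRM and flagged NA by the GWAS. All randomness flows from explicit integer
seeds and every stage is byte-identical on re-run.

## Known limitations

- Equal-width binning on heavy-tailed abundances is outlier-sensitive (see
  above); use the equal-frequency flag as a sensitivity check.
- The REML screen's resolution near the 0.15 threshold is bounded by
  √(2m)/n; cohorts below ~1,500 animals cannot make a sharp 0.10 vs 0.15
  distinction.
- The layer-wise beam search is deterministic but not guaranteed complete
  when the beam truncates; completeness holds exactly when the beam is
  disabled.
- Per-layer multiple-testing correction does not control the FDR jointly
  across layers.
- No mixed-model (GRM-adjusted) association scan; confounding by cryptic
  relatedness in the GWAS comparison is out of scope.
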