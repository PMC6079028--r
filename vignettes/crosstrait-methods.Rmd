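---
title: "Methods: cross-trait proxy-phenotype analysis and its synthetic testbed"
author: "crosstrait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-trait proxy-phenotype analysis and its synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the statistics it implements,
the choices made where the design was genuinely open, and what the
synthetic-data generator does and does not emulate. Nothing here states
an empirical result that the test suite or `scripts/acceptance.R` does
not itself compute.

## 1. The analysis chain

### Harmonization

Two GWAS summary-statistics tables are reduced to one aligned SNP
universe: intersection on SNP id; trait b re-expressed on trait a's
allele coding (sign-flipping the beta and folding the allele frequency
when the effect/other alleles are swapped); non-ACGT or irreconcilable
allele pairs dropped; optionally A/T and C/G strand-ambiguous SNPs
dropped. Positions are 1-based and every window in the package is
inclusive on both ends.

Three QC filters mirror common practice and are applied in a fixed,
documented order (alleles → coverage → allele-frequency divergence), so
every dropped SNP is attributed to exactly one first-failing rule and
`QcReport` drops always sum to `n_input − n_output`:

* **Coverage** (`coverage_filter`): keep SNPs with `n_eff ≥ min_n`.
  `n_eff` is deliberately unit-agnostic — a per-SNP sample size or a
  cohort count both work, since real files report either.
* **Allele-frequency divergence** (`maf_divergence_filter`): drop SNPs
  in the extreme tails of the distribution of *signed* differences of
  aligned effect-allele frequencies (default 1st and 99th percentile).
  Signed differences (not absolute) are used because a two-tailed
  percentile rule implies a signed distribution. Percentiles are
  computed with `quantile(type = 6)` — the linear-interpolation
  definition that treats the two tails symmetrically, so bounds of
  1/99 on 1,000 distinct values drop exactly 10 per tail. The filter
  runs after allele alignment, so a strand flip shows up as a large
  frequency divergence, which is exactly what the filter is for.

### Proxy-phenotype lookup

Lead SNPs are selected on the better-powered proxy trait by greedy LD
clumping (`ld_clump`): repeatedly take the smallest-P unassigned SNP
with `P < 1e-5` as a lead and assign to it all unassigned SNPs within
the window with `r² > 0.1`; iterate until no eligible SNP remains. This
is the PLINK clumping algorithm; a window set larger than any chromosome
makes clumping effectively chromosome-wide, and the parameter is honored
literally so users can reproduce that idiom. SNPs absent from the
reference panel are kept as their own leads with a warning — dropping
them silently would bias lead counts.

The second stage looks the leads up in the target trait at the
preregistered family-wise level: `P_target < alpha / n_leads`. The
Bonferroni denominator is always the number of *selected* leads, even if
some are missing from the target file (they are reported with a missing
flag); shrinking the denominator post hoc would be anti-conservative.

### Enrichment statistics

* **Raw enrichment** (`raw_enrichment`): with `N_T` independent leads
  overall and shares `τ_proxy`, `τ_target` below the two thresholds, the
  expected double-threshold count under independence is
  `N_T · τ_proxy · τ_target`; the factor is observed/expected.
* **MAF-matched rank test** (`draw_matched_null`,
  `mannwhitney_enrichment`): each lead is matched to `k` pool SNPs with
  folded MAF within one percentage point, drawn without replacement
  *globally* — reuse across leads would create duplicate ranks in the
  Mann–Whitney statistic. MAF for matching is the folded frequency of
  the target-trait file. The test is the two-sided normal approximation
  with tie correction; the suite cross-checks it against
  `wilcox.test(exact = FALSE, correct = FALSE)`.
* **Sign concordance** (`sign_concordance_test`): exact binomial at
  p = 1/2, two-sided by doubling the smaller tail (capped at 1). Tail
  doubling, not the minimum-likelihood convention, is used because it is
  the standard convention at p = 1/2 and reproduces the published
  P values (0.40 for 263/506, 0.38 for 13/21) to the printed digits.
  Exact-zero betas carry no sign and are excluded with a message.
* **Novelty proportions** (`novelty_proportions_test`): two-sided
  Fisher's exact test (the minimum-likelihood convention of R's
  `fisher.test`). The published 2×2 comparison (6/110 vs 50/51,528) is
  reproduced by the table `(6, 104; 50, 51478)`, i.e. with the
  six proxy-informed novel SNPs also counted inside the 50 — that
  reading yields 2.4×10⁻⁹ and is the one used in `reference_checks()`.

### Winner's curse, power, credibility

Selected effect estimates are biased away from zero. The corrected
estimate (`winners_curse_correct`) is the conditional MLE under the
normal model truncated to the selection region `|beta|/se ≥ z(alpha/2)`,
found by 60 steps of monotone bisection on `[0, beta_hat]` (sign-
symmetric, so the correction never crosses zero). For this family the
conditional MLE provably coincides with inverting the conditional mean
`E[beta_hat | beta, selection]` — the score equation *is* the
mean-matching equation — so the `method = "mean_inversion"` flag is an
alias kept for sensitivity-analysis interfaces, and the test suite
asserts the equivalence. The meaningful simulation oracle is therefore
inversion: the correction applied to a Monte-Carlo estimate of the
conditional mean recovers the generating effect (to ~0.5% at 10⁵
accepted draws). No deterministic correction can make the *per-draw
average* of corrected estimates unbiased (Jensen's inequality); the
suite documents this by testing the inversion property.

Power at the selection threshold is `Φ(−c + β/se) + Φ(−c − β/se)`.
When per-SNP standard errors are not reported, they are reconstructed
from the case-control design as
`se = sqrt(1/(2·maf·(1−maf)) · (1/n_cases + 1/n_controls))`. The
published per-SNP power values are *not* recoverable by this (or any
standard) reconstruction from the printed OR/EAF/N — so when
`credibility_table` is asked to reproduce published posterior columns,
printed power is accepted as an input (`power =`), and the package's own
power path is used otherwise.

Odds ratios convert to variance explained through Cohen's d:
`d = ln(OR)·√3/π`, `a = 1/(maf(1−maf))`, `R² = d²/(d²+a)` — the group
imbalance factor `(n₁+n₂)²/(n₁n₂)` with group sizes proportional to
allele frequencies. The posterior probability that a significant
association is true is `power·π / (power·π + α·(1−π))`. One published
posterior (62.2% at printed power 1.6%) differs from the formula's 62.06%
— consistent with the printed one-decimal power being a rounded input —
and the formula is implemented as written, not imitated.
`implied_causal_count(h2, r2_max) = h2 / r2_max` gives the
equal-effects lower bound on the number of causal loci used to anchor
the most skeptical prior.

### LD scores and the LD-aware enrichment test

`ld_scores` computes `ℓ_i = Σ_k r²_ik` over a window (self term
included, so `ℓ ≥ 1`), with an optional finite-sample adjustment
`r² − (1−r²)/(n−2)` floored at 0. The floor leaves a small positive
residual (~`0.4·m/n`) on truly unlinked panels; the tests account for
this rather than hide it.

The LD-aware test asks whether a candidate SNP's association exceeds
what its LD score predicts for a purely polygenic trait:
`E[χ²] = N·h²·ℓ/M + (1+Na)`. Each observed z is tested against a normal
with that variance; per-SNP P values are combined with Fisher's method
(`−2Σln p ~ χ²(2k)`), with a documented floor of 1e-300 for zero
P values. h² and intercept come either from `fit_h2` or from user
config, since published estimates are often preferable. Candidates
missing from the LD-score universe get the best proxy with `r² > 0.8`
within 500 kb; the implementation warns when two combined SNPs lie
within 1 Mb, because Fisher's method assumes independence and proxy
substitution could silently reintroduce LD. The test also inherits
LD-score regression's assumption that allele frequency is uncorrelated
with effect size; the generator's `maf_effect_coupling` mode exists to
*demonstrate* that limitation, not to fix it.

### LDSC-lite

`fit_h2` regresses per-SNP χ² on `N·ℓ/M` with weights `1/(2·E[χ²]²)`
iterated twice from an OLS start — a deliberately "lite" scheme adequate
for synthetic calibration, not a replica of the reference
implementation's weighting (hence no numerical-parity claim). No χ²
cap is applied by default (synthetic data has no confounded outliers);
a `chisq_max` flag exists. Standard errors via an optional delete-one
block jackknife, off by default. `fit_cross` regresses `z_a·z_b` on
`√(N_a N_b)·ℓ/M`; the intercept estimates the estimation-error
correlation induced by sample overlap, and `r_g = cov_g/√(h²_a h²_b)`.

A design fact worth knowing: with `N/M` large the regressor `N·ℓ/M`
never approaches zero, so the intercept is an extrapolation and is
estimated with considerable noise. This is inherent to the model, not a
defect of the fit; the GWIS wrapper therefore clamps the implied overlap
correlation to `[−1, 1]` with a warning.

### GWIS

The purged trait is `eff_e = eff_a − β·eff_b` per SNP with
`β = cov_g(a,b)/var_g(b)` and delta-method standard error
`sqrt(se_a² + β²se_b² − 2β·ρ·se_a·se_b)`, with ρ the overlap-induced
error correlation (from the cross-trait intercept, or supplied). β is
treated as fixed — the first-order delta method — with an optional
`beta_var` term that propagates β's sampling variance for sensitivity
analysis, since the literature's exact convention is ambiguous. All
effects are put on the standardized z-derived scale `z/√n` before
purging, so the LD-score scale and the per-SNP scale agree; `var_g(b)`
is estimated by the *self-cross* regression (the same design and
weighting as the covariance fit), which makes the purge cancel the
shared component structurally rather than up to two independent fits'
noise. Variance exactly zero occurs only for complete annihilation (a
trait purged of itself at β = ρ = 1), where the effect is exactly zero;
`z` is defined as 0 there. GWIS input is aligned with strand-ambiguous
SNPs dropped — stricter than the lookup QC, matching how derived traits
are usually built. The output is a standard summary-statistics table,
so every other stage consumes it unchanged.

### Polygenic scores and the heterogeneity F test

Scores are built by MAF filter → clump → weight extraction, with
natural-log odds-ratio weights for case-control sources. Two
sign-concordance split strategies exist: partitioning the already-pruned
parent (conservative: LD-pruned within and across halves; the halves
partition the parent exactly) and sign-sorting the full SNP set before
within-half clumping (more SNPs, since cross-half LD is not pruned; on
LD-blocked data it demonstrably retains more SNPs, which the suite
asserts directionally).

Scoring uses the sum convention `Σ weight·dosage` by default because it
makes the baseline model (outcome ~ parent + companion + covariates)
*exactly* nested in the split model (outcome ~ concordant + discordant
+ companion + covariates): the parent score vector is identically the
sum of its halves, to 1e-12. The per-allele average convention is
available for parity with common scoring tools, with the caveat that
nesting then holds only approximately. All scores are standardized to
unit variance within the complete-case analysis sample (standardizing
before the complete-case restriction would leak excluded individuals
into the scale). The F statistic is
`((SSR_base − SSR_split)/1) / (SSR_split/(n − p − 1))`; case-status
outcomes use a linear probability model by default. The random-split
control repeats the test on uniformly random partitions of the parent
that preserve the observed half sizes, making the permutation F
distribution directly comparable.

## 2. What the generator emulates — and what it does not

`architecture_spec` + `simulate_study` produce: a variant map on 22
autosomes with LD blocks 5 Mb apart (SNPs 1 kb apart within a block, so
1 Mb clumping windows never bridge blocks); Gaussian-copula genotypes —
per gamete, a block-shared latent factor mixed at `√r` with noise and
thresholded at the MAF quantile, dosage = sum of two gametes — giving
Hardy–Weinberg dosages with exchangeable within-block LD; a five-class
effect mixture (concordant, discordant, specific-a, specific-b, null)
with per-class variances scaled so total genic variance equals each
trait's h²; a quantitative proxy trait; a liability-threshold
case-control target trait with balanced ascertainment (all cases plus an
equal number of controls, `n_eff` = included count); a third trait
sharing the concordant component (a planted truth for purging); and a
patient cohort of cases and screened controls with symptom measures
(loadings on the standardized concordant/discordant genic components)
and genetic principal components. All cohorts are sample-disjoint by
construction, and everything is bit-reproducible from (spec, seed) via
the per-stage seed scheme `seed·1000 + stage`.

Sign-matched effect pairs have per-class effect correlation `2/π`
(folded-normal moments), so the implied cross-trait effect correlation
is `(2/π)(f_conc − f_disc)·√(v_a v_b)/√(h²_a h²_b)` — computable in
closed form (`implied_rg`) and zero at the default balanced mixture:
the generator's defaults *are* the study's hypothesized pattern, strong
dependence with vanishing correlation.

**Default parameter choices.** 20,000 SNPs in 2,000 blocks of 10;
per-block latent correlation uniform on (0.3, 0.9) — real genomes have
variable LD, and constant-r blocks would make all LD scores in a block
identical, degrading every LD-score regression; MAF uniform on
(0.05, 0.5); class fractions 0.25/0.25/0.10/0.10/0.30 — the hypothesis
under study is an architecture *dominated* by shared loci of mixed sign;
h² = 0.25 (proxy trait) and 0.21 (target liability), the latter chosen
to match the familiar SNP-heritability scale of schizophrenia;
prevalence 0.10 — a desk-scale compromise: at the clinical ~1% a
balanced case-control cohort would need implausibly large simulated
pools; one symptom with loadings ±0.6 and noise sd 0.53, sized so the
planted heterogeneity is a clear, well-powered demonstration at patient
cohorts of several hundred cases. These are demonstration conditions,
set once; they are not estimates of real-world quantities.

**What passing tests do not show about real data.** The copula
genotypes have no realistic allele-frequency spectrum, no long-range LD,
no population structure (the patient PCs capture noise, standing in for
the covariate role real PCs play), no imputation error, and blocks are
exactly independent. The case-control GWAS uses one-step logistic score
statistics, not full logistic fits. Ascertainment is balanced by fiat.
Assortative mating is a simplified rank-matching model with Mendelian
offspring sampling — adequate to show the directional effect of
assortment on genic variance, not a demographic model. Consequently the
calibration and recovery results here validate the *statistics*, not
any claim about real cohorts.

## 3. Numerical choices and degenerate inputs

* Percentiles: `type = 6`; windows inclusive; positions 1-based.
* Binomial two-sided P: tail doubling, capped at 1.
* Fisher-combination floor: 1e-300; P values from z statistics floored
  at 1e-320 before table validation (which requires P ∈ (0, 1]).
* Bisection for the winner's-curse MLE: 60 iterations on `[0, z]`,
  vectorized; at `|z| = c` the corrected effect approaches 0 but the
  bracket guarantees it never crosses.
* Monomorphic SNPs: GWAS emits them with undefined statistics and a
  warning; table validation then drops and counts them.
* LD r² on pairwise-complete dosages, no imputation; fewer than 3
  complete pairs or a monomorphic variant is an explicit error.
* Proxy ties: highest r², then smaller distance, then lexicographic id.
* Clump ties: smaller P, then lexicographic id.
* `rg` is flagged undefined when either h² estimate is non-positive.

## 4. Problem sizes used by the test suite

The statistical acceptance checks run at sizes chosen to finish a full
suite comfortably on one CPU while leaving each check well-identified;
the vignette records them as the package's own study design:

* Winner's-curse inversion: 10⁵ accepted draws at β₀/se ∈ {3, 4, 5},
  α = 0.05/506.
* Enrichment-test calibration: 600 null replicates of 25-SNP panels;
  10⁴ draws for per-SNP uniformity.
* Matched-null negative control: 60 seeds, 40 leads × 10 matches.
* LDSC-lite and GWIS: 4,000 SNPs in 1,000 blocks (per-block r uniform on
  (0.5, 0.95)), reference panel n = 1,500, GWAS cohorts n = 12,000,
  six replicate effect+cohort draws; the GWIS study plants
  h² = 0.5 traits with 40% of the auxiliary trait's genic variance from
  the shared component.
* Heterogeneity F test: 4,000 SNPs, proxy GWAS n = 16,000, target
  GWAS pool n = 20,000 (≈2,000 cases), patients n = 1,000 (≈500 cases);
  four heterogeneous seeds plus a null-loadings study with 16
  regenerated patient cohorts; 100-permutation random-split controls.

## 5. Known limitations

* LDSC-lite is not numerically interchangeable with the reference
  implementation (different weighting and no χ² filtering by default);
  it is calibrated on the generator, not on real traits.
* The LD-aware enrichment test treats proxied candidates as independent;
  the 1 Mb proximity warning is a guard, not a correction.
* The winner's-curse correction conditions only on the selection event
  at the stated α; two-stage selection designs (select on one trait,
  test on another) induce milder curses that this deliberately does not
  model.
* Case-status prediction by linear probability model is a convenience;
  no pseudo-R² parity with published patient-cohort tables is claimed,
  and reproducing those tables requires the original individual-level
  data.
* `n_eff` for ascertained case-control GWAS is the included sample
  count; liability-scale conversions of h² are out of scope.
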