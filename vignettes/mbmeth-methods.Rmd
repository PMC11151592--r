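---
title: "Methods: microbiome-methylome association screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microbiome-methylome association screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbmeth)
```

This vignette is the package's account of its statistical machinery: the
models, the defaults and why they are set where they are, what the
synthetic-data generator does and does not emulate, and the places where
the design was genuinely open and a choice had to be made.

## The problem

Paired tumor / adjacent-normal studies of colorectal cancer produce, for
the same subjects, a tissue microbiome profile (16S or metagenomic taxa
abundances) and a base-resolution DNA methylome (WGBS counts). The
scientific question — which taxa co-vary with methylation at which CpG
loci — is a screen over tens of thousands of locus-by-taxon hypotheses
with a few dozen samples, compositional predictors, and overdispersed
count responses. Each stage of the package addresses one layer of that
problem; the synthetic generator supplies cohorts with *planted, recorded
truth* so that the whole chain can be validated end to end.

## Synthetic cohorts

`sim_config()` fixes the study design; its defaults describe the
reference conditions used throughout the tests: 40 samples, 50 taxa, 200
CpG loci, 20 planted taxon-locus pairs with |β| = 0.8 (logit scale per
CLR unit), beta-binomial dispersion φ = 0.05, mean coverage 30×, and the
three clinical covariates (gender ~ Bernoulli(0.5), age ~ Uniform(40, 80)
years, disease subtype ~ Bernoulli(0.5)) with modest planted effects
(0.3, 0.01 per year, 0.3 on the logit scale). The paired
differential-methylation design uses 13 samples per group — the size of a
typical WGBS arm — with 50 planted loci at Δ = 0.3.

*Taxa.* Per-sample log abundances are normal around a fixed community
mean; the softmax gives the composition and counts are multinomial at
10⁵ reads. The log-normal spread (default SD 1) produces realistic
between-sample variation and, with 50 taxa of community mean drawn from a
standard normal, keeps essentially every taxon above the 10⁻⁴/10%
retention rule, matching the "50 taxa after filtering" design. A
Dirichlet-multinomial variant is available (`dirichlet = TRUE`) but not
the default — the log-normal model is the simplest one giving
overdispersed counts. The *true* compositions are carried on the table so
oracle comparisons never re-estimate them.

*Methylome.* Locus baselines αₗ are normal on the logit scale (mean 0,
SD 1.2: levels concentrated away from the boundaries but spanning them).
For sample *s*, p(ℓ,s) = logistic(αₗ + Σₖ βₗₖ·clr(x)ₛₖ + covariates);
coverage is gamma-Poisson (shape 10, so coverage CV ≈ 0.33, typical of
WGBS) floored at one read, and methylated counts are beta-binomial via a
latent Beta(p(1−φ)/φ, (1−p)(1−φ)/φ) draw. φ = 0 degenerates exactly to
binomial sampling, which the tests exploit as a variance oracle.

*Two-group methylomes.* Both groups share the baselines; planted loci
shift the tumor-like group by Δ on the proportion scale. Baselines of
planted loci are drawn inside the subinterval of (0.02, 0.98) that keeps
both group means in (0, 1); a configuration that cannot satisfy this
raises an error rather than silently truncating.

*Meta-cohorts.* Study effects θᵢ ~ N(θ, τ²); transformed abundances are
normal with SD 0.12 around 0.7 (safely inside [0, π/2], so the
back-transform sin²(t) stays in [0, 1] without distorting the planted
effect), and the case mean is shifted by θᵢ·SD so that the
arcsine-square-root scale realizes θᵢ exactly.

*Seeding.* A single integer seed drives one RNG substream per component
(taxa, covariates, truth, methylome, coverage, folds, subsampling), so
enlarging one component does not perturb another's draws, and every
serialized artifact is byte-reproducible.

What the generator does **not** emulate: read-level sequence data,
bisulfite conversion error, 16S copy-number bias, spatially structured
methylation (baselines are exchangeable across loci), phylogenetic
correlation among taxa, or batch effects. Passing tests therefore
demonstrate statistical correctness of the chain under a faithful but
idealized data model, not robustness to every artifact of real cohorts.

## Differential methylation

The depth rule keeps loci with coverage ≥ 10 in *every* sample of the
comparison. The source convention ("depth greater than 10×") is ambiguous
about strictness and scope; requiring all samples guarantees each
retained locus has a complete design, at the cost of dropping ~20% of
loci at 30× coverage with 26 samples.

Smoothing is a coverage-weighted moving average: summed X over summed N
within ±250 bp on the same chromosome. It is the transparent, exactly
testable counterpart of the smoother inside dedicated WGBS packages,
whose internals are not re-specified here. `window_bp = 0` disables it;
isolated loci are returned as raw X/N.

The Wald test puts coverage-weighted group means of smoothed levels in
the numerator and beta-binomial variances in the denominator, with φ per
locus and group by method of moments, floored at 0 and capped below 1.
Degenerate loci (a group constant at 0 or 1) get the standard error
floored at 10⁻⁸ with a warning rather than NaN. DML thresholds are the
conventional |Δ| > 0.20 with q < 0.05 (BH in one family per comparison).
DMR construction merges same-sign qualifying loci with gaps ≤ 100 bp and
keeps regions with ≥ 3 CpGs, ≥ 50% individually significant members, and
|mean Δ| > 0.20; the gap/size/fraction parameters are exposed because
only the Δ and q thresholds are fixed by convention. A sign flip splits a
run: a hyper- and a hypomethylated stretch are never one region.

## The association screen

The response is the smoothed methylation proportion per locus — the same
quantity the DML stage tests. Predictors are CLR-transformed taxa
(pseudocount: half the smallest non-zero relative abundance, applied only
when zeros exist — the standard compositional convention) plus the three
covariates, all standardized. Zero-variance columns are dropped with a
message; loci with response variance below 10⁻⁸ are skipped.

**Initial fit and noise level.** Each locus is fitted with the scaled
lasso — alternating σ̂ = RSS/n with a lasso at λ = σ̂·λ₀ — at
λ₀ = 0.7·√(2·log p/n). The full universal level √(2 log p/n) over-shrinks
at n = 40: too much signal is left in the residual, σ̂ inflates, and
power at the downstream FDR gate suffers. Choosing λ by per-locus CV
(lambda.min) has the opposite failure: under the null the fit absorbs
noise, σ̂ collapses, and the screen becomes anti-conservative. The 0.7
factor sits between the two regimes; the null-calibration and
planted-recovery studies in the acceptance suite verify both sides under
the reference conditions.

**De-sparsified inference.** bⱼ = β̂ⱼ + Zⱼᵀ(y − Xβ̂)/(ZⱼᵀXⱼ) with Zⱼ the
residual of a nodewise lasso of Xⱼ on the other columns (λ by 10-fold CV
with the 1-SE rule, folds seeded; computed once per design and reused
across all loci). The standard error is σ̂‖Zⱼ‖₂/|ZⱼᵀXⱼ|.

p-values use a **t reference with n − df̂ − 1 degrees of freedom** (df̂ =
active-set size), with σ̂ correspondingly df-corrected, rather than the
normal limit. The reason is quantitative: pooling all locus × predictor
tests into one BH family of ~10⁴ tests means discoveries live at the
10⁻⁵–10⁻⁷ quantiles, where at n = 40 the Gaussian tail is more than an
order of magnitude too light — a normal reference produced spurious
"retained" associations on fully null cohorts. The t reference restores
null control there and, as a bonus, makes the low-dimensional λ→0 limit
reproduce the classical OLS t-test exactly. At n = 100 and the 0.05
level, t and normal differ by well under one percentage point, so
moderate-level calibration is unaffected.

A column whose nodewise projection explains it (almost) perfectly —
duplicated predictors are the canonical case — has ZⱼᵀXⱼ ≈ 0 and no
identifying variation; such columns are flagged and assigned p = 1
rather than an unstable small p. Note that a CLR block is rank-deficient
by construction (rows sum to zero); the nodewise *lasso* residual retains
identifying variation in practice, but exact duplicates do not.

**Multiplicity.** The default BH family is global (all loci × predictors
together); `family = "per_locus"` adjusts within each locus instead. The
source convention does not scope its correction; the global family is the
stricter and simpler default.

**Stability selection.** Complementary pairs: B = 50 random splits into
two disjoint halves of ⌊n/2⌋, so 100 half-sample fits per locus. Each
fit follows the lasso path from λ_max downward and keeps the first
q = ⌈√p⌉ predictors to enter; the selection frequency across half-samples
is thresholded at 0.75, and the expected-false-positive bound
q²/((2·0.75 − 1)·p) is attached to every result. The subsample fits run
in compiled code (coordinate descent with entering-order tracking, active
set updates, path of 40 λ values to 0.02·λ_max): only the *identity* of
the first entrants is needed, so a moderate coordinate tolerance (10⁻⁴)
suffices and the same subsamples are shared across loci. B, q and the
cutoff are exposed because no reference values exist for them; the
defaults are the common ones in the stability-selection literature.

**Retention contract.** retained = (q < 0.1) ∧ (stab_freq ≥ 0.75) ∧
(predictor is a taxon). Gender, age and subtype rows are kept in the
output for inspection but can never be retained findings.

## Region annotation and enrichment

Gene models are single-TSS records with optional first-exon and UTR
intervals. TSS flanks are strand-aware: TSS200 is the 200 bp immediately
upstream of the TSS in transcript orientation, TSS1500 the 201–1500 bp
band. Within a gene the precedence is 5′UTR → first exon → 3′UTR → body:
since the sub-gene intervals lie inside the gene body, the body must be
checked *after* the features it contains or the 3′UTR category could
never be assigned. Loci are attached to the nearest TSS on their
chromosome (ties broken lexicographically by gene id), and a locus
matching none of its nearest gene's categories is intergenic. Enrichment
of a hit set against a background is the one-sided hypergeometric upper
tail; the odds ratio uses Haldane's 0.5 correction for empty cells,
except that a hit set exhausting the background reports the neutral OR
of 1. BED interfaces convert between the package's 1-based inclusive
coordinates and BED's 0-based half-open convention.

## Meta-analysis

Group summaries are computed on arcsine-square-root transformed relative
abundances. Hedges' g uses J = 1 − 3/(4·df − 1) and the usual
large-sample variance (n₁+n₂)/(n₁n₂) + g²/(2(n₁+n₂)). Pooling is
DerSimonian–Laird by default — closed-form, hence exactly testable
against its textbook formula — with REML as an option (profile
likelihood maximized on a bracket that is re-expanded if the optimum
lands on its edge). CIs and p-values are Wald-normal without the
Knapp–Hartung adjustment, matching common defaults. The screen flags a
pathway only when I² < 50% *and* BH q < 0.05 across pathways: a strong
but heterogeneous effect is deliberately not reported. Direction
convention: group 1 is the case group, so positive g means higher in
cases.

## Numerical choices and degenerate inputs

- glmnet is always called on pre-standardized designs
  (`standardize = FALSE`) with seeded folds; fixed-λ solutions are read
  off a warm-started path ending at the target (threshold 10⁻¹²), which
  is what makes the λ = 0 limit agree with `lm()` to machine precision.
- The scaled lasso iterates to a 10⁻⁴ relative tolerance on σ̂ (at most
  25 iterations), with σ̂ floored at 10⁻⁸; constant responses return the
  zero fit.
- PCoA axes are ordered by eigenvalue and sign-fixed so the
  largest-magnitude loading is positive, making ordinations reproducible
  across platforms.
- Pielou evenness at S = 1 returns 0 with a warning (H/ln S is 0/0);
  Chao1 uses F₁²/(2F₂) with the bias-corrected F₁(F₁−1)/2 fallback when
  no doubletons exist; ACE uses the abundance-coverage estimator with
  rare threshold 10 and falls back to a Chao1-style correction when the
  rare group is all singletons.
- Paired global comparisons use the exact signed-rank distribution
  whenever R's implementation allows it (no ties among non-zero
  differences); an all-zero difference vector returns p = 1 directly.
- All-zero samples are errors for CLR and Bray–Curtis; empty filter
  results warn (taxa) or error with a count (depth filter).

## Problem sizes in the tests

The acceptance studies run at the reference design: 20 planted and 20
null association cohorts, 500 calibration replicates at n = 100 /
p = 150 over a fixed design, 100 stability-selection null replicates,
1000-locus DML cohorts with 5 power replicates, 200 simulated
meta-analyses for τ² recovery, and two full pipeline runs compared
checksum-for-checksum. These sizes give Monte-Carlo error comfortably
inside the margins being tested while keeping the suite to a few
minutes on a single core.

## Known limitations

- The screen treats loci independently; with the default 100-bp CpG
  spacing the 500-bp smoother couples neighboring loci, so per-locus
  effect attribution is cleanest when loci are ≥ window/2 apart (the
  synthetic association scenarios space loci 1000 bp apart for exactly
  this reason). A locus-cluster-aware screen is out of scope.
- De-sparsified inference assumes approximately sparse true signals and
  homoscedastic noise; methylation proportions are mildly
  heteroscedastic by construction, which the t reference does not fully
  absorb.
- The stability PFER bound is an expectation bound under exchangeability
  assumptions; it is verified empirically on the synthetic null, not
  proven for arbitrary designs.
- Meta-analysis pools study-level summaries only; no publication-bias
  diagnostics or influence analysis are provided.
- Gene models carry one TSS per gene: multi-isoform promoter structure
  is not resolved.
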