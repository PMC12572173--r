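---
title: "Methods: a three-stage Mendelian randomisation screen with mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a three-stage Mendelian randomisation screen with mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the design

Adiposity raises the risk of several cancers, and circulating metabolites
are plausible intermediates on that path. `mrtriad` implements a three-stage
two-sample Mendelian randomisation (MR) screen over GWAS summary
statistics:

1. **Stage 1** estimates the causal effect of an anthropometric exposure
   (e.g. BMI or waist-hip ratio) on each plasma metabolite, keeping the
   Bonferroni-significant metabolites that survive a sensitivity battery.
2. **Stage 2** estimates the effect of each surviving metabolite on the
   risk of a binary disease outcome, expressed as an odds ratio per SD of
   the metabolite, gated by the same sensitivity battery, an optional
   replication dataset, and enumeration colocalisation.
3. **Stage 3** quantifies how much of the exposure's total effect on the
   outcome is mediated by each surviving metabolite, by the multivariable-MR
   difference method with a product-of-coefficients fallback.

All stages operate on one tabular currency — a `sumstats` tibble with one
row per variant (GRCh37 coordinates, effect/other allele, EAF, beta, SE,
p, n) — and an LD reference panel of genotype dosages.

## Core estimators

With harmonised per-variant effects $(\hat\beta_{X_j}, \hat\beta_{Y_j})$
and SEs, the single-instrument **Wald ratio** is
$\hat\theta_j = \hat\beta_{Y_j}/\hat\beta_{X_j}$ with first-order SE
$\sigma_{Y_j}/|\hat\beta_{X_j}|$. The **IVW** estimate is the
inverse-variance weighted mean of the $\hat\theta_j$, equivalently a
weighted regression of $\hat\beta_Y$ on $\hat\beta_X$ through the origin
with weights $1/\sigma_{Y}^2$. The random-effects variant multiplies the
fixed-effects SE by $\sqrt{\max(1, Q/(k-1))}$, a multiplicative
overdispersion floored at one so it reduces to the fixed-effects model
under homogeneity. **MR-Egger** frees the intercept after orienting every
instrument to a non-negative exposure effect; a non-null intercept
indicates directional pleiotropy. The **median**, **mode** (kernel density
peak with a modified Silverman bandwidth, $0.9\min(sd, mad)\,k^{-1/5}$)
and profile **maximum-likelihood** estimators complete the battery.
**Cochran's Q** around the IVW estimate (first-order ratio weights,
$\chi^2_{k-1}$), leave-one-out refits, and bidirectional MR (both
directions significant at the nominal 0.05) supply the exclusion rules: a
pair fails on heterogeneity, a significant Egger intercept, a single
driving SNP, or a reverse signal.

A deliberate design point: the sensitivity battery always runs at the
nominal 0.05 level (`stage_config(sensitivity_alpha=)`), separate from the
screening `alpha` that is Bonferroni-divided across tests. Coupling the two
would make a *stricter* screen admit *more* survivors (a smaller alpha
makes the heterogeneity and pleiotropy gates fire less often), breaking the
monotonicity a screen should have.

## Instrument selection and harmonisation

Instruments are genome-wide-significant variants ($p < 5\times10^{-8}$,
MAF $> 0.01$) greedily clumped at $r^2 < 0.01$ within 0.5 Mb against the
panel, keeping the smallest-p variant per LD neighbourhood (ties broken by
position then identifier, for determinism). The MHC region
(chr6:28,477,897–33,448,354, GRCh37) is removed before clumping because of
its extreme LD and pervasive pleiotropy. Harmonisation aligns outcome
records to the exposure's effect allele: swapped alleles flip the sign and
EAF, strand flips are resolved by complementing, and palindromic (A/T,
C/G) variants — whose strand the alleles cannot resolve — are dropped when
the exposure MAF exceeds 0.42 and otherwise aligned by EAF concordance
(nearest of `eaf_out` and `1 − eaf_out` to `eaf_exp`; an exact tie is
treated as ambiguous). Inferring strand below 0.42 rather than dropping
mirrors the convention implied by removing *only* the high-MAF
palindromes. When no instrument survives harmonisation, a proxy with panel
$r^2 > 0.8$ within 0.5 Mb substitutes, its alleles mapped through the sign
of the dosage correlation.

Per-instrument strength is $F_j = (\hat\beta_{X_j}/\sigma_{X_j})^2$, with
the weak-instrument flag raised when $\min_j F_j < 10$ — a conservative
reading of the conventional rule; the mean is reported alongside. Post-hoc
power uses the one-term asymptotic
$\Phi\!\big(\sqrt{N r^2 \phi(1-\phi)}\,|\log \mathrm{OR}| - z_{1-\alpha/2}\big)$
for a binary outcome with case fraction $\phi$. At the null OR this gives
$\alpha/2$ (one tail); we note that the exact two-sided power adds the
opposite tail, so the one-term form is an approximation that understates
power near the null.

## Colocalisation

For a ±0.5 Mb region around an instrument, each shared variant gets a
Wakefield log approximate Bayes factor
$\tfrac12\log(1-r) + \tfrac12 r z^2$, $r = W/(V+W)$, with prior effect
SD 0.20 per SD for quantitative traits and 0.15 in log-odds for binary
traits. Under at most one causal variant per trait, the five hypothesis
likelihoods (H0 none; H1/H2 one trait; H3 both, distinct variants; H4
both, shared) accumulate through log-sum-exp, so $|z|$ up to 200 cannot
overflow. Priors scale with the locus: $p_1 = p_2 = 1/(10\,n_{snps})$,
$p_{12} = p_1/10$; $PP_{H4} > 0.8$ counts as colocalisation, and a
sensitivity curve traces $PP_{H4}$ over a log-spaced $p_{12}$ grid (it is
monotone non-decreasing on fixed data). Posteriors depend on $z^2$ only,
so allele orientation cannot change them; the per-SNP H4 contributions are
exposed so the most likely shared variant is reportable.

## Mediation

The **difference method** takes `indirect = total − direct`, with the
direct effect from multivariable MR (MVMR): a weighted regression of
outcome betas on the exposure-beta matrix, no intercept, weights
$1/\sigma_Y^2$, over instruments re-clumped from the union of the traits'
significant variants ranked by their best p-value in any trait. Its
diagnostics are the conditional F per exposure (the Q-statistic of that
exposure's betas regressed on the others', scaled by $L - p + 1$) and a
modified Cochran's Q with $L - p$ degrees of freedom, both of which accept
per-variant covariance terms $\rho_{jl}\sigma_{ji}\sigma_{li}$ built from a
phenotypic correlation matrix estimated from the z-score correlation over
variants null in every trait ($p > 0.01$; identity fallback below 1000
overlapping variants, with a warning). Conditional F $< 10$ or modified-Q
$p < 0.05$ flags the fit, and the **product method** substitutes:
`indirect = β_EM × β_MO` with the product delta-method SE. The proportion
mediated divides by the total effect, with a delta-method CI in both
methods; the difference-method SE treats total and direct as independent —
conservative, since the summary statistics provide no covariance. Two
filters precede estimation: mediators whose implied path sign opposes the
total effect are excluded, and instrument pairs within 0.5 Mb at
$r^2 \ge 0.01$ across the exposure and mediator sets are de-overlapped by
removing the member from the larger-sample GWAS (ties remove from the
exposure set, whose instrument count is larger in this design). Mediated
effects of correlated mediators are reported per mediator and never
summed, which would double-count shared pathway contributions. A
user-supplied exclusion list of known-pleiotropic instruments stands in
for a manual catalogue lookup; all estimates are computed after its
removal.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
not human genetics in detail:

* **Panel.** Block-diagonal LD from a latent Gaussian factor model
  thresholded to haplotypes; the latent correlation is calibrated through
  the tetrachoric integral so the *dosage* correlation hits the requested
  value exactly. One MAF is drawn per block (MAFs vary across blocks) —
  the price of exact calibration with a single latent correlation per
  block. Blocks sit 2 Mb apart on one chromosome, with an optional block
  placed inside the MHC for exclusion tests.
* **Triads.** One causal variant per block; exposure causal effects are
  scaled to the requested heritability; metabolite effects are
  `beta_EM` times the exposure effects plus a metabolite-specific
  component on disjoint blocks; binary-outcome log-odds combine the
  direct and mediated paths, by a logistic-score approximation (beta is
  the log-odds effect; SE from counts and MAF) rather than
  individual-level fits — standard in MR simulation and fast enough for
  hundreds of replicates. SEs follow $1/\sqrt{2\,n\,p(1-p)\,v}$ with the
  case/control-balanced analogue for binary traits. Optional pleiotropy
  gives a fraction of instruments direct outcome effects; a nonzero mean
  is applied relative to the exposure-raising allele, which is what makes
  it *directional* in the frame Egger regression uses.
* **Palindromes.** A configurable fraction of variants is relabelled to
  A/T or C/G pairs, chosen preferentially among variants with panel MAF
  ≥ 0.40 so their EAF lands near 0.5 and the 0.42 rule is exercised on
  both sides; relabelling never changes the truth, and EAFs stay
  consistent with panel MAFs. Each study independently reports some
  variants on the opposite effect allele, so harmonisation is always
  exercised.
* **Seeds.** A master seed expands into fixed per-component streams
  (`panel`, `exposure`, `metabolite`, `outcome`, `palindrome`, `coloc`,
  `bootstrap`) via a documented affine rule, so identical configurations
  reproduce byte-identical outputs and components can be varied
  independently (`metabolite_stream` re-draws only the metabolite noise,
  letting many metabolites share one exposure draw).

What the generator does **not** emulate: realistic human LD decay,
imputation error, sample overlap between studies, sex stratification, or
non-normal effect-size distributions. Passing tests therefore demonstrate
the correctness and calibration of the statistical machinery under the
stated model, not robustness to every artefact of real consortium data.

## Numerical choices and problem sizes

Quantitative effect sizes are SD-standardised throughout (the metabolite
GWAS scale is not otherwise identifiable from summary statistics alone).
The maximum-likelihood estimator profiles out the per-SNP nuisance means
and optimises the slope to a tolerance of 1e-10, with the SE from the
profile curvature; hitting the search boundary flags non-convergence
rather than failing. Bootstrap SEs (median and mode) default to 1000
seeded parametric replicates. Clumping ties break by position then
identifier. Degenerate inputs are signalled, not silently absorbed: a zero
exposure effect in a Wald ratio, an empty harmonised set, an exactly
collinear MVMR exposure matrix, and a zero total effect in a proportion
all raise typed conditions.

The packaged simulation studies use desk-scale sizes chosen so each
experiment measures what it claims: null calibration runs 500 replicates
on a 100-block panel (50 instruments, GWAS of 20,000); effect recovery
runs 200 replicates with a consortium-scale exposure GWAS (500,000) and a
metabolite GWAS of 50,000 — the sample-size asymmetry the screen assumes,
under which instrument-selection (winner's-curse) bias is negligible;
proportion-mediated recovery uses strong-instrument
consortium-scale studies (GWAS of 100,000; 200,000 cases and controls)
with a mediator→outcome effect of 0.5 log-odds per SD, because at small
total effects the proportion's denominator noise, not estimator error,
dominates the mean absolute error; colocalisation calibration uses
two-block, 50-variant loci at causal $|z| = 12$. Estimator unbiasedness
was verified separately with oracle (true causal) instruments.

## Known limitations

* The difference-method SE ignores the total–direct covariance
  (conservative; flagged in the output).
* Conditional F follows the two-sample convention implemented here and is
  validated against degenerate cases, not against an external reference
  implementation.
* The logistic-score approximation is accurate for modest per-variant
  log-odds effects; very large effects would need individual-level fits.
* Proxy search requires the target variant to be present in the panel;
  variants absent from the panel are excluded from clumping with a logged
  reason rather than imputed.
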