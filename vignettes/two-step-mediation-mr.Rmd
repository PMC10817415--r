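---
title: "Two-sample MR and two-step mediation: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample MR and two-step mediation: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The causal model

`mrmediate` estimates the effect of an exposure X on an outcome Y, and how
much of it flows through a mediator M, from three sets of GWAS summary
statistics. The identifying assumptions are the usual instrumental-variable
triad for each pairwise analysis: every instrument (i) is robustly
associated with its exposure, (ii) shares no confounder with the outcome,
and (iii) affects the outcome only through the exposure (no horizontal
pleiotropy). For each harmonized SNP *j* the Wald ratio
ρⱼ = β_Yⱼ / β_Xⱼ estimates the causal effect; the estimators differ in how
they pool the ρⱼ and in how much instrument invalidity they tolerate.

The primary estimator is multiplicative random-effects IVW:
β̂ = Σwⱼρⱼ / Σwⱼ with first-order weights wⱼ = β_Xⱼ²/se_Yⱼ², fixed-effect
SE (Σwⱼ)^(−1/2) inflated by max(1, √(Q/(k−1))) where Q is Cochran's
statistic. The floor at 1 means the random-effects SE never undercuts the
fixed-effect SE; under homogeneity the two coincide. Seven companions are
provided because each relaxes a different assumption: MR-Egger allows
directional pleiotropy via a free intercept (instruments oriented
exposure-positive, t reference with k−2 df, overdispersion floored at 1);
the simple/weighted medians are consistent when (half the weight of) the
instruments are valid; the penalized weighted median downweights each SNP
by min(1, 20·qⱼ) where qⱼ is the chi-square(1) upper tail of its
contribution to Q about the weighted-median fit; the modes assume only
that the largest group of instruments agreeing on an effect is valid; and
the maximum-likelihood estimator models both error sides,
β_Xⱼ ~ N(ξⱼ, se_Xⱼ²), β_Yⱼ ~ N(θξⱼ, se_Yⱼ²), profiling out ξⱼ in closed
form so the profile deviance is Σ(β_Yⱼ − θβ_Xⱼ)²/(se_Yⱼ² + θ²se_Xⱼ²),
maximized numerically from the IVW start with the SE taken from the
observed information.

Two-step mediation multiplies the X→M effect (β₁) by the M→Y effect (β₂).
The delta-method (Sobel) SE is √(β₁²se₂² + β₂²se₁²) with a normal 95% CI
and two-sided p. The direct effect is defined as total − β₁β₂, so the
decomposition total = direct + indirect holds exactly by construction. The
mediated proportion divides the indirect effect — rounded to 5 decimals,
matching the display convention of published mediation tables — by the
total; the unrounded value is also reported, and when indirect and total
effects disagree in sign the result is labelled inconsistent mediation and
no percentage is given. When a published table's printed CI for the
indirect effect is reproduced by this construction but its printed p-value
is not, the package reports the delta-method p; it does not attempt to
match an unreproducible value.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `p_threshold` | 5×10⁻⁸ | genome-wide significance, strict `<` |
| `r2_threshold` | 0.001 | LD pruning cutoff (pairwise r²) |
| `window_kb` | 10,000 kb | clumping distance |
| `f_threshold` | 10 | weak-instrument cutoff on F = (n−2)R²/(1−R²) |
| `palindrome_window` | (0.42, 0.58) | EAF band where A/T, C/G SNPs are dropped |
| `n_boot` | 1000 | parametric bootstrap replicates for median/mode SEs |
| `penalty_k` | 20 | penalized-weighted-median constant |
| `bandwidth_factor` | 1 | multiplier on the modified Silverman bandwidth |
| `alpha` | 0.05 | flag level for heterogeneity/pleiotropy/causal calls |

R² per SNP is computed as 2·EAF(1−EAF)β² (standardized trait) when EAF is
available and as t²/(t²+n−2) otherwise; both conventions are exposed
because summary-statistic sources differ in which is applicable. The
palindrome window and the drop-on-missing-EAF rule are deliberately
conservative: strand alignment of an A/T or C/G SNP is undecidable from
labels, and near 50% frequency even EAF cannot arbitrate.

## Numerical choices

Bootstrap SEs resample β_X and β_Y from their sampling normals and
recompute the point estimator; each estimator in a run receives a distinct
stream derived from the master seed, so whole runs are reproducible
byte for byte. The mode estimators evaluate the weighted normal-kernel
density on a 512-point grid spanning [min ρ − 3h, max ρ + 3h] with
h = `bandwidth_factor` × 0.9 × min(sd, MAD) × k^(−1/5); ties at the maximum
resolve toward the smaller ratio for determinism, and an all-equal ratio
set short-circuits to the common value. The weighted median interpolates
the ordered ratios against standardized cumulative weights
(Sⱼ − wⱼ/2)/S at 0.5; this coincides with the minimizer of weighted
absolute deviation whenever the cumulative weight crosses one half cleanly,
and sits inside the flat minimum when it does not. Clumping p-ties break
lexicographically by rsID. An in-window SNP pair with no r² available is an
error rather than an assumption of independence.

The leave-one-out flag marks an exclusion when the remaining-SNP estimate
changes sign, escapes the full-set CI, or leaves the full-set estimate
outside its own CI. The last clause is needed because a gross outlier
inflates the random-effects CI of the full fit so much that the first two
criteria go blind exactly when they matter.

## What the simulator emulates — and what it does not

`simulate_chain()` draws, per instrument, a MAF ~ U(`maf_range`), per-trait
SEs (2·MAF(1−MAF)·n)^(−1/2), and a true effect rejection-sampled from
|N(0, `gamma_sd`)| until its expected GWAS p-value clears 5×10⁻⁸ (capped at
1000 attempts, then an error). Effects are coded on the trait-increasing
allele — the convention under which directional pleiotropy has a
well-defined sign after Egger's exposure-positive orientation. Exposure
instruments propagate to the mediator (×θ_xm) and the outcome
(×(θ_direct + θ_xm·θ_my), plus a per-SNP pleiotropic αⱼ ~
N(`pleiotropy_mean`, `pleiotropy_sd`²)); mediator-specific instruments
propagate to the outcome (×θ_my); optional outcome-specific instruments
touch nothing else and exist so reverse-direction analyses have something
to select. Mediator-specific instruments are not an optional nicety: if
the M→Y step is run on the exposure's instruments, each contributes the
ratio (θ_direct + θ_xm·θ_my)/θ_xm rather than θ_my and the mediation
decomposition is structurally biased. For the same reason the pipeline by
default excludes SNPs that are genome-wide significant for the exposure
from the step-2 instrument set (the package's analogue of a
confounder-lookup exclusion list; configurable).

Instruments sit farther apart than the clumping window except planted LD
proxies, which are built from a small latent reference panel
(`n_ref` haplotype pairs): a proxy haplotype copies its parent with
probability √r², giving dosage correlations near the target and an
empirical r² table suitable for clumping tests. Binary outcomes are
approximated on the log-odds scale with normal summary statistics — the
analysis consumes only (β, se) pairs — with no liability-threshold model.
Not emulated: realistic genome-wide architecture, population structure,
sample overlap between the GWAS, indels/multi-allelics, or between-cohort
heterogeneity. Passing recovery tests therefore demonstrate correctness of
the estimators under their own sampling assumptions, not robustness to
those real-data complications.

The default configuration mirrors a small protein-exposure study: 3
exposure instruments at n = 3,301, 7 mediator instruments at n = 21,758, a
binary outcome GWAS at n = 337,199, and chain coefficients
(θ_xm = 0.3249, θ_my = 0.00358, θ_direct = 0.00092) giving a total log-odds
effect of 0.00208 with ~56% mediated. At that scale single-run estimates
are noisy by design; the calibration and recovery checks use stronger
configurations (k = 20–50 instruments, n = 5×10⁴–10⁵ per GWAS, θ_xm = 0.4,
θ_my = 0.5, θ_direct = 0.2; 50 recovery replicates, 200 null replicates,
100 pleiotropy replicates with mean α = 0.02, SD 0.01) — sizes chosen so
Monte-Carlo error is small relative to the effects being recovered while a
full run stays in the tens of seconds.

## Design choices that were genuinely open

- **Interface**: functions plus the report renderer, in the style of the
  established MR toolkits for R; the orchestration entry point is
  `run_two_step()` rather than a shell command, since the audience works
  in R.
- **Wald-ratio SEs are first-order** (outcome-side only) for IVW, medians
  and modes — the convention of the methods' source implementations; the
  maximum-likelihood estimator is where exposure-side error enters.
- **Reverse direction degrades, never crashes**: a reverse exposure with no
  significant independent instruments yields a structured not-estimable
  record, and the IVW p ≥ α case is flagged "no causal effect" rather than
  silently omitted.
- **No multiple-testing adjustment** across the three pairwise analyses;
  each is reported at α = 0.05, with the flags recomputable at any level.
- **Rounding for display only**: TSV reports print effects and ORs at 5
  decimals and p-values at 4 significant digits; all computation and the
  decomposition identity run unrounded, and unrounded values accompany the
  mediation table.

## Known limitations

Palindromic handling, the R²/F convention, and the leave-one-out flag are
reasonable defaults, not reconstructions of any particular published
study's unstated choices. The delta-method mediation CI is symmetric and
normal-theory; bootstrap or product-distribution CIs are not implemented.
Weak-instrument bias is only flagged (F < 10), not corrected. No
Steiger filtering, proxy-SNP search, MR-PRESSO, or multivariable MR.
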