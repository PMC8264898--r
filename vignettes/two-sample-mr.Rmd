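---
title: "Two-sample Mendelian randomisation with tsmr: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomisation with tsmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsmr)
```

## The problem and the model

Mendelian randomisation (MR) uses genetic variants as instrumental
variables to estimate the causal effect of a modifiable exposure (here
thought of as lung function or liability to COPD, measured per SD) on a
disease outcome (a binary trait on the log-odds scale, such as
Alzheimer's disease), using only summary-level GWAS associations from
two non-overlapping samples. Because genotypes are fixed at conception,
a valid instrument is immune to the confounding and reverse causation
that afflict observational epidemiology — provided three assumptions
hold: the variant is robustly associated with the exposure (relevance),
independent of confounders (exchangeability), and affects the outcome
only through the exposure (no horizontal pleiotropy).

Writing $\gamma_j$ for variant $j$'s true effect on the exposure,
$\alpha_j$ for its direct (pleiotropic) effect on the outcome and
$\theta$ for the causal effect, the true outcome association is
$\Gamma_j = \theta\,\gamma_j + \alpha_j$. Each estimator in the package
is a different way of pooling the per-SNP Wald ratios
$\hat\theta_j = \hat\beta_{yj}/\hat\beta_{xj}$ so as to be robust to
different patterns of non-zero $\alpha_j$:

* **IVW** assumes all $\alpha_j = 0$: a zero-intercept weighted
  regression of $\hat\beta_{y}$ on $\hat\beta_{x}$ with weights
  $1/\sigma_{yj}^2$.
* **MR-Egger** allows $\alpha_j$ with a non-zero mean, provided the
  InSIDE condition holds (pleiotropy uncorrelated with instrument
  strength); instruments are oriented so $\hat\beta_{xj} \ge 0$, the
  free intercept estimates the mean pleiotropy, the slope estimates
  $\theta$.
* **Weighted median** is consistent when at least half of the
  inverse-variance weight comes from valid instruments.
* **Weighted mode** is consistent when the single largest cluster of
  instruments shares the true $\theta$ (zero modal pleiotropy).

## Tunable parameters and their defaults

| Parameter | Default | Units / meaning |
|---|---|---|
| significance threshold | 5e-8 | exposure GWAS p-value below which a variant may instrument; 5e-9 mirrors stricter lung-function practice |
| clump window / r² | 10,000 kb / 0.001 | greedy index-variant clumping against a supplied r² matrix |
| ambiguity window | [0.42, 0.58] | EAF band inside which a palindromic SNP is unresolvable |
| Steiger mode | directional | strict r²(exposure) > r²(outcome); an optional one-sided z-test mode exists |
| IVW SE policy | multiplicative RE | SE inflated by max(1, √(Q/(k−1))); `"fe"` gives the fixed-effect SE |
| CI level | 95% | matches standard reporting |
| bootstrap | n_boot = 1000, explicit seed | parametric bootstrap for median/mode SEs |
| mode bandwidth | factor 1 on 0.9·min(sd, IQR/1.34)·k^(−1/5) | normal-kernel density on a 10,000-point grid |

Choices worth explaining:

* **Palindrome policy.** Only palindromic SNPs with intermediate
  frequency (or any missing EAF) are excluded; outside the window the
  orientation is recovered from frequency agreement, since for an A/T or
  C/G pair a label match is strand-uninformative. Widening the window
  can only exclude more variants, never fewer.
* **Clumping determinism.** Ties on p-value break by (chromosome,
  position). Variants absent from the r² matrix are treated as
  independent with a warning, since no offline package can query a
  population LD reference.
* **Steiger on the reported scale.** Variance explained is
  $t^2/(t^2+n-2)$ on each trait's own scale, for binary as well as
  continuous traits; this is an approximation for case-control outcomes
  and is applied symmetrically, so the comparison direction is
  unaffected by uniform scale changes (a tested invariant).
* **Egger dispersion floor.** Coefficient SEs are scaled by the residual
  dispersion bounded below by 1, so exactly-fitting data keep
  unit-dispersion uncertainty rather than collapsing to zero SEs; slope
  and intercept inference uses t with k−2 df.
* **First-order ratio SEs.** $\mathrm{se}(\hat\theta_j) =
  \sigma_{yj}/|\hat\beta_{xj}|$ throughout (delta method, first order);
  second-order corrections are deliberately out of scope and matter only
  for weak instruments that the F-statistic screen should have removed.

## What the synthetic generator emulates

`simulate_two_sample()` draws paired exposure/outcome summary tables
with known ground truth. Frequencies are uniform on the MAF range;
standard errors follow the standardised-genotype form
$1/\sqrt{2p(1-p)n}$, with the additional $\mathrm{cf}(1-\mathrm{cf})$
factor for a case-control outcome; observed effects are normal around
their truths with independent noise in the two tables (the two-sample,
no-overlap design). LD blocks share one true exposure effect and
correlate the observed noise at the genotype correlation $\sqrt{r^2}$,
which is exactly the structure clumping must undo. A single seed with a
fixed draw order makes every dataset bit-reproducible.

Two generator conventions deserve emphasis:

* **Oriented instruments.** True exposure effects are folded normal
  ($\gamma_j = |N(0, s^2)|$): each instrument is reported for its
  exposure-increasing allele, the convention under which "directional"
  pleiotropy is well defined. Without it, the Egger orientation step
  would flip half the pleiotropy draws and balance away any directional
  signal by construction.
* **Discovery truncation.** Real MR instruments are genome-wide
  significant hits, never effects indistinguishable from zero. The
  generator therefore left-truncates the folded normal at an expected-F
  floor (default 30, roughly the strength implied by p < 5e-8), via the
  inverse CDF so determinism is preserved. The `weak_instruments`
  preset disables the floor and calibrates the spread so the mean F is
  about 10, deliberately recreating the weak-instrument regime.

The default effect spread (`instrument_effect_sd = 0.1`) puts per-SD
effects in roughly the 0.02–0.3 range, the top of what large lung
function or anthropometric GWASs report, and yields mean F statistics
in the hundreds-to-thousands. This matters for MR-Egger specifically:
its slope and intercept attenuate by the factor known as
$I^2_{GX}$ when exposure effects carry measurement error, and with a
narrow effect spread that attenuation (a fraction of a percent here,
several percent for spreads a third as wide) is detectable in averages
over hundreds of replicates even though it is scientifically
negligible. For the same reason the two pleiotropy presets
(`balanced_pleiotropy`, `directional_pleiotropy`) use a ten-fold larger
exposure sample: those scenarios exist to probe the intercept's
behaviour under horizontal pleiotropy, and the larger sample keeps
regression-dilution attenuation — a separate, well-understood
phenomenon — from leaking into that check. The causal-recovery and
coverage scenarios keep the realistic sample sizes (exposure
n = 400,102; outcome 24,807 cases / 55,058 controls).

What the generator does **not** emulate: real human LD maps (blocks are
equicorrelated and synthetic), selection or survivor bias, sample
overlap between the two GWASs, population stratification, and
winner's-curse inflation of discovery effect sizes. Tests passing on
this generator therefore validate the estimators and the pipeline
plumbing under the stated model, not robustness to those further
departures.

## Validation design

The suite checks three layers. Exact layer: closed-form examples
(Wald ratio, F = β²/SE², hand-computed Q), reduction identities
(IVW with one instrument *is* the Wald ratio, computed by the same
ratio formula so the identity is exact in floating point; homogeneous
fixtures collapse every estimator to the common ratio). Oracle layer:
each pooled estimator is compared at tolerance 1e-10 against an
independent brute-force implementation — explicit normal equations for
IVW and Egger, interpolation of the cumulative weight function for the
median, a point-by-point dense-grid density scan for the mode.
Statistical layer: seeded replicate studies confirm that all four
estimators recover θ = 0.3 to within 0.02 on average, that IVW CI
coverage is nominal, that the fixed-effect IVW type-I error sits at 5%
under the null (the multiplicative policy is additionally checked to be
no less conservative — its inflation floor can only widen intervals),
and that the Egger intercept tracks the simulated mean pleiotropy under
InSIDE while remaining null under balanced pleiotropy.

Replicate counts (200 for means, 500 for rates) keep the whole suite
inside a couple of minutes on one CPU while leaving Monte-Carlo error
well below the tolerances being asserted; inside replicate loops the
median and mode are evaluated as point estimates only, since bootstrap
SEs do not enter a mean-of-point-estimates check.

## Degenerate inputs and tie-breaks

* A variant with $\hat\beta_{x} = 0$ cannot form a ratio: the Wald ratio
  errors, and upstream significance filtering makes this unreachable in
  practice.
* All ratios identical: Q = 0 with p = 1, no RE inflation, the mode's
  bandwidth is zero and the estimate is the common value.
* Fewer than three instruments: Egger, median and mode are skipped with
  a message; with one instrument IVW reduces to the Wald ratio; zero
  surviving instruments is an explicit `no-instruments` error.
* Empty tables round-trip as header-only files; `EAF` is the only field
  allowed missing and survives write/read as `NA`.

## Known limitations

* Proxy-SNP lookup for instruments missing from the outcome GWAS is not
  attempted; such variants are excluded and audited.
* The Steiger variance-explained formula is an approximation on the
  log-odds scale for case-control traits.
* MR-Egger inherits its usual weaknesses: low power, sensitivity to
  InSIDE violations (the generator can simulate such violations via
  `inside_violation`), and attenuation under weak-instrument
  measurement error as discussed above.
* LD clumping requires a user-supplied r² matrix; there is no built-in
  reference panel.
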