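---
title: "Bidirectional two-sample Mendelian randomization with bidirmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bidirectional two-sample Mendelian randomization with bidirmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Observational associations between circulating inflammatory markers (such as
C-reactive protein, procalcitonin, or interleukin-8) and immune-mediated
disease are confounded by treatment, infection, and reverse causation:
disease activity itself changes cytokine levels. Mendelian randomization
(MR) side-steps this by using genetic variants as instrumental variables.
Because genotypes are fixed at conception, a variant that raises a
biomarker's level provides a randomized, lifelong "dose" of that exposure.
Two-sample MR needs only published GWAS summary statistics: per-variant
effect sizes on the exposure from one cohort and on the outcome from
another. Running the analysis in both directions — biomarker as exposure
with disease as outcome, then disease as exposure with each biomarker as
outcome — separates upstream causes from downstream consequences.

`bidirmr` implements this workflow end to end: reading and validating
summary statistics, selecting instruments, harmonizing alleles across
datasets, estimating the causal effect with five complementary estimators,
and probing the instrumental-variable assumptions with heterogeneity,
leave-one-out, funnel, and simulation-based pleiotropy diagnostics. A
synthetic-data module generates two-sample summary statistics with known
ground truth, so the entire pipeline is testable without access to any
external GWAS.

## Model and estimators

For variant $j$, let $\gamma_j$ (SE $\sigma_{\gamma j}$) be its effect on
the exposure and $\Gamma_j$ (SE $\sigma_{\Gamma j}$) its effect on the
outcome, aligned to the same effect allele. A valid instrument satisfies
relevance (associated with the exposure), independence (not associated with
confounders), and the exclusion restriction (affects the outcome only
through the exposure). Under these, each variant gives a Wald ratio
$\hat\theta_j = \Gamma_j/\gamma_j$ with first-order delta-method standard
error $\sigma_{\Gamma j}/|\gamma_j|$ (a second-order variant adding the
exposure-error term is available via `second_order = TRUE`, off by default
since the first-order form is the field's convention).

* **IVW** combines the ratios with weights $w_j = 1/\sigma_{\Gamma j}^2$,
  equivalently a zero-intercept weighted regression of $\Gamma$ on
  $\gamma$: $\hat\theta = \sum w_j\gamma_j\Gamma_j / \sum w_j\gamma_j^2$.
  The default is *multiplicative random effects*: the fixed-effect SE is
  inflated by $\sqrt{\max(1, Q/(J-1))}$, so between-instrument
  heterogeneity widens the interval but can never narrow it below the
  fixed-effect SE.
* **MR-Egger** frees the intercept after orienting every $\gamma_j > 0$.
  The slope estimates the causal effect under the InSIDE assumption
  (pleiotropic effects independent of instrument strength); a nonzero
  intercept estimates directional horizontal pleiotropy and flags bias in
  IVW. SEs carry the same multiplicative overdispersion floor and
  inference uses $t_{J-2}$.
* **Weighted median**: the inverse-variance-weighted median of the ratios,
  by linear interpolation of the standardized cumulative weights
  $s_j = (\sum_{k\le j} w_k - w_j/2)/\sum_k w_k$ at $s = 1/2$. Consistent
  when at least half the instrument weight is valid. SE by parametric
  bootstrap (redrawing every $\gamma_j$, $\Gamma_j$ from their reported
  normal sampling distributions).
* **Weighted mode**: the mode of a normal-kernel inverse-variance-weighted
  density of the ratios, with modified Silverman bandwidth
  $h = \phi\, 0.9 \min(\mathrm{sd}_w, \mathrm{mad}_w/0.6745) J^{-1/5}$
  and $\phi = 1$ by default. Consistent when the largest cluster of
  similar ratios is valid. SE by the same bootstrap.
* **Cochran's Q** across ratios, with $I^2 = \max(0, (Q - df)/Q)$,
  quantifies heterogeneity; leave-one-out IVW and funnel data (ratio vs
  precision, with a standardized signed-rank symmetry score) localize it.

The pleiotropy residual-sum-of-squares framework (`mr_presso()`) computes
$RSS = \sum_j w_j(\Gamma_j - \hat\theta_{(-j)}\gamma_j)^2$ with
leave-one-out IVW slopes, simulates its null distribution by redrawing
$\Gamma_j^* \sim N(\hat\theta_{(-j)}\gamma_j, \sigma_{\Gamma j}^2)$ and
$\gamma_j^* \sim N(\gamma_j, \sigma_{\gamma j}^2)$ $K$ times, and reports
(i) a global empirical p-value, (ii) per-variant outlier tests
(Bonferroni-adjusted across $J$ at $\alpha = 0.05$), and (iii) a distortion
test comparing the outlier-corrected estimate against removals of equally
many random variants. Empirical p-values use the add-one correction
$(1 + \#\{\cdot\})/(K+1)$, so they are bounded below by $1/(K+1)$ and never
zero. $K$ defaults to 1000; at least four instruments are required so that
every leave-one-out slope rests on three.

## Scales and the binary-trait conversion

Exposure effects are analyzed on whatever scale their GWAS reports
(inverse-normal-transformed cytokine concentrations, natural-log acute
phase protein concentrations). Binary disease traits analyzed with a
linear mixed model (BOLT-LMM) report linear-scale effects; for a case
fraction $\mu$ these convert to log odds ratios by
$\log OR \approx \beta/(\mu(1-\mu))$, with the SE divided by the same
factor. The conversion is exactly invertible, preserves every z-score and
p-value, and for the default rare-disease setting
($\mu = 470/216569$) the divisor is $\mu(1-\mu) \approx 0.0021655$.
Forward results on a binary outcome are reported both as $\hat\theta$ (log
odds ratio) and $OR = e^{\hat\theta}$; reverse results (disease as
exposure, biomarker as outcome) stay on the biomarker's beta scale.

## Instrument selection

Selection is a filter chain, each stage logging its exclusions:

1. **Threshold**: genome-wide significance $5\times10^{-8}$ when at least
   3 variants reach it, otherwise the relaxed $1\times10^{-5}$ — rare
   phenotypes and under-powered biomarker GWASs rarely yield three
   genome-wide hits, and the rule (with both thresholds and the count
   configurable) records which branch fired.
2. **LD clumping** at $r^2 < 0.001$ within a 10 Mb window, greedy by
   ascending p-value with variant id as the tie-break, so the output is
   invariant to input row order. LD comes from a local pair table
   (`ld_reference()`); there is no online lookup and no genotype-panel
   computation. Datasets whose instrument lists are already independent
   (published instrument tables) can set `pre_clumped = TRUE`.
3. **Confounder and outcome screens**: for each screen dataset
   (body-mass index and age at recruitment are the intended confounder
   screens; the outcome itself can be screened the same way), instruments
   present in the screen are removed if associated at
   $0.05/(\text{number of instruments testable in that screen})$. The
   denominator counts testable instruments because a p-value threshold can
   only apply to variants the screen actually measured; untestable
   instruments are retained and logged.
4. **Weak-instrument filter**: per-variant explained variance
   $R^2 = 2\,EAF(1-EAF)\beta^2$ and $F = R^2(N-2)/(1-R^2)$; variants with
   $F < 10$ are excluded. The boundary $F = 10$ is retained, reading the
   exclusion rule strictly.
5. **Proxy substitution**: instruments absent from the outcome dataset are
   replaced by the highest-$r^2$ outcome-present variant with $r^2 > 0.9$
   (ties broken by smaller outcome p-value). The proxy's own exposure row
   is used when available — in practice exposure GWASs are genome-wide, so
   it almost always is; otherwise the variant is dropped and logged.

## Harmonization

Outcome rows are aligned to the exposure's effect allele: matched alleles
are copied; swapped alleles negate the outcome beta and complement its
EAF; alleles that match only after complementing the outcome pair are
strand-corrected first. Palindromic variants (A/T, C/G) are excluded
unconditionally — their strand is unresolvable from the alleles, and no
frequency-based rescue is attempted. Unresolvable allele pairs and
variants missing from the outcome are excluded with reasons. Harmonization
never changes $|\Gamma_j|$ or $\sigma_{\Gamma j}$, is idempotent, and is
invariant to wholesale re-orientation of the outcome dataset; proxies are
harmonized (and palindrome-checked) after substitution. An aligned-EAF
difference above 0.2 triggers a warning, not an exclusion, since no such
filter is part of the procedure being implemented — it is surfaced for the
analyst to judge.

## Multiple testing across a panel

When a panel of exposures is screened against one disease,
`mr_run_bidirectional()` Bonferroni-adjusts the per-direction p-values with
$m$ equal to the number of exposure traits (configurable). Both the raw and
the adjusted p-value are reported, and the `significant_raw` flag uses the
raw p at $\alpha = 0.05$: screening studies in this area conventionally
headline associations that are significant unadjusted while reporting the
Bonferroni correction alongside, and showing both keeps that tension
visible rather than hiding it.

## The synthetic-data generator

`mr_scenario()`/`simulate_mr_pair()` realize the instrumental-variable
causal diagram as a generative model: true instrument effects
$\gamma_j \sim N(\mu_\gamma, \sigma_\gamma)$, observed effects drawn with
the standardized-trait SE approximation
$\sigma \approx 1/\sqrt{2\,EAF(1-EAF)N}$ (EAF drawn Uniform(0.05, 0.95) to
avoid degenerate $R^2$), and true outcome effects
$\Gamma_j = \theta\gamma_j + \alpha_j$ with the pleiotropy term controlled
by the scenario: `none`, `balanced` (zero-mean), `directional` (nonzero
mean applied to a configurable fraction of instruments; InSIDE holds), or
`inside_violated` ($\alpha_j = \rho\gamma_j + \text{noise}$, the minimal
construction that correlates pleiotropy with instrument strength). Binary
outcomes are emitted on the BOLT-LMM linear scale so the conversion path is
always exercised. Allele-encoding quirks (palindrome rate, strand-flip
rate, allele-swap rate, outcome missingness) and block LD structure are
configurable, and the truth record reproduces every emitted number given
the seed.

The default scenario mirrors the study shape the package targets: 30
candidate instruments, a cytokine-scale exposure GWAS of 8 293, a disease
GWAS of 216 569 with case fraction $470/216569$.
`simulate_mr_panel()` scales this to the full bidirectional screen — 41
cytokine-like factors, two natural-log acute-phase proteins (GWAS sizes
206 158 and 3 301), one disease — with a single designated active factor
whose forward effect defaults to $\log(1.42)$, so exactly one true signal
is buried among 41 tests.

What the generator deliberately does *not* emulate: sample overlap between
cohorts, winner's-curse from discovering instruments in the same data,
fine-scale LD (within-block $r^2$ is constant), population stratification,
and EAF drift between cohorts. Passing calibration tests therefore shows
the estimators and tests behave as designed under their own assumptions,
not that any particular real-data finding is correct.

## Numerical choices

* Overdispersion in IVW-MRE and Egger is floored at 1, never deflating
  SEs below their fixed-effect values.
* $I^2$ is clipped to $[0, 1]$; $Q = 0$ gives $I^2 = 0$.
* Weighted-mode bandwidth: if the weighted spread is degenerate (all
  ratios equal, or weighted MAD 0), the estimate falls back to the common
  ratio / weighted median instead of dividing by a zero bandwidth; the
  density mode is located on a 512-point grid spanning the ratios plus or
  minus three bandwidths.
* Monte-Carlo p-values use the add-one correction; identical
  (seed, $K$, input) gives bit-identical results, and every stochastic
  stage of the pipeline derives its own seed from one master seed.
* Clumping and duplicate handling use total orders (p ascending, then
  variant id) so results are independent of row order.
* p-values of exactly 0 in input files are replaced by the smallest
  positive normal double (and logged) to keep $-\log_{10} p$ finite.
* Duplicate variant ids keep the smallest-p row, matching the
  instrument-selection intent of keeping the strongest evidence.

## Problem sizes used by the checks

The package's calibration checks run at sizes chosen to give informative
Monte-Carlo precision while staying comfortably interactive: IVW interval
coverage over 500 clean replicates of 30-instrument pairs (binomial SE
under 1 percentage point); type-I error of the global pleiotropy test over
200 replicates at $K = 500$; parameter recovery at $\theta = 0.35$ with 30
strong instruments (exposure GWAS size 206 158, matching the large
acute-phase-protein cohort, so that instrument measurement error and
winner's curse are negligible and all five estimators are expected to
cover the truth). The directional-pleiotropy check uses 250 instruments
with 15% carrying a shared pleiotropic effect: the intercept test's power
grows like $\sqrt{J}\,f$ while the weighted median's contamination bias
relative to its own interval grows like $\sqrt{J}\,q(f)$, so a small
invalid fraction with many instruments is the regime where the intercept
is detectable *and* the median stays consistent — the check aggregates 16
fixed-seed replicates (mean intercept z, median coverage rate) because the
per-replicate intercept z has unit sampling spread around a mean near 2.5.

## Limitations

* SNP-only: indels and multi-allelic variants are rejected on read.
* No Steiger directionality filtering, multivariable MR, or robust
  adjusted profile scores; the estimator set is deliberately the classic
  five plus the RSS outlier framework.
* LD must be supplied as a local table; accuracy of clumping and proxy
  search is bounded by that table's coverage.
* The per-1%-change presentation sometimes used for log-scale biomarkers
  is left to the caller; estimates are reported per unit of the exposure's
  analysis scale and labelled with that scale.
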