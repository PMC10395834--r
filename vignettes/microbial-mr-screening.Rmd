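---
title: "Screening gut-microbial risk factors by two-sample Mendelian randomization: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening gut-microbial risk factors by two-sample Mendelian randomization: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrscreen)
```

## The estimation problem

Two-sample Mendelian randomization treats genetic variants as
instruments for an exposure: a variant that shifts the abundance of a
gut bacterium, measured in one GWAS cohort, can be paired with its
effect on disease risk in a second cohort, and the ratio of the two
effects estimates the causal effect of the bacterium on the disease —
provided the variant affects disease only through the bacterium.
`mrscreen` implements this programme for panels of microbial traits
against tumour outcomes at several subsites and stages, together with
the sensitivity analyses that probe the "only through" assumption, a
Bayesian multivariable layer for correlated exposures, and a two-step
mediation layer for diet → microbe → disease pathways.

The core identities, in the field's notation (per variant $j$:
exposure effect $\beta_{Xj}$ with SE $\sigma_{Xj}$, outcome effect
$\beta_{Yj}$ with SE $\sigma_{Yj}$, weights $w_j = 1/\sigma_{Yj}^2$):

* Wald ratio: $\hat\theta_j = \beta_{Yj}/\beta_{Xj}$, first-order SE
  $\sigma_{Yj}/|\beta_{Xj}|$.
* IVW: $\hat\theta = \sum_j w_j \beta_{Xj}\beta_{Yj} / \sum_j w_j
  \beta_{Xj}^2$ — algebraically the precision-weighted mean of the
  Wald ratios with weights $\beta_{Xj}^2/\sigma_{Yj}^2$ (this identity
  is asserted numerically in the test suite).
* Multiplicative random effects: the fixed-effects SE
  $1/\sqrt{\sum_j w_j\beta_{Xj}^2}$ is inflated by
  $\max\!\big(1, \sqrt{Q/(J-1)}\big)$ where
  $Q = \sum_j w_j(\beta_{Yj} - \hat\theta\beta_{Xj})^2$.  The floor at
  1 means under-dispersion never shrinks an interval.
* MR-Egger: weighted regression of $\beta_Y$ on $\beta_X$ *with* an
  intercept; the slope is the causal estimate under the InSIDE
  assumption, the intercept the average directional pleiotropy.

Binary outcomes enter on the log-odds scale, so estimates exponentiate
to odds ratios per SD of (rank-normalized) bacterial abundance.

## Why the multiplicative random-effects model is the headline estimator

With strong instruments and a non-null causal effect, the IVW residual
variance is not $\sigma_{Yj}^2$ but
$\sigma_{Yj}^2 + \theta^2\sigma_{Xj}^2$ (measurement noise in
$\beta_X$ re-enters through the fit), and horizontal pleiotropy adds a
further variance floor.  Cochran's Q is therefore often significant
even in clean simulations with a strong effect, and a fixed-effects SE
would under-cover.  The multiplicative scaling absorbs generic
over-dispersion without modelling its source; the package reports Q
alongside every IVW fit so the user sees the dispersion it absorbed.

P-value conventions follow the reference implementations: Wald and IVW
use the normal reference; Egger uses the $t$ reference with $J-2$
degrees of freedom (its SEs already carry the dispersion scaling, and
the $t$ reference keeps the intercept test close to nominal at
moderate $J$).

## Harmonization rules

Variants are matched by identifier, and the outcome row is re-expressed
on the exposure's effect allele: swapped alleles negate $\beta_Y$ and
complement the frequency; strand-complement pairs are complemented then
aligned.  Palindromic variants (A/T, C/G) cannot be resolved by letters
— both strand readings produce the same pair — so orientation falls
back on allele-frequency matching, which is only trustworthy away from
0.5: palindromes with minor-allele frequency above 0.3 (the
`palindrome_maf` setting) are excluded as ambiguous, as are palindromes
missing a frequency.  Instruments with $F = (\beta_X/\sigma_X)^2 < 10$
are excluded as weak.  Every removal carries a reason code
(`unmatched`, `allele_mismatch`, `palindrome_ambiguous`,
`weak_instrument`), and the union of the retained set and the exclusion
log is exactly the input variant set — an invariant the tests assert.

LD clumping is greedy: keep the smallest-p remaining variant, drop
same-chromosome variants within the window whose squared correlation
with it reaches the threshold.  The defaults are $r^2 \ge 0.01$ within
10,000 kb.  A note on the threshold's scale: correlation-based pruning
conventions in this field are stated sometimes as $r$ and sometimes as
$r^2$; this package implements the squared-correlation reading (the
clumping convention), and the threshold is a plain configuration value
for users who intend the other.  Ties on p-value break by (chromosome,
position, identifier) so output is deterministic.

## The PRESSO-style outlier battery

The global test builds, for each instrument, the leave-one-out IVW
prediction $\hat\theta_{(-j)}\beta_{Xj}$ and sums squared standardized
residuals into an observed RSS.  The null distribution is parametric:
$\beta_{Yj}^* \sim N(\hat\theta_{(-j)}\beta_{Xj}, \sigma_{Yj})$,
$\beta_{Xj}^* \sim N(\beta_{Xj}, \sigma_{Xj})$, with leave-one-out
predictions recomputed inside each simulated dataset.  Empirical
p-values use the $+1$ correction, so they are bounded below by
$1/(S+1)$ and never exactly zero.  The per-variant outlier test
compares each observed squared residual to that variant's own simulated
distribution, Bonferroni-adjusted across instruments at
$\alpha = 0.05$; note the floor implies outliers can only be flagged
when $S \gtrsim J/\alpha$, which is why the default is $S = 1000$.
The distortion test compares the shift in the estimate after removing
flagged outliers with the shifts produced by removing equally sized
random non-outlier subsets (closed-form IVW downdates, so the
bootstrap is cheap).

## Colocalization

For loci driving a nominally causal microbial trait, the package
computes Wakefield approximate Bayes factors per variant
($\log \mathrm{ABF} = \tfrac12[\log(1-r) + r z^2]$,
$r = W/(V+W)$) and combines them over the five single-causal-variant
hypotheses with priors $p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$; the
H3 sum excludes the shared-variant diagonal and all accumulation is by
log-sum-exp (an explicit numerical contract, tested against brute-force
enumeration over variant pairs).  `PP.H4 > 0.8` flags the locus: if
exposure and outcome associations trace to one shared variant, the MR
effect at that locus may be a single-locus artefact rather than an
exposure-mediated pathway.  The effect-prior SD defaults to 0.15
(log-odds scale for binary traits); the analysis window around each
instrument is the user's choice — the region supplied *is* the
analysis region.

## MR-BMA: model averaging over exposure subsets

Microbial traits are strongly genetically correlated, so univariable
screens cannot tell which of several co-moving taxa drives risk.  The
multivariable layer whitens the outcome effects by their SEs and
scores every exposure subset $S$ by its Gaussian marginal likelihood
under independent $N(0, \sigma_p^2)$ effect priors
($\sigma_p = 0.5$), combined with the inclusion prior
$p^{|S|}(1-p)^{K-|S|}$, $p = 0.1$.  The reported quantities are each
exposure's marginal inclusion probability (MIP: summed posterior of
models containing it) and model-averaged causal effect (MACE:
posterior-weighted conditional ridge estimate, counted as zero where
the exposure is absent — deliberately conservative, and the reason
$|\mathrm{MACE}| \le \max_S |\hat\theta_{k|S}|$).  The model space
includes the empty model, which is what lets a single uninformative
exposure recover its prior as its MIP.

Enumeration is exhaustive through $K = 15$ ($2^{15}$ models); beyond
that a seeded shotgun search (add/delete/swap neighbourhoods, next
model sampled by posterior weight, all evaluations memoized) explores
at most `search_budget` distinct models (default 10,000 — at desk
scale the budget exceeds the space and the search is effectively
exhaustive, which the tests exploit by requiring search MIPs to match
enumeration within 0.02 at $K = 12$).  Posteriors are normalized over
the evaluated space; under a partial search this is an approximation,
reported as such.  Before fitting, exposures whose instrument-effect
vectors correlate above 0.985 are greedily pruned, keeping the member
with the smaller univariable p — near-duplicate taxa otherwise make
subsets unidentifiable.

Influence diagnostics compute per-variant Cook's distances and
squared whitened residuals for the top posterior models, flagging
points above $4/J$.  One caveat stated plainly: Cook's distance from a
studentized fit is scale-free, so even clean homogeneous data flags a
few percent of points at the $4/J$ convention; the flag is a pointer
for the analyst (and the `exclude_variants` re-run hook), not a test
with a controlled error rate, and the test suite asserts detection of
planted leverage points plus a bounded false-flag fraction rather than
zero flags.

## Two-step mediation

For a dietary habit $E$, microbial mediator $M$ and outcome $Y$:
$b_1$ ($E \to Y$), $b_2$ ($E \to M$) and $b_3$ ($M \to Y$) are each
estimated by univariable MR with trait-appropriate instrument
thresholds ($5\times10^{-8}$ for the habit, $10^{-5}$ for the
microbe).  The indirect effect is the coefficient product
$b = b_2 b_3$ with delta-method SE
$\sqrt{b_2^2\sigma_3^2 + b_3^2\sigma_2^2}$; the mediated proportion
$100\,b/b_1$ is passed through unclipped (published tables legitimately
contain negative proportions and proportions above 100% when direct
and indirect paths oppose or the total effect is small).  The reported
mediation probability is the one-sided upper-tail normal probability
$P(b \le 0)$ — small when the indirect effect is reliably positive.
This one-sided reading is an implementer's resolution of an ambiguous
reporting convention in this literature (the printed pattern —
essentially zero for large positive indirect effects, near one for
negative ones — is consistent only with the one-sided form); a
two-sided option is available.  Report tables round half-away-from-zero
at two decimals; internal values are never rounded.

## The synthetic-data generator

All validation runs on generated summary statistics with known truth.
The generator's defaults are the study conditions the package targets,
chosen once:

* outcome GWAS $n = 221{,}814$ (biobank-scale colorectal-cancer
  phenotype), microbial exposure $n = 7{,}738$, dietary exposure
  $n = 360{,}726$;
* SE model $\sigma = 1/\sqrt{2 n \,\mathrm{eaf}(1-\mathrm{eaf})}$ for
  a standardized trait (log-odds approximation for binary outcomes);
  allele frequencies Uniform(0.05, 0.95);
* microbial SNP-effect SD 0.4, which at these settings yields retained
  instrument $F$ statistics averaging in the several-hundreds — the
  strength regime reported for microbiome GWAS instruments; dietary
  SNP-effect SD 0.05;
* a 10% palindromic-variant fraction plus deliberate allele swaps and
  strand flips in the emitted outcome table, so harmonization is
  exercised on every run;
* pleiotropy modes: none, balanced $N(0, \sigma_a^2)$, directional
  $N(\mu, \sigma_a^2)$, and an InSIDE-violating mode correlating
  direct effects with instrument strength; planted outliers add
  $\pm\,\mathrm{scale}\times\sigma_Y$ direct effects to a random
  variant subset;
* identical seeds give byte-identical output, and each pipeline stage
  derives an independent sub-seed from the root seed.

What it does **not** emulate: real LD (the default LD matrix is the
identity; clumping correctness is tested on synthetic block-LD
matrices), sample overlap between cohorts, allele-frequency
mismatch between populations, winner's-curse in instrument discovery,
and the compositional/zero-inflated character of the underlying
abundance data.  Passing tests therefore certify the statistical
machinery under its stated model, not robustness to those real-data
features.

## Problem sizes and numerical choices

The test suite's stochastic experiments use: IVW recovery at
$\theta = 0.2$, $J = 50$, 200 seeds (mean bias below 0.02, CI coverage
within [0.90, 0.98]); Egger calibration at 500 balanced-pleiotropy
seeds (rejection within [0.02, 0.09]) and power at 200 directional
seeds ($\ge 80\%$); outlier detection at 60 seeds of 30 instruments
with 10% five-sigma outliers and 1000 simulations ($\ge 80\%$ of seeds
flag a planted outlier), with null global p-values checked for
uniformity over 200 seeds at 499 simulations; model-averaging
recovery at $K = 3$ over 200 seeds and search-vs-enumeration at
$K = 12$; colocalization scenario recovery over 100 seeds.  These
sizes were chosen as the smallest runs that give the binomial margins
room to discriminate.

Numerical contracts: log-sum-exp for all Bayes-factor accumulation;
Woodbury-style $K$-dimensional evidence evaluation (never a $J \times
J$ solve); Cholesky with explicit rank checks, so exactly collinear
subsets raise a typed collinearity error rather than a silent
pseudo-inverse fit; simulated p-values floored at the smallest normal
double so extreme associations never emit an invalid $p = 0$; empirical
p-values carry the $+1$ correction; clumping and ranking ties break
lexicographically for determinism.

## Known limitations

Single-causal-variant colocalization only; no weighted-median or mode
estimators (not part of this design); network module-shift scores are
consumed as an input column, never computed; mediation is single
mediator per pathway, without exposure–mediator interaction; the
stochastic search normalizes over the evaluated model space, which
underestimates nothing at desk scale but is approximate for large
$K$; and all calibration statements inherit the generator's modelling
assumptions listed above.
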