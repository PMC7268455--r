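---
title: "Models and methods behind tidymr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tidymr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tidymr)
```

`tidymr` implements the statistical machinery of a two-sample Mendelian
randomization (MR) study of a binary disease outcome — instrument
construction from an exposure GWAS, four causal estimators, a sensitivity
battery, polygenic-score style association, and post-hoc power — together
with a synthetic-data generator with known truth. This vignette is the
package's own account of the models, the tunable parameters, the numerical
choices, and what the validation simulations do and do not establish.

## The two-sample model

For SNP $j$, let $\gamma_j$ be its effect on the exposure (in SD units per
allele, from one GWAS) and $\Gamma_j$ its effect on the outcome (log odds
per allele, from an independent GWAS). If SNP $j$ is a valid instrument —
associated with the exposure, free of confounder pathways, and affecting
the outcome only through the exposure — then $\Gamma_j = \beta\,\gamma_j$,
where $\beta$ is the causal log odds ratio per SD of exposure. Each SNP
yields a Wald ratio $\hat\beta_j = \hat\Gamma_j/\hat\gamma_j$ with
first-order standard error $se(\hat\Gamma_j)/|\hat\gamma_j|$; the
estimators differ in how they pool the $\hat\beta_j$ when some instruments
are invalid (horizontal pleiotropy: a direct SNP–outcome effect $\alpha_j$
so that $\Gamma_j = \beta\gamma_j + \alpha_j$).

## Estimators

**IVW** (`mr_ivw()`). Weighted least squares of $\hat\Gamma$ on
$\hat\gamma$ through the origin with weights $w_j = 1/se(\hat\Gamma_j)^2$:
$\hat\beta = \sum w_j\hat\gamma_j\hat\Gamma_j / \sum w_j\hat\gamma_j^2$,
fixed-effects $se = (\sum w_j \hat\gamma_j^2)^{-1/2}$. The default
multiplicative random-effects model inflates the SE by
$\sqrt{\max(1, Q/(J-1))}$ with $Q$ Cochran's statistic; the floor at 1
means random effects never claim more precision than fixed effects. A
single SNP reduces exactly to its Wald ratio.

**MR-Egger** (`mr_egger()`). The same regression with a free intercept,
after orienting each pair so $\hat\gamma_j \ge 0$ (without a fixed
orientation the intercept has no directional-pleiotropy interpretation).
The slope is the pleiotropy-corrected estimate; the intercept estimates
mean directional pleiotropy. SEs come from the model-based
$(X^\top W X)^{-1}$ inflated by $\sqrt{\max(1, Q'/(J-2))}$, $Q'$ the
weighted residual sum of squares (Rucker's statistic). The method needs
$\ge 3$ SNPs, genuine spread in $\hat\gamma$ (we refuse collinear
designs), and the InSIDE assumption; with instrument-strength spread
comparable to the exposure-side estimation error the slope suffers
regression dilution, which is why the recovery simulations use
$sd(\gamma)$ well above $se(\hat\gamma)$.

**Weighted median** (`mr_weighted_median()`). The weighted median of the
Wald ratios with normalized weights $\gamma_j^2/se(\hat\Gamma_j)^2$ (the
inverse first-order ratio variance; a second-order option adds the
exposure-side term). The estimate interpolates linearly between the two
ordered ratios whose centred cumulative weights straddle 0.5. Consistent
while valid instruments carry more than half the weight.

**Mode-based** (`mr_mode()`). The mode of the weighted Gaussian kernel
density of the ratios, bandwidth $\varphi \times 0.9\,\min(sd,
\mathrm{mad})\,J^{-1/5}$ (the mad-based modified Silverman rule;
$\varphi = 1$ by default). The mode is located on a 512-point grid
spanning the ratio range ± 3 bandwidths; if the robust scale degenerates
to zero (a majority of identical ratios) the highest-weight ratio is
returned directly. This is the simple weighted form; the NOME-assumption
variant is out of scope.

**Uncertainty for the median and mode.** Both use a seeded parametric
bootstrap (default 1000 draws): $\hat\gamma_j^*, \hat\Gamma_j^*$ are
resampled from their normal sampling distributions, ratios and weights are
recomputed, and the SE is the bootstrap SD with a normal-theory CI and
p-value. `n_boot = 0` skips the bootstrap (point estimate only), which the
large simulation studies use. IVW and Egger report normal-reference
p-values and $\hat\beta \pm 1.96\,se$ intervals, keeping p and CI mutually
consistent (some field software uses a t reference for Egger; with the
SNP counts involved the difference is small).

**Scale conversion** (`to_odds_ratio()`). Continuous exposures are
reported as OR per SD, $e^{\hat\beta}$. Binary exposures are rescaled to
the OR per doubling of exposure odds by raising the OR and its CI to the
power $\ln 2 \approx 0.693$.

## Harmonization and instrument construction

Instruments are SNPs with exposure $p < 5\times10^{-8}$ (strict
inequality), greedily LD-clumped at $r^2 < 0.001$: keep the lowest-p
remaining SNP, discard all remaining SNPs with $r^2 \ge$ threshold against
it; ties break by (p, chromosome, position, id); cross-chromosome pairs
and pairs missing from the LD source count as independent (the latter with
a logged warning).

`harmonize()` puts outcome effects on the exposure's effect-allele frame:
identical coding is kept; swapped coding (including strand complements)
negates $\hat\Gamma$ and reflects the allele frequency. Palindromic SNPs
(A/T, C/G) cannot be resolved from allele codes; they are kept only when
both datasets' aligned frequencies sit on the same side of 0.5 **and**
outside $(0.42, 0.58)$ — the conventional conservative frequency-inference
rule; the limit is a parameter. Everything else is dropped with an
explicit status (`dropped_palindromic`, `dropped_missing`,
`dropped_mismatch`), so kept + flipped + dropped always equals the
instrument size. No LD-proxy search is attempted for SNPs missing from the
outcome: proxies require a reference panel and add an inferential step the
rest of the pipeline cannot audit.

## Sensitivity battery

Cochran's $Q = \sum w_j(\hat\beta_j - \hat\beta_{IVW})^2$ (ratio weights,
$J-1$ df) measures heterogeneity of the per-SNP causal estimates; Rucker's
$Q'$ is the Egger residual version ($J-2$ df), with $Q - Q'$ (1 df) as the
model-choice statistic — $Q' \le Q$ always, by nested least squares. The
radial reparameterization regresses $\hat\beta_j\sqrt{w_j}$ on
$\sqrt{w_j}$ through the origin; its slope is algebraically the
fixed-effects IVW, and the per-SNP contributions $q_j$ sum exactly to $Q$,
giving outlier flags at the Bonferroni-corrected upper-$\alpha$
chi-square(1) point. Leave-one-out re-runs IVW-MRE omitting each SNP in
turn.

The Steiger test compares the pseudo-variance-explained
$\sum z_j^2/(z_j^2+n)$ on the exposure and outcome sides and orients the
effect toward the side explaining less; significance comes from Fisher's
r-to-z on the two multiple correlations. For a binary outcome the same
pseudo-$R^2$ is used on the log-odds scale — a liability-scale correction
is out of scope and the output carries a note saying so.

Concordance labels mirror the reporting convention of MR results tables:
a sensitivity estimator that does not reach $p < 0.05$ is *uncertain*;
otherwise it *agrees* with IVW when the sign matches and the 95% CIs
overlap, else *disagrees*. "Magnitude agrees" has no canonical definition;
CI overlap is our operationalization, and a sign-only mode is provided.

## Meta-analysis, λ~GC~, LD score regression

`meta_fixed()` is the METAL-style fixed-effects inverse-variance
combination, sharing the harmonization allele rules so that one convention
governs the whole package; unresolvable SNPs are excluded per study with
an audit message. λ~GC~ is the median χ² over the null median
($\approx 0.4549$).

`ldsc_fit()` regresses χ² on LD scores under
$E[\chi^2_j] = a + N h^2 \ell_j/M$. The default weighting is IRLS with
weights $1/(2\mu_j^2)$ — the approximate inverse variance of a χ² variable
with mean $\mu_j$ — refit twice from an OLS start (fitted means floored at
0.05 to keep weights finite); a plain OLS mode exists and is exact on
noiseless inputs. SEs come from a delete-a-block jackknife over SNPs
(default 200 contiguous blocks, reduced for small inputs). The intercept
extrapolates to $\ell = 0$, where few SNPs sit, so its sampling spread is
wide under the stochastic χ² model; $h^2$ is estimated much more tightly.

## PRS-style association and power

`prs_association()` is the summary-statistic equivalent of scoring: select
at the relaxed $p < 10^{-5}$, clump, harmonize, and combine with
**fixed-effects** IVW. At the strict threshold it reproduces the
instrument's fixed-effects IVW bit for bit. The relaxed threshold captures
more variance (smaller SE) at the price of pleiotropy-driven false
positives; the type-I simulations confirm calibration only under no
pleiotropy.

`mr_power()` computes two-sided analytic power with noncentrality
$\lambda = \sqrt{n\,R^2\,cf(1-cf)}\,|\beta|$ for a case-control outcome
(the $cf(1-cf)$ term drops for continuous outcomes):
$\Phi(\lambda - z_{1-\alpha/2}) + \Phi(-\lambda - z_{1-\alpha/2})$. We use
the full two-term expression rather than the common one-term
approximation so that power equals $\alpha$ exactly at $\beta = 0$ and the
formula matches simulation at low power; the two agree for any
non-trivial effect. Both the binary and continuous forms are exposed
because either may be appropriate depending on the outcome trait.
`bonferroni_thresholds()` reports the strict family threshold
$\alpha/m$ at full precision (0.05/36 ≈ 1.39×10⁻³, conventionally quoted
rounded to 10⁻³) and the suggestive band up to 0.05.

## The synthetic-data generator

`simulate_two_sample()` draws true instrument effects
$\gamma_j \sim N(\mu_\gamma, \sigma_\gamma)$, direct effects $\alpha_j$
from the chosen pleiotropy model, sets
$\Gamma_j = \beta\gamma_j + \alpha_j$, and adds independent noise on each
side with the standard per-allele variance approximation
$se \approx 1/\sqrt{2\,p(1-p)\,n}$, divided by $\sqrt{cf(1-cf)}$ on the
log-odds scale of the case-control outcome. The binary outcome is
generated directly on the summary scale — no individual-level logistic
sampling — which is what makes desk-scale replicate studies feasible.
Defaults emulate the setting the package is designed around: a 100,000
sample exposure GWAS instrumenting 50 SNPs with
$\gamma \sim N(0.04, 0.01)$, against a glioma-scale outcome of 5739 cases
and 5501 controls pooled over two consortia (`glioma_study_sizes()`).

Pleiotropy models: *balanced* ($\alpha_j \sim N(0,\sigma_p)$, averages
out), *directional* ($N(\mu_p, \sigma_p)$, $\mu_p \ne 0$, biases IVW and
is what the Egger intercept detects), and *InSIDE-violating*
($\alpha_j$ constructed with correlation $\rho$ to $\gamma_j$, defeating
Egger's assumption). The directional study condition used in validation,
$\sigma_p = 0.03$ and $\mu_p = 2\sigma_p$, was chosen from an a-priori
power analysis of the intercept test at the default instrument
distribution (analytic power ≈ 0.7).

`split_consortia()` decomposes a pooled GWAS into sub-studies whose SEs
scale as $1/\sqrt{f_k}$ and whose estimates are drawn conditionally on the
pooled value — independent per-study noise recentred so the fixed-effects
meta of the splits reproduces the pooled estimate exactly. This makes
"split then meta-analyse" an exact round trip, a sharper validation than
a Monte-Carlo approximate one, and a single fraction of 1 returns the
pooled study unchanged.

`simulate_ld_panel()` builds dosage matrices in independent blocks: within
a block each haplotype copies a per-individual template allele with
probability $r^2{}^{1/4}$, giving pairwise allele correlation
$\sqrt{r^2}$ and dosage LD near the target. All SNPs in a block share the
block's allele frequency, because the copying construction only preserves
marginal frequencies when they are equal — a deliberate simplification.
`simulate_ldsc_inputs()` draws $\chi^2_j$ as its model expectation times a
1-df chi-square (mean-matching, variance $2\mu_j^2$), with a noiseless
mode for exact-recovery tests.

**What the generator does not emulate:** realistic human LD maps and MAF
spectra, sample overlap between the two GWAS, imputation quality,
winner's-curse selection of instruments, liability-scale effects, and sex
chromosomes. Passing validation therefore shows the *estimators and
pipeline* behave as their theory predicts under the stated generating
model — not that any real-data analysis is unbiased.

## Validation design and problem sizes

The acceptance suite runs: exact oracle equivalence of IVW/Egger/radial
against independently coded weighted least squares (100 datasets of 12
SNPs, 10⁻¹⁰ tolerance); algebraic identities (single-SNP IVW = Wald;
$\sum q_j = Q$; $Q' \le Q$; meta of $k$ identical studies gives
$se/\sqrt{k}$); type-I error of IVW-MRE over 1000 null replicates at
J = 50; recovery of $\beta = 0.3$ by all four estimators (150
replicates); weighted-median robustness with 40% directional-pleiotropy
SNPs while IVW shifts; Steiger accuracy over 500 replicates at instrument
$R^2 = 0.02$; an analytic-vs-empirical power cross-check over 2000
replicates; and LDSC recovery of (intercept 1, h² 0.3) at M = 10⁴.
Replicate counts are the package's choice, sized so the whole suite runs
in a couple of minutes on one core.

Recovery is judged as "mean estimate within 3 SDs of the replicate
distribution" of the truth. For the weighted median under partial
directional pleiotropy this is the only meaningful reading: the estimator
converges to a weighted quantile of the valid-instrument ratio
distribution, so its residual bias and its sampling SD scale *together*
with the Wald-ratio noise (bias ≈ 2 SD at J = 50, 40% invalid weight),
and no replicate count can push the bias below a 3 SD/√R band. The same
scenario asserts that IVW's bias *exceeds* its own 3 SD band, preserving
the robustness contrast the weighted median is known for.

Two scenario choices deserve note. The estimator-recovery block uses
$\gamma \sim N(0.04, 0.015)$ — spread well above the exposure-side
estimation error — because the Egger slope is only identifiable with
instrument-strength heterogeneity and is otherwise attenuated by
regression dilution (a property of the estimator, not a defect). The
power cross-check uses a deep (n = 10⁶) exposure GWAS so that instrument
estimation error, which the analytic formula does not model, does not
confound the formula-vs-simulation comparison; the instrument $R^2$ is a
function of the $\gamma$ distribution, not of the exposure sample size.

## Degenerate inputs and numerical conventions

p-values of exactly 0 are floored to the smallest positive double (with a
warning) so log/quantile transforms stay finite; stored p-values
inconsistent with $\hat\beta/se$ beyond 0.5 log₁₀ units warn but do not
drop (published files are rounded). Duplicate SNP ids keep the first
occurrence. Zero exposure effects make Wald ratios undefined and error
explicitly. Collinear Egger designs error. The weighted-median cumulative
weights use the centred convention $S_j = \mathrm{cum}(w) - w_j/2$;
boundary cases clamp to the extreme ratio. All bootstraps and simulations
take explicit integer seeds and restore the caller's RNG state.

## Known limitations

Single-exposure models only (no multivariable MR); no MR-PRESSO or
contamination-mixture estimators; no funnel plots or I²; no proxy-SNP
search; no liability-scale Steiger correction; the LD panel is a
statistical stand-in, not a population-genetic simulation; and the
pipeline's Bonferroni tiering treats exposures as independent tests,
which correlated risk factors are not.
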