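---
title: "Drug-target Mendelian randomization with metabolite mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-target Mendelian randomization with metabolite mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpath)
```

## The design

`mrpath` implements two-sample summary-data Mendelian randomization (MR)
for the drug-target design: cis-eQTLs of a drug's target gene proxy
pharmacological modulation of the target; their associations with a
disease outcome, taken from an independent GWAS, identify the causal
effect of target modulation under the three instrumental-variable
assumptions (relevance, exchangeability, exclusion restriction). A
two-step extension decomposes that effect through a circulating
metabolite: step 1 estimates the target's effect on the metabolite
($\beta_1$, from the target's cis instruments), step 2 the metabolite's
effect on the disease ($\beta_2$, from the metabolite's own instruments),
and the product $\beta_1\beta_2$ is the mediated part of the total effect
$\tau$, with

$$\text{proportion mediated} = 100\,\frac{\beta_1\beta_2}{\tau}\ \%,
\qquad \text{direct effect} = \tau - \beta_1\beta_2 .$$

All effects are kept on the log scale: log-odds for binary outcomes, SD
units for quantitative traits (output metadata records this convention;
whether an external metabolite GWAS is SD-standardised cannot be checked
from summary data alone and is the caller's responsibility).

## Instrument selection

`select_instruments()` applies, in a fixed and fully logged order:
association p-value ($p < 10^{-5}$ by default), single-SNP F-statistic
$F=(\hat\beta/\mathrm{se})^2 > 10$ against weak instruments, a cis window
(gene span $\pm$ 100 kb), MAF $\ge$ 0.01, a user-supplied rsID exclusion
list (the stand-in for confounder-lookup services such as PhenoScanner —
no web service is called), removal of palindromic (A/T, C/G) SNPs, and
greedy LD clumping at $r^2 < 0.3$ within 100 kb. Every removal is
recorded as `(snp, reason)`, so the input always partitions exactly into
kept instruments plus the provenance log — a property the tests enforce.

Choices where the convention is genuinely open:

* **Filter order.** Clumping runs last so that the strongest independent
  signals are retained after all content filters; p-value ties during
  clumping break by (chromosome, position, rsID) for determinism.
* **Missing frequencies.** SNPs without an allele frequency pass the MAF
  filter with a warning by default (`strict_maf = TRUE` makes them fail);
  nothing is imputed.
* **Palindromes** are dropped outright. No frequency-based strand
  inference is attempted: at intermediate frequencies it is unreliable,
  and the sets this package targets lose little by exclusion.
* **LD** is consumed as a precomputed pairwise $r^2$ table (absent pairs
  are treated as independent); the package does not compute LD from
  genotype panels.
* The cis rule is interpreted as $[\text{gene start} - 100\,\text{kb},\
  \text{gene end} + 100\,\text{kb}]$ on the gene's chromosome, with the
  gene region always supplied by the caller — no coordinates are
  hard-coded.

`harmonize()` aligns outcome effects to the exposure's effect allele
(sign-flipping swapped alleles and complementing frequencies), drops
incompatible allele pairs, and is a no-op on already-aligned tables.

## The estimator suite

For a harmonized set of $L$ instruments with effects
$(\hat\beta_{Xj}, \hat\beta_{Yj})$ and outcome standard errors
$\sigma_{Yj}$, with weights $w_j = \sigma_{Yj}^{-2}$:

* **Wald ratio** ($L=1$): $\hat\beta_Y/\hat\beta_X$ with first-order SE
  $\sigma_Y/|\hat\beta_X|$ (no second-order term).
* **IVW**: $\hat\tau = \sum w_j \hat\beta_{Xj}\hat\beta_{Yj} / \sum w_j
  \hat\beta_{Xj}^2$, the weighted zero-intercept regression. The
  random-effects variant (the default and primary method) multiplies the
  fixed-effect SE by $\max(1, \sqrt{Q/(L-1)})$ — multiplicative
  overdispersion with no underdispersion credit, so FE and RE coincide
  when Cochran's $Q \le L-1$. P-values are two-sided normal.
* **MR-Egger**: weighted regression with a free intercept after orienting
  all $\hat\beta_{Xj} \ge 0$; the intercept estimates directional
  pleiotropy, the slope is the adjusted causal effect. SEs carry
  $\max(1,\sqrt{Q_{\text{resid}}/(L-2)})$ and p-values use $t_{L-2}$ —
  the deliberately mixed normal/t convention of common MR software,
  stated here explicitly.
* **Weighted median**: the 0.5-quantile of the per-SNP ratio estimates
  under inverse-variance weights (first-order ratio variances
  $\sigma_{Yj}^2/\hat\beta_{Xj}^2$), interpolated between cumulative
  weight midpoints; consistent while valid instruments hold a majority
  of the weight.
* **Mode estimators**: the argmax of a Gaussian kernel density over the
  ratio estimates with the modified Silverman bandwidth
  $\varphi\, 0.9 \min(\mathrm{sd}, \mathrm{IQR}/1.349)\,L^{-1/5}$
  ($\varphi = 1$ by default) on a fixed 1000-point grid spanning
  $[\min r - 3h, \max r + 3h]$; the weighted variant scales each kernel
  by its normalized IVW weight. If every ratio coincides, that ratio is
  returned directly.

Median and mode SEs come from a parametric bootstrap (default 1000
replicates, seeded; the seed is recorded in the run manifest) that
redraws both sides from their sampling normals; the mode uses
$1.4826 \times \mathrm{MAD}$ of the bootstrap draws. `mr_all_methods()`
emits the published row order — Egger, weighted median, IVW, simple
mode, weighted mode — with the Wald ratio alone at $L=1$ and IVW alone
at $L=2$.

## Diagnostics

`cochran_q()` reports $Q = \sum_j w_j(\hat\beta_{Yj} -
\hat\tau\hat\beta_{Xj})^2$ against $\chi^2_{L-1}$ and the derived
$I^2 = \max(0, (Q-\mathrm{df})/Q) \times 100$ (the Q-based statistic,
labelled as such; it is not the instrument-strength $I^2_{GX}$).

`mr_presso()` is a from-scratch implementation of the residual-sum-of-
squares resampling framework: per-SNP contributions use leave-one-out
*fixed-effect* IVW slopes (the original algorithm's choice); null
replicates redraw both sides; Monte-Carlo p-values use add-one smoothing
$(1+\#)/(n_{\text{sim}}+1)$ so they are never zero; per-SNP p-values are
Bonferroni-multiplied by $L$ and flagged below $\alpha = 0.05$. The
distortion test is available but off by default. Given `(seed, n_sim)`
the result is reproducible bit-for-bit.

`leave_one_out()` refits the random-effects IVW dropping each SNP in
turn and raises a stability flag when any drop flips the estimate's sign
or moves its p-value across 0.05. `funnel_data()` exports ratio versus
precision pairs for plotting; no styled figures are produced.

## Mediation and MVMR

`mediation_effect()` propagates variances by the delta method with zero
cross-covariances:
$\mathrm{var}(\beta_1\beta_2) = \beta_1^2\sigma_2^2 +
\beta_2^2\sigma_1^2$, and for the proportion
$(100/\tau)^2\,\mathrm{var}(\beta_1\beta_2) +
(100\,\beta_1\beta_2/\tau^2)^2\,\sigma_\tau^2$, with a normal interval.
The zero-covariance assumption reflects the two-sample design; it is a
documented approximation, because the outcome GWAS is shared between the
step-2 and total-effect estimates. The interval itself is a first-order
(symmetric) approximation to the sampling distribution of a ratio, which
is right-skewed: in the package's own Monte-Carlo check the interval
width agrees with a 100,000-draw simulation to a few percent while the
individual bounds can differ by 10–15% of the width, and when the total
effect is estimated with large relative error (as with the published
interval's roughly 40% relative SE) the upper tail of the true
distribution extends far beyond the delta bound. Step 2 defaults to the
mediator's univariable IVW; conditioning it on the exposure via MVMR is
available as an option, since printed published tables are ambiguous
about which variant entered their product.

`mvmr_ivw()` regresses outcome betas on several exposures' beta columns
without intercept (weights $\sigma_{Yj}^{-2}$), with the same
overdispersion floor at $\sqrt{Q_{\text{resid}}/(L-k)}$ and normal
p-values, and rejects rank-deficient designs. `screen_mediators()`
filters step-1 results at $\alpha = 0.05$ with no multiplicity
correction by default (Bonferroni/BH are available but clearly optional
behavior, since the workflow this package mirrors applied none).

## The synthetic-data generator

`sim_scenario()` defines the study conditions; `simulate_triplet()`
realizes one dataset of exposure, mediator and outcome summary
statistics with a ground-truth file. Per SNP: frequency
$\sim U(0.05, 0.5)$; standard errors follow
$1/\sqrt{2n\,p(1-p)}$ for standardized quantitative traits and
$1/\sqrt{2nv\,p(1-p)}$ for the binary outcome with case fraction
$v = 0.01$ (a rare disease), avoiding individual-level simulation while
matching SE magnitudes; true instrument effects have $|\gamma_j|/\mathrm{se}
\sim U(5, 9)$ with random sign (so F-statistics fall in $[25, 81]$,
mean about 50); the mediator's true effect is $\beta_1\gamma_j$ plus an
optional pleiotropy term and the outcome's is $\beta_{\text{direct}}
\gamma_j + \beta_2 \times (\text{true mediator effect})$ plus
outcome-side pleiotropy. Pleiotropic effects are drawn
$N(\mu_\alpha, \sigma_\alpha)$ on a fraction $\pi$ of instruments and
applied relative to the exposure-increasing allele — the convention
under which a nonzero $\mu_\alpha$ is directional and detectable as an
Egger intercept. LD blocks correlate both the sampling errors and
(attenuated) true effects of neighbouring SNPs at $\sqrt{r^2}$ and are
reported in a pairwise $r^2$ table; palindromic allele pairs are
assigned at a configurable rate; a fraction of mediator/outcome rows is
reported on the swapped allele so harmonization is always exercised.

The default path coefficients are calibrated so the true odds ratios of
the three legs are 0.917 (exposure to mediator), 2.0499 (mediator to
outcome) and 0.4957 (total), at GWAS sizes 31,684 / 118,000 / 317,252 —
the metabolite GWAS size is a documented placeholder, as the NMR
metabolite GWAS series it emulates does not pin a single value. The
implied true proportion mediated is
$100 \ln(0.917)\ln(2.0499)/\ln(0.4957) = 8.86\%$; note this differs
from the published table's printed 10.41%, whose product cannot be
reproduced exactly from the printed step odds ratios — both computation
variants are therefore exposed and neither is asserted as "the" value
beyond the printed-table identities.

One calibration tension is worth stating. With these sample sizes the
per-SNP ratio SE is $(1/\sqrt{F})\sqrt{n_{\text{exp}}/(n_{\text{out}}
v)}$ regardless of allele frequency, so requiring strong instruments
(mean F about 50) forces the simulated total-effect SE to about 0.1 —
narrower than the published interval's 0.29, which reflects noisier
real eQTL data. The generator keeps the strong-instrument regime, since
estimator calibration (coverage, type-I error) is what the simulations
must demonstrate; the step-1 SE (about 0.016) matches its published
counterpart almost exactly. `paper_like_scenario()` additionally turns
off palindromes and LD so that exactly 30 instruments are analyzed, as
in the headline analysis; the default scenario keeps both nuisances on.

What the generator does *not* emulate: realistic LD beyond equicorrelated
blocks, allele-frequency–dependent effect sizes, sample overlap between
studies, population stratification, and winner's-curse selection of
instruments. Passing tests therefore demonstrate correctness of the
estimators and pipeline under clean two-sample conditions, not
robustness to those real-data complications.

## Problem sizes and determinism

The shipped test-and-validation suite uses 500 replicates for type-I
error and coverage, 300 for mediation-interval coverage, 200 datasets
for the MR-PRESSO null rate (999 resamples each; 1000 when hunting a
single injected outlier), and 1000 bootstrap replicates for median/mode
SEs — sizes chosen so Monte-Carlo error is comfortably inside the
asserted bands while the whole suite runs in well under a minute.
Every stochastic routine takes an explicit seed, restores the caller's
RNG state, and records the seed in the run manifest; identical
configurations produce byte-identical outputs.

## Worked example

```{r example}
s <- paper_like_scenario()
sim <- simulate_mediation_study(s, seed = 7)
dir <- file.path(tempdir(), "mrpath-demo")
write_simulation(sim, file.path(dir, "data"))

res <- run_mediation_pipeline(list(
  exposure = file.path(dir, "data", "exposure.tsv"),
  outcome = file.path(dir, "data", "outcome.tsv"),
  mediators = list(hdl_vl_conc = file.path(dir, "data", "mediator.tsv")),
  gene_region = s$gene_region,
  out_dir = file.path(dir, "out"), seed = 7))
res$mediation
```

## Known limitations

* Wald-ratio and ratio-variance formulas are first-order; very weak
  instruments (F near the cutoff) bias ratios toward the null.
* The delta-method proportion interval is symmetric while the exact
  distribution is skewed (see above); a bootstrap interval is not
  provided because the mirrored workflow used the delta method.
* MVMR assumes the exposure-beta design is well-conditioned; collinear
  mediators must be adjusted one at a time.
* No Steiger directionality filtering, MR-RAPS, Radial-MR, or
  contamination-mixture models; no reference-panel LD computation; no
  VCF ingestion or liftover.
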