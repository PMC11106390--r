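---
title: "Two-sample Mendelian randomization with mrflow: models, decisions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrflow)
```

## The causal model

Two-sample Mendelian randomization estimates the effect of an exposure
(here: genetically predicted abundance of a gut bacterial taxon) on an
outcome (a disease endpoint such as a lymphoma subtype) using genetic
variants as instrumental variables. For instrument $j$ the two GWAS supply
the exposure association $\hat\beta_{x,j} \sim N(\beta_{x,j}, s_{x,j}^2)$
and the outcome association $\hat\beta_{y,j} \sim N(\beta_{y,j},
s_{y,j}^2)$, measured in independent samples. The working model is

$$\beta_{y,j} = \theta\,\beta_{x,j} + \alpha_j,$$

where $\theta$ is the causal effect (a log odds ratio for binary
outcomes) and $\alpha_j$ is the variant's direct (horizontally
pleiotropic) effect on the outcome. A valid instrument has $\alpha_j = 0$;
every method in the package is a different compromise about how many
instruments may violate that.

Per instrument the Wald ratio is $\hat\theta_j = \hat\beta_{y,j} /
\hat\beta_{x,j}$ with first-order standard error $s_{y,j} /
|\hat\beta_{x,j}|$, which ignores the uncertainty in
$\hat\beta_{x,j}$ (the NOME simplification used throughout the field's
standard toolchain). The estimators combine the ratios:

- **IVW**: weighted mean with weights $w_j = \hat\beta_{x,j}^2 /
  s_{y,j}^2$; algebraically identical to weighted regression of
  $\hat\beta_y$ on $\hat\beta_x$ through the origin with weights
  $1/s_{y,j}^2$. Fixed-effects standard error $1/\sqrt{\sum w_j}$;
  the multiplicative random-effects variant inflates it by
  $\max(1, \sqrt{Q/(J-1)})$.
- **MR-Egger**: the same regression with a free intercept, instruments
  oriented so $\hat\beta_{x,j} > 0$. The slope is consistent under the
  InSIDE assumption even with directional pleiotropy; the intercept
  estimates the mean pleiotropic effect. Standard errors are the
  unit-variance weighted-least-squares values inflated by the residual
  scale when it exceeds 1; inference uses $t_{J-2}$ because $J$ is small.
- **Weighted median**: the ratio at cumulative midpoint weight 0.5
  (weights as in IVW, normalized; linear interpolation between order
  statistics); consistent when valid instruments carry half the weight.
- **Simple/weighted mode**: the argmax of a normal-kernel density of the
  ratios with modified Silverman bandwidth $h = \varphi \cdot 0.9 \cdot
  \min(\mathrm{sd}, \mathrm{IQR}/1.349)\,J^{-1/5}$ on a 512-point grid
  over $[\min - 3h, \max + 3h]$; consistent when the largest group of
  instruments is valid. $\varphi = 1$ by default.

Median and mode standard errors come from a parametric bootstrap (default
1000 replicates, seed 20240507): both association vectors are resampled
from normals at their stated standard errors and the estimator recomputed.
All estimates are reported as OR $= e^{\hat\theta}$ with 95% interval
$\exp(\hat\theta \pm 1.96\,\mathrm{se})$.

## Instrument selection

Selection mirrors standard microbiome-MR practice, where few taxa reach
genome-wide significance:

| parameter | default | meaning |
|---|---|---|
| `p_threshold` | 1e-5 (strict `<`) | exposure-association cut for candidate instruments |
| `clump_r2` | 0.001 | pairwise r² at or above which variants clump |
| `clump_kb` | 10,000 kb | clumping window (base-pair distance) |
| `f_min` | 10 (strict `<` removed) | weak-instrument F bound |
| `palindrome_eaf_limit` | 0.42 | minor-allele-frequency bound for resolving A/T, C/G variants |

Variance explained is $R^2 = 2\,\mathrm{eaf}(1-\mathrm{eaf})\beta^2$ and
instrument strength $F = R^2 (N-2)/(1-R^2)$. Clumping is greedy: rank by
p-value (ties by identifier, for determinism), keep the best, remove
correlated neighbours within the window, repeat. The LD source is an
injectable pairwise r² table — reference-panel LD estimation is a
different problem, and the algorithm, not the panel, is the testable
content; unlisted pairs count as r² = 0. Confounder screening is a static
exclusion list of variant ids supplied in configuration, replacing a live
phenotype-database lookup so runs are reproducible and offline.

Directionality is checked per instrument by MR-Steiger: the variant should
explain more variance in the exposure than in the outcome
($R^2_x > R^2_y$, strict; ties fail). The comparison p-value uses the
Fisher z-transform of the implied correlations with the two sample sizes.
Both sides use the same $R^2$ formula; no liability-scale correction is
applied for binary outcomes — a documented caveat, since the outcome-side
$R^2$ of a log-OR association is only approximate. Steiger filtering runs
before MR-PRESSO in the pipeline (configurable off), so outlier removal
operates on directionally valid instruments.

## Harmonization

Outcome records are aligned to the exposure's effect allele: identical
orientation passes through; swapped alleles invert the outcome effect sign
and complement the outcome frequency; alleles matching only after strand
complement (A↔T, C↔G) are complemented first. Palindromic variants carry
no strand information in their labels, so orientation is inferred from
allele frequencies — only when both minor-allele frequencies fall below
0.42 (frequencies in [0.42, 0.58] are uninformative; the limit follows
common two-sample MR practice). Ambiguous palindromes, palindromes with a
missing frequency, and irreconcilable allele sets are dropped with a
per-variant reason. Indel alleles are compared literally; complementing
multi-base alleles is ill-defined. The alignment is idempotent and
invariant to jointly flipping a record's alleles and effect sign.

## Sensitivity battery

**Cochran's Q** is $\sum_j w_j (\hat\theta_j - \hat\theta_{IVW})^2$
against $\chi^2_{J-1}$; a significant Q indicates the instruments
disagree. **The Egger intercept** tests directional pleiotropy
($t_{J-2}$). **Leave-one-out** recomputes fixed-effects IVW without each
instrument in turn.

**MR-PRESSO** is reconstructed from the original method's description:
the observed statistic is $\mathrm{RSS} = \sum_j (\hat\beta_{y,j} -
\hat\theta_{(-j)} \hat\beta_{x,j})^2 / s_{y,j}^2$ with
$\hat\theta_{(-j)}$ the IVW estimate excluding $j$; its null distribution
comes from `k_sim` parametric replicates drawing $\beta^*_{x,j} \sim
N(\hat\beta_{x,j}, s_{x,j})$ and $\beta^*_{y,j} \sim
N(\hat\theta_{(-j)}\hat\beta_{x,j}, s_{y,j})$ and recomputing the
statistic. Monte-Carlo p-values use $(1 + \#\{\mathrm{sim} \ge
\mathrm{obs}\})/(K+1)$, so they are floored at $1/(K+1)$ and never zero.
The per-variant outlier test compares each observed term against its own
simulated distribution, Bonferroni-corrected across $J$. Recursive removal
eliminates one variant per round — the smallest outlier p, ties broken by
the larger weighted residual — re-running the global test until it is
non-significant or fewer than four instruments remain ("exhausted"). The
outlier-corrected estimate is fixed-effects IVW on the surviving set.
Defaults: `k_sim = 1000`, `alpha = 0.05`. The distortion test of the
original method is intentionally out of scope. In simulation the global
test holds its nominal 0.05 size exactly when exposure effects are
noise-free; with realistic exposure-side sampling noise it runs slightly
hot (≈0.06), a finite-sample property of the method worth knowing when
interpreting borderline global p-values.

## Primary method and evidence classification

The decision rule mirrors the reporting convention of microbiome-MR
studies: a significant Egger intercept promotes MR-Egger to primary
(pleiotropy invalidates IVW's mean-zero assumption); otherwise a
significant Q promotes the weighted median, with random-effects IVW
reported alongside; otherwise fixed-effects IVW is primary. Pleiotropy
takes precedence when both fire. With two instruments neither Egger nor
the median is defined, so the rule degenerates to IVW (random-effects
under heterogeneity); a single instrument reports the Wald ratio.

The primary method's p-value is classified against per-taxonomic-rank
Bonferroni thresholds — $0.05/9$ (phylum), $/15$ (class), $/20$ (order),
$/32$ (family), $/119$ (genus) — as *significant* below the adjusted
threshold, *suggestive* between it and 0.05, and *none* otherwise.

Batch runs derive one RNG seed per exposure–outcome pair from the global
seed and the pair labels (a deterministic string hash), so any pair can be
reproduced in isolation and the batch is reproducible as a whole.

## The synthetic-data generator

`simulate_two_sample()` emulates the two-sample design end to end:
frequencies uniform on `eaf_range` (default [0.1, 0.9]); reported standard
errors from sampling theory on a standardized trait, $s = 1/\sqrt{2p(1-p)n}$,
which makes the $R^2$ formula exact on synthetic data; exposure sample
size 18,340 and outcome sample size 325,496 by default, the scale of a
microbiome-abundance GWAS paired with a biobank case-control endpoint.
True exposure effects are drawn as $|N(0, 0.1)|$ and redrawn until the
expected F reaches 30 (instruments selected at $p < 10^{-5}$ in an
n≈18k GWAS are comfortably strong; set `f_floor = 0` to study weak
instruments). Reporting the effect allele as the exposure-increasing
allele follows GWAS convention and matters statistically: with
symmetrically signed exposure effects, Egger's positive-orientation step
would flip half the pleiotropic effects and cancel a directional
intercept by construction. Pleiotropy enters as $\alpha_j \sim
N(\mu_\alpha, \sigma_\alpha)$ on a configurable fraction of instruments;
outliers as an additive outcome-effect shift; LD blocks as co-located
variant groups listed in the emitted r² table (exchangeable r² within a
block, zero between — sufficient to exercise the clumping contract, not a
model of real LD decay); about half the outcome rows are emitted with
swapped allele order so harmonization always has real work to do.
`se_x_scale`/`se_y_scale` scale the sampling noise applied to the observed
effects (0 gives the noise-free limit in which every ratio equals
$\theta$ exactly).

What the generator does *not* emulate — real minor-allele-frequency
spectra, LD decay, liability-scale case-control effects, winner's-curse
selection bias, sample overlap — bounds what passing tests show: they
validate the algorithms under the stated model, not robustness to every
pathology of real GWAS data.

## Numerical choices and degenerate inputs

- Strict inequalities where the selection rules state them: `p <
  threshold`, `F < 10` removed, Steiger ties excluded.
- Monte-Carlo p-values never zero by the $(1+x)/(K+1)$ convention;
  simulated p-values in the generator are floored at 1e-300 to respect
  the (0, 1] invariant.
- Zero kernel bandwidth (degenerate ratio spread) falls back to the
  standard deviation, then to the common ratio when all ratios coincide.
- Egger refuses zero exposure-effect variance ("no slope identifiable");
  IVW and Q refuse any $\hat\beta_x = 0$ (the caller drops such
  instruments or uses the Wald ratio path).
- Clumping excludes variants with missing positions (with a warning)
  rather than guessing.
- Duplicate variant ids keep the first occurrence; invalid rows are
  tallied by reason rather than silently dropped.

## Problem sizes in the test suite

The statistical checks run at: 100 random instances for the
estimator-vs-oracle equivalences (tolerance 1e-10); 1000 null replicates
for IVW type-I error and 5000 for the MR-PRESSO global test's rejection
rate (its true size ≈0.06 is close enough to nominal that a precise
estimate needs small Monte-Carlo error; `k_sim` stays 300); 500
replicates for recovery of $\theta = 0.3$ at $J = 100$; 200 replicates
each for outlier removal and pleiotropy detection; 1000 random instances
for the clumping contract. The full suite runs in about a minute on one
CPU.

## Known limitations

- First-order Wald weights ignore exposure-side uncertainty (NOME); under
  strong effects this inflates Cochran's Q, which is why the worked
  examples sometimes select the weighted median as primary even for clean
  simulated data. This matches the behavior of the field's standard
  tools rather than correcting it.
- No liability-scale correction in Steiger's outcome-side $R^2$.
- The confounder filter is only as good as the supplied exclusion list.
- MR-PRESSO's distortion test, radial MR, MR-RAPS and multivariable MR
  are out of scope.
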