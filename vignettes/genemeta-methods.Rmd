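---
title: "Methods: pooling genetic association studies from summary tables"
author: "genemeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooling genetic association studies from summary tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genemeta)
```

## The problem

Genetic association meta-analysis pools evidence about a SNP–trait
relationship across published studies that never share individual-level
data. Each study contributes only what its table reported: genotype counts,
a risk-allele frequency (RAF), an odds ratio (OR) with a confidence
interval, a per-allele regression coefficient β with an SE, CI or p-value,
or per-genotype trait means and SDs. The packaged *G6PC2* tables —
case-control studies of type 2 diabetes (T2D) and quantitative studies of
fasting glucose (FG, mmol/l) at rs560887, rs573225 and rs16856187 — are a
representative instance: 18 case-control records and 35 quantitative
records, heterogeneous in what they disclose.

`genemeta` standardizes these fragments into effect sizes on a common
scale, pools them under a random-effects model, quantifies heterogeneity,
probes small-study bias, and translates pooled ORs into population
attributable risk (PAR) and power.

## From records to effect sizes

**Genetic models.** A genotype triple is always ordered (hom-risk, het,
hom-other). The *allele* model compares risk versus other alleles (two per
person); *dominant* compares carriers with non-carriers; *recessive*
compares risk homozygotes with the rest; *additive* here means the crude
per-allele contrast, computed as the allele-count 2×2 OR — no logistic
dose–response model is fit to summary counts, because none can be without
individual data. All ORs carry the Woolf standard error
$\sqrt{\sum 1/n_{ij}}$ on the log scale.

**Hardy–Weinberg reconstruction.** Studies reporting only case and control
RAFs contribute expected genotype counts $n\,(f^2, 2f(1-f), (1-f)^2)$.
Counts are deliberately kept fractional: rounding would bias allele-count
recovery of $f$ and adds nothing, since the Woolf variance accepts real
cells. The same HWE law underpins the genotype χ² test (1 df, no
continuity correction; monomorphic samples return χ² = 0 with a flag).

**Zero cells.** Any collapsed 2×2 containing a zero receives the
Haldane–Anscombe 0.5 added to every cell (configurable off, in which case
a zero cell is a hard error). This is the standard finite-OR device; at the
rare extreme of the packaged tables (e.g. a RAF of 0.971, where the
expected hom-other class is a handful of individuals) it matters, and its
use is visible in the per-study pathway log.

**SE recovery.** When a study reports an estimate with a 95% CI, the SE is
$(t(u)-t(l))/(2\,z_{0.975})$ with $t = \log$ for ratio measures; when it
reports an estimate with a two-sided p-value, the SE is
$|\hat\theta|/z_{p/2}$. Both inversions are exact for Wald-type reporting
and are covered by round-trip tests. The exact normal quantile
(1.959964…) is used throughout, never 1.96.

**SMD.** Per-genotype trait summaries can be contrasted against the
hom-other reference as standardized mean differences: Cohen's
$d = (m_1 - m_0)/s_{\text{pooled}}$ with
$SE = \sqrt{1/n_1 + 1/n_0 + d^2/(2(n_1+n_0))}$. Cohen's flavour is the
default because the large samples typical of this literature make the
small-sample correction negligible; Hedges' $g$ (both estimate and SE
scaled by $J = 1 - 3/(4(n_1+n_0-2)-1)$) is selectable where small studies
dominate.

**Derivation precedence.** When a case-control record offers several
routes, the pipeline prefers (1) the reported OR/CI — it may carry
covariate adjustment the counts cannot reproduce — then (2) genotype
counts, then (3) RAF reconstruction, and logs the pathway per study.
RAF reconstruction requires *both* case and control frequencies; a single
frequency of unstated provenance (as printed in the packaged T2D table) is
stored as `raf_control` and supports no OR on its own, which is why those
fixture records are flagged `has_effect_pathway = FALSE` at read time.

## Pooling and heterogeneity

Fixed-effect weights are $w_i = 1/se_i^2$. The DerSimonian–Laird moment
estimator takes Cochran's $Q = \sum w_i (y_i - \hat y_{FE})^2$ and sets

$$\hat\tau^2 = \max\!\left(0,\; \frac{Q - (k-1)}{\sum w_i - \sum w_i^2 / \sum w_i}\right),$$

re-pooling with $w_i^* = 1/(se_i^2 + \hat\tau^2)$. Truncation at zero makes
the random-effects result collapse exactly onto the fixed-effect one
whenever $Q \le k-1$, a property the tests assert. DL is used rather than
REML or Paule–Mandel because it is the default of the tooling this
literature reports with; no alternative estimators are offered in this
version.

Heterogeneity is summarized by $I^2 = \max(0, (Q - df)/Q) \cdot 100$ and by
*H²* in two variants. The headline `h2` is the *excess* ratio
$(Q - df)/df$, chosen because it is the variant consistent with most
printed *I²*/*H²* pairs in the source literature (e.g. $I^2 = 72\% \gets
H^2 = 2.56$, since $I^2 = H^2/(1+H^2)$ under the excess convention); the
classical $Q/df$ is always reported alongside as `h2_classical`. Note the
printed source pairs are not all internally consistent under either
convention (its $I^2=39$, $H^2=0.42$ row fits the excess form, its
$I^2=80$, $H^2=3.28$ row fits neither exactly); the package computes, it
does not transcribe.

The *I²* interval is the test-based ln-H interval: with
$H = \max(1, \sqrt{Q/df})$,
$SE(\ln H) = \tfrac12 (\ln Q - \ln df)/(\sqrt{2Q} - \sqrt{2\,df - 1})$ for
$Q > df + 1$ and the small-Q form
$\sqrt{\tfrac{1}{2(k-2)}\left(1 - \tfrac{1}{3(k-2)^2}\right)}$ otherwise;
bounds are transformed to the *I²* scale and clamped to [0, 100]. At
$df = 1$ with small *Q* the small-sample SE is undefined (division by
$k - 2 = 0$) and the interval is reported as `NA` rather than invented.

Subgroup pooling repeats the engine within each level of a grouping column
(ethnicity in the packaged tables); a single-study level is passed through
with its own SE and undefined heterogeneity, mirroring how single-country
rows appear in published subgroup tables. Leave-one-out re-pools with each
study omitted; the sensitivity report flags omissions whose study's own
estimate lies outside the parent pooled CI, a conservative outlier signal
that fires on gross contamination and stays quiet on homogeneous input.

Pooled allele frequencies use inverse-variance weights
$w = 2n/(f(1-f))$ — the reciprocal binomial variance of an allele-count
frequency — with monomorphic studies excluded (their variance is zero);
an unweighted mean is also provided and is the default input to PAR
(below).

## Publication bias

Egger's test is the classic unweighted regression of the standardized
effect $y_i/se_i$ on precision $1/se_i$; the intercept's t test (k − 2 df)
is reported. The weighted variant was not adopted: on the residual-free
constructions used as oracles both agree, and the classic form is what the
source literature's tooling runs. The test is undefined when all SEs are
equal (constant predictor) and errors accordingly.

Begg's test correlates variance-standardized deviations from the
fixed-effect pool, $(y_i - \hat y_{FE})/\sqrt{se_i^2 - se_{FE}^2}$, with
the variances $se_i^2$ (Kendall's τ). The p-value is exact for $k \le 8$
(ties permitting) and otherwise uses the continuity-corrected normal
approximation; variances not exceeding the pooled variance are floored at
a small positive value with a message. A bias p-value at or below 0.1 is
annotated as suspicious in pipeline output, never used as a filter.

Funnel output is plain data (study points plus pseudo-95% boundary) so no
graphics stack is required; any plotting front-end can consume the CSV.

## Attributable risk and power

Under the multiplicative genotype model with risk-allele frequency $f$ and
per-allele OR $\gamma$, the mean population relative risk is
$X = (1-f)^2 + 2f(1-f)\gamma + f^2\gamma^2 = (1 + f(\gamma - 1))^2$ and
$PAR = (X-1)/X$. The formula presupposes $\gamma > 1$ for the named
allele; `orient = TRUE` re-expresses a protective allele via its
complement ($\gamma \to 1/\gamma$, $f \to 1-f$) and records the flip. The
unweighted mean of study RAFs is the default frequency input because that
is the convention under which the packaged literature's own Asian PAR
(18.3% at $\gamma = 1.120$, $f = 0.8845$) reproduces exactly; the
inverse-variance pool is available alongside. The corresponding Caucasian
and total-sample PAR values printed in that literature (5.3%, 5.4%) do
not follow from any combination of its printed ORs and frequencies that
we tried ($\gamma = 0.964$ is protective, giving negative PAR for the G
allele and ~9–10% for the complement), so they are deliberately not
encoded as expectations anywhere.

Case-control power uses the closed-form normal approximation to the Wald
test of the log allelic OR: expected case/control allele frequencies
follow from $f$, $\gamma$ and the prevalence under the multiplicative
model and HWE (baseline penetrance $r_0 = K/X$), and the variance is the
Woolf form at the implied allele counts. Quantitative power uses the
non-central χ²(1) with $\lambda = n \cdot 2f(1-f)\,\beta^2/\sigma^2$.
These are standard desk approximations: they reproduce the qualitative
published power statements (e.g. >99.99% for β = 0.075 mmol/l at
n = 13,752, f = 0.67, σ = 0.8) but are not bit-compatible with the QUANTO
program's likelihood machinery, which is out of scope.

## The synthetic-data generator

The generator exists so that every pipeline stage has a ground truth. It
emulates: between-study heterogeneity in true effects
($\theta_i \sim N(\mu, \tau^2)$), study-specific allele frequencies,
multinomial HWE genotype sampling, case/control genotype distributions
under the multiplicative risk model at a stated prevalence (case
probabilities $\propto f_g \gamma^g$, control probabilities
$\propto f_g(1 - r_0\gamma^g)$), and normal per-genotype trait values with
a per-allele dose effect. It does **not** emulate selective publication,
covariate adjustment, genotyping error, population stratification or
linkage structure — so green tests certify the statistical engine, not
robustness to those real-data pathologies.

Determinism: one integer seed; study $i$ draws from a substream seeded by
a fixed affine hash of (seed, $i$), so earlier studies are unchanged when
$k$ grows. Degenerate genotype draws (no allele-dose variance) are redrawn
(bounded retries); a genotype class with fewer than 2 subjects suppresses
the per-genotype summaries for that study, leaving the regression summary.

Three presets fix the study conditions used throughout the tests:

- **A** `g6pc2-fg-like` — quantitative, k = 32, μ = 0.07 mmol/l per
  allele, τ = 0.01, RAF 0.6–0.97, n 300–5,000, σ = 0.8, baseline
  5.0 mmol/l. The shape mirrors the large FG meta-analysis: many mid-size
  cohorts, high risk-allele frequencies, an effect near 0.07.
- **B** `null-symmetric` — quantitative, k = 15, μ = 0, τ = 0, RAF
  0.3–0.7, n 200–2,000. A selection-free symmetric funnel for
  type-I-error checks of the bias tests.
- **C** `hetero-or` — case-control, k = 15, μ = ln 0.96, τ = 0.05, RAF
  0.6–0.9, n 1,500–3,000 per group, prevalence 8.8%. A modestly protective
  allele with real heterogeneity, the regime of the T2D analyses.

The baseline of 5.0 mmol/l, σ = 0.8, and the size/frequency ranges are
fixed editorial choices representing typical FG cohorts; they are stated
here once and not tuned.

Two calibration facts shape the tests. First, the allelic (2×2) OR equals
the per-allele genotype relative risk only in the rare-disease limit; at
8.8% prevalence the allelic log-OR of a γ = 1.5 allele is inflated by
about 0.04. The generator-mean test therefore uses a 1% prevalence
scenario, where the discrepancy (<0.01) is inside its 0.02 band; at the
small effects of preset C the discrepancy is negligible relative to CI
width. Second, DL confidence intervals are known to undercover slightly
when τ² is non-trivial at moderate k; the preset-C coverage check
(expected band 92–98% at nominal 95%) measured ~94% over 200 replicates.

## Problem sizes and numerical choices

Stochastic test suites use 200 replicates for coverage and end-to-end
recovery and 500 for bias-test type-I error, sizes at which the binomial
bands quoted above have comfortable margins; the whole suite runs in a few
minutes on one core. Tolerances: closed-form oracle comparisons at 1e-10;
machine-precision identities (X factorization, frequency recovery) at
1e-12–1e-14; frozen two-decimal literature values at the precision
printed. Tables are serialized with 17 significant digits, which makes the
writer/reader pair the identity on doubles and output files byte-stable
across reruns of the same seed and configuration.

## Known limitations

- Reported ORs with heterogeneous covariate adjustment are pooled as
  exchangeable effect sizes, exactly as summary-level meta-analyses must;
  the pathway log at least makes the mixture visible.
- No meta-regression, Hartung–Knapp adjustment, REML/PM τ² estimators,
  trim-and-fill, or selection models in this version.
- The quantitative per-genotype fallback slope approximates the residual
  variance by the pooled within-genotype variance (the 1-df lack-of-fit
  component is unavailable from summaries); with β of realistic size the
  approximation is conservative by a negligible margin.
- The packaged study tables reproduce accounting totals and allele
  frequencies, not pooled effects: the source's per-study effect sizes
  exist only in its figures, so its pooled columns cannot be recomputed
  from any machine-readable input, here or anywhere.
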