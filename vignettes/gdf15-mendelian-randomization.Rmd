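---
title: "Two-sample Mendelian randomization of GDF-15 on cardiovascular outcomes: methods and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization of GDF-15 on cardiovascular outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gdfmr)
```

## The question and the design

Circulating growth differentiation factor 15 (GDF-15) is a stress-responsive
TGF-β-superfamily cytokine repeatedly associated with cardiovascular disease
in observational cohorts, where confounding and reverse causation (sick
hearts raise GDF-15) cannot be excluded. Mendelian randomization (MR) sidesteps
both by using genetic variants as instrumental variables: alleles are
assorted at conception, so a SNP that raises circulating GDF-15 provides a
randomized, lifelong "dose" of the exposure. In the *two-sample* design the
SNP–exposure effects $\hat\gamma_j$ come from a GDF-15 GWAS and the
SNP–outcome effects $\hat\Gamma_j$ from independent disease GWAS
(stroke subtypes, atrial fibrillation, heart failure, nonischemic
cardiomyopathy, coronary artery disease, myocardial infarction), combined
purely at the summary-statistic level.

`gdfmr` implements each stage of that pipeline as a tested function:
plain-text I/O for summary statistics and LD matrices, instrument
selection, allele harmonization, the estimators with their diagnostics,
and a generator of synthetic summary statistics with known ground truth.
The numbered scripts under `analysis/` are thin drivers over these
functions.

## Instrument selection

Candidates become instruments by passing three filters, applied in a fixed
order:

1. **Genome-wide significance**: keep $p < 5\times10^{-8}$, strictly — a
   SNP at exactly the threshold is dropped.
2. **LD pruning**: correlated instruments double-count information, so for
   any pair with $r^2 \ge 0.8$ one member is dropped. Pruning is greedy:
   the unprocessed SNP with the smallest p-value is kept and all SNPs at
   or above the threshold with it are dropped (recording the retained
   partner and the $r^2$), until none remain. Ties in p-value break by
   lexicographic rsID so results are deterministic. Greedy smallest-p-first
   is standard clumping behavior; the published record does not say which
   member of each correlated pair was retained, so this is the package's
   choice.
3. **Pleiotropy exclusions**: an offline rsID list stands in for a
   database screen (e.g. PhenoScanner) of known secondary trait
   associations. File-based so the analysis is reproducible without
   network access.

The selection report partitions the input exactly: every candidate rsID is
kept or appears in exactly one dropped bucket, and selection re-run on its
own output is a no-op.

The shipped 9-SNP fixture (`gdf15_fixture()`) carries the nine published
candidate rsIDs for GDF-15 on chromosome 19. The published record names
only the membership of the kept and dropped sets — one SNP above the
significance threshold, three in high LD with retained SNPs — not the
candidate p-values or the LD pairings, so the fixture's p-values and
$r^2$ values are constructed to realize that partition and are labelled
synthetic. Default selection on it keeps the five published instruments:

```{r}
fx <- gdf15_fixture()
sel <- select_instruments(fx$exposure, fx$ld)
print(sel$report)
```

## Harmonization

The two GWAS may report a SNP against different effect alleles or opposite
strands. Each outcome record is aligned to the exposure's effect allele:
matching alleles pass through; swapped alleles flip the outcome beta's
sign (and replace eaf by 1 − eaf); strand complements are complemented
first and the same rules applied. Palindromic SNPs (A/T, G/C) are their
own complements, so strand is ambiguous; the default policy resolves them
by allele frequency when both studies report an eaf outside
$[0.42, 0.58]$ and drops them otherwise. The window and the
frequency-resolution rule are standard practice choices — the source
analysis is silent on how (or whether) palindromic instruments were
handled. Indels and multi-allelic records are rejected at read time.

Harmonization is audited: every shared rsID receives exactly one action
(`unchanged`, `flipped`, `dropped_palindromic`, `dropped_mismatch`), and
the test suite verifies *flip invariance* — corrupting outcome records by
allele swaps (with sign and frequency adjustment) leaves every downstream
estimate unchanged to machine precision.

## Estimators

Per SNP, the Wald ratio is $\hat\theta_j = \hat\Gamma_j / \hat\gamma_j$.
Its default standard error is first-order delta,
$se_j = se_{\Gamma j}/|\hat\gamma_j|$, which propagates outcome noise
only — the common two-sample default when instruments are strong. A
second-order option adds the exposure-noise term
$\hat\Gamma_j^2 se_{\gamma j}^2/\hat\gamma_j^4$. The delta expansion
itself assumes a strong instrument: at instrument z-scores near 2 the
ratio distribution is heavy-tailed and no finite-sample SD matches it,
which is why the Monte-Carlo validation of the delta SE in the test suite
uses instrument z = 10.

**IVW** pools the ratios with inverse-variance weights $w_j = se_j^{-2}$:
$\hat\theta = \sum w_j\hat\theta_j / \sum w_j$, fixed-effects
$se = (\sum w_j)^{-1/2}$. Fixed effects is the default because the
published per-outcome p-values are consistent with fixed-effects normal
inference; a multiplicative random-effects model (SE inflated by
$\max(1, \sqrt{Q/(L-1)})$) is available. Cochran's
$Q = \sum w_j(\hat\theta_j - \hat\theta)^2$ with a $\chi^2_{L-1}$ test
quantifies heterogeneity; significant Q suggests invalid instruments.

**Weighted median**: sort the ratios, form cumulative-weight midpoints
$p_j = \sum_{k\le j}\tilde w_k - \tilde w_j/2$ from the normalized
weights, and linearly interpolate the sorted ratios at $p = 0.5$. It is
consistent while valid instruments carry at least half the weight. Its SE
comes from a seeded parametric bootstrap (default 1000 replicates) drawing
$\theta_j^* \sim N(\hat\theta_j, se_j)$ — the source analysis does not
state its SE method, and the parametric bootstrap is the reference
implementation's approach.

**MR-Egger**: orient all instruments so $\hat\gamma_j > 0$ (estimates are
invariant to this), then regress $\hat\Gamma_j$ on $\hat\gamma_j$ by
weighted least squares with a free intercept and weights
$1/se_{\Gamma j}^2$. Under the InSIDE assumption (pleiotropic effects
independent of instrument strengths) the slope is a pleiotropy-robust
causal estimate and the intercept estimates the average direct
(pleiotropic) effect; a nonzero intercept flags directional pleiotropy.
Standard errors use $(X^TWX)^{-1}$ inflated by the multiplicative
overdispersion factor $\max(1, \sqrt{RSS_w/(L-2)})$, computed directly
from the design matrix so an exactly linear input (zero residuals) still
yields finite SEs. MR-Egger additionally assumes negligible measurement
error in the exposure effects (NOME); its calibration experiments below
therefore use tight exposure SEs.

All p-values are two-sided normal rather than t: with a handful of
instruments this matches the field's reference implementations. Odds
ratios are $e^{\hat\theta}$ with CI $e^{\hat\theta \pm z_{0.975}\,se}$.
The 0.05 significance convention is reported but never gates any
computation, and no multiple-testing correction is applied across the
nine outcomes, mirroring the source analysis; the run manifest records
this.

## The synthetic generator and what it does (not) show

`simulate_pair()` draws, per SNP, an instrument strength $\gamma_j \sim
U(\text{gamma\_range})$, a pleiotropic effect $\alpha_j$ (zero for valid
SNPs; $N(\alpha_\mu, \alpha_\sigma)$ for the configured invalid
fraction), and observed effects

$$\hat\gamma_j \sim N(\gamma_j, se_{xj}^2), \qquad
  \hat\Gamma_j \sim N(\theta\gamma_j + \alpha_j, se_{yj}^2),$$

which is exactly the sampling regime the estimators assume. Defaults are
50 SNPs, $\theta = 0.1$, $\gamma_j \in [0.1, 0.3]$, exposure SEs in
$[0.01, 0.02]$ and outcome SEs in $[0.02, 0.05]$ — instrument z-scores of
roughly 5–30 and per-SNP ratio SEs of roughly 0.1–0.5, the scale of a
well-powered cis-protein GWAS paired with large case-control outcome
GWAS. Pipeline-shaped tests use 5 SNPs with $\gamma_j \in [0.2, 0.3]$ and
exposure SEs of 0.005–0.01 so that every simulated candidate clears the
genome-wide filter, as the five published instruments did. Because
$\alpha_j$ is drawn independently of $\gamma_j$, InSIDE holds by
construction.

Simulation is at the summary level only. Real data differ in ways the
generator deliberately omits: LD between instruments (the generator's LD
matrices are block toys for testing the pruner), sample overlap between
exposure and outcome studies, case-control liability-scale effects,
winner's curse in instrument discovery, and InSIDE violations. Passing
calibration here shows the estimators are implemented correctly, not that
those assumptions hold in any real application.

Calibration experiments (reproduced at full size in the test suite, at
200 replicates in `analysis/04_estimator_calibration.R`):

- *Recovery*: with no pleiotropy, mean IVW, weighted-median and Egger-slope
  estimates over 500 replicates of the 50-SNP default scenario fall within
  three Monte-Carlo SEs of $\theta = 0.1$.
- *Pleiotropy detection*: with directional pleiotropy
  ($\alpha_\mu = 0.05$, every SNP invalid, InSIDE holding) the Egger
  intercept's mean is within Monte-Carlo error of 0.05 while IVW is
  markedly biased. Exposure SEs are tightened to 0.005–0.01 in this
  scenario so NOME holds; with the default exposure noise a small
  regression-dilution bias would contaminate the intercept, which is a
  property of MR-Egger, not of this implementation.
- *Type-I error*: under zero pleiotropy the intercept test rejects at
  5% within binomial error over 1000 replicates. The $\max(1,\cdot)$
  overdispersion floor makes the test slightly conservative, which the
  band accommodates.

## Numerical and policy choices

- P-value boundary semantics are strict on both filters: keep only
  $p < 5\times10^{-8}$; drop at $r^2 \ge 0.8$.
- Simulated p-values are clamped at the smallest positive double; strong
  instruments would otherwise underflow to an invalid $p = 0$.
- Weighted-median interpolation uses `rule = 2` (clamped extrapolation),
  so a single dominant weight returns that SNP's ratio.
- Missing `eaf`/`n` are empty fields in files, never 0; positions are
  1-based; the canonical dialect is tab-separated with header, and commas
  are accepted on read.
- With fewer than three harmonized instruments the pipeline reports IVW
  and marks the sensitivity methods not applicable; with fewer than one,
  the outcome is marked failed and sibling outcomes continue.
- Instruments are selected once on the exposure study and reused across
  outcomes; harmonization is per-outcome. Forest rows carry the IVW
  estimate, one per outcome.

## Limitations

The consortium GWAS behind the published analysis are not shipped, so the
package cannot reproduce the published per-outcome estimates end-to-end;
the nine outcome files in the fixture are synthetic stand-ins generated
around the published effect scales. What the package does reproduce from
the published record alone: the 9 → 5 instrument selection partition, the
odds-ratio conversions, and the two-sided p-values implied by the
published estimate/SE pairs. The published record also contains an
internal inconsistency — its table caption mentions three instruments
while its abstract and results name five — which the pipeline surfaces by
recording the instrument count per outcome in the results grid rather
than guessing.
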