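# gdfmr

Two-sample Mendelian randomization (MR) of circulating growth
differentiation factor 15 (GDF-15) against nine cardiovascular outcomes —
any ischemic stroke and its cardioembolic / large-artery / small-vessel
subtypes, atrial fibrillation, heart failure, nonischemic cardiomyopathy,
coronary artery disease and myocardial infarction — built as a reusable,
tested pipeline over GWAS summary statistics. It is written for
epidemiologists and statistical geneticists who want each stage of such an
analysis to be an auditable function rather than a one-off script.

## The method

Genetic variants are randomized at conception, so a SNP that raises
circulating GDF-15 acts as an instrumental variable free of the
confounding and reverse causation that plague observational biomarker
studies. With SNP–exposure effects γ̂ⱼ (se_xⱼ) from a GDF-15 GWAS and
SNP–outcome effects Γ̂ⱼ (se_yⱼ) from independent disease GWAS:

- **Wald ratio** per SNP: θ̂ⱼ = Γ̂ⱼ/γ̂ⱼ, delta-method SE (first-order
  se_yⱼ/|γ̂ⱼ| by default).
- **IVW**: θ̂ = Σwⱼθ̂ⱼ/Σwⱼ with wⱼ = 1/seⱼ², fixed-effects
  SE (Σwⱼ)^(−1/2), Cochran's Q heterogeneity test on L−1 df.
- **Weighted median**: the weighted 50th percentile of the sorted ratios
  (consistent while valid instruments hold ≥ 50% of the weight), bootstrap
  SE.
- **MR-Egger**: weighted regression of Γ̂ on γ̂ with a free intercept;
  the slope is robust to directional pleiotropy under InSIDE and the
  intercept tests for it.

Estimates are reported on the log-odds scale and as odds ratios with 95%
CIs; all p-values are two-sided normal. Instruments are selected by a
strict genome-wide filter (p < 5×10⁻⁸), greedy LD pruning (drop at
r² ≥ 0.8) and an offline pleiotropy exclusion list, then harmonized
per outcome (allele swaps, strand complements, frequency-resolved
palindromes). A synthetic summary-statistics generator with known causal
effect and configurable pleiotropy backs the validation suite.

## Worked example

The shipped fixture carries the nine published candidate instruments for
GDF-15 (chromosome 19; the candidate p-values and LD values are synthetic
stand-ins realizing the published kept/dropped partition, since the source
GWAS are not redistributable):

```r
library(gdfmr)
fx  <- gdf15_fixture()
sel <- select_instruments(fx$exposure, fx$ld)
print(sel$report)
#> Instrument selection: 9 candidates -> 5 kept
#>   dropped (p-value):  1 rs16982345
#>   dropped (LD):       3 rs1054564 rs3746181 rs1363120
#>   dropped (excluded): 0
```

One SNP misses genome-wide significance and three are pruned for high LD
(r² ≥ 0.8) with a retained SNP, leaving the five published instruments.
Estimation against the cardioembolic-stroke outcome file:

```r
h <- harmonize_sets(sel$stats, fx$outcomes$CES)$harmonized
r <- wald_ratio(h)
rbind(as.data.frame(ivw(r)),
      as.data.frame(weighted_median(r, seed = 1)),
      as.data.frame(mr_egger(h)))
#>           method n_snps estimate     se  pval odds_ratio ci_low ci_high
#>              IVW      5   0.0717 0.0696 0.303      1.074  0.937    1.23
#>  weighted_median      5   0.0551 0.0856 0.519      1.057  0.893    1.25
#>         MR_Egger      5  -0.0482 0.9950 0.961      0.953  0.136    6.70
```

Read: a log-odds estimate of 0.0717 per unit GDF-15 means an IVW odds
ratio of 1.07 (95% CI 0.94–1.23) for cardioembolic stroke per unit
increase in genetically predicted GDF-15; Q = 0.90 (p = 0.92) shows no
heterogeneity across the five ratios and the Egger intercept 0.015
(p = 0.90) no directional pleiotropy. These numbers describe the synthetic
outcome files, not the consortium data.

The full analysis is scripted:

```sh
Rscript analysis/01_build_inputs.R            # fixture + simulated inputs
Rscript analysis/02_select_instruments.R      # 9 -> 5 selection report
Rscript analysis/03_run_mr.R                  # 9-outcome grid, forest rows
Rscript analysis/04_estimator_calibration.R   # recovery/pleiotropy checks
```

Outputs land under `results/`: a Table-1-style grid
(`mr_results.tsv`: per-outcome IVW / weighted-median / MR-Egger estimate,
SE, p, Egger intercept and p, IVW OR with CI), forest-plot rows, selection
and harmonization reports, and a JSON run manifest.

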