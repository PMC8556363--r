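# driverdelta

Burden-adjusted differential prevalence of somatic driver mutations, for
cancer-genomics analysts comparing a metastatic and a localized disease
state — prostate cancer being the motivating setting — and screening the
enriched mutations as prognostic biomarkers of relapse.

## The problem and the statistic

Metastatic castration-resistant prostate cancer (mCRPC) carries several
times the SNV burden and percent genome altered (PGA) of localized
disease, so raw prevalence differences in any driver gene partly reflect
background mutation rate rather than selection. For each driver mutation
type *g* (a gene × class pair over CNA gain/loss, coding SNV, non-coding
SNV, SV), `driverdelta` computes

- observed Δ = P̂(g | mCRPC) − P̂(g | localized), each prevalence over the
  samples assayed for that class (missing assays are `NA`, never 0);
- expected Δ = the mean of Monte-Carlo simulations in which each sample
  *i* carries *g* independently with its burden-implied null probability
  P_i = 1 − (1 − g/G)^(N_i) (SNV classes: N_i variants from the sample's
  SNVs/Mbp; CNA classes: a segment process with M_i ∝ PGA_i segments of
  mean length λ);
- **adjusted Δ = observed Δ − expected Δ**, with a two-sided empirical
  p-value from the simulated null (halved for CNA classes, floored at
  1/n_iter) and BH-FDR q-values across all mutation types.

Mutation types with q < 0.05 and ≥5% localized prevalence are screened
by univariable Cox proportional hazards against the metastasis endpoint,
with Kaplan–Meier/log-rank, Schoenfeld checks, and 2×2 odds ratios
(Woolf CI, Fisher exact p) alongside. A synthetic-cohort generator with
planted enrichment effects and hazard ratios makes every stage testable
without any data download.

## Worked example

Prevalence confidence intervals and 2×2 associations from published
counts:

```r
library(driverdelta)
wald_ci(395 / 555, 555)     # AR gain in mCRPC: 71.2%
#>   ci_low ci_high
#> 1  0.674   0.749
two_by_two(9, 27, 18, 323)  # loss vs metastatic relapse
#>       a     b     c     d odds_ratio ci_low ci_high fisher_p
#> 1     9    27    18   323       5.98   2.45    14.6 0.000329
```

A synthetic cohort with one planted enrichment (δ = 0.25 excess
probability in mCRPC) and a planted hazard ratio of 4:

```r
library(dplyr)
catalog <- synthetic_driver_catalog(6)
truth <- synthetic_truth(catalog, delta = c("G002:CNA_loss" = 0.25),
                         log_hr = c("G002:CNA_loss" = log(4)))
cfg <- synthetic_config(n_localized = 300, n_mcrpc = 150, seed = 7,
                        null = null_model_config(n_iter = 10000, seed = 7,
                                                 cna_segment_mbp = 1))
cohort <- generate_cohort(cfg, catalog, truth)
diff <- differential_table(cohort$matrix, cohort$samples, catalog, cfg$null)
diff |> select(mutation_type, observed_delta, expected_delta,
               adjusted_delta, q_value, direction)
#>   mutation_type observed_delta expected_delta adjusted_delta q_value direction
#> 1 G001:CNA_gain        0.283          0.222         0.0613    0.126  null
#> 2 G002:CNA_loss        0.43           0.260         0.170     0.0006 enriched_mCRPC
#> 3 G003:SNV            -0.00333        0.0279       -0.0312    0.126  null
#> 4 G004:ncSNV           0.01           0.00693       0.00307   0.898  null
#> 5 G005:SV              0.343          0.349        -0.00531   0.898  null
#> 6 G006:CNA_gain        0.373          0.373         0.000227  0.738  null
```

Only the planted gene is called enriched: its observed prevalence gap of
0.43 decomposes into 0.26 explained by the higher mCRPC burden and 0.17
of genuine excess (the planted 0.25 diluted by probability clipping and
sampling). The outcome screen then recovers it as prognostic:

```r
screen_candidates(diff, cohort$matrix, cohort$samples, cohort$outcomes)
#>   mutation_type prevalence_localized differential_q    hr ci_low ci_high        p method selected
#> 1 G002:CNA_loss               0.0833         0.0006  4.19   2.62    6.69  2.08e-9    cox     TRUE
```

The estimated hazard ratio of 4.19 brackets the planted value of 4
inside its Wald CI. `run_pipeline()` chains these stages (simulate →
matrix → prevalence → differential → screen) and writes TSV outputs with
a JSON manifest whose checksums are identical for identical config and
seed; `inst/scripts/driverdelta.R` wraps it for the shell.

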