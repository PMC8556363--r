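---
title: "Burden-adjusted differential prevalence of driver mutations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Burden-adjusted differential prevalence of driver mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driverdelta)
library(dplyr)
```

## The problem

Metastatic castration-resistant prostate cancer (mCRPC) carries far more
somatic mutation than localized disease: several-fold higher SNV burden
and a much larger fraction of the genome altered by copy-number
aberrations (PGA). A driver mutation that is more *prevalent* in mCRPC is
therefore not automatically more *selected* in mCRPC — some of the excess
is exactly what a higher background mutation rate produces by chance in
any gene of that size. `driverdelta` separates the two: for each driver
mutation type (a gene or locus crossed with a mutation class — CNA gain,
CNA loss, coding SNV, non-coding SNV, or SV) it asks how much of the
prevalence difference between disease states survives after accounting
for each sample's own global burden. Mutation types enriched beyond
burden are then candidate prognostic biomarkers, screened against relapse
outcomes in the localized stratum.

## Prevalence bookkeeping

Prevalence of a mutation type is the per-patient proportion
$P = x / n$ over samples *assayed for that class* — cohorts differ in
which platforms they ran, so each class has its own denominator and a
cell that was never assayed is `NA`, not 0. Wald 95% intervals
$P \pm 1.96\sqrt{P(1-P)/n}$ are clipped to $[0,1]$ after the
$\pm$ computation (`wald_ci()`).

Per-gene combined prevalence ("a mutation of any kind") defaults to the
exact empirical union: the proportion of samples with at least one
present cell across the gene's classes. A second method,
`eq3_literal`, evaluates the closed-form bookkeeping
$(P_{CNA}+P_{SNV}+P_{SV}) - (P_{CNA\&SNV}+P_{CNA\&SV}+P_{SNV\&SV}+P_{CNA\&SNV\&SV})$
with every term on its own denominator. This form *subtracts* the triple
joint term where standard inclusion–exclusion adds it, so on a sample
carrying all three classes the two methods differ by exactly twice the
triple proportion; whether joints mean "at least both" or "exactly both"
is also ambiguous in the published bookkeeping, and we take "at least
both". The union method is the default precisely because it is exact and
assumption-free; the literal form is retained for reproduction, and the
propagation-of-error terms
($PE = \sqrt{CI_{up}^2 + CI_{low}^2}$ per class, variance
$\sqrt{\sum PE_{singles} - \sum PE_{joints}}$) are evaluated literally on
CI *bounds*, returning `NaN` with a flag when the radicand is negative
rather than reinterpreting the formula.

## The burden-weighted binomial null

The core statistic is the **adjusted Δ proportion**. For mutation type
$g$:

* observed Δ = prevalence in mCRPC − prevalence in localized;
* expected Δ = the mean prevalence difference across Monte-Carlo
  iterations in which every sample $i$ carries the mutation independently
  with its own null probability $p_i$;
* adjusted Δ = observed − expected.

The per-sample null probability is the chance that the sample's global
burden alone hits the gene's footprint at least once:

* **SNV classes.** A sample with burden $b$ SNVs/Mbp over reference size
  $G$ Mbp carries $N = \mathrm{round}(bG)$ variants; each lands in the
  coding footprint $g$ Mbp with probability $g/G$, so
  $P = 1-(1-g/G)^N$, computed in log space. $G$ is the genome
  (3000 Mbp) for WGS-derived burdens; a per-sample `snv_ref_mbp` column
  supports exome-derived burdens, for which we default to 45 Mbp — the
  size of a typical exome capture design.
* **CNA classes.** Per-base independence is untenable here: PGA of even a
  few percent would make every gene's null probability saturate near 1.
  We therefore model the sample's copy-number disruption as a segment
  process: $M = \max(1, \mathrm{round}(\mathrm{PGA} \cdot G/\lambda))$
  segments of mean length $\lambda$ (default 10 Mbp, the scale of arm- and
  band-level events; exposed as `cna_segment_mbp`), each overlapping a
  gene of span $g$ bp with probability $(g/10^6+\lambda)/G$. This
  preserves burden weighting — the null probability is monotone in PGA —
  without degeneracy, and $P = 1-(1-p_{seg})^M$.

Each iteration draws one Bernoulli per sample and records the simulated
prevalence difference; 100,000 iterations by default (tests and examples
scale down to 10^4^, which changes Monte-Carlo error only). The empirical
p-value is the two-sided exceedance about the null mean,
$\#\{|\delta_{sim}-\bar\delta| \ge |\delta_{obs}-\bar\delta|\}/n_{iter}$.
For CNA classes the exceedance is halved, reproducing the published
rule that accounts for a CNA being either a gain or a loss; note this
makes the CNA p-values nominally anti-conservative by a factor of two
relative to plain exceedance — the calibration tests assert uniformity
for the plain-exceedance classes and the doubled rate for CNA classes,
rather than pretending both are uniform. The p-value is floored at
$1/n_{iter}$ (an empirical zero is never reported; the floor is applied
*after* the halving) and BH-FDR corrected jointly across all tested
mutation types.

Two implementation details matter for reproducibility and symmetry:

* Every mutation type derives an order-independent substream seed from
  the run seed and its alphabetical rank, so adding or reordering
  catalog entries never changes another entry's result.
* Uniform draws are made per sample in cohort order, not per state, so
  swapping the two state labels under the same seed negates every
  simulated difference *exactly* — observed, expected and adjusted Δ are
  all antisymmetric bitwise, which the tests assert with `identical()`.

## From differential to biomarker

Candidates must pass two gates: differential $q < 0.05$, and prevalence
of at least 5% among all assayed localized samples (rarer lesions cannot
be practically useful biomarkers). Each candidate is then fit in a
univariable Cox proportional-hazards model against the metastasis
endpoint in the localized stratum (Efron tie handling — follow-up is
recorded in months, so ties are common and Efron is the less biased
choice), with BH correction across the candidate set only.
Proportional hazards is checked per covariate via the Schoenfeld-residual
test; a violating candidate's p-value falls back to the log-rank test,
and the report records which was used. Complete separation (e.g. every
carrier relapsing) raises an error rather than returning a divergent
estimate. 2×2 associations (`two_by_two()`) report the cross-product
odds ratio with a Woolf CI on the log scale and a two-sided Fisher exact
p; a zero cell triggers the Haldane–Anscombe +0.5 correction for the
OR/CI only, never for the Fisher test.

## Scores

* `pga()` — union of altered segments over the genome size; the adjusted
  form excludes a chromosome from *both* numerator and denominator (the
  source method states only that the chromosome is omitted; dropping it
  from both sides is our choice — it keeps the statistic a true
  proportion of the assayable genome).
* `fraser_signature()` — the six-feature clinico-genomic score: MYC gain,
  ATM SNV, chr7:61 Mbp translocation, TCERGL1 hypomethylation, ACTL6B
  hypermethylation (methylation dichotomized at the cohort median), and
  clinical T category (cT2c = 1). The 0–6 integer sum is the regression
  covariate; the median-dichotomized bin is display-only.
* `ccp_score()` — mean log2 abundance of the cell-cycle-progression gene
  set minus the housekeeping mean; exactly shift-invariant. Gene lists
  are supplied by the caller (the canonical 31/15 identities are cited to
  commercial assays, not printed, so the package ships no hard-coded
  list).
* `youden_cutpoint()` — exhaustive scan of observed values in both
  orientations for the threshold maximizing sensitivity + specificity − 1;
  ties break toward the lower threshold, making the result deterministic.
* `stratify_abundance()` — median or quartile bins; boundary ties go to
  the lower bin.

## The synthetic cohort generator

`generate_cohort()` emulates the structure the analysis assumes, and its
defaults are fixed study conditions, not tuning knobs:

* SNV burden: log-normal, median 1 SNV/Mbp localized vs 4 SNVs/Mbp
  mCRPC, sdlog 0.5 — the several-fold burden elevation reported for
  metastatic disease at realistic WGS scales.
* PGA: Beta(2, 38) localized (mean 5%) vs Beta(5, 15) mCRPC (mean 25%).
* Cohort sizes default to 200 localized / 100 mCRPC and scale up to the
  real cohorts' 1289/555.
* Planted enrichment is *additive on the probability scale*
  ($p = \min(1, p_{null} + \delta\,[\text{mCRPC}])$), so a planted
  $\delta$ is directly comparable to an adjusted Δ. Genes with
  $\delta = 0$ form the calibration set.
* Outcomes are exponential proportional-hazards times
  ($\lambda_0 e^{\sum \beta_g x_g}$, baseline 0.01/month) with
  independent Uniform(0, b) censoring, b solved numerically so the
  marginal censoring fraction under the baseline rate matches the
  configured target (0.6 for the recovery experiments, i.e. ~40%
  events); the solution is approximate when planted hazards shift event
  times.
* The expression/methylation generator couples log2 RNA to a standard
  normal promoter M-value with coefficient 0.4 and residual sd
  $\sqrt{1-0.4^2}$, targeting Spearman ρ ≈ −0.4, with carriers of the
  designated loss shifted down in RNA and up in methylation.

What the generator does *not* emulate: real genome coordinates beyond
footprint bookkeeping, subclonality, multifocality, cohort-specific
caller artifacts, or correlated co-mutation structure. Passing tests
therefore demonstrate that the statistical machinery is correct under
its stated model, not that the model captures every feature of real
cohorts — in particular, the published per-cohort pipelines differed
("unique analysis pipelines per cohort" is explicitly out of scope here,
replaced by one harmonization).

## Problem sizes and numerical choices

The shipped tests run the calibration at 78 mutation types × 250 samples
× 10^4^ iterations, the enrichment recovery at 20 seeds × 400 samples,
and the hazard-ratio coverage at 100 seeds × 400 samples — sizes at
which every asserted property has comfortable statistical margin while a
full run stays in the minutes range. The recovery experiment's 200
samples per state follow from an a-priori power computation: at
$\delta = 0.15$ the prevalence-gap standard error must be below ~0.033
for 90% detection at the BH-corrected level, requiring roughly 190
samples per state. Other fixed choices: Cox convergence tolerance
10^-9^; Monte-Carlo chunking keeps peak memory near a few million
doubles regardless of `n_iter`; SEG input is treated as 1-based
inclusive and converted to 0-based half-open on read; a CNA hits a gene
on any ≥1 bp overlap (the catalog carries gene-level spans only);
unknown SV subtypes count toward unrestricted SV entries, while
subtype-restricted entries (e.g. inversions-only) accept only their
listed subtypes.

## Known limitations

* The published adjusted-Δ headline values are not reproducible without
  the real cohorts' per-sample burdens; the package validates the method
  on synthetic cohorts with known truth instead.
* The segment-process CNA null is a modeling choice; the source method
  does not specify how PGA becomes discrete events, and λ shifts
  absolute null probabilities (it is exposed in the configuration for
  sensitivity analysis).
* The literal combined-prevalence form and the PE variance can produce
  values outside [0,1] or `NaN` on extreme inputs; they are flagged, not
  silently repaired.
* Fisher exact p-values are emitted alongside the simulation p-values
  because the published figure legends attribute significance to
  "adjusted Fisher's Exact tests" while the methods describe the
  simulation; both are available and neither is asserted to be the
  published q-value's source.
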