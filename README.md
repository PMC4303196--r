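# regact — transcription-factor regulatory activity scoring for survival prognosis

A transcription factor's transcript level is a weak proxy for its activity;
the expression of its *target genes* is the functional readout.  regact
implements the full analysis chain around that idea, for anyone who has an
expression cohort with survival annotation and a target-gene signature (or
ChIP-seq binding data to derive one):

* **Signature derivation** — TIP-style probabilistic target calling from
  TSS-proximal binding signal (BED/bedGraph in, weighted binding score, z,
  upper-tail normal p, Benjamini–Hochberg FDR at 1% by default), and
  consensus construction by intersecting per-cell-line target sets.
* **Activity scoring (iRAS)** — for each sample, genes are ranked by
  decreasing relative expression and the score is the signed maximum
  deviation between the target and non-target rank CDFs:

  $$\mathrm{iRAS} = d(i^\*),\quad d(i) = F_T(i) - F_N(i),$$

  so |iRAS| is the two-sample Kolmogorov–Smirnov D between target and
  non-target ranks and the sign is positive when targets sit at high
  expression.  Significance comes from a permutation null of random
  same-size gene sets (≥10,000 draws by convention), with z-scores and
  add-one empirical p-values.
* **Periodicity** — Fisher's exact g-test on activity/expression time
  courses (largest periodogram ordinate over total spectral power).
* **Survival** — Kaplan–Meier/log-rank comparison of the iRAS > 0 vs
  iRAS < 0 groups, Cox proportional-hazards models with
  clinicopathological covariates (Efron ties, via the survival package),
  gene-wise survival screens, signature enrichment among survival genes
  (fold + Fisher exact), Nottingham Prognostic Index banding
  (<3.4 / 3.4–5.4 / >5.4) and single-gene median-split stratification.
* **Intrinsic subtypes** — centroid assignment by Spearman correlation
  (argmax over shared genes, exclusion below 0.1), and the
  subtype-by-activity composition table.
* **Simulators** — cohorts with planted activity and survival, periodic
  time courses, TSS-proximal binding and centroid-structured subtypes,
  each returning its ground truth, so every stage is validated end-to-end
  with no external data.

Data containers are Bioconductor S4: expression lives in a
`RegExprSet` (a `SummarizedExperiment` carrying its channel mode — one-channel
log intensities must be gene-wise median-centred before scoring, and the
package enforces this), TSS annotation in a `GRanges`, results in small
validated classes.

## Worked example

```r
library(regact)

## a simulated 300-sample cohort: 2,000 genes, a 100-gene signature whose
## expression is shifted by a latent per-sample activity, exponential
## survival with higher hazard in high-activity samples
sim <- genCohort(simConfig(nGenes = 2000, nSamples = 300, signatureSize = 100,
                           effectBeta = 1.5, seed = 2024))

act <- computeIrasMatrix(sim$expr, sim$signature, nPerm = 1000, seed = 1)
act
#> ActivityScores for 'planted': 300 samples (164 positive, 136 negative), 1000 permutations
#>   iras range: [-0.986, 0.969]
head(activityTable(act), 3)
#>   sample_id       iras         z       p_emp    group
#> 1     s0001  0.5452632  6.008940 0.000999001 positive
#> 2     s0002  0.3042105  3.331388 0.000999001 positive
#> 3     s0003 -0.1510526 -1.663222 0.020979021 negative

## dichotomize at iRAS = 0 and relate activity to outcome
grp <- dichotomize(act)
cd  <- clinicalData(sim$clinical)
kmLogrank(cd$surv_time, cd$surv_event, grp)$p
#> [1] 1.04e-09

fitCox(data.frame(activity = grp, age = cd$age, grade = cd$grade,
                  size = cd$tumor_size, er = cd$er_status,
                  ln = cd$ln_status), cd$surv_time, cd$surv_event)
#> CoxResult: 300 samples, 221 events
#>   activitypositive         HR 2.316 (95% CI 1.75-3.07), p = 4.55e-09
#>   age                      HR 1.022 (95% CI 1.01-1.04), p = 0.00168
#>   grade                    HR 1.205 (95% CI 0.99-1.46), p = 0.0565
#>   size                     HR 1.016 (95% CI 1.00-1.03), p = 0.0266
#>   erpositive               HR 0.811 (95% CI 0.60-1.11), p = 0.186
#>   lnpositive               HR 1.089 (95% CI 0.82-1.44), p = 0.555
```

The high-activity group carries roughly twice the hazard of the
low-activity group even after covariate adjustment — the planted effect
(log HR 0.7, i.e. HR ≈ 2) recovered through the whole pipeline: expression
→ ranking → signed KS-type score → dichotomization → Cox model.

Enrichment of a signature among survival-associated genes, from the screen
counts of a published genome-wide analysis (751 of 10,333 genes significant
overall vs 58 of the 102 measured signature genes):

```r
enrichmentFold(10333, 751, 102, 58)
#> EnrichmentResult: 58/102 in set vs 751/10333 overall -> 7.82-fold (Fisher p = 8.4e-40)
```

See the vignette (`vignettes/regulatory-activity-scoring.Rmd`) for the
model details, conventions (tie rules, channel modes, thresholds) and the
validation design.

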