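# ddrFoci

Quantitative scoring of 53BP1 DNA-damage-response (DDR) patterns in
lymphoid-lesion immunofluorescence, with dual-color interphase FISH
genotyping and the diagnostic statistics built on top of both.

## The problem

Distinguishing early B-cell lymphomas (follicular lymphoma, mantle cell
lymphoma, MALT lymphoma) from benign lymphoid proliferations in small biopsy
specimens is hard on morphology alone. 53BP1, a DNA damage response protein,
forms discrete nuclear foci (NF) at double-strand breaks, and the
per-nucleus pattern of 53BP1 staining carries diagnostic signal. Each
nucleus is assigned one of five patterns:

| pattern | definition | grouping |
|---|---|---|
| stable | no or weak staining, no foci | normal |
| low DDR | 1–2 discrete NF < 1 µm | normal |
| high DDR | ≥ 3 discrete NF < 1 µm | abnormal |
| large focus | any NF ≥ 1 µm | abnormal |
| diffuse | intense, heterogeneous pan-nuclear staining | abnormal |

The per-case **abnormal fraction** — the percentage of nuclei that are high
DDR, large focus or diffuse — separates malignant from benign lesions:
lesions are compared against Youden-optimal cutoffs (27.2 % for
follicular-shape lesions, 33.6 % for small-cell lesions, 22.9 % for
large-cell lesions). In MALT lymphoma the abnormal fraction further
associates with the t(11;18)(q21;q21) BIRC3–MALT1 fusion, detected by
dual-color FISH as colocalized green/orange signals, which marks
eradication-therapy-resistant disease.

## What the package does

- **Synthetic data** (`lesionParams`, `sampleCohort`, `composeNucleusTruths`,
  `renderIfImage`, `renderFishImage`, `simulateIfCase`,
  `simulateFishSlide`): generates cohorts whose per-case abnormal fractions
  follow the published per-lesion median/IQR summaries (location-scale Beta
  fits), and renders multichannel fields (DAPI + 53BP1, or DAPI +
  green/orange probes) with per-nucleus ground truth.
- **Segmentation and focus detection** (`projectZstack`, `segmentNuclei`,
  `detectFoci`, `diffuseMetrics`): Otsu + distance-transform watershed
  nucleus segmentation; multiscale Laplacian-of-Gaussian blob detection with
  relative thresholds; focus sizes reported as area-equivalent diameters of
  the half-maximum region, in µm.
- **Pattern classification** (`classifyNucleus`, `assignRegion`,
  `summarizeCase`): the five-class rule with precedence
  diffuse > largeFocus > focus counts; FDC/BCL2 region gating (GC, PF, MM,
  LA); per-case class fractions.
- **FISH calling** (`detectFishSignals`, `pairFusions`,
  `callNucleusGenotype`, `summarizeFishCase`): greedy minimum-distance
  green–orange pairing within a 0.6 µm colocalization radius; per-nucleus
  genotypes (wild / fusion / trisomy 18q21 / other / uninformative); slide
  calls requiring ≥ 150 informative nuclei and a 10 % case threshold.
- **Diagnostics** (`rocAuc`, `youdenCutoff`, `exactWilcoxon`,
  `spearmanRank`, `ordinalTrend`, `maltAssociation`, `diagnoseLesion`):
  Mann–Whitney AUC with DeLong confidence intervals, Youden-index cutoffs,
  an exact permutation Wilcoxon rank-sum test with mid-rank tie handling,
  the MALT association/therapy analysis, and the decision-flow rule engine.
- **Pipelines** (`runIfPipeline`, `runFishPipeline`, `writeImageField`,
  `readImageField`): TIFF + JSON-sidecar I/O and end-to-end scoring with
  CSV outputs and deterministic run reports.

## Worked example

Simulate a mantle-cell-lymphoma case at the published median abnormal
fraction (44.5 %), score the rendered images, and summarize:

```r
library(ddrFoci)
p   <- lesionParams()
mcl <- p[p$lesion_label == "MCL", ]
case <- list(case_id = "demo", lesion_label = "MCL", n_nuclei = 60,
             true_abnormal_fraction = 44.5)
sim <- simulateIfCase(case, mcl, seed = 7)
rec <- scoreSimulatedCase(sim)          # segment + detect + classify
summarizeCase(rec, lesion_label = "MCL")
#>  case_id lesion_label n_nuclei pct_stable pct_lowDDR pct_highDDR pct_largeFocus
#>     demo          MCL       60         35      26.67          20          13.33
#>  pct_diffuse abnormal_fraction
#>            5             38.33
attr(sim$truth, "true_abnormal_fraction")   # realized truth: 38.3
```

The recovered abnormal fraction (38.33 %) matches the realized ground truth
of the 60 rendered nuclei (38.3 %): the multinomial draw at n = 60 lands
near, not on, the 44.5 % target, and the scorer recovers what was rendered.

A synthetic follicular cohort (25 GC vs 38 FL cases drawn from the
published summaries) gives the expected separation:

```r
cohort <- sampleCohort(cohortSpec(data.frame(
  case_id = sprintf("c%02d", 1:63),
  lesion_label = rep(c("GC", "FL1", "FL2", "FL3A"), c(25, 14, 18, 6))),
  seed = 42))
rocAuc(cohort$true_abnormal_fraction, cohort$is_malignant)
#> ROC: AUC 0.976 (95% CI 0.928-1.000); Youden cutoff 24.6% -> sens 97.4%, spec 100.0% (J = 0.97)
```

The packaged 19-case MALT lymphoma table reproduces the published
association analysis:

```r
maltAssociation()
#> MALT lymphoma association analysis (19 cases, cutoff 33.6%)
#>   high-abnormal: 6 (31.6%); of these t(11;18)+: 5 (83.3%), trisomy+: 2
#>   low-abnormal: 1 translocated, 9 wild, 3 no-signal
#>   t(11;18)+ (n=6) vs t(11;18)- (n=10): exact Wilcoxon p = 0.0145
#>   aberration+ (n=7) vs wild (n=9): exact Wilcoxon p = 0.0010
#>   responders: high 2/5 (40.0%), low 7/9 (77.8%)
```

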