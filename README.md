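# cnrquant

Quantitative immunohistochemistry (IHC) for biomarkers expressed in
both the nucleus and the cytoplasm — with survivin (BIRC5) in breast
cancer as the motivating case — and the downstream prognostic analysis
that turns pixel counts into survival statistics.

Manual scoring of markers that stain both compartments is notoriously
irreproducible. The approach implemented here replaces it with an
automated chain over tissue-microarray (TMA) core images:

1. **Tissue classification.** A supervised per-pixel classifier
   separates five patterns: tumour positive, tumour negative, stromal
   fibroblasts/matrix, lymphocytes and slide background, from colour,
   stain and texture features.
2. **Stain separation and compartment quantification.** Hematoxylin
   and DAB are unmixed by colour deconvolution in optical-density (OD)
   space (`OD = -log10((v+1)/256)` per channel, standard stain
   vectors). Nuclei are segmented within tumour on the hematoxylin
   channel; cytoplasm is tumour minus nuclei. DAB-positive pixels are
   counted and binned weak/medium/strong per compartment, and a
   pseudo-colour mark-up image (nuclear positivity red, cytoplasmic
   orange/yellow) is rendered for review.
3. **Composite scoring.** Each compartment gets an *autoscore* =
   100 x (positive-pixel fraction) x (mean positive DAB OD / OD_max),
   bounded in [0, 100]. The patient-level nuclear autoscore is the
   SNAS; the **cytoplasmic-to-nuclear ratio** CNR =
   cytoplasmic / nuclear autoscore is scale-free. Duplicate cores are
   aggregated by the per-measure maximum, and the patient CNR is the
   ratio of the maxima.
4. **Cut-point discovery.** Prognostic thresholds on the continuous
   scores are found by survival decision trees: recursive binary
   splitting maximizing the two-sample log-rank statistic over all
   midpoint thresholds, selected across 10 cross-validation folds by
   held-out concordance, with normalized variable importance.
5. **Cohort statistics.** Pearson chi-square association tables,
   Kaplan-Meier curves with log-rank tests, Cox proportional-hazards
   models (Efron ties, Wald intervals) for overall and
   breast-cancer-specific survival (OS/BCSS), Spearman duplicate-core
   concordance, and subgroup (e.g. ER-positive, tamoxifen-treated)
   filters.

Because no suitable public imaging cohort exists, the package carries
a first-class **synthetic-data module**: Beer-Lambert-rendered H&DAB
core images with exact pixel-level ground truth, and patient cohorts
with configurable covariate marginals, correlated lognormal autoscores,
duplicate-core noise, a planted CNR changepoint and
proportional-hazards survival with competing other-cause mortality.
Every stage is validated by parameter recovery against that ground
truth.

## Worked example

```r
library(cnrquant)

## one synthetic core, quantified against its own ground truth
g <- generate_core_image(stain_params(fraction_positive_nuclei = 0.4,
                                      fraction_positive_cytoplasm = 0.7),
                         256, 256, seed = 11)
q <- quantify_compartments(g$image, g$truth$class_mask)
q
#> Compartment quantification (tumour 20588 px, evaluable )
#>   nuclear      1658/5385 positive (w/m/s 49/118/1491), mean OD 0.875
#>   cytoplasmic  10635/15203 positive (w/m/s 8157/2456/22), mean OD 0.351

rec <- autoscore_record(q, patient_id = "MA-0412")
round(c(rec$nuclear_autoscore, rec$cyt_autoscore, rec$cnr), 2)
#> [1] 13.47 12.26  0.91
```

The nuclear compartment is 31% positive at strong intensity (mean OD
0.875, i.e. normalized intensity 0.44), giving autoscore
100 x 0.31 x 0.44 = 13.5; the cytoplasm is 70% positive but weak, and
the CNR of 0.91 marks this core as nuclear-dominant (poor-prognosis
pattern).

```r
## a synthetic cohort with a planted protective high-CNR effect
sim <- generate_cohort(cohort_sim_config(n_patients = 359,
                                         log_hr = c(cnr_high = log(0.47)),
                                         seed = 7))
sim
#> Synthetic cohort: 359 patients, 718 cores; 130 BCSS events, 287 OS events

## threshold discovery on the measured (noisy, max-aggregated) scores
dd <- with(sim$patients, data.frame(snas = snas,
                                    cytoplasmic = cytoplasmic_autoscore,
                                    cnr = cnr, bcss_time = bcss_time,
                                    bcss_event = bcss_event))
select_model_cv(dd, seed = 7)
#> 10-fold CV: selected fold 1 (concordance 0.698)
#> Root split: cnr at 5.031

## Cox regression recovers the planted hazard ratio
cox_fit(sim$patients, "cnr_group", outcome = "BCSS")[
  , c("term", "hazard_ratio", "ci_low", "ci_high", "p")]
#>            term hazard_ratio    ci_low   ci_high           p
#> 1 cnr_grouphigh    0.4665595 0.3220698 0.6758715 5.53755e-05
```

The cross-validated tree rediscovers the planted CNR changepoint of 5
(root split at 5.03) from the noisy measured scores, and the Cox model
estimates HR 0.47 for the high-CNR group — the planted effect.

## Command line

`inst/cli/cnrquant-cli.R` exposes the stages as verbs
(`simulate-images`, `simulate-cohort`, `train`, `classify`,
`quantify`, `score`, `threshold`, `stats`, `run-all`), each taking
`--seed`, `--config` (YAML/JSON) and `--out`. `run_pipeline()` is the
equivalent R entry point; it writes per-stage CSV/JSON artifacts plus
a `manifest.json` recording seed, configuration, per-stage counts and
outputs.

Key CSV contracts: per-core scores
(`patient_id, replicate, nuclear_pct, nuclear_intensity, cyt_pct,
cyt_intensity, nuclear_autoscore, cyt_autoscore, cnr, evaluable`),
patient-level scores (same minus `replicate`, plus `snas_group`,
`cnr_group`), and the scored cohort (covariates + outcomes + scores).
Masks are single-channel PNGs with labels 0-4 (background, tumour
positive, tumour negative, stroma, lymphocyte).

## Vignette

`vignettes/cnr-quantification.Rmd` documents the model and its
assumptions, the synthetic-data calibration (what it emulates, what it
does not), all numerical choices and known limitations.
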