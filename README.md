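# prmpanel

Serum protein biomarkers for conditions such as intracranial aneurysm are
usually discovered in two stages: untargeted (discovery) proteomics nominates
candidate proteins, and targeted mass spectrometry — parallel reaction
monitoring (PRM) — quantifies a few hundred proteotypic peptides across a
clinical cohort, after which a small diagnostic panel is distilled by machine
learning. `prmpanel` implements the computational side of that workflow as a
tested R package, aimed at proteomics bioinformaticians who need each stage to
be reproducible and auditable:

* **Assay design** — in-silico tryptic digestion, proteotypic-peptide
  filtering (uniqueness, 7–25 residues, mass ≤ 6000 Da, predicted
  detectability > 0.5, no Met/Cys), precursor charge selection inside the
  350–1250 m/z scan range, top-3 transition selection excluding short b/y
  fragments, and 3-minute scheduled elution windows. The
  detectability/retention-time predictor is pluggable; a transparent,
  non-learned heuristic ships as the default.
* **Quantification** — log10 transform of Skyline-style exported peak areas
  and a two-step normalization: a longitudinal (within-batch, per-sample)
  correction anchored on spiked stable-isotope-labeled (SIL) reference
  peptides and pooled-QC runs, then a transverse (between-batch,
  per-feature) batch-median centering. Absolute amounts follow the internal
  standard formula `C_endogenous = C_SIS × area_endogenous / area_SIS`.
* **Statistics** — Mann–Whitney U (exact for small samples),
  Benjamini–Hochberg adjustment, linear-scale fold change, volcano
  classification, OPLS-DA with variable importance in projection
  (VIP, normalized so that `Σ VIP² = p`), and per-feature ROC AUC.
* **Panel selection** — differential feature reservation
  (FC > 1.2 two-sided, P < 0.05, VIP > 1), one best peptide per protein by
  AUC, a stratified 3:1 train/validation split, and recursive feature
  elimination over ridge-stabilized logistic regression with 10-fold
  cross-validation repeated 10 times; the panel size maximizing mean CV
  accuracy wins.
* **Evaluation** — sensitivity, specificity, accuracy, PPV, NPV, Matthews
  correlation coefficient

  `MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN))`,

  ROC curves, DeLong confidence intervals for the AUC, and learning curves.
* **Synthetic cohorts** — `generate_cohort()` emits PRM cohorts with known
  planted group effects, shared batch offsets, pooled-QC injections and
  heavy-reference peptides, so the entire pipeline can be validated by
  parameter recovery.

## Worked example

Simulate a discovery cohort at the default scale (212 serum samples: 100
controls, 57 unruptured, 55 ruptured; 113 peptide features, 6 batches,
18 SIL references), run the full pipeline for the aneurysm-vs-control
contrast, and inspect the report:

```r
library(prmpanel)
cfg <- run_config(contrast = "IA_vs_NC", syn = syn_config(seed = 1), seed = 1)
res <- run_pipeline(cfg)
res$report
#>   panel  dataset   auc ci_lo ci_hi    sn    sp    ac   ppv   npv   mcc
#> 1   P12 training 0.987 0.967 0.995 94.05 93.33 93.71 94.05 93.33 0.874
#> 2   P12 internal 0.929 0.820 0.974 89.29 72.00 81.13 78.12 85.71 0.625
#> 3   P12 external 0.921 0.749 0.978 66.67 95.00 84.38 88.89 82.61 0.664
```

The rows are the training partition (75% of the discovery cohort), the
internal validation partition (the held-out 25%) and a synthetic external
cohort (32 samples) scored with the frozen training model. Percent columns
are sensitivity/specificity/accuracy and predictive values; `mcc` is the
Matthews correlation. `res$panel_features` lists the selected peptides and
`res$model$cv_trace` the mean CV accuracy at every panel size visited by the
elimination. With the default generator the planted markers (`PEP001`–
`PEP006` for this contrast) dominate the selected panel.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch —
both contrasts on freshly generated default-scale cohorts, through
normalization, statistics, DFR, RFE-CV and evaluation — printing the metric
reports and writing its JSON output to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
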