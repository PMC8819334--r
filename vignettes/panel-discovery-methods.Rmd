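---
title: "Methods: from targeted serum proteomics to a diagnostic panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from targeted serum proteomics to a diagnostic panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`prmpanel` covers the computational chain of a targeted (PRM) serum
biomarker study: assay design, peak-area normalization, differential
statistics, candidate-bank bookkeeping, and machine-learning panel
selection with diagnostic-metric reporting. This vignette documents the
models behind each stage, the tunable parameters and their defaults, the
numerical choices, and what the synthetic-data validation does and does
not establish.

## Assay design

Proteins are digested in silico with trypsin rules: cleavage C-terminal to
K or R, suppressed before proline. Missed cleavages default to 0 for
proteotypic-peptide (PTP) selection — the cleanest definition of "one
peptide, one protein" — and are configurable for other uses. Candidate
peptides pass a fixed-order rule chain: uniqueness in the background
proteome, length 7–25, monoisotopic mass ≤ 6000 Da, predicted
detectability > 0.5, and no methionine or cysteine (oxidation- and
modification-prone residues make poor surrogates). The first failing rule
is the recorded rejection reason, so audit counts add up. At most two
accepted peptides are retained per protein (by detectability) and
proteins left without any eligible peptide are reported as uncovered.
Additional modification motifs can be banned via a regular-expression
list; the default is empty because only M and C are excluded explicitly
by the standard rule set.

Precursor m/z is `(M + z·1.007276)/z`. Among charges 1–3 with m/z inside
the 350–1250 instrument scan range we prefer 2+, then 3+, then 1+.
In practice the "better" charge state is picked by a human looking at
signal response; that is not algorithmically reproducible, so the
priority order — justified by tryptic peptides ionizing predominantly at
2+ — is the documented surrogate. Transitions are ranked by
spectral-library intensity after dropping b1–b3/y1–y3 (short fragments
carry little specificity); ties break toward the higher ordinal, then the
y series, a convention we fixed because library exports rarely tie except
at quantization limits. Scheduling windows are `RT ± width/2` with
`width = 3` min, clipped to the gradient; the maximum number of
concurrently open windows is reported since it bounds the instrument duty
cycle.

The detectability/iRT predictor is pluggable. The shipped
`heuristic_predictor()` is deliberately *not* a learned model: it scores
detectability with a logistic function of peptide length (peaking near
typical tryptic length 12) and the Kyte–Doolittle GRAVY index, and maps
iRT linearly from GRAVY (`50 + 25·GRAVY`). It is deterministic, bounded
in [0, 1], and exists so the rule layer can be exercised and tested
end-to-end; swap in an instrument-specific model for real designs.

## Normalization model

Peak areas are analyzed in log10, where multiplicative instrument drift
becomes additive. The two-step normalization is implemented as:

1. **Longitudinal (within batch).** Each sample is shifted by the
   difference between its spiked-reference median and the reference
   median of its batch's pooled-QC runs. This anchors every run to the
   batch's QC level and removes run-to-run drift. Batches without QC runs
   fall back to the batch-wide reference median. Which peptides anchor
   the correction (SIL references, iRT standards, or QC totals) is not
   standardized across laboratories; we default to the SIL references and
   expose the id set as an argument.
2. **Transverse (between batches).** Each feature is centered on its
   per-batch median and re-anchored at its grand median. Afterwards every
   feature's per-batch medians agree to machine precision, and the
   feature's grand median is unchanged — re-applying the step is the
   identity.

Both steps are shifts in log space (scalings in linear space), the
standard drift model, and both use medians for robustness to outlier
runs. Zero or missing areas propagate as missing values — no imputation
by default, because imputation belongs to discovery-stage tooling, not to
targeted quantification; features observed in under 50% of samples are
flagged (`flag_sparse_features()`, threshold configurable). Absolute
quantification uses the internal-standard identity
`C_endogenous = C_SIS · area_endogenous / area_SIS` with the light/heavy
ratio reported as log2.

## Differential statistics

The Mann–Whitney U test uses the exact null distribution when the pooled
sample size is ≤ 12 with no ties (where full enumeration is tractable and
the test suite verifies it against one), otherwise a normal approximation
with tie and continuity correction. Welch's t statistic is provided for
tissue-style comparisons; a double zero-variance case returns p = 1 with
a flag rather than NaN. Multiplicity is handled by Benjamini–Hochberg
step-up. Fold change is computed on linear-scale group means of the
normalized areas (the convention of the common metabolomics tooling);
volcano calls use a symmetric log2 cutoff (0.585 ≈ 1.5-fold for serum,
1.0 for tissue) and either raw or BH-adjusted p, both configurable
because published figures differ on which line they draw.

OPLS-DA is implemented from scratch in the Trygg–Wold style: columns are
autoscaled (unit variance — the standard when VIPs are the goal; constant
columns are dropped with a warning), the requested number of y-orthogonal
components is deflated out, and one predictive component is extracted.
`n_orthogonal` defaults to 1 and the model reduces exactly to PLS1 at 0.
VIP is computed from the predictive weights,
`VIP_j = sqrt(p · w_j² / Σ w²)`, so `Σ VIP² = p` and VIP > 1 keeps its
conventional "more important than average" reading.

## Panel selection

The differential feature reservation (DFR) filter keeps features with
FC > 1.2, P < 0.05 and VIP > 1. The fold-change rule is applied
two-sided (≥ 1.2 or ≤ 1/1.2): down-regulated proteins are legitimate
panel members, so a one-sided reading would discard half the signal. The
p-value is the Mann–Whitney p at 0.05; a stricter 0.001 is used in some
reporting contexts for single-peptide comparisons, but the machine-
learning pre-filter convention is 0.05 and both are arguments. Proteins
represented by several peptides are reduced to the best peptide by AUC
(ties: smaller p, then lexicographic id).

DFR and VIP are, by default, computed on the full discovery cohort before
the train/validation split — faithful to common practice, but it leaks
filter information into the internal validation set. A `strict_mode`
confines every filter statistic to the training partition; a dedicated
test checks that strict mode does not *outperform* the leaky default on
average, which is the direction the leak predicts.

The split is stratified 3:1 by class with `round(fraction · n)` per
class. RFE then eliminates one feature at a time, the one with the
smallest absolute standardized logistic coefficient in a full-training
fit (the elimination statistic is our choice; "RFE" alone does not name
one), with ties broken toward the larger univariate p. At every visited
size the mean held-out accuracy of 10-fold stratified CV repeated 10
times is recorded; fold assignments re-randomize per repeat from named
sub-seeds of the master seed. The final size maximizes mean CV accuracy
with ties toward the smaller panel, and the model is refit on the full
training set. Logistic fits use IRLS with step-halving and a small ridge
penalty (`lambda = 1e-4` on standardized features, effectively maximum
likelihood) so that completely separable subsets — common at small n —
converge to a finite, reproducible optimum instead of erroring. The
classification cutoff is 0.5 on the predicted probability.

## Evaluation

Confusion-matrix metrics follow their textbook definitions; a zero
denominator yields NA rather than a silent 0, except MCC where the
conventional 0 is returned with an explicit flag. AUC is the rank-sum
statistic with ties counted one half, identical to the trapezoid area
under the empirical ROC. The AUC confidence interval uses DeLong's
variance with a logit-scale interval clipped to [0, 1] — DeLong is the
default of the clinical ROC tools this field uses, but since published
tables rarely state their CI method, CI endpoints are never treated as
reproduction targets. A bootstrap alternative was considered and dropped:
DeLong is deterministic, which matters for byte-identical reruns.
Learning curves refit the panel on stratified subsamples: training
accuracy from the full-subsample fit (so fraction 1.0 reproduces the
full-data fit exactly) and validation accuracy from CV within the
subsample.

## The synthetic world

`generate_cohort()` draws light-channel log10 areas as
`mu_j + beta_j·g(i) + b_batch(i) + eps` with `eps ~ N(0, residual_sd²)`.
Defaults state the world the pipeline expects: 113 features over 212
samples (100 NC / 57 UR / 55 R) in 6 batches, 18 heavy SIL references,
`residual_sd = 0.2` (a ~50% linear-scale CV, typical for scheduled PRM
on serum), `batch_sd = 0.3` (batch offsets comparable to or larger than
biological effects, which is why normalization is non-optional), planted
effect size `d = 1.5` residual SDs on the log10 scale (a strong marker:
univariate AUC ≈ Φ(d/√2) ≈ 0.86), feature baselines uniform in log10
area 4.5–7.5, and three pooled-QC injections per batch. The cohort size
follows the discovery cohort the package targets; the external cohort
(20 NC / 6 UR / 6 R) reuses the same ground-truth means with fresh
batches, emulating a later acquisition campaign. QC aliquots are the
unweighted mean of the three group means — pool composition is rarely
reported, so it is exposed as configuration rather than asserted. Heavy
references are group-independent by construction (spiked after
digestion). All randomness flows through named sub-streams of one master
seed, so a fixed seed yields bit-identical cohorts, panels and reports.

What a green synthetic run establishes: the pipeline recovers planted
multiplicative group effects under additive log-normal noise and shared
per-run batch offsets, at the stated sizes. What it does not establish:
robustness to interference and integration errors in chromatographic
peaks, non-MCAR missingness (dropout here is optional MCAR only),
heavy-tailed biological variation, or correlated features from shared
pathways — real serum data have all of these, and performance numbers
from the generator must not be read as clinical estimates.

## Known limitations

* The detectability heuristic is a stand-in; its absolute scores are
  meaningless off the synthetic world, only its determinism and bounds
  are guaranteed.
* Accession normalization strips isoform suffixes, which merges isoforms
  deliberately; studies tracking isoform-specific markers need their own
  policy.
* The RFE path explores one elimination order; features eliminated early
  on a tie are never reconsidered.
* `n_orthogonal` is fixed, not cross-validated; the default of 1 is the
  common choice for single-block class discrimination.
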