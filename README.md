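# uipclassify

Development workflow for a genomic classifier of usual interstitial
pneumonia (UIP) from transbronchial biopsy (TBB) RNA-seq.

## Why

UIP is the radiologic/histopathologic pattern that defines idiopathic
pulmonary fibrosis. Confirming it usually takes a surgical lung biopsy; a
molecular test on transbronchial biopsies — small samples taken during
bronchoscopy — would spare patients that procedure. The statistical
obstacles are characteristic of the setting, and this package implements
the machinery for each of them:

* **TBBs are patchy and correlated.** Several biopsies are taken per
  patient, so cross-validation must hold out *patients*, never samples,
  and the intended clinical assay physically pools a patient's biopsies.
  The package provides leave-one-patient-out (LOPO) nested
  cross-validation and *in-silico mixing* — averaging a patient's
  normalized counts to emulate the pooled assay — with technical-noise
  replication of every mixed score.
* **Prospective samples arrive alone.** Normalization is *frozen*:
  median-of-ratios size factors against stored reference gene means and a
  closed-form variance-stabilizing transformation (VST) whose parameters
  are locked at training time, so a sample's value never depends on what
  else is in the batch.
* **Batches drift.** Sentinel control RNA re-processed in every batch
  yields per-gene variance components (fixed source + random batch +
  residual); the most batch-sensitive genes are removed before training,
  and the same components parameterize the technical-noise model and a
  score-level monitoring rule (`sigma_sv`) for gating future processing
  runs.
* **The call must be prospective.** A decision boundary is selected, ahead
  of validation, from replicated in-silico mixed scores under an averaged
  specificity > 0.90 constraint with a sensitivity floor of 0.65, then
  locked together with the model and applied once to an independent test
  cohort.

Since cohorts of this kind are not publicly deposited, the package
includes a synthetic cohort generator with the full hierarchy — patients,
lobes, biopsies, batches, lobe-level pathology diagnoses (including
discordant-lobe UIP patients and unlabelable cases), sentinel replicates,
and in-vitro pooled samples — used by all examples and tests.

## Worked example

Generate a 40-patient population, train on 30 patients, validate on the
10 held-back patients via pooled samples:

```r
library(uipclassify)

cohort <- generate_cohort(cohort_config(n_patients = 40, n_genes = 800,
                                        seed = 1))
cohort <- generate_sentinels(cohort, n_sentinels = 4, n_batches = 4,
                             seed = 2)
train_p <- cohort$truth$patients$patient_id[1:30]
test_p  <- cohort$truth$patients$patient_id[31:40]

prep <- prepare_training_data(subset_cohort(cohort, train_p),
                              n_replicates = 50)
cv <- run_lopo(prep$counts, prep$expr, prep$labels, prep$patient_map,
               prep$frozen, prep$noise, n_draws = 6, inner_k = 3, seed = 3)
cv
#> LOPO CV: 30 patients, pooled sample-level AUC 1.000, in-silico patient-level AUC 1.000

locked <- lock_final_classifier(prep, cv, n_draws = 6, inner_k = 3, seed = 4)
locked$model
#> penalized logistic classifier: 19 genes, lambda = 0.001064, mixing = 0.92
locked$boundary
#> decision boundary -5.17 (mean sens 1.000, mean spec 1.000)

pools <- generate_invitro_pools(cohort, test_p, seed = 5)
tc <- pools$counts[, paste0("pool_", test_p)]
colnames(tc) <- test_p
validate_classifier(locked$model, locked$boundary, tc, prep$frozen,
                    cohort_patient_labels(cohort)[test_p],
                    train_patients = train_p)
#> validation: AUC 1.000; sensitivity 1.00 [0.48-1.00]; specificity 1.00 [0.48-1.00]
```

(Synthetic cohorts at the default effect size are deliberately easy;
saturated performance here is a pipeline-closure check, not a clinical
estimate. Intervals are exact Clopper–Pearson.)

Monitoring a processing batch with control-pool scores:

```r
sv  <- estimate_score_variability(pool_run_scores, reference_scores)
thr <- derive_sv_threshold(rowMeans(cv$replicate_scores), prep$labels,
                           locked$boundary)
monitor_batch(control_scores, thr)$pass
```

See the methods vignette (`vignettes/classifier-development.Rmd`) for the
models, parameter defaults and their rationale, and numerical choices.

## Reproduction

Run the test suite (unit, property, and acceptance tests) against the
installed package:

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "uipclassify",
                               load_package = "installed")'
```

The acceptance script executes the full seeded workflow (90 synthetic
patients split 60/30, 2000 genes, LOPO, boundary locking, independent
validation, mixing-fidelity and score-variability analyses) and writes the
headline numbers as flat JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

Both finish in a few minutes on one CPU. All randomness is controlled by
the explicit seeds; rerunning with the same seed reproduces every number
bit for bit.
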