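---
title: "Developing a UIP classifier from multi-biopsy RNA-seq: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developing a UIP classifier from multi-biopsy RNA-seq: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scientific setting

Usual interstitial pneumonia (UIP) is the histopathologic hallmark of
idiopathic pulmonary fibrosis. Confirming it normally requires a surgical
lung biopsy; a molecular classifier on transbronchial biopsies (TBBs) — a
far less invasive bronchoscopic procedure — is clinically attractive, but
TBBs are small and patchy: a single biopsy can miss the disease, several
biopsies of one patient are correlated, and the assay must keep working
when samples are processed one at a time, months apart, on different
reagent lots.

`uipclassify` implements the development workflow for such a classifier:

1. **frozen normalization** — median-of-ratios size factors and a
   closed-form variance-stabilizing transformation (VST) whose parameters
   are estimated once on training data and then applied per sample, so a
   prospective sample's value never depends on which other samples arrive
   with it;
2. **batch-robust feature filtering** — per-gene variance components fitted
   on *sentinel* control replicates (the same RNA sources re-processed in
   every batch), removing the most batch-sensitive genes;
3. **in-silico mixing** — averaging a patient's normalized biopsy counts
   into one pseudo-sample, emulating the physical pooling of biopsies in
   the intended clinical assay, with Gaussian technical-noise replicates;
4. **patient-stratified nested cross-validation** of elastic-net penalized
   logistic classifiers (leave-one-patient-out, LOPO: all samples of a
   patient are held out together);
5. **prospective decision-boundary selection** from the replicated mixed
   scores under an averaged specificity > 0.90 constraint with a
   sensitivity floor of 0.65;
6. **score-variability monitoring** — variance components of control-pool
   scores across processing runs compared against a derived threshold
   sigma_sv for batch gating;
7. **one-shot validation** of the locked model + boundary on an independent
   test cohort.

Because real cohorts of this kind are not publicly deposited, the package
also provides a synthetic cohort generator with the same hierarchical
structure (patients, lobes, biopsies, batches, sentinels, pooled
"in-vitro" samples), used for all examples and tests.

# The normalization model

## Size factors

Sample depth is estimated by the median-of-ratios method. For counts
$K_{gi}$, the reference is the per-gene geometric mean across training
samples, and

$$ s_i = \mathrm{median}_g \left( K_{gi} / \left(\textstyle\prod_j
K_{gj}\right)^{1/n} \right), $$

taken in log space over genes whose geometric mean is positive and whose
count in sample $i$ is nonzero. `estimate_size_factors()` reproduces the
reference implementation (`DESeq2::estimateSizeFactorsForMatrix`) exactly;
the test suite asserts this plus an explicit-loop brute-force oracle.

In `freeze_normalization()` the reference geometric means are stored, so a
future sample's size factor is a median over *stored* references — a pure
per-sample function, which is what a prospective clinical assay requires.
`apply_vst()` refuses to impute: any model gene absent from an incoming
matrix is a hard error.

## Dispersion trend and VST

Counts are modelled as negative binomial with a mean–dispersion trend
$\alpha(\mu) = \alpha_t + \alpha_e/\mu$. The trend is fitted by iteratively
re-trimmed least squares (2-MAD trimming, up to 10 iterations) on
method-of-moments gene dispersions $d_g = (\mathrm{var}_g -
\bar\mu_g)/\bar\mu_g^2$.

The VST integrates $1/\sqrt{v(\mu)}$ with $v(\mu) = (1+\alpha_e)\mu +
\alpha_t\mu^2$ and has the closed form

$$ \mathrm{vst}(q) = \log_2 \frac{1 + \alpha_e + 2\alpha_t q +
2\sqrt{\alpha_t q\,(1 + \alpha_e + \alpha_t q)}}{4 \alpha_t}, $$

which is monotone and asymptotically $\log_2 q$ (the $\sqrt{\alpha_t}$
scaling needed for that asymptote is part of the closed form; the test
suite checks increments against numeric integration).

# The sentinel variance-component model

For sentinel source $j$ measured in batch $i$, the per-gene model is

$$ g_{ij} = \mu + \beta \cdot \mathrm{sample}_j + \mathrm{batch}_i +
e_{ij}, $$

with fixed source effects and random batch effects. On the balanced
one-observation-per-cell design the components have closed-form
method-of-moments estimates (batch variance truncated at zero); unbalanced
designs fall back to `lme4` REML. The *total variation*
$\sigma^2_{batch} + \sigma^2_e$ ranks genes, and the top 5% (ceiling) are
removed, with a lexicographic tie-break for reproducibility. The same
components later parameterize the technical-noise model: each gene's
replicate noise SD is $\tau_g = \sqrt{\sigma^2_{batch} + \sigma^2_e}$.

# In-silico mixing

A patient's pseudo-sample is the arithmetic mean of their normalized
counts, $K^p_g = \mathrm{mean}_i\, (K_{gi}/s_i)$, transformed directly with
the frozen VST (no re-estimation of size factors on mixes). Identities
that hold exactly and are asserted in tests: a single-sample patient's mix
is that sample; a mix of equal samples is any one of them; mixing is
invariant to sample order. Fidelity is measured against synthetic
"in-vitro" pools — fresh libraries counted from the patient's latent
expression — as squared Pearson correlation per patient;
`concordance()` reports the mean and SD over patients.

# Classification and cross-validation

`train_penalized_logistic()` minimizes average binomial deviance plus
$\lambda(\alpha \|w\|_1 + \tfrac{1-\alpha}{2}\|w\|^2)$ via `glmnet`, with
"UIP" always the positive class (independent of the collation locale).
Hyperparameters are tuned by random search (log-uniform $\lambda$, uniform
mixing) under patient-stratified inner cross-validation, selecting the most
regularized candidate within one standard error of the minimum deviance.

The outer loop is leave-one-patient-out: the held-out patient contributes
their individual biopsy scores and the replicated scores of their in-silico
mix; no model sees any data from the patient it scores.

## Pooling scores across folds

Pooled leave-one-out scores are pessimistically biased: holding out a
patient shifts the training class balance against that patient's label,
and for heavily regularized models the resulting intercept shifts order
held-out scores by class. On permuted labels the raw pooled LOPO AUC of a
60-patient synthetic cohort sat around 0.2–0.3 instead of 0.5. `run_lopo()`
therefore references every fold's scores to the fold model's mean training
score (`center_classifier()`), and `lock_final_classifier()` re-references
the locked model identically so the decision boundary, selected on
cross-validated replicate scores, applies unchanged to prospective
samples. With the correction, permuted-label AUC is centred at 0.5 and
planted-signal AUC is unaffected.

# Boundary selection and monitoring

`select_boundary()` scans a 0.01-step grid over the replicated mixed
scores. For each candidate $b$, sensitivity and specificity are averaged
over replicates (a sample equal to the boundary is called non-UIP); a
candidate is admissible when averaged specificity exceeds 0.90 and averaged
sensitivity is at least 0.65, and ties resolve to maximal specificity, then
maximal sensitivity, then the smallest boundary. When nothing is
admissible the constraint failure is reported (`criteria_met = FALSE`)
rather than silently relaxed.

`estimate_score_variability()` decomposes control-pool scores into
between-run and intra-run SDs (balanced ANOVA method of moments, REML when
unbalanced); the total is the root sum of squares, also expressed as a
percentage of the 5%–95% score range so differently scaled classifiers can
be compared. `derive_sv_threshold()` finds, by bisection, the largest
Gaussian score-noise SD that shifts averaged sensitivity and specificity at
the locked boundary by at most 0.02; `monitor_batch()` passes a processing
batch only while the pooled control-score SD stays strictly below that
sigma_sv.

# The synthetic cohort generator

`generate_cohort()` draws, per gene, a baseline log2 mean
$\mathcal{N}(5, 2)$, then adds:

* a class effect $\mathcal{N}(0, \texttt{effect\_size\_sd})$ on a fraction
  `frac_informative_genes` of genes (UIP patients only);
* a subtype shift on small disjoint gene sets for each of eight non-UIP
  subtypes (sarcoidosis, hypersensitivity pneumonitis, etc.) — non-UIP
  conditions are molecularly heterogeneous by design;
* patient, (patient, lobe), and batch random effects.

Counts are negative binomial at library sizes of 0.5–1.5 million with the
technical dispersion trend. Biopsies follow the typical lobe pattern
(lower, upper, lower, ...) with 3–5 samples per patient; per-lobe
pathology diagnoses produce patient reference labels by the guideline
rule — any UIP lobe makes the patient UIP, discordant-lobe UIP patients
included; patients with only non-diagnostic/unclassifiable lobes are
unlabelable and excluded from training. `generate_sentinels()` re-measures
a set of RNA sources in every batch; `generate_invitro_pools()` counts
fresh libraries from a patient's mean latent expression, for mixing
fidelity studies.

## Default parameters and why

| parameter | default | rationale |
|---|---|---|
| `n_patients` | 90 | development-cohort scale |
| `frac_uip` | 0.59 | training prevalence of the emulated design |
| `samples_per_patient_range` | 3–5 | TBB sampling practice |
| `n_genes` | 2000 | desk-scale stand-in for a capture panel |
| `frac_informative_genes` | 0.10 | sparse informative biology |
| `effect_size_sd` | 1.0 | log2 class-effect spread |
| `lobe_effect_sd`, `patient_effect_sd` | 0.30 | within-patient heterogeneity below the class effect |
| `batch_sd` | 0.20 | moderate batch effects, removable by filtering |
| `dispersion_params` | $\alpha_t = 0.01$, $\alpha_e = 1$ | technical-replicate scale; see below |
| `discordant_lobe_rate` | 3/90 | rare discordant-lobe UIP patients |
| `nondiagnostic_rate` | 0.05 | occasional uninformative lobes |

The dispersion default deserves a note: all *biological* variation in the
generator lives in the latent log2 means, so the NB stage represents only
library-prep and counting noise, for which technical-replicate-scale
dispersion is appropriate. With biological-scale dispersion (e.g.
$\alpha_t = 0.05$, $\alpha_e = 2$) the generator double-counts biology and
in-silico/in-vitro pool concordance saturates near $r^2 \approx 0.95$,
below the $\approx 0.99$ observed for real technical pool replicates.

Planted signal genes (informative and subtype-shift) are always
protein-coding and on-panel: the assay panel is designed around the
informative biology, and annotation filtering should not delete the
ground truth.

# Worked example

```{r, eval = FALSE}
library(uipclassify)

cohort <- generate_cohort(cohort_config(n_patients = 30, n_genes = 800,
                                        seed = 1))
cohort <- generate_sentinels(cohort, n_sentinels = 4, n_batches = 4,
                             seed = 2)

prep <- prepare_training_data(cohort, n_replicates = 50)
cv <- run_lopo(prep$counts, prep$expr, prep$labels, prep$patient_map,
               prep$frozen, prep$noise, n_draws = 6, inner_k = 3, seed = 3)
locked <- lock_final_classifier(prep, cv, n_draws = 6, inner_k = 3,
                                seed = 4)
cv
locked$boundary
```

Validation on an independent arm of the same population:

```{r, eval = FALSE}
test_p <- setdiff(cohort$truth$patients$patient_id, names(prep$labels))
pools <- generate_invitro_pools(cohort, test_p, seed = 5)
tc <- pools$counts[, paste0("pool_", test_p)]
colnames(tc) <- test_p
validate_classifier(locked$model, locked$boundary, tc, prep$frozen,
                    cohort_patient_labels(cohort)[test_p],
                    train_patients = names(prep$labels))
```

# Numerical and testing choices

* Size factors, AUC (Mann–Whitney midranks), and the elastic-net solution
  are each validated against independent oracles (explicit-loop
  median-of-ratios, pair counting, a full-gradient proximal optimizer, and
  the DESeq2/pROC reference implementations).
* Variance-component recovery is tested at the study's 8-source × 8-batch
  sentinel design over 2000 genes (±20% on the median), the dispersion
  trend at 2000 genes × 200 samples (±30% on $\alpha_t$).
* Confidence intervals are exact Clopper–Pearson (`binom.test`).
* All randomness flows through explicit seeds; `with_seed()` restores the
  RNG state so library code never perturbs a caller's stream.

# Limitations

* The generator's technical noise is Gaussian on the VST scale at the
  score level and negative binomial at the count level; real run effects
  can be structured (e.g. GC-dependent) in ways the sentinel model only
  captures in aggregate.
* Synthetic cohorts with the default effect size are easier than real
  TBB cohorts; headline performance saturates near 1.0 and should be read
  as a pipeline-closure check, not a clinical estimate.
* The score-variability threshold sigma_sv is derived from
  cross-validated scores of the development cohort; a production assay
  would re-derive it from dedicated control material.
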