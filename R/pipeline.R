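#' Prepare training artifacts from a simulated cohort
#'
#' Convenience driver for the development workflow on a generated cohort:
#' freezes the normalization on the labeled biopsy counts, applies the
#' annotation / low-expression filters, fits the sentinel variance
#' components and removes the most batch-sensitive genes, and assembles the
#' technical-noise model. Patients whose lobe diagnoses yield no reference
#' label are excluded throughout.
#'
#' @param cohort A `simulated_cohort` containing sentinel samples (append
#'   them with [generate_sentinels()] first).
#' @param top_fraction Batch-sensitivity removal fraction (default 0.05).
#' @param n_replicates Noise replicates for in-silico mixing (default 100).
#' @return list with `frozen`, `genes` (retained classifier universe),
#'   `expr` (filtered VST expression of labeled biopsy samples),
#'   `counts` (raw counts of those samples), `patient_map`,
#'   `labels` (named per-patient), `sample_labels`, `noise`,
#'   `batch_models`, `filter_trace` (genes surviving each stage).
#' @export
prepare_training_data <- function(cohort, top_fraction = 0.05,
                                  n_replicates = 100L) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  meta <- cohort$sample_meta
  if (!any(meta$role == "sentinel"))
    stop("cohort has no sentinel samples; run generate_sentinels() first")
  labels <- cohort_patient_labels(cohort)
  labeled <- names(labels)[labels != "unlabelable"]
  labels <- labels[labeled]
  bio <- meta[meta$role == "biopsy" & meta$patient_id %in% labeled, ]
  counts <- cohort$counts[, bio$sample_id, drop = FALSE]
  frozen <- freeze_normalization(counts)

  g1 <- filter_by_annotation(rownames(counts), cohort$annotation)
  g2 <- filter_low_expression(counts, g1)

  sent <- meta[meta$role == "sentinel", ]
  sent_expr <- apply_vst(cohort$counts[, sent$sample_id, drop = FALSE],
                         frozen)[g2, , drop = FALSE]
  models <- fit_gene_batch_model(sent_expr,
                                 data.frame(sample_id = sent$sample_id,
                                            source = sent$patient_id,
                                            batch = sent$batch,
                                            stringsAsFactors = FALSE))
  g3 <- filter_batch_sensitive(models, g2, top_fraction = top_fraction)

  expr <- apply_vst(counts, frozen)[g3, , drop = FALSE]
  patient_map <- stats::setNames(bio$patient_id, bio$sample_id)
  sample_labels <- labels[bio$patient_id]
  names(sample_labels) <- bio$sample_id
  list(frozen = frozen, genes = g3, expr = expr, counts = counts,
       patient_map = patient_map, labels = labels,
       sample_labels = sample_labels,
       noise = noise_model(models, n_replicates = n_replicates),
       batch_models = models,
       filter_trace = list(universe = rownames(counts), annotation = g1,
                           low_expression = g2, batch_robust = g3))
}

#' Train and lock a final classifier with a prospective boundary
#'
#' Tunes hyperparameters on the full training set (random search +
#' one-standard-error rule over patient-stratified inner CV), fits the final
#' penalized logistic model, and locks the decision boundary selected from
#' replicated in-silico patient-level LOPO scores.
#'
#' @param prep Output of [prepare_training_data()].
#' @param cv A `cv_result` from [run_lopo()] on the same prep (supplies the
#'   replicate scores the boundary is selected from).
#' @param spec_min,sens_floor Boundary constraints (defaults 0.90 / 0.65).
#' @param n_draws,lambda_range,mixing_range,inner_k,seed Tuning controls.
#' @return list(model = locked `trained_classifier`,
#'   boundary = `boundary_selection`).
#' @export
lock_final_classifier <- function(prep, cv, spec_min = 0.90,
                                  sens_floor = 0.65, n_draws = 20L,
                                  lambda_range = c(1e-3, 1),
                                  mixing_range = c(0.1, 1), inner_k = 5L,
                                  seed = 1L) {
  tuned <- tune_nested(prep$expr, prep$sample_labels, prep$patient_map,
                       n_draws = n_draws, lambda_range = lambda_range,
                       mixing_range = mixing_range, inner_k = inner_k,
                       seed = seed)
  model <- train_penalized_logistic(prep$expr, prep$sample_labels,
                                    lambda = tuned$lambda,
                                    mixing = tuned$mixing)
  ## reference the locked model to the training cohort so its score scale
  ## matches the centered cross-validated replicate scores the boundary is
  ## selected from
  model <- center_classifier(model, prep$expr)
  boundary <- select_boundary(cv$replicate_scores, prep$labels,
                              spec_min = spec_min, sens_floor = sens_floor)
  list(model = model, boundary = boundary)
}
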