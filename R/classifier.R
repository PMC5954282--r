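#' Patient-stratified cross-validation fold plan
#'
#' Builds folds in which all samples of a patient travel together: either
#' leave-one-patient-out (one fold per patient) or k-fold with patients
#' assigned to folds stratified by patient label.
#'
#' @param patients data.frame with columns `patient_id`, `label` (binary,
#'   "UIP"/"non-UIP" or any two values).
#' @param mode `"lopo"` or an integer k for k-fold.
#' @param seed RNG seed (k-fold assignment).
#' @return Object of class `fold_plan`: list of folds, each with `held_out`
#'   and `train` patient ID vectors, plus `mode`.
#' @export
make_fold_plan <- function(patients, mode = "lopo", seed = 1L) {
  stopifnot(is.data.frame(patients),
            all(c("patient_id", "label") %in% names(patients)))
  ids <- patients$patient_id
  if (anyDuplicated(ids)) stop("duplicate patient IDs")
  if (identical(mode, "lopo")) {
    folds <- lapply(ids, function(p)
      list(held_out = p, train = setdiff(ids, p)))
  } else {
    k <- as.integer(mode)
    if (is.na(k) || k < 2) stop("mode must be \"lopo\" or an integer k >= 2")
    if (length(unique(patients$label)) < 2)
      stop("k-fold stratification needs both classes among patients")
    assign <- integer(length(ids))
    with_seed(seed, {
      for (lv in unique(patients$label)) {
        idx <- sample(which(patients$label == lv))
        assign[idx] <- rep_len(sample(k), length(idx))
      }
    })
    folds <- lapply(seq_len(k), function(f)
      list(held_out = ids[assign == f], train = ids[assign != f]))
    for (f in folds) {
      tr_lab <- patients$label[patients$patient_id %in% f$train]
      if (length(unique(tr_lab)) < 2)
        warning("fold with single-class training partition kept")
    }
  }
  structure(list(folds = folds, mode = mode, seed = seed),
            class = "fold_plan")
}

## Binary label encoding with a fixed positive class: "UIP" is always
## positive when present; otherwise the lexicographically last level is.
## Independent of the collation locale.
label_to_binary <- function(labels) {
  lab <- as.character(labels)
  lv <- sort(unique(lab), method = "radix")
  if (length(lv) > 2) stop("labels must be binary")
  if ("UIP" %in% lv) lv <- c(setdiff(lv, "UIP"), "UIP")
  list(y = as.integer(lab == lv[length(lv)]), positive = lv[length(lv)])
}

#' Train an elastic-net penalized logistic classifier
#'
#' Minimizes the average binomial deviance plus
#' lambda * (mixing * L1 + (1 - mixing)/2 * L2) over sparse linear weights on
#' the genes. Features are standardized internally on the training data and
#' the standardization is folded back into the exported weights and
#' intercept, so the classification score is the log-odds linear predictor
#' on the original expression scale.
#'
#' @param expr Expression matrix, genes x samples.
#' @param labels Binary per-sample labels (factor/character/0-1); "UIP" is
#'   the positive class when present, otherwise the lexicographically last
#'   label is.
#' @param lambda Penalty strength (> 0).
#' @param mixing Elastic-net mixing in \[0, 1\]: 1 = lasso, 0 = ridge.
#' @param standardize Standardize features internally (default TRUE).
#' @param thresh Coordinate-descent convergence threshold.
#' @return Object of class `trained_classifier`: `genes` (nonzero-weight
#'   genes), `weights`, `intercept`, `lambda`, `mixing`, and the full
#'   coefficient vector used for scoring.
#' @export
train_penalized_logistic <- function(expr, labels, lambda, mixing = 0.5,
                                     standardize = TRUE, thresh = 1e-9) {
  enc <- label_to_binary(labels)
  y <- enc$y
  if (length(unique(y)) < 2) stop("both classes must be present for training")
  if (!(lambda > 0)) stop("lambda must be > 0")
  if (mixing < 0 || mixing > 1) stop("mixing must be in [0,1]")
  x <- t(expr)
  ## short warm-start path down to the requested lambda for a stable solution
  path <- lambda * c(8, 4, 2, 1)
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = mixing,
                        lambda = path, standardize = standardize,
                        thresh = thresh)
  beta <- as.numeric(stats::coef(fit, s = lambda))
  intercept <- beta[1]
  w <- beta[-1]
  names(w) <- rownames(expr)
  nz <- w[w != 0]
  structure(list(genes = names(nz), weights = nz, intercept = intercept,
                 lambda = lambda, mixing = mixing,
                 positive_class = enc$positive),
            class = "trained_classifier")
}

#' @export
print.trained_classifier <- function(x, ...) {
  cat(sprintf("penalized logistic classifier: %d genes, lambda = %.4g, mixing = %.2f\n",
              length(x$genes), x$lambda, x$mixing))
  invisible(x)
}

#' Classification scores (log-odds linear predictor)
#'
#' score = intercept + sum over classifier genes of weight * expression.
#' Scores are on the log-odds scale, not probabilities.
#'
#' @param model A `trained_classifier`.
#' @param expr Expression matrix whose rows must include every model gene.
#' @return Named numeric vector, one score per column.
#' @export
score_samples <- function(model, expr) {
  stopifnot(inherits(model, "trained_classifier"))
  miss <- setdiff(model$genes, rownames(expr))
  if (length(miss))
    stop("model gene(s) missing from expression: ",
         paste(utils::head(miss, 10), collapse = ", "))
  if (length(model$genes) == 0)
    return(stats::setNames(rep(model$intercept, ncol(expr)), colnames(expr)))
  drop(crossprod(expr[model$genes, , drop = FALSE], model$weights)) +
    model$intercept
}

#' Reference a classifier's scores to a training cohort
#'
#' Shifts the intercept so that the model's mean score over the supplied
#' training expression is zero. Scores from models trained on different
#' (e.g. cross-validation) subsets are only comparable after this
#' referencing: changing the training class balance by one patient shifts
#' every score through the intercept, which biases pooled cross-validated
#' AUC pessimistically and misaligns a boundary locked on cross-validated
#' scores with the final model's score scale.
#'
#' @param model A `trained_classifier`.
#' @param expr Training expression matrix the model was fitted on.
#' @return The model with a re-referenced intercept.
#' @export
center_classifier <- function(model, expr) {
  stopifnot(inherits(model, "trained_classifier"))
  model$intercept <- model$intercept - mean(score_samples(model, expr))
  model
}

#' Weighted score-averaging ensemble
#'
#' Combines per-column score vectors from several component classifiers by a
#' weighted mean after standardizing each component with supplied training
#' statistics. Defaults (`centers = 0`, `scales = 1`) combine the raw
#' scores.
#'
#' @param component_scores List of equal-length named score vectors over the
#'   same columns.
#' @param weights Non-negative weights summing to 1 (default equal).
#' @param centers,scales Per-component training mean and SD used to
#'   standardize each component before averaging.
#' @return Combined score vector.
#' @export
ensemble_score <- function(component_scores,
                           weights = rep(1 / length(component_scores),
                                         length(component_scores)),
                           centers = rep(0, length(component_scores)),
                           scales = rep(1, length(component_scores))) {
  k <- length(component_scores)
  if (length(weights) != k || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8)
    stop("weights must be non-negative and sum to 1")
  cols <- names(component_scores[[1]])
  for (s in component_scores)
    if (length(s) != length(component_scores[[1]]) ||
        (!is.null(cols) && !identical(names(s), cols)))
      stop("component score vectors must cover identical columns")
  std <- Map(function(s, c0, s0) (s - c0) / s0,
             component_scores, centers, scales)
  Reduce(`+`, Map(`*`, std, weights))
}

## Binomial deviance of linear-predictor scores against 0/1 labels.
binomial_deviance <- function(eta, y) {
  p <- 1 / (1 + exp(-eta))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -2 * mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Nested random-search hyperparameter tuning with the one-SE rule
#'
#' Draws `n_draws` (lambda, mixing) candidates — lambda log-uniform over
#' `lambda_range`, mixing uniform over `mixing_range` — and evaluates each by
#' patient-stratified inner cross-validation on the training partition,
#' scoring held-in folds by binomial deviance. The selected candidate is the
#' most regularized (largest lambda) among those whose mean inner-CV
#' deviance is within one standard error of the minimum.
#'
#' @param expr Expression matrix (genes x samples) of the training
#'   partition.
#' @param labels Per-sample binary labels.
#' @param patient_map Named sample -> patient map for inner stratification.
#' @param n_draws Number of random candidates (>= 2 unless exactly 1 is
#'   supplied via `candidates`).
#' @param lambda_range,mixing_range Search ranges.
#' @param inner_k Inner CV folds (patient-stratified).
#' @param seed RNG seed for draws and inner fold assignment.
#' @param candidates Optional data.frame(lambda, mixing) overriding the
#'   random draws.
#' @return list(lambda, mixing, table = per-candidate mean deviance and SE).
#' @export
tune_nested <- function(expr, labels, patient_map, n_draws = 20L,
                        lambda_range = c(1e-3, 1), mixing_range = c(0.1, 1),
                        inner_k = 5L, seed = 1L, candidates = NULL) {
  if (is.null(candidates)) {
    if (n_draws < 2) stop("n_draws must be >= 2")
    candidates <- with_seed(seed, data.frame(
      lambda = exp(stats::runif(n_draws, log(lambda_range[1]),
                                log(lambda_range[2]))),
      mixing = stats::runif(n_draws, mixing_range[1], mixing_range[2])))
  }
  y <- label_to_binary(labels)$y
  pm <- patient_map[colnames(expr)]
  pat <- unique(pm)
  pat_lab <- vapply(pat, function(p) y[pm == p][1], integer(1))
  plan <- make_fold_plan(data.frame(patient_id = pat, label = pat_lab),
                         mode = min(inner_k, length(pat)), seed = seed)
  dev <- matrix(NA_real_, nrow(candidates), length(plan$folds))
  for (f in seq_along(plan$folds)) {
    tr <- pm %in% plan$folds[[f]]$train
    te <- !tr
    if (length(unique(y[tr])) < 2 || !any(te)) next
    for (cand in seq_len(nrow(candidates))) {
      mod <- train_penalized_logistic(expr[, tr, drop = FALSE], y[tr],
                                      lambda = candidates$lambda[cand],
                                      mixing = candidates$mixing[cand],
                                      thresh = 1e-7)
      eta <- score_samples(mod, expr[, te, drop = FALSE])
      dev[cand, f] <- binomial_deviance(eta, y[te])
    }
  }
  used <- colSums(is.na(dev)) == 0
  mean_dev <- rowMeans(dev[, used, drop = FALSE])
  se_dev <- apply(dev[, used, drop = FALSE], 1, stats::sd) /
    sqrt(max(sum(used), 1))
  sel <- select_one_se(candidates, mean_dev, se_dev)
  list(lambda = candidates$lambda[sel], mixing = candidates$mixing[sel],
       table = cbind(candidates, mean_deviance = mean_dev, se = se_dev))
}

#' One-standard-error candidate selection
#'
#' Among candidates whose mean loss is within one standard error of the
#' minimum mean loss, picks the most regularized: largest lambda, ties
#' broken by largest mixing (sparser), then by order.
#'
#' @param candidates data.frame(lambda, mixing).
#' @param mean_loss Mean cross-validated loss per candidate.
#' @param se_loss Standard error per candidate (the SE of the minimizer is
#'   the one used for the band).
#' @return Index of the selected candidate.
#' @export
select_one_se <- function(candidates, mean_loss, se_loss) {
  if (nrow(candidates) == 1) return(1L)
  best <- which.min(mean_loss)
  band <- mean_loss <= mean_loss[best] + se_loss[best]
  adm <- which(band)
  adm[order(-candidates$lambda[adm], -candidates$mixing[adm])][1]
}

#' Leave-one-patient-out cross-validation with in-silico mixing
#'
#' For each patient: tunes hyperparameters by nested inner CV on the
#' remaining patients' samples, trains on those samples, scores (i) the
#' held-out patient's individual samples and (ii) `noise$n_replicates`
#' technical-noise replicates of the held-out patient's in-silico mixed
#' pseudo-sample. No model ever sees any data from the patient it scores.
#' All held-out scores are referenced to the fold model's training-score
#' mean ([center_classifier()]) so that scores pooled across folds share a
#' common scale.
#'
#' @param counts Raw training counts (genes x samples; full gene set, used
#'   for mixing).
#' @param expr Variance-stabilized expression (classifier gene set x
#'   samples).
#' @param labels Named per-patient labels ("UIP" positive).
#' @param patient_map Named sample -> patient map.
#' @param frozen `frozen_normalization` (for mixing and VST of mixes).
#' @param noise `noise_model` for replicate scoring.
#' @param n_draws,lambda_range,mixing_range,inner_k Tuning controls passed
#'   to [tune_nested()].
#' @param seed RNG seed.
#' @return Object of class `cv_result`: `sample_scores` data.frame
#'   (sample_id, patient_id, label, score, fold), `replicate_scores` matrix
#'   patients x R, `patient_labels`, `auc_sample`, `auc_patient`,
#'   `fold_train_patients` (list, for leakage audits).
#' @export
run_lopo <- function(counts, expr, labels, patient_map, frozen, noise,
                     n_draws = 20L, lambda_range = c(1e-3, 1),
                     mixing_range = c(0.1, 1), inner_k = 5L, seed = 1L) {
  pm <- patient_map[colnames(expr)]
  patients <- unique(pm)
  if (!all(patients %in% names(labels)))
    stop("labels missing for patient(s): ",
         paste(setdiff(patients, names(labels)), collapse = ", "))
  lab <- labels[patients]
  sf <- estimate_size_factors(counts,
                              reference = frozen$reference_geomeans[rownames(counts)])
  mixed <- mix_within_patient(counts, sf, patient_map)
  mixed_expr <- vst_mixed(mixed, frozen)[rownames(expr), , drop = FALSE]
  R <- noise$n_replicates
  rep_scores <- matrix(NA_real_, length(patients), R,
                       dimnames = list(patients, NULL))
  sample_rows <- list()
  fold_train <- list()
  y01 <- as.integer(lab == "UIP")
  for (k in seq_along(patients)) {
    p <- patients[k]
    tr_cols <- which(pm != p)
    te_cols <- which(pm == p)
    fold_seed <- seed + k
    tuned <- tune_nested(expr[, tr_cols, drop = FALSE],
                         lab[pm[tr_cols]], patient_map,
                         n_draws = n_draws, lambda_range = lambda_range,
                         mixing_range = mixing_range, inner_k = inner_k,
                         seed = fold_seed)
    mod <- train_penalized_logistic(expr[, tr_cols, drop = FALSE],
                                    lab[pm[tr_cols]],
                                    lambda = tuned$lambda,
                                    mixing = tuned$mixing)
    ## scores from different folds are pooled below, so each fold model is
    ## referenced to its own training cohort (see center_classifier)
    mod <- center_classifier(mod, expr[, tr_cols, drop = FALSE])
    sc <- score_samples(mod, expr[, te_cols, drop = FALSE])
    sample_rows[[k]] <- data.frame(
      sample_id = colnames(expr)[te_cols], patient_id = p,
      label = unname(lab[p]), score = unname(sc), fold = k,
      stringsAsFactors = FALSE)
    reps <- replicate_with_noise(mixed_expr[, p, drop = FALSE], noise,
                                 R = R, seed = fold_seed)
    reps_mat <- matrix(reps[, 1, ], nrow = dim(reps)[1],
                       dimnames = list(rownames(mixed_expr),
                                       sprintf("rep%03d", seq_len(R))))
    rep_scores[p, ] <- unname(score_samples(mod, reps_mat))
    fold_train[[k]] <- setdiff(patients, p)
  }
  sample_scores <- do.call(rbind, sample_rows)
  auc_sample <- roc_auc(sample_scores$score,
                        sample_scores$label == "UIP")$auc
  auc_patient <- roc_auc(rowMeans(rep_scores), y01)$auc
  structure(list(sample_scores = sample_scores,
                 replicate_scores = rep_scores,
                 patient_labels = lab,
                 auc_sample = auc_sample, auc_patient = auc_patient,
                 fold_train_patients = fold_train),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("LOPO CV: %d patients, pooled sample-level AUC %.3f, in-silico patient-level AUC %.3f\n",
              length(x$patient_labels), x$auc_sample, x$auc_patient))
  invisible(x)
}
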