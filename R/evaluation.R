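#' ROC curve and AUC
#'
#' AUC via the Mann-Whitney statistic with midrank tie handling; ROC points
#' are emitted at every distinct score threshold.
#'
#' @param scores Numeric scores (higher = more UIP-like).
#' @param labels Logical or binary vector; TRUE / 1 / "UIP" marks the
#'   positive class.
#' @return list(auc, roc = data.frame(threshold, tpr, fpr)).
#' @export
roc_auc <- function(scores, labels) {
  y <- if (is.character(labels) || is.factor(labels))
    as.character(labels) == "UIP" else as.logical(labels)
  if (any(is.na(y)) || any(is.na(scores))) stop("missing scores or labels")
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)                       # midranks
  auc <- (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  roc <- data.frame(
    threshold = c(Inf, thr),
    tpr = c(0, vapply(thr, function(t) mean(scores[y] >= t), numeric(1))),
    fpr = c(0, vapply(thr, function(t) mean(scores[!y] >= t), numeric(1))))
  list(auc = auc, roc = roc)
}

#' Sensitivity and specificity with exact binomial intervals
#'
#' Point estimates are the usual confusion-matrix ratios; 95\% two-sided
#' Clopper-Pearson intervals are attached. A zero denominator yields an
#' NA estimate flagged as undefined rather than an error.
#'
#' @param calls Character calls ("UIP" / "non-UIP").
#' @param labels Reference labels on the same vocabulary.
#' @param conf_level Confidence level, default 0.95.
#' @return list(sensitivity, specificity) where each is
#'   list(estimate, lower, upper, x, n, undefined).
#' @export
sens_spec <- function(calls, labels, conf_level = 0.95) {
  stopifnot(length(calls) == length(labels))
  prop_ci <- function(x, n) {
    if (n == 0)
      return(list(estimate = NA_real_, lower = NA_real_, upper = NA_real_,
                  x = x, n = n, undefined = TRUE))
    bt <- stats::binom.test(x, n, conf.level = conf_level)
    list(estimate = x / n, lower = bt$conf.int[1], upper = bt$conf.int[2],
         x = x, n = n, undefined = FALSE)
  }
  pos <- labels == "UIP"
  list(sensitivity = prop_ci(sum(calls == "UIP" & pos), sum(pos)),
       specificity = prop_ci(sum(calls == "non-UIP" & !pos), sum(!pos)))
}

#' Fold-wise and pooled cross-validated AUC
#'
#' The cross-validated AUC is the mean of per-fold empirical AUCs; the
#' pooled AUC combines all held-out scores first. Folds containing a single
#' class (every LOPO fold, for instance) are excluded from the mean with a
#' warning; the pooled AUC is always computable.
#'
#' @param fold_scores List of folds, each a list/data.frame with `scores`
#'   and `labels`.
#' @return list(mean_fold_auc, pooled_auc, fold_aucs, n_excluded).
#' @export
cv_auc <- function(fold_scores) {
  fa <- vapply(fold_scores, function(f) {
    y <- if (is.character(f$labels) || is.factor(f$labels))
      as.character(f$labels) == "UIP" else as.logical(f$labels)
    if (length(unique(y)) < 2) return(NA_real_)
    roc_auc(f$scores, f$labels)$auc
  }, numeric(1))
  n_excl <- sum(is.na(fa))
  if (n_excl > 0)
    warning(sprintf("%d single-class fold(s) excluded from the fold-mean AUC",
                    n_excl))
  all_s <- unlist(lapply(fold_scores, function(f) f$scores))
  all_l <- unlist(lapply(fold_scores, function(f) as.character(f$labels)))
  list(mean_fold_auc = if (all(is.na(fa))) NA_real_ else mean(fa, na.rm = TRUE),
       pooled_auc = roc_auc(all_s, all_l)$auc,
       fold_aucs = fa, n_excluded = n_excl)
}

#' Validate a locked classifier on an independent test cohort
#'
#' Normalizes the test counts with the frozen training normalization, scores
#' them with the locked model, applies the locked boundary, and reports AUC,
#' sensitivity and specificity with confidence intervals. The function only
#' accepts an already-locked model + boundary; there is no refitting path.
#' An audit flags any overlap between test patients and the supplied
#' training patient set.
#'
#' @param model Locked `trained_classifier`.
#' @param boundary Locked boundary (`boundary_selection` or numeric).
#' @param test_counts Test count matrix (genes x test samples, one pooled
#'   sample per patient).
#' @param frozen Frozen training normalization.
#' @param labels Named per-test-sample (or per-patient) reference labels.
#' @param train_patients Optional character vector of training patient IDs
#'   for the overlap audit (test column names are compared against it).
#' @return Object of class `performance_report`: `auc` (with DeLong-free
#'   empirical value), `sensitivity`, `specificity`, `confusion`, `scores`,
#'   `calls`, `boundary`, `patient_overlap`.
#' @export
validate_classifier <- function(model, boundary, test_counts, frozen, labels,
                                train_patients = character(0)) {
  stopifnot(inherits(model, "trained_classifier"))
  if (inherits(boundary, "boundary_selection")) boundary <- boundary$boundary
  if (!ncol(test_counts)) stop("empty test set")
  expr <- apply_vst(test_counts, frozen)
  sc <- score_samples(model, expr)
  lab <- labels[colnames(test_counts)]
  if (any(is.na(lab))) stop("labels missing for test sample(s)")
  calls <- classify_scores(sc, boundary)
  ss <- sens_spec(calls, lab)
  overlap <- intersect(colnames(test_counts), train_patients)
  confusion <- table(call = factor(calls, c("UIP", "non-UIP")),
                     truth = factor(lab, c("UIP", "non-UIP")))
  structure(list(auc = roc_auc(sc, lab)$auc, sensitivity = ss$sensitivity,
                 specificity = ss$specificity, confusion = confusion,
                 scores = sc, calls = calls, boundary = boundary,
                 patient_overlap = overlap), class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("validation: AUC %.3f; sensitivity %.2f [%.2f-%.2f]; specificity %.2f [%.2f-%.2f]\n",
              x$auc, x$sensitivity$estimate, x$sensitivity$lower,
              x$sensitivity$upper, x$specificity$estimate,
              x$specificity$lower, x$specificity$upper))
  if (length(x$patient_overlap))
    cat("WARNING: test/train patient overlap: ",
        paste(x$patient_overlap, collapse = ", "), "\n")
  invisible(x)
}

#' Sample and patient counts of the development study design
#'
#' The biopsy-study design the synthetic generator emulates: per-class
#' sample and patient counts in the training arm and patient counts in the
#' independent test arm. Useful for checking the arithmetic of design
#' prevalences (UIP fraction of training samples and of test patients).
#'
#' @return data.frame with columns `class`, `train_samples`,
#'   `train_patients`, `test_patients`.
#' @export
reference_cohort_counts <- function() {
  data.frame(class = c("UIP", "non-UIP"),
             train_samples = c(212L, 142L),
             train_patients = c(53L, 37L),
             test_patients = c(23L, 26L),
             stringsAsFactors = FALSE)
}
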