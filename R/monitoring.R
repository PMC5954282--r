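#' Variance components of classification scores across processing runs
#'
#' Decomposes replicated pool scores as score = mu + pool (fixed) + run
#' (random) + residual, mirroring at the score level the sentinel gene
#' model: pools are biologically distinct (signal), runs are technical
#' noise. Balanced designs (every pool replicated equally in every run) use
#' closed-form ANOVA method of moments; unbalanced designs fall back to
#' REML. Each SD is also expressed as a percentage of the 5\%-95\%
#' inter-quantile range of a reference score distribution, so classifiers
#' with different score scales can be compared.
#'
#' @param scores data.frame with columns `pool`, `run`, `score` (one row per
#'   replicate measurement).
#' @param reference_scores Numeric vector defining the score range (e.g. all
#'   cross-validated scores of the classifier).
#' @return Object of class `score_variability`: `sd_between_run`,
#'   `sd_intra_run`, `sd_total` (root sum of squares), `pct_of_range`
#'   (named vector over the three SDs), `range`.
#' @export
estimate_score_variability <- function(scores, reference_scores) {
  stopifnot(is.data.frame(scores),
            all(c("pool", "run", "score") %in% names(scores)))
  pool <- factor(scores$pool); run <- factor(scores$run)
  if (nlevels(run) < 2 || nlevels(pool) < 2)
    stop("need >= 2 runs and >= 2 pools")
  cell <- table(pool, run)
  if (any(rowSums(cell) < 2))
    stop("degenerate design: each pool needs >= 2 measurements")
  y <- scores$score
  n <- length(y)
  P <- nlevels(pool); B <- nlevels(run)
  balanced <- length(unique(as.vector(cell))) == 1 && all(cell >= 1)
  if (balanced) {
    r <- unique(as.vector(cell))            # replicates per (pool, run)
    gm <- mean(y)
    pm <- tapply(y, pool, mean); rm_ <- tapply(y, run, mean)
    ss_run <- r * P * sum((rm_ - gm)^2)
    ss_pool <- r * B * sum((pm - gm)^2)
    ss_tot <- sum((y - gm)^2)
    ss_e <- max(ss_tot - ss_run - ss_pool, 0)
    df_e <- n - P - B + 1
    ms_run <- ss_run / (B - 1)
    ms_e <- ss_e / df_e
    sigma2_run <- max((ms_run - ms_e) / (r * P), 0)
    sigma2_e <- ms_e
  } else {
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(score ~ pool + (1 | run), data = scores, REML = TRUE)))
    vc <- as.data.frame(lme4::VarCorr(fit))
    sigma2_run <- vc$vcov[vc$grp == "run"]
    sigma2_e <- vc$vcov[vc$grp == "Residual"]
  }
  sd_between <- sqrt(sigma2_run)
  sd_intra <- sqrt(sigma2_e)
  sd_total <- sqrt(sigma2_run + sigma2_e)
  rng <- unname(diff(stats::quantile(reference_scores, c(0.05, 0.95))))
  pct <- 100 * c(between_run = sd_between, intra_run = sd_intra,
                 total = sd_total) / rng
  structure(list(sd_between_run = sd_between, sd_intra_run = sd_intra,
                 sd_total = sd_total, pct_of_range = pct, range = rng),
            class = "score_variability")
}

#' @export
print.score_variability <- function(x, ...) {
  cat(sprintf("score variability: between-run %.3f (%.1f%%), intra-run %.3f (%.1f%%), total %.3f (%.1f%%)\n",
              x$sd_between_run, x$pct_of_range["between_run"],
              x$sd_intra_run, x$pct_of_range["intra_run"],
              x$sd_total, x$pct_of_range["total"]))
  invisible(x)
}

#' Rank classifiers by score robustness
#'
#' Orders a named set of `score_variability` objects by total SD as a
#' percentage of score range, ascending: the smallest proportion is the most
#' robust classifier. Ties are broken by name for a stable order.
#'
#' @param variabilities Named list of `score_variability` objects.
#' @return data.frame (classifier, pct_total, rank) ordered by rank.
#' @export
compare_classifiers <- function(variabilities) {
  stopifnot(length(variabilities) >= 1, !is.null(names(variabilities)))
  pct <- vapply(variabilities, function(v) unname(v$pct_of_range["total"]),
                numeric(1))
  ord <- order(pct, names(variabilities))
  data.frame(classifier = names(variabilities)[ord], pct_total = pct[ord],
             rank = seq_along(ord), row.names = NULL)
}

#' Derive the score-variability monitoring threshold
#'
#' Reconstructs a tolerance-based definition of the maximum acceptable score
#' SD: sigma_sv is the largest s such that adding Gaussian(0, s) noise to
#' the patient-level cross-validated scores shifts the averaged sensitivity
#' and specificity at the locked boundary by at most `tolerance` (estimated
#' over `n_draws` noise draws). Found by bisection on s.
#'
#' @param patient_scores Named per-patient scores (e.g. replicate means from
#'   LOPO in-silico mixing).
#' @param labels Named per-patient labels ("UIP" positive).
#' @param boundary Locked decision boundary (or `boundary_selection`).
#' @param tolerance Maximum acceptable absolute shift in sensitivity and in
#'   specificity (> 0), default 0.02.
#' @param n_draws Noise draws per candidate s.
#' @param seed RNG seed.
#' @param s_max Upper bracket for the search (default: score range).
#' @return Object of class `monitoring_threshold`: `sigma_sv`, `tolerance`,
#'   `n_draws`, `seed`.
#' @export
derive_sv_threshold <- function(patient_scores, labels, boundary,
                                tolerance = 0.02, n_draws = 200L, seed = 1L,
                                s_max = diff(range(patient_scores))) {
  if (inherits(boundary, "boundary_selection")) boundary <- boundary$boundary
  if (!(tolerance > 0)) stop("tolerance must be > 0")
  lab <- labels[names(patient_scores)]
  pos <- lab == "UIP"
  if (!any(pos) || all(pos)) stop("both classes must be present")
  sens0 <- mean(patient_scores[pos] > boundary)
  spec0 <- mean(patient_scores[!pos] <= boundary)
  shift <- function(s) {
    with_seed(seed, {
      n <- length(patient_scores)
      sens <- spec <- numeric(n_draws)
      for (d in seq_len(n_draws)) {
        noisy <- patient_scores + stats::rnorm(n, 0, s)
        sens[d] <- mean(noisy[pos] > boundary)
        spec[d] <- mean(noisy[!pos] <= boundary)
      }
      max(abs(mean(sens) - sens0), abs(mean(spec) - spec0))
    })
  }
  lo <- 0; hi <- max(s_max, 1e-6)
  if (shift(hi) <= tolerance) {
    sigma_sv <- hi
  } else {
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      if (shift(mid) <= tolerance) lo <- mid else hi <- mid
      if (hi - lo < 1e-6 * max(1, s_max)) break
    }
    sigma_sv <- lo
  }
  structure(list(sigma_sv = sigma_sv, tolerance = tolerance,
                 n_draws = as.integer(n_draws), seed = as.integer(seed)),
            class = "monitoring_threshold")
}

#' Gate a processing batch with control-sample scores
#'
#' Estimates the pooled SD of each control's scores across batches and
#' passes the batch only while that SD remains strictly below sigma_sv.
#'
#' @param control_scores data.frame with columns `control`, `batch`,
#'   `score`; each control needs measurements in >= 2 batches.
#' @param threshold `monitoring_threshold` (or a bare sigma_sv value).
#' @return list(pass = logical, sd_pooled, per_control = named SD vector,
#'   sigma_sv).
#' @export
monitor_batch <- function(control_scores, threshold) {
  sigma_sv <- if (inherits(threshold, "monitoring_threshold"))
    threshold$sigma_sv else threshold
  stopifnot(is.data.frame(control_scores),
            all(c("control", "batch", "score") %in% names(control_scores)))
  by_ctrl <- split(control_scores, control_scores$control)
  if (any(vapply(by_ctrl, nrow, integer(1)) < 2))
    stop("each control needs >= 2 batch measurements")
  per <- vapply(by_ctrl, function(d) stats::sd(d$score), numeric(1))
  ## pooled across controls: root mean within-control variance
  sd_pooled <- sqrt(mean(per^2))
  list(pass = sd_pooled < sigma_sv, sd_pooled = sd_pooled,
       per_control = per, sigma_sv = sigma_sv)
}
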