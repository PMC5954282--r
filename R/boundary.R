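#' Prospective decision-boundary selection
#'
#' Scans a grid of candidate thresholds over the span of the replicated
#' in-silico patient-level scores. For each candidate b, every replicate
#' draw yields one sensitivity and one specificity (call UIP iff score > b);
#' these are averaged over replicates. A candidate is admissible when its
#' averaged specificity exceeds `spec_min` and its averaged sensitivity is
#' at least `sens_floor`. The selected boundary is the admissible candidate
#' with maximal specificity; ties go to maximal sensitivity, then to the
#' smallest boundary. When no candidate meets both constraints, the
#' specificity-maximizing candidate among those meeting the sensitivity
#' floor is returned with `criteria_met = FALSE`.
#'
#' @param replicate_scores Matrix patients x replicates of in-silico mixed
#'   scores (e.g. `cv_result$replicate_scores`).
#' @param labels Named per-patient labels; "UIP" is the positive class.
#' @param spec_min Specificity constraint (strict >), default 0.90.
#' @param sens_floor Sensitivity floor (>=), default 0.65.
#' @param grid_step Grid resolution on the score scale, default 0.01.
#' @return Object of class `boundary_selection`: `boundary`, `criteria_met`,
#'   `grid` (data.frame: boundary, sensitivity, specificity, admissible),
#'   `spec_min`, `sens_floor`.
#' @export
select_boundary <- function(replicate_scores, labels, spec_min = 0.90,
                            sens_floor = 0.65, grid_step = 0.01) {
  if (!is.matrix(replicate_scores) || !nrow(replicate_scores) ||
      !ncol(replicate_scores))
    stop("replicate_scores must be a non-empty patients x replicates matrix")
  lab <- labels[rownames(replicate_scores)]
  if (any(is.na(lab))) stop("labels missing for some patients")
  pos <- lab == "UIP"
  if (!any(pos) || all(pos)) stop("both classes must be present")
  grid <- seq(min(replicate_scores) - grid_step,
              max(replicate_scores) + grid_step, by = grid_step)
  ## per-patient call probability over replicates; averaging these within a
  ## class equals averaging per-replicate sens/spec over replicates
  sens <- vapply(grid, function(b)
    mean(rowMeans(replicate_scores[pos, , drop = FALSE] > b)), numeric(1))
  spec <- vapply(grid, function(b)
    mean(rowMeans(replicate_scores[!pos, , drop = FALSE] <= b)), numeric(1))
  adm <- spec > spec_min & sens >= sens_floor
  tab <- data.frame(boundary = grid, sensitivity = sens, specificity = spec,
                    admissible = adm)
  pick <- function(idx) {
    idx[order(-spec[idx], -sens[idx], grid[idx])][1]
  }
  if (any(adm)) {
    sel <- pick(which(adm)); met <- TRUE
  } else {
    cand <- which(sens >= sens_floor)
    if (!length(cand)) cand <- seq_along(grid)
    sel <- pick(cand); met <- FALSE
  }
  structure(list(boundary = grid[sel], criteria_met = met, grid = tab,
                 spec_min = spec_min, sens_floor = sens_floor,
                 sensitivity = sens[sel], specificity = spec[sel]),
            class = "boundary_selection")
}

#' @export
print.boundary_selection <- function(x, ...) {
  cat(sprintf("decision boundary %.2f (mean sens %.3f, mean spec %.3f)%s\n",
              x$boundary, x$sensitivity, x$specificity,
              if (x$criteria_met) "" else "  [criteria unmet]"))
  invisible(x)
}

#' Apply a locked decision boundary
#'
#' Scores strictly above the boundary are called "UIP"; scores equal to or
#' below it are called "non-UIP".
#'
#' @param scores Numeric scores.
#' @param boundary Finite threshold (or a `boundary_selection`).
#' @return Character vector of calls.
#' @export
classify_scores <- function(scores, boundary) {
  if (inherits(boundary, "boundary_selection")) boundary <- boundary$boundary
  if (!is.finite(boundary)) stop("boundary must be finite")
  calls <- rep("non-UIP", length(scores))
  calls[scores > boundary] <- "UIP"
  names(calls) <- names(scores)
  calls
}
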