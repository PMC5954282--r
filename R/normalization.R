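#' Median-of-ratios size factors
#'
#' Computes one positive scale factor per sample as the median, over usable
#' genes, of the ratio of that sample's count to the gene's geometric mean
#' across the reference samples. Genes with a zero count in any reference
#' sample have geometric mean zero and drop out of the median; zero counts in
#' the sample being scaled are likewise excluded (the standard convention,
#' shared with DESeq2). Dividing counts by their size factor puts all samples
#' on a common sequencing-depth scale.
#'
#' @param counts Integer matrix, genes in rows, samples in columns, with
#'   dimnames.
#' @param reference Optional named vector of per-gene geometric means to use
#'   as the ratio denominator (a frozen training reference). When omitted the
#'   reference is computed from `counts` itself.
#' @return An object of class `size_factors`: a list with `s` (named
#'   per-sample factors) and `reference` (the per-gene geometric means used).
#' @examples
#' K <- matrix(c(10, 30, 20, 60), 2, dimnames = list(c("g1","g2"), c("A","B")))
#' estimate_size_factors(K)$s  # c(A = 0.7071, B = 1.4142)
#' @export
estimate_size_factors <- function(counts, reference = NULL) {
  check_count_matrix(counts)
  if (is.null(reference)) {
    loggeo <- rowMeans(log(counts))     # -Inf where any zero
    reference <- exp(loggeo)
    names(reference) <- rownames(counts)
  } else {
    if (is.null(names(reference)))
      stop("`reference` geometric means must be named by gene")
    missing <- setdiff(rownames(counts), names(reference))
    if (length(missing))
      stop("genes absent from the frozen reference: ",
           paste(utils::head(missing, 5), collapse = ", "))
    reference <- reference[rownames(counts)]
    loggeo <- log(reference)
  }
  usable <- is.finite(loggeo) & reference > 0
  if (!any(usable))
    stop("size factors unidentifiable: no gene has a positive geometric mean")
  s <- vapply(seq_len(ncol(counts)), function(i) {
    k <- counts[, i]
    r <- log(k) - loggeo
    r <- r[usable & k > 0]
    if (!length(r)) return(NA_real_)
    exp(stats::median(r))
  }, numeric(1))
  if (any(!is.finite(s)) || any(s <= 0))
    stop("size factors unidentifiable for sample(s): ",
         paste(colnames(counts)[!is.finite(s) | s <= 0], collapse = ", "))
  names(s) <- colnames(counts)
  structure(list(s = s, reference = reference), class = "size_factors")
}

#' Normalize counts by size factors
#'
#' @param counts Count matrix (genes x samples).
#' @param sf A `size_factors` object covering all columns of `counts`.
#' @return Real matrix of depth-normalized counts C = K / s.
#' @export
normalize_counts <- function(counts, sf) {
  stopifnot(inherits(sf, "size_factors"))
  miss <- setdiff(colnames(counts), names(sf$s))
  if (length(miss)) stop("no size factor for sample(s): ",
                         paste(miss, collapse = ", "))
  sweep(counts, 2, sf$s[colnames(counts)], "/")
}

#' Fit the parametric dispersion trend
#'
#' Per-gene method-of-moments dispersions d_g = max(0, (var - mean) / mean^2)
#' on depth-normalized counts are regressed against 1/mean with the trend
#' d(mu) = alpha_t + alpha_e / mu, by iteratively re-trimmed least squares:
#' at each of up to `max_iter` passes, genes whose residual exceeds 2 median
#' absolute deviations are set aside and the line refitted. alpha_t is the
#' asymptotic (large-count) dispersion; alpha_e captures the extra-Poisson
#' term that dominates at low counts.
#'
#' @param counts Count matrix (genes x samples).
#' @param sf `size_factors` for the columns of `counts`.
#' @param min_genes Minimum number of genes with positive dispersion required.
#' @param max_iter Maximum trimming iterations.
#' @return Named numeric vector `c(alpha_t=, alpha_e=)` with alpha_t > 0 and
#'   alpha_e >= 0.
#' @export
fit_dispersion_trend <- function(counts, sf, min_genes = 50L, max_iter = 10L) {
  C <- normalize_counts(counts, sf)
  mu <- rowMeans(C)
  v <- apply(C, 1, stats::var)
  d <- (v - mu) / mu^2
  keep <- is.finite(d) & d > 0 & mu > 0
  if (sum(keep) < min_genes)
    stop(sprintf("dispersion trend needs >= %d genes with positive dispersion, have %d",
                 min_genes, sum(keep)))
  x <- 1 / mu[keep]; y <- d[keep]
  use <- rep(TRUE, length(y))
  fit <- NULL
  for (it in seq_len(max_iter)) {
    fit <- stats::lm.fit(cbind(1, x[use]), y[use])
    res <- y - (fit$coefficients[1] + fit$coefficients[2] * x)
    s <- stats::mad(res[use])
    if (s <= 0) break
    new_use <- abs(res) <= 2 * s
    if (sum(new_use) < min_genes || identical(new_use, use)) break
    use <- new_use
  }
  alpha_t <- max(unname(fit$coefficients[1]), 1e-8)
  alpha_e <- max(unname(fit$coefficients[2]), 0)
  c(alpha_t = alpha_t, alpha_e = alpha_e)
}

#' Closed-form variance-stabilizing transform
#'
#' The antiderivative of 1/sqrt(v(mu)) for the negative-binomial variance
#' v(mu) = mu (1 + alpha_e) + alpha_t mu^2, rescaled to base 2 so that
#' vst(q) - log2(q) -> 0 as q grows:
#' vst(q) = log2( (1 + alpha_e + 2 alpha_t q +
#'                 2 sqrt(alpha_t q (1 + alpha_e + alpha_t q))) / (4 alpha_t) ).
#'
#' @param q Non-negative normalized counts (any numeric shape).
#' @param alpha_t Asymptotic dispersion, > 0.
#' @param alpha_e Extra-Poisson dispersion term, >= 0.
#' @return Transformed values, same shape as `q`.
#' @export
vst_transform <- function(q, alpha_t, alpha_e = 0) {
  if (!is.finite(alpha_t) || alpha_t <= 0) stop("alpha_t must be > 0")
  if (!is.finite(alpha_e) || alpha_e < 0) stop("alpha_e must be >= 0")
  if (any(q < 0)) stop("negative normalized counts")
  log2((1 + alpha_e + 2 * alpha_t * q +
          2 * sqrt(alpha_t * q * (1 + alpha_e + alpha_t * q))) / (4 * alpha_t))
}

#' Freeze a normalization on training data
#'
#' Fits the per-gene geometric-mean reference and the VST dispersion trend on
#' a training count matrix, returning a frozen object that is reapplied
#' verbatim to any future sample. Freezing makes the transform of each new
#' sample a function of that sample alone, as a locked clinical assay
#' requires.
#'
#' @param counts Training count matrix (genes x samples).
#' @return Object of class `frozen_normalization` with fields `gene_order`,
#'   `reference_geomeans`, `alpha_t`, `alpha_e`, `version`.
#' @export
freeze_normalization <- function(counts) {
  sf <- estimate_size_factors(counts)
  disp <- fit_dispersion_trend(counts, sf)
  structure(list(gene_order = rownames(counts),
                 reference_geomeans = sf$reference,
                 alpha_t = unname(disp["alpha_t"]),
                 alpha_e = unname(disp["alpha_e"]),
                 version = "1"),
            class = "frozen_normalization")
}

#' @export
print.frozen_normalization <- function(x, ...) {
  cat(sprintf("frozen normalization: %d genes, alpha_t = %.4g, alpha_e = %.4g\n",
              length(x$gene_order), x$alpha_t, x$alpha_e))
  invisible(x)
}

#' Apply a frozen normalization to counts
#'
#' Computes each sample's size factor against the frozen per-gene geometric
#' means, divides, and applies the frozen closed-form VST. The result for any
#' sample depends only on that sample's counts and the frozen parameters,
#' never on which other samples are present.
#'
#' @param counts Count matrix whose genes must all be present in `frozen`
#'   (missing genes are a hard error: a locked model must see its exact
#'   feature space).
#' @param frozen A `frozen_normalization`.
#' @return Real matrix of variance-stabilized expression, genes x samples.
#' @export
apply_vst <- function(counts, frozen) {
  stopifnot(inherits(frozen, "frozen_normalization"))
  check_count_matrix(counts)
  miss <- setdiff(rownames(counts), frozen$gene_order)
  if (length(miss))
    stop("genes absent from the frozen normalization: ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) sprintf(" (+%d more)", length(miss) - 5) else "")
  sf <- estimate_size_factors(counts,
                              reference = frozen$reference_geomeans[rownames(counts)])
  q <- normalize_counts(counts, sf)
  vst_transform(q, frozen$alpha_t, frozen$alpha_e)
}
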