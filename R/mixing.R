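#' In-silico mixing of samples within patient
#'
#' Depth-normalizes raw counts (C = K / s) and averages them with equal
#' weight over each patient's samples, producing one pseudo-sample per
#' patient: the computational analogue of pooling a patient's biopsies by
#' equal mass before library preparation. Mixed columns are already on the
#' common normalized scale, so no further size-factoring is applied.
#'
#' @param counts Raw count matrix (genes x samples).
#' @param sf `size_factors` covering all columns (typically computed against
#'   the frozen training reference).
#' @param patient_map Named character vector mapping sample ID -> patient ID,
#'   covering every column of `counts`.
#' @return Real matrix of mixed normalized counts, genes x patients.
#' @export
mix_within_patient <- function(counts, sf, patient_map) {
  miss <- setdiff(colnames(counts), names(patient_map))
  if (length(miss))
    stop("samples without a patient assignment: ", paste(miss, collapse = ", "))
  C <- normalize_counts(counts, sf)
  patients <- unique(patient_map[colnames(counts)])
  mixed <- vapply(patients, function(p) {
    cols <- colnames(counts)[patient_map[colnames(counts)] == p]
    if (!length(cols)) stop("patient with zero samples: ", p)
    rowMeans(C[, cols, drop = FALSE])
  }, numeric(nrow(counts)))
  dimnames(mixed) <- list(rownames(counts), patients)
  mixed
}

#' Apply the frozen VST to mixed normalized counts
#'
#' The frozen closed-form transform is applied to the mixed values directly:
#' the inputs are averages of already depth-normalized counts, so no size
#' factor is recomputed for the mixed columns.
#'
#' @param mixed Matrix of mixed normalized counts from [mix_within_patient()].
#' @param frozen A `frozen_normalization`; its gene set must cover `mixed`.
#' @return Variance-stabilized expression matrix, genes x patients.
#' @export
vst_mixed <- function(mixed, frozen) {
  stopifnot(inherits(frozen, "frozen_normalization"))
  miss <- setdiff(rownames(mixed), frozen$gene_order)
  if (length(miss))
    stop("genes absent from the frozen normalization: ",
         paste(utils::head(miss, 5), collapse = ", "))
  vst_transform(mixed, frozen$alpha_t, frozen$alpha_e)
}

#' Technical-noise model for mixed-sample replication
#'
#' Per-gene technical standard deviations taken from the sentinel variance
#' components: tau_j = sqrt(sigma2_batch + sigma2_e) by default, or the
#' residual component alone.
#'
#' @param models Output of [fit_gene_batch_model()].
#' @param components `"total"` (batch + residual, default) or `"residual"`.
#' @param n_replicates Number of noise replicates to draw (default 100).
#' @param seed RNG seed.
#' @return Object of class `noise_model`: list with `tau` (named per-gene
#'   SDs), `n_replicates`, `seed`.
#' @export
noise_model <- function(models, components = c("total", "residual"),
                        n_replicates = 100L, seed = 1L) {
  components <- match.arg(components)
  v <- if (components == "total") models$total_variation else models$sigma2_e
  tau <- sqrt(pmax(v, 0))
  names(tau) <- models$gene_id
  structure(list(tau = tau, n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), components = components),
            class = "noise_model")
}

#' Replicate mixed expression with technical noise
#'
#' Adds independent Gaussian noise with per-gene SD tau to the VST expression
#' of each mixed sample, `R` times, emulating the technical variability a
#' pooled sample would show across processing runs.
#'
#' @param expr Expression matrix of mixed samples (genes x patients).
#' @param noise A `noise_model` whose `tau` covers every gene of `expr`.
#' @param R Number of replicates (default `noise$n_replicates`).
#' @param seed RNG seed (default `noise$seed`).
#' @return 3-d array genes x patients x R.
#' @export
replicate_with_noise <- function(expr, noise, R = noise$n_replicates,
                                 seed = noise$seed) {
  stopifnot(inherits(noise, "noise_model"))
  miss <- setdiff(rownames(expr), names(noise$tau))
  if (length(miss))
    stop("no technical SD for gene(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  tau <- noise$tau[rownames(expr)]
  m <- nrow(expr); p <- ncol(expr)
  with_seed(seed, {
    out <- array(stats::rnorm(m * p * R, mean = 0, sd = tau),
                 dim = c(m, p, R),
                 dimnames = list(rownames(expr), colnames(expr), NULL))
    out + as.vector(expr)
  })
}

#' Concordance between paired expression matrices
#'
#' Squared Pearson correlation across genes for each paired column (e.g. a
#' patient's in-silico mix vs its in-vitro pool), with the mean and SD over
#' pairs.
#'
#' @param insilico Expression matrix (genes x units).
#' @param invitro Expression matrix with the same genes.
#' @param pairing Named character vector mapping `insilico` column ->
#'   `invitro` column; defaults to matching column names.
#' @return list(per_pair = named r-squared vector, mean, sd).
#' @export
concordance <- function(insilico, invitro,
                        pairing = stats::setNames(colnames(insilico),
                                                  colnames(insilico))) {
  if (!all(names(pairing) %in% colnames(insilico)))
    stop("pairing names must be in-silico columns")
  if (!all(pairing %in% colnames(invitro)))
    stop("unpaired column(s): ",
         paste(setdiff(pairing, colnames(invitro)), collapse = ", "))
  genes <- intersect(rownames(insilico), rownames(invitro))
  if (!length(genes)) stop("no shared genes")
  r2 <- vapply(names(pairing), function(a)
    stats::cor(insilico[genes, a], invitro[genes, pairing[a]])^2, numeric(1))
  list(per_pair = r2, mean = mean(r2), sd = stats::sd(r2))
}
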