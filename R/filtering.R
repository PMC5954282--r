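#' Filter genes by annotation class
#'
#' Removes genes outside the enrichment panel, then genes whose biotype marks
#' them as uninformative for a coding-transcriptome assay: pseudogenes,
#' ribosomal RNAs, and individual T-cell-receptor / immunoglobulin exon
#' features.
#'
#' @param universe Character vector of gene IDs.
#' @param annotation data.frame with columns `gene_id`, `biotype`,
#'   `in_target_panel`; every universe gene must be annotated.
#' @param drop_biotypes Biotypes to remove after the panel filter.
#' @return Character vector of retained gene IDs (ordered as `universe`).
#' @export
filter_by_annotation <- function(universe, annotation,
                                 drop_biotypes = c("pseudogene", "rRNA",
                                                   "TR_IG_exon")) {
  stopifnot(is.data.frame(annotation),
            all(c("gene_id", "biotype", "in_target_panel") %in% names(annotation)))
  if (anyDuplicated(universe)) stop("duplicate gene IDs in universe")
  miss <- setdiff(universe, annotation$gene_id)
  if (length(miss))
    stop("unannotated gene(s): ", paste(utils::head(miss, 10), collapse = ", "))
  ann <- annotation[match(universe, annotation$gene_id), ]
  keep <- ann$in_target_panel & !(ann$biotype %in% drop_biotypes)
  universe[keep]
}

#' Filter lowly expressed genes
#'
#' Removes gene j when its summed raw count over all training samples is
#' below `total_floor`, or when it is detected (count > 0) in fewer than
#' `presence_frac` of the samples.
#'
#' @param counts Training count matrix (genes x samples) covering `universe`.
#' @param universe Gene IDs to consider.
#' @param total_floor Minimum summed raw count (default 5).
#' @param presence_frac Minimum detected-sample fraction (default 0.05).
#' @return Character vector of retained gene IDs.
#' @export
filter_low_expression <- function(counts, universe, total_floor = 5L,
                                  presence_frac = 0.05) {
  miss <- setdiff(universe, rownames(counts))
  if (length(miss))
    stop("counts do not cover gene(s): ", paste(utils::head(miss, 10), collapse = ", "))
  K <- counts[universe, , drop = FALSE]
  keep <- rowSums(K) >= total_floor &
    rowMeans(K > 0) >= presence_frac
  universe[keep]
}

#' Per-gene batch variance components from sentinel replicates
#'
#' For each gene, fits expression = mu + sample (fixed, biological sentinel
#' source) + batch (random) + residual on the sentinel columns. For the
#' balanced crossed design (every source in every batch, equal replication)
#' the fit is closed-form ANOVA method of moments: sigma2_batch = (batch mean
#' square - residual mean square) / (sources per batch), truncated at zero;
#' unbalanced designs fall back to a per-gene REML fit (lme4). The "total
#' variation" sigma2_batch + sigma2_e measures a gene's sensitivity to
#' technical processing, excluding biological differences among sources.
#'
#' @param expr Variance-stabilized expression matrix restricted to sentinel
#'   columns (genes x sentinel samples).
#' @param sentinel_meta data.frame with one row per column of `expr`,
#'   columns `sample_id`, `source` (biological sentinel), `batch`.
#' @return data.frame with one row per gene: `gene_id`, `mu`, `sigma2_batch`,
#'   `sigma2_e`, `total_variation`.
#' @export
fit_gene_batch_model <- function(expr, sentinel_meta) {
  stopifnot(is.matrix(expr),
            all(c("sample_id", "source", "batch") %in% names(sentinel_meta)))
  meta <- sentinel_meta[match(colnames(expr), sentinel_meta$sample_id), ]
  if (any(is.na(meta$sample_id)))
    stop("sentinel_meta does not cover all expression columns")
  src <- factor(meta$source); bat <- factor(meta$batch)
  S <- nlevels(src); B <- nlevels(bat)
  if (B < 2 || S < 2)
    stop("need >= 2 batches and >= 2 sentinel sources")
  cell <- table(src, bat)
  balanced <- length(unique(as.vector(cell))) == 1 && all(cell >= 1)
  n <- ncol(expr)
  if (balanced && all(cell == 1)) {
    ## one observation per (source, batch) cell: two-way ANOVA MoM
    Zb <- stats::model.matrix(~ bat - 1)   # n x B
    Zs <- stats::model.matrix(~ src - 1)   # n x S
    bm <- expr %*% Zb / S                  # per-gene batch means
    sm <- expr %*% Zs / B                  # per-gene source means
    gm <- rowMeans(expr)
    ss_b <- S * rowSums((bm - gm)^2)
    ss_s <- B * rowSums((sm - gm)^2)
    ss_t <- rowSums((expr - gm)^2)
    ss_e <- pmax(ss_t - ss_b - ss_s, 0)
    ms_b <- ss_b / (B - 1)
    ms_e <- ss_e / ((B - 1) * (S - 1))
    sigma2_batch <- pmax((ms_b - ms_e) / S, 0)
    sigma2_e <- ms_e
    out <- data.frame(gene_id = rownames(expr), mu = gm,
                      sigma2_batch = sigma2_batch, sigma2_e = sigma2_e,
                      stringsAsFactors = FALSE)
  } else {
    ## unbalanced: per-gene REML
    out <- do.call(rbind, lapply(seq_len(nrow(expr)), function(g) {
      d <- data.frame(y = expr[g, ], src = src, bat = bat)
      fit <- suppressMessages(suppressWarnings(
        lme4::lmer(y ~ src + (1 | bat), data = d, REML = TRUE)))
      vc <- as.data.frame(lme4::VarCorr(fit))
      data.frame(gene_id = rownames(expr)[g], mu = mean(expr[g, ]),
                 sigma2_batch = vc$vcov[vc$grp == "bat"],
                 sigma2_e = vc$vcov[vc$grp == "Residual"],
                 stringsAsFactors = FALSE)
    }))
  }
  out$total_variation <- out$sigma2_batch + out$sigma2_e
  rownames(out) <- NULL
  out
}

#' Remove the most batch-sensitive genes
#'
#' Ranks genes by total technical variation (batch variance + residual
#' variance from the sentinel model) and removes the top fraction. Ties at
#' the cut are broken by gene ID in lexicographic order so the removal set
#' is deterministic.
#'
#' @param models Output of [fit_gene_batch_model()], covering `universe`.
#' @param universe Gene IDs to filter.
#' @param top_fraction Fraction removed, in (0, 1); default 0.05.
#' @return Character vector of retained gene IDs.
#' @export
filter_batch_sensitive <- function(models, universe, top_fraction = 0.05) {
  check_proportion(top_fraction, "top_fraction", open = TRUE)
  miss <- setdiff(universe, models$gene_id)
  if (length(miss))
    stop("no batch model for gene(s): ", paste(utils::head(miss, 10), collapse = ", "))
  tv <- models$total_variation[match(universe, models$gene_id)]
  n_remove <- ceiling(top_fraction * length(universe))
  ord <- order(-tv, universe)
  removed <- universe[ord[seq_len(n_remove)]]
  setdiff(universe, removed)
}
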