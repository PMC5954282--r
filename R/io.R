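#' Write / read a count matrix as TSV
#'
#' Genes as rows, samples as columns, header row of sample IDs, first column
#' `gene_id`.
#'
#' @param counts Count matrix.
#' @param path File path.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Serialize a frozen normalization as JSON
#'
#' @param frozen A `frozen_normalization`.
#' @param path File path.
#' @export
write_frozen_normalization <- function(frozen, path) {
  stopifnot(inherits(frozen, "frozen_normalization"))
  jsonlite::write_json(
    list(gene_order = frozen$gene_order,
         reference_geomeans = unname(frozen$reference_geomeans),
         alpha_t = frozen$alpha_t, alpha_e = frozen$alpha_e,
         version = frozen$version),
    path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_frozen_normalization
#' @export
read_frozen_normalization <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(gene_order = x$gene_order,
                 reference_geomeans = stats::setNames(x$reference_geomeans,
                                                      x$gene_order),
                 alpha_t = x$alpha_t, alpha_e = x$alpha_e,
                 version = x$version),
            class = "frozen_normalization")
}

#' Serialize a locked classifier as JSON
#'
#' @param model A `trained_classifier`.
#' @param path File path.
#' @param boundary Optional locked decision boundary to embed.
#' @export
write_classifier <- function(model, path, boundary = NULL) {
  stopifnot(inherits(model, "trained_classifier"))
  if (inherits(boundary, "boundary_selection")) boundary <- boundary$boundary
  jsonlite::write_json(
    list(genes = model$genes, weights = unname(model$weights),
         intercept = model$intercept, lambda = model$lambda,
         mixing = model$mixing, positive_class = model$positive_class,
         boundary = boundary),
    path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- structure(list(genes = x$genes,
                          weights = stats::setNames(x$weights, x$genes),
                          intercept = x$intercept, lambda = x$lambda,
                          mixing = x$mixing,
                          positive_class = x$positive_class),
                     class = "trained_classifier")
  attr(model, "boundary") <- x$boundary
  model
}

#' Write a gene set, one ID per line
#'
#' @param genes Character vector of gene IDs.
#' @param path File path.
#' @export
write_gene_set <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' @rdname write_gene_set
#' @export
read_gene_set <- function(path) readLines(path)
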