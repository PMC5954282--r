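#' @keywords internal
"_PACKAGE"

## Internal validators shared across modules.

check_count_matrix <- function(K, arg = "counts") {
  if (!is.matrix(K) || !is.numeric(K))
    stop(sprintf("`%s` must be a numeric matrix (genes x samples)", arg))
  if (is.null(rownames(K)) || is.null(colnames(K)))
    stop(sprintf("`%s` must carry gene rownames and sample colnames", arg))
  if (anyDuplicated(rownames(K)) || anyDuplicated(colnames(K)))
    stop(sprintf("`%s` has duplicated gene or sample identifiers", arg))
  if (any(K < 0)) stop(sprintf("`%s` contains negative counts", arg))
  if (any(abs(K - round(K)) > 1e-8))
    stop(sprintf("`%s` contains non-integral counts", arg))
  invisible(K)
}

check_proportion <- function(x, arg, open = FALSE) {
  ok <- length(x) == 1L && is.finite(x) &&
    if (open) (x > 0 && x < 1) else (x >= 0 && x <= 1)
  if (!ok) stop(sprintf("`%s` must be a proportion %s", arg,
                        if (open) "in (0,1)" else "in [0,1]"))
  invisible(x)
}

## Seeded evaluation that restores the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}
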