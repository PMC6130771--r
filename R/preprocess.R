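#' Normalize raw counts to counts per million
#'
#' Library-size normalization only: each stage column is rescaled to sum to
#' one million. No transcript-length correction is applied, matching
#' tag-based protocols (e.g. CEL-Seq) where reads come from transcript ends.
#'
#' @param x A [devo_expr] table on the `raw_count` scale.
#' @return A [devo_expr] table on the `normalized_linear` scale.
#' @export
normalize_cpm <- function(x) {
  if (expr_scale(x) != "raw_count") {
    abort("`normalize_cpm()` expects a raw_count table; declared scale differs.")
  }
  m <- expr_matrix(x)
  tot <- colSums(m)
  if (any(tot <= 0)) {
    abort(sprintf(
      "Stage column(s) with zero total count cannot be normalized: %s",
      paste(colnames(m)[tot <= 0], collapse = ", ")
    ))
  }
  expr_from_matrix(x$gene_id, sweep(m, 2L, tot, "/") * 1e6, "normalized_linear")
}

#' Remove genes with low mean expression
#'
#' Drops genes whose mean expression across stages is strictly below
#' `threshold` (default 1, i.e. mean CPM/FPKM < 1), keeping gene order.
#'
#' @param x A [devo_expr] table on a linear scale.
#' @param threshold Removal threshold on the mean across stages.
#' @return A filtered [devo_expr] table.
#' @export
filter_low_mean <- function(x, threshold = 1) {
  if (expr_scale(x) == "log_transformed") {
    abort("`filter_low_mean()` expects a linear-scale table.")
  }
  m <- expr_matrix(x)
  keep <- rowMeans(m) >= threshold
  devo_expr(tibble::as_tibble(x)[keep, , drop = FALSE], scale = expr_scale(x))
}

#' Transform expression values
#'
#' Applies the weighting transform used for transcriptome indexes:
#' `log2` computes `log2(x + 1)` (the pseudocount maps 0 to 0 and keeps
#' weights nonnegative), `sqrt` computes the square root, and `identity`
#' passes values through. Log or sqrt transforms of an already
#' log-transformed table are refused to avoid double transformation.
#'
#' @param x A [devo_expr] table.
#' @param mode One of `"log2"`, `"sqrt"`, `"identity"`.
#' @return A [devo_expr] table; the scale is tagged `log_transformed` after
#'   `log2`, and left linear after `sqrt`/`identity` on linear input.
#' @export
transform_expression <- function(x, mode = c("log2", "sqrt", "identity")) {
  mode <- match.arg(mode)
  scale <- expr_scale(x)
  if (scale == "log_transformed" && mode != "identity") {
    abort("Input is already log transformed; only mode = 'identity' is valid.")
  }
  m <- expr_matrix(x)
  out <- switch(mode, log2 = log2(m + 1), sqrt = sqrt(m), identity = m)
  out_scale <- if (mode == "log2") "log_transformed" else scale
  expr_from_matrix(x$gene_id, out, out_scale)
}

#' Binary expressed calls per gene and stage
#'
#' Converts expression into boolean expressed/not-expressed calls, either by
#' an absolute threshold (`value > t`, e.g. FPKM > 1) or by per-stage rank
#' (`rank_top`: within each stage a gene is called expressed iff its
#' descending rank position is at most `ceiling(q * n_genes)`; ties take
#' average ranks, so a tie group straddling the cutoff is called as a block).
#' Per-stage ranking keeps the number of expressed genes comparable across
#' stages, which is what a "signal rank in top q" call is for.
#'
#' @param x A [devo_expr] table (linear scale required for `threshold`).
#' @param rule `"threshold"` or `"rank_top"`.
#' @param threshold Call threshold for `rule = "threshold"`.
#' @param q Top fraction in (0, 1] for `rule = "rank_top"`.
#' @return A tibble of class `expr_calls`: `gene_id` plus one logical column
#'   per stage.
#' @export
call_expressed <- function(x, rule = c("threshold", "rank_top"), threshold = 1, q = 0.7) {
  rule <- match.arg(rule)
  m <- expr_matrix(x)
  if (rule == "threshold") {
    if (expr_scale(x) == "log_transformed") {
      abort("Threshold calls are defined on linear-scale expression.")
    }
    calls <- m > threshold
  } else {
    if (!is.numeric(q) || length(q) != 1L || is.na(q) || q <= 0 || q > 1) {
      abort("`q` must be a single number in (0, 1].")
    }
    cutoff <- ceiling(q * nrow(m))
    calls <- apply(m, 2L, function(v) rank(-v, ties.method = "average") <= cutoff)
    if (is.null(dim(calls))) calls <- matrix(calls, nrow = nrow(m))
    dimnames(calls) <- dimnames(m)
  }
  out <- tibble::as_tibble(as.data.frame(calls, optional = TRUE))
  out <- tibble::add_column(out, gene_id = x$gene_id, .before = 1L)
  structure(out, class = c("expr_calls", class(tibble::tibble())))
}
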