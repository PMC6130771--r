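#' Developmental expression tables
#'
#' A developmental expression table holds one row per gene and one column per
#' developmental stage, in sampled order, together with a declared measurement
#' scale. The scale is never inferred from the values: upstream sources mix
#' raw counts, linear normalized units (CPM/FPKM) and already log-transformed
#' microarray intensities, and silent inference risks double transformation.
#'
#' @param x A data frame whose first column is `gene_id` and whose remaining
#'   columns are numeric per-stage expression values (stage order = column
#'   order).
#' @param scale Declared measurement scale: `"raw_count"`,
#'   `"normalized_linear"`, or `"log_transformed"`.
#'
#' @return A tibble of class `devo_expr` with a `scale` attribute.
#'
#' @details Invariants enforced: unique gene identifiers, no missing cells
#' (absence is encoded as 0 on linear scales), and nonnegative values unless
#' the scale is `log_transformed`.
#'
#' @examples
#' m <- devo_expr(
#'   tibble::tibble(gene_id = c("g1", "g2"), s1 = c(1, 3), s2 = c(2, 0)),
#'   scale = "normalized_linear"
#' )
#' expr_stages(m)
#' @export
devo_expr <- function(x, scale = c("raw_count", "normalized_linear", "log_transformed")) {
  scale <- match.arg(scale)
  stop_if_not_df(x, "x")
  if (ncol(x) < 2L) {
    abort("Expression table needs a `gene_id` column plus at least one stage column.")
  }
  x <- tibble::as_tibble(x)
  names(x)[1L] <- "gene_id"
  x$gene_id <- as.character(x$gene_id)
  if (anyDuplicated(x$gene_id)) {
    dup <- unique(x$gene_id[duplicated(x$gene_id)])
    abort(sprintf("Duplicated gene ids: %s", paste(utils::head(dup, 5L), collapse = ", ")))
  }
  vals <- x[-1L]
  ok_num <- vapply(vals, is.numeric, logical(1L))
  if (!all(ok_num)) {
    abort(sprintf(
      "Non-numeric stage column(s): %s",
      paste(names(vals)[!ok_num], collapse = ", ")
    ))
  }
  if (anyNA(vals)) {
    abort("Missing expression cells are not allowed; encode absence as 0 on linear scales.")
  }
  if (scale != "log_transformed" && any(vapply(vals, function(v) any(v < 0), logical(1L)))) {
    abort(sprintf("Negative expression values are invalid on scale '%s'.", scale))
  }
  structure(x, scale = scale, class = c("devo_expr", class(tibble::tibble())))
}

#' @rdname devo_expr
#' @export
expr_scale <- function(x) {
  s <- attr(x, "scale", exact = TRUE)
  if (is.null(s)) {
    abort("`x` has no declared expression scale; rebuild it with `devo_expr()`.")
  }
  s
}

#' @rdname devo_expr
#' @export
expr_stages <- function(x) names(x)[-1L]

# genes x stages numeric matrix with gene ids as rownames
expr_matrix <- function(x) {
  m <- as.matrix(x[-1L])
  rownames(m) <- x$gene_id
  m
}

# rebuild a devo_expr from a gene id vector + matrix, keeping stage order
expr_from_matrix <- function(gene_id, m, scale) {
  out <- tibble::as_tibble(as.data.frame(m, optional = TRUE))
  out <- tibble::add_column(out, gene_id = gene_id, .before = 1L)
  devo_expr(out, scale = scale)
}

#' Read and write gene-by-stage expression tables
#'
#' The interchange format is a tab-delimited UTF-8 file with a header row of
#' stage identifiers, a first column of gene identifiers, and `.` as decimal
#' separator. Stage order is taken from column order and preserved through
#' the whole pipeline.
#'
#' @param path Path to a TSV file.
#' @inheritParams devo_expr
#'
#' @return `read_expression()` returns a [devo_expr] table;
#'   `write_expression()` returns `path` invisibly.
#' @export
read_expression <- function(path, scale = c("raw_count", "normalized_linear", "log_transformed")) {
  scale <- match.arg(scale)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  if (ncol(raw) < 2L) {
    abort("Expression file needs a gene id column and at least one stage column.")
  }
  vals <- raw[-1L]
  parsed <- lapply(vals, function(v) {
    out <- suppressWarnings(as.numeric(v))
    if (anyNA(out) && !all(is.na(out) == is.na(v))) {
      bad <- v[is.na(out) & !is.na(v)][1L]
      abort(sprintf("Non-numeric expression cell: '%s'", bad))
    }
    out
  })
  out <- tibble::as_tibble(c(stats::setNames(raw[1L], "gene_id"), parsed))
  devo_expr(out, scale = scale)
}

#' @rdname read_expression
#' @param x A [devo_expr] table.
#' @export
write_expression <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path)
  invisible(path)
}
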