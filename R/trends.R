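# all permutations of 1..n, as a matrix with one permutation per row;
# only used for tiny n (exact Spearman p over S! stage orderings)
perms <- function(n) {
  if (n == 1L) {
    return(matrix(1L, 1L, 1L))
  }
  sub <- perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# Spearman correlation with p-value: exact permutation enumeration for
# n < exact_below, t-approximation otherwise; two-sided.
spearman_p <- function(x, y, exact_below = 5L) {
  n <- length(x)
  rho <- cor(x, y, method = "spearman")
  if (is.na(rho)) {
    return(list(rho = NA_real_, p = NA_real_))
  }
  if (n < exact_below) {
    ry <- rank(y)
    rx <- rank(x)
    all_rho <- apply(perms(n), 1L, function(p) cor(rx, ry[p]))
    p <- mean(abs(all_rho) >= abs(rho) - 1e-12)
  } else if (abs(rho) >= 1) {
    # monotone without ties: t statistic diverges; bound by the exact
    # probability of a perfectly concordant or discordant ordering
    p <- 2 / factorial(n)
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = min(p, 1))
}

#' Retrogene expression trend across development
#'
#' Retrogenes arise by reverse transcription of mRNA and usually lack their
#' parent's regulatory elements; if late development is permissive for
#' transcription (as testis is in adult anatomy), their median expression
#' should rise with developmental time. This computes the per-stage median
#' expression of retrogenes and a Spearman correlation between stage rank
#' (1..S) and those medians. Testis-specific genes can be excluded (pass the
#' `gene_id`s flagged by [compute_tau()]), since testis differentiates after
#' middle development and would confound the trend.
#'
#' @param x A [devo_expr] table.
#' @param annotation Annotation tibble with an `is_retrogene` column.
#' @param exclude Optional character vector of gene ids to drop before the
#'   analysis (e.g. testis-specific genes).
#' @return An object of class `retro_trend`: a tibble with columns `stage`,
#'   `median_expression`, and attributes `rho`, `p_value`, `n_genes`.
#' @export
retrogene_trend <- function(x, annotation, exclude = NULL) {
  annotation <- validate_annotation(annotation)
  if (!"is_retrogene" %in% names(annotation)) {
    abort("Annotation has no `is_retrogene` column.")
  }
  if (length(expr_stages(x)) < 3L) {
    abort("At least three stages are needed for a trend.")
  }
  retro <- annotation$gene_id[annotation$is_retrogene %in% TRUE]
  retro <- setdiff(intersect(retro, x$gene_id), exclude)
  if (!length(retro)) {
    abort("No retrogenes left after exclusion.")
  }
  m <- expr_matrix(x)[retro, , drop = FALSE]
  med <- apply(m, 2L, median)
  sp <- spearman_p(seq_along(med), med)
  structure(
    tibble::tibble(stage = colnames(m), median_expression = unname(med)),
    rho = sp$rho, p_value = sp$p, n_genes = length(retro),
    class = c("retro_trend", class(tibble::tibble()))
  )
}

#' Connectivity versus duplicability
#'
#' Dosage balance predicts that highly connected proteins tolerate
#' duplication poorly, so paralog count should fall with protein
#' connectivity — though empirically the relation can be non-monotone
#' (rising first, then falling). Reports the Spearman correlation between
#' connectivity and paralog count plus a binned trend (mean paralog count
#' per connectivity quantile bin) that exposes non-monotone shapes a single
#' coefficient would hide.
#'
#' @param annotation Annotation tibble with `connectivity` and
#'   `paralog_count` columns; at least 10 genes with both.
#' @param bins Number of connectivity quantile bins for the trend table.
#' @return An object of class `conn_dup`: a list with `rho`, `p_value`,
#'   `undefined` (`TRUE` when connectivity is all-tied so the correlation
#'   does not exist), `n_genes`, and `trend`, a tibble with one row per bin
#'   (`bin`, `n`, `mean_connectivity`, `mean_paralogs`).
#' @export
connectivity_duplicability <- function(annotation, bins = 5) {
  annotation <- validate_annotation(annotation)
  for (col in c("connectivity", "paralog_count")) {
    if (!col %in% names(annotation)) {
      abort(sprintf("Annotation has no `%s` column.", col))
    }
  }
  dat <- annotation[!is.na(annotation$connectivity) & !is.na(annotation$paralog_count), ]
  if (nrow(dat) < 10L) {
    abort("At least 10 genes with both connectivity and paralog_count are required.")
  }
  undefined <- length(unique(dat$connectivity)) == 1L
  if (undefined) {
    rho <- NA_real_
    p <- NA_real_
  } else {
    sp <- spearman_p(dat$connectivity, dat$paralog_count)
    rho <- sp$rho
    p <- sp$p
  }
  trend <- dat |>
    dplyr::mutate(bin = dplyr::ntile(.data$connectivity, bins)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_connectivity = mean(.data$connectivity),
      mean_paralogs = mean(.data$paralog_count),
      .groups = "drop"
    )
  structure(
    list(rho = rho, p_value = p, undefined = undefined, n_genes = nrow(dat), trend = trend),
    class = "conn_dup"
  )
}

#' @export
print.conn_dup <- function(x, ...) {
  cat(sprintf("Connectivity vs duplicability (%d genes)\n", x$n_genes))
  if (x$undefined) {
    cat("  Spearman correlation undefined: connectivity has no variation\n")
  } else {
    cat(sprintf("  Spearman rho = %.3f, p = %.3g\n", x$rho, x$p_value))
  }
  print(x$trend)
  invisible(x)
}
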