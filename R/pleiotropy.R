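#' Flag temporally pleiotropic genes
#'
#' Temporal pleiotropy uses expression breadth across development as a proxy
#' for the number of traits a gene can affect: a gene is flagged pleiotropic
#' when it is called expressed in strictly more than `breadth_threshold` of
#' the stages considered (default > 50%, with > 70% a common sensitivity
#' setting). By default every sampled stage counts in the denominator;
#' `include_premzt = FALSE` drops pre-MZT stages from both numerator and
#' denominator (requires `timeline`).
#'
#' @param calls An `expr_calls` table from [call_expressed()].
#' @param breadth_threshold Breadth fraction in (0, 1); strict inequality.
#' @param include_premzt Count pre-MZT stages in the breadth computation?
#' @param timeline A [stage_timeline]; only needed when
#'   `include_premzt = FALSE`.
#' @return A tibble with columns `gene_id` and `pleiotropic`.
#' @export
pleiotropy_flags <- function(calls, breadth_threshold = 0.5,
                             include_premzt = TRUE, timeline = NULL) {
  if (!inherits(calls, "expr_calls")) {
    abort("`calls` must come from call_expressed().")
  }
  if (!is.numeric(breadth_threshold) || breadth_threshold <= 0 || breadth_threshold >= 1) {
    abort("`breadth_threshold` must lie in (0, 1).")
  }
  cm <- as.matrix(calls[-1L])
  if (!include_premzt) {
    if (is.null(timeline)) {
      abort("`timeline` is required when include_premzt = FALSE.")
    }
    keep <- timeline$stage[timeline$period != "preMZT"]
    cm <- cm[, colnames(cm) %in% keep, drop = FALSE]
  }
  tibble::tibble(
    gene_id = calls$gene_id,
    pleiotropic = rowMeans(cm) > breadth_threshold
  )
}

#' Per-stage pleiotropic-gene proportions with a goodness-of-fit test
#'
#' For each stage, the proportion of pleiotropic genes among genes called
#' expressed at that stage. A chi-square goodness-of-fit test compares the
#' per-stage pleiotropic counts with expected counts proportional to the
#' per-stage expressed totals — the natural null of a stage-constant
#' pleiotropic fraction — on `n_stages - 1` degrees of freedom.
#'
#' @inheritParams pleiotropy_flags
#' @param flags Output of [pleiotropy_flags()] on the same `calls`.
#' @return An object of class `pleiotropy_profile`: a tibble with columns
#'   `stage`, `n_expressed`, `n_pleiotropic`, `proportion` and attributes
#'   `chi2_statistic`, `df`, `p_value`.
#' @export
pleiotropy_profile <- function(calls, flags) {
  if (!inherits(calls, "expr_calls")) {
    abort("`calls` must come from call_expressed().")
  }
  if (!identical(flags$gene_id, calls$gene_id)) {
    abort("`flags` must cover the same genes, in the same order, as `calls`.")
  }
  cm <- as.matrix(calls[-1L])
  if (ncol(cm) < 2L) {
    abort("At least two stages are needed for the goodness-of-fit test (df >= 1).")
  }
  n_expressed <- colSums(cm)
  if (any(n_expressed == 0)) {
    abort(sprintf(
      "Stage(s) with zero expressed genes: %s",
      paste(colnames(cm)[n_expressed == 0], collapse = ", ")
    ))
  }
  n_pleio <- colSums(cm & flags$pleiotropic)
  gof <- suppressWarnings(
    chisq.test(x = n_pleio, p = n_expressed / sum(n_expressed))
  )
  structure(
    tibble::tibble(
      stage = colnames(cm),
      n_expressed = as.integer(n_expressed),
      n_pleiotropic = as.integer(n_pleio),
      proportion = unname(n_pleio / n_expressed)
    ),
    chi2_statistic = unname(gof$statistic),
    df = unname(gof$parameter),
    p_value = unname(gof$p.value),
    class = c("pleiotropy_profile", class(tibble::tibble()))
  )
}

#' Compare an evolutionary parameter between two gene groups
#'
#' Wilcoxon rank-sum (Mann-Whitney) two-sided comparison of a parameter —
#' typically omega0 between pleiotropic and non-pleiotropic genes. The exact
#' distribution is used when both groups have fewer than 25 genes and there
#' are no ties; otherwise the normal approximation with tie correction.
#'
#' @param annotation Per-gene annotation tibble.
#' @param param Name of the numeric annotation column to compare.
#' @param groups A data frame with columns `gene_id` and a logical group
#'   column (e.g. the output of [pleiotropy_flags()]), or a logical vector
#'   aligned with `annotation`.
#' @return A one-row tibble: `statistic` (W), `p_value`, `n_in_group`,
#'   `n_out_group`, `median_in`, `median_out`.
#' @export
compare_param_by_group <- function(annotation, param, groups) {
  annotation <- validate_annotation(annotation)
  if (!param %in% names(annotation)) {
    abort(sprintf("Annotation has no column '%s'.", param))
  }
  if (is.data.frame(groups)) {
    flag_col <- setdiff(names(groups), "gene_id")[1L]
    flag <- groups[[flag_col]][match(annotation$gene_id, groups$gene_id)]
  } else {
    flag <- as.logical(groups)
    if (length(flag) != nrow(annotation)) {
      abort("Logical `groups` must align with `annotation` rows.")
    }
  }
  keep <- !is.na(annotation[[param]]) & !is.na(flag)
  v <- annotation[[param]][keep]
  flag <- flag[keep]
  g_in <- v[flag]
  g_out <- v[!flag]
  if (!length(g_in) || !length(g_out)) {
    abort("Both groups must be nonempty.")
  }
  exact <- max(length(g_in), length(g_out)) < 25 && !anyDuplicated(v)
  ht <- suppressWarnings(
    wilcox.test(g_in, g_out, alternative = "two.sided", exact = exact, correct = !exact)
  )
  tibble::tibble(
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    n_in_group = length(g_in),
    n_out_group = length(g_out),
    median_in = median(g_in),
    median_out = median(g_out)
  )
}
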