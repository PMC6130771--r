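# Core weighted mean: W is a genes x stages weight matrix (transformed
# expression), E the per-gene parameter. Callers guarantee alignment.
tei_core <- function(W, E) {
  den <- colSums(W)
  as.numeric(crossprod(W, E)) / unname(den)
}

# Align an expression table with a parameter column of the annotation;
# returns list(W, E, stages) restricted to genes carrying the parameter.
align_param <- function(x, annotation, param) {
  annotation <- validate_annotation(annotation)
  if (!param %in% names(annotation)) {
    abort(sprintf("Annotation has no column '%s'.", param))
  }
  ann <- annotation[!is.na(annotation[[param]]), c("gene_id", param)]
  keep <- intersect(x$gene_id, ann$gene_id)
  if (!length(keep)) {
    abort(sprintf("No genes shared between expression table and '%s' annotation.", param))
  }
  W <- expr_matrix(x)[keep, , drop = FALSE]
  E <- ann[[param]][match(keep, ann$gene_id)]
  den <- colSums(W)
  if (any(den <= 0)) {
    abort(sprintf(
      "Zero total expression weight at stage(s): %s",
      paste(colnames(W)[den <= 0], collapse = ", ")
    ))
  }
  list(W = W, E = as.numeric(E), stages = colnames(W))
}

#' Per-stage transcriptome evolutionary index
#'
#' The transcriptome evolutionary index (TEI) at stage \eqn{s} is the
#' expression-weighted mean of a gene-level evolutionary parameter:
#' \deqn{TEI_s = \sum_i E_i e_{is} / \sum_i e_{is},}
#' where \eqn{e_{is}} is the (typically log2-transformed) expression of gene
#' \eqn{i} at stage \eqn{s} and \eqn{E_i} the parameter (omega0 gives the
#' divergence index TDI, phylostratum the age index TAI, paralog count the
#' paralog index TPI, connectivity the connectivity index TCI). Genes
#' lacking the parameter are excluded from numerator and denominator alike,
#' never imputed.
#'
#' @param x A [devo_expr] table holding the weights (apply
#'   [transform_expression()] first if desired).
#' @param annotation Per-gene annotation tibble (see [read_annotation()]).
#' @param param Name of the annotation column to use as \eqn{E_i}.
#' @return A tibble with columns `stage`, `tei`, `n_genes`; stage order
#'   matches the expression table.
#'
#' @examples
#' m <- devo_expr(
#'   tibble::tibble(gene_id = c("g1", "g2"), s1 = c(1, 3), s2 = c(3, 1)),
#'   scale = "normalized_linear"
#' )
#' ann <- tibble::tibble(gene_id = c("g1", "g2"), omega0 = c(1, 3))
#' compute_tei(m, ann, "omega0")
#' @export
compute_tei <- function(x, annotation, param) {
  al <- align_param(x, annotation, param)
  tibble::tibble(
    stage = al$stages,
    tei = tei_core(al$W, al$E),
    n_genes = nrow(al$W)
  )
}

#' Transcriptome index profile with bootstrap confidence intervals
#'
#' Resamples gene identifiers with replacement `n_boot` times, recomputing
#' the full per-stage index for each resample; the confidence band at each
#' stage is the empirical quantile interval of the resampled indexes
#' (type-7 quantiles). One shared gene resample is used across all stages of
#' a replicate, so each replicate is an internally consistent developmental
#' curve. The point estimate comes from the original, unresampled data.
#'
#' @inheritParams compute_tei
#' @param n_boot Number of bootstrap resamples (>= 2; 10,000 by default).
#' @param level Confidence level (default 0.95, i.e. quantiles 2.5% and
#'   97.5%).
#' @param seed Optional integer seed; the session RNG state is untouched.
#' @return A tibble of class `tei_profile` with columns `stage`, `tei`,
#'   `ci_lower`, `ci_upper`, `n_genes`, and attributes `param`, `n_boot`,
#'   `level`, `seed`.
#' @export
tei_profile <- function(x, annotation, param, n_boot = 10000, level = 0.95, seed = NULL) {
  if (!is.numeric(n_boot) || n_boot < 2) {
    abort("`n_boot` must be at least 2.")
  }
  n_boot <- as.integer(n_boot)
  al <- align_param(x, annotation, param)
  G <- nrow(al$W)
  point <- tei_core(al$W, al$E)

  idx <- local_seed(seed, matrix(sample.int(G, G * n_boot, replace = TRUE), nrow = n_boot))
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  lo <- hi <- numeric(length(al$stages))
  for (s in seq_along(al$stages)) {
    num <- (al$E * al$W[, s])[idx]
    den <- al$W[, s][idx]
    dim(num) <- dim(den) <- dim(idx)
    reps <- rowSums(num) / rowSums(den)
    qs <- quantile(reps, probs, names = FALSE, type = 7, na.rm = FALSE)
    lo[s] <- qs[1L]
    hi[s] <- qs[2L]
  }
  structure(
    tibble::tibble(
      stage = al$stages, tei = point,
      ci_lower = lo, ci_upper = hi, n_genes = G
    ),
    param = param, n_boot = n_boot, level = level, seed = seed,
    class = c("tei_profile", class(tibble::tibble()))
  )
}

#' Confidence-interval ratio stability diagnostic
#'
#' The ratio of the upper to the lower confidence bound per stage puts
#' confidence-band width on a common, unitless scale across expression
#' transforms. A transform whose ratio curve is flatter and closer to 1
#' yields a more stable index, less driven by a handful of very highly
#' expressed genes.
#'
#' @param profile A [tei_profile].
#' @return A tibble with columns `stage` and `ci_ratio`.
#' @export
ci_ratio <- function(profile) {
  if (!inherits(profile, "tei_profile")) {
    abort("`profile` must be a tei_profile.")
  }
  if (any(profile$ci_lower <= 0)) {
    abort(paste(
      "ci_ratio is undefined when a lower confidence bound is <= 0;",
      "shift-parameterize the evolutionary parameter to positive values first."
    ))
  }
  tibble::tibble(stage = profile$stage, ci_ratio = profile$ci_upper / profile$ci_lower)
}
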