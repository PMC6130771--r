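#' Early-minus-middle index contrast
#'
#' The test statistic of the hourglass-versus-early-conservation contrast:
#' the mean index over early stages minus the mean over middle (phylotypic)
#' stages. Pre-MZT stages are excluded from both means because their
#' transcriptome is dominated by maternal transcripts, and late stages are
#' not part of the contrast.
#'
#' @param tei A tibble with columns `stage` and `tei` (as returned by
#'   [compute_tei()] or [tei_profile()]).
#' @param timeline A [stage_timeline] covering those stages.
#' @return A single number, `mean(early) - mean(middle)`.
#' @export
delta_em <- function(tei, timeline) {
  stop_if_not_df(tei, "tei")
  if (!all(c("stage", "tei") %in% names(tei))) {
    abort("`tei` must have columns `stage` and `tei`.")
  }
  missing <- setdiff(tei$stage, timeline$stage)
  if (length(missing)) {
    abort(sprintf("Stage(s) absent from timeline: %s", paste(missing, collapse = ", ")))
  }
  period <- as.character(timeline$period)[match(tei$stage, timeline$stage)]
  for (need in c("early", "middle")) {
    if (!need %in% period) {
      abort(sprintf("No '%s' stage among the index's stages.", need))
    }
  }
  mean(tei$tei[period == "early"]) - mean(tei$tei[period == "middle"])
}

#' Permutation test of the hourglass versus early-conservation model
#'
#' Tests whether the transcriptome index in middle development differs from
#' early development in the direction predicted by the hourglass model,
#' against a null in which the evolutionary parameter is decoupled from
#' expression timing. The observed statistic is [delta_em()]; the null is
#' built by shuffling parameter values across genes (expression fixed)
#' `n_perm` times and recomputing the statistic. Two one-sided p-values are
#' returned: `p_normal`, from a normal approximation to the permutation
#' null (the probability that a randomly sampled statistic is at least as
#' extreme as the observed one, in the tested direction), and
#' `p_empirical`, the add-one-corrected permutation p-value.
#'
#' For parameters where conservation means *low* values expressed in the
#' phylotypic period (omega0, phylostratum, paralog count) the hourglass
#' prediction is `direction = "middle_lower"` (observed statistic large and
#' positive); for connectivity, where conserved stages express *more*
#' connected genes, the prediction flips to `direction = "middle_higher"`.
#'
#' @inheritParams compute_tei
#' @param timeline A [stage_timeline] matching the expression table's stages.
#' @param direction `"middle_lower"` or `"middle_higher"`; defaults to
#'   `"middle_higher"` for `param = "connectivity"`, `"middle_lower"`
#'   otherwise.
#' @param n_perm Number of permutations (default 10,000; fewer than 100
#'   raises a warning).
#' @param seed Optional integer seed; the session RNG state is untouched.
#' @return An object of class `devo_perm`: a list with `delta_observed`,
#'   `null_mean`, `null_sd`, `p_normal`, `p_empirical`, `direction`,
#'   `n_perm`, `seed`, `degenerate`, `param`, `n_genes`, and the vector of
#'   permuted statistics `null_deltas`. `degenerate` is `TRUE` (with both
#'   p-values 1) when the permutation null has zero spread, e.g. a constant
#'   parameter.
#' @export
permutation_test <- function(x, annotation, param, timeline,
                             direction = NULL, n_perm = 10000, seed = NULL) {
  if (is.null(direction)) {
    direction <- if (identical(param, "connectivity")) "middle_higher" else "middle_lower"
  }
  if (!direction %in% c("middle_lower", "middle_higher")) {
    abort("`direction` must be 'middle_lower' or 'middle_higher'.")
  }
  if (!is.numeric(n_perm) || n_perm < 1) {
    abort("`n_perm` must be a positive integer.")
  }
  if (n_perm < 100) {
    warn("Fewer than 100 permutations gives a very coarse null; interpret p-values with care.")
  }
  n_perm <- as.integer(n_perm)
  check_timeline_matches(x, timeline)
  al <- align_param(x, annotation, param)
  period <- as.character(timeline$period)

  # Per-gene contribution to delta_em: delta = sum_g E_g * a_g with
  # a_g = mean over early stages of the gene's weight share minus the same
  # mean over middle stages. Shuffling E against fixed a is equivalent to
  # recomputing the whole index on each permutation, but linear-time.
  share <- sweep(al$W, 2L, colSums(al$W), "/")
  a <- rowMeans(share[, period == "early", drop = FALSE]) -
    rowMeans(share[, period == "middle", drop = FALSE])
  delta_obs <- sum(al$E * a)

  null_deltas <- local_seed(
    derive_seed(seed, "permutation") %||% NULL,
    vapply(seq_len(n_perm), function(i) sum(al$E[sample.int(length(a))] * a), numeric(1L))
  )
  null_mean <- mean(null_deltas)
  null_sd <- stats::sd(null_deltas)
  degenerate <- !is.na(null_sd) && null_sd == 0

  if (degenerate) {
    p_normal <- 1
    p_empirical <- 1
  } else {
    z <- (delta_obs - null_mean) / null_sd
    p_normal <- if (direction == "middle_lower") pnorm(z, lower.tail = FALSE) else pnorm(z)
    extreme <- if (direction == "middle_lower") {
      sum(null_deltas >= delta_obs)
    } else {
      sum(null_deltas <= delta_obs)
    }
    p_empirical <- (1 + extreme) / (n_perm + 1)
  }

  structure(
    list(
      delta_observed = delta_obs, null_mean = null_mean, null_sd = null_sd,
      p_normal = p_normal, p_empirical = p_empirical,
      direction = direction, n_perm = n_perm, seed = seed,
      degenerate = degenerate, param = param, n_genes = nrow(al$W),
      null_deltas = null_deltas
    ),
    class = "devo_perm"
  )
}

#' @export
print.devo_perm <- function(x, ...) {
  cat(sprintf(
    "Early-vs-middle permutation test (%s, direction: %s)\n", x$param, x$direction
  ))
  cat(sprintf("  genes: %d, permutations: %d\n", x$n_genes, x$n_perm))
  cat(sprintf(
    "  delta (early - middle): %.6g  [null mean %.3g, sd %.3g]\n",
    x$delta_observed, x$null_mean, x$null_sd
  ))
  if (x$degenerate) {
    cat("  degenerate null (zero spread); p = 1\n")
  } else {
    cat(sprintf("  p (normal approx): %.4g, p (empirical): %.4g\n", x$p_normal, x$p_empirical))
  }
  invisible(x)
}
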