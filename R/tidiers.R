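#' Tidiers for devindex result objects
#'
#' `tidy()` returns the per-stage (or per-gene) table of a result as a plain
#' tibble; `glance()` returns a one-row summary of the fit-level quantities.
#'
#' @param x A `tei_profile`, `devo_perm`, `pleiotropy_profile`,
#'   `retro_trend`, or `conn_dup` object.
#' @param ... Unused, for generic consistency.
#' @return A tibble.
#' @name devindex_tidiers
NULL

#' @rdname devindex_tidiers
#' @export
tidy.tei_profile <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$ci_ratio <- ifelse(out$ci_lower > 0, out$ci_upper / out$ci_lower, NA_real_)
  out
}

#' @rdname devindex_tidiers
#' @export
glance.tei_profile <- function(x, ...) {
  tibble::tibble(
    param = attr(x, "param", exact = TRUE),
    n_stages = nrow(x),
    n_genes = x$n_genes[1L],
    n_boot = attr(x, "n_boot", exact = TRUE),
    level = attr(x, "level", exact = TRUE)
  )
}

#' @rdname devindex_tidiers
#' @export
tidy.devo_perm <- function(x, ...) {
  tibble::tibble(
    param = x$param,
    delta_observed = x$delta_observed,
    null_mean = x$null_mean,
    null_sd = x$null_sd,
    p_normal = x$p_normal,
    p_empirical = x$p_empirical,
    direction = x$direction,
    degenerate = x$degenerate
  )
}

#' @rdname devindex_tidiers
#' @export
glance.devo_perm <- function(x, ...) {
  tibble::tibble(
    param = x$param, n_genes = x$n_genes, n_perm = x$n_perm,
    p_normal = x$p_normal, p_empirical = x$p_empirical
  )
}

#' @rdname devindex_tidiers
#' @export
tidy.pleiotropy_profile <- function(x, ...) tibble::as_tibble(x)

#' @rdname devindex_tidiers
#' @export
glance.pleiotropy_profile <- function(x, ...) {
  tibble::tibble(
    chi2_statistic = attr(x, "chi2_statistic", exact = TRUE),
    df = attr(x, "df", exact = TRUE),
    p_value = attr(x, "p_value", exact = TRUE)
  )
}

#' @rdname devindex_tidiers
#' @export
tidy.retro_trend <- function(x, ...) tibble::as_tibble(x)

#' @rdname devindex_tidiers
#' @export
glance.retro_trend <- function(x, ...) {
  tibble::tibble(
    rho = attr(x, "rho", exact = TRUE),
    p_value = attr(x, "p_value", exact = TRUE),
    n_genes = attr(x, "n_genes", exact = TRUE)
  )
}

#' @rdname devindex_tidiers
#' @export
tidy.conn_dup <- function(x, ...) x$trend

#' @rdname devindex_tidiers
#' @export
glance.conn_dup <- function(x, ...) {
  tibble::tibble(
    rho = x$rho, p_value = x$p_value,
    undefined = x$undefined, n_genes = x$n_genes
  )
}
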