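#' Tau tissue-specificity index and testis-specific genes
#'
#' Tau for a gene with expression \eqn{x_1, \dots, x_n} over \eqn{n} tissues
#' is \deqn{\tau = \sum_i (1 - \hat x_i) / (n - 1), \quad
#' \hat x_i = x_i / \max_j x_j,} ranging from 0 (uniform expression) to 1
#' (expression confined to a single tissue). Negative (log-scale) values are
#' floored at 0 before computing, and genes not expressed in any tissue
#' (all-zero after flooring) are removed. A gene is testis specific when its
#' highest expression is in the designated testis tissue and
#' `tau >= specificity_cutoff` (0.8 by default).
#'
#' @param panel A [tissue_panel].
#' @param specificity_cutoff Minimum Tau for the testis-specific flag.
#' @return A tibble with columns `gene_id`, `tau`, `top_tissue`,
#'   `is_testis_specific`. Ties for the top tissue are broken by column
#'   order.
#'
#' @examples
#' panel <- tissue_panel(tibble::tibble(
#'   gene_id = c("a", "b"),
#'   brain = c(8, 0), testis = c(8, 5), liver = c(8, 0)
#' ))
#' compute_tau(panel)
#' @export
compute_tau <- function(panel, specificity_cutoff = 0.8) {
  if (!inherits(panel, "tissue_panel")) {
    abort("`panel` must be a tissue_panel (see tissue_panel()).")
  }
  testis <- attr(panel, "testis", exact = TRUE)
  m <- as.matrix(panel[-1L])
  m[m < 0] <- 0
  mx <- apply(m, 1L, max)
  keep <- mx > 0
  m <- m[keep, , drop = FALSE]
  mx <- mx[keep]
  n <- ncol(m)
  xhat <- m / mx
  tau <- rowSums(1 - xhat) / (n - 1)
  top <- colnames(m)[apply(m, 1L, which.max)]
  tibble::tibble(
    gene_id = panel$gene_id[keep],
    tau = tau,
    top_tissue = top,
    is_testis_specific = top == testis & tau >= specificity_cutoff
  )
}
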