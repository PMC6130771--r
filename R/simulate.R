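# Calibrate the latent Gaussian-copula correlation so that the *realized*
# Spearman correlation of the two discrete margins hits `target`. Count
# margins tie heavily at small values, which attenuates rank correlations;
# a fixed-seed Monte Carlo curve inverted with uniroot absorbs that.
the_calibration_cache <- new.env(parent = emptyenv())

calibrate_latent_rho <- function(target, qfun1, qfun2, n = 20000L) {
  if (target == 0) {
    return(0)
  }
  key <- sprintf("%.6f", target)
  if (!is.null(the_calibration_cache[[key]])) {
    return(the_calibration_cache[[key]])
  }
  realized <- function(r) {
    local_seed(76543L, {
      z1 <- rnorm(n)
      z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n)
      cor(qfun1(pnorm(z1)), qfun2(pnorm(z2)), method = "spearman")
    }) - target
  }
  lo <- max(-0.999, target * 1.6 - 0.2)
  if (realized(lo) > 0) {
    abort(sprintf("Target rank correlation %.2f is infeasible for these margins.", target))
  }
  root <- stats::uniroot(realized, lower = lo, upper = 0, tol = 1e-3)$root
  the_calibration_cache[[key]] <- root
  root
}

#' Simulate a developmental transcriptome with coupled evolutionary parameters
#'
#' Generates a gene-by-stage expression matrix, a stage timeline, a per-gene
#' evolutionary annotation, and a tissue panel, with controlled coupling
#' between each gene's expression timing and its evolutionary parameters.
#' Each gene is assigned a peak period; its expected expression follows a
#' Gaussian bump (sd 1.5 stages) over the stage axis around a peak stage in
#' that period, on top of a lognormal baseline, except pre-MZT (maternal)
#' genes which start high and decay exponentially. Counts are drawn from a
#' negative binomial around that expectation (`noise = "negbin"`), or
#' log-scale intensities with additive Gaussian noise (`"lognormal"`).
#'
#' Under `pattern = "hourglass"` the conserved period is `middle`; under
#' `"early_conservation"` it is `early`; genes peaking in the conserved
#' period have omega0 and phylostratum shifted down (stronger purifying
#' selection, older), paralog count shifted down, and connectivity shifted
#' up, each by `effect_size` latent standard deviations. Under `"null"` all
#' parameters are drawn independently of expression timing. Connectivity
#' and paralog count are coupled through a Gaussian copula calibrated so
#' their realized Spearman correlation matches `conn_paralog_rho`.
#' Retrogene flags are drawn with the odds for late-peaking genes multiplied
#' by `retro_late_enrichment`. A fraction `testis_frac` of genes is made
#' testis-dominant with Tau >= 0.8 by construction.
#'
#' @param n_genes Number of genes.
#' @param stages Named integer vector of stages per period,
#'   `c(preMZT =, early =, middle =, late =)`; `preMZT` may be 0, the rest
#'   must be >= 1.
#' @param pattern `"hourglass"`, `"early_conservation"`, or `"null"`.
#' @param effect_size Parameter shift for conserved-period genes, in latent
#'   standard deviations (>= 0; ignored for `"null"`).
#' @param noise `"negbin"` (counts, dispersion `dispersion`) or
#'   `"lognormal"` (log2 intensities, sd `sigma_log`).
#' @param dispersion Negative binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param sigma_log Gaussian sd of log2 intensities for `"lognormal"`.
#' @param n_strata Number of phylostrata (1 = oldest).
#' @param conn_paralog_rho Target Spearman correlation between connectivity
#'   and paralog count, in `[-1, 0]`.
#' @param retro_rate Baseline retrogene probability.
#' @param retro_late_enrichment Odds multiplier (>= 1) for retrogene flags
#'   among late-peaking genes.
#' @param n_tissues Number of tissues in the panel (last one is testis).
#' @param testis_frac Fraction of genes made testis-specific by
#'   construction.
#' @param seed Optional integer seed; fixed seed gives bit-identical output.
#' @return A list with elements `expression` ([devo_expr], scale
#'   `raw_count` or `log_transformed`), `timeline` ([stage_timeline]),
#'   `annotation` (tibble), `tissue` ([tissue_panel]), and `truth` (tibble
#'   with each gene's simulated peak period, for validation).
#' @export
simulate_devo_data <- function(n_genes = 2000,
                               stages = c(preMZT = 1, early = 3, middle = 2, late = 4),
                               pattern = c("hourglass", "early_conservation", "null"),
                               effect_size = 1,
                               noise = c("negbin", "lognormal"),
                               dispersion = 0.2,
                               sigma_log = 0.5,
                               n_strata = 10,
                               conn_paralog_rho = -0.3,
                               retro_rate = 0.02,
                               retro_late_enrichment = 3,
                               n_tissues = 6,
                               testis_frac = 0.1,
                               seed = NULL) {
  pattern <- match.arg(pattern)
  noise <- match.arg(noise)
  stages <- stages[match(period_levels(), names(stages))]
  names(stages) <- period_levels()
  stages[is.na(stages)] <- 0L
  if (stages[["preMZT"]] < 0 || any(stages[c("early", "middle", "late")] < 1)) {
    abort("`stages` needs >= 1 early, middle and late stage (preMZT may be 0).")
  }
  if (!is.numeric(effect_size) || effect_size < 0) {
    abort("`effect_size` must be >= 0.")
  }
  if (conn_paralog_rho < -1 || conn_paralog_rho > 0) {
    abort("`conn_paralog_rho` must lie in [-1, 0].")
  }
  if (retro_late_enrichment < 1) {
    abort("`retro_late_enrichment` must be >= 1.")
  }

  S <- sum(stages)
  period <- rep(period_levels(), times = stages)
  timeline <- stage_timeline(sprintf("s%02d", seq_len(S)), period)
  conserved <- switch(pattern,
    hourglass = "middle", early_conservation = "early", null = NA_character_
  )

  conn_q <- function(u) stats::qnbinom(u, mu = 15, size = 2)
  para_q <- function(u) stats::qnbinom(u, mu = 2.5, size = 1.2)
  latent_r <- calibrate_latent_rho(conn_paralog_rho, conn_q, para_q)

  local_seed(derive_seed(seed, "simulation"), {
    gene_id <- sprintf("g%05d", seq_len(n_genes))
    peak_period <- sample(period_levels(), n_genes, replace = TRUE, prob = stages / S)
    is_cons <- if (is.na(conserved)) rep(FALSE, n_genes) else peak_period == conserved
    eff <- ifelse(is_cons, effect_size, 0)

    # expected expression: lognormal baseline x stage profile (+ small floor
    # so most genes are detectable somewhere outside their peak)
    baseline <- rlnorm(n_genes, meanlog = log(60), sdlog = 1)
    stage_idx <- seq_len(S)
    peak_stage <- vapply(
      peak_period,
      function(p) sample(rep(which(period == p), 2L), 1L),
      numeric(1L)
    )
    prof <- matrix(0, n_genes, S)
    maternal <- peak_period == "preMZT"
    if (any(maternal)) {
      prof[maternal, ] <- exp(-0.8 * outer(rep(1, sum(maternal)), stage_idx - 1))
    }
    if (any(!maternal)) {
      prof[!maternal, ] <- exp(-outer(peak_stage[!maternal], stage_idx, "-")^2 / (2 * 1.5^2))
    }
    mu <- baseline * (0.05 + prof)

    if (noise == "negbin") {
      vals <- matrix(
        rnbinom(n_genes * S, mu = as.vector(mu), size = 1 / dispersion),
        n_genes, S
      )
      scale <- "raw_count"
    } else {
      vals <- log2(mu + 1) + matrix(rnorm(n_genes * S, sd = sigma_log), n_genes, S)
      scale <- "log_transformed"
    }
    colnames(vals) <- timeline$stage
    expression <- expr_from_matrix(gene_id, vals, scale)

    # evolutionary parameters, shifted for conserved-period genes
    omega0 <- rlnorm(n_genes, meanlog = log(0.12) - eff * 0.5, sdlog = 0.5)
    ps_latent <- rnorm(n_genes, mean = -eff)
    phylostratum <- pmin(n_strata, pmax(1L, ceiling(pnorm(ps_latent) * n_strata)))
    z1 <- rnorm(n_genes)
    z2 <- latent_r * z1 + sqrt(1 - latent_r^2) * rnorm(n_genes)
    connectivity <- conn_q(pnorm(z1 + eff))
    paralog_count <- para_q(pnorm(z2 - eff))
    retro_p <- stats::plogis(
      stats::qlogis(retro_rate) +
        ifelse(peak_period == "late", log(retro_late_enrichment), 0)
    )
    is_retrogene <- runif(n_genes) < retro_p

    annotation <- tibble::tibble(
      gene_id = gene_id,
      omega0 = omega0,
      phylostratum = as.integer(phylostratum),
      paralog_count = as.integer(paralog_count),
      connectivity = as.integer(connectivity),
      is_retrogene = is_retrogene
    )

    # tissue panel on a log2-like scale; testis-specific genes have all
    # non-testis tissues below 15% of the testis value, forcing Tau >= 0.85
    tissues <- c(sprintf("t%02d", seq_len(n_tissues - 1L)), "testis")
    tis <- matrix(rnorm(n_genes * n_tissues, mean = 5, sd = 0.7), n_genes, n_tissues)
    tis <- pmax(tis, 0)
    ts_genes <- runif(n_genes) < testis_frac
    if (any(ts_genes)) {
      k <- sum(ts_genes)
      tv <- runif(k, 6, 10)
      tis[ts_genes, ] <- tv * matrix(runif(k * n_tissues, 0, 0.15), k, n_tissues)
      tis[ts_genes, n_tissues] <- tv
    }
    colnames(tis) <- tissues
    tissue <- tissue_panel(
      tibble::add_column(
        tibble::as_tibble(as.data.frame(tis, optional = TRUE)),
        gene_id = gene_id, .before = 1L
      ),
      testis = "testis"
    )

    list(
      expression = expression,
      timeline = timeline,
      annotation = annotation,
      tissue = tissue,
      truth = tibble::tibble(gene_id = gene_id, peak_period = peak_period)
    )
  })
}
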