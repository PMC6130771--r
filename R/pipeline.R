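#' Run the full developmental-constraint analysis pipeline
#'
#' Orchestrates preprocessing (normalization, low-expression filtering,
#' transformation), transcriptome index profiles with bootstrap confidence
#' intervals, early-versus-middle permutation tests per evolutionary
#' parameter, temporal-pleiotropy profiling, and — when inputs allow — Tau
#' tissue specificity, the retrogene trend (excluding testis-specific
#' genes when a tissue panel is present), and the connectivity-duplicability
#' analysis. Per-stage tables are written as TSV, test summaries as JSON,
#' and a manifest records the package version, seed, and configuration.
#'
#' All randomness flows from one root `seed`, split into named substreams
#' per component and parameter, so e.g. bootstrap intervals do not change
#' when the permutation tests are reconfigured.
#'
#' @param config A YAML file path or a named list with entries:
#'   `expression`, `expression_scale`, `annotation`, `timeline` (paths or
#'   in-memory objects), optional `tissue`; `transform` (`"log2"`,
#'   `"sqrt"`, `"none"`), `low_mean_threshold`, `call` (list with `rule`
#'   plus `threshold` or `q`), `params` (annotation columns to index),
#'   `directions` (named overrides), `n_boot`, `n_perm`,
#'   `breadth_threshold`, `seed`.
#' @param out_dir Output directory; overrides `config$out_dir`. When `NULL`
#'   and absent from the config, nothing is written and only the result
#'   bundle is returned.
#' @param quiet Suppress per-stage log lines?
#' @return (Invisibly) a list with elements `expression` (the preprocessed,
#'   transformed table), `profiles`, `tests`, `pleiotropy`, `wilcoxon`,
#'   `tau`, `retro`, `conn_dup`, and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    abort("`config` must be a YAML path or a named list.")
  }
  say <- function(...) if (!quiet) message(sprintf(...))
  out_dir <- out_dir %||% config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  seed <- config$seed
  transform <- config$transform %||% "log2"
  if (transform == "none") transform <- "identity"
  threshold <- config$low_mean_threshold %||% 1
  call_cfg <- config$call %||% list(rule = "threshold", threshold = 1)
  params <- unlist(config$params %||% "omega0")
  n_boot <- config$n_boot %||% 10000
  n_perm <- config$n_perm %||% 10000
  breadth <- config$breadth_threshold %||% 0.5

  load_input <- function(x, reader, ...) {
    if (is.character(x) && length(x) == 1L) reader(x, ...) else x
  }
  expression <- load_input(
    config$expression, read_expression,
    scale = config$expression_scale %||% "raw_count"
  )
  timeline <- load_input(config$timeline, read_timeline)
  annotation <- validate_annotation(load_input(config$annotation, read_annotation))
  tissue <- if (!is.null(config$tissue)) {
    load_input(config$tissue, read_tissue_panel, testis = config$testis %||% "testis")
  }
  missing_params <- setdiff(params, names(annotation))
  if (length(missing_params)) {
    abort(sprintf(
      "Requested parameter column(s) absent from annotation: %s",
      paste(missing_params, collapse = ", ")
    ))
  }
  say("inputs: %d genes x %d stages", nrow(expression), length(expr_stages(expression)))

  # preprocessing
  if (expr_scale(expression) == "raw_count") {
    expression <- normalize_cpm(expression)
    say("normalize_cpm: columns rescaled to 1e6")
  }
  if (expr_scale(expression) != "log_transformed") {
    n0 <- nrow(expression)
    expression <- filter_low_mean(expression, threshold)
    say("filter_low_mean(%.3g): %d -> %d genes", threshold, n0, nrow(expression))
    linear <- expression
  } else {
    linear <- NULL
    if (transform != "identity") {
      say("input already log transformed; transform forced to identity")
      transform <- "identity"
    }
  }
  check_timeline_matches(expression, timeline)
  weights <- transform_expression(expression, transform)

  # indexes + permutation tests per parameter
  directions <- config$directions %||% list()
  profiles <- list()
  tests <- list()
  for (i in seq_along(params)) {
    p <- params[[i]]
    dir_p <- directions[[p]] %||%
      (if (identical(p, "connectivity")) "middle_higher" else "middle_lower")
    prof <- tei_profile(
      weights, annotation, p,
      n_boot = n_boot,
      seed = if (is.null(seed)) NULL else derive_seed(seed, "bootstrap") + i
    )
    test <- permutation_test(
      weights, annotation, p, timeline,
      direction = dir_p, n_perm = n_perm,
      seed = if (is.null(seed)) NULL else derive_seed(seed, "permutation") + i
    )
    say(
      "%s: %d genes, delta_em = %.4g, p_normal = %.3g",
      p, test$n_genes, test$delta_observed, test$p_normal
    )
    profiles[[p]] <- prof
    tests[[p]] <- test
  }

  # temporal pleiotropy (needs a linear-scale matrix for threshold calls)
  pleio <- NULL
  wilcox <- NULL
  call_source <- if (identical(call_cfg$rule, "threshold")) linear else weights
  if (!is.null(call_source)) {
    calls <- if (identical(call_cfg$rule, "threshold")) {
      call_expressed(call_source, "threshold", threshold = call_cfg$threshold %||% 1)
    } else {
      call_expressed(call_source, "rank_top", q = call_cfg$q %||% 0.7)
    }
    flags <- pleiotropy_flags(calls, breadth_threshold = breadth)
    pleio <- pleiotropy_profile(calls, flags)
    say(
      "pleiotropy: %d/%d genes flagged, chi2 = %.3g (p = %.3g)",
      sum(flags$pleiotropic), nrow(flags),
      attr(pleio, "chi2_statistic", exact = TRUE), attr(pleio, "p_value", exact = TRUE)
    )
    if ("omega0" %in% names(annotation)) {
      wilcox <- compare_param_by_group(annotation, "omega0", flags)
    }
  }

  # tissue specificity and retrogene trend
  tau_tbl <- if (!is.null(tissue)) compute_tau(tissue)
  retro <- NULL
  if ("is_retrogene" %in% names(annotation) && any(annotation$is_retrogene, na.rm = TRUE)) {
    exclude <- if (!is.null(tau_tbl)) tau_tbl$gene_id[tau_tbl$is_testis_specific]
    retro <- retrogene_trend(expression, annotation, exclude = exclude)
    say(
      "retrogene trend: %d genes, rho = %.3f",
      attr(retro, "n_genes", exact = TRUE), attr(retro, "rho", exact = TRUE)
    )
  }
  cd <- if (all(c("connectivity", "paralog_count") %in% names(annotation)) &&
    sum(!is.na(annotation$connectivity) & !is.na(annotation$paralog_count)) >= 10) {
    connectivity_duplicability(annotation)
  }

  manifest <- list(
    package = "devindex",
    version = as.character(utils::packageVersion("devindex")),
    seed = seed,
    transform = transform,
    n_boot = n_boot,
    n_perm = n_perm,
    params = as.list(params),
    n_genes_input = nrow(expression),
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")])
  )

  bundle <- list(
    expression = weights, profiles = profiles, tests = tests,
    pleiotropy = pleio, wilcoxon = wilcox, tau = tau_tbl,
    retro = retro, conn_dup = cd, manifest = manifest
  )

  if (!is.null(out_dir)) {
    for (p in names(profiles)) {
      readr::write_tsv(tidy(profiles[[p]]), file.path(out_dir, sprintf("tei_%s.tsv", p)))
      jsonlite::write_json(
        c(as.list(tidy(tests[[p]])), list(n_perm = tests[[p]]$n_perm, seed = seed)),
        file.path(out_dir, sprintf("perm_%s.json", p)),
        auto_unbox = TRUE, digits = NA
      )
    }
    if (!is.null(pleio)) {
      readr::write_tsv(tidy(pleio), file.path(out_dir, "pleiotropy.tsv"))
      jsonlite::write_json(
        as.list(glance(pleio)),
        file.path(out_dir, "pleiotropy_test.json"), auto_unbox = TRUE, digits = NA
      )
    }
    if (!is.null(wilcox)) {
      jsonlite::write_json(
        as.list(wilcox),
        file.path(out_dir, "wilcoxon_omega0.json"), auto_unbox = TRUE, digits = NA
      )
    }
    if (!is.null(tau_tbl)) readr::write_tsv(tau_tbl, file.path(out_dir, "tau.tsv"))
    if (!is.null(retro)) {
      readr::write_tsv(tidy(retro), file.path(out_dir, "retrogene_trend.tsv"))
      jsonlite::write_json(
        as.list(glance(retro)),
        file.path(out_dir, "retrogene_trend.json"), auto_unbox = TRUE, digits = NA
      )
    }
    if (!is.null(cd)) {
      readr::write_tsv(cd$trend, file.path(out_dir, "connectivity_trend.tsv"))
      jsonlite::write_json(
        as.list(glance(cd)),
        file.path(out_dir, "connectivity_duplicability.json"), auto_unbox = TRUE, digits = NA
      )
    }
    jsonlite::write_json(
      manifest, file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(bundle)
}
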