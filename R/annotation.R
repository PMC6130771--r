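#' Read a per-gene evolutionary annotation table
#'
#' The annotation table carries one row per gene and the evolutionary
#' parameters used to weight transcriptome indexes: `omega0` (dN/dS of the
#' codon subset under purifying selection in a branch-site model; lower means
#' stronger purifying selection), `phylostratum` (discrete phyletic-age
#' class, 1 = oldest), `paralog_count`, `connectivity` (number of
#' protein-protein interaction partners), and `is_retrogene`. Any field may
#' be missing for a gene (empty cell); each downstream index uses only genes
#' with that field present.
#'
#' @param path Path to a TSV with columns `gene_id, omega0, phylostratum,
#'   paralog_count, connectivity, is_retrogene` (all but `gene_id` optional).
#' @return A tibble with one row per gene.
#' @export
read_annotation <- function(path) {
  col_spec <- readr::cols(
    gene_id = readr::col_character(),
    omega0 = readr::col_double(),
    phylostratum = readr::col_integer(),
    paralog_count = readr::col_integer(),
    connectivity = readr::col_integer(),
    is_retrogene = readr::col_logical(),
    .default = readr::col_guess()
  )
  ann <- readr::read_tsv(path, col_types = col_spec)
  validate_annotation(ann)
}

validate_annotation <- function(ann) {
  stop_if_not_df(ann, "annotation")
  if (!"gene_id" %in% names(ann)) {
    abort("Annotation table must have a `gene_id` column.")
  }
  ann <- tibble::as_tibble(ann)
  ann$gene_id <- as.character(ann$gene_id)
  if (anyDuplicated(ann$gene_id)) {
    abort("Annotation table has duplicated gene ids; resolve to one row per gene first.")
  }
  if ("omega0" %in% names(ann) && any(ann$omega0 < 0, na.rm = TRUE)) {
    abort("`omega0` must be nonnegative.")
  }
  if ("phylostratum" %in% names(ann) && any(ann$phylostratum < 1, na.rm = TRUE)) {
    abort("`phylostratum` must be >= 1 (1 = oldest).")
  }
  for (col in c("paralog_count", "connectivity")) {
    if (col %in% names(ann) && any(ann[[col]] < 0, na.rm = TRUE)) {
      abort(sprintf("`%s` must be nonnegative.", col))
    }
  }
  ann
}

#' @rdname read_annotation
#' @param ann Annotation tibble as returned by [read_annotation()].
#' @export
write_annotation <- function(ann, path) {
  readr::write_tsv(tibble::as_tibble(ann), path)
  invisible(path)
}

#' Resolve duplicate branch values of omega0 to one value per gene
#'
#' Branch-site models can yield two omega0 values for a gene on the focal
#' branch when a duplication occurred there: one for the branch preceding the
#' duplication and one for the branch following it. The value of the branch
#' following the duplication is kept and the preceding one discarded; genes
#' with a single (`unique`) branch keep that value. Genes with more than two
#' branch records (nested duplications) are not supported and raise an error.
#'
#' @param records Data frame with columns `gene_id`, `branch_relation`
#'   (one of `"pre_duplication"`, `"post_duplication"`, `"unique"`), and
#'   `omega0`.
#' @return A tibble with columns `gene_id` and `omega0`, one row per gene.
#'
#' @examples
#' resolve_omega0(tibble::tibble(
#'   gene_id = c("g1", "g1", "g2"),
#'   branch_relation = c("pre_duplication", "post_duplication", "unique"),
#'   omega0 = c(0.10, 0.05, 0.20)
#' ))
#' @export
resolve_omega0 <- function(records) {
  stop_if_not_df(records, "records")
  need <- c("gene_id", "branch_relation", "omega0")
  if (!all(need %in% names(records))) {
    abort(sprintf("`records` must have columns %s.", paste(need, collapse = ", ")))
  }
  ok <- c("pre_duplication", "post_duplication", "unique")
  bad <- setdiff(unique(records$branch_relation), ok)
  if (length(bad)) {
    abort(sprintf("Unknown branch_relation value(s): %s", paste(bad, collapse = ", ")))
  }
  records <- tibble::as_tibble(records)
  dup <- records |>
    dplyr::count(.data$gene_id, .data$branch_relation) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    abort(sprintf(
      "Gene(s) with repeated branch_relation: %s",
      paste(unique(dup$gene_id), collapse = ", ")
    ))
  }
  n_rec <- records |> dplyr::count(.data$gene_id)
  if (any(n_rec$n > 2L)) {
    abort("Genes with more than two branch records (nested duplications) are not supported.")
  }
  mixed <- records |>
    dplyr::filter(.data$branch_relation == "unique") |>
    dplyr::semi_join(
      dplyr::filter(records, .data$branch_relation != "unique"),
      by = "gene_id"
    )
  if (nrow(mixed)) {
    abort("A gene cannot mix a 'unique' branch with duplication branches.")
  }
  records |>
    dplyr::mutate(
      pref = dplyr::case_match(
        .data$branch_relation,
        "post_duplication" ~ 1L, "unique" ~ 1L, "pre_duplication" ~ 2L
      )
    ) |>
    dplyr::arrange(.data$gene_id, .data$pref) |>
    dplyr::distinct(.data$gene_id, .keep_all = TRUE) |>
    dplyr::select("gene_id", "omega0")
}

#' Read a gene-by-tissue expression panel
#'
#' Tissue panels are used for the Tau tissue-specificity index and for
#' flagging testis-specific genes. Values are expected on a log scale
#' (negative values are floored at 0 when Tau is computed).
#'
#' @param path Path to a TSV with header row of tissue names and first
#'   column gene ids.
#' @param testis Name of the tissue column to treat as testis.
#' @return A tibble of class `tissue_panel` with a `testis` attribute.
#' @export
read_tissue_panel <- function(path, testis = "testis") {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_double()
  ))
  names(raw)[1L] <- "gene_id"
  tissue_panel(raw, testis = testis)
}

#' @rdname read_tissue_panel
#' @param x Data frame with a `gene_id` first column and one numeric column
#'   per tissue.
#' @export
tissue_panel <- function(x, testis = "testis") {
  stop_if_not_df(x, "x")
  x <- tibble::as_tibble(x)
  names(x)[1L] <- "gene_id"
  x$gene_id <- as.character(x$gene_id)
  if (ncol(x) < 3L) {
    abort("A tissue panel needs at least two tissues.")
  }
  if (!testis %in% names(x)[-1L]) {
    abort(sprintf("Designated testis tissue '%s' not found among panel columns.", testis))
  }
  vals <- x[-1L]
  if (!all(vapply(vals, is.numeric, logical(1L))) || anyNA(vals) ||
    any(vapply(vals, function(v) any(!is.finite(v)), logical(1L)))) {
    abort("Tissue panel values must be finite numerics with no missing cells.")
  }
  if (anyDuplicated(x$gene_id)) {
    abort("Tissue panel has duplicated gene ids.")
  }
  structure(x, testis = testis, class = c("tissue_panel", class(tibble::tibble())))
}
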