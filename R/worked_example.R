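#' A small deterministic worked example
#'
#' A hand-checkable 12-gene, 6-stage dataset (one pre-MZT, two early, one
#' middle, two late stages) with maternal, early-, middle- and late-peaking
#' genes, two broadly expressed genes (including `g_const`, constant across
#' stages and tissues), and a 5-tissue panel containing a single-tissue gene
#' and a uniformly expressed gene. Expression is on the normalized linear
#' scale. The same tables are shipped as TSV/YAML fixtures under
#' `inst/extdata/worked_example/`, together with expected analysis values
#' frozen from an independent loop-based evaluation of the formulas.
#'
#' @return A list with `expression`, `timeline`, `annotation`, `tissue`.
#' @examples
#' ex <- worked_example()
#' compute_tei(transform_expression(ex$expression, "log2"), ex$annotation, "omega0")
#' @export
worked_example <- function() {
  stages <- c("pm1", "e1", "e2", "m1", "l1", "l2")
  vals <- matrix(
    c(
      16, 8, 4, 2, 1, 0, # g01 maternal, decaying
      8, 4, 2, 1, 0, 0, # g02 maternal, decaying
      2, 8, 16, 4, 2, 1, # g03 early peak
      1, 4, 8, 2, 1, 0, # g04 early peak
      0, 2, 4, 16, 4, 2, # g05 middle peak
      1, 2, 8, 16, 8, 2, # g06 middle peak
      0, 1, 2, 4, 16, 8, # g07 late peak (retrogene)
      0, 0, 1, 2, 8, 16, # g08 late peak (retrogene)
      1, 1, 2, 4, 8, 16, # g09 late peak (retrogene)
      4, 4, 4, 4, 4, 4, # g10 broad
      0.5, 0.5, 0.5, 0.5, 0.5, 0.5, # g11 broad, low (retrogene)
      3, 3, 3, 3, 3, 3 # g_const
    ),
    nrow = 12, byrow = TRUE
  )
  gene_id <- c(sprintf("g%02d", 1:11), "g_const")
  colnames(vals) <- stages
  expression <- expr_from_matrix(gene_id, vals, "normalized_linear")

  timeline <- stage_timeline(
    stages,
    c("preMZT", "early", "early", "middle", "late", "late")
  )

  annotation <- tibble::tibble(
    gene_id = gene_id,
    omega0 = c(0.10, 0.12, 0.08, 0.10, 0.04, 0.05, 0.20, 0.25, 0.18, 0.15, 0.30, 0.15),
    phylostratum = c(2L, 3L, 1L, 2L, 1L, 1L, 5L, 6L, 4L, 3L, 6L, 2L),
    paralog_count = c(1L, 2L, 0L, 1L, 0L, 1L, 4L, 6L, 3L, 2L, 5L, 1L),
    connectivity = c(10L, 8L, 20L, 15L, 30L, 25L, 5L, 3L, 6L, 12L, 2L, 9L),
    is_retrogene = c(
      FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
      TRUE, TRUE, TRUE, FALSE, TRUE, FALSE
    )
  )

  tis <- matrix(
    c(
      5, 4, 5, 6, 5, # g01 broad
      6, 5, 4, 5, 5, # g02 broad
      8, 2, 1, 1, 0, # g03 brain-dominant
      4, 4, 5, 4, 4, # g04 broad
      6, 6, 5, 5, 4, # g05 broad
      5, 5, 5, 6, 5, # g06 broad
      0, 0, 0, 0, 5, # g07 testis only -> Tau = 1
      1, 0, 0, 0, 8, # g08 testis-dominant
      2, 4, 8, 1, 1, # g09 muscle-dominant
      8, 8, 8, 8, 8, # g10 uniform -> Tau = 0
      0, 0, 0, 0, 6, # g11 testis only
      2, 4, 8, 2, 3 # g_const
    ),
    nrow = 12, byrow = TRUE
  )
  colnames(tis) <- c("brain", "gut", "muscle", "ovary", "testis")
  tissue <- tissue_panel(
    tibble::add_column(
      tibble::as_tibble(as.data.frame(tis, optional = TRUE)),
      gene_id = gene_id, .before = 1L
    ),
    testis = "testis"
  )

  list(
    expression = expression, timeline = timeline,
    annotation = annotation, tissue = tissue
  )
}

#' Write the worked example to a directory in interchange formats
#'
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_worked_example <- function(dir) {
  ex <- worked_example()
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression(ex$expression, file.path(dir, "expression.tsv"))
  write_timeline(ex$timeline, file.path(dir, "timeline.yaml"))
  write_annotation(ex$annotation, file.path(dir, "annotation.tsv"))
  readr::write_tsv(tibble::as_tibble(ex$tissue), file.path(dir, "tissues.tsv"))
  invisible(dir)
}
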