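#' Stage timelines
#'
#' A stage timeline orders the sampled developmental stages and assigns each
#' to one of four broad periods: `preMZT` (before the start of the
#' maternal-to-zygotic transition, when the transcriptome is dominated by
#' maternal transcripts), `early` (after the MZT and before the phylotypic
#' period), `middle` (the phylotypic period), and `late` (after it). Period
#' boundaries are species knowledge supplied by the user, not inferred from
#' expression.
#'
#' @param stage Character vector of ordered stage identifiers.
#' @param period Character vector, one of `"preMZT"`, `"early"`, `"middle"`,
#'   `"late"` per stage.
#'
#' @return A tibble of class `stage_timeline` with columns `stage` and
#'   `period`.
#'
#' @details Periods must form contiguous blocks in developmental order
#' (`preMZT` then `early` then `middle` then `late`); `preMZT` and `late`
#' blocks may be absent, but at least one `early` and one `middle` stage are
#' required so the early-versus-middle contrast is defined.
#'
#' @examples
#' stage_timeline(
#'   stage  = c("cleavage", "gastrula", "germband", "larva"),
#'   period = c("early", "early", "middle", "late")
#' )
#' @export
stage_timeline <- function(stage, period) {
  stage <- as.character(stage)
  period <- as.character(period)
  if (length(stage) != length(period)) {
    abort("`stage` and `period` must have the same length.")
  }
  if (anyDuplicated(stage)) {
    abort("Stage identifiers must be unique.")
  }
  bad <- setdiff(unique(period), period_levels())
  if (length(bad)) {
    abort(sprintf(
      "Unknown period label(s): %s (expected %s).",
      paste(bad, collapse = ", "), paste(period_levels(), collapse = ", ")
    ))
  }
  blocks <- rle(period)$values
  if (anyDuplicated(blocks)) {
    abort("Periods must form contiguous blocks (a period label reappears after another period).")
  }
  if (!identical(blocks, intersect(period_levels(), blocks))) {
    abort("Period blocks must appear in the order preMZT, early, middle, late.")
  }
  for (need in c("early", "middle")) {
    if (!need %in% period) {
      abort(sprintf("Timeline must contain at least one '%s' stage.", need))
    }
  }
  structure(
    tibble::tibble(stage = stage, period = factor(period, levels = period_levels())),
    class = c("stage_timeline", class(tibble::tibble()))
  )
}

#' Read a stage timeline from YAML or JSON
#'
#' The file must contain a top-level `stages` list whose entries have `id`
#' and `period` keys, in developmental order.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [stage_timeline].
#' @export
read_timeline <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$stages) || !length(cfg$stages)) {
    abort("Timeline file must have a non-empty top-level `stages` list.")
  }
  ids <- vapply(cfg$stages, function(s) as.character(s$id %||% NA_character_), character(1L))
  pds <- vapply(cfg$stages, function(s) as.character(s$period %||% NA_character_), character(1L))
  if (anyNA(ids) || anyNA(pds)) {
    abort("Every timeline stage needs both an `id` and a `period`.")
  }
  stage_timeline(ids, pds)
}

#' @rdname read_timeline
#' @param timeline A [stage_timeline].
#' @export
write_timeline <- function(timeline, path) {
  stages <- purrr::pmap(
    list(timeline$stage, as.character(timeline$period)),
    function(id, period) list(id = id, period = period)
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(stages = stages), path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(list(stages = stages), path)
  }
  invisible(path)
}

# check that a timeline covers exactly the stages of an expression table,
# in the same order
check_timeline_matches <- function(x, timeline) {
  if (!identical(expr_stages(x), timeline$stage)) {
    abort("Timeline stages must match the expression table's stage columns in order.")
  }
  invisible(TRUE)
}
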