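#' Write analysis tables and a JSON summary to disk
#'
#' Emits `partition_<basis>.csv`, `person_level_<basis>.csv`,
#' `subgroups_<basis>.csv` (when present) and
#' `contributors_<category>_<basis>.csv`, plus `summary.json` carrying every
#' partition twice: unrounded, and rounded to one decimal place half away
#' from zero (the convention of published tables; derived ratios such as
#' "UPF that is also HFSS" are computed from unrounded values and only then
#' rounded).
#'
#' @param analysis An [`overlap_analysis`][analyze_diet].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
render_partition_report <- function(analysis, dir) {
  stopifnot(inherits(analysis, "overlap_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()

  for (b in analysis$partitions$basis) {
    p <- file.path(dir, sprintf("partition_%s.csv", b))
    readr::write_csv(analysis$partitions[analysis$partitions$basis == b, ], p,
                     progress = FALSE)
    paths <- c(paths, p)
    p <- file.path(dir, sprintf("person_level_%s.csv", b))
    readr::write_csv(
      analysis$person_level[analysis$person_level$basis == b, ], p,
      progress = FALSE)
    paths <- c(paths, p)
    if (!is.null(analysis$subgroups)) {
      p <- file.path(dir, sprintf("subgroups_%s.csv", b))
      readr::write_csv(analysis$subgroups[analysis$subgroups$basis == b, ], p,
                       progress = FALSE)
      paths <- c(paths, p)
    }
    for (cl in category_levels()) {
      tab <- analysis$contributors[
        analysis$contributors$basis == b & analysis$contributors$category == cl, ]
      p <- file.path(dir, sprintf("contributors_%s_%s.csv", cl, b))
      readr::write_csv(tab, p, progress = FALSE)
      paths <- c(paths, p)
    }
  }

  num_cols <- setdiff(names(analysis$partitions), "basis")
  rounded <- analysis$partitions
  rounded[num_cols] <- lapply(rounded[num_cols], round_half_up, digits = 1)
  summary <- list(
    model = analysis$model,
    n_events = nrow(analysis$events),
    n_participants = length(unique(analysis$events$participant_id)),
    exclusions = analysis$exclusions,
    partitions = analysis$partitions,
    partitions_rounded = rounded
  )
  p <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  paths <- c(paths, p)
  invisible(paths)
}
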