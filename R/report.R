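#' Assemble a pipeline summary report
#'
#' Collates per-stage reports into one summary: per-stage monitor
#' extrema and seeds, plus a file manifest with md5 content hashes so a
#' completed run is exactly identifiable.
#'
#' @param stage_reports list of stage report lists (possibly empty), as
#'   produced by [run_stage_sequence()] (`$reports`).
#' @param files character vector of output files to fingerprint.
#' @param path optional path; when given the summary is written as JSON.
#' @return the summary list, invisibly when written to `path`.
#' @export
assemble_report <- function(stage_reports = list(), files = character(0),
                            path = NULL) {
  stages <- lapply(stage_reports, function(r) {
    list(name = r$name, type = r$type, seeds = r$seeds,
         monitor_extrema = r$monitor_extrema,
         termination = r$termination, fired = r$fired,
         cycles = r$cycles, work = r$work)
  })
  fired <- vapply(stage_reports, function(r)
    !is.null(r$fired) && !is.na(r$fired), logical(1))
  manifest <- if (length(files)) {
    ex <- files[file.exists(files)]
    data.frame(file = ex, md5 = unname(tools::md5sum(ex)),
               stringsAsFactors = FALSE)
  } else data.frame(file = character(0), md5 = character(0))
  summary <- list(n_stages = length(stage_reports), stages = stages,
                  transition_success = any(fired),
                  manifest = manifest)
  if (!is.null(path)) {
    jsonlite::write_json(summary, path, auto_unbox = TRUE, pretty = TRUE,
                         dataframe = "rows")
    return(invisible(summary))
  }
  summary
}
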