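#' Write analysis summaries as JSON
#'
#' Serializes the tabular/structured analysis outputs (a [regime_fit],
#' the [interchain_stats()] list, or any list of them) to a JSON file, the
#' interchange format for downstream comparison scripts.
#'
#' @param x a `regime_fit`, the list returned by [interchain_stats()], or a
#'   named list combining such objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_analysis_json <- function(x, path) {
  strip <- function(o) {
    if (inherits(o, "regime_fit")) unclass(o)
    else if (is.data.frame(o)) o
    else if (is.list(o)) lapply(o, strip)
    else o
  }
  jsonlite::write_json(strip(x), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
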