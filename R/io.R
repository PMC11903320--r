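#' Write a decomposition report as JSON
#'
#' Serialises a `component_decomposition` (plus optional extras such as the
#' eigen gap) to a JSON file.
#'
#' @param dec A `component_decomposition`.
#' @param path Output file path.
#' @param extra Optional named list merged into the report.
#' @return `path`, invisibly.
#' @export
write_decomposition <- function(dec, path, extra = list()) {
  stopifnot(inherits(dec, "component_decomposition"))
  report <- c(
    list(
      feature = dec$feature,
      svm = dec$svm, dim = dec$dim, iim = dec$iim, total = dec$total,
      percentages = as.list(dec$percentages),
      irr_leak = dec$irr_leak
    ),
    extra
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a task configuration file
#'
#' Reads a YAML or JSON file of task-generator settings (seed, n_levels,
#' p_min, p_max, duration, total_rate, min_block_length, switch_window,
#' switch_threshold); missing entries fall back to the package defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list of settings.
#' @export
read_task_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  defaults <- list(
    seed = NULL, n_levels = 6, p_min = 0.2, p_max = 0.8,
    duration = 1.3, total_rate = 40, min_block_length = 30,
    switch_window = 20, switch_threshold = 0.8
  )
  utils::modifyList(defaults, cfg[!vapply(cfg, is.null, logical(1))])
}
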