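#' Read an analysis configuration from YAML or JSON
#'
#' Reads a flat key-value file (extension `.yaml`/`.yml` or `.json`) whose
#' keys are [polyomic_config()] arguments; unknown keys are rejected so
#' typos fail loudly.
#'
#' @param path config file path.
#' @return an `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "polyomics_error_missing_file")
  }
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(polyomic_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")),
          class = "polyomics_error_bad_config")
  }
  do.call(polyomic_config, vals)
}

#' Write a run manifest to JSON
#'
#' Serializes the reproducibility manifest of a [run_polyomic()] result —
#' configuration snapshot, seed, cohort sizes, split assignment, per-layer
#' bookkeeping and content hashes — so a run can be audited or compared
#' against a replay.
#'
#' @param run a `polyomic_run`.
#' @param path output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(run, path) {
  m <- run$manifest
  m$split <- as.data.frame(m$split)
  m$layer_summary <- as.data.frame(m$layer_summary)
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
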