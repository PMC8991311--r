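#' Read and write run configuration files
#'
#' Run configurations (simulation, membership, matching-policy and
#' workflow parameters) are plain nested lists stored as YAML (`.yaml` /
#' `.yml`) or JSON (`.json`), chosen by file extension.
#'
#' @param path file path.
#' @param config a named list.
#' @return `read_run_config()` returns the configuration list;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format: .", ext, " (use .yaml or .json)",
         call. = FALSE)
  }
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(config, path)
  } else if (ext == "json") {
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    stop("unsupported config format: .", ext, " (use .yaml or .json)",
         call. = FALSE)
  }
  invisible(path)
}
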