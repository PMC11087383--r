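#' Default run configuration
#'
#' All tunable parameters of the screening pipeline with their default
#' values, as a plain named list suitable for serialization.
#'
#' @return Named list with elements `qc` (see [qc_thresholds()]), `score`
#'   (see [module_score_params()]), `min_cells`, `k`, `clonotype_key`,
#'   `signature`.
#' @export
default_run_config <- function() {
  list(qc = unclass(qc_thresholds()),
       score = unclass(module_score_params()),
       min_cells = 3,
       k = 3,
       clonotype_key = "cdr3nt_vj",
       signature = activation_signature())
}

#' Read a run configuration file
#'
#' Accepts YAML (if the `yaml` package is installed) or JSON. Fields present
#' in the file override the defaults of [default_run_config()]; unknown
#' fields are an error, so typos do not silently fall back to defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A configuration list in the shape of [default_run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (requireNamespace("yaml", quietly = TRUE)) {
    yaml::read_yaml(path)
  } else {
    stop("reading YAML configs requires the 'yaml' package; ",
         "use JSON or install yaml")
  }
  base <- default_run_config()
  merge_level <- function(base, user, where) {
    unknown <- setdiff(names(user), names(base))
    if (length(unknown)) {
      stop("unknown config field(s) in ", where, ": ",
           paste(unknown, collapse = ", "))
    }
    for (nm in names(user)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(user[[nm]])) {
        merge_level(base[[nm]], user[[nm]], paste0(where, "$", nm))
      } else user[[nm]]
    }
    base
  }
  merge_level(base, user, "config")
}

#' Read a signature file
#'
#' Plain text, one gene symbol per line; blank lines and `#` comments are
#' ignored.
#'
#' @param path signature file path, or the string `"default"` for the
#'   embedded 10-gene activation signature.
#' @return Character vector of gene symbols.
#' @export
read_signature <- function(path = "default") {
  if (identical(path, "default")) return(activation_signature())
  if (!file.exists(path)) stop("signature file not found: ", path)
  lines <- trimws(readLines(path))
  genes <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(genes) == 0) stop("signature file contains no gene symbols")
  if (anyDuplicated(genes)) stop("duplicate gene symbols in signature file")
  genes
}

#' Write the QC report as JSON
#'
#' @param report report list from [filter_cells()] (or any report list).
#' @param path output JSON path.
#' @return Invisibly, `path`.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
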