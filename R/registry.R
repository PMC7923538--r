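# Editor-registry persistence: a flat tab-delimited key-value table that
# round-trips bit-exactly, so labs can maintain their own editor sets
# (windows, PAMs, constraints) without touching code.

REGISTRY_COLS <- c(
  "name", "class", "pam", "window_start", "window_end", "constraint",
  "efficiency_note"
)

#' Write an editor registry file
#'
#' @param editors Editor tibble (see [builtin_editors()]).
#' @param path Output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_editor_registry <- function(editors, path) {
  editors <- validate_editors(editors)
  readr::write_tsv(editors[, REGISTRY_COLS], path, na = "")
  invisible(path)
}

#' Read an editor registry file
#'
#' Reads a tab-delimited registry written by [write_editor_registry()] (or
#' edited by hand). Malformed entries are rejected with the offending field
#' named.
#'
#' @param path Registry file path.
#' @return A validated editor tibble.
#' @export
read_editor_registry <- function(path) {
  ed <- readr::read_tsv(path,
    col_types = readr::cols(
      name = readr::col_character(),
      class = readr::col_character(),
      pam = readr::col_character(),
      window_start = readr::col_integer(),
      window_end = readr::col_integer(),
      constraint = readr::col_character(),
      efficiency_note = readr::col_character()
    ),
    na = "", progress = FALSE
  )
  validate_editors(ed)
}
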