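# Shared condition classes and small IO helpers.
#
# Two error families are distinguished so callers (and the command-line
# wrapper) can map them to exit codes: schema/parse problems in input files
# versus domain errors (operations applied to invalid values).

stop_schema <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("epgdb_schema_error", "error", "condition")))
}

stop_domain <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("epgdb_domain_error", "error", "condition")))
}

stop_lookup <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("epgdb_lookup_error", "epgdb_domain_error",
                                "error", "condition")))
}

# Accept a file path, a connection, or a character vector of lines.
# A single string containing a newline is treated as inline text.
read_source_lines <- function(source) {
  if (inherits(source, "connection")) return(readLines(source, warn = FALSE))
  if (!is.character(source)) {
    stop_schema("text source must be a file path, connection, or character vector")
  }
  if (length(source) == 1L && !grepl("[\n\t]", source)) {
    if (!file.exists(source)) stop_schema("file not found: %s", source)
    return(readLines(source, warn = FALSE))
  }
  unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
}

# Read a TSV dialect used throughout: UTF-8, '#' comment lines, header row.
read_tsv_dialect <- function(source, required = character()) {
  lines <- read_source_lines(source)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_schema("empty table source")
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          sep = "\t", header = TRUE, quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop_schema("missing required column(s): %s", paste(missing, collapse = ", "))
  }
  df
}

write_tsv_dialect <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

as_count <- function(x, what) {
  suppressWarnings(v <- as.numeric(x))
  if (anyNA(v) || any(v < 0) || any(v != floor(v))) {
    bad <- which(is.na(v) | v < 0 | v != floor(v))[1L]
    stop_schema("non-numeric or negative %s at row %d: '%s'", what, bad, x[bad])
  }
  as.integer(v)
}

split_semicolon <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character())
  trimws(strsplit(x, ";", fixed = TRUE)[[1L]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
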