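# Internal helpers: classed conditions and TSV plumbing shared by all readers.

fc_abort <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "funcoreg_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

fc_format_error    <- function(msg, ...) fc_abort("funcoreg_format_error", msg, ...)
fc_integrity_error <- function(msg, ...) fc_abort("funcoreg_integrity_error", msg, ...)
fc_domain_error    <- function(msg, ...) fc_abort("funcoreg_domain_error", msg, ...)
fc_config_error    <- function(msg, ...) fc_abort("funcoreg_config_error", msg, ...)
fc_io_error        <- function(msg, ...) fc_abort("funcoreg_io_error", msg, ...)

fc_log <- function(msg, ...) {
  message(sprintf(paste0("[funcoreg] ", msg), ...))
}

# Tab-delimited reader: '#' comment lines ignored, header required.
# Returns a character data.frame; callers coerce columns as needed.
fc_read_tsv <- function(path, required_cols = NULL) {
  if (!file.exists(path)) fc_io_error("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = character(0))
  if (!is.null(required_cols)) {
    missing <- setdiff(required_cols, names(df))
    if (length(missing) > 0)
      fc_format_error("%s: missing required column(s): %s",
                      path, paste(missing, collapse = ", "))
  }
  df
}

fc_write_tsv <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n",
                     fileEncoding = "UTF-8")
  invisible(path)
}

# Stable canonical ordering of an unordered regulator pair.
canonical_pair <- function(a, b) {
  swap <- b < a
  list(a = ifelse(swap, b, a), b = ifelse(swap, a, b))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
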