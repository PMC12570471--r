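# shared internal helpers

`%||%` <- function(x, y) if (is.null(x)) y else x

# readr is chatty by default; all internal reads go through these
read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, ...)
}

# Sniff a delimiter from the first non-empty line (tab beats comma).
sniff_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) return("\t")
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

stop_annodiff <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == round(x)
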