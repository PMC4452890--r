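# Internal helpers shared across modules.

# Error signalled when a query term cannot yield a result (unknown id,
# obsolete term, term annotating no protein, empty pool). Callers that
# implement the NA semantics catch this class; it is deliberately distinct
# from `gocooc_parse_error`, which signals malformed input files.
abort_na <- function(message, ...) {
  abort(message, class = "gocooc_term_error", ...)
}

abort_parse <- function(message, ...) {
  abort(message, class = "gocooc_parse_error", ...)
}

is_go_id <- function(x) {
  grepl("^GO:[0-9]{7}$", x)
}

# log(sum(exp(x))) without overflow; -Inf-safe.
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Write a data frame as a plain, deterministic TSV (no quoting surprises,
# "" for NA, no row names). readr is avoided so that store round-trips are
# byte-stable across locales.
write_tsv_plain <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) {
      df[[j]] <- ifelse(is.na(df[[j]]), "",
                        formatC(df[[j]], digits = 15, format = "g"))
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

read_tsv_plain <- function(path) {
  as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                              colClasses = "character", quote = "",
                              comment.char = "", na.strings = NULL,
                              check.names = FALSE))
}
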