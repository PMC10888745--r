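# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
sc_log <- function(...) {
  if (isTRUE(getOption("sigconnect.verbose", FALSE))) {
    message("[sigconnect] ", sprintf(...))
  }
  invisible(NULL)
}

#' Parse a value-plus-unit string such as "10 uM" or "6h"
#'
#' Units are compared case-insensitively; the micro sign (and Greek mu) are
#' folded to "u", and hour spellings ("h", "hr", "hrs") are folded to "h".
#' Numbers use decimal points (scientific notation accepted).
#'
#' @param x a scalar character like "10 uM", or a numeric (unitless).
#' @return list with components `value` (numeric) and `unit` (normalized
#'   character, possibly "").
#' @keywords internal
parse_quantity <- function(x) {
  if (is.numeric(x)) return(list(value = as.numeric(x), unit = ""))
  stopifnot(is.character(x), length(x) == 1L)
  x <- trimws(x)
  m <- regexec("^([-+]?[0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?)\\s*(.*)$", x)
  parts <- regmatches(x, m)[[1]]
  if (length(parts) != 3L) {
    stop(sprintf("cannot parse quantity '%s' (expected '<number> <unit>')", x),
         call. = FALSE)
  }
  value <- as.numeric(parts[2L])
  unit <- normalize_unit(parts[3L])
  list(value = value, unit = unit)
}

normalize_unit <- function(u) {
  u <- tolower(trimws(u))
  u <- gsub("µ|μ", "u", u)   # micro sign / mu -> u
  if (u %in% c("hr", "hrs", "hour", "hours")) u <- "h"
  u
}

#' Numeric-with-unit equality at relative tolerance 1e-9
#' @keywords internal
quantity_equal <- function(a, b, tol = 1e-9) {
  qa <- parse_quantity(a)
  qb <- parse_quantity(b)
  if (qa$unit != qb$unit) return(FALSE)
  isTRUE(abs(qa$value - qb$value) <= tol * max(1, abs(qa$value), abs(qb$value)))
}

# FNV-1a hash of a character scalar, as 8 hex digits. Used only to fingerprint
# run configurations in reports (not cryptographic).
fnv1a_hex <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # xor with a byte only touches the low 8 bits
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply, split into 16-bit halves to stay exact in doubles
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * p) %% 65536) * 65536 + h0 * p) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Write a data.frame as a plain TSV (UTF-8, no quoting surprises).
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE, fileEncoding = "UTF-8", ...)
}

# Derive a 32-bit sub-seed from a base seed and a stream index, so distinct
# pipeline stages / cell lines use distinct but reproducible RNG streams.
sub_seed <- function(seed, stream) {
  ((as.double(seed) %% 2147483647) * 7919 + stream * 104729) %% 2147483647
}
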