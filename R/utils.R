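# Internal helpers shared across modules.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Round half-up to integer percent
#'
#' Computes `floor(100 * k / n + 0.5)`, the half-up integer rounding used
#' throughout reporting (base R's `round()` rounds half to even, which does
#' not reproduce published percentages such as 52/248 -> 21).
#'
#' @param k Numerator count.
#' @param n Denominator count.
#' @return Integer percent. `n = 0` returns 0 with a warning.
#' @export
percent_int <- function(k, n) {
  if (length(n) == 1L && n == 0) {
    warnf("percent of an empty denominator reported as 0")
    return(0L)
  }
  as.integer(floor(100 * k / n + 0.5))
}

round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Canonicalize gene symbols
#'
#' Uppercases and strips surrounding whitespace. No alias resolution is
#' attempted: published interactome lists are symbol-based.
#'
#' @param x Character vector of symbols.
#' @return Canonical character vector.
#' @export
canonical_symbol <- function(x) {
  toupper(trimws(as.character(x)))
}

assert_count <- function(x, field, min = 0L) {
  if (length(x) != 1L || is.na(x) || !is.numeric(x) || x < min || x != floor(x)) {
    stopf("invalid configuration: '%s' must be a single integer >= %d", field, min)
  }
  invisible(as.integer(x))
}

assert_fraction <- function(x, field) {
  if (length(x) != 1L || is.na(x) || !is.numeric(x) || x < 0 || x > 1) {
    stopf("invalid configuration: '%s' must be a fraction in [0, 1]", field)
  }
  invisible(as.numeric(x))
}

assert_range <- function(x, field, min = 0L) {
  if (length(x) != 2L || any(is.na(x)) || !is.numeric(x) || x[1] > x[2] || any(x < min)) {
    stopf("invalid configuration: '%s' must be an integer interval c(lo, hi) with lo <= hi", field)
  }
  invisible(as.integer(x))
}

# Derive a per-stream child seed from one root seed, so each generator stage
# can be re-run independently yet deterministically.  Kept below 2^31.
stream_seed <- function(seed, stream) {
  offsets <- c(apms = 1L, crapome = 2L, string = 3L, bret = 4L,
               genesets = 5L, variants = 6L, layout = 7L, peptides = 8L)
  if (!stream %in% names(offsets)) stopf("unknown RNG stream '%s'", stream)
  (as.integer(seed) %% 2146483L) * 1000L + offsets[[stream]]
}

# Fixed-format table writers so identical inputs give byte-identical files.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, ...)
}

write_csv <- function(df, path) {
  utils::write.table(df, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}
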