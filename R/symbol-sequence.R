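#' Symbolic sequence over a finite alphabet
#'
#' A symbol sequence is an integer vector with values in `0..n_symbols - 1`
#' plus an explicit alphabet size, so that symbols absent from a particular
#' sample still count as zero-probability bins in all plug-in estimators.
#'
#' @param x Integer vector (or coercible) of symbols in `0..n_symbols - 1`.
#' @param n_symbols Alphabet size `L`. If `NULL`, inferred as `max(x) + 1`.
#' @return An integer vector of class `painf_seq` with attribute `n_symbols`.
#' @examples
#' s <- symbol_sequence(c(0, 1, 0, 1, 0, 1))
#' n_symbols(s)
#' @export
symbol_sequence <- function(x, n_symbols = NULL) {
  if (length(x) < 1) stop("a symbol sequence must contain at least one symbol")
  xi <- as.integer(x)
  if (anyNA(xi) || any(abs(as.numeric(x) - xi) > 0))
    stop("symbols must be integers")
  if (is.null(n_symbols)) n_symbols <- max(xi) + 1L
  n_symbols <- as.integer(n_symbols)
  if (n_symbols < 1L) stop("n_symbols must be positive")
  if (any(xi < 0L) || any(xi >= n_symbols))
    stop("symbols must lie in [0, n_symbols - 1]")
  structure(xi, n_symbols = n_symbols, class = "painf_seq")
}

#' @rdname symbol_sequence
#' @export
as_symbol_sequence <- function(x, n_symbols = NULL) {
  if (inherits(x, "painf_seq") && is.null(n_symbols)) return(x)
  symbol_sequence(unclass(x), n_symbols)
}

#' @rdname symbol_sequence
#' @export
n_symbols <- function(x) {
  L <- attr(x, "n_symbols")
  if (is.null(L)) max(as.integer(x)) + 1L else L
}

#' @export
print.painf_seq <- function(x, ...) {
  cat(sprintf("<symbol sequence: N = %d, alphabet size L = %d>\n",
              length(x), n_symbols(x)))
  show <- head(unclass(x), 25L)
  cat(paste(show, collapse = " "),
      if (length(x) > 25L) "..." else "", "\n")
  invisible(x)
}

#' @export
`[.painf_seq` <- function(x, i) {
  symbol_sequence(unclass(x)[i], n_symbols = attr(x, "n_symbols"))
}

# coerce any numeric input + optional L to a validated integer vector,
# returning list(x, L); the workhorse for all estimator entry points
.as_seq <- function(x, n_symbols = NULL) {
  s <- as_symbol_sequence(x, n_symbols)
  list(x = as.integer(s), L = n_symbols(s))
}

.parse_symbol_lines <- function(lines) {
  header_L <- NA_integer_
  keep <- logical(length(lines))
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "") next
    if (startsWith(ln, "#")) {
      m <- regmatches(ln, regexec("L\\s*=\\s*([0-9]+)", ln))[[1]]
      if (length(m) == 2) header_L <- as.integer(m[[2]])
      next
    }
    keep[i] <- TRUE
  }
  body <- trimws(lines[keep])
  if (length(body) == 0) stop("no data lines found in input")
  if (length(body) == 1 && grepl("[,[:space:]]", body)) {
    toks <- strsplit(body, "[,[:space:]]+")[[1]]
    toks <- toks[toks != ""]
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals))
      stop(sprintf("could not parse token '%s' on line %d",
                   toks[which(is.na(vals))[1]], which(keep)[1]))
  } else {
    vals <- suppressWarnings(as.numeric(body))
    if (anyNA(vals)) {
      bad <- which(is.na(vals))[1]
      stop(sprintf("could not parse '%s' on line %d",
                   body[bad], which(keep)[bad]))
    }
  }
  list(values = vals, header_L = header_L)
}

#' Read and write symbol sequences as plain text
#'
#' The on-disk format is one integer symbol per line, or a single
#' delimited line (comma and/or whitespace separated); the two layouts are
#' autodetected. An optional comment line `# L=4` declares the alphabet
#' size; otherwise it is inferred as `max + 1`.
#'
#' @param path File path.
#' @param n_symbols Optional alphabet-size override.
#' @return `read_symbol_sequence()` returns a [symbol_sequence()].
#' @export
read_symbol_sequence <- function(path, n_symbols = NULL) {
  parsed <- .parse_symbol_lines(readLines(path, warn = FALSE))
  L <- if (!is.null(n_symbols)) n_symbols
       else if (!is.na(parsed$header_L)) parsed$header_L
       else NULL
  symbol_sequence(parsed$values, L)
}

#' @rdname read_symbol_sequence
#' @param x A symbol sequence.
#' @param header Write a `# L=<L>` alphabet header line?
#' @export
write_symbol_sequence <- function(x, path, header = TRUE) {
  s <- as_symbol_sequence(x)
  con <- file(path, "w")
  on.exit(close(con))
  if (header) writeLines(sprintf("# L=%d", n_symbols(s)), con)
  writeLines(format(as.integer(s), scientific = FALSE), con)
  invisible(path)
}

#' Read and write real-valued series as plain text
#'
#' One float per line, or a single delimited line (autodetected);
#' the metric-series counterpart of [read_symbol_sequence()].
#'
#' @param path File path.
#' @return `read_numeric_series()` returns a numeric vector.
#' @export
read_numeric_series <- function(path) {
  .parse_symbol_lines(readLines(path, warn = FALSE))$values
}

#' @rdname read_numeric_series
#' @param x Numeric vector.
#' @export
write_numeric_series <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(format(as.numeric(x), scientific = FALSE, digits = 15,
                    trim = TRUE), con)
  invisible(path)
}
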