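HLA_LOCI <- c("A", "B", "C", "DRB1")

#' Parse an HLA allele name
#'
#' Parses designations of the form \code{"<locus>*<field>[:<field>...][suffix]"},
#' e.g. \code{"A*33"}, \code{"B*44:02"}, \code{"A*24:09N"}. The locus is matched
#' case-insensitively against A, B, C and DRB1; fields must be non-empty runs of
#' digits; an optional trailing expression-suffix letter (N, L, S, C, A, Q) is
#' preserved but plays no role in matching.
#'
#' @param text A single allele-name string. Surrounding whitespace is trimmed.
#' @return An object of class \code{"hla_allele"}: a list with elements
#'   \code{locus}, \code{fields} (character vector of digit strings, in order)
#'   and \code{suffix} (possibly \code{""}).
#' @examples
#' parse_allele("A*33")
#' parse_allele("B*44:02")
#' @seealso [truncate_allele()], [alleles_equal()]
#' @export
parse_allele <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  s <- trimws(text)
  m <- regmatches(s, regexec("^([A-Za-z][A-Za-z0-9]*)\\*(.*)$", s))[[1]]
  if (length(m) == 0L)
    stop("cannot parse allele name ", sQuote(text),
         ": expected '<locus>*<fields>'", call. = FALSE)
  locus <- toupper(m[2L])
  if (!locus %in% HLA_LOCI)
    stop("unknown HLA locus ", sQuote(m[2L]), " in ", sQuote(text), call. = FALSE)
  rest <- m[3L]
  sm <- regmatches(rest, regexec("^([0-9:]*)([A-Za-z]*)$", rest))[[1]]
  if (length(sm) == 0L || sm[2L] == "")
    stop("cannot parse allele fields in ", sQuote(text), call. = FALSE)
  fields <- strsplit(sm[2L], ":", fixed = TRUE)[[1]]
  if (length(fields) == 0L || any(fields == "") || any(!grepl("^[0-9]+$", fields))) {
    bad <- which(fields == "" | !grepl("^[0-9]+$", fields))
    stop("empty or non-numeric field at position ",
         if (length(bad)) bad[1L] else length(fields) + 1L,
         " in ", sQuote(text), call. = FALSE)
  }
  structure(list(locus = locus, fields = fields, suffix = sm[3L]),
            class = "hla_allele")
}

#' @export
format.hla_allele <- function(x, ...) {
  paste0(x$locus, "*", paste(x$fields, collapse = ":"), x$suffix)
}

#' @export
print.hla_allele <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
as.character.hla_allele <- function(x, ...) format(x)

#' Truncate an allele name to a lower field resolution
#'
#' Keeps the leading \code{n_fields} numeric fields (or all of them if the name
#' is already shorter). The expression suffix is dropped whenever truncation
#' actually removes fields, since a suffix qualifies the full-resolution name.
#' The operation is idempotent.
#'
#' @param a An \code{"hla_allele"} (or a string, parsed on the fly).
#' @param n_fields Number of leading fields to keep; must be >= 1.
#' @return An \code{"hla_allele"}.
#' @examples
#' format(truncate_allele("B*44:02", 1))  # "B*44"
#' @export
truncate_allele <- function(a, n_fields = 1L) {
  if (is.character(a)) a <- parse_allele(a)
  stopifnot(inherits(a, "hla_allele"))
  if (!is.numeric(n_fields) || length(n_fields) != 1L || n_fields < 1)
    stop("n_fields must be a single integer >= 1", call. = FALSE)
  n_fields <- as.integer(n_fields)
  if (length(a$fields) <= n_fields) return(a)
  structure(list(locus = a$locus, fields = a$fields[seq_len(n_fields)],
                 suffix = ""),
            class = "hla_allele")
}

#' Compare two allele names at a given resolution
#'
#' Two alleles are equal at resolution \code{r} when they share a locus and
#' their names truncated to \code{r} fields coincide digit-for-digit.
#' Expression suffixes are ignored. Symmetric and reflexive.
#'
#' @param x,y Alleles (\code{"hla_allele"} objects or strings).
#' @param resolution Number of fields compared (default 1, the resolution at
#'   which bank lines are matched to recipients).
#' @return Logical scalar.
#' @examples
#' alleles_equal("A*02:01", "A*02:06", resolution = 1)  # TRUE
#' alleles_equal("A*02:01", "A*02:06", resolution = 2)  # FALSE
#' @export
alleles_equal <- function(x, y, resolution = 1L) {
  if (is.character(x)) x <- parse_allele(x)
  if (is.character(y)) y <- parse_allele(y)
  if (x$locus != y$locus) return(FALSE)
  tx <- truncate_allele(x, resolution)
  ty <- truncate_allele(y, resolution)
  length(tx$fields) == length(ty$fields) && all(tx$fields == ty$fields)
}

## Canonical string key at a working resolution; the reserved pseudo-allele
## "OTHER" (unlisted residual mass) passes through untouched and can never
## equal a named allele.
allele_key <- function(x, resolution = 1L) {
  vapply(x, function(s) {
    if (identical(s, "OTHER") || (is.character(s) && s == "OTHER")) return("OTHER")
    format(truncate_allele(if (is.character(s)) parse_allele(s) else s,
                           resolution))
  }, character(1L), USE.NAMES = FALSE)
}

is_other <- function(key) key == "OTHER"
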