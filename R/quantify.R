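#' Classify an aligned indel pattern
#'
#' Consumes the dash/lowercase amplicon notation: in the observed pattern a
#' dash against a reference base is a deleted nucleotide, a lowercase letter
#' against a reference dash is an inserted nucleotide, and an uppercase
#' mismatch is a substitution. A frameshift is called when the net length
#' change (insertions minus deletions) is not a multiple of 3 — the premature
#' stop it causes silences the allele through nonsense-mediated decay.
#'
#' @param ref_pattern,obs_pattern Equal-length aligned strings.
#' @return An \code{"indel_call"}: list with \code{inserted_nt},
#'   \code{deleted_nt}, \code{net_change}, \code{substitutions},
#'   \code{frameshift}.
#' @examples
#' classify_indel("ACGTACGT", "AC--ACGT")  # 2-nt deletion, frameshift
#' classify_indel("ACGTACGT", "AC---CGT")  # 3-nt deletion, in frame
#' @export
classify_indel <- function(ref_pattern, obs_pattern) {
  stopifnot(is.character(ref_pattern), is.character(obs_pattern),
            length(ref_pattern) == 1L, length(obs_pattern) == 1L)
  if (nchar(ref_pattern) != nchar(obs_pattern))
    stop("ref and observed patterns differ in length", call. = FALSE)
  r <- strsplit(ref_pattern, "")[[1L]]
  o <- strsplit(obs_pattern, "")[[1L]]
  if (!all(grepl("^[ACGTN-]$", r)))
    stop("illegal character in reference pattern", call. = FALSE)
  if (!all(grepl("^[ACGTNacgtn-]$", o)))
    stop("illegal character in observed pattern", call. = FALSE)
  ref_base <- r != "-"
  obs_del <- o == "-"
  obs_ins <- grepl("^[acgtn]$", o)
  if (any(!ref_base & obs_del))
    stop("gap aligned to gap in the pattern pair", call. = FALSE)
  if (any(obs_ins & ref_base))
    stop("lowercase (inserted) base aligned to a reference base", call. = FALSE)
  if (any(!ref_base & !obs_ins))
    stop("reference gap must face a lowercase inserted base", call. = FALSE)
  deleted <- sum(ref_base & obs_del)
  inserted <- sum(obs_ins)
  subs <- sum(ref_base & !obs_del & o != r)
  net <- inserted - deleted
  structure(list(inserted_nt = inserted, deleted_nt = deleted,
                 net_change = net, substitutions = subs,
                 frameshift = (net %% 3L) != 0L),
            class = "indel_call")
}

#' @export
print.indel_call <- function(x, ...) {
  cat(sprintf("indel: +%d/-%d nt (net %+d), %d substitution(s), %s\n",
              x$inserted_nt, x$deleted_nt, x$net_change, x$substitutions,
              if (x$frameshift) "FRAMESHIFT" else "in frame"))
  invisible(x)
}

#' Indel frequency from read counts
#'
#' @param n_edited,n_total Read counts, 0 <= n_edited <= n_total,
#'   n_total > 0.
#' @param min_reads Depth below which the estimate is flagged low-confidence
#'   (default 100).
#' @return The fraction edited, with attribute \code{low_confidence}.
#' @export
indel_frequency <- function(n_edited, n_total, min_reads = 100L) {
  stopifnot(length(n_edited) == 1L, length(n_total) == 1L)
  if (n_total <= 0) stop("n_total must be positive", call. = FALSE)
  if (n_edited < 0 || n_edited > n_total)
    stop("need 0 <= n_edited <= n_total", call. = FALSE)
  structure(n_edited / n_total, low_confidence = n_total < min_reads)
}

#' Per-allele edit status
#'
#' @param allele Allele name (string or \code{"hla_allele"}).
#' @param call One of \code{"intact"}, \code{"in_frame_indel"},
#'   \code{"frameshift"}.
#' @return An \code{"allele_edit_status"}.
#' @export
allele_edit_status <- function(allele,
                               call = c("intact", "in_frame_indel", "frameshift")) {
  call <- match.arg(call)
  if (is.character(allele)) allele <- parse_allele(allele)
  structure(list(allele = allele, call = call), class = "allele_edit_status")
}

LOCUS_PREFIX <- c(A = "A", B = "B", C = "C", DRB1 = "D")

#' Genotype label from two allele edit statuses
#'
#' Both alleles frameshifted gives a null locus ("D-/-"); exactly one
#' frameshift gives a hemizygous label retaining the intact allele's first
#' field ("A02/-", order as supplied); no frameshift gives "+/+". An
#' in-frame indel is assumed to retain expression and never counts as a
#' knockout (a warning notes it).
#'
#' @param status1,status2 \code{"allele_edit_status"} objects at one locus.
#' @return The genotype label string.
#' @examples
#' knockout_call(allele_edit_status("A*02", "intact"),
#'               allele_edit_status("A*03", "frameshift"))  # "A02/-"
#' @export
knockout_call <- function(status1, status2) {
  stopifnot(inherits(status1, "allele_edit_status"),
            inherits(status2, "allele_edit_status"))
  if (status1$allele$locus != status2$allele$locus)
    stop("allele statuses are at different loci", call. = FALSE)
  pre <- LOCUS_PREFIX[[status1$allele$locus]]
  fs <- c(status1$call == "frameshift", status2$call == "frameshift")
  if (any(c(status1$call, status2$call) == "in_frame_indel"))
    warning("in-frame indel treated as retaining expression", call. = FALSE)
  if (all(fs)) return(paste0(pre, "-/-"))
  if (!any(fs)) return(paste0(pre, "+/+"))
  part <- function(st, is_fs)
    if (is_fs) "-" else st$allele$fields[[1L]]
  paste0(pre, part(status1, fs[1L]), "/", part(status2, fs[2L]))
}

#' Mitotic index from a division histogram
#'
#' Given counts of cells observed per division generation g = 0, 1, 2, ...,
#' the absolute precursor number is P = sum_g n_g 2^-g (each cell in
#' generation g descends from 2^-g of a starting cell) and the number of
#' mitotic events is M = sum_g n_g (1 - 2^-g) (a precursor reaching
#' generation g underwent 2^g - 1 divisions, spread over its 2^g
#' descendants). The mitotic index is M / P: 0 for an undivided population
#' and unbounded as cells accumulate divisions. Scale-invariant in the
#' counts.
#'
#' @param counts Nonnegative cell counts per generation.
#' @param generations Integer generations, parallel to \code{counts}
#'   (default 0, 1, 2, ...).
#' @return The mitotic index (nonnegative number).
#' @examples
#' mitotic_index(c(100))        # undivided: 0
#' mitotic_index(c(0, 100))     # all at one division: 1
#' mitotic_index(c(0, 0, 100))  # all at two divisions: 3
#' @export
mitotic_index <- function(counts, generations = seq_along(counts) - 1L) {
  stopifnot(length(counts) == length(generations))
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and nonnegative", call. = FALSE)
  if (sum(counts) <= 0) stop("all-zero division histogram", call. = FALSE)
  w <- 2^(-generations)
  precursors <- sum(counts * w)
  events <- sum(counts * (1 - w))
  events / precursors
}

#' Read a division histogram from TSV
#'
#' Expects columns \code{generation}, \code{count}.
#' @param path TSV path.
#' @return A data.frame with those columns, sorted by generation.
#' @export
read_division_histogram <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t")
  if (length(setdiff(c("generation", "count"), names(df))))
    stop("histogram TSV needs columns generation, count", call. = FALSE)
  df[order(df$generation), c("generation", "count"), drop = FALSE]
}

#' Read aligned indel patterns from TSV
#'
#' Expects columns \code{clone}, \code{allele}, \code{ref_pattern},
#' \code{obs_pattern}; one [classify_indel()] call per row.
#' @param path TSV path.
#' @return The input data.frame with appended columns \code{inserted_nt},
#'   \code{deleted_nt}, \code{net_change}, \code{substitutions},
#'   \code{frameshift}.
#' @export
read_indel_patterns <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  need <- c("clone", "allele", "ref_pattern", "obs_pattern")
  if (length(setdiff(need, names(df))))
    stop("indel TSV needs columns ", paste(need, collapse = ", "), call. = FALSE)
  calls <- lapply(seq_len(nrow(df)), function(i)
    classify_indel(df$ref_pattern[i], df$obs_pattern[i]))
  df$inserted_nt <- vapply(calls, `[[`, 0L, "inserted_nt")
  df$deleted_nt <- vapply(calls, `[[`, 0L, "deleted_nt")
  df$net_change <- vapply(calls, `[[`, 0L, "net_change")
  df$substitutions <- vapply(calls, `[[`, 0L, "substitutions")
  df$frameshift <- vapply(calls, `[[`, NA, "frameshift")
  df
}
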