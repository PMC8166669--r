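#' Construct a locus genotype
#'
#' An unordered pair of alleles at one locus; the pair may be identical
#' (homozygous). Both alleles must carry the stated locus.
#'
#' @param locus One of "A", "B", "C", "DRB1".
#' @param a1,a2 Alleles (strings or \code{"hla_allele"} objects).
#' @return A \code{"locus_genotype"}: list with \code{locus} and \code{alleles}
#'   (list of two \code{"hla_allele"}).
#' @export
locus_genotype <- function(locus, a1, a2) {
  locus <- toupper(locus)
  if (!locus %in% HLA_LOCI) stop("unknown locus ", sQuote(locus), call. = FALSE)
  if (is.character(a1)) a1 <- parse_allele(a1)
  if (is.character(a2)) a2 <- parse_allele(a2)
  if (a1$locus != locus || a2$locus != locus)
    stop("alleles ", format(a1), ", ", format(a2),
         " do not both belong to locus ", locus, call. = FALSE)
  structure(list(locus = locus, alleles = list(a1, a2)),
            class = "locus_genotype")
}

#' Construct a candidate cell line
#'
#' A heterozygous (or homozygous) parental line with one genotype each at
#' HLA-A, -B and -DRB1. DRB1 is carried for reporting only: every engineered
#' bank line is DRB1-null, so DRB1 never enters combo identity or matching.
#'
#' @param line_id Unique identifier.
#' @param A,B,DRB1 Length-2 character vectors of allele names, or
#'   \code{"locus_genotype"} objects.
#' @return A \code{"cell_line"}.
#' @examples
#' h9 <- cell_line("H9", A = c("A*02", "A*03"), B = c("B*35", "B*44"),
#'                 DRB1 = c("DRB1*15", "DRB1*07"))
#' @export
cell_line <- function(line_id, A, B, DRB1) {
  as_gt <- function(locus, x) {
    if (inherits(x, "locus_genotype")) {
      if (x$locus != locus) stop("genotype locus mismatch for ", locus, call. = FALSE)
      return(x)
    }
    stopifnot(length(x) == 2L)
    locus_genotype(locus, x[[1L]], x[[2L]])
  }
  stopifnot(is.character(line_id), length(line_id) == 1L, nzchar(line_id))
  structure(list(line_id = line_id,
                 genotypes = list(A = as_gt("A", A), B = as_gt("B", B),
                                  DRB1 = as_gt("DRB1", DRB1))),
            class = "cell_line")
}

#' @export
format.cell_line <- function(x, ...) {
  gt <- function(l) paste(vapply(x$genotypes[[l]]$alleles, format, ""), collapse = "/")
  sprintf("%s [A: %s; B: %s; DRB1: %s]", x$line_id, gt("A"), gt("B"), gt("DRB1"))
}

#' @export
print.cell_line <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

PANEL_COLS <- c("line_id", "A_1", "A_2", "B_1", "B_2", "DRB1_1", "DRB1_2")

#' Read a cell-line panel from TSV or JSON
#'
#' TSV files must carry a header row with columns \code{line_id, A_1, A_2,
#' B_1, B_2, DRB1_1, DRB1_2} holding allele-name strings; JSON files are
#' arrays of records with the same keys. Line ids must be unique.
#'
#' @param path Path to a UTF-8 TSV or JSON file; files ending in
#'   \code{.json} are read as JSON, anything else as TSV.
#' @return A list of \code{"cell_line"} objects.
#' @export
read_panel <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  } else {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            colClasses = "character", fileEncoding = "UTF-8")
  }
  missing <- setdiff(PANEL_COLS, names(df))
  if (length(missing))
    stop("panel file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$line_id))
    stop("duplicate line_id in panel: ",
         paste(unique(df$line_id[duplicated(df$line_id)]), collapse = ", "),
         call. = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    cell_line(df$line_id[i],
              A = c(df$A_1[i], df$A_2[i]),
              B = c(df$B_1[i], df$B_2[i]),
              DRB1 = c(df$DRB1_1[i], df$DRB1_2[i])))
}

#' Write a cell-line panel to TSV
#'
#' @param panel List of \code{"cell_line"}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_panel <- function(panel, path) {
  row1 <- function(ln) {
    al <- function(l, i) format(ln$genotypes[[l]]$alleles[[i]])
    data.frame(line_id = ln$line_id,
               A_1 = al("A", 1L), A_2 = al("A", 2L),
               B_1 = al("B", 1L), B_2 = al("B", 2L),
               DRB1_1 = al("DRB1", 1L), DRB1_2 = al("DRB1", 2L),
               stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, lapply(panel, row1))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
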