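revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

check_nt <- function(s, what = "sequence") {
  if (!grepl("^[ACGTN]*$", s))
    stop(what, " contains illegal characters (only A/C/G/T/N allowed)",
         call. = FALSE)
}

## Protospacer-orientation offsets (0-based over the 23-nt site: spacer
## 0..19 with 19 PAM-proximal, PAM N/G/G at 20/21/22). The seed is the ten
## PAM-proximal spacer positions plus the PAM GG.
SEED_OFFSETS <- c(10:19, 21:22)

## Map a genomic window index w (1..23, + strand orientation) to the
## protospacer-orientation offset for a site on the given strand.
proto_offset <- function(w, strand) if (strand == "+") w - 1L else 23L - w

#' Enumerate SpCas9 protospacer sites in a sequence
#'
#' Finds every 23-nt window ending in NGG on the plus strand and beginning
#' in CCN on the minus strand (reported in protospacer orientation, i.e.
#' 20-nt spacer followed by its NGG PAM). Windows whose PAM GG positions are
#' N are excluded. Coordinates are 0-based half-open on the plus strand.
#'
#' @param seq A nucleotide string (A/C/G/T/N), length >= 23.
#' @return A data.frame with columns \code{spacer}, \code{pam},
#'   \code{strand}, \code{start}, \code{end}, sorted by start then strand
#'   (\code{+} before \code{-}).
#' @examples
#' find_protospacers(paste0(strrep("A", 20), "TGG"))
#' @export
find_protospacers <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- toupper(seq)
  check_nt(s)
  L <- nchar(s)
  if (L < 23L) stop("sequence shorter than 23 nt", call. = FALSE)
  ch <- strsplit(s, "")[[1L]]
  hits <- list()
  for (i in seq_len(L - 22L)) {
    win <- substr(s, i, i + 22L)
    if (ch[i + 21L] == "G" && ch[i + 22L] == "G")
      hits[[length(hits) + 1L]] <- data.frame(
        spacer = substr(win, 1L, 20L), pam = substr(win, 21L, 23L),
        strand = "+", start = i - 1L, end = i + 22L,
        stringsAsFactors = FALSE)
    if (ch[i] == "C" && ch[i + 1L] == "C") {
      rc <- revcomp(win)
      hits[[length(hits) + 1L]] <- data.frame(
        spacer = substr(rc, 1L, 20L), pam = substr(rc, 21L, 23L),
        strand = "-", start = i - 1L, end = i + 22L,
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L)
    return(data.frame(spacer = character(0L), pam = character(0L),
                      strand = character(0L), start = integer(0L),
                      end = integer(0L), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct an aligned allele sequence pair
#'
#' Holds a target allele sequence (the one to cut) and a spare allele
#' sequence (the one to leave intact), with an end-to-end gapped alignment.
#' If no alignment is supplied, a global pairwise alignment is computed.
#'
#' @param target_id,spare_id Record identifiers.
#' @param target_seq,spare_seq Ungapped nucleotide strings.
#' @param aligned_target,aligned_spare Optional gapped strings of equal
#'   length whose gap-free content equals the respective sequences.
#' @return An \code{"allele_pair"}.
#' @export
allele_pair <- function(target_id, spare_id, target_seq, spare_seq,
                        aligned_target = NULL, aligned_spare = NULL) {
  target_seq <- toupper(target_seq); spare_seq <- toupper(spare_seq)
  check_nt(target_seq, "target sequence"); check_nt(spare_seq, "spare sequence")
  if (!nzchar(target_seq) || !nzchar(spare_seq))
    stop("sequences must be non-empty", call. = FALSE)
  if (is.null(aligned_target) || is.null(aligned_spare)) {
    aln <- Biostrings::pairwiseAlignment(target_seq, spare_seq,
                                         type = "global")
    aligned_target <- as.character(Biostrings::alignedPattern(aln))
    aligned_spare <- as.character(Biostrings::alignedSubject(aln))
  }
  aligned_target <- toupper(aligned_target)
  aligned_spare <- toupper(aligned_spare)
  if (nchar(aligned_target) != nchar(aligned_spare))
    stop("aligned strings differ in length", call. = FALSE)
  if (gsub("-", "", aligned_target, fixed = TRUE) != target_seq ||
      gsub("-", "", aligned_spare, fixed = TRUE) != spare_seq)
    stop("alignment does not cover the sequences end to end", call. = FALSE)
  structure(list(target_id = target_id, spare_id = spare_id,
                 target_seq = target_seq, spare_seq = spare_seq,
                 aligned_target = aligned_target,
                 aligned_spare = aligned_spare),
            class = "allele_pair")
}

#' Read an allele pair from FASTA
#'
#' Expects exactly two records, target first. If both records have equal
#' length and contain gap characters they are taken as a pre-computed
#' alignment; otherwise a global alignment is built internally.
#'
#' @param path FASTA path.
#' @return An \code{"allele_pair"}.
#' @export
read_allele_pair <- function(path) {
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) != 2L)
    stop("allele-pair FASTA must hold exactly two records", call. = FALSE)
  s1 <- as.character(recs[[1L]]); s2 <- as.character(recs[[2L]])
  ids <- names(recs)
  if (nchar(s1) == nchar(s2) && (grepl("-", s1, fixed = TRUE) ||
                                 grepl("-", s2, fixed = TRUE)))
    allele_pair(ids[1L], ids[2L],
                gsub("-", "", s1, fixed = TRUE), gsub("-", "", s2, fixed = TRUE),
                aligned_target = s1, aligned_spare = s2)
  else
    allele_pair(ids[1L], ids[2L], s1, s2)
}

#' Find allele-discriminating (or shared) Cas9 guides
#'
#' In \code{"discriminating"} mode, keeps target protospacers whose aligned
#' counterpart in the spare allele differs in the seed (the ten PAM-proximal
#' spacer nucleotides) or in the PAM GG by at least
#' \code{min_seed_mismatches} positions, or is disrupted by an alignment
#' gap; additionally the exact 20-nt spacer must not occur perfectly
#' anywhere in the spare sequence on either strand. Such guides cut the
#' target allele while sparing the other — the basis of subtype-specific
#' mono-allelic knockouts. In \code{"shared"} mode, keeps sites perfectly
#' identical in both alleles (for bi-allelic knockouts).
#'
#' N bases never count as matching and are treated as differences.
#'
#' @param pair An \code{"allele_pair"}.
#' @param mode \code{"discriminating"} or \code{"shared"}.
#' @param min_seed_mismatches Minimum seed/PAM differences (default 1).
#' @return A data.frame of guide candidates: \code{spacer}, \code{pam},
#'   \code{strand}, \code{start}, \code{end}, \code{cut_site},
#'   \code{seed_mismatches}, \code{gap_overlap},
#'   \code{discriminating_positions} (comma-joined protospacer-orientation
#'   offsets where the spare differs), \code{mode}. Discriminating results
#'   are sorted by \code{seed_mismatches} descending then \code{start};
#'   shared results by \code{start}.
#' @export
discriminating_guides <- function(pair, mode = c("discriminating", "shared"),
                                  min_seed_mismatches = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(pair, "allele_pair"))
  sites <- find_protospacers(pair$target_seq)
  if (nrow(sites) == 0L) return(empty_guides())
  tcols <- which(strsplit(pair$aligned_target, "")[[1L]] != "-")
  ta <- strsplit(pair$aligned_target, "")[[1L]]
  sa <- strsplit(pair$aligned_spare, "")[[1L]]
  spare_fwd <- pair$spare_seq
  spare_rev <- revcomp(spare_fwd)
  rows <- lapply(seq_len(nrow(sites)), function(k) {
    st <- sites$start[k]; strand <- sites$strand[k]
    cols <- tcols[(st + 1L):(st + 23L)]
    ## spare insertions between site columns count as a gap overlapping it
    gap_ins <- any(diff(cols) > 1L)
    tch <- ta[cols]; sch <- sa[cols]
    diffpos <- which(tch != sch | tch == "N" | sch == "N")
    gap_del <- any(sch[diffpos] == "-")
    offs <- sort(vapply(diffpos, proto_offset, 0L, strand = strand))
    seed_mm <- sum(offs %in% SEED_OFFSETS)
    gap_overlap <- gap_ins || gap_del
    keep <- if (mode == "shared") {
      length(diffpos) == 0L && !gap_ins
    } else {
      (seed_mm >= min_seed_mismatches || gap_overlap) &&
        !grepl(sites$spacer[k], spare_fwd, fixed = TRUE) &&
        !grepl(sites$spacer[k], spare_rev, fixed = TRUE)
    }
    if (!keep) return(NULL)
    cut <- if (strand == "+") st + 17L else st + 6L
    data.frame(spacer = sites$spacer[k], pam = sites$pam[k], strand = strand,
               start = st, end = st + 23L, cut_site = cut,
               seed_mismatches = seed_mm, gap_overlap = gap_overlap,
               discriminating_positions = paste(offs, collapse = ","),
               mode = mode, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) return(empty_guides())
  out <- do.call(rbind, rows)
  out <- if (mode == "discriminating")
    out[order(-out$seed_mismatches, out$start), , drop = FALSE]
  else out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_guides <- function() {
  data.frame(spacer = character(0L), pam = character(0L),
             strand = character(0L), start = integer(0L), end = integer(0L),
             cut_site = integer(0L), seed_mismatches = integer(0L),
             gap_overlap = logical(0L),
             discriminating_positions = character(0L), mode = character(0L),
             stringsAsFactors = FALSE)
}

#' Write guide candidates to TSV
#' @param guides Data.frame from [discriminating_guides()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_guides <- function(guides, path) {
  utils::write.table(guides, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
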