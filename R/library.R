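combo_key <- function(a, b) paste(a, b, sep = " / ")

#' Enumerate the hemizygous edit products of one parental line
#'
#' Mono-allelic knockout of HLA-A and HLA-B leaves one retained allele at
#' each locus, so a line heterozygous at both loci yields the four products
#' of its A alleles crossed with its B alleles; homozygosity at a locus
#' halves the count. Allele names are truncated to the working resolution
#' before deduplication, so a line heterozygous only below that resolution
#' collapses accordingly. DRB1 is excluded: every bank line is DRB1-null.
#'
#' @param line A \code{"cell_line"}.
#' @param resolution Field resolution for combo identity (default 1).
#' @return A \code{"combo_library"} with 1, 2 or 4 combos, each sourced to
#'   this line.
#' @examples
#' h9 <- cell_line("H9", c("A*02", "A*03"), c("B*35", "B*44"),
#'                 c("DRB1*15", "DRB1*07"))
#' enumerate_combos(h9)
#' @export
enumerate_combos <- function(line, resolution = 1L) {
  stopifnot(inherits(line, "cell_line"))
  if (is.null(line$genotypes$A) || is.null(line$genotypes$B))
    stop("line ", line$line_id, " lacks an A or B genotype", call. = FALSE)
  a <- unique(allele_key(line$genotypes$A$alleles, resolution))
  b <- unique(allele_key(line$genotypes$B$alleles, resolution))
  grid <- expand.grid(allele_A = a, allele_B = b,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$allele_A, grid$allele_B), , drop = FALSE]
  rownames(grid) <- NULL
  grid$sources <- I(rep(list(line$line_id), nrow(grid)))
  structure(grid, resolution = as.integer(resolution),
            class = c("combo_library", "data.frame"))
}

#' Build the deduplicated combo library of a panel
#'
#' Takes the union of every line's hemizygous products; combos identical at
#' the working resolution are merged and their source lines accumulated.
#'
#' @param panel List of \code{"cell_line"} with unique ids.
#' @param resolution Field resolution for combo identity.
#' @return A \code{"combo_library"}: data.frame with columns
#'   \code{allele_A}, \code{allele_B} and list-column \code{sources}
#'   (character vectors of line ids), sorted by (A, B) key.
#' @export
build_library <- function(panel, resolution = 1L) {
  stopifnot(length(panel) >= 1L)
  ids <- vapply(panel, function(l) l$line_id, character(1L))
  if (anyDuplicated(ids))
    stop("duplicate line_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  per <- lapply(panel, enumerate_combos, resolution = resolution)
  all <- do.call(rbind, lapply(per, as.data.frame))
  key <- combo_key(all$allele_A, all$allele_B)
  first <- !duplicated(key)
  out <- all[first, c("allele_A", "allele_B"), drop = FALSE]
  out$sources <- I(lapply(key[first], function(k)
    sort(unique(unlist(all$sources[key == k])))))
  out <- out[order(out$allele_A, out$allele_B), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, resolution = as.integer(resolution),
            class = c("combo_library", "data.frame"))
}

#' @export
print.combo_library <- function(x, ...) {
  cat(sprintf("Hemizygous A x B combo library: %d combos (resolution %d)\n",
              nrow(x), attr(x, "resolution")))
  df <- data.frame(allele_A = x$allele_A, allele_B = x$allele_B,
                   sources = vapply(x$sources, paste, "", collapse = ";"),
                   stringsAsFactors = FALSE)
  print.data.frame(df, ...)
  invisible(x)
}

#' Export a combo library to TSV
#'
#' Columns \code{allele_A}, \code{allele_B}, \code{sources}
#' (semicolon-joined line ids).
#' @param lib A \code{"combo_library"}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_library <- function(lib, path) {
  df <- data.frame(allele_A = lib$allele_A, allele_B = lib$allele_B,
                   sources = vapply(lib$sources, paste, "", collapse = ";"),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

## Subset a combo library, keeping class and attributes.
lib_subset <- function(lib, i) {
  out <- as.data.frame(lib)[i, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, resolution = attr(lib, "resolution"),
            class = c("combo_library", "data.frame"))
}
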