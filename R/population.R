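## Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

NORM_TOL <- 1e-6

#' Build a normalized per-locus allele frequency table
#'
#' Allele names are truncated to the working resolution and duplicates summed.
#' If the raw frequencies sum to s <= 1 (within tolerance), the missing mass
#' 1 - s is assigned to the reserved pseudo-allele \code{OTHER}, which stands
#' for every unlisted allele and can never be matched by a bank line — a
#' conservative choice that understates rather than overstates coverage.
#' A sum exceeding 1 beyond tolerance is an error: silent rescaling would
#' hide data-entry mistakes.
#'
#' @param alleles Character vector of allele names (or a named numeric vector
#'   of frequencies, in which case \code{frequencies} is ignored).
#' @param frequencies Nonnegative finite frequencies, same length.
#' @param population Population label.
#' @param locus Locus of every allele.
#' @param resolution Working field resolution (default 1).
#' @return A \code{"freq_table"}: data.frame with columns \code{allele}
#'   (canonical truncated names) and \code{frequency}, with attributes
#'   \code{population}, \code{locus}, \code{residual_other},
#'   \code{resolution}.
#' @examples
#' frequency_table(c("A*01", "A*02"), c(0.3, 0.5), "POP", "A")
#' @export
frequency_table <- function(alleles, frequencies = NULL, population, locus,
                            resolution = 1L) {
  if (is.numeric(alleles) && !is.null(names(alleles))) {
    frequencies <- unname(alleles)
    alleles <- names(alleles)
  }
  locus <- toupper(locus)
  if (!locus %in% HLA_LOCI) stop("unknown locus ", sQuote(locus), call. = FALSE)
  if (length(alleles) == 0L) stop("empty frequency table", call. = FALSE)
  if (length(frequencies) != length(alleles))
    stop("alleles and frequencies differ in length", call. = FALSE)
  if (any(!is.finite(frequencies)) || any(frequencies < 0))
    stop("frequencies must be finite and nonnegative", call. = FALSE)
  parsed <- lapply(alleles, parse_allele)
  bad <- vapply(parsed, function(a) a$locus != locus, logical(1L))
  if (any(bad))
    stop("allele(s) not at locus ", locus, ": ",
         paste(alleles[bad], collapse = ", "), call. = FALSE)
  keys <- allele_key(parsed, resolution)
  f <- tapply(frequencies, keys, sum)
  s <- sum(f)
  if (s > 1 + NORM_TOL)
    stop(sprintf("total frequency mass %.6g exceeds 1", s), call. = FALSE)
  residual <- max(0, 1 - s)
  tab <- data.frame(allele = names(f), frequency = as.numeric(f),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$allele), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, population = population, locus = locus,
            residual_other = residual, resolution = as.integer(resolution),
            class = c("freq_table", "data.frame"))
}

#' @export
print.freq_table <- function(x, ...) {
  cat(sprintf("HLA-%s allele frequencies, population %s (resolution %d)\n",
              attr(x, "locus"), attr(x, "population"), attr(x, "resolution")))
  print.data.frame(x, ...)
  cat(sprintf("residual OTHER mass: %.6g\n", attr(x, "residual_other")))
  invisible(x)
}

#' Build an A-B haplotype table as a linkage-equilibrium product
#'
#' Under linkage equilibrium the A and B alleles on a chromosome are
#' independent, so p(a, b) = f_a * f_b over all named alleles plus the
#' \code{OTHER} residual on each side. The result carries
#' \code{provenance = "product_LE"} so downstream reports declare the
#' assumption. Real A-B linkage disequilibrium is strong; prefer a supplied
#' haplotype table when one is available.
#'
#' @param freq_A,freq_B \code{"freq_table"}s at loci A and B.
#' @param on_population_mismatch \code{"warn"} (default) or \code{"error"}.
#' @return A \code{"haplotype_table"}: data.frame with columns
#'   \code{allele_A}, \code{allele_B}, \code{frequency}; attributes
#'   \code{population}, \code{provenance}, \code{resolution}.
#' @export
haplotypes_under_le <- function(freq_A, freq_B,
                                on_population_mismatch = c("warn", "error")) {
  on_population_mismatch <- match.arg(on_population_mismatch)
  stopifnot(inherits(freq_A, "freq_table"), inherits(freq_B, "freq_table"))
  if (attr(freq_A, "locus") != "A" || attr(freq_B, "locus") != "B")
    stop("haplotypes_under_le needs an A table and a B table, in that order",
         call. = FALSE)
  if (!identical(attr(freq_A, "population"), attr(freq_B, "population"))) {
    msg <- sprintf("population labels differ: %s vs %s",
                   attr(freq_A, "population"), attr(freq_B, "population"))
    if (on_population_mismatch == "error") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }
  side <- function(ft) {
    a <- ft$allele; f <- ft$frequency
    if (attr(ft, "residual_other") > 0) {
      a <- c(a, "OTHER"); f <- c(f, attr(ft, "residual_other"))
    }
    list(a = a, f = f)
  }
  A <- side(freq_A); B <- side(freq_B)
  grid <- expand.grid(allele_A = A$a, allele_B = B$a,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$frequency <- A$f[match(grid$allele_A, A$a)] * B$f[match(grid$allele_B, B$a)]
  haplotype_table(grid$allele_A, grid$allele_B, grid$frequency,
                  population = attr(freq_A, "population"),
                  provenance = "product_LE",
                  resolution = attr(freq_A, "resolution"))
}

#' Construct an A-B haplotype frequency table
#'
#' Directly supplied haplotype frequencies (e.g. published population tables)
#' are validated and normalized: any mass missing from 1 goes to the
#' unmatched pseudo-haplotype (\code{OTHER}, \code{OTHER}); mass exceeding 1
#' beyond tolerance is an error. Duplicate haplotypes (after truncation to
#' the working resolution) are summed.
#'
#' @param allele_A,allele_B Character vectors of allele names at A and B
#'   (\code{"OTHER"} allowed).
#' @param frequency Nonnegative haplotype frequencies.
#' @param population Population label.
#' @param provenance One of \code{"product_LE"}, \code{"supplied"},
#'   \code{"synthetic"}.
#' @param resolution Working field resolution.
#' @return A \code{"haplotype_table"}.
#' @export
haplotype_table <- function(allele_A, allele_B, frequency, population,
                            provenance = c("supplied", "product_LE", "synthetic"),
                            resolution = 1L) {
  provenance <- match.arg(provenance)
  n <- length(frequency)
  stopifnot(length(allele_A) == n, length(allele_B) == n, n >= 1L)
  if (any(!is.finite(frequency)) || any(frequency < 0))
    stop("haplotype frequencies must be finite and nonnegative", call. = FALSE)
  kA <- allele_key(as.list(allele_A), resolution)
  kB <- allele_key(as.list(allele_B), resolution)
  chk <- function(k, loc, raw) {
    named <- !is_other(k)
    bad <- named & !startsWith(k, paste0(loc, "*"))
    if (any(bad))
      stop("haplotype allele(s) not at locus ", loc, ": ",
           paste(unique(raw[bad]), collapse = ", "), call. = FALSE)
  }
  chk(kA, "A", allele_A); chk(kB, "B", allele_B)
  key <- paste(kA, kB, sep = "\t")
  f <- tapply(frequency, key, sum)
  s <- sum(f)
  if (s > 1 + NORM_TOL)
    stop(sprintf("total haplotype mass %.6g exceeds 1", s), call. = FALSE)
  parts <- strsplit(names(f), "\t", fixed = TRUE)
  tab <- data.frame(allele_A = vapply(parts, `[`, "", 1L),
                    allele_B = vapply(parts, `[`, "", 2L),
                    frequency = as.numeric(f), stringsAsFactors = FALSE)
  if (s < 1 - 1e-12) {
    i <- which(tab$allele_A == "OTHER" & tab$allele_B == "OTHER")
    if (length(i)) tab$frequency[i] <- tab$frequency[i] + (1 - s)
    else tab <- rbind(tab, data.frame(allele_A = "OTHER", allele_B = "OTHER",
                                      frequency = 1 - s))
  }
  tab <- tab[order(tab$allele_A, tab$allele_B), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, population = population, provenance = provenance,
            resolution = as.integer(resolution),
            class = c("haplotype_table", "data.frame"))
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("A-B haplotype table, population %s (%d haplotypes, provenance %s)\n",
              attr(x, "population"), nrow(x), attr(x, "provenance")))
  print.data.frame(utils::head(as.data.frame(x), 20L), ...)
  if (nrow(x) > 20L) cat("...", nrow(x) - 20L, "more rows\n")
  invisible(x)
}

## Marginal allele frequencies of a haplotype table at one locus.
marginal_frequencies <- function(h, locus = c("A", "B")) {
  locus <- match.arg(locus)
  col <- if (locus == "A") h$allele_A else h$allele_B
  out <- tapply(h$frequency, col, sum)
  stats::setNames(as.numeric(out), names(out))
}

#' Sample diploid genotypes under Hardy-Weinberg equilibrium
#'
#' Each individual is two haplotypes drawn independently from the table
#' (random mating). Deterministic for a fixed seed.
#'
#' @param h A \code{"haplotype_table"}.
#' @param n Number of individuals, >= 1.
#' @param seed Integer RNG seed.
#' @return A data.frame with one row per individual: integer haplotype row
#'   indices \code{hap1}, \code{hap2} and allele keys \code{a1}, \code{b1},
#'   \code{a2}, \code{b2}.
#' @export
sample_genotypes <- function(h, n, seed) {
  stopifnot(inherits(h, "haplotype_table"))
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n must be a single integer >= 1", call. = FALSE)
  n <- as.integer(n)
  p <- h$frequency / sum(h$frequency)
  idx <- with_seed(seed,
                   matrix(sample.int(nrow(h), 2L * n, replace = TRUE, prob = p),
                          ncol = 2L))
  data.frame(hap1 = idx[, 1L], hap2 = idx[, 2L],
             a1 = h$allele_A[idx[, 1L]], b1 = h$allele_B[idx[, 1L]],
             a2 = h$allele_A[idx[, 2L]], b2 = h$allele_B[idx[, 2L]],
             stringsAsFactors = FALSE)
}

#' Read an allele frequency table from TSV
#'
#' Expects columns \code{population, locus, allele, frequency}; all rows must
#' share one population and one locus.
#' @param path TSV path.
#' @param resolution Working resolution for [frequency_table()].
#' @return A \code{"freq_table"}.
#' @export
read_frequency_table <- function(path, resolution = 1L) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          fileEncoding = "UTF-8",
                          colClasses = c(frequency = "numeric"))
  need <- c("population", "locus", "allele", "frequency")
  if (length(setdiff(need, names(df))))
    stop("frequency TSV needs columns ", paste(need, collapse = ", "), call. = FALSE)
  if (length(unique(df$population)) != 1L || length(unique(df$locus)) != 1L)
    stop("frequency TSV must hold a single population and locus", call. = FALSE)
  frequency_table(df$allele, df$frequency, population = df$population[1L],
                  locus = df$locus[1L], resolution = resolution)
}

#' Read an A-B haplotype frequency table from TSV
#'
#' Expects columns \code{population, allele_A, allele_B, frequency};
#' \code{OTHER} is accepted literally on either side.
#' @param path TSV path.
#' @param resolution Working resolution.
#' @return A \code{"haplotype_table"} with provenance \code{"supplied"}.
#' @export
read_haplotype_table <- function(path, resolution = 1L) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          fileEncoding = "UTF-8",
                          colClasses = c(frequency = "numeric"))
  need <- c("population", "allele_A", "allele_B", "frequency")
  if (length(setdiff(need, names(df))))
    stop("haplotype TSV needs columns ", paste(need, collapse = ", "), call. = FALSE)
  if (length(unique(df$population)) != 1L)
    stop("haplotype TSV must hold a single population", call. = FALSE)
  haplotype_table(df$allele_A, df$allele_B, df$frequency,
                  population = df$population[1L], provenance = "supplied",
                  resolution = resolution)
}

#' Write a haplotype table to TSV
#' @param h A \code{"haplotype_table"}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_haplotype_table <- function(h, path) {
  df <- data.frame(population = attr(h, "population"),
                   allele_A = h$allele_A, allele_B = h$allele_B,
                   frequency = h$frequency, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
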