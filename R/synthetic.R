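## Symmetric Dirichlet draw via normalized gammas.
rdirichlet1 <- function(n, concentration) {
  g <- stats::rgamma(n, shape = concentration, rate = 1)
  while (sum(g) == 0) g <- stats::rgamma(n, shape = concentration, rate = 1)
  g / sum(g)
}

synth_allele_names <- function(locus, n) {
  sprintf("%s*%02d", locus, seq_len(n))
}

#' Generate a synthetic allele frequency table
#'
#' Frequencies are drawn from a symmetric Dirichlet; concentrations below 1
#' give the skewed spectra (few dominant alleles) typical of real HLA loci.
#' Allele names are sequential one-field names at the locus. A configurable
#' share of the mass can be reserved for unlisted alleles (\code{OTHER}).
#'
#' @param n_alleles Number of named alleles, >= 2.
#' @param concentration Dirichlet concentration, > 0 (default 0.5).
#' @param seed Integer RNG seed.
#' @param locus Target locus (default "A").
#' @param residual_other Mass in [0, 1) withheld for unlisted alleles
#'   (default 0).
#' @param population Population label (default "SYNTH").
#' @param resolution Working resolution (default 1).
#' @return A \code{"freq_table"}.
#' @export
synth_frequency_table <- function(n_alleles, concentration = 0.5, seed,
                                  locus = "A", residual_other = 0,
                                  population = "SYNTH", resolution = 1L) {
  if (!is.numeric(n_alleles) || n_alleles < 2)
    stop("n_alleles must be >= 2", call. = FALSE)
  if (!is.numeric(concentration) || concentration <= 0)
    stop("concentration must be > 0", call. = FALSE)
  if (residual_other < 0 || residual_other >= 1)
    stop("residual_other must lie in [0, 1)", call. = FALSE)
  f <- with_seed(seed, rdirichlet1(as.integer(n_alleles), concentration))
  frequency_table(synth_allele_names(toupper(locus), n_alleles),
                  f * (1 - residual_other), population = population,
                  locus = locus, resolution = resolution)
}

#' Generate a synthetic A-B haplotype table
#'
#' \code{ld_mode = "independent"} multiplies two synthetic allele frequency
#' tables (linkage equilibrium; provenance \code{product_LE}).
#' \code{ld_mode = "dirichlet_joint"} draws one Dirichlet over the full
#' A x B grid, which induces nonzero linkage disequilibrium between loci
#' (provenance \code{synthetic}).
#'
#' @param n_alleles_A,n_alleles_B Named allele counts, >= 2.
#' @param concentration Dirichlet concentration (default 0.5).
#' @param ld_mode \code{"independent"} or \code{"dirichlet_joint"}.
#' @param seed Integer RNG seed.
#' @param residual_other Mass withheld per locus (independent mode) or for
#'   the unmatched pseudo-haplotype (joint mode); default 0.
#' @param population Population label.
#' @param resolution Working resolution.
#' @return A \code{"haplotype_table"}.
#' @export
synth_haplotype_table <- function(n_alleles_A, n_alleles_B,
                                  concentration = 0.5,
                                  ld_mode = c("independent", "dirichlet_joint"),
                                  seed, residual_other = 0,
                                  population = "SYNTH", resolution = 1L) {
  ld_mode <- match.arg(ld_mode)
  if (ld_mode == "independent") {
    tabs <- with_seed(seed, {
      fa <- rdirichlet1(as.integer(n_alleles_A), concentration)
      fb <- rdirichlet1(as.integer(n_alleles_B), concentration)
      list(fa = fa, fb = fb)
    })
    fA <- frequency_table(synth_allele_names("A", n_alleles_A),
                          tabs$fa * (1 - residual_other),
                          population = population, locus = "A",
                          resolution = resolution)
    fB <- frequency_table(synth_allele_names("B", n_alleles_B),
                          tabs$fb * (1 - residual_other),
                          population = population, locus = "B",
                          resolution = resolution)
    return(haplotypes_under_le(fA, fB))
  }
  grid <- expand.grid(allele_A = synth_allele_names("A", n_alleles_A),
                      allele_B = synth_allele_names("B", n_alleles_B),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  p <- with_seed(seed, rdirichlet1(nrow(grid), concentration))
  haplotype_table(grid$allele_A, grid$allele_B, p * (1 - residual_other),
                  population = population, provenance = "synthetic",
                  resolution = resolution)
}

#' Draw a synthetic panel of heterozygous candidate lines
#'
#' Each line's A/B genotype is two haplotypes drawn from the table under
#' Hardy-Weinberg equilibrium, conditioned on carrying named alleles (a
#' real typed line never reads \code{OTHER}); DRB1 is filled with a
#' placeholder heterozygous genotype, since every engineered bank line is
#' DRB1-null and DRB1 never enters matching.
#'
#' @param h A \code{"haplotype_table"} with some fully named mass.
#' @param n_lines Number of lines, >= 1.
#' @param seed Integer RNG seed.
#' @return A list of \code{"cell_line"} with ids \code{SL001}, ...
#' @export
synth_line_panel <- function(h, n_lines, seed) {
  stopifnot(inherits(h, "haplotype_table"))
  if (!is.numeric(n_lines) || n_lines < 1)
    stop("n_lines must be >= 1", call. = FALSE)
  n_lines <- as.integer(n_lines)
  named <- !is_other(h$allele_A) & !is_other(h$allele_B)
  if (!any(named))
    stop("haplotype table has no fully named haplotypes", call. = FALSE)
  p <- h$frequency[named] / sum(h$frequency[named])
  hi <- which(named)
  idx <- with_seed(seed,
                   matrix(hi[sample.int(length(hi), 2L * n_lines,
                                        replace = TRUE, prob = p)],
                          ncol = 2L))
  lapply(seq_len(n_lines), function(i) {
    cell_line(sprintf("SL%03d", i),
              A = c(h$allele_A[idx[i, 1L]], h$allele_A[idx[i, 2L]]),
              B = c(h$allele_B[idx[i, 1L]], h$allele_B[idx[i, 2L]]),
              DRB1 = c("DRB1*04", "DRB1*15"))
  })
}

#' Generate a planted-difference allele sequence pair
#'
#' Builds a random target sequence containing one guaranteed plus-strand
#' NGG protospacer site, then derives the spare sequence by planting a
#' stated number of substitutions and gap events at recorded positions.
#' The returned truth (planted positions) lets tests assert guide calls
#' without re-inferring ground truth.
#'
#' @param length Target length, >= 30.
#' @param n_substitutions Substitutions to plant (>= 0).
#' @param n_gap_events Single-base deletion events to plant in the spare
#'   (>= 0).
#' @param seed Integer RNG seed.
#' @param sub_in_seed If TRUE (and \code{n_substitutions} >= 1), the first
#'   substitution is planted inside the guaranteed site's seed region.
#' @return An \code{"allele_pair"} with attribute \code{planted}: list with
#'   \code{site_start} (0-based start of the guaranteed site),
#'   \code{sub_positions} (1-based target coordinates),
#'   \code{del_positions}.
#' @export
synth_allele_pair <- function(length, n_substitutions = 1L, n_gap_events = 0L,
                              seed, sub_in_seed = TRUE) {
  if (length < 30L) stop("length must be >= 30", call. = FALSE)
  if (n_substitutions < 0 || n_gap_events < 0)
    stop("counts must be nonnegative", call. = FALSE)
  bases <- c("A", "C", "G", "T")
  out <- with_seed(seed, {
    tch <- sample(bases, length, replace = TRUE)
    ## plant one + strand site mid-sequence: window [site+1, site+23] with GG
    site0 <- sample(seq(3L, length - 26L), 1L)
    tch[site0 + 22L] <- "G"; tch[site0 + 23L] <- "G"
    sch <- tch
    ## seed region of the planted site: spacer offsets 10..19 ->
    ## target 1-based positions site0+11 .. site0+20
    seed_pos <- (site0 + 11L):(site0 + 20L)
    sub_pool <- setdiff(seq(2L, length - 1L), c(site0 + 22L, site0 + 23L))
    subs <- integer(0L)
    if (n_substitutions >= 1L) {
      first <- if (sub_in_seed) sample(seed_pos, 1L) else sample(sub_pool, 1L)
      rest <- if (n_substitutions > 1L)
        sample(setdiff(sub_pool, first), n_substitutions - 1L) else integer(0L)
      subs <- sort(c(first, rest))
      for (p in subs) sch[p] <- sample(setdiff(bases, tch[p]), 1L)
    }
    dels <- if (n_gap_events >= 1L)
      sort(sample(setdiff(seq(2L, length - 1L), subs), n_gap_events))
    else integer(0L)
    list(tch = tch, sch = sch, site0 = site0, subs = subs, dels = dels)
  })
  aligned_t <- paste(out$tch, collapse = "")
  sch <- out$sch
  sch[out$dels] <- "-"
  aligned_s <- paste(sch, collapse = "")
  pair <- allele_pair("target", "spare",
                      target_seq = aligned_t,
                      spare_seq = gsub("-", "", aligned_s, fixed = TRUE),
                      aligned_target = aligned_t, aligned_spare = aligned_s)
  attr(pair, "planted") <- list(site_start = out$site0,
                                sub_positions = out$subs,
                                del_positions = out$dels)
  pair
}

#' Write an allele pair as aligned FASTA
#' @param pair An \code{"allele_pair"}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_allele_pair <- function(pair, path) {
  x <- Biostrings::BStringSet(c(pair$aligned_target, pair$aligned_spare))
  names(x) <- c(pair$target_id, pair$spare_id)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
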