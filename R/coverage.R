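## Per-combo indicator vectors over the haplotypes of h: mA[i] is TRUE when
## haplotype i carries the combo's retained A allele (OTHER never matches),
## mB likewise for B. Keys are re-truncated when a coarser resolution is
## requested than the one the objects were built at.
combo_indicators <- function(lib, h, resolution = NULL) {
  kA <- h$allele_A; kB <- h$allele_B
  cA <- lib$allele_A; cB <- lib$allele_B
  if (!is.null(resolution)) {
    kA <- allele_key(as.list(kA), resolution)
    kB <- allele_key(as.list(kB), resolution)
    cA <- allele_key(as.list(cA), resolution)
    cB <- allele_key(as.list(cB), resolution)
  }
  lapply(seq_along(cA), function(j) {
    list(mA = !is_other(kA) & kA == cA[j],
         mB = !is_other(kB) & kB == cB[j])
  })
}

res_or_na <- function(r) if (is.null(r)) NA_integer_ else as.integer(r)

check_normalized <- function(h) {
  if (abs(sum(h$frequency) - 1) > 1e-9)
    stop("haplotype table is not normalized (total mass ",
         format(sum(h$frequency)), ")", call. = FALSE)
}

#' Does a hemizygous combo match a recipient genotype?
#'
#' A graft expressing only the retained alleles (a, b) is matched when the
#' recipient carries a at HLA-A and b at HLA-B, on either haplotype
#' (cross-haplotype carriage counts: matching is at the allele level, in the
#' host-versus-graft direction, so the recipient's unshared alleles are
#' irrelevant). The \code{OTHER} pseudo-allele never matches.
#'
#' @param combo A one-row \code{"combo_library"} slice, or a list with
#'   \code{allele_A}, \code{allele_B}.
#' @param genotype A list or one-row data.frame with allele keys \code{a1},
#'   \code{a2}, \code{b1}, \code{b2} (as returned by [sample_genotypes()]).
#' @param resolution Field resolution at which alleles are compared.
#' @return Logical scalar.
#' @export
combo_matches <- function(combo, genotype, resolution = 1L) {
  a <- allele_key(list(combo$allele_A[1L]), resolution)
  b <- allele_key(list(combo$allele_B[1L]), resolution)
  gA <- allele_key(list(genotype$a1[1L], genotype$a2[1L]), resolution)
  gB <- allele_key(list(genotype$b1[1L], genotype$b2[1L]), resolution)
  !is_other(a) && !is_other(b) && a %in% gA && b %in% gB
}

coverage_result <- function(coverage, method, resolution, population,
                            level, n = NA_integer_, se = NA_real_) {
  structure(list(coverage = coverage, method = method, n = n, se = se,
                 resolution = resolution, population = population,
                 level = level),
            class = "coverage_result")
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf("Population coverage: %.4f (%s, %s-level, resolution %d, population %s)\n",
              x$coverage, x$method, x$level, x$resolution, x$population))
  if (x$method == "monte_carlo")
    cat(sprintf("  n = %d samples, SE = %.5f\n", x$n, x$se))
  invisible(x)
}

#' Exact population coverage of a combo library
#'
#' The fraction of individuals matched by at least one bank combo, computed
#' exactly under the haplotype model by enumerating ordered haplotype pairs:
#' C = sum over (h1, h2) of p(h1) p(h2) 1[some combo matches the genotype].
#' The default genotype-level rule asks only that the recipient carry the
#' combo's two alleles somewhere in the diplotype; \code{level =
#' "haplotype"} is the stricter variant where one recipient haplotype must
#' equal the combo outright, giving C = 1 - (1 - q)^2 with q the matched
#' haplotype mass.
#'
#' @param lib A \code{"combo_library"} (possibly empty).
#' @param h A normalized \code{"haplotype_table"}.
#' @param resolution Field resolution; defaults to the library's.
#' @param level \code{"genotype"} (default) or \code{"haplotype"}.
#' @return A \code{"coverage_result"} with \code{method = "analytic"}.
#' @examples
#' fa <- frequency_table(c("A*01", "A*02"), c(0.5, 0.5), "POP", "A")
#' fb <- frequency_table(c("B*01", "B*02"), c(0.5, 0.5), "POP", "B")
#' h <- haplotypes_under_le(fa, fb)
#' pan <- list(cell_line("L1", c("A*01", "A*02"), c("B*01", "B*02"),
#'                       c("DRB1*04", "DRB1*07")))
#' analytic_coverage(build_library(pan), h)
#' @export
analytic_coverage <- function(lib, h, resolution = NULL,
                              level = c("genotype", "haplotype")) {
  level <- match.arg(level)
  check_normalized(h)
  if (is.null(resolution)) resolution <- attr(lib, "resolution")
  pop <- attr(h, "population")
  if (nrow(lib) == 0L)
    return(coverage_result(0, "analytic", res_or_na(resolution), pop, level))
  ind <- combo_indicators(lib, h, resolution)
  p <- h$frequency
  if (level == "haplotype") {
    hit <- Reduce(`|`, lapply(ind, function(m) m$mA & m$mB))
    q <- sum(p[hit])
    return(coverage_result(1 - (1 - q)^2, "analytic", res_or_na(resolution),
                           pop, level))
  }
  M <- pair_matched_matrix(ind, nrow(h))
  C <- as.numeric(crossprod(p, M %*% p))
  coverage_result(min(1, max(0, C)), "analytic", res_or_na(resolution), pop,
                  level)
}

## n_hap x n_hap matrix of genotype matched indicators, OR'd over combos.
pair_matched_matrix <- function(ind, n_hap, init = NULL) {
  M <- if (is.null(init)) matrix(FALSE, n_hap, n_hap) else init
  for (m in ind)
    M <- M | (outer(m$mA, m$mA, `|`) & outer(m$mB, m$mB, `|`))
  M
}

#' Cumulative coverage along an ordered combo list
#'
#' C_k is the exact coverage of the first k combos; the curve is
#' nondecreasing and its endpoint equals the coverage of the full set.
#'
#' @param lib An ordered \code{"combo_library"} with distinct (A, B) keys.
#' @param h A normalized \code{"haplotype_table"}.
#' @param resolution Field resolution; defaults to the library's.
#' @param level Matching level, as in [analytic_coverage()].
#' @return A \code{"coverage_curve"}: data.frame with columns \code{k},
#'   \code{combo}, \code{cumulative_coverage}.
#' @export
cumulative_coverage <- function(lib, h, resolution = NULL,
                                level = c("genotype", "haplotype")) {
  level <- match.arg(level)
  check_normalized(h)
  if (is.null(resolution)) resolution <- attr(lib, "resolution")
  keys <- combo_key(lib$allele_A, lib$allele_B)
  if (anyDuplicated(keys))
    stop("duplicate combo keys in ordered list: ",
         paste(unique(keys[duplicated(keys)]), collapse = "; "), call. = FALSE)
  ind <- combo_indicators(lib, h, resolution)
  p <- h$frequency
  out <- numeric(nrow(lib))
  if (level == "haplotype") {
    hit <- rep(FALSE, nrow(h))
    for (k in seq_along(ind)) {
      hit <- hit | (ind[[k]]$mA & ind[[k]]$mB)
      out[k] <- 1 - (1 - sum(p[hit]))^2
    }
  } else {
    M <- matrix(FALSE, nrow(h), nrow(h))
    for (k in seq_along(ind)) {
      M <- pair_matched_matrix(ind[k], nrow(h), init = M)
      out[k] <- as.numeric(crossprod(p, M %*% p))
    }
  }
  structure(data.frame(k = seq_along(keys), combo = keys,
                       cumulative_coverage = out, stringsAsFactors = FALSE),
            resolution = res_or_na(resolution),
            population = attr(h, "population"),
            level = level, class = c("coverage_curve", "data.frame"))
}

#' Monte Carlo estimate of population coverage
#'
#' Samples n diploid genotypes under Hardy-Weinberg equilibrium and reports
#' the matched fraction with its binomial standard error
#' sqrt(C (1 - C) / n). Deterministic for a fixed seed; used to validate
#' the exact computation.
#'
#' @param lib A \code{"combo_library"}.
#' @param h A normalized \code{"haplotype_table"}.
#' @param n Number of simulated individuals, >= 1.
#' @param seed Integer RNG seed.
#' @param resolution Field resolution; defaults to the library's.
#' @param level Matching level, as in [analytic_coverage()].
#' @return A \code{"coverage_result"} with \code{method = "monte_carlo"}.
#' @export
monte_carlo_coverage <- function(lib, h, n, seed, resolution = NULL,
                                 level = c("genotype", "haplotype")) {
  level <- match.arg(level)
  check_normalized(h)
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n must be a single integer >= 1", call. = FALSE)
  if (is.null(resolution)) resolution <- attr(lib, "resolution")
  n <- as.integer(n)
  g <- sample_genotypes(h, n, seed)
  matched <- rep(FALSE, n)
  if (nrow(lib) > 0L) {
    ind <- combo_indicators(lib, h, resolution)
    i <- g$hap1; j <- g$hap2
    for (m in ind) {
      if (level == "haplotype") {
        hit <- m$mA & m$mB
        matched <- matched | hit[i] | hit[j]
      } else {
        matched <- matched |
          ((m$mA[i] | m$mA[j]) & (m$mB[i] | m$mB[j]))
      }
    }
  }
  C <- mean(matched)
  coverage_result(C, "monte_carlo", res_or_na(resolution),
                  attr(h, "population"), level,
                  n = n, se = sqrt(C * (1 - C) / n))
}

#' Write a coverage report to JSON
#'
#' @param x A \code{"coverage_result"}.
#' @param lib The \code{"combo_library"} it was computed for (fingerprinted
#'   as the sorted combo keys).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_coverage_report <- function(x, lib, path) {
  rep <- list(population = x$population, resolution = x$resolution,
              method = x$method, level = x$level, coverage = x$coverage,
              n = if (is.na(x$n)) NULL else x$n,
              se = if (is.na(x$se)) NULL else x$se,
              library_fingerprint = sort(combo_key(lib$allele_A, lib$allele_B)))
  jsonlite::write_json(rep[!vapply(rep, is.null, logical(1L))], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
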