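# Independent oracles and small generators. Everything here works from the
# plain data.frame columns of the package's objects and reimplements the
# probability logic from scratch (explicit loops, string comparison), so the
# fast analytic paths are checked against genuinely separate code.

make_line <- function(id, a1, a2, b1, b2) {
  cell_line(id, A = c(a1, a2), B = c(b1, b2), DRB1 = c("DRB1*04", "DRB1*15"))
}

# genotype-level match by direct string membership; OTHER never matches
oracle_pair_matched <- function(lib, aA, aB, bA, bB) {
  for (k in seq_len(nrow(lib))) {
    a <- lib$allele_A[k]; b <- lib$allele_B[k]
    if (a == "OTHER" || b == "OTHER") next
    if ((a == aA || a == bA) && (b == aB || b == bB)) return(TRUE)
  }
  FALSE
}

# exact coverage by looping over ordered haplotype pairs
oracle_coverage_enum <- function(lib, h) {
  total <- 0
  for (i in seq_len(nrow(h))) for (j in seq_len(nrow(h))) {
    if (oracle_pair_matched(lib, h$allele_A[i], h$allele_B[i],
                            h$allele_A[j], h$allele_B[j]))
      total <- total + h$frequency[i] * h$frequency[j]
  }
  total
}

# coverage by inclusion-exclusion over combo subsets: P(union matched) =
# sum over nonempty S of (-1)^(|S|+1) P(genotype carries every allele in S)
oracle_coverage_inclexcl <- function(lib, h) {
  n <- nrow(lib)
  if (n == 0L) return(0)
  carries_all <- function(as, bs, aA, bA, aB, bB) {
    all(as %in% c(aA, bA)) && all(bs %in% c(aB, bB))
  }
  total <- 0
  for (bits in seq_len(2^n - 1L)) {
    S <- which(bitwAnd(bits, 2^(seq_len(n) - 1L)) > 0L)
    as <- unique(lib$allele_A[S]); bs <- unique(lib$allele_B[S])
    if (any(as == "OTHER") || any(bs == "OTHER")) next
    pS <- 0
    if (length(as) <= 2L && length(bs) <= 2L) {
      for (i in seq_len(nrow(h))) for (j in seq_len(nrow(h))) {
        if (carries_all(as, bs, h$allele_A[i], h$allele_A[j],
                        h$allele_B[i], h$allele_B[j]))
          pS <- pS + h$frequency[i] * h$frequency[j]
      }
    }
    total <- total + (-1)^(length(S) + 1L) * pS
  }
  total
}

# smallest number of combos reaching tau, by exhaustive subset search
oracle_min_combos <- function(lib, h, tau) {
  n <- nrow(lib)
  for (k in seq_len(n)) {
    for (S in utils::combn(n, k, simplify = FALSE)) {
      if (oracle_coverage_enum(lib[S, , drop = FALSE], h) >= tau - 1e-12)
        return(k)
    }
  }
  NA_integer_
}

rand_hap_table <- function(nA, nB, seed, residual = 0, concentration = 0.8) {
  synth_haplotype_table(nA, nB, concentration = concentration,
                        ld_mode = "dirichlet_joint", seed = seed,
                        residual_other = residual)
}

rand_panel <- function(h, n, seed) synth_line_panel(h, n, seed)
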