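le_table <- function(fa_named, fb_named, pop = "POP") {
  haplotypes_under_le(
    frequency_table(names(fa_named), unname(fa_named), pop, "A"),
    frequency_table(names(fb_named), unname(fb_named), pop, "B"))
}

test_that("the combo match rule is allele-level and OTHER never matches", {
  lib <- build_library(list(make_line("L", "A*02", "A*02", "B*35", "B*35")))
  # cross-haplotype carriage: A*02 on one haplotype, B*35 on the other
  g <- list(a1 = "A*02", b1 = "B*44", a2 = "A*03", b2 = "B*35")
  expect_true(combo_matches(lib[1, ], g))
  expect_true(combo_matches(lib[1, ], list(a1 = "A*02", b1 = "B*35",
                                           a2 = "A*02", b2 = "B*35")))
  expect_false(combo_matches(lib[1, ], list(a1 = "OTHER", b1 = "B*35",
                                            a2 = "OTHER", b2 = "B*35")))
})

test_that("single-combo coverage under LE matches the closed form", {
  set.seed(3)
  for (i in 1:25) {
    fa <- runif(1, 0.05, 0.95); fb <- runif(1, 0.05, 0.95)
    h <- le_table(c("A*01" = fa), c("B*01" = fb))
    lib <- build_library(list(make_line("L", "A*01", "A*01", "B*01", "B*01")))
    C <- analytic_coverage(lib, h)$coverage
    expect_equal(C, (1 - (1 - fa)^2) * (1 - (1 - fb)^2), tolerance = 1e-12)
    # and against the independent pair-enumeration oracle
    expect_equal(C, oracle_coverage_enum(lib, h), tolerance = 1e-12)
  }
})

test_that("empty library has zero coverage; full named match loses OTHER mass", {
  h <- le_table(c("A*01" = 0.9), c("B*01" = 0.9))
  lib <- build_library(list(make_line("L", "A*01", "A*01", "B*01", "B*01")))
  empty <- lib[0, ]
  expect_equal(analytic_coverage(empty, h)$coverage, 0)
  C <- analytic_coverage(lib, h)$coverage
  expect_lt(C, 1)  # residual OTHER mass at each locus is never matched
  expect_equal(C, oracle_coverage_enum(lib, h), tolerance = 1e-12)
})

test_that("analytic coverage equals the inclusion-exclusion oracle", {
  set.seed(17)
  for (i in 1:12) {
    h <- rand_hap_table(sample(3:5, 1), sample(3:5, 1), seed = i,
                        residual = runif(1, 0, 0.2))
    pan <- rand_panel(h, 1, seed = i + 30)
    lib <- build_library(pan)
    lib <- lib[seq_len(min(nrow(lib), 4L)), ]
    expect_equal(analytic_coverage(lib, h)$coverage,
                 oracle_coverage_inclexcl(lib, h), tolerance = 1e-12)
  }
})

test_that("cumulative coverage is nondecreasing, permutation-stable at the end", {
  h <- rand_hap_table(5, 5, seed = 2)
  lib <- build_library(rand_panel(h, 3, seed = 9))
  cur <- cumulative_coverage(lib, h)
  expect_true(all(diff(c(0, cur$cumulative_coverage)) >= -1e-12))
  expect_equal(cur$cumulative_coverage[nrow(lib)],
               analytic_coverage(lib, h)$coverage, tolerance = 1e-12)
  perm <- lib[sample(nrow(lib)), ]
  cur2 <- cumulative_coverage(perm, h)
  expect_equal(cur2$cumulative_coverage[nrow(lib)],
               cur$cumulative_coverage[nrow(lib)], tolerance = 1e-12)
  expect_equal(cumulative_coverage(lib[1, ], h)$cumulative_coverage,
               analytic_coverage(lib[1, ], h)$coverage, tolerance = 1e-12)
  expect_error(cumulative_coverage(lib[c(1, 1), ], h), "duplicate combo")
})

test_that("Monte Carlo coverage agrees with analytic within 4 SE", {
  for (i in 1:4) {
    h <- rand_hap_table(6, 6, seed = 40 + i)
    lib <- build_library(rand_panel(h, 2, seed = 80 + i))
    mc <- monte_carlo_coverage(lib, h, n = 50000, seed = 7 * i)
    an <- analytic_coverage(lib, h)
    expect_lt(abs(mc$coverage - an$coverage), 4 * max(mc$se, 1e-4))
  }
  # degenerate: one haplotype fully matched by one combo
  h1 <- le_table(c("A*01" = 1), c("B*01" = 1))
  lib1 <- build_library(list(make_line("L", "A*01", "A*01", "B*01", "B*01")))
  mc1 <- monte_carlo_coverage(lib1, h1, n = 100, seed = 1)
  expect_equal(mc1$coverage, 1)
  expect_equal(mc1$se, 0)
  expect_equal(monte_carlo_coverage(lib1[0, ], h1, n = 100, seed = 1)$coverage, 0)
})

test_that("coverage is monotone in the library and under coarsening", {
  set.seed(31)
  for (i in 1:8) {
    h <- rand_hap_table(5, 5, seed = 200 + i)
    lib <- build_library(rand_panel(h, 3, seed = 300 + i))
    k <- sample(nrow(lib), max(1, nrow(lib) - 3))
    sub <- lib[sort(k), ]
    expect_lte(analytic_coverage(sub, h)$coverage,
               analytic_coverage(lib, h)$coverage + 1e-12)
  }
  # 2-field model coarsened to 1 field never loses coverage
  fa <- frequency_table(c("A*02:01", "A*02:06", "A*03:01"), c(0.3, 0.2, 0.4),
                        "POP", "A", resolution = 2)
  fb <- frequency_table(c("B*35:01", "B*44:02"), c(0.5, 0.4), "POP", "B",
                        resolution = 2)
  h2 <- haplotypes_under_le(fa, fb)
  lib2 <- build_library(list(make_line("L", "A*02:01", "A*03:01",
                                       "B*35:01", "B*44:02")), resolution = 2)
  c2 <- analytic_coverage(lib2, h2, resolution = 2)$coverage
  c1 <- analytic_coverage(lib2, h2, resolution = 1)$coverage
  expect_gte(c1, c2 - 1e-12)
})

test_that("haplotype-level coverage is the stricter variant", {
  h <- rand_hap_table(4, 4, seed = 77)
  lib <- build_library(rand_panel(h, 2, seed = 78))
  cg <- analytic_coverage(lib, h, level = "genotype")$coverage
  ch <- analytic_coverage(lib, h, level = "haplotype")$coverage
  expect_lte(ch, cg + 1e-12)
  # closed form: 1 - (1 - q)^2 with q the matched haplotype mass
  q <- sum(h$frequency[paste(h$allele_A, h$allele_B) %in%
                         paste(lib$allele_A, lib$allele_B)])
  expect_equal(ch, 1 - (1 - q)^2, tolerance = 1e-12)
})

test_that("coverage reports serialize to JSON with a library fingerprint", {
  h <- le_table(c("A*01" = 0.5, "A*02" = 0.5), c("B*01" = 0.5, "B*02" = 0.5))
  lib <- build_library(list(make_line("L", "A*01", "A*02", "B*01", "B*02")))
  p <- tempfile(fileext = ".json")
  write_coverage_report(analytic_coverage(lib, h), lib, p)
  rep <- jsonlite::fromJSON(p)
  expect_equal(rep$method, "analytic")
  expect_equal(length(rep$library_fingerprint), 4L)
  expect_true(is.numeric(rep$coverage))
})
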