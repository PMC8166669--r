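test_that("frequency tables normalize with OTHER residual and reject excess mass", {
  ft <- frequency_table(c("A*01", "A*02"), c(0.3, 0.5), "POP", "A")
  expect_equal(attr(ft, "residual_other"), 0.2)
  expect_equal(sum(ft$frequency) + attr(ft, "residual_other"), 1, tolerance = 1e-12)
  expect_error(frequency_table(c("A*01", "A*02"), c(0.6, 0.6), "POP", "A"),
               "exceeds 1")
  expect_error(frequency_table(character(0), numeric(0), "POP", "A"), "empty")
  expect_error(frequency_table("A*01", -0.1, "POP", "A"), "nonnegative")
  expect_error(frequency_table("A*01", NaN, "POP", "A"), "finite")
})

test_that("duplicate names after resolution truncation are summed", {
  ft <- frequency_table(c("A*02:01", "A*02:06"), c(0.3, 0.2), "POP", "A",
                        resolution = 1)
  expect_equal(nrow(ft), 1L)
  expect_equal(ft$allele, "A*02")
  expect_equal(ft$frequency, 0.5)
  expect_equal(attr(ft, "residual_other"), 0.5)
})

test_that("the LE product haplotype table multiplies marginals, OTHER included", {
  f1 <- frequency_table("A*01", 1, "POP", "A")
  g1 <- frequency_table("B*01", 1, "POP", "B")
  h1 <- haplotypes_under_le(f1, g1)
  expect_equal(nrow(h1), 1L)
  expect_equal(h1$frequency, 1)

  fa <- frequency_table(c("A*01", "A*02"), c(0.5, 0.5), "POP", "A")
  fb <- frequency_table(c("B*01", "B*02"), c(0.5, 0.5), "POP", "B")
  h4 <- haplotypes_under_le(fa, fb)
  expect_equal(nrow(h4), 4L)
  expect_true(all(abs(h4$frequency - 0.25) < 1e-12))
  expect_identical(attr(h4, "provenance"), "product_LE")

  fr <- frequency_table("A*01", 0.7, "POP", "A")
  hr <- haplotypes_under_le(fr, g1)
  expect_equal(hr$frequency[hr$allele_A == "A*01"], 0.7)
  expect_equal(hr$frequency[hr$allele_A == "OTHER"], 0.3)
  expect_error(haplotypes_under_le(fb, fa), "A table and a B table")
  expect_warning(haplotypes_under_le(
    frequency_table("A*01", 1, "P1", "A"),
    frequency_table("B*01", 1, "P2", "B")), "population labels differ")
})

test_that("marginalizing the LE product recovers each input table exactly", {
  set.seed(13)
  for (i in 1:10) {
    fa <- synth_frequency_table(sample(3:8, 1), 0.7, seed = i, locus = "A",
                                residual_other = runif(1, 0, 0.3))
    fb <- synth_frequency_table(sample(3:8, 1), 0.7, seed = i + 100, locus = "B",
                                residual_other = runif(1, 0, 0.3))
    h <- haplotypes_under_le(fa, fb)
    expect_equal(sum(h$frequency), 1, tolerance = 1e-9)
    mA <- hemibank:::marginal_frequencies(h, "A")
    expect_equal(unname(mA[fa$allele]), fa$frequency, tolerance = 1e-12)
    mB <- hemibank:::marginal_frequencies(h, "B")
    expect_equal(unname(mB[fb$allele]), fb$frequency, tolerance = 1e-12)
  }
})

test_that("supplied haplotype tables normalize residual into OTHER/OTHER", {
  h <- haplotype_table(c("A*01", "A*02"), c("B*01", "B*02"), c(0.4, 0.3),
                       population = "POP")
  expect_equal(sum(h$frequency), 1, tolerance = 1e-12)
  expect_equal(h$frequency[h$allele_A == "OTHER" & h$allele_B == "OTHER"], 0.3)
  expect_error(haplotype_table("A*01", "B*01", 1.5, "POP"), "exceeds 1")
  expect_error(haplotype_table("A*01", "A*02", 1, "POP"), "locus B")
})

test_that("HWE genotype sampling is seeded, sized, and matches marginals", {
  f1 <- frequency_table("A*01", 1, "POP", "A")
  g1 <- frequency_table("B*01", 1, "POP", "B")
  h1 <- haplotypes_under_le(f1, g1)
  g <- sample_genotypes(h1, 5, seed = 1)
  expect_equal(nrow(g), 5L)
  expect_true(all(g$a1 == "A*01" & g$a2 == "A*01"))

  fa <- frequency_table(c("A*01", "A*02"), c(0.5, 0.5), "POP", "A")
  fb <- frequency_table(c("B*01", "B*02"), c(0.5, 0.5), "POP", "B")
  h <- haplotypes_under_le(fa, fb)
  s1 <- sample_genotypes(h, 1000, seed = 99)
  s2 <- sample_genotypes(h, 1000, seed = 99)
  expect_identical(s1, s2)

  n <- 100000
  s <- sample_genotypes(h, n, seed = 5)
  se <- sqrt(0.25 * 0.75 / (2 * n))
  for (k in seq_len(nrow(h))) {
    emp <- (sum(s$hap1 == k) + sum(s$hap2 == k)) / (2 * n)
    expect_lt(abs(emp - 0.25), 4 * se)
  }
  expect_error(sample_genotypes(h, 0, seed = 1), "n must be")
})

test_that("frequency and haplotype tables round-trip through TSV", {
  dir <- tempfile(); dir.create(dir)
  fa <- frequency_table(c("A*01", "A*02"), c(0.3, 0.5), "POP", "A")
  fp <- file.path(dir, "fa.tsv")
  writeLines(c("population\tlocus\tallele\tfrequency",
               "POP\tA\tA*01\t0.3", "POP\tA\tA*02\t0.5"), fp)
  expect_equal(read_frequency_table(fp)$frequency, fa$frequency)
  h <- haplotype_table(c("A*01", "A*02"), c("B*01", "B*02"), c(0.4, 0.3), "POP")
  hp <- file.path(dir, "h.tsv")
  write_haplotype_table(h, hp)
  back <- read_haplotype_table(hp)
  expect_equal(back$frequency, h$frequency)
  expect_equal(back$allele_A, h$allele_A)
})
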