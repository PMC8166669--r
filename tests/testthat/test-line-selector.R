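test_that("combo greedy reaches feasible thresholds and stops at infeasible ones", {
  h <- rand_hap_table(4, 4, seed = 11)
  lib <- build_library(rand_panel(h, 3, seed = 12))
  full <- analytic_coverage(lib, h)$coverage
  plan <- greedy_select_combos(lib, h, threshold = full)
  expect_true(plan$reached)
  expect_gte(plan$coverage, full - 1e-12)
  expect_true(all(plan$picks$id %in% paste(lib$allele_A, "/", lib$allele_B)))

  # tau = 1 with residual OTHER mass present is unreachable
  hres <- rand_hap_table(4, 4, seed = 13, residual = 0.15)
  lib2 <- build_library(rand_panel(hres, 3, seed = 14))
  plan2 <- greedy_select_combos(lib2, hres, threshold = 1)
  expect_false(plan2$reached)
  expect_true(all(plan2$picks$gain > 0))
  expect_error(greedy_select_combos(lib[0, ], h, 0.5), "empty candidate")
  expect_error(greedy_select_combos(lib, h, 0), "threshold")
})

test_that("greedy combo counts match the exhaustive minimum on small LE instances", {
  set.seed(29)
  ok <- 0L
  for (i in 1:10) {
    fa <- synth_frequency_table(4, 1, seed = 500 + i, locus = "A")
    fb <- synth_frequency_table(4, 1, seed = 600 + i, locus = "B")
    h <- haplotypes_under_le(fa, fb)
    pan <- rand_panel(h, 3, seed = 700 + i)
    lib <- build_library(pan)
    lib <- lib[seq_len(min(6L, nrow(lib))), ]
    if (oracle_coverage_enum(lib, h) < 0.5) next
    plan <- greedy_select_combos(lib, h, threshold = 0.5)
    kmin <- oracle_min_combos(lib, h, 0.5)
    expect_true(plan$reached)
    expect_gte(plan$n_combos, kmin)
    # greedy on coverage (a submodular objective) is near-optimal; on these
    # small instances it should in fact find the optimum
    expect_equal(plan$n_combos, kmin)
    ok <- ok + 1L
  }
  expect_gte(ok, 5L)  # enough feasible instances actually exercised
})

test_that("line greedy skips redundant lines and prunes zero-gain combos", {
  h <- rand_hap_table(4, 4, seed = 21)
  l1 <- rand_panel(h, 1, seed = 22)[[1]]
  dup <- cell_line("ZZ_dup", A = vapply(l1$genotypes$A$alleles, format, ""),
                   B = vapply(l1$genotypes$B$alleles, format, ""),
                   DRB1 = c("DRB1*04", "DRB1*15"))
  full <- analytic_coverage(build_library(list(l1)), h)$coverage
  plan <- greedy_select_lines(list(l1, dup), h, threshold = full)
  expect_true(plan$reached)
  expect_equal(plan$n_lines, 1L)
  expect_false("ZZ_dup" %in% plan$picks$id)
  expect_lte(plan$n_combos, 4L)
  # pruned combos reproduce the plan's coverage exactly
  expect_equal(analytic_coverage(plan$combos, h, resolution = 1)$coverage,
               plan$coverage, tolerance = 1e-12)
})

test_that("greedy line plans respect the exhaustive oracle and submodularity", {
  for (i in 1:8) {
    h <- rand_hap_table(4, 4, seed = 900 + i, residual = 0.05)
    pan <- rand_panel(h, 5, seed = 950 + i)
    full <- analytic_coverage(build_library(pan), h)$coverage
    tau <- 0.8 * full
    orc <- exhaustive_min_lines(pan, h, tau)
    plan <- greedy_select_lines(pan, h, tau)
    expect_true(orc$feasible)
    expect_true(plan$reached)
    expect_gte(plan$n_lines, orc$n_min)
    expect_gte(plan$coverage, tau - 1e-12)
    # marginal line gains are nonincreasing along the greedy order
    expect_true(all(diff(plan$picks$gain) <= 1e-9))
    # cumulative coverage is nondecreasing
    expect_true(all(diff(c(0, plan$picks$cumulative)) >= -1e-12))
  }
})

test_that("plans are deterministic and exportable", {
  h <- rand_hap_table(5, 5, seed = 61)
  pan <- rand_panel(h, 4, seed = 62)
  p1 <- design_bank(pan, h, threshold = 0.6)
  p2 <- design_bank(pan, h, threshold = 0.6)
  expect_identical(p1$picks, p2$picks)
  pc <- design_bank(pan, h, threshold = 0.6, strategy = "combo")
  expect_identical(pc$strategy, "combo_greedy")
  expect_gte(pc$coverage, min(0.6, p1$coverage) - 1e-9)
  out <- tempfile(fileext = ".json")
  write_plan(p1, out)
  js <- jsonlite::fromJSON(out)
  expect_equal(js$n_lines, p1$n_lines)
  expect_equal(js$threshold, 0.6)
})

test_that("the exhaustive oracle validates its own guarantees", {
  h <- rand_hap_table(3, 3, seed = 71, residual = 0.1)
  pan <- rand_panel(h, 4, seed = 72)
  full <- analytic_coverage(build_library(pan), h)$coverage
  res <- exhaustive_min_lines(pan, h, threshold = full)
  expect_true(res$feasible)
  sub <- pan[match(res$lines, vapply(pan, function(l) l$line_id, ""))]
  expect_gte(analytic_coverage(build_library(sub), h)$coverage, full - 1e-12)
  inf <- exhaustive_min_lines(pan, h, threshold = 1)
  expect_false(inf$feasible)
  expect_error(exhaustive_min_lines(pan, h, threshold = -1), "threshold")
  expect_error(exhaustive_min_lines(pan, h, 0.5, max_panel = 2), "max_panel")
})
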