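GAIN_TOL <- 1e-15

## Incremental coverage state shared by the greedy searches. `add` folds a
## combo's indicator into the matched set; `gain` is its marginal coverage.
coverage_state <- function(h, level) {
  p <- h$frequency
  n <- nrow(h)
  if (level == "haplotype") {
    hit <- rep(FALSE, n)
    cov_of <- function(v) 1 - (1 - sum(p[v]))^2
    union_gain <- function(ind) {
      hit2 <- hit
      for (m in ind) hit2 <- hit2 | (m$mA & m$mB)
      cov_of(hit2) - cov_of(hit)
    }
    list(gain = function(m) union_gain(list(m)),
         union_gain = union_gain,
         add = function(m) hit <<- hit | (m$mA & m$mB),
         coverage = function() cov_of(hit))
  } else {
    P <- outer(p, p)
    M <- matrix(FALSE, n, n)
    pair_mat <- function(m) outer(m$mA, m$mA, `|`) & outer(m$mB, m$mB, `|`)
    union_gain <- function(ind) {
      Mu <- M
      for (m in ind) Mu <- Mu | pair_mat(m)
      sum(P[Mu & !M])
    }
    list(gain = function(m) union_gain(list(m)),
         union_gain = union_gain,
         add = function(m) M <<- M | pair_mat(m),
         coverage = function() sum(P[M]))
  }
}

check_threshold <- function(threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]", call. = FALSE)
}

new_plan <- function(strategy, threshold, picks, reached, n_lines, n_combos,
                     coverage, resolution, population, level, combos) {
  structure(list(strategy = strategy, threshold = threshold, picks = picks,
                 reached = reached, n_lines = n_lines, n_combos = n_combos,
                 coverage = coverage, resolution = resolution,
                 population = population, level = level, combos = combos),
            class = "hemibank_plan")
}

## Greedy hitting of chosen combos by source lines: repeatedly take the line
## covering the most still-unhit combos (ties lexicographic by line_id).
min_hitting_lines <- function(sources) {
  if (length(sources) == 0L) return(character(0L))
  chosen <- character(0L)
  unhit <- rep(TRUE, length(sources))
  while (any(unhit)) {
    lines <- sort(unique(unlist(sources[unhit])))
    cnt <- vapply(lines, function(l)
      sum(vapply(sources[unhit], function(s) l %in% s, logical(1L))), 0L)
    pick <- lines[which.max(cnt)]
    chosen <- c(chosen, pick)
    unhit <- unhit & !vapply(sources, function(s) pick %in% s, logical(1L))
  }
  chosen
}

#' Greedy combo selection to a coverage threshold
#'
#' Repeatedly adds the candidate combo with the largest marginal coverage
#' gain (ties broken lexicographically by the (A, B) key) until cumulative
#' coverage reaches the threshold or no combo contributes a positive gain.
#' The number of parental lines needed is the greedy minimal hitting of the
#' chosen combos' source sets.
#'
#' @param candidates A \code{"combo_library"}.
#' @param h A normalized \code{"haplotype_table"}.
#' @param threshold Target coverage in (0, 1]; reaching it is tested with
#'   \code{>=} (a printed bound like ">90\%" maps to 0.90 inclusive).
#' @param resolution Field resolution; defaults to the library's.
#' @param level Matching level, as in [analytic_coverage()].
#' @return A \code{"hemibank_plan"} with strategy \code{"combo_greedy"}.
#' @export
greedy_select_combos <- function(candidates, h, threshold, resolution = NULL,
                                 level = c("genotype", "haplotype")) {
  level <- match.arg(level)
  check_threshold(threshold)
  check_normalized(h)
  if (nrow(candidates) == 0L) stop("empty candidate set", call. = FALSE)
  if (is.null(resolution)) resolution <- attr(candidates, "resolution")
  ord <- order(candidates$allele_A, candidates$allele_B)
  candidates <- lib_subset(candidates, ord)
  keys <- combo_key(candidates$allele_A, candidates$allele_B)
  ind <- combo_indicators(candidates, h, resolution)
  st <- coverage_state(h, level)
  avail <- rep(TRUE, length(ind))
  picks <- data.frame(id = character(0L), gain = numeric(0L),
                      cumulative = numeric(0L), stringsAsFactors = FALSE)
  C <- 0
  while (C < threshold - 1e-12 && any(avail)) {
    gains <- rep(-Inf, length(ind))
    gains[avail] <- vapply(which(avail), function(j) st$gain(ind[[j]]), 0)
    j <- which.max(gains)
    if (gains[j] <= GAIN_TOL) break
    st$add(ind[[j]])
    C <- st$coverage()
    avail[j] <- FALSE
    picks <- rbind(picks, data.frame(id = keys[j], gain = gains[j],
                                     cumulative = C, stringsAsFactors = FALSE))
  }
  chosen <- lib_subset(candidates, match(picks$id, keys))
  n_lines <- length(min_hitting_lines(chosen$sources))
  new_plan("combo_greedy", threshold, picks, reached = C >= threshold - 1e-12,
           n_lines = n_lines, n_combos = nrow(picks), coverage = C,
           resolution = resolution, population = attr(h, "population"),
           level = level, combos = chosen)
}

#' Greedy line selection to a coverage threshold
#'
#' Greedy over parental lines: a line's gain is the coverage gained by
#' adding all of its hemizygous combos at once (ties broken by line_id).
#' After line selection each chosen line's combos are pruned, in pick order,
#' to those with a positive marginal gain — yielding the number of distinct
#' engineered lines (combos) the bank actually needs.
#'
#' @param panel List of \code{"cell_line"} with unique ids.
#' @param h A normalized \code{"haplotype_table"}.
#' @param threshold Target coverage in (0, 1], reached with \code{>=}.
#' @param resolution Field resolution for combo identity.
#' @param level Matching level, as in [analytic_coverage()].
#' @return A \code{"hemibank_plan"} with strategy \code{"line_greedy"}.
#' @export
greedy_select_lines <- function(panel, h, threshold, resolution = 1L,
                                level = c("genotype", "haplotype")) {
  level <- match.arg(level)
  check_threshold(threshold)
  check_normalized(h)
  if (length(panel) == 0L) stop("empty panel", call. = FALSE)
  ids <- vapply(panel, function(l) l$line_id, character(1L))
  panel <- panel[order(ids)]
  ids <- sort(ids)
  libs <- lapply(panel, enumerate_combos, resolution = resolution)
  inds <- lapply(libs, combo_indicators, h = h, resolution = resolution)
  st <- coverage_state(h, level)
  avail <- rep(TRUE, length(panel))
  picks <- data.frame(id = character(0L), gain = numeric(0L),
                      cumulative = numeric(0L), stringsAsFactors = FALSE)
  C <- 0
  while (C < threshold - 1e-12 && any(avail)) {
    gains <- rep(-Inf, length(panel))
    for (j in which(avail))
      gains[j] <- st$union_gain(inds[[j]])
    j <- which.max(gains)
    if (gains[j] <= GAIN_TOL) break
    for (m in inds[[j]]) st$add(m)
    C <- st$coverage()
    avail[j] <- FALSE
    picks <- rbind(picks, data.frame(id = ids[j], gain = gains[j],
                                     cumulative = C, stringsAsFactors = FALSE))
  }
  ## prune chosen lines' combos to positive-marginal ones, in pick order
  st2 <- coverage_state(h, level)
  kept <- list()
  for (id in picks$id) {
    j <- match(id, ids)
    for (ci in seq_along(inds[[j]])) {
      g <- st2$gain(inds[[j]][[ci]])
      if (g > GAIN_TOL) {
        st2$add(inds[[j]][[ci]])
        kept[[length(kept) + 1L]] <- as.data.frame(libs[[j]])[ci, , drop = FALSE]
      }
    }
  }
  combos <- if (length(kept)) {
    out <- do.call(rbind, kept)
    rownames(out) <- NULL
    structure(out, resolution = as.integer(resolution),
              class = c("combo_library", "data.frame"))
  } else lib_subset(libs[[1L]], integer(0L))
  new_plan("line_greedy", threshold, picks, reached = C >= threshold - 1e-12,
           n_lines = nrow(picks), n_combos = nrow(combos), coverage = C,
           resolution = resolution, population = attr(h, "population"),
           level = level, combos = combos)
}

#' Smallest line subset reaching a threshold (exhaustive oracle)
#'
#' Searches subsets of the panel in increasing cardinality and returns the
#' first whose combined combo library reaches the coverage threshold.
#' Exponential; intended as a test oracle for small panels.
#'
#' @param panel List of \code{"cell_line"} (at most \code{max_panel}).
#' @param h A normalized \code{"haplotype_table"}.
#' @param threshold Target coverage in (0, 1].
#' @param resolution Field resolution.
#' @param level Matching level.
#' @param max_panel Guard on panel size (default 15).
#' @return List with \code{feasible} (logical), \code{n_min} (count or NA)
#'   and \code{lines} (ids of one witness subset, or NULL).
#' @export
exhaustive_min_lines <- function(panel, h, threshold, resolution = 1L,
                                 level = c("genotype", "haplotype"),
                                 max_panel = 15L) {
  level <- match.arg(level)
  check_threshold(threshold)
  if (length(panel) > max_panel)
    stop("panel larger than max_panel = ", max_panel, call. = FALSE)
  ids <- vapply(panel, function(l) l$line_id, character(1L))
  for (k in seq_along(panel)) {
    subs <- utils::combn(length(panel), k, simplify = FALSE)
    for (s in subs) {
      lib <- build_library(panel[s], resolution = resolution)
      C <- analytic_coverage(lib, h, resolution, level)$coverage
      if (C >= threshold - 1e-12)
        return(list(feasible = TRUE, n_min = k, lines = ids[s]))
    }
  }
  list(feasible = FALSE, n_min = NA_integer_, lines = NULL)
}

#' Design a hemizygous haplobank for a population
#'
#' The package's central fitting routine: from a panel of heterozygous
#' parental lines and a population haplotype model, greedily selects the
#' lines (or combos) whose engineered hemizygous products reach a coverage
#' threshold, and returns the ordered plan with its cumulative coverage
#' curve.
#'
#' @param panel List of \code{"cell_line"}.
#' @param h A normalized \code{"haplotype_table"}.
#' @param threshold Target coverage in (0, 1] (default 0.9).
#' @param strategy \code{"line"} (default; greedy over parental lines, then
#'   combo pruning) or \code{"combo"} (greedy over individual combos).
#' @param resolution Field resolution for matching (default 1).
#' @param level Matching level, as in [analytic_coverage()].
#' @return A \code{"hemibank_plan"}; see [greedy_select_lines()] /
#'   [greedy_select_combos()] for the fields.
#' @examples
#' fa <- frequency_table(c("A*01", "A*02", "A*03"), c(0.4, 0.35, 0.2), "POP", "A")
#' fb <- frequency_table(c("B*01", "B*02", "B*03"), c(0.5, 0.3, 0.15), "POP", "B")
#' h <- haplotypes_under_le(fa, fb)
#' pan <- list(
#'   cell_line("L1", c("A*01", "A*02"), c("B*01", "B*02"), c("DRB1*04", "DRB1*07")),
#'   cell_line("L2", c("A*01", "A*03"), c("B*01", "B*03"), c("DRB1*01", "DRB1*13")))
#' design_bank(pan, h, threshold = 0.5)
#' @export
design_bank <- function(panel, h, threshold = 0.9,
                        strategy = c("line", "combo"), resolution = 1L,
                        level = c("genotype", "haplotype")) {
  strategy <- match.arg(strategy)
  level <- match.arg(level)
  if (strategy == "line")
    greedy_select_lines(panel, h, threshold, resolution, level)
  else
    greedy_select_combos(build_library(panel, resolution), h, threshold,
                         resolution, level)
}

#' @export
print.hemibank_plan <- function(x, ...) {
  cat(sprintf("Haplobank selection plan (%s, population %s)\n",
              x$strategy, x$population))
  cat(sprintf("  threshold %.3f: %s (final coverage %.4f)\n", x$threshold,
              if (x$reached) "reached" else "NOT reached", x$coverage))
  cat(sprintf("  %d parental line(s), %d engineered combo(s)\n",
              x$n_lines, x$n_combos))
  invisible(x)
}

#' @export
summary.hemibank_plan <- function(object, ...) {
  print(object)
  cat("Picks (in greedy order):\n")
  print.data.frame(object$picks, digits = 4)
  invisible(object)
}

#' @export
coef.hemibank_plan <- function(object, ...) {
  stats::setNames(object$picks$cumulative, object$picks$id)
}

#' Plot the cumulative coverage curve of a plan
#'
#' @param x A \code{"hemibank_plan"}.
#' @param ... Passed to [graphics::plot()].
#' @return \code{x}, invisibly.
#' @export
plot.hemibank_plan <- function(x, ...) {
  k <- seq_len(nrow(x$picks))
  graphics::plot(c(0, k), c(0, x$picks$cumulative), type = "s",
                 xlab = "picks", ylab = "cumulative coverage",
                 ylim = c(0, 1), ...)
  graphics::abline(h = x$threshold, lty = 2)
  invisible(x)
}

#' Export a selection plan to JSON
#'
#' @param plan A \code{"hemibank_plan"}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_plan <- function(plan, path) {
  out <- list(strategy = plan$strategy, threshold = plan$threshold,
              picks = plan$picks, reached = plan$reached,
              n_lines = plan$n_lines, n_combos = plan$n_combos,
              coverage = plan$coverage, resolution = plan$resolution,
              population = plan$population, level = plan$level)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
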