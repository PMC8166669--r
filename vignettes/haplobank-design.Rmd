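---
title: "Designing HLA hemizygous haplobanks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing HLA hemizygous haplobanks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemibank)
```

## The matching model

A bank line engineered by mono-allelic knockout of *HLA-A* and *HLA-B* (and
bi-allelic knockout of *HLA-DRB1*) expresses exactly one A antigen `a` and
one B antigen `b`. In the host-versus-graft direction such a graft presents
nothing foreign to any recipient who carries `a` and `b` anywhere in their
diplotype; the recipient's remaining alleles are irrelevant, which is what
makes a hemizygous line "homozygous-like". The package's default match rule
is therefore **genotype-level**: combo `(a, b)` matches a recipient with
haplotypes `(a1, b1), (a2, b2)` iff `a ∈ {a1, a2}` and `b ∈ {b1, b2}` —
cross-haplotype carriage counts. A stricter **haplotype-level** rule
(`level = "haplotype"`), under which one recipient haplotype must equal
`(a, b)` outright, is provided for sensitivity analysis; it can only lower
coverage, and in our view over-restricts what the biology requires, which
is why it is not the default.

Recipients are modeled by Hardy–Weinberg equilibrium: an individual is two
independent draws from the population's A–B haplotype distribution
`p(h)`. Coverage of a library `L` is

$$C(L) = \sum_{h_1, h_2} p(h_1)\, p(h_2)\; \mathbf 1\left[\exists\,(a,b)
\in L:\; a \in \{a_1, a_2\},\ b \in \{b_1, b_2\}\right].$$

This is computed **exactly** by enumerating ordered haplotype pairs with a
per-combo indicator cache — `O(|H|^2 \cdot |L|)` time and `O(|H|^2)`
memory. We chose enumeration over inclusion–exclusion because the latter
is exponential in `|L|`; inclusion–exclusion survives in the test suite as
an independent oracle for libraries of up to four combos. The practical
envelope is a few thousand haplotypes and on the order of a hundred
combos, comfortably within a minute on one core; test and acceptance runs
use 3–12 alleles per locus (10–150 haplotypes) so the whole suite stays
fast.

## Population input modes

Published HLA data come in two forms, and the package ingests both,
stamping every table with its `provenance`:

* **allele frequencies + linkage equilibrium** (`haplotypes_under_le()`):
  `p(a, b) = f_a f_b`. Simple and always available, but real A–B linkage
  disequilibrium is strong, so LE-derived coverage should be treated as an
  approximation.
* **supplied haplotype frequencies** (`read_haplotype_table()`): the
  preferred mode when a population's A–B haplotype table exists.

Frequency mass not assigned to a named allele becomes the reserved
pseudo-allele `OTHER` (for supplied haplotype tables, the pseudo-haplotype
`(OTHER, OTHER)`). `OTHER` can never be matched by a bank line, so all
reported coverage is an **understatement** — the conservative direction
for bank planning. Raw masses exceeding 1 (beyond a `1e-6` tolerance) are
an error rather than being rescaled: silent rescaling hides data-entry
mistakes. Normalized tables sum to 1 within `1e-9`, and marginalizing an
LE product recovers its inputs to `1e-12`.

## Allele resolution

All matching happens at an explicit **field resolution**. The default is
one field (`A*33`, serological-level subtypes), because banking decisions
are made at the antigen level at which donor registries report matches;
two-field names (`A*33:03`) are parsed, preserved and usable by setting
`resolution = 2` everywhere. Truncation keeps leading fields, drops the
expression suffix when fields are removed, and is idempotent; equality at
a fine resolution implies equality at every coarser one, so coarsening a
model can only merge alleles and never decreases coverage. Expression
suffixes (N, L, ...) are parsed but ignored for matching — the package
does not model null-allele biology.

## Greedy bank design

Coverage is a monotone **submodular** set function of the library (adding
a combo helps less the more is already covered), so the classical greedy
heuristic is the natural selection engine and carries the usual
`1 − 1/e` approximation guarantee for a fixed budget. Two strategies are
exposed because a bank can be counted in two units:

* `strategy = "combo"`: greedy over individual combos; the parental-line
  count is then the greedy minimal hitting of the chosen combos' source
  sets.
* `strategy = "line"` (default): greedy over parental lines, a line's gain
  being the joint gain of all four of its products; chosen lines' combos
  are then pruned, in pick order, to those with positive marginal gain.
  This directly yields both numbers a banking program needs — how many
  parental lines to edit and how many engineered clones to maintain — and
  is therefore the default.

Ties are broken lexicographically (by `(a, b)` key or by `line_id`), so
plans are deterministic. A coverage threshold `τ` is met inclusively
(`C ≥ τ`): a target stated as "more than 90%" maps to `τ = 0.90`.
Selection stops at the first prefix reaching `τ` or when no candidate adds
positive gain (within `1e-15`); `reached = FALSE` plans are returned, not
errors, since `τ = 1` is unattainable whenever `OTHER` mass exists.
`exhaustive_min_lines()` searches subsets in increasing cardinality and is
the optimality oracle for panels of ≤ 15 lines; the test suite checks
greedy feasibility and counts against it on random instances.

## Guide design

Subtype-specific knockouts need Cas9 guides that cut the targeted allele
but not the retained one. `find_protospacers()` enumerates standard SpCas9
sites: 20-nt spacer, NGG PAM, cut site 3 nt 5′ of the PAM, both strands,
0-based half-open coordinates on the plus strand. A site discriminates
(`discriminating_guides()`) when the aligned counterpart in the spared
allele differs in the **seed** — defined here as the ten PAM-proximal
spacer nucleotides plus the PAM GG, the region where single mismatches
most reliably abolish cleavage — or is disrupted by an alignment gap; in
addition the exact 20-mer must not occur perfectly anywhere in the spared
sequence on either strand. These thresholds (`min_seed_mismatches = 1`,
10-nt seed) are standard SpCas9 practice and are exposed as parameters; no
on-target efficiency scoring or genome-wide off-target search is included,
as mature external tools handle those. `N` bases never count as matching
and disqualify PAM GG positions — the conservative reading for ambiguous
reference bases. For bi-allelic targets (e.g. *DRB1*), `mode = "shared"`
returns sites perfectly identical in both alleles. Alignments are taken
from input when pre-aligned FASTA is supplied and otherwise built with a
global pairwise alignment.

## Edit quantification

Amplicon sequencing of edited clones is summarized in the dash/lowercase
pattern notation: dashes in the observed read are deletions, lowercase
letters opposite reference gaps are insertions, uppercase mismatches are
substitutions. `classify_indel()` calls a **frameshift iff the net length
change is not a multiple of 3**; a frameshift introduces a premature stop
and the transcript is lost to nonsense-mediated decay, so frameshifted
alleles are counted as knockouts. Premature-stop detection from translated
sequence (e.g. a large in-frame deletion removing a start codon) is
deliberately out of scope; in-frame indels are assumed to retain
expression and trigger a warning rather than a knockout call.
`knockout_call()` produces the genotype labels used for clone bookkeeping
(`A02/-`, `D-/-`, `A+/+`; ASCII hyphens).

Proliferation readouts are reduced to a **mitotic index** from a division
histogram `n_g` (cells observed in generation `g`): the absolute precursor
count is `P = Σ n_g 2^{-g}` and the mitotic events are
`M = Σ n_g (1 − 2^{-g})`, giving index `M / P` — 0 for an undivided
population, 1 when all cells divided once, 3 at two divisions. The
generation-histogram formulation is this package's own reconstruction of
the events-per-precursor ratio; deriving generations from dye-dilution
intensity (peak deconvolution) is upstream of this module and out of
scope.

## Synthetic data

`synth_frequency_table()` draws allele frequencies from a symmetric
Dirichlet; the default concentration 0.5 produces the skewed spectra
(a few dominant alleles, a long tail) characteristic of real HLA loci.
`synth_haplotype_table()` offers `independent` (LE product) and
`dirichlet_joint` (one Dirichlet over the A×B grid, inducing nonzero LD)
modes; `synth_line_panel()` draws heterozygous candidate lines from the
haplotype model under HWE, conditioned on fully named types;
`synth_allele_pair()` plants substitutions and gaps at recorded positions
around a guaranteed protospacer site, returning ground truth alongside the
data so tests assert against the plan, never against re-inference. Every
generator takes an explicit integer seed and is bit-reproducible.

What the generator does **not** emulate: actual population frequency
values (no attempt is made to imitate any published table), coalescent or
mutational realism, typing ambiguity or errors, and editing-efficiency or
clone-viability variation. Passing tests therefore demonstrate the
correctness of the computations under the stated model — not that any
particular real population reaches a particular coverage; real studies
must supply their own frequency tables and line registries through the
TSV interfaces.

## Numerical choices, degenerate inputs, limitations

* Tolerances: table normalization `1e-6` on input, `1e-9` as invariant,
  `1e-12` for exact-agreement tests; greedy positive-gain cutoff `1e-15`;
  threshold comparisons use `1e-12` slack so `τ` equal to an achievable
  coverage counts as reached.
* Degenerate inputs are first-class: single-haplotype tables, homozygous
  lines (1 combo), empty libraries (coverage 0), duplicate lines
  (rejected), duplicate combos in ordered curves (rejected).
* Monte Carlo results carry `SE = sqrt(C(1−C)/n)`; analytic and Monte
  Carlo routes agree within 4 SE by construction of both, which the test
  suite verifies end to end on synthetic pipelines.
* The exact engine's `O(|H|^2)` memory bounds practical haplotype-table
  size to a few thousand rows; beyond that, pre-aggregate alleles to a
  coarser resolution or collapse rare haplotypes into `OTHER`.
* Greedy plans are near-optimal, not provably minimal; for ≤ 15 lines the
  exhaustive oracle certifies minimality.
* Only HLA-A, -B and -DRB1 are modeled (the loci edited in the banking
  strategy); HLA-C/DQ/DP, minor histocompatibility antigens, KIR-ligand
  and NK-licensing effects are outside the model.
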