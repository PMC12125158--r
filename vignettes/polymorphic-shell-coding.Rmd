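---
title: "From polymorphic individuals to species-level parsimony: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From polymorphic individuals to species-level parsimony: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shellphylo)
```

## The problem

Morphological characters of skeletal material — the worked example throughout
this package is the shell of soft-shelled turtles (Trionychidae) — are scored
on *individuals*, but phylogenetic matrices are built from *species*. The two
are separated by three confounds:

* **Intraspecific polymorphism.** Many osteological characters vary within a
  species through ordinary phenotypic plasticity; a terminal scored with every
  state ever observed carries little signal.
* **Ontogeny.** Dermal ossifications (callosities) grow throughout life, so a
  juvenile genuinely lacks structures that define its species' adult
  morphology. Adult-biased museum samples mitigate but do not remove this.
* **Measurement uncertainty.** Morphometric characters are discretized
  continuous quantities; specimens near a bin threshold are not confidently
  assignable to one state.

`shellphylo` implements a complete, auditable route from an individual-level
NEXUS matrix to species-level codings and their phylogenetic evaluation:
an ontogenetic screen, two polymorphism-reduction strategies, a parsimony
engine for set-valued terminals, and quartet-based accuracy scores against a
reference topology.

## The ontogenetic screen

Relative skeletal maturity of a specimen is its straight carapace length as a
percentage of the largest documented individual of its species
(`relative_maturity()`); specimens known only as a size range enter at the
midpoint of the estimate. For each character, `scc()` computes the Spearman
rank-order correlation (SCC) between individual scores and maturity as
*average ranks followed by a product-moment correlation of the rank vectors*
— the tie-corrected Spearman, identical to the spreadsheet recipe of ranking
with `RANK.AVG` and correlating with `CORREL`. Polymorphic cells enter as the
arithmetic mean of their states (the least information-destroying
scalarization: `0/1` becomes 0.5). Correlation magnitudes are banded as
absent [0, 0.25), weak [0.25, 0.5), moderate [0.5, 0.75) and strong
[0.75, 1], with the sign carried separately; boundary values go to the upper
band because the verbal definitions of the bands overlap at their endpoints
and a half-open convention is required. No significance test is attached: the
screen is a triage device deciding which characters are coded from mature
individuals, not an inferential claim.

## Species coding: MinPoly and MaxPoly

`code_species()` produces the primary, polymorphism-reduced terminal set
("MinPoly") and a maximal-polymorphism alternative ("MaxPoly", the plain
union of observed states). The MinPoly rules, per species and character:

1. **Inclusion.** Missing and inapplicable observations never count;
   observations flagged abnormal (asymmetries, split or supernumerary
   elements) are excluded by default. For characters where absence of the
   substrate is itself the primitive state, inapplicable scores can be folded
   into state 0 (`inapplicable_to_zero`) so that analysis software cannot
   conflate "element absent" with "no data".
2. **Frequency filter.** A state is retained when more than 20% of included
   individuals *display* it — a polymorphic individual displays every state
   in its cell, counting fully toward each, so display fractions may sum past
   one. The strict ">" comparator is the default (one displaying individual
   out of five is exactly 20% and is suppressed); an "at least" comparator is
   available. If nothing passes, the single modal state survives (smallest
   label on ties, a deterministic tie-break).
3. **Maturity rule.** For ontogeny-controlled characters, candidate states
   are the union over the most skeletally mature individuals — the top decile
   of relative maturity with a floor of 3 specimens (the notion "most
   skeletally mature individuals" has no published quantification; the top
   decile-with-floor is this package's choice and is configurable). A
   candidate is retained when it passes the frequency filter over *all*
   included individuals — a 20% threshold is a statement about the species
   sample; three specimens cannot support it — **and** is corroborated
   within the mature subset, i.e. displayed by at least two similarly mature
   adults or by the single most mature individual itself. If no candidate
   survives, the subset's modal state is used. This keeps juvenile-only
   states out of the coding while still scoring a species polymorphic when
   similarly sized adults straddle a threshold.
4. **Overrides.** Taxon-specific exceptions (e.g., forcing a state the rules
   would suppress, when suppression would render an otherwise-clean character
   uninformative) are declarative `(species, character, states, rationale)`
   records applied last and logged. An empty override list reproduces pure
   rule-based coding; the per-cell audit log records which rule fired and how
   many specimens it used.

Morphometric characters are discretized by `discretize_measurement()`: the
base state is the bin containing the value, and a value within the
character's margin of a bin edge is scored with both flanking states (a
nuchal-callosity width of 53% against edges 30/50/70 and a 3-point margin
scores `1/2`). Values outside the outer bins clamp to the extreme states;
margins must be smaller than half the narrowest bin, so at most one edge can
ever be within range.

Two derived characters (formation pathway and closure timing of the
suprascapular fontanelles) cannot be scored specimen-by-specimen; they are
extracted from a deactivated helper observation column by
`derive_fontanelle_characters()` — pathway as the mode of first-contact
observations, closure as the minimum relative maturity among
closed-fontanelle specimens banded at 30/70% of adult size, with the printed
"never or rarely closes" label 4 used for species whose large adults stay
open.

## The parsimony engine

Terminals are state *sets*: polymorphic cells use uncertainty semantics (the
tip may be assigned any member of its set — the treatment TNT applies to
bracketed states), and missing/inapplicable tips are the full set. Unordered
characters are scored by set-valued Fitch passes, ordered morphoclines by a
Sankoff dynamic programme with linear `|i - j|` costs; both cores are
compiled, cross-validate each other on binary columns, and are checked in the
test suite against brute-force enumeration of internal labelings and against
an independent parsimony implementation.

`heuristic_search()` repeats random-addition-sequence tree building followed
by branch swapping to a local optimum. The default neighborhood is TBR (every
branch cut, fragments rejoined across all edge pairs; this includes all SPR
and NNI moves — requesting `"spr"` therefore runs the TBR neighborhood, and
`"nni"` is the cheap fallback). After the replicates, the optimum's
neighborhood is expanded to closure so that all equal-score trees reachable
by swapping are collected, up to the tree buffer. Implied weighting
optimizes `sum h/(h+K)` directly, where `h = s - m` is a character's extra
steps over its minimum conceivable steps `m` (minimum hitting set of the tip
sets minus one for unordered characters, the span between the largest lower
bound and smallest upper bound for ordered ones); the equal-weights length of
the optima is reported alongside. Before trees are counted, branches whose
minimum optimal length is zero are collapsed (contracting the branch leaves
the score unchanged), so resolution never rests on unsupported edges;
because addition order is randomized, optimal-tree *counts* are
reproducible only per seed and are reported rather than asserted against.

Searches are bit-reproducible given `rng_seed`. Defaults (`n_ras = 10`,
`tree_buffer = 1000`) are sized for matrices of tens of taxa; study-scale
settings for a full empirical matrix (1000 replicates, 40,000-tree buffer)
are plain parameter changes.

`root_by_clade()` performs secondary rooting of an unrooted optimum so that a
named group (e.g., one of the two primary subfamilies) is monophyletic,
erroring informatively when no edge separates the group. `strict_consensus()`
retains exactly the shared bipartitions.

## Quartet accuracy

`compare_quartets()` classifies every four-taxon subset by the pair of
induced subtree topologies: resolved identically (s), resolved differently
(d), resolved in only one tree (r1/r2), or unresolved in both (u). Strict
Joint Assertions, `sja = s/(s + d)`, is the fraction of jointly resolved
quartets that agree; it is undefined (and flagged) when no quartet is
resolved in both trees. Rooting is ignored — quartets are unrooted objects —
and comparisons are made after pruning any outgroup taxa. Enumeration is
direct: at 29 terminals there are only `Q = choose(29, 4) = 23751` quartets,
so the O(n⁴) loop is instant and its simplicity doubles as its own oracle;
the test suite additionally checks it against a per-quartet brute-force
checker built on tree pruning and path distances. `average_over_mpts()`
reports the arithmetic mean of per-tree values (mean of ratios, not ratio of
means): the per-tree sja is the defined metric, and averages over an
optimal-tree set are descriptive summaries of it. The mean number of
conflicting quartets reported is strictly category d; the full category
breakdown is always available so alternative readings can be tallied.

## The synthetic-data generator

Because the deposited specimen-level data of any one study cannot stand in
for a correctness argument, every stage is validated on generated data with
known ground truth (`simulate_morph_dataset()`):

* a random binary species tree (uniform over labelled topologies);
* unordered characters evolving under a symmetric k-state Markov jump per
  branch, ordered characters under a nearest-neighbour (±1) walk that
  respects the morphocline — a branch draw never moves a state by two;
  per-character change probabilities are drawn from a range, yielding a mix
  of clean and homoplastic columns;
* per-species individuals with relative maturities drawn Uniform[30, 100] —
  mimicking adult-biased osteological collections, which strongly
  undersample juveniles;
* ontogeny-controlled characters expressed as a threshold step function:
  the juvenile state (the morphocline origin, "structure not yet formed")
  below a maturity threshold (default 60%), the species' adult state above
  it. A continuous ontogenetic gradation through every intermediate state is
  deliberately *not* simulated: it would make subadults legitimate displayers
  of adult-adjacent states at ~40% frequency, turning the 20% filter
  inoperative by construction rather than by biology;
* minority-state polymorphism: with the configured per-cell rate (default
  10%), an individual displays a random neighbouring state alongside its
  true state, so the expected display fraction of any minority state sits
  below the 20% filter;
* morphometric characters emitting a continuous measurement (bin centre plus
  Gaussian noise) re-binned through `discretize_measurement()`, so
  edge-straddling polymorphism arises the same way it does in real
  measurement series;
* missing data and rare abnormal individuals with flagged aberrant scores.

What passing these simulations shows — and what it does not: the pipeline
recovers known codings and topologies under controlled polymorphism, missing
data and ontogenetic confounding; it does not certify performance under
correlated characters, heterogeneous sampling across species, sexual
dimorphism (negligible for this system and not simulated) or
taxonomically misassigned specimens.

## Study conditions used by the tests and the acceptance script

Problem sizes were chosen so each check is decisive yet runs in minutes:

* *Search oracle*: 100 random matrices (7–8 taxa, 10 characters, mixed
  ordered/unordered, ~10% polymorphic cells) against exhaustive enumeration
  over all 945 / 10,395 unrooted binary topologies.
* *Quartet oracle*: 100 random tree pairs (6–10 leaves, random polytomies)
  against the brute-force per-quartet checker.
* *Rank correlation*: exact agreement (1e-12) with the classical
  `1 - 6Σd²/(n(n²-1))` formula on tie-free data and with a naive
  average-rank oracle on tied data.
* *Coding recovery*: 100 replicates of 8 species × 20 characters, 20
  individuals per species, 10% minority polymorphism, 5% missingness,
  adult-biased maturity; MinPoly must recover ≥95% of true cells
  (measured ≈96%) and MaxPoly must contain MinPoly everywhere.
* *End-to-end recovery*: clean low-rate simulations (8 species, 300
  characters, per-branch change probability 0.02–0.04, no noise) must be
  recovered at 100% mean sja. The rate matters: at per-branch rates around
  0.1 a few percent of seeds produce matrices whose most parsimonious tree
  genuinely beats the generating topology — parsimony estimation error, not
  an implementation defect — which is why the "clean" condition is defined
  in the consistency regime (low rate, many characters).

## Numerical and degenerate-input choices

* Scores are compared with an absolute tolerance of 1e-9 when deciding
  ties among trees (implied-weight costs are sums of small rationals; exact
  equality is not meaningful in floating point).
* `scc()` is undefined with fewer than two complete pairs or a constant
  vector; the result is `NA` with classification "absent" and the pair count
  reported.
* A species with nothing scored for a character codes as missing.
* Cells are stored as canonical strings (`"0/2"`, `"?"`, `"-"`); writing and
  re-reading a matrix is bit-exact, and all four input polymorphism dialects
  (`{02}`, `(02)`, `0/2`, `0\2`) normalize to the same representation.
* State labels above the 32-symbol output alphabet are rejected at write
  time; the largest real state space carried here is 10.
* Character 1 (carapacial disk size) defaults to its 10-state binning, with
  the published 5-state alternative carried in the metadata as
  `alt_bin_edges`; programs that cannot accept 10 symbols can switch.

## Known limitations

* The deposited 530-specimen matrix of the motivating study is not bundled;
  the tests that would reproduce its published tree statistics require the
  user to supply it (see `tests/testthat/test-acceptance.R`). The shipped
  29-taxon molecular consensus newick is a labelled transcription assembled
  from the cited molecular hypotheses, not a verified copy of any figure.
* TBR neighborhoods are enumerated exhaustively per swap step; this is the
  right trade-off for tens of taxa but not for hundreds.
* The collapse rule contracts each zero-minimum-length branch found
  simultaneously; pathological cases where two adjacent branches are
  individually but not jointly collapsible are accepted as-is (the same
  convention as the common software default).
* MPT counts depend on the collapse rule and the search path; only scores
  and topological accuracy are treated as reproducible quantities.
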