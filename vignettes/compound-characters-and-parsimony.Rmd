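---
title: "Compound characters, parsimony, and tree-length decay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compound characters, parsimony, and tree-length decay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladatom)
```

## The problem

Morphological character matrices often contain *compound characters*:
single columns that conflate two or more logically independent attributes
(say, "antorbital fossa: absent / shallow and round / deep and
keyhole-shaped", which mixes presence, depth, and shape).  Compound coding
packs several potential synapomorphies into one column, so a matrix that
atomizes those columns into independent characters can extract more
grouping information from exactly the same observations.  `cladatom`
implements the full analysis workflow in which that claim can be made and
tested: parsimony scoring and search, compound-character recoding, clade
support, synapomorphy mapping, and a character-jackknife experiment that
compares two codings of the same data by their tree-length behaviour.

## Parsimony scoring

Trees are unrooted `ape::phylo` objects, polytomies allowed.  For an
unordered character the minimum number of state changes a tree requires is
computed with the Hartigan generalisation of the Fitch pass: at each node
the state set is the set of states carried by the largest number of child
sets, and the step count grows by (number of children) minus that count.
This rule is exact on binary *and* multifurcating trees, which is why
consensus trees can be scored directly.  Ordered (additive) characters use
a Sankoff pass with linear costs `|i - j|`.  Missing (`?`) and
inapplicable (`-`) cells are scored identically as free assignments — the
two codes are kept distinct only so files round-trip — and a polymorphic
cell is satisfied by any member state, with no extra step for the
within-taxon variation.  All characters default to unordered; ordered
scoring is available per character but off unless a file or the user says
otherwise, since published matrices of this kind rarely declare orderings.

Per-character bookkeeping follows the classical quantities: observed steps
`s`, minimum conceivable steps `m` (for unordered characters, one less
than the smallest state set that intersects every scored cell), maximum
conceivable steps `g` (scored cells minus the largest state class), and
homoplasy `h = s - m`.  The ensemble consistency index is `sum(m)/sum(s)`
and the ensemble retention index `(sum(g) - sum(s))/(sum(g) - sum(m))`,
with characters incapable of homoplasy (`g = m`) excluded from the RI
sums.  The RI is exactly invariant when the character set is duplicated —
the property that makes it comparable across matrices of different size,
and one of the package's acceptance checks.  Implied weighting scores a
tree by the concave fit `F = sum(k/(k + h_i))`; the concavity defaults to
`k = 3`, the long-standing default of the parsimony programs that
popularised the method, and is a configuration knob throughout.

## Tree search

`exhaustive_search()` enumerates all `(2n-5)!!` unrooted binary topologies
up to nine taxa and is the oracle against which the heuristic is tested.
`heuristic_search()` grows a Wagner tree for each random addition sequence
(each taxon joined at the branch that least increases the objective,
first-found-best on ties, all iteration seeded) and refines it with branch
swapping to a local optimum; optima are pooled across sequences and
deduplicated by bipartition sets.  The default swapper is TBR; SPR and NNI
are restrictions of the same bisection-reconnection enumeration in which
one side keeps (or stays adjacent to) its original attachment.  Candidate
reconnections are evaluated in O(characters) from per-edge directional
state-set tables computed once per bisection, the same device serious
parsimony programs use, and validated here against full rescoring and
exhaustive enumeration.  "New technology" metaheuristics (ratchet,
sectorial searches, tree fusing) are deliberately out of scope: more
random addition sequences are the supported way to buy reliability, and on
noisy data the search can terminate on an equal-length plateau that a
ratchet would traverse.  Zero-length branches are not collapsed, so counts
of equally optimal trees refer to fully binary topologies.

Bootstrap support resamples the active characters with replacement to the
original count (implemented as integer reweighting), re-searches each
replicate with a lighter setting (`bootstrap_additions`, default 1), and
records the bipartitions of each replicate's strict consensus.  Supports
are absolute percentages.  The majority-rule consensus retains splits
present in strictly more than half of the replicates — at exactly 50%
two splits can be incompatible — and `map_supports()` transfers the
percentages onto any other tree, e.g. an MPT, where splits never seen
score 0.

## Diagnostics

`ancestral_states()` reconstructs node states by a Sankoff down-pass and a
top-down assignment in which every node receives a state that is
conditionally optimal given its parent; every such assignment realises the
character's minimum steps.  Where several states tie, ACCTRAN prefers the
change (pushing transformations rootward, favouring reversals) and
DELTRAN prefers the parent's state (favouring parallelisms).  A change is
reported as *ambiguous* when the two resolutions disagree about it, which
matches the working definition of an "unambiguous synapomorphy" in
systematic practice.  `count_synapomorphies()` counts changes on a clade's
stem branch and `count_apomorphies()` on a terminal branch; both require
the tree to be rooted, normally via `root_on_outgroup()`.  Because these
counts are resolution-dependent, reproducing published counts should be
attempted under each mode.

## The jackknife experiment

`run_jackknife()` removes a stated number of characters uniformly at
random (without replacement), re-searches under the equal-weights
objective — length comparisons are step counts, so implied weighting
applies only to headline topology searches — and records the replicate
tree length.  Two bivariate summaries follow the original experimental
design: the *decay plot* of (full length − replicate length) against
characters removed, and an OLS regression of replicate length on
characters analysed (`length_plot_regression()`), unweighted because the
experiment it emulates was a spreadsheet workflow.  `compare_matrices()`
runs the same protocol on two codings over the same taxa and reports the
full-length difference, the difference between the regression lines over
the overlapping range of analysed-character counts, and the RI of each
coding's best tree.  If two codings carry the same information, the
atomized one is only slightly longer despite its extra columns — far less
than adding that many independent characters would cost — and its
regression line sits lower at matched counts; that contrast, not the raw
length, is the evidence that atomization reduced character conflict.

Replicate lengths are guaranteed to satisfy `delta >= 0`: each replicate's
reported length is the better of its own search and the full-matrix
optimum scored on the replicate's characters, i.e. the replicate search is
seeded with the full optimum.  Exact optima would have this property
automatically; seeding makes it robust to heuristic unluckiness.  Removal
counts default to 5%–50% of characters in 5% steps with 20 replicates
each, spanning the regression range at desk-scale cost.

## The synthetic-data generator

`simulate_matrix()` evolves each character along a known tree under a
symmetric Mk-style process.  The per-character rate is expressed as
expected changes per root-to-tip path; each edge changes state with
probability `1 - exp(-rate/depth)`, and recorded change counts are
state-flips along edges, so parsimony steps on the true tree can never
exceed the recorded truth.  Characters are conditioned on being variable
(constant columns are redrawn, with a forced single change as the
rate-to-zero fallback), mirroring the fact that real matrices only score
variable characters.  Missingness is applied afterwards, uniformly within
taxon classes: a configurable fraction of ingroup taxa are designated
incomplete "fossils" whose cells are lost at a multiple (default 3x) of
the base rate, scaled so the overall missing fraction matches the
configuration.  Outgroup taxa subtend the uniformly drawn ingroup topology
as a pectinate basal grade, the arrangement in which non-ingroup taxa
typically root empirical matrices.

The study-shaped defaults emulate the dimensions typical of a large
early-dinosaur analysis: 46 taxa of which 18 are outgroup, 366 atomic
characters, mostly binary (80% binary, 15% three-state, 5% four-state),
rate 1.5 changes per path — which yields an ensemble CI near 0.4 and RI
near 0.75 at this size, typical of large morphological matrices — and 30%
missing data with the fossil bias.  Twenty-five synthetic compound
characters are built by merging 22 pairs and 3 triples of binary atoms
(joint states enumerated over observed combinations), so the compound
matrix has 338 columns and atomizing it with the recorded inverse rules
adds back exactly 28.  What the generator does **not** emulate: character
correlation beyond the constructed compounds, rate heterogeneity across
lineages, and the anatomical structure of real character lists.  Passing
tests therefore demonstrate the correctness of the machinery and the
qualitative behaviour of the experiment, not the specific step counts of
any particular empirical matrix.

`recovery_experiment()` is the validation harness: simulate, search,
compare the strict consensus to the generating tree by Robinson-Foulds
distance.  Its preset (20 taxa, 200 characters split evenly between three-
and four-state, rate 0.25, three addition sequences) was fixed by a single
calibration study: binary-heavy characters plateau around 85–93% perfect
recovery because tied optima collapse the strict consensus, while richer
state spaces distinguish branches and reach ≈97% — the regime the
"clean data recover the truth" acceptance check runs in.

## Numerical and design choices

* Ties during search (Wagner placement, swap acceptance) are broken
  first-found-best under seeded iteration order; all randomness flows from
  a single seed, so every search, bootstrap, and jackknife is reproducible
  bit-for-bit.
* Objective comparisons use an absolute tolerance of 1e-9, relevant only
  to the implied-weights objective (lengths are integers).
* Character ids are 1-based as published and never renumbered by
  subsetting or atomization, so reports remain citable against printed
  character lists.
* Inapplicable cells propagate as inapplicable through atomization;
  scoring treats them like missing, so this affects only file fidelity.
* `min_max_steps()` for ordered characters uses the unit-interval
  crossing formula for `g`; both formulas are property-tested against
  exhaustive tree enumeration on small instances.
* Degenerate inputs are refused loudly: empty matrices, dropping all
  taxa, removal counts that exhaust the characters, exhaustive search
  beyond nine taxa, unrooted trees passed to diagnostics.

## Problem sizes used in the shipped checks

The test suite and the acceptance script size their simulations for a
single desktop CPU: 200 random 5–7-taxon matrices for the
heuristic-vs-exhaustive oracle, 100 simulate-and-search repetitions at
20 x 200 for recovery, 50 replicates per removal count at 20 x 100 for the
jackknife contracts, and a 20-taxon, 120-character compound/atomized pair
for the coding contrast; the full 46 x 366 emulation is exercised for the
atomization accounting and a single headline search.

## Known limitations

Inapplicable states are scored as missing rather than with a
coherent-subcharacter algorithm; supports come only from the bootstrap (no
Bremer decay); implied weighting uses plain `k/(k+h)` without extended
variants; and the heuristic offers no plateau traversal, so on
low-signal data the reported MPT set can be a subset of the optimal
plateau reachable by stronger metaheuristics.
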