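---
title: "Block-permuted RNA motifs: model, scanner, covariation screen and kinetics"
author: "permotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Block-permuted RNA motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permotif)
```

## The problem

Self-cleaving ribozymes such as the hammerhead catalyze scission of one
specific phosphodiester bond in their own backbone. The hammerhead catalytic
core consists of three helices (stems I–III) arranged around two conserved
sequence boxes — CUGAnGA and GAAA — and the cleavage site, with an
additional tertiary interaction between the loops of stems I and II that
accelerates cleavage. Because the functional requirement is on the 3D
arrangement rather than on the 5′→3′ connectivity, the core can be cut into
*blocks* whose internal order is fixed but whose order along the transcript
is not:

* **Block C** — one half-site of stem I, the CUGAnGA box, one half-site of
  stem II;
* **Block G** — the other half-site of stem II, the GAAA box, one half-site
  of stem III;
* **Block S** — the other half-site of stem III, the cleavage site in its
  conserved NUH context, and the remaining half-site of stem I.

Three blocks admit 3! = 6 orderings. Three of them (CGS, GSC, SCG — the
classical types I, II and III) are cyclic rotations of one another: on a
line their stems nest and the structure is a three-stem junction. The other
three (SGC, CSG, GCS) are *non-circular* permutations: their stems cannot
be drawn without crossings, i.e. the same catalytic core becomes a deeply
pseudoknotted fold. This package provides the computational machinery for
working with such block-permuted motifs: a descriptor model and topology
classifier, a permutation-aware sequence scanner with cleavage-site
prediction, a covariation screen for candidate alignments, a cleavage
kinetics fitter, and a ground-truthed simulator that ties the pieces
together.

## The descriptor model

A `MotifDescriptor` holds blocks (ordered lists of elements: degenerate
IUPAC literals, stem half-sites, bounded spacers, and at most one
cleavage-site marker), `StemSpec`s (length range in bp, G·U wobble flag,
mismatch budget, required/optional), and a linker range applied between
consecutive blocks in any ordering. Descriptors are deliberately
order-free: every field must be valid for every permutation.

Design choices worth stating explicitly:

* **Pseudoknot count is helix-level.** `countPseudoknots()` counts crossing
  *stem pairs* — unordered pairs of stems whose linear extents interleave
  (i < i′ < j < j′) — not crossing base pairs. This makes the count
  invariant under stem length and matches the "crossing lines" reading of a
  linear diagram. A layout is a `junction` iff the count is zero. For the
  hammerhead blocks the circular orders give 0 and all three non-circular
  orders give exactly 3; published descriptions say "at least two
  pseudoknots" for the latter, and we report the crossing-pair count as
  computed rather than forcing any particular convention.
* **Type names** are the 5′→3′ concatenation of block labels (`"SGC"`),
  and enumeration returns layouts in lexicographic order of type name.
* **Optional stems are excluded from topology by default.** The stem I–II
  interaction is a tertiary contact, not part of the three-stem core; an
  `includeOptional` flag adds any optional stem whose two half-sites are
  placed in blocks.
* **The grammar is line-oriented** (`motif`, `stem`, `linker`, `block`,
  `seq`/`stem5`/`stem3`/`spacer`/`cleave`) rather than an existing pattern
  language, so that descriptors can be serialized and round-tripped
  losslessly (`parseDescriptor(descriptorText(d))` is the identity).
* **The built-in hammerhead fixture** encodes the block decomposition
  above. The conserved context of the cleavage site is written as the
  canonical hammerhead NUH triplet immediately 5′ of the scissile bond
  (H = A/C/U); stem ranges are I: 3–8, II: 3–8, III: 2–6 bp with wobble
  allowed, and linkers 0–8 nt (the natural type-SGC linker between stems I
  and II is typically 3 nt). The twister fixture is a schematic three-block
  decomposition whose literals are placeholders; it exists to exercise
  generic multi-block support, including an optional pseudoknot helix with
  placed half-sites.

```{r topology}
d <- builtinDescriptor("hammerhead")
topologyTable(d)
```

## The scanner

`compilePattern()` turns a (descriptor, layout) pair into a linear plan of
matchable units with length bounds plus pairing constraints;
`scanSequence()` performs exhaustive backtracking over element lengths and
start positions, so its match set is exactly the language of the pattern —
including pseudoknotted configurations, which ordinary regular-expression
engines cannot express because the two halves of a crossing stem must
agree. Numerical/behavioral choices:

* Coordinates are 0-based half-open on the forward strand everywhere (BED
  convention); minus-strand matches are found by scanning the reverse
  complement and mapping back.
* Default pairing is Watson–Crick; G·U wobble is a per-stem descriptor
  flag (a scan option can force it globally); the default mismatch budget
  is 0, since published curation tolerance is not machine-specified.
* T ≡ U and case-insensitive; ambiguous sequence characters (N, …) fail
  both literal and pairing checks unless explicitly allowed.
* Element lengths are explored shortest-first; output ties are broken by
  (start, end, type name); duplicates by (span, element spans) are removed.
* Overlapping matches of different permutation types are all reported — a
  non-circular permutation's match cannot be derived from another type's.

Each match carries per-element spans and, when the descriptor annotates a
cleavage site, the predicted inter-nucleotide cleavage coordinate.
`predictCleavage()` converts that coordinate into 5′/3′ fragment lengths,
which always sum to the construct length — the quantity a denaturing gel of
a co-transcriptional cleavage reaction reads out directly.

## The covariation screen

Compensatory mutations — paired columns changing jointly so that base
pairing is preserved — are the accepted evidence that a predicted structure
is under selection. The screen formalizes a manual criterion, so every
threshold is an explicit, configurable stand-in rather than an inferred
constant:

* **Statistics per pair** (`pairStatistics()`): pair-type counts, a
  compensatory count (row pairs differing at both columns with both rows
  Watson–Crick), mutual information in bits, MI with average-product
  correction, and a permutation-null p-value from independent
  within-column shuffles (1000 by default, seed mandatory).
* **APC is computed with column means over all column pairs** of the
  alignment. The textbook APC term mean(i)·mean(j)/mean(all) only removes
  a *background* trend when the column means are dominated by non-pair
  partners; if the means were restricted to the consensus pairs themselves
  — where every column participates in at most one pair — the correction
  would equal MI²/mean(MI) and subtract precisely the signal being tested.
  The all-pairs form is the one in standard use and is the package's
  choice.
* **Gapped rows are excluded pairwise**, not alignment-wide, preserving
  signal in ragged alignments.
* **Filters**: a sequence whose realized stem pairs contain a C–G/G–C
  fraction below 0.15 is flagged (scarce C–G pairs are a hallmark of
  spurious matches); insertions longer than 12 nt are flagged unless an
  exhaustive search finds a hairpin of ≥ 3 bp with a ≥ 3 nt loop that
  would let the insertion fold away. Raising the C–G threshold never
  unflags a sequence.
* **Verdict** (`evaluateCandidate()`): "promising" requires at least K = 3
  consensus pairs each with ≥ 1 compensatory pair and permutation p <
  0.05, and no required stem entirely invariant. Alignments with fewer
  than two sequences are "insufficient data" — a single example cannot
  exhibit covariation, which is exactly the situation of a lone candidate
  sequence.

This screen deliberately does not reimplement the G-test-based statistic
of dedicated covariation software; MI+APC with a permutation null is a
documented, self-contained stand-in.

## Cleavage kinetics

During in vitro transcription at constant transcription rate, the fraction
of full-length transcript f = L/(L+S) decays with the observed cleavage
rate. `fitDecay()` fits the one-phase exponential decay

$$f(t) = (y_0 - p)\,e^{-k_\mathrm{obs} t} + p$$

by bounded nonlinear least squares (Levenberg–Marquardt via minpack.lm),
initialized from a log-linear regression of f − min f. All three parameters
are fitted by default because published fits do not state whether y₀ or the
plateau were constrained; either can be fixed (`fixPlateau = 0` gives the
two-parameter decay to baseline). Constant series and series of fewer than
four points are flagged as non-converged, never silently fitted. R² is
1 − SS_res/SS_tot. `summarizeReplicates()` averages k across converged
replicates and reports a two-significant-figure formatted value alongside
full precision, the convention of published rate tables.

For simulation, the default time grid places 30 points across 3/k (more
than four half-lives): slow rates near 0.004 min⁻¹ are unidentifiable on
short windows, so the window must scale with 1/k. Noisy simulated
fractions are clipped to [0, 1] with the clipped count recorded.

```{r kinetics}
fit <- fitDecay(simulateDecay(0.026, sigma = 0.02, seed = 1))
fit
```

## The simulator, and what passing tests do and do not show

`sampleInstance()` emits concrete motif instances with full ground truth
(element spans, cleavage coordinate, mutation log); `plantInBackground()`
hides them in i.i.d. background sequences of chosen GC content on random
strands; `simulateAlignment()` creates gapless alignments with joint
Watson–Crick rewrites of stem positions at a chosen per-position rate
(default 0.3 across 50 sequences in the validation runs — enough variation
to covary, little enough to stay recognizably one family);
`simulateDecay()` inverts the kinetic model. All generators are pure
functions of (parameters, seed); G·U wobble pairs are emitted with
probability 0.1 per eligible stem position when the stem permits wobble.

The background model is i.i.d., not Markov, and the simulated alignments
are gapless and error-free. Recall and specificity measured against these
simulations therefore demonstrate algorithmic correctness — exhaustive
search really is exhaustive, compensatory signal really is detected — but
not performance on real metatranscriptome assemblies, where misassembly,
indels, alignment error and compositional structure all degrade matters.
The per-position test-suite problem sizes (planted records of 120–150 nt,
hundreds of records, 100-seed kinetic recovery grids) were chosen as the
smallest sizes at which the statistical assertions are stable.

Pair-breaking mutations interact subtly with exhaustive search: breaking
the *outermost* pair of a stem that may legally be shorter does not
invalidate the instance — the scanner correctly reports the shorter-stem
placement. Guarantees about pair-breaking edits are therefore stated (and
tested) on descriptors whose stems have fixed lengths.

## Known limitations

* No thermodynamics: stems are combinatorial constraints, not free-energy
  models, and the hairpin test in the insertion filter is purely
  topological.
* The descriptor grammar has no alternation or optional elements (beyond
  optional stems); motifs with genuinely alternative block contents need
  one descriptor per variant.
* The scanner is exhaustive and therefore exponential in the worst case;
  it is meant for desk-scale scans and planted-motif validation, not for
  screening entire sequence databases (that is the role of
  covariance-model homology search, which is out of scope here).
* Synthetic analogues of the experimentally validated constructs reproduce
  published construct *geometry* (lengths and cleavage positions), not
  primary sequence; they are labelled synthetic throughout.
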