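---
title: "Detecting distant homology between membrane-protein families with tmskit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting distant homology between membrane-protein families with tmskit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmskit)
```

## The problem

Families of alpha-helical membrane proteins diverge beyond the reach of
ordinary pairwise sequence comparison long before their transmembrane
architecture does. Two families may share a common ancestor — typically a
small bundle of transmembrane segments (TMSs) that was duplicated
intragenically, then trimmed or extended (an 8-TMS protein arising as
4+4, a 7-TMS protein as 3+4 after loss of the N-terminal TMS) — while no
single pairwise alignment between their reference members is significant.
`tmskit` implements a combined strategy for this regime:

1. **Topology evidence.** Hydropathy profiling and TMS calling establish
   each protein's TMS architecture, and bundle-vs-bundle alignment
   (`find_repeats`, `cross_repeat`) detects the internal repeat units
   that record the ancestral duplication.
2. **Transitivity of homology.** If A is homologous to B, B to C, and C
   to D, then A is homologous to D. `screen_homologs` collects
   intermediate homologs (B, C) for anchor members (A, D) of the two
   families, and `compare_families` searches all B-C pairs for a
   significant bridge whose aligned TMSs correspond colinearly.
3. **Corroborating criteria.** Domain-content agreement within the
   aligned region (`check_domain_overlap`, with `project_domain` to
   transfer annotations onto members lacking direct hits), plus
   externally supplied motif and structural evidence, enter a five-way
   decision rule (`evaluate_criteria`).
4. **Confidence and context.** Accepted inferences are scored
   (`confidence_score`), normalized per run, banded into high / medium /
   low levels, and exported as a family network; bit-score hierarchical
   clustering (`bitscore_distance`, `agnes_average`) summarizes the
   relationships among all members.

## Alignment and significance

Local alignment uses the Smith-Waterman algorithm with affine gaps
(BLOSUM50, gap open 10, gap extend 2 by default — the classical SSEARCH
setup; a gap of length L costs `open + extend * L`). The dynamic
programming is delegated to `Biostrings::pairwiseAlignment`; the test
suite verifies its raw scores against an exhaustive, independently
written DP oracle on a thousand random pairs. Among co-optimal
alignments the engine's deterministic traceback selects one; runs are
therefore bitwise reproducible, though the specific co-optimal chosen is
an implementation detail.

Membrane proteins are compositionally biased — long hydrophobic stretches
inflate alignment scores under standard null models. Significance is
therefore estimated by **composition-preserving shuffling**: the subject
sequence is permuted K times (default 1000), each shuffle is aligned
against the query, and a Gumbel (type-I extreme-value) distribution is
fitted to the K optimal scores by maximum likelihood. The E-value of the
observed score S is `context_size * P(S' >= S)` under the fitted null.
Two numerical details matter:

* The ML scale equation is solved by bracketed root finding started from
  the method-of-moments estimate; all exponentials are max-shifted.
* When the shuffled score sample has zero spread (degenerate fit) and
  the observed score exceeds it, the conservative bound `1/K` is
  reported and flagged rather than an extrapolated number.

A uniform-p calibration check (empirical `P(E <= 0.05)` on unrelated
random pairs) is part of the acceptance suite. Note that a
block-structured membrane protein compared against a *residue*-shuffled
null can legitimately look non-random even without homology — shared
hydrophobic-block architecture is real signal under this null. This is
exactly why the pipeline never accepts sequence similarity alone but
requires topology congruence and domain agreement on top (criterion
logic below).

Bit scores use `bits = (lambda * S - ln K) / ln 2`. Published ungapped
Gumbel constants are shipped for BLOSUM50 and BLOSUM62 and published
gapped constants for BLOSUM62 (11, 1); for the default gapped system
(BLOSUM50, 10/2) the package ships constants calibrated once by ML
Gumbel fits to Smith-Waterman scores of shuffled 300-residue random
pairs (lambda = 0.174, K = 0.023). Any scoring system can instead supply
a run-specific `gumbel_fit` via `fit_constants`.

## Hydropathy and TMS calling

Hydropathy profiles are Kyte-Doolittle values averaged over a centered
window (default 19 residues, the classical transmembrane setting; the
window shrinks at sequence ends and those positions are flagged). The
TMS caller marks maximal runs with window-averaged hydropathy at or
above 1.0, merges runs separated by fewer than 4 residues, discards runs
shorter than 15 residues, and recursively splits runs longer than 30 at
their interior hydropathy minimum. All four knobs live in `run_config`.
Imported annotations (HMMTOP one-line format or TSV) always take
precedence over the native caller when supplied, and the native caller is
deliberately simple: it exists so that every pipeline stage can be
exercised and benchmarked without an external predictor.

Some real proteins carry single hydrophobic peaks that actually span two
TMSs; resolving those requires cross-homolog comparison and remains a
manual judgment — the toolkit reports peaks and lets imported
annotations override them.

Per-TMS complexity classification (`classify_tms`) combines segment
Shannon entropy with mean hydropathy: entropy < 2 bits with mean KD > 2
is `simple` (bias-prone, weak homology evidence), entropy in [2, 3] bits
or mean KD in [1, 2] is `twilight`, anything else `complex`. These bands
approximate published hydrophobicity/complexity classifiers whose exact
discriminants are not reproduced here; the classification is advisory
and enters no automated decision.

MSA support follows the same conventions: per-column average hydropathy
over non-gap residues (optionally window-smoothed along columns),
average similarity as the mean substitution score over all ordered
residue pairs in the column rescaled to [0, 1] (the ordered-pair form
keeps the profile invariant under duplicating rows), and strict
`< 30%`-gap column trimming (`trim_msa`, idempotent).

## Repeat units

`enumerate_bundles` cuts a protein into all contiguous windows of k TMSs
(default flank: 5 loop residues, clamped to the sequence; the flank is
configurable because there is no canonical choice for how much loop
context belongs to a bundle). `find_repeats` aligns every TMS-disjoint
bundle pair — when two bundles' flanks would meet inside a short
connecting loop, the loop is split at its midpoint so slices never share
residues — and reports hits at E <= 1e-3 (configurable; borderline
repeat evidence in the literature sits near 5e-4). `cross_repeat` does
the same across two homologs, excluding identically-positioned bundle
pairs, since only *offset* pairings (TMSs 1-4 of one protein against
5-8 of another) evidence an internal repeat rather than plain homology.

Guided repeat searches over a whole homolog set are composed from these
parts (`cross_repeat` over member pairs, with `msa_profile` to choose
section points); automatic selection of section points is not attempted
because that choice is driven by inspection of average-hydropathy plots.
Only equal-k bundle pairs are enumerated; comparisons of unequal bundle
sizes (e.g. 3 vs 4 TMSs after a loss event) are run by varying k.

## The transitivity engine

Screening keeps candidates with shuffle E-value < 1e-4 covering at least
40% of the shorter sequence, then removes redundancy greedily at 90%
identity (longest-first, join requires the identity threshold over at
least 80% of the shorter sequence). Family comparison requires E < 1e-5
for all three path alignments (A-B, B-C, C-D) and at least 3
corresponding TMSs in the B-C alignment — the minimal repeat-unit size.

"TMSs in the alignment" is deliberately operationalized as *matched
colinear TMS pairs* under a 50% overlap rule (`map_tms_correspondence`):
TMS i of B pairs with TMS j of C when their images in alignment columns
overlap by at least half the shorter segment, crossings resolved
greedily by overlap size. This is the stricter of the plausible
readings (each protein merely *spanning* 3 TMSs is weaker); both counts
are reported on every inference (`n_tms`, `n_tms_span_b`,
`n_tms_span_c`).

Two-stage significance testing keeps the search tractable: a raw score
whose *predicted* E-value under the shipped Gumbel constants is more
than three orders of magnitude above the threshold cannot plausibly
pass, so the expensive shuffle calibration is reserved for plausible
pairs. The slack factor of 1e3 is far larger than the observed spread of
fitted constants across random pairs.

The five criteria — (1) significant similarity throughout the path, (2)
topology congruent with the families' repeat units, (3) overlap of the
families' characteristic domains within the alignment (at least 3 TMSs,
or the full domain when it spans fewer; clan identity recorded as
support), (4) motif conservation, (5) structural agreement — are
combined by `evaluate_criteria`: with no structures available all four
sequence criteria must pass; with structures, 4 of 5. Criterion 1 and
the TMS-correspondence count are computed here; criterion 2's final
verdict (congruence with the families' *repeat-unit history*) and
criteria 4-5 are recorded flags, because motif discovery and structural
superposition are out of scope and topology congruence ultimately needs
a human looking at the hydropathy overlays. Flags still `manual` block
an automatic accept and mark the inference "needs review".

## Confidence scores, network, clustering

`Score = -N * log10(E)` with N the matched TMS count and E the B-C
E-value; scores are normalized per run by the highest-scoring inference
(so normalized scores are not comparable across runs), and banded:
high >= 0.6 > medium >= 0.4 > low. The family network keeps one edge per
family pair (best inference) with node degree as the shading value;
exports are edge-list TSV and GraphML.

Clustering converts all-vs-all bit scores to dissimilarities
`d(i,j) = 1 - b(i,j) / min(b(i,i), b(j,j))`, clamped to [0, 1]. The
min-self normalization is chosen so identical sequences land at 0 and a
short protein fully contained in a longer one is recognized as close;
the max-self alternative is available by flag. Average-linkage
agglomerative nesting and the agglomerative coefficient (mean over items
of one minus first-merge height over final height) come from
`cluster::agnes`; trees export to Newick and Nexus with merge heights as
branch lengths.

## The synthetic generator and what it does (not) show

`make_protein` plants exact TMS intervals: hydrophobic segments of 18-24
residues drawn from a weighted pool of I/L/V/F/A/M (window-averaged KD
around 3.7), loops of 8-40 residues drawn from a small-polar-plus-charged
pool (around -1.9). `evolve_family` applies the evolutionary events the
analysis targets — intragenic duplication, loss of the N-terminal TMS,
central TMS insertion — then diverges members by per-site substitution
(replacements weighted by BLOSUM50 exchangeabilities, `2^(s/3)`) and
geometric-length indels confined to loops. Confining indels to loops
keeps the planted TMS coordinates exact, matching the model in which TMS
gain and loss are discrete events rather than drift. `make_benchmark`
builds a positive pair (two families descending from one duplicated
4-TMS ancestor; default total planted divergence 0.4, split across the
two founders, with 0.15 within-family divergence and 3 members per
family) plus decoy families that descend from composition-preserving
*shuffles* of the real founders — composition-matched, internally
coherent, but without TMS architecture or homology to the real families.

What passing these benchmarks shows: the pipeline's machinery (calling,
screening, bridging, scoring) is correct and calibrated under a model
where topology is clean, TMS hydrophobicity is strong, and divergence is
memoryless. What it does not show: performance on real proteins with
marginal or compound hydrophobic peaks, site-rate heterogeneity,
low-complexity regions, or families whose divergence far exceeds the
planted 40% — on real data the manual topology verdict and the domain
and motif criteria carry correspondingly more weight.

## Problem sizes and seeds

The shipped verification suite uses sizes chosen to exercise each claim
meaningfully: 1000 random pairs for alignment-oracle agreement, 500 null
pairs at K = 200 shuffles for E-value calibration, 100 seeded
duplication fixtures at 30% divergence for repeat recovery, 50 related
and 50 decoy family pairs for transitivity sensitivity and specificity,
and 20 seeds of three-family clustering for family recovery. The
production default of K = 1000 shuffles is reduced to K = 100-200 in
these runs; at the E-value thresholds involved the decisions are
identical. Every randomized step is driven by an explicit seed (all
derived seeds stay below 2^31), and every stage logs its thresholds so a
run is reconstructable from its outputs.

## Known limitations

* E-values from shuffle calibration agree with other tools only to order
  of magnitude; tool-specific internal regressions differ.
* The native TMS caller is a threshold heuristic, not an HMM; marginal
  and compound peaks need imported annotations.
* The complexity classifier approximates published discriminants.
* Normalized confidence scores are run-relative by construction.
* Criterion 2's final congruence call, and criteria 4-5, are externally
  supplied; the package computes and records, but does not replace, that
  judgment.
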