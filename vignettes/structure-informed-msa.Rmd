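---
title: "Structure-informed multiple sequence alignment with foldmsa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-informed multiple sequence alignment with foldmsa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldmsa)
```

## The problem

Protein families that share a fold but have drifted below roughly 30%
sequence identity are where pure sequence aligners break down: the
substitution signal in the conserved secondary-structure elements is too
weak to keep strands and helices in register, and the variable loops
between them carry essentially no alignable signal at all. Structural
information resolves both problems — backbone geometry identifies the
homologous core even when sequences disagree — but all-against-all
structural alignment does not scale.

`foldmsa` implements the divide-and-conquer strategy used by
structure-informed alignment pipelines at desk scale, with every engine
built in:

1. **clean** — greedy identity clustering removes redundant sequences
   (default cutoff 0.9).
2. **match** — each sequence is matched to a structure: a user-provided
   file, a pluggable model provider, or nothing (the sequence is then
   *structureless*). Structures with too many unresolved residues
   (default > 25%) are excluded.
3. **subset** — a second, permissive clustering pass (default cutoff 0.3)
   groups mutually similar structured sequences into subsets; leftovers
   are pooled into collated subsets or labelled *orphans*.
4. **align** — each subset is aligned by an iterative structure-aware
   aligner (below). Subsets are independent jobs; parallel and
   sequential execution give identical output.
5. **merge** — subset alignments are combined by profile–profile
   alignment under a strict shape-preservation contract: the only edit
   ever applied to a subset alignment is insertion of full-height gap
   columns. Orphans and structureless sequences are then inserted one at
   a time.
6. **squeeze** — loop regions between conserved secondary-structure
   blocks are re-packed to remove the gap inflation that merging
   produces, leaving block columns untouched.

A Column Score (CS) evaluator and a synthetic family generator with
ground truth complete the toolkit, so the whole pipeline is testable
without any external data or binaries.

## The structure-aware pairwise aligner

`pairwise_struct_align()` is a simplified iterative structural aligner in
the spirit of TM-align-style methods:

* **Seed.** Global affine-gap dynamic programming (Gotoh; gap open 8,
  extend 0.5 — penalties are positive costs) on
  $w_\mathrm{seq}\,\mathrm{BLOSUM62}(a_i,b_j)/4 +
  w_\mathrm{ss}\,\delta(s_i = s_j)$ with $w_\mathrm{seq}=1$,
  $w_\mathrm{ss}=2$, where $s$ is the 3-state secondary structure.
* **Superpose.** The currently aligned, structurally resolved pairs are
  fitted by Kabsch superposition. The fit is *trimmed*: pairs fitting
  worse than max(1.5 Å, median residual) are iteratively discarded and
  the transform refitted, so the conserved core defines the frame even
  while flexible loops are mispaired. Without trimming, loop pairs bias
  the frame enough that the structural term cannot correct block
  registers.
* **Refine.** The DP is re-run with an added structural proximity term
  $w_d / (1 + (d_{ij}/d_0)^2)$ on superposed CA–CA distances
  ($w_d = 4$, $d_0 = 5$ Å — a fixed, TM-score-like scale chosen for
  small single-domain proteins rather than a length-dependent one), and
  the loop repeats until the aligned pair set is stable or 10
  iterations. Unresolved positions contribute sequence/SS terms only.

`align_subset()` builds a guide tree by average-linkage clustering of the
pairwise scores (ties broken lexicographically by id, so results are
independent of input order) and aligns progressively. Internal nodes use
profile–profile DP whose column score is the *mean* pairwise
sequence + SS (+ structural) score over the non-gap pairs — the mean,
not the sum, keeps the fixed gap penalties on a profile-size-independent
scale. The SS agreement term is symmetric (+1 match, −1 mismatch) so
that placing helix or strand residues against coil is actively
penalised; this is what holds block boundaries in register. The
structural term at profile level uses a common coordinate frame: every
member is superposed onto the lexicographically first member through the
trimmed core of its pairwise alignment.

## Merging and the loop-pairing decision

`merge_two()` aligns two alignments column-against-column with the same
affine DP (mean BLOSUM62/4 column score by default) and interleaves them
so that each input's columns appear unchanged and in order. The
shape-preservation contract — restriction to either input's rows plus
removal of all-gap columns reproduces that input bit-exactly — holds by
construction, recursively through any number of merges and insertions.

The pipeline's merge additionally uses the SS-agreement and common-frame
structural terms, and sets `pair_loops = FALSE`: column pairs in which
both profiles are loop-dominated (majority coil among SS-bearing rows)
are never aligned to each other. Two observations motivate this. First,
at the identity levels where this tool is useful, a cross-subset
loop-residue pairing asserts a homology the data cannot support; the
position of loop residues relative to the conserved blocks is what
matters, not their identity. Second, profile merging of dissimilar
subsets is exactly the step that inflates loop gaps in practice, and the
squeeze step exists to undo it — so the merge leaves loops as
per-subset bands and delegates loop packing to the squeeze, which owns
that decision. With loops force-paired instead, a correctly registered
merge is already gap-minimal and the squeeze has nothing to do.

## The squeeze

`annotate_columns()` marks a column *conserved* when, for some category
in {H, E}, the fraction of structure-bearing non-gap rows in that state
reaches the threshold (default 0.8) with at least 2 supporting rows
**and** at least 60% of the structure-bearing rows are non-gap in the
column (`min_coverage`). The coverage requirement is essential: in a
staggered merge, columns where most rows are gaps but the few residues
agree would otherwise freeze mis-stacked loop residues in place.
Conserved blocks are maximal conserved runs of length ≥ 2.

`squeeze_msa()` copies block columns unchanged and re-packs every loop
region between them: per-row residue segments are extracted and
re-aligned by sequence-only progressive DP (gap open 4, extend 0.5,
longest segment first), then all-gap columns are dropped. Residues never
cross block boundaries, every row still degaps to its input sequence,
and a region whose re-packing would widen it is left untouched, so the
total gap count never increases. Re-packing by re-alignment (rather than
naive left-justification) preserves residue matches where they exist
while still reaching the gap-minimal width. Squeezing is idempotent on
the families the generator produces because loop residues are coil:
re-annotation after a squeeze cannot create new conserved blocks inside
packed loops.

## Column Score

`column_score()` implements the strict total-column metric: each
reference column is the set of (row, residue index) pairs it contains;
a reference column scores 1 only if some query column contains exactly
that set over the shared rows. Matching is by residue index, never by
residue character, so repeated residues cannot create false matches.
Reference columns that are all-gap in the shared rows are excluded from
the denominator — they carry no alignment information. Region masks
(e.g. conserved blocks vs loops, derived from `annotate_columns()` on
the reference) give region-resolved scores. The test suite pins the
implementation against a brute-force column-set oracle on hundreds of
random alignment pairs.

## The synthetic family generator

`generate_family()` emulates the data regime the pipeline targets: a
family with conserved secondary-structure blocks, all indels confined to
loops, tunable mean pairwise identity, a planted clade structure, and
matching ideal backbone coordinates.

* **Architecture.** An ordered list of blocks (helix/strand, fixed
  length) and loops (length bounds). The default,
  `bab_architecture(2)`, is a β(6)–loop–α(10)–loop repeat closed by a
  final strand — about 70–90 residues with loops of 2–6 — mimicking the
  repeat layout of classic α/β folds.
* **Evolution.** An ancestor is sampled uniformly; descendants are
  produced along a balanced binary tree (default; a star tree is
  available when uniform divergence is wanted), substituting each site
  per edge uniformly over the 19 alternatives. This is deliberately
  non-phylogenetic — no rate matrix, no rate variation — because the
  generator only needs identity control, not evolutionary realism.
  The per-edge substitution probability is calibrated by bisection
  (tolerance 0.02, at most 50 steps) against the realized mean pairwise
  identity *as measured by `pairwise_identity()`*, i.e. the same
  alignment-based, shorter-sequence-denominator statistic the clustering
  uses. Separate within-/between-clade targets calibrate two rates.
* **Indels.** Per loop and sequence, a Poisson number of events
  (default rate 0.3) with geometric lengths (p = 0.5) grows or shrinks
  the loop within its bounds; loop content is inherited left-to-right,
  so loop position *k* always descends from ancestor loop position *k*.
  The ground-truth alignment is therefore exact: block columns are
  gapless and loops are left-justified.
* **Coordinates.** Blocks use canonical geometry — α-helix with 1.5 Å
  rise, 100°/residue, 2.3 Å radius; strand as an extended zigzag with
  3.8 Å CA–CA — placed at identical offsets in every family member, so
  the planted structural correspondence is exact; loops are
  self-avoiding random walks (3.8 Å steps), unique per sequence.
  `assign_ss()` (a P-SEA-style CA-geometry assignment) recovers the
  planted states from these coordinates; full DSSP file parsing is also
  available for real data.
* **Degradation.** `degrade_structure()` removes one contiguous
  coordinate segment, emulating partially resolved models for the
  exclusion-filter path, and `inflate_loops()` re-lays loop regions into
  per-group bands, reproducing the loop-gap inflation of joint profile
  merges — the canonical slack-bearing input for squeeze tests.

What the generator does *not* emulate: real indel processes inside
blocks, structural divergence of the conserved core (block coordinates
are identical across members), model/prediction error in coordinates,
and compositional biases. Passing tests therefore demonstrate the
machinery is correct and well-behaved under its stated assumptions, not
that alignment accuracy on real families matches the synthetic numbers.

## Pipeline mechanics

`run_pipeline()` executes the stages with a JSON manifest per stage
(input content hashes, outputs, status). A rerun in the same output
directory skips every stage whose inputs — including the slice of the
configuration that stage depends on — are unchanged, which is also what
makes each stage independently scriptable (`stages =` argument, or the
stage subcommands of the CLI script in `inst/cli/`). Subset alignment
may run on several workers; jobs are independent and aggregated in
canonical order, so worker count never changes the output. All
tie-breaks in clustering, guide trees and merge order are lexicographic
by sequence id, making the whole pipeline byte-deterministic.

Defaults follow the recommendations for this family of pipelines:
redundancy cutoff 0.9, subset cutoff 0.3, minimum subset size 2,
unresolved-fraction cutoff 0.25 (a configurable default; the exclusion
rule itself is principled, the exact number is not), collation of small
clusters enabled (so every vetted sequence gets structure-aware
alignment rather than being bolted on afterwards), squeeze enabled with
categories H and E.

## Problem sizes

The shipped tests and the acceptance script run entirely on generated
data at desk scale: families of 8–24 sequences of ~70–90 residues,
five seeds for the end-to-end checks, 100–200 random instances for the
property checks. These sizes were chosen so the full suite exercises
every stage — including two full pipeline runs and a concurrent one —
in a few minutes on a single CPU; the algorithms themselves are
O(n²) in sequence count by design (all-pairs identity and structural
alignment), which is the documented trade-off for determinism and
zero external dependencies. The `ExternalAligner`-style adapter point
for swapping in heavier engines is the config's provider block and the
per-stage file interfaces, not a compiled-in dependency.

## Known limitations

* The built-in aligner makes no claim of score-level equivalence with
  consistency-based structural aligners; parity is demonstrated only as
  alignment quality on generated families.
* `d0` is fixed at 5 Å rather than length-dependent; very large or very
  small chains would warrant rescaling.
* The geometric SS assignment is CA-only and window-based; termini and
  very short elements relax to coil, and it is not a DSSP replacement
  when hydrogen-bond-accurate states matter.
* Live structure retrieval is an interface with a local-directory test
  double; network fetchers satisfy the same provider contract but are
  not part of the test surface.
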