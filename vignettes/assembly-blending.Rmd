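---
title: "Blending long-read and co-barcoded assemblies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blending long-read and co-barcoded assemblies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapblend)
```

## The problem

Third-generation sequencing (TGS) long reads assemble into highly
contiguous contigs, but the consensus carries residual small-scale errors
(substitutions and short indels), and without extra information the
assembly collapses the two haplotypes of a diploid genome into a single
mosaic. Synthetic long-read / co-barcoded (SLR) technologies such as stLFR
or linked reads give the opposite trade-off: the short reads are accurate
and, with trio binning, haplotype-resolved, but limited capture efficiency
leaves the scaffolds fragmented and full of `N` gaps.

`hapblend` combines the two: the TGS assembly is the backbone, and each
SLR haplotype assembly is independently *blended* into it. Wherever the
two assemblies disagree on a small scale, the disagreement is attributed
to a TGS consensus error and replaced with the SLR sequence; large-scale
disagreements are left untouched, because at that scale the short-read
assembly is the less trustworthy witness. Running the procedure once per
SLR haplotype yields two corrected, haplotype-resolved assemblies that
keep the contiguity of the long-read backbone.

## Screening alignment blocks

Whole-assembly alignment (SLR scaffolds as query, TGS contigs as target)
produces a set of *alignment blocks* per scaffold. Blocks can be noisy:
repeats cause off-target mappings, and collapsed regions attract both
haplotypes. A collinear chain is selected per scaffold by dynamic
programming. For blocks $b_i$ sorted by query start, a chain
$b_{k_1}, \dots, b_{k_m}$ scores

$$s = \sum_{i=1}^{m} \mathrm{len}(b_{k_i}) + \sum_{i=1}^{m-1} p(b_{k_i}, b_{k_{i+1}}),$$

where $\mathrm{len}(b)$ is the aligned length on the scaffold and $p$ is a
non-positive pair penalty. The DP recursion is

$$s_i = \mathrm{len}(b_i) + \max\left(0, \max_{j<i}\, (s_j + p(b_j, b_i))\right),$$

with trace-back from the best $s_i$; the inner $\max(0,\cdot)$ lets a
chain restart, so an incompatible prefix is simply dropped.

The penalty has two regimes. A pair mapped to different target contigs,
to different strands, or whose target-interval overlap exceeds 80% of the
shorter block's target span, is incompatible and receives a sentinel of
$-10^9$ — far below any achievable score, so such a pair can never occur
inside a returned chain. Otherwise, with $g_q$ and $g_t$ the (clamped,
non-negative) gaps between the query and target intervals and $o$ the
target overlap, compatible pairs score $-|g_q - g_t|$ when the target
intervals are disjoint and $-(g_q + o)$ when they overlap.

The published description of the two compatible cases is typeset
ambiguously (the overlap case reads as a *positive* contribution if taken
literally). We adopt the gap-difference form above — the standard
collinear-chaining cost, which also makes the two cases genuinely
different — and expose the alternative plain-sum reading
($-(g_q + g_t + o)$ for every compatible pair) behind
`chain_config(penalty_form = "gap_sum")`. When query intervals themselves
overlap (repeat-induced multi-mapping), the query overlap is added to the
penalty like a target overlap and $g_q$ is clamped to zero.

Two chaining rounds are run per scaffold, one per strand, and the higher
score wins (ties favour `+`). Discarded blocks that map to a different
contig or strand than the winning chain are *flagged*; they are reported
in the block table but deliberately not used for replacement — a flagged
block is exactly the kind of evidence (off-target, wrong strand) the
screen exists to remove. Ties in the trace-back predecessor choose the
smallest index, making the selection deterministic. The sort key for
blocks is positional (query start, then target start, then longer span
first); an alignment-quality-weighted order was considered and not
adopted, since the DP requires positional order for its `prev/next`
contracts.

## Replacing error-prone sequence

Selected blocks become target regions, grouped per TGS contig and sorted
by start. Overlaps between consecutive regions are resolved with two
rules: a region entirely contained in its predecessor is dropped, and on
partial overlap the *later* region wins — the earlier one is truncated at
the later region's start, its query interval shortened proportionally
(the exact base-level correspondence is not known before re-alignment, so
a proportional cut is the only coordinate map available at this stage;
the subsequent re-alignment absorbs the approximation).

Each resolved region pair is then re-aligned at base level (the query
segment reverse-complemented first for `-` strand regions, so every edit
lives in forward target coordinates) and the resulting cs difference
string is decomposed into substitution, insertion and deletion events.
Consecutive single-base `*` operations merge into one substitution run:
a run of mismatched bases is one event, and the length threshold applies
to it as a whole. Two filters decide each event's fate:

* **Length threshold** (default 50 bp, strict): events with
  $\max(|\mathrm{ref}|, |\mathrm{alt}|) < 50$ are corrected; events at or
  above are structural-scale differences and are left untouched. The
  boundary is configurable; "strictly below" is the literal reading of
  the rule and events of exactly 50 bp are therefore skipped.
* **N rule**: an event whose replacement sequence contains `N`, or whose
  SLR context within ±1 bp contains `N`, is skipped regardless of length.
  The published rule ("disregard any N bases") does not state a scope; a
  conservative local window keeps gap-adjacent edits out while leaving
  the rest of the region correctable.

Surviving edits are applied right-to-left so positions always refer to
the input contig; regions never overlap after resolution, so neither do
edit footprints. Contigs with no selected block pass through unchanged.

## The built-in aligner

The pipeline is self-contained: an external PAF (with cs tags) can be
supplied, but by default both alignment passes use a built-in engine.

*Whole-assembly pass*: k-mers (k = 21) occurring exactly once across the
target contigs are matched against each scaffold on both strands,
clustered into collinear runs (splitting on query gaps > 5 kb or
diagonal jumps > 1.2 kb), and each cluster becomes one alignment block.
Blocks are extended outward across their anchor-free flanks — bounded by
scaffold `N` runs and contig ends — so errors within a k-mer of a block
edge stay inside the alignment.

*Base-level pass*: banded global alignment with affine gap costs
(mismatch 4, gap open 12, gap extend 1). Affine costs matter here: with
unit costs, a large insertion can be fragmented by chance matches into
several sub-threshold pieces, which would let fragments of a structural
event slip under the correction threshold. With affine costs a
contiguous gap is strictly cheaper than a split one unless the
intervening match run is longer than the gap-open cost, which random
sequence essentially never provides.

Two numerical safeguards keep the band honest. The band half-width
starts at 64 bp and doubles until the alignment cost stops improving
(capped at 4096); watching only whether the optimal path touches the
band edge is not sufficient, because a path constrained by a too-narrow
band can be interior to it. Long near-identical pairs are cut at unique
shared-k-mer anchors into ~20 kb pieces aligned independently and
re-joined (merging match runs across the seams), keeping memory at
(piece length) × (band width) instead of quadratic.

## Evaluating haplotyping

Haplotype-specific k-mers (*hapmers*) are built by trio set algebra:
paternal hapmers are (paternal \ maternal) ∩ offspring reads, and
symmetrically; the two sets are disjoint by construction. All k-mers are
canonical (lexicographic minimum of the k-mer and its reverse
complement) and windows containing `N` are skipped.

For an assembly expected to represent one haplotype:

$$\mathrm{Precision} = \frac{\text{correctly found hapmers}}{\text{all found hapmers}},\qquad
\mathrm{Recall} = \frac{\text{correctly found hapmers}}{\text{offspring hapmers of that haplotype}},$$

with F1 their harmonic mean. The consensus quality value uses the k-mer
survival convention: with $b$ assembly-only k-mers out of $t$,
$p = 1 - (1 - b/t)^{1/k}$ and $\mathrm{QV} = -10\log_{10} p$, capped (at
99) when $b = 0$. Completeness is the recovered fraction of the solid
read k-mer set; "solid" defaults to multiplicity ≥ 2, a choice the
package exposes because the sources define it only verbally.

Phase blocks come from the positional hapmer track: maximal
same-haplotype runs, where an other-haplotype marker is absorbed as one
switch error if the block haplotype re-appears within a 20 kb window, and
a persistent run (or a > 20 kb marker gap) terminates the block. Blocks
need "more than two" markers; we read that literally as ≥ 3 and expose
the knob. Each absorbed marker counts as one switch error (the
alternative — counting a consecutive run as a single error — is a
recognized ambiguity; per-marker counting is the stricter choice).

At the variant level, switch errors are counted by a binary-state DP over
phased heterozygous variants in genomic order: flipping the global
orientation between variants costs 5 (a long switch), a variant
disagreeing with the current orientation costs 1 (a short switch), and
the program minimizes $5\,n_{\mathrm{long}} + n_{\mathrm{short}}$ (ties
resolved toward fewer long switches). Phase blocks are the spans between
long switches and are summarized by their N50.

## The synthetic study system

The generator builds the complete test bed: a uniform random reference
(500 kb by default) with heterozygous SNPs at $10^{-3}$ per bp and short
indels at $10^{-4}$ per bp (geometric lengths, mean 3, capped at 20); a
TGS-like assembly copying one haplotype (or a segment-wise collapsed
mixture, switching haplotype every 50 kb) with exactly 200 small errors
(< 50 bp; substitutions and geometric indels, mean 3) and 5 large events
(uniform 50–500 bp) at non-overlapping positions; and SLR-like scaffolds
cutting a haplotype into ~50 kb exponential fragments joined by `N` runs
of 100–500 bp. Every step returns a replayable ledger, and a fixed seed
reproduces every byte. Indel length laws are the generator's own choice —
the only boundary that matters to the method is the 50 bp threshold, and
the large-event range brackets it from above. Error positions keep a
100 bp margin from contig ends, emulating the well-supported consensus
at assembly ends.

What the generator deliberately does **not** emulate: read-level error
chemistries (the method consumes assemblies, not reads, so errors are
injected at assembly level); repeat structure (a uniform random reference
makes almost every 21-mer unique, so anchoring is easier than in a real
repeat-rich genome); and barcode-level SLR capture noise. Passing tests
therefore demonstrate the correctness of the screening/replacement
machinery and the evaluation statistics under clean mapping conditions —
they do not measure robustness to repeat-induced mis-anchoring, which in
the intended workflow is the external aligner's responsibility.

Test problem sizes are the package's own balance of coverage and
turnaround: the full 500 kb study fixture for the acceptance-level
checks, 30–60 kb fixtures for unit-level pipeline tests, and 200 random
instances of ≤ 10 blocks / ≤ 12 variants for the oracle-equivalence
checks of the two DPs (sizes at which exhaustive enumeration is exact
and fast).

## Degenerate inputs and tie-breaks

Empty PAF input screens to an empty result with a warning; an empty
chain has score 0. Equal chain scores between strand rounds pick `+`.
Blocks tied on query start sort by target start, then longer span first.
In `apply_edits`, overlapping footprints are a contract violation and
raise an error rather than silently reordering. `kmerize` warns when k
exceeds every sequence; QV on an empty assembly set and completeness on
an empty solid set are errors, not NaNs.

## Known limitations

* The chain DP is quadratic in blocks per scaffold — appropriate for
  assembly-vs-assembly block counts, not for read mapping scale.
* K-mer sets are held in memory as character vectors; genome-scale
  evaluation should use a disk-backed k-mer counter upstream and feed
  the sets in.
* The built-in aligner assumes near-identical sequence pairs (anchors +
  banded refinement); it is not a general-purpose mapper, and diverged
  or heavily repetitive regions should come from an external aligner's
  PAF instead.
* Flagged blocks are reported but never used for correction; rescuing
  genuine translocation evidence from them is out of scope.
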