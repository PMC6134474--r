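---
title: "Establishing a protein-coding phylogenetic marker: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Establishing a protein-coding phylogenetic marker: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(markerforge)
```

## The problem

The 16S rRNA gene is the workhorse of bacterial identification, but among
closely related congeners — *Streptomyces* species being a notorious case —
its sequences are often too similar to resolve relationships with
confidence. A standard remedy is to recruit a faster-evolving
protein-coding gene as an additional marker. Establishing such a marker
involves a chain of steps that this package implements as one tested
pipeline:

1. find blocks of conserved residues in a protein multiple alignment of
   the candidate gene family across distant relatives;
2. back-translate two blocks into a consensus-clamp/degenerate-core
   ("CODEHOP"-style) PCR primer pair;
3. verify, in silico, that the pair amplifies a single product of the
   expected size from each strain;
4. build distance trees (Kimura 2-parameter + neighbour joining, with a
   column-resampling bootstrap) from the amplified marker and from the
   established comparison markers;
5. quantify how congruent the marker trees are and which subgroups of
   strains are stable across all of them.

A seeded simulator generates every input the pipeline needs — a species
tree, marker alignments of contrasting rates, and an hsp70-like protein
family with planted conserved blocks — so the whole chain is verifiable
end to end without downloading a single sequence.

## Conservation analysis

`classify_columns()` assigns each alignment column one of four categories,
mirroring the `*` / `:` / `.` notation of Clustal-style alignment output:
**identical** (one residue, no gaps), **strong** or **weak** (all residues
within one of the published Gonnet-derived strong/weak groups, available
from `clustal_groups()` and overridable), and **none**. Two deliberate
rules:

* *Any gap demotes a column to `none`.* A primer cannot span an indel, so
  a column that is not physically continuous in every sequence is useless
  for design regardless of how conserved its residues are.
* *Blocks are maximal runs of `identical`/`strong` columns*, filtered by a
  minimum length (default 8 columns; at least 4 are required, since a
  degenerate core needs a few codons to anneal) and a minimum fraction of
  fully identical columns (default 0.8). When more blocks are found than
  primers are needed, `rank_blocks()` orders them by mean identity, then
  length — conservation quality first, room to place a clamp second.

## Primer design

The primer architecture is a 5′ **consensus clamp** (default 22 nt) taken
verbatim from one chosen reference coding sequence, followed by a 3′
**degenerate core** (default 12 nt) that is the positionwise union of *all*
codons of the conserved residues, compressed to IUPAC symbols
(`back_translate()`, `iub_compress()`). The clamp stabilises annealing and
doubles as a sequencing primer; the core guarantees a perfect 3′ match to
every family member whose protein is conserved in the block, because the
union covers every codon choice. No codon-usage weighting is applied: the
genomes being amplified are unknown at design time, and full unions are
the conservative choice.

Coordinates are 1-based inclusive on the plus strand everywhere. An
antisense primer is written 5′→3′ on the minus strand, so its written 3′
core corresponds to the *low*-coordinate end of its plus-strand span, and
the span's start position is the primer's 3′ end. This convention makes a
designed pair's span arithmetic directly comparable with published primer
tables that report antisense primers by plus-strand positions.

Degeneracy is the product of per-position expansion sizes
(`primer_degeneracy()`), verified in the tests against brute-force
enumeration (`expand_primer()`, capped at 4096 to keep enumeration
tractable). Melting temperatures use
`Tm = 64.9 + 41 (GC − 16.4) / N` for primers longer than 14 nt and the
Wallace rule below that; for a degenerate primer `melting_range()` bounds
the Tm over all expansions from per-position GC minima/maxima without
enumeration. The formula is a configuration choice, not a claim: only the
ordering and the min = max degenerate/non-degenerate contracts are relied
on.

## In-silico PCR

`find_sites()` scans concrete templates for windows IUPAC-compatible with
the primer (or its reverse complement), allowing at most `max_mismatch`
mismatches (default 2) but **zero** in the `anchor3` 3′-terminal bases
(default 3) — polymerase extension is far more sensitive to 3′ mismatches
than internal ones. `predict_amplicons()` pairs each forward site with its
*nearest downstream* reverse site and applies product-size bounds; nested
and overlapping products are not enumerated, matching the
dominant-single-band behaviour expected on a gel. Degenerate templates are
refused rather than guessed at, and circular templates are out of scope.

## Distances, trees, bootstrap

The Kimura 2-parameter distance is implemented from its closed form,

d = −½ · ln[(1 − 2P − Q) · √(1 − 2Q)],

with `P` and `Q` the transition and transversion proportions among
**pairwise-deleted** sites (columns with a gap or ambiguity in either
sequence are dropped for that pair only). Pairwise deletion keeps all
taxa comparable even when one sequence has a ragged end — the common
situation with directly sequenced PCR products. Outside the domain
`1 − 2P − Q > 0, 1 − 2Q > 0` the pair is *saturated*: `k2p()` raises a
typed error, and `k2p_distance_matrix()` either fails loudly (listing the
pairs) or records a mask, which the bootstrap uses to discard and count
affected replicates. The tests check the closed form against an
independent numerical inversion of the model's expected-proportion
equations on a (P, Q) grid, and the whole matrix against an independent
K80 implementation.

Neighbour joining follows the standard agglomeration: join the pair
minimising `Q(i,j) = (m−2) d(i,j) − R_i − R_j`, assign branch lengths by
the rate-corrected split, reduce, repeat. Three details are pinned down
because they affect reproducibility:

* **Ties** in the join criterion are broken by the lexicographically
  smallest pair of cluster labels (a cluster is labelled by its smallest
  leaf), making the output deterministic.
* **Negative branch lengths** are kept as computed rather than clamped;
  clamping would destroy the exact-additivity property the tests rely on
  (NJ must reproduce any additive matrix's topology exactly and its branch
  lengths to 1e−9).
* The result is returned **unrooted** (trifurcation at the last join), as
  NJ trees are.

The bootstrap (`nj_bootstrap()`) resamples alignment columns with
replacement, rebuilds distances and the NJ tree per replicate, and maps
supports onto the *point-estimate* tree — not a consensus tree — as
`round(100 × fraction of usable replicates containing the bipartition)`,
the way published NJ figures display them. Replicates with any saturated
pair are discarded and counted. Per-replicate RNG streams are pre-drawn
from the seed, so supports are identical across runs and independent of
evaluation order.

## Tree congruence

Trees are compared unrooted via canonical bipartitions; `rf_distance()` is
the Robinson–Foulds symmetric difference over nontrivial splits.
"Stability" of a strain subgroup is operationalised as: *the clade is
present in every compared tree with support at least `min_support`*
(default 50%). The threshold is exposed because the underlying notion —
"stable branches" — has no canonical formula. `congruence_report()`
returns all qualifying shared splits rather than only set-maximal ones: a
well-supported clade nested inside a larger one is independent evidence of
congruence, and dropping it would hide exactly the information a
marker-comparison table is meant to show.

## The synthetic generator: what it emulates, and what it does not

`simulate_tree()` draws a random binary species tree with uniform edge
lengths (defaults 0.0005–0.005 in time units). With the slow marker at
rate 1 this yields pairwise 16S-like divergences of roughly 0.2–5%, the
range typical of congeneric bacterial strains.

`make_marker_panel()` evolves each marker on the *same* tree under K2P
with independent site histories. Defaults: a slow 16S-like marker
(rate 1, 1500 sites, κ = 2) and fast protein-coding markers (rate 20,
1300 sites and rate 25, 1200 sites, κ = 4). The 20–25× contrast encodes
the published observation that gyrB-class genes evolve orders of magnitude
faster per site than 16S rRNA; only the ordering matters here, and the
multipliers are chosen so that even the longest paths stay safely inside
the K2P-estimable range at these sequence lengths. The simulation model
deliberately matches the inference model, so distance recovery is a clean
correctness surface; model-mismatch experiments are out of scope.

`make_hsp70_family()` evolves a 600-residue protein by a uniform
residue-exchange process (rate multiplier 30 — cross-genus-like divergence
outside conserved motifs) with two planted invariant blocks (defaults
120–131 and 560–571; with the default 22 + 12 primer architecture these
imply a 1352 bp product, the ~1.3 kb regime the pipeline targets). Two
generator choices make the planted truth exact rather than probable:

* the columns immediately flanking each block are forced hypervariable
  (cycling residues from disjoint physicochemical groups), so a
  conserved run can never extend past a planted span by chance;
* codon realisations are shared across taxa *inside* the blocks (strong
  codon conservation at primer sites) and drawn independently per taxon
  outside them, so the designed clamp+core matches every strain exactly
  while the amplified core region still differs between strains.

What the generator does **not** emulate: indels (hence no gapped columns
in simulated alignments), among-site rate heterogeneity beyond the
invariant mask, base-composition and codon-usage bias, intragenomic 16S
copy variation, and alignment uncertainty (inputs are true alignments by
construction). Passing tests therefore demonstrate the *algorithms* are
correct under the stated models, not that any particular real gene will
amplify or resolve a real genus; the real-data step additionally depends
on sequence retrieval and alignment choices outside this package.

## Problem sizes and numerical conventions

The shipped analyses and tests use the study-scale sizes: 16 taxa,
~1.3–1.5 kb markers, 1000 bootstrap replicates for headline support
values, 100 replicates per panel when averaging over ten independently
seeded panels, and distance-recovery checks at L ∈ {500, 1300, 5000}.
K2P closed-form agreement is asserted to 1e−6, NJ additivity to 1e−9,
degeneracy always against brute force under the 4096 cap. All generators
are pure functions of (parameters, seed); every script states its seed.

## Known limitations

* Single-gene distance trees only — no likelihood or Bayesian inference,
  no rate-heterogeneity models, by scope.
* In-silico PCR scores mismatch counts, not hybridisation thermodynamics;
  a site with two tolerated internal mismatches may still fail on the
  bench.
* Clamp placement takes the reference verbatim wherever the window falls;
  if a clamp extends beyond the conserved block it will be reference-biased
  for divergent strains (the mismatch allowance is there to absorb this).
* Circular genomes, nested amplicons and multi-product mixtures are not
  modelled.
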