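# markerforge

Tools for establishing a new protein-coding phylogenetic marker for
bacterial strain identification — the situation where 16S rRNA is too
conserved to separate close congeners (e.g. *Streptomyces* species) and a
faster gene such as *hsp70* (DnaK) or *gyrB* must be recruited and
validated. The package implements the complete chain as tested, reusable
functions:

* **Conserved-block discovery** in a protein multiple alignment
  (`classify_columns()`, `find_conserved_blocks()`), using the Clustal
  `*`/`:`/`.` strong- and weak-group notation.
* **Consensus-clamp / degenerate-core primer design** ("CODEHOP"-style):
  a non-degenerate 5′ clamp taken from a reference CDS plus a fully
  degenerate 3′ core back-translated from conserved residues
  (`back_translate()`, `design_primer_pair()`), with IUPAC degeneracy
  accounting (`primer_degeneracy()`, `expand_primer()`).
* **In-silico PCR** (`find_sites()`, `predict_amplicons()`): IUPAC-aware
  binding-site search with a strict 3′ anchor, nearest-downstream product
  pairing.
* **Phylogenetics from first principles**: Kimura 2-parameter distances
  `d = −½ ln[(1 − 2P − Q)√(1 − 2Q)]` with pairwise deletion and
  saturation handling (`k2p()`, `k2p_distance_matrix()`), neighbour
  joining with deterministic tie-breaking (`nj_tree()`), and a
  column-resampling bootstrap with percentage supports mapped onto the
  point tree (`nj_bootstrap()`).
* **Cross-marker congruence**: Robinson–Foulds distances, per-clade
  support lookup and stable-subgroup detection
  (`rf_distance()`, `clade_support()`, `congruence_report()`).
* **A seeded simulator** for every input: species trees
  (`simulate_tree()`), multi-rate marker panels emulating the slow-16S /
  fast-protein-gene contrast (`make_marker_panel()`), and hsp70-like
  protein families with planted conserved blocks, matching coding
  sequences and genomic templates (`make_hsp70_family()`).

## Worked example: the analysis workflow

The `analysis/` directory contains the pipeline as six numbered scripts;
each is a thin driver over the package functions and writes its tables
under `results/`:

```sh
Rscript analysis/01_simulate_data.R     # species tree, marker panel, protein family
Rscript analysis/02_conserved_blocks.R  # conservation profile -> blocks.tsv
Rscript analysis/03_design_primers.R    # primer pair + published-set checks
Rscript analysis/04_insilico_pcr.R      # amplicons across all 16 templates
Rscript analysis/05_build_trees.R       # K2P/NJ/bootstrap per marker
Rscript analysis/06_compare_markers.R   # RF matrix, clade supports, stable subgroups
```

Output from a run (seed 7, as committed in the scripts):

```
Simulated 16 strains; 3 markers (lengths 1500/1300/1200 nt); protein family
  of 600 residues with blocks 120-131 and 560-571
2 conserved block(s): 120-131, 560-571 | planted: 120-131, 560-571
Designed pair: product 1352 bp on the reference; degeneracies 192 / 96
Published set: degeneracies hsp70-U7F = 27, hsp70-1326R = 12, U1F = 1, 2R = 1
Span consistency: hsp70-U7F ok, hsp70-1326R MISMATCH, U1F ok, 2R ok
16 product(s) across 16 templates; lengths: 1352 | planted: 1352
gyrb_like    1000/1000 usable replicates; internal supports: min 100, median 100, max 100
hsp70_like   1000/1000 usable replicates; internal supports: min 100, median 100, max 100
s16_like     1000/1000 usable replicates; internal supports: min 65,  median 98,  max 100
RF to the generating tree: gyrb_like=0, hsp70_like=0, s16_like=0
13 subgroup(s) stable in every marker at support >= 50%
```

Reading this: block discovery recovers exactly the two planted conserved
regions; the designed clamp+core pair amplifies one product per strain at
precisely the predicted 1352 bp; all three markers recover the generating
topology, but the slow 16S-like marker's bootstrap supports sag on short
internal edges (minimum 65%) where the fast protein-coding markers hold
100% — the quantitative version of the argument for recruiting a faster
marker. The `hsp70-1326R MISMATCH` line flags a genuine internal
inconsistency of the published primer table (a 36-base primer listed with
a 38-position span); the three other rows check out, and the brute-force
degeneracies (27 and 12) equal the per-position product formula.

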