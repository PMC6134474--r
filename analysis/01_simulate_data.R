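#!/usr/bin/env Rscript
# Step 1 — simulate the study system: a 16-strain species tree, a
# three-marker alignment panel (slow 16S-like vs fast hsp70/gyrB-like), and
# an hsp70-like protein family with two planted conserved blocks plus
# per-strain coding sequences and genomic templates.
#
# Everything downstream (blocks, primers, in-silico PCR, trees, congruence)
# reads from results/data/, so this is the only place a seed is chosen.

suppressMessages(library(markerforge))
seed <- 7
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

tree <- simulate_tree(n_taxa = 16, seed = seed)
write_tree(tree, "results/data/species_tree.nwk")

panel <- make_marker_panel(tree, seed = seed + 1)
for (m in names(panel)) {
  write_fasta(aln_to_seqs(panel[[m]]),
              sprintf("results/data/marker_%s.fasta", m))
}

fam <- make_hsp70_family(tree, family_spec(), seed = seed + 2)
write_fasta(aln_to_seqs(fam$proteins), "results/data/family_proteins.fasta")
write_fasta(fam$cds, "results/data/family_cds.fasta")
write_fasta(fam$templates, "results/data/family_templates.fasta")
truth <- list(
  reference_id = fam$reference_id,
  block_spans = fam$truth$block_spans,
  expected_product_len = fam$truth$expected_product_len(),
  cds_span = fam$truth$cds_span
)
writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, pretty = TRUE),
           "results/data/family_truth.json")

cat("Simulated", length(tree$tip.label), "strains;",
    length(panel), "markers (lengths",
    paste(vapply(panel, aln_ncol, numeric(1)), collapse = "/"), "nt);",
    "protein family of", aln_ncol(fam$proteins), "residues with blocks",
    paste(vapply(fam$truth$block_spans, paste, character(1), collapse = "-"),
          collapse = " and "), "\n")
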