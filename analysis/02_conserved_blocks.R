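#!/usr/bin/env Rscript
# Step 2 — conservation profile of the simulated protein family and the
# conserved blocks that can seed primers. With the generator's planted
# design the two blocks should be recovered at exactly their planted spans.

suppressMessages(library(markerforge))

proteins <- as_alignment(read_sequences("results/data/family_proteins.fasta",
                                        moltype = "aa"))
profile <- classify_columns(proteins)
write.csv(profile, "results/blocks_profile.csv", row.names = FALSE)

blocks <- find_conserved_blocks(profile, min_len = 8, min_identical_frac = 0.8)
write.table(blocks, "results/blocks.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

truth <- jsonlite::fromJSON("results/data/family_truth.json")
cat("Column categories:", paste(names(table(profile$category)),
                                table(profile$category), collapse = ", "),
    "\n")
cat(nrow(blocks), "conserved block(s):",
    paste(sprintf("%d-%d", blocks$start, blocks$end), collapse = ", "),
    "| planted:",
    paste(apply(rbind(truth$block_spans), 1, paste, collapse = "-"),
          collapse = ", "),
    "\n")
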