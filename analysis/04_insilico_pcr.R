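#!/usr/bin/env Rscript
# Step 4 — in-silico amplification of the designed pair against every
# strain's genomic template; the computational stand-in for PCR + gel.

suppressMessages(library(markerforge))

primers <- read.delim("results/primers.tsv")
templates <- read_sequences("results/data/family_templates.fasta",
                            moltype = "nt")
truth <- jsonlite::fromJSON("results/data/family_truth.json")

mk <- function(row) {
  degenerate_primer(row$name, row$seq, row$orientation,
                    clamp_len = 22, core_len = nchar(row$seq) - 22,
                    ref_start = row$start, ref_end = row$end)
}
pair <- structure(list(forward = mk(primers[primers$orientation == "sense", ]),
                       reverse = mk(primers[primers$orientation == "antisense", ]),
                       predicted_product_len = NA_integer_),
                  class = "primer_pair")

amp <- predict_amplicons_set(pair, templates, size_bounds = c(1000, 1600),
                             max_mismatch = 2, anchor3 = 3)
write.table(amp[, setdiff(names(amp), "product_seq")],
            "results/amplicons.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
prods <- setNames(amp$product_seq,
                  sprintf("%s|%d-%d", amp$template_id, amp$start, amp$end))
write_fasta(seq_set(prods, "nt"), "results/amplicons.fasta")

cat(nrow(amp), "product(s) across", length(templates), "templates;",
    "lengths:", paste(sort(unique(amp$product_len)), collapse = ", "),
    "| planted:", truth$expected_product_len, "\n")
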