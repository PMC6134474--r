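test_that("IUPAC compression and expansion are mutually inverse", {
  # published degeneracy-code footnote: B = G/C/T; V = A/G/C; S = C/G; H = A/C/T
  expect_identical(iub_compress(c("G", "C", "T")), "B")
  expect_identical(iub_compress(c("A", "G", "C")), "V")
  expect_identical(iub_compress(c("C", "G")), "S")
  expect_identical(iub_compress(c("A", "C", "T")), "H")
  expect_identical(iub_compress("A"), "A")
  expect_identical(iub_compress(c("A", "C", "G", "T")), "N")
  expect_error(iub_compress(character(0)), "empty")
  for (sym in c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                "B", "D", "H", "V", "N")) {
    expect_identical(iub_compress(iub_expand(sym)), sym)
  }
})

test_that("back-translation takes positionwise codon unions", {
  expect_identical(back_translate("M"), "ATG")
  expect_identical(back_translate("W"), "TGG")
  expect_identical(back_translate("D"), "GAY")
  expect_identical(back_translate("MW"), "ATGTGG")
  # K: AAA/AAG -> AAR; F: TTT/TTC -> TTY
  expect_identical(back_translate("KF"), "AARTTY")
  expect_error(back_translate("MBZ"), "unknown residue")
})

test_that("degeneracy equals the brute-force expansion count", {
  u7f <- "CGTGCAGTCGGTATCGACCTCGGBACVACBAACTC"
  r1326 <- "CGATGCCGTTGGCGTCGATGTCGAASGHSACCTCGA"
  expect_equal(primer_degeneracy(u7f), 27)
  expect_equal(primer_degeneracy(r1326), 12)
  expect_equal(length(unique(expand_primer(u7f))), 27)
  expect_equal(length(unique(expand_primer(r1326))), 12)
  expect_equal(primer_degeneracy("ACGTACGTACGTACGTACGT"), 1)
  expect_identical(expand_primer("ATG"), "ATG")
  # property: degeneracy == |expand|, and compress(expand(p)) == p
  for (s in 1:8) {
    p <- random_iupac_seq(12, seed = 100 + s)
    ex <- expand_primer(p)
    expect_equal(length(unique(ex)), primer_degeneracy(p))
    expect_identical(compress_seqs(ex), p)
  }
  expect_error(expand_primer("NNNNNNN"), "cap")
})

test_that("melting range bounds every enumerated expansion", {
  expect_gt(melting_range(strrep("G", 20))[1], melting_range(strrep("A", 20))[2])
  nd <- melting_range("ACGTACGTACGTACGTACGT")
  expect_equal(nd[["tm_min"]], nd[["tm_max"]])
  u7f <- "CGTGCAGTCGGTATCGACCTCGGBACVACBAACTC"
  rng <- melting_range(u7f)
  tms <- vapply(expand_primer(u7f), function(s) melting_range(s)[["tm_min"]],
                numeric(1))
  expect_true(all(tms >= rng[["tm_min"]] - 1e-9))
  expect_true(all(tms <= rng[["tm_max"]] + 1e-9))
  expect_error(melting_range("ACGTACGT"), "short")
})

test_that("primer records enforce the clamp/core architecture", {
  expect_error(degenerate_primer("p", "ACGR", "sense", clamp_len = 2,
                                 core_len = 1), "clamp_len \\+ core_len")
  expect_error(degenerate_primer("p", "ACRG", "sense", clamp_len = 3,
                                 core_len = 1), "non-degenerate")
  p <- degenerate_primer("p", "ACGTACGTACGR", "sense", clamp_len = 11,
                         core_len = 1, ref_start = 1, ref_end = 12)
  expect_equal(p$degeneracy, 2)
})

test_that("designed pairs match the reference and every taxon CDS", {
  fx <- default_family()
  fam <- fx$fam
  prof <- classify_columns(fam$proteins)
  blocks <- find_conserved_blocks(prof, min_len = 8, min_identical_frac = 0.8)
  pair <- design_primer_pair(blocks, fam$proteins, fam$reference_cds,
                             fam$reference_id)
  fwd <- pair$forward; rev <- pair$reverse
  expect_equal(fwd$clamp_len + fwd$core_len, nchar(fwd$seq))
  expect_equal(primer_degeneracy(substr(fwd$seq, 1, fwd$clamp_len)), 1)
  # forward clamp is the reference plus strand verbatim
  expect_identical(substr(fwd$seq, 1, fwd$clamp_len),
                   substr(fam$reference_cds, fwd$ref_start,
                          fwd$ref_end - fwd$core_len))
  # both primers match the reference with 0 mismatches under IUPAC semantics
  expect_equal(iupac_mismatches(
    fwd$seq, substr(fam$reference_cds, fwd$ref_start, fwd$ref_end)), 0)
  expect_equal(iupac_mismatches(
    revcomp(rev$seq), substr(fam$reference_cds, rev$ref_start, rev$ref_end)), 0)
  # and every taxon's CDS, by construction of the degenerate cores
  for (id in names(fam$cds)) {
    cds <- unclass(fam$cds)[[id]]
    expect_equal(iupac_mismatches(
      fwd$seq, substr(cds, fwd$ref_start, fwd$ref_end)), 0)
    expect_equal(iupac_mismatches(
      revcomp(rev$seq), substr(cds, rev$ref_start, rev$ref_end)), 0)
  }
  expect_equal(pair$predicted_product_len,
               rev$ref_end - fwd$ref_start + 1)
  # blocks 1.3 kb apart cannot give a 100-200 bp product
  expect_error(design_primer_pair(blocks, fam$proteins, fam$reference_cds,
                                  fam$reference_id,
                                  product_range = c(100, 200)),
               "outside allowed range")
})

test_that("reverse primers are written 5'->3' on the minus strand", {
  # the published sequencing clamp illustrates the convention: the written
  # antisense clamp is the reverse complement of the low-coordinate end of
  # its plus-strand span
  fx <- default_family()
  fam <- fx$fam
  blocks <- find_conserved_blocks(classify_columns(fam$proteins),
                                  min_len = 8, min_identical_frac = 0.8)
  pair <- design_primer_pair(blocks, fam$proteins, fam$reference_cds,
                             fam$reference_id)
  rev <- pair$reverse
  clamp_plus <- substr(fam$reference_cds, rev$ref_start + rev$core_len,
                       rev$ref_end)
  expect_identical(substr(rev$seq, 1, rev$clamp_len), revcomp(clamp_plus))
})
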