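make_primer <- function(seq, orientation = "sense", name = "p") {
  degenerate_primer(name, seq, orientation,
                    clamp_len = nchar(gsub("[^ACGT]", "", seq)) * 0,
                    core_len = nchar(seq))
}

test_that("exact planted sites are found once with zero mismatches", {
  core <- "ACGTTGCAGGTCAAT"
  tpl <- c(g1 = paste0(random_concrete_seq(60, 1), core,
                       random_concrete_seq(60, 2)))
  p <- make_primer(core)
  hits <- find_sites(p, tpl)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 61)
  expect_equal(hits$end, 75)
  expect_equal(hits$mismatches, 0)
  expect_identical(hits$strand, "+")
})

test_that("the 3' anchor rule vetoes terminal mismatches", {
  core <- "ACGTTGCAGGTCAAT"
  tpl <- c(g1 = paste0(random_concrete_seq(50, 3), core,
                       random_concrete_seq(50, 4)))
  altered <- paste0(substr(core, 1, 14), "G")  # change 3'-terminal base (T->G)
  p <- make_primer(altered)
  expect_equal(nrow(find_sites(p, tpl, max_mismatch = 2, anchor3 = 3)), 0)
  # the same mismatch is tolerated when it lies outside the anchor
  altered5 <- paste0("G", substr(core, 2, 15))
  expect_equal(nrow(find_sites(make_primer(altered5), tpl,
                               max_mismatch = 2, anchor3 = 3)), 1)
})

test_that("antisense primers are searched as their plus-strand complement", {
  site_plus <- "ACGTTGCAGGTCAAT"
  tpl <- c(g1 = paste0(random_concrete_seq(40, 5), site_plus,
                       random_concrete_seq(40, 6)))
  p <- make_primer(revcomp(site_plus), orientation = "antisense")
  hits <- find_sites(p, tpl)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 41)
  expect_identical(hits$strand, "-")
})

test_that("site counts agree with brute force over expansions and offsets", {
  brute_count <- function(primer, tseq, max_mismatch, anchor3) {
    pat <- if (primer$orientation == "sense") primer$seq else revcomp(primer$seq)
    anchor_pos <- if (primer$orientation == "sense") {
      (nchar(pat) - anchor3 + 1):nchar(pat)
    } else seq_len(anchor3)
    n <- 0L
    for (off in seq_len(nchar(tseq) - nchar(pat) + 1)) {
      win <- substr(tseq, off, off + nchar(pat) - 1)
      mm_pos <- which(!mapply(function(a, b) b %in% iub_expand(a),
                              strsplit(pat, "")[[1]], strsplit(win, "")[[1]]))
      if (length(mm_pos) <= max_mismatch && !any(mm_pos %in% anchor_pos)) {
        n <- n + 1L
      }
    }
    n
  }
  set.seed(99)
  for (rep in 1:5) {
    tseq <- random_concrete_seq(2000, seed = 200 + rep)
    # short, degenerate primer so random hits actually occur
    p <- degenerate_primer("p", paste0("RYN", random_iupac_seq(5, 300 + rep),
                                       "NN"), sample(c("sense", "antisense"), 1),
                           clamp_len = 0, core_len = 10)
    got <- nrow(find_sites(p, c(g = tseq), max_mismatch = 2, anchor3 = 2))
    expect_equal(got, brute_count(p, tseq, max_mismatch = 2, anchor3 = 2))
  }
})

test_that("degenerate templates are refused", {
  p <- make_primer("ACGTTGCAGG")
  expect_error(find_sites(p, c(g = "ACGTNACGTACGTAAACGT")), "concrete")
})

test_that("amplicon prediction pairs forward sites with the nearest
           downstream reverse site", {
  fwd_site <- "GACCTGGTCAACGCT"
  rev_site_plus <- "TTGGCACGATCAGGA"
  insert <- random_concrete_seq(1272, 7)
  tpl <- c(g = paste0(random_concrete_seq(50, 8), fwd_site, insert,
                      rev_site_plus, random_concrete_seq(50, 9)))
  pair <- structure(list(
    forward = make_primer(fwd_site, "sense", "fwd"),
    reverse = make_primer(revcomp(rev_site_plus), "antisense", "rev"),
    predicted_product_len = 15 + 1272 + 15), class = "primer_pair")
  amp <- predict_amplicons(pair, tpl, size_bounds = c(1000, 1600))
  expect_equal(nrow(amp), 1)
  expect_equal(amp$product_len, 15 + 1272 + 15)
  expect_equal(amp$start, 51)
  expect_identical(substr(amp$product_seq, 1, 15), fwd_site)
  # product ends match the primers under the same compatibility rule
  expect_equal(iupac_mismatches(fwd_site, substr(amp$product_seq, 1, 15)), 0)
  # no reverse site -> nothing amplifies
  tpl2 <- c(g = paste0(random_concrete_seq(50, 10), fwd_site,
                       random_concrete_seq(1400, 11)))
  expect_equal(nrow(predict_amplicons(pair, tpl2)), 0)
})

test_that("predictions are invariant to flanking sequence and find all
           planted pairs", {
  fwd_site <- "GACCTGGTCAACGCT"
  rev_site_plus <- "TTGGCACGATCAGGA"
  unit <- paste0(fwd_site, random_concrete_seq(1270, 12), rev_site_plus)
  pair <- structure(list(
    forward = make_primer(fwd_site, "sense", "fwd"),
    reverse = make_primer(revcomp(rev_site_plus), "antisense", "rev"),
    predicted_product_len = nchar(unit)), class = "primer_pair")
  for (padlen in c(0, 37, 512)) {
    pad <- if (padlen) random_concrete_seq(padlen, 13) else ""
    tpl <- c(g = paste0(pad, unit, pad))
    amp <- predict_amplicons(pair, tpl)
    expect_equal(nrow(amp), 1)
    expect_equal(amp$product_len, nchar(unit))
    expect_equal(amp$start, padlen + 1)
  }
  # two planted site pairs -> exactly two products
  tpl2 <- c(g = paste0(random_concrete_seq(30, 14), unit,
                       random_concrete_seq(80, 15), unit,
                       random_concrete_seq(30, 16)))
  expect_equal(nrow(predict_amplicons(pair, tpl2)), 2)
})

test_that("the synthetic family amplifies once per taxon at the planted
           length", {
  fx <- default_family()
  fam <- fx$fam
  blocks <- find_conserved_blocks(classify_columns(fam$proteins),
                                  min_len = 8, min_identical_frac = 0.8)
  pair <- design_primer_pair(blocks, fam$proteins, fam$reference_cds,
                             fam$reference_id)
  amp <- predict_amplicons_set(pair, fam$templates)
  expect_equal(nrow(amp), length(fam$templates))
  expect_setequal(amp$template_id, names(fam$templates))
  expect_true(all(amp$product_len == fam$truth$expected_product_len()))
})
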