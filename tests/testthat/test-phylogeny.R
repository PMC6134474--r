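test_that("substitution counting uses pairwise deletion", {
  r <- count_substitutions("ACGT", "ACGT")
  expect_equal(r, list(P = 0, Q = 0, n_valid = 4))
  r <- count_substitutions("AG", "GG")
  expect_equal(r$P, 0.5)
  expect_equal(r$Q, 0)
  expect_equal(r$n_valid, 2)
  r <- count_substitutions("A-CT", "AGCA")
  expect_equal(r$n_valid, 3)
  expect_equal(r$P, 0)
  expect_equal(r$Q, 1 / 3)
  # ambiguity codes are excluded like gaps
  r <- count_substitutions("ANCT", "AGCT")
  expect_equal(r$n_valid, 3)
  expect_error(count_substitutions("--", "AC"), "undefined pair")
})

test_that("k2p matches the closed form and rejects the saturated domain", {
  expect_equal(k2p(0, 0), 0)
  expect_equal(k2p(0.1, 0.05), 0.17019, tolerance = 1e-5 / 0.17)
  expect_equal(k2p(0.1, 0.05),
               -0.5 * log((1 - 0.2 - 0.05) * sqrt(1 - 0.1)))
  expect_error(k2p(0.5, 0.25), class = "mf_saturated_pair")
  expect_error(k2p(0.2, 0.5), class = "mf_saturated_pair")
  # d >= p-distance, equality only at P = Q = 0
  for (P in c(0, 0.05, 0.15)) for (Q in c(0, 0.05, 0.15)) {
    d <- k2p(P, Q)
    expect_gte(d, P + Q - 1e-12)
    if (P + Q > 0) expect_gt(d, P + Q)
  }
})

test_that("k2p inverts the model's expected P/Q equations (grid oracle)", {
  # independent oracle: recover alpha*t and beta*t numerically from the
  # expected-proportion equations, then d = (alpha + 2 beta) t
  invert_numeric <- function(P, Q) {
    b <- -log(1 - 2 * Q) / 4
    f <- function(a) 0.25 + 0.25 * exp(-4 * b) - 0.5 * exp(-2 * (a + b)) - P
    a <- uniroot(f, c(-10, 60), tol = 1e-12)$root
    a + 2 * b
  }
  for (P in seq(0.01, 0.25, by = 0.04)) {
    for (Q in seq(0.01, 0.25, by = 0.04)) {
      if (1 - 2 * P - Q <= 0.05) next
      expect_equal(k2p(P, Q), invert_numeric(P, Q), tolerance = 1e-6)
    }
  }
})

test_that("distance matrices are symmetric, zero-diagonal and agree with an
           independent K80 implementation", {
  aln <- evolve_alignment(rand_tree(8, seed = 21, lo = 0.01, hi = 0.1),
                          marker_config("m", 1, 800), seed = 22)
  dm <- k2p_distance_matrix(aln)
  expect_identical(dm$d, t(dm$d))
  expect_true(all(diag(dm$d) == 0))
  bin <- ape::as.DNAbin(aln$mat)
  oracle <- as.matrix(ape::dist.dna(bin, model = "K80",
                                    pairwise.deletion = TRUE))
  expect_equal(dm$d, oracle[dm$labels, dm$labels], tolerance = 1e-12,
               ignore_attr = TRUE)
  # identical sequences -> zero matrix
  z <- k2p_distance_matrix(nt_aln(a = "ACGTACGT", b = "ACGTACGT",
                                  c = "ACGTACGT"))
  expect_true(all(z$d == 0))
})

test_that("saturated pairs are reported or masked as requested", {
  # maximally diverged pair: all transversions
  aln <- nt_aln(a = strrep("A", 40), b = strrep("C", 40), c = strrep("A", 40))
  expect_error(k2p_distance_matrix(aln), "undefined.*a/b")
  dm <- k2p_distance_matrix(aln, on_undefined = "mask")
  expect_false(dm$defined["a", "b"])
  expect_true(dm$defined["a", "c"])
})

test_that("NJ recovers the 3-taxon closed form", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  # a = (d12 + d13 - d23)/2 = 1, b = 2, c = 3
  lens <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[["A"]], 1)
  expect_equal(lens[["B"]], 2)
  expect_equal(lens[["C"]], 3)
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
})

test_that("NJ is exact on additive matrices (random trees, n = 4..16)", {
  for (n in c(4, 7, 10, 16)) {
    truth <- rand_tree(n, seed = 400 + n)
    tr <- nj_tree(additive_matrix(truth))
    expect_equal(rf_distance(tr, truth), 0)
    D <- additive_matrix(truth)
    expect_equal(max(abs(cophenetic(tr)[rownames(D), rownames(D)] - D)), 0,
                 tolerance = 1e-9)
  }
  # four-point construction: ((A:1,B:1):2,(C:1,D:1))
  truth <- ape::read.tree(text = "((A:1,B:1):2,(C:1,D:1):0);")
  tr <- nj_tree(additive_matrix(truth))
  expect_equal(rf_distance(tr, truth), 0)
  tab <- internal_edge_table(tr)
  expect_equal(tab$length, 2)
})

test_that("NJ agrees topologically with an independent implementation", {
  for (s in 1:3) {
    truth <- rand_tree(9, seed = 500 + s)
    D <- additive_matrix(truth)
    ours <- nj_tree(D)
    theirs <- ape::nj(as.dist(D))
    expect_equal(rf_distance(ours, theirs), 0)
  }
})

test_that("Q-score ties are broken by the lexicographically smallest pair", {
  labs <- c("B", "A", "D", "C")
  d <- matrix(2, 4, 4, dimnames = list(labs, labs)); diag(d) <- 0
  tr <- nj_tree(d)
  # with all distances equal, the first join must be {A, B}
  expect_identical(names(tree_splits(tr)),
                   markerforge:::.split_key(c("A", "B"), labs))
})

test_that("bootstrap supports are reproducible, bounded and mapped onto the
           point tree", {
  sp <- simulate_tree(12, seed = 31)
  aln <- evolve_alignment(sp, marker_config("m", 20, 600), seed = 32)
  b1 <- nj_bootstrap(aln, n_reps = 50, seed = 77)
  b2 <- nj_bootstrap(aln, n_reps = 50, seed = 77)
  expect_identical(b1$split_freq, b2$split_freq)
  expect_identical(b1$tree$node.label, b2$tree$node.label)
  supports <- as.integer(b1$tree$node.label[nzchar(b1$tree$node.label)])
  expect_true(all(supports >= 0 & supports <= 100))
  # the trifurcation node carries no support
  expect_true(any(!nzchar(b1$tree$node.label)))
  expect_error(nj_bootstrap(aln, n_reps = 0, seed = 1), "n_reps")
})

test_that("support for a true clade rises with internal edge length", {
  # stochastic but seeded: 5 edge lengths x 3 alignments each
  mean_support <- vapply(c(0.001, 0.005, 0.02, 0.05, 0.1), function(len) {
    txt <- sprintf(paste0(
      "(((a:0.02,b:0.02):0.02,(c:0.02,d:0.02):0.02):%.4f,",
      "(e:0.02,f:0.02):0.02,(g:0.02,h:0.02):0.02);"), len)
    tr <- ape::read.tree(text = txt)
    mean(vapply(1:3, function(s) {
      aln <- evolve_alignment(tr, marker_config("m", 1, 1300),
                              seed = 600 + round(1e4 * len) + s)
      boot_support(nj_bootstrap(aln, n_reps = 60, seed = s),
                   c("a", "b", "c", "d"))
    }, numeric(1)))
  }, numeric(1))
  expect_gt(mean(diff(mean_support)), 0)   # increasing on average
  expect_gt(mean_support[5], mean_support[1])
})
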