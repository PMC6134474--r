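# Shared fixture builders: everything is generated in code.

# random unrooted binary tree with positive edge lengths
rand_tree <- function(n, seed, lo = 0.05, hi = 0.5) {
  set.seed(seed)
  ape::rtree(n, rooted = FALSE, br = function(k) runif(k, lo, hi))
}

# tiny nucleotide alignment from named strings
nt_aln <- function(...) {
  as_alignment(seq_set(c(...), moltype = "nt"))
}

aa_aln <- function(...) {
  as_alignment(seq_set(c(...), moltype = "aa"))
}

# path-length (additive) distance matrix of a tree, labels sorted
additive_matrix <- function(tree) {
  D <- cophenetic(tree)
  D[sort(rownames(D)), sort(rownames(D))]
}

random_concrete_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_iupac_seq <- function(n, seed, symbols = c("A", "C", "G", "T", "R",
                                                  "Y", "S", "W", "K", "M")) {
  set.seed(seed)
  paste(sample(symbols, n, replace = TRUE), collapse = "")
}

# default synthetic family used across modules (cached per session)
default_family <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tr <- simulate_tree(16, seed = 7)
      cache <<- list(tree = tr, fam = make_hsp70_family(tr, seed = 7))
    }
    cache
  }
})
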