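# Seeded generators for everything the pipeline consumes: species trees,
# multi-rate nucleotide marker panels evolved under K2P, and hsp70-like
# protein families with planted invariant blocks plus matching coding
# sequences and genomic templates. All generators are pure functions of
# (parameters, seed).

#' Simulate a random species tree
#'
#' Random binary topology (via \pkg{ape}) with i.i.d. uniform edge lengths.
#' Default edge lengths of 0.0005-0.005 (time units, i.e. expected
#' substitutions per site for a marker of rate multiplier 1) give
#' within-genus 16S-like divergences of roughly 0.2-5%.
#'
#' @param n_taxa Number of leaves (>= 3; default 16, the size of a typical
#'   strain panel).
#' @param seed Integer seed.
#' @param edge_min,edge_max Uniform bounds for edge lengths.
#' @return An unrooted binary `phylo` with labels `t01`, `t02`, ...
#' @export
simulate_tree <- function(n_taxa = 16, seed = 1,
                          edge_min = 5e-4, edge_max = 5e-3) {
  if (n_taxa < 3) stop("n_taxa must be >= 3")
  set.seed(seed)
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(n) stats::runif(n, edge_min, edge_max))
  tr$tip.label <- sprintf("t%02d", as.integer(sub("t", "", tr$tip.label)))
  tr
}

#' Marker simulation settings
#'
#' @param name Marker name.
#' @param rate_multiplier Substitution rate relative to the species-tree
#'   time scale (> 0).
#' @param length Alignment length in sites.
#' @param kappa Transition/transversion rate ratio (alpha/beta, > 0).
#' @param invariant_mask Optional integer site indices held fixed.
#' @return A list of class `marker_config`.
#' @export
marker_config <- function(name, rate_multiplier, length, kappa = 4,
                          invariant_mask = NULL) {
  if (rate_multiplier < 0) stop("rate_multiplier must be >= 0")
  if (length < 1) stop("length must be >= 1")
  if (kappa <= 0) stop("kappa must be > 0")
  structure(list(name = name, rate_multiplier = rate_multiplier,
                 length = as.integer(length), kappa = kappa,
                 invariant_mask = invariant_mask),
            class = "marker_config")
}

#' Default three-marker panel configuration
#'
#' A slow ribosomal-like marker (rate 1, 1500 sites) against two fast
#' protein-coding markers (20x and 25x, ~1300 and 1200 sites), mirroring
#' the published contrast between 16S rRNA and hsp70/gyrB substitution
#' rates, which is used here only as an ordering (slow vs fast).
#'
#' @export
default_marker_configs <- function() {
  list(
    marker_config("s16_like", rate_multiplier = 1, length = 1500, kappa = 2),
    marker_config("hsp70_like", rate_multiplier = 20, length = 1300, kappa = 4),
    marker_config("gyrb_like", rate_multiplier = 25, length = 1200, kappa = 4)
  )
}

# K2P transition probabilities for one branch: given duration t in expected
# substitutions/site and kappa = alpha/beta with rates normalised to
# alpha + 2 beta = 1.
.k2p_probs <- function(t, kappa) {
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  e1 <- exp(-4 * beta * t)
  e2 <- exp(-2 * (alpha + beta) * t)
  c(same = 0.25 + 0.25 * e1 + 0.5 * e2,
    ts = 0.25 + 0.25 * e1 - 0.5 * e2,
    tv = 0.25 - 0.25 * e1)  # each of the two transversions
}

# one K2P step for a vector of parent base codes (1=A,2=C,3=G,4=T)
.k2p_step <- function(codes, t, kappa) {
  pr <- .k2p_probs(t, kappa)
  u <- stats::runif(length(codes))
  partner_ts <- c(3L, 4L, 1L, 2L)
  tv1 <- c(2L, 1L, 2L, 1L)
  tv2 <- c(4L, 3L, 4L, 3L)
  out <- codes
  is_ts <- u >= pr["same"] & u < pr["same"] + pr["ts"]
  is_tv1 <- u >= pr["same"] + pr["ts"] & u < pr["same"] + pr["ts"] + pr["tv"]
  is_tv2 <- u >= pr["same"] + pr["ts"] + pr["tv"]
  out[is_ts] <- partner_ts[codes[is_ts]]
  out[is_tv1] <- tv1[codes[is_tv1]]
  out[is_tv2] <- tv2[codes[is_tv2]]
  out
}

#' Evolve a nucleotide alignment along a tree under K2P
#'
#' The root sequence is uniform over `{A,C,G,T}`; each edge applies the
#' exact K2P transition probabilities for duration
#' `edge length * rate_multiplier` with transition/transversion ratio
#' `kappa`. Sites in `invariant_mask` never change. Site histories are
#' independent.
#'
#' @param tree A `phylo` with edge lengths.
#' @param config A [marker_config()].
#' @param seed Integer seed.
#' @return A nucleotide `marker_aln` with one row per leaf.
#' @export
evolve_alignment <- function(tree, config, seed = 1) {
  set.seed(seed)
  n <- length(tree$tip.label)
  nn <- tree$Nnode
  L <- config$length
  root_codes <- sample.int(4L, L, replace = TRUE)
  seqs <- vector("list", n + nn)
  root <- n + 1L
  seqs[[root]] <- root_codes
  tr <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  mask <- config$invariant_mask
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    t <- tr$edge.length[e] * config$rate_multiplier
    child <- .k2p_step(seqs[[par]], t, config$kappa)
    if (!is.null(mask)) child[mask] <- root_codes[mask]
    seqs[[ch]] <- child
  }
  bases <- c("A", "C", "G", "T")
  mat <- do.call(rbind, lapply(seq_len(n), function(i) bases[seqs[[i]]]))
  rownames(mat) <- tree$tip.label
  as_alignment(mat, moltype = "nt")
}

#' Simulate a multi-marker alignment panel on one species tree
#'
#' All markers are evolved on the same tree with independent site
#' histories, so their true topologies agree while their resolving power
#' differs with rate.
#'
#' @param tree Species tree (`phylo`).
#' @param configs List of [marker_config()]s with distinct names and at
#'   least two distinct rate multipliers.
#' @param seed Integer seed; per-marker streams are derived from it.
#' @return Named list marker name -> nucleotide `marker_aln`.
#' @export
make_marker_panel <- function(tree, configs = default_marker_configs(),
                              seed = 1) {
  nms <- vapply(configs, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate marker names")
  if (length(unique(vapply(configs, `[[`, numeric(1), "rate_multiplier"))) < 2) {
    stop("need at least two distinct rate multipliers")
  }
  set.seed(seed)
  marker_seeds <- sample.int(.Machine$integer.max - 1L, length(configs))
  out <- lapply(seq_along(configs), function(i) {
    evolve_alignment(tree, configs[[i]], seed = marker_seeds[i])
  })
  stats::setNames(out, nms)
}

#' Protein-family simulation settings
#'
#' Describes an hsp70-like family: a protein whose sequence drifts freely
#' except in two planted invariant blocks, which flank the variable core
#' that a primer pair is meant to amplify across taxa.
#'
#' @param n_taxa Number of taxa (>= 4; default 16).
#' @param protein_length Protein length in residues (default 600,
#'   comfortably holding a ~1.3 kb amplicon between the default blocks).
#' @param block_spans List of two disjoint residue ranges `c(start, end)`
#'   held invariant (defaults 120-131 and 560-571; with the default primer
#'   architecture these imply a 1352 bp product, matching the "about 1300
#'   bp" regime the pipeline targets).
#' @param core_divergence Rate multiplier for non-block residues relative
#'   to the species-tree time scale (default 30: cross-genus-like
#'   divergence outside the conserved motifs).
#' @return A list of class `family_spec`.
#' @export
family_spec <- function(n_taxa = 16, protein_length = 600,
                        block_spans = list(c(120, 131), c(560, 571)),
                        core_divergence = 30) {
  if (n_taxa < 4) stop("n_taxa must be >= 4")
  if (length(block_spans) != 2) stop("exactly two block spans required")
  b1 <- block_spans[[1]]; b2 <- block_spans[[2]]
  if (b1[1] > b1[2] || b2[1] > b2[2]) stop("invalid block span")
  if (b1[2] >= b2[1]) stop("block spans must be disjoint and ordered")
  if (b2[2] > protein_length || b1[1] < 2) {
    stop("blocks must lie within positions 2..protein_length")
  }
  structure(list(n_taxa = as.integer(n_taxa),
                 protein_length = as.integer(protein_length),
                 block_spans = block_spans,
                 core_divergence = core_divergence),
            class = "family_spec")
}

# uniform-exchange residue step over the 20 amino-acid letters:
# stay with prob 1/20 + (19/20) exp(-20 t / 19), else uniform over the rest
.aa_step <- function(codes, t) {
  p_same <- 1 / 20 + (19 / 20) * exp(-20 * t / 19)
  change <- stats::runif(length(codes)) >= p_same
  idx <- which(change)
  if (length(idx)) {
    shift <- sample.int(19L, length(idx), replace = TRUE)
    codes[idx] <- ((codes[idx] - 1L + shift) %% 20L) + 1L
  }
  codes
}

#' Generate an hsp70-like protein family with planted conserved blocks
#'
#' Proteins evolve along the tree by a uniform residue-exchange process;
#' residues inside the planted blocks are frozen. The two columns
#' immediately flanking each block are made hypervariable (cycling through
#' residues of different physicochemical groups) so the planted spans are
#' unambiguous ground truth for block discovery. Coding sequences realise
#' each protein at the codon level: synonymous codons are drawn per taxon
#' outside the blocks, while inside the blocks one shared codon realisation
#' is used for all taxa (strong codon conservation at the primer sites).
#' Templates embed each CDS in random genomic flanks.
#'
#' @param tree Species tree (`phylo`) whose leaves name the taxa.
#' @param spec A [family_spec()]; its `n_taxa` must equal the number of
#'   leaves.
#' @param seed Integer seed.
#' @param flank_range Uniform bounds for the random flank lengths (bases).
#' @return List with `proteins` (aa `marker_aln`), `cds` (`seq_set`),
#'   `reference_id`, `reference_cds` (string), `templates` (`seq_set`),
#'   and `truth`: list with `block_spans` (residue coords), `cds_span`
#'   per template, and `expected_product_len(clamp_len, core_len)`.
#' @export
make_hsp70_family <- function(tree, spec = family_spec(), seed = 1,
                              flank_range = c(150, 400)) {
  taxa <- tree$tip.label
  if (length(taxa) != spec$n_taxa) {
    stop("tree has ", length(taxa), " leaves but spec$n_taxa = ", spec$n_taxa)
  }
  set.seed(seed)
  L <- spec$protein_length
  n <- length(taxa)
  b1 <- spec$block_spans[[1]]; b2 <- spec$block_spans[[2]]
  block_sites <- c(seq(b1[1], b1[2]), seq(b2[1], b2[2]))
  flank_sites <- intersect(c(b1[1] - 1L, b1[2] + 1L, b2[1] - 1L, b2[2] + 1L),
                           seq_len(L))

  # evolve protein codes (1..20 over AA_LETTERS)
  root_codes <- sample.int(20L, L, replace = TRUE)
  nn <- tree$Nnode
  seqs <- vector("list", n + nn)
  seqs[[n + 1L]] <- root_codes
  tr <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    t <- tr$edge.length[e] * spec$core_divergence
    child <- .aa_step(seqs[[par]], t)
    child[block_sites] <- root_codes[block_sites]
    seqs[[ch]] <- child
  }
  # hypervariable flank columns: cycle residues across taxa through groups
  # that share no strong/weak class (P, W, E, V)
  flank_codes <- match(c("P", "W", "E", "V"), AA_LETTERS)
  prot <- do.call(rbind, lapply(seq_len(n), function(i) AA_LETTERS[seqs[[i]]]))
  rownames(prot) <- taxa
  for (j in flank_sites) {
    prot[, j] <- AA_LETTERS[rep_len(flank_codes, n)]
  }
  proteins <- as_alignment(prot, moltype = "aa")

  # codon realisation: shared inside blocks, per-taxon synonymous outside
  tbl <- .codon_table()
  pick_codon <- function(aa) {
    cods <- tbl[[aa]]
    cods[sample.int(length(cods), 1L)]
  }
  shared_codons <- character(L)
  for (j in block_sites) shared_codons[j] <- pick_codon(prot[1, j])
  cds <- vapply(seq_len(n), function(i) {
    paste(vapply(seq_len(L), function(j) {
      if (j %in% block_sites) shared_codons[j] else pick_codon(prot[i, j])
    }, character(1)), collapse = "")
  }, character(1))
  names(cds) <- taxa
  cds_set <- seq_set(cds, moltype = "nt")
  reference_id <- taxa[1]

  flanks <- function() {
    len <- round(stats::runif(1, flank_range[1], flank_range[2]))
    paste(c("A", "C", "G", "T")[sample.int(4L, len, replace = TRUE)],
          collapse = "")
  }
  cds_span <- vector("list", n)
  templates <- vapply(seq_len(n), function(i) {
    up <- flanks(); down <- flanks()
    cds_span[[i]] <<- c(start = nchar(up) + 1L,
                        end = nchar(up) + nchar(cds[[i]]))
    paste0(up, cds[i], down)
  }, character(1))
  names(templates) <- taxa
  names(cds_span) <- taxa

  truth <- list(
    block_spans = spec$block_spans,
    cds_span = cds_span,
    expected_product_len = function(clamp_len = 22, core_len = 12) {
      3L * (b2[1] - b1[2]) + 2L * (clamp_len + core_len) - 3L
    }
  )
  list(proteins = proteins, cds = cds_set, reference_id = reference_id,
       reference_cds = unname(cds[1]), templates = seq_set(templates, "nt"),
       truth = truth)
}
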