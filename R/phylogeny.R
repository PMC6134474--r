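# Kimura 2-parameter distances, neighbour-joining and the column-resampling
# bootstrap, implemented from the closed forms. ape/phangorn equivalents are
# used only as independent cross-checks in the test suite.

#' Transition/transversion counts between two aligned sequences
#'
#' Pairwise deletion: columns where either sequence has a gap or any
#' non-`ACGT` symbol are excluded. `P` is the proportion of transitions
#' (A<->G, C<->T) and `Q` of transversions among the `n_valid` remaining
#' columns.
#'
#' @param seq_i,seq_j Equal-length aligned nucleotide strings (or character
#'   vectors of single residues).
#' @return List with `P`, `Q`, `n_valid`.
#' @export
count_substitutions <- function(seq_i, seq_j) {
  x <- if (length(seq_i) == 1L) strsplit(toupper(seq_i), "")[[1]] else toupper(seq_i)
  y <- if (length(seq_j) == 1L) strsplit(toupper(seq_j), "")[[1]] else toupper(seq_j)
  if (length(x) != length(y)) stop("sequences must be aligned (equal length)")
  cx <- match(x, c("A", "C", "G", "T"))
  cy <- match(y, c("A", "C", "G", "T"))
  ok <- !is.na(cx) & !is.na(cy)
  n_valid <- sum(ok)
  if (n_valid == 0L) stop("undefined pair: no valid (gap- and ambiguity-free) columns")
  cx <- cx[ok]; cy <- cy[ok]
  diff <- cx != cy
  # transitions: A(1)<->G(3), C(2)<->T(4): codes differ by 2
  ts <- diff & (abs(cx - cy) == 2L)
  list(P = sum(ts) / n_valid, Q = sum(diff & !ts) / n_valid,
       n_valid = n_valid)
}

#' Kimura 2-parameter distance
#'
#' `d = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q))`, defined only when
#' `1 - 2P - Q > 0` and `1 - 2Q > 0`; outside that domain the pair is
#' saturated and an error of class `mf_saturated_pair` is thrown.
#'
#' @param P Transition proportion, or the list from
#'   [count_substitutions()] (then `Q` is ignored).
#' @param Q Transversion proportion.
#' @return Distance in expected substitutions per site.
#' @examples
#' k2p(0.1, 0.05)  # 0.17019...
#' @export
k2p <- function(P, Q = NULL) {
  if (is.list(P)) { Q <- P$Q; P <- P$P }
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    cond <- structure(
      list(message = sprintf(
        "saturated pair: P=%.4g Q=%.4g outside the K2P domain", P, Q),
        call = sys.call(-1)),
      class = c("mf_saturated_pair", "error", "condition"))
    stop(cond)
  }
  -0.5 * log(w1 * sqrt(w2))
}

# One-hot encode an alignment: list of four n x L 0/1 matrices (A,C,G,T).
.onehot <- function(aln) {
  lapply(c("A", "C", "G", "T"), function(b) (aln$mat == b) * 1)
}

#' Pairwise K2P distance matrix of a nucleotide alignment
#'
#' All pairs are computed with pairwise deletion via
#' [count_substitutions()] and [k2p()] (vectorised over pairs internally).
#' Saturated or empty pairs are either a hard error listing the offending
#' pairs (`on_undefined = "error"`, the default) or recorded as undefined
#' in the `defined` mask (`"mask"`, used by the bootstrap to discard
#' replicates).
#'
#' @param aln A nucleotide `marker_aln` with at least 3 rows.
#' @param on_undefined `"error"` or `"mask"`.
#' @return Object of class `dist_mx`: list with `labels`, `d` (symmetric
#'   numeric matrix, zero diagonal), `defined` (logical matrix).
#' @export
k2p_distance_matrix <- function(aln, on_undefined = c("error", "mask")) {
  on_undefined <- match.arg(on_undefined)
  aln <- as_alignment(aln)
  if (aln$moltype != "nt") stop("expected a nucleotide alignment")
  n <- aln_ntaxa(aln)
  if (n < 3) stop("need at least 3 taxa")
  X <- .onehot(aln)
  # counts[b][c] (n x n): columns where row i has base b and row j base c
  N <- array(0, dim = c(n, n))
  ts_n <- tv_n <- valid_n <- matrix(0, n, n)
  for (b in 1:4) {
    for (cc in 1:4) {
      Nbc <- X[[b]] %*% t(X[[cc]])
      valid_n <- valid_n + Nbc
      if (b != cc) {
        if (abs(b - cc) == 2L) ts_n <- ts_n + Nbc else tv_n <- tv_n + Nbc
      }
    }
  }
  d <- matrix(0, n, n)
  defined <- matrix(TRUE, n, n)
  P <- ifelse(valid_n > 0, ts_n / valid_n, NA_real_)
  Q <- ifelse(valid_n > 0, tv_n / valid_n, NA_real_)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  bad <- valid_n == 0 | w1 <= 0 | w2 <= 0
  diag(bad) <- FALSE
  d <- suppressWarnings(-0.5 * log(w1 * sqrt(w2)))
  d[bad] <- NA_real_
  diag(d) <- 0
  defined[bad] <- FALSE
  labels <- aln_labels(aln)
  dimnames(d) <- dimnames(defined) <- list(labels, labels)
  if (on_undefined == "error" && any(!defined)) {
    idx <- which(!defined & upper.tri(defined), arr.ind = TRUE)
    pairs <- apply(idx, 1, function(r) paste(labels[r[1]], labels[r[2]], sep = "/"))
    stop("undefined (saturated or empty) pairs: ", paste(pairs, collapse = ", "))
  }
  structure(list(labels = labels, d = d, defined = defined),
            class = "dist_mx")
}

#' Build a distance-matrix object from a plain matrix
#' @param m Symmetric numeric matrix with dimnames.
#' @export
dist_mx <- function(m) {
  if (is.null(rownames(m))) stop("matrix must have dimnames")
  if (!isTRUE(all.equal(m, t(m)))) stop("matrix must be symmetric")
  structure(list(labels = rownames(m), d = m,
                 defined = !is.na(m)), class = "dist_mx")
}

#' Neighbour-joining tree construction
#'
#' Standard neighbour joining: iteratively join the pair minimising
#' `Q(i,j) = (m-2) d(i,j) - R_i - R_j` (with `R_i = sum_k d(i,k)` over the
#' current clusters), assign branch lengths by the rate-corrected split
#' `l_i = d(i,j)/2 + (R_i - R_j) / (2(m-2))`, and reduce the matrix with
#' `d(u,k) = (d(i,k) + d(j,k) - d(i,j)) / 2`. Ties in `Q` are broken by
#' joining the pair whose (lexicographically smallest member, then partner)
#' labels sort first, so results are deterministic. On an additive matrix
#' the generating topology and branch lengths are recovered exactly.
#' Negative branch lengths are kept as computed.
#'
#' @param dm A `dist_mx` (fully defined) or symmetric matrix with dimnames.
#' @return An unrooted binary `phylo` (trifurcation at the root node).
#' @export
nj_tree <- function(dm) {
  if (is.matrix(dm)) dm <- dist_mx(dm)
  if (any(!dm$defined)) stop("distance matrix has undefined pairs")
  d <- dm$d
  labels <- dm$labels
  m <- length(labels)
  if (m < 3) stop("need at least 3 taxa")
  # cluster state: newick fragment and representative (smallest leaf) label
  nwk <- labels
  rep_lab <- labels
  fmt <- function(x) sprintf("%.12g", x)
  while (m > 3) {
    R <- rowSums(d)
    Qm <- (m - 2) * d - outer(R, R, "+")
    diag(Qm) <- Inf
    qmin <- min(Qm)
    cand <- which(Qm - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1, function(r) {
      p <- sort(c(rep_lab[r[1]], rep_lab[r[2]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    new_nwk <- paste0("(", nwk[i], ":", fmt(li), ",", nwk[j], ":", fmt(lj), ")")
    new_rep <- min(rep_lab[i], rep_lab[j])
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
               c(dk[keep], 0))
    nwk <- c(nwk[keep], new_nwk)
    rep_lab <- c(rep_lab[keep], new_rep)
    m <- m - 1L
  }
  l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  txt <- paste0("(", nwk[1], ":", fmt(l1), ",", nwk[2], ":", fmt(l2),
                ",", nwk[3], ":", fmt(l3), ");")
  ape::read.tree(text = txt)
}

#' Neighbour-joining with a column-resampling bootstrap
#'
#' Builds the point-estimate NJ tree from the full alignment, then for each
#' replicate resamples alignment columns with replacement (same length),
#' recomputes the K2P distances and the NJ tree, and scores each internal
#' edge of the point tree by the percentage of usable replicates containing
#' the same bipartition (`round(100 * fraction)`). Replicates in which any
#' pair is saturated are discarded and counted. Replicate RNG streams are
#' pre-drawn from `seed`, so results are reproducible and independent of
#' evaluation order.
#'
#' @param aln Nucleotide `marker_aln`.
#' @param n_reps Number of bootstrap replicates (>= 1; 1000 in typical
#'   published use).
#' @param seed Integer seed.
#' @return Object of class `boot_tree`: list with `tree` (point-estimate
#'   `phylo`, internal-node labels = integer percentage supports),
#'   `split_freq` (named numeric vector: percentage, over usable
#'   replicates, of every nontrivial split observed in any replicate),
#'   `n_used`, `n_discarded`.
#' @export
nj_bootstrap <- function(aln, n_reps = 1000, seed = 1) {
  aln <- as_alignment(aln)
  if (n_reps < 1) stop("n_reps must be >= 1")
  point <- nj_tree(k2p_distance_matrix(aln))
  L <- aln_ncol(aln)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  counts <- new.env(hash = TRUE, parent = emptyenv())
  n_used <- 0L
  for (r in seq_len(n_reps)) {
    set.seed(rep_seeds[r])
    cols <- sample.int(L, L, replace = TRUE)
    rep_aln <- aln_subset_cols(aln, cols)
    dm <- k2p_distance_matrix(rep_aln, on_undefined = "mask")
    if (any(!dm$defined)) next
    rep_tree <- nj_tree(dm)
    n_used <- n_used + 1L
    for (key in names(tree_splits(rep_tree))) {
      counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
    }
  }
  if (n_used == 0L) stop("all bootstrap replicates were discarded (saturation)")
  keys <- ls(counts)
  split_freq <- stats::setNames(
    vapply(keys, function(k) 100 * counts[[k]] / n_used, numeric(1)), keys)
  point_splits <- tree_splits(point)
  tree <- .set_split_supports(point, vapply(names(point_splits), function(k) {
    v <- split_freq[k]
    as.integer(round(if (is.na(v)) 0 else v))
  }, integer(1)))
  structure(list(tree = tree, split_freq = split_freq,
                 n_used = n_used, n_discarded = n_reps - n_used),
            class = "boot_tree")
}

#' @export
print.boot_tree <- function(x, ...) {
  cat(sprintf("<boot_tree> %d leaves, %d/%d usable replicates\n",
              length(x$tree$tip.label), x$n_used, x$n_used + x$n_discarded))
  invisible(x)
}

#' Bootstrap support of a given split
#'
#' @param boot A `boot_tree`.
#' @param taxa Character vector of leaf labels (either side of the split).
#' @return Percentage support (0 when the split never occurred).
#' @export
boot_support <- function(boot, taxa) {
  key <- .split_key(taxa, x_all = boot$tree$tip.label)
  v <- boot$split_freq[key]
  if (is.na(v)) 0 else unname(v)
}
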