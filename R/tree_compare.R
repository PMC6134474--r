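# Bipartition (split) machinery, Robinson-Foulds distances and the
# cross-marker congruence report. Trees are compared unrooted; any input
# rooting is cosmetic and discarded.

# Canonical key of a split: the side NOT containing the lexicographically
# smallest leaf, sorted and pipe-joined. Complementary sides map to the
# same key, so lookups are rooting-invariant.
.split_key <- function(taxa, x_all) {
  taxa <- sort(unique(taxa))
  anchor <- min(x_all)
  if (anchor %in% taxa) taxa <- sort(setdiff(x_all, taxa))
  paste(taxa, collapse = "|")
}

# tips under each node of a phylo (list indexed by node number)
.tips_under <- function(tree) {
  n <- length(tree$tip.label)
  nn <- tree$Nnode
  tr <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", n + nn)
  for (i in seq_len(n)) sets[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    sets[[par]] <- c(sets[[par]], sets[[ch]])
  }
  sets
}

#' Nontrivial bipartitions of an unrooted tree
#'
#' Each internal edge of an unrooted tree splits the leaves in two; the
#' splits are returned keyed canonically so complementary sides and
#' arbitrary rootings compare equal. An unrooted binary n-leaf tree has
#' exactly `n - 3` nontrivial splits.
#'
#' @param tree A `phylo` with unique leaf labels. Internal node labels, if
#'   present, are interpreted as integer percentage supports.
#' @param include_trivial Also return the n leaf splits.
#' @return Named list (key = canonical split id); each element a list with
#'   `side` (sorted label vector, the canonical side) and `support`
#'   (integer or `NA`).
#' @export
tree_splits <- function(tree, include_trivial = FALSE) {
  labs <- tree$tip.label
  if (anyDuplicated(labs)) stop("duplicate leaf labels")
  n <- length(labs)
  tree <- ape::unroot(tree)
  sets <- .tips_under(tree)
  has_support <- !is.null(tree$node.label)
  out <- list()
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2]
    side <- sets[[ch]]
    k <- length(side)
    trivial <- k == 1L || k == n - 1L
    if (trivial && !include_trivial) next
    supp <- NA_integer_
    if (!trivial && has_support && ch > n) {
      lab <- tree$node.label[ch - n]
      if (!is.null(lab) && !is.na(lab) && nzchar(lab)) {
        supp <- suppressWarnings(as.integer(lab))
      }
    }
    key <- .split_key(side, labs)
    out[[key]] <- list(side = sort(side), support = supp)
  }
  out
}

# Write integer supports (named by split key) onto the point tree's
# internal node labels; nodes whose edge is trivial/absent get "".
.set_split_supports <- function(tree, supports) {
  tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  sets <- .tips_under(tree)
  node.label <- rep("", tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2]
    if (ch <= n) next
    side <- sets[[ch]]
    if (length(side) == 1L || length(side) == n - 1L) next
    key <- .split_key(side, tree$tip.label)
    if (key %in% names(supports)) {
      node.label[ch - n] <- as.character(supports[[key]])
    }
  }
  tree$node.label <- node.label
  tree
}

#' Robinson-Foulds distance between two trees
#'
#' The size of the symmetric difference of the two trees' nontrivial
#' bipartition sets; `0 <= rf <= 2(n-3)` for binary trees on the same n
#' leaves.
#'
#' @param tree_a,tree_b `phylo` objects over the same leaf set.
#' @return Integer distance.
#' @export
rf_distance <- function(tree_a, tree_b) {
  la <- sort(tree_a$tip.label); lb <- sort(tree_b$tip.label)
  if (!identical(la, lb)) {
    stop("leaf sets differ; only in first: ",
         paste(setdiff(la, lb), collapse = ","),
         "; only in second: ", paste(setdiff(lb, la), collapse = ","))
  }
  sa <- names(tree_splits(tree_a))
  sb <- names(tree_splits(tree_b))
  length(setdiff(sa, sb)) + length(setdiff(sb, sa))
}

#' Bootstrap support of a clade in a tree
#'
#' Looks up the bipartition isolating exactly `taxa` (or equivalently its
#' complement — the tree is unrooted) and returns its integer support, or
#' `NA` when no edge induces that split.
#'
#' @param tree A `phylo` whose internal node labels carry supports.
#' @param taxa Leaf subset, `2 <= |taxa| <= n - 2`.
#' @return Integer support, or `NA` if the taxa do not form a clade.
#' @export
clade_support <- function(tree, taxa) {
  labs <- tree$tip.label
  if (!all(taxa %in% labs)) {
    stop("taxa not in tree: ", paste(setdiff(taxa, labs), collapse = ","))
  }
  k <- length(unique(taxa))
  if (k < 2 || k > length(labs) - 2) {
    stop("clade size must be between 2 and n-2")
  }
  splits <- tree_splits(tree)
  key <- .split_key(taxa, labs)
  if (!key %in% names(splits)) return(NA_integer_)
  splits[[key]]$support
}

#' Cross-marker congruence report
#'
#' For a set of marker trees over the same strains: the pairwise
#' Robinson-Foulds matrix, a per-marker support table for named strain
#' sets, and the congruent subgroups — splits present in every tree with
#' support at least `min_support` in every tree.
#'
#' @param trees Named list of `phylo` objects (marker name -> tree), all on
#'   one leaf set, with bootstrap supports as internal node labels.
#' @param named_sets Named list of character vectors (set name -> leaf
#'   labels); may be empty.
#' @param min_support Stability threshold in percent (default 50).
#' @return Object of class `marker_comparison`: list with `markers`, `rf`
#'   (matrix), `clade_table` (data frame set x marker, `NA` = absent),
#'   `congruent_subgroups` (list of sorted label vectors), `min_support`.
#' @export
congruence_report <- function(trees, named_sets = list(), min_support = 50) {
  if (is.null(names(trees)) || any(!nzchar(names(trees)))) {
    stop("trees must be a named list (marker names)")
  }
  markers <- names(trees)
  ref <- sort(trees[[1]]$tip.label)
  for (m in markers[-1]) {
    if (!identical(sort(trees[[m]]$tip.label), ref)) {
      stop("leaf sets differ between markers '", markers[1], "' and '", m, "'")
    }
  }
  nm <- length(markers)
  rf <- matrix(0L, nm, nm, dimnames = list(markers, markers))
  for (i in seq_len(nm)) for (j in seq_len(nm)) {
    if (i < j) rf[i, j] <- rf[j, i] <- rf_distance(trees[[i]], trees[[j]])
  }
  splits <- lapply(trees, tree_splits)

  clade_table <- NULL
  if (length(named_sets) > 0) {
    clade_table <- data.frame(set = names(named_sets))
    for (m in markers) {
      clade_table[[m]] <- vapply(named_sets, function(taxa) {
        key <- .split_key(taxa, ref)
        if (key %in% names(splits[[m]])) {
          s <- splits[[m]][[key]]$support
          if (is.na(s)) 0L else s
        } else NA_integer_
      }, integer(1))
    }
  }

  shared <- Reduce(intersect, lapply(splits, names))
  keep <- vapply(shared, function(k) {
    all(vapply(splits, function(sp) {
      s <- sp[[k]]$support
      !is.na(s) && s >= min_support
    }, logical(1)))
  }, logical(1))
  congruent <- lapply(shared[keep], function(k) splits[[1]][[k]]$side)
  names(congruent) <- shared[keep]

  structure(list(markers = markers, rf = rf, clade_table = clade_table,
                 congruent_subgroups = congruent, min_support = min_support),
            class = "marker_comparison")
}

#' @export
print.marker_comparison <- function(x, ...) {
  cat("<marker_comparison>", length(x$markers), "markers\n")
  cat("Robinson-Foulds distances:\n")
  print(x$rf)
  if (!is.null(x$clade_table)) {
    cat("Named-set supports (NA = not monophyletic):\n")
    print(x$clade_table, row.names = FALSE)
  }
  cat(length(x$congruent_subgroups), "congruent subgroup(s) at support >=",
      x$min_support, "\n")
  invisible(x)
}

#' Internal edges of an unrooted tree with their splits
#'
#' Convenience view used when scoring bootstrap support against a known
#' generating tree: one row per internal (nontrivial) edge, with its length
#' and canonical split key.
#'
#' @param tree A `phylo` with edge lengths.
#' @return Data frame with columns `key`, `length`, and a list column
#'   `side` of sorted label vectors.
#' @export
internal_edge_table <- function(tree) {
  tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  sets <- .tips_under(tree)
  rows <- list()
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2]
    side <- sets[[ch]]
    if (length(side) == 1L || length(side) == n - 1L) next
    rows[[length(rows) + 1L]] <- list(
      key = .split_key(side, tree$tip.label),
      length = tree$edge.length[e],
      side = sort(side))
  }
  data.frame(
    key = vapply(rows, `[[`, character(1), "key"),
    length = vapply(rows, `[[`, numeric(1), "length"),
    side = I(lapply(rows, `[[`, "side"))
  )
}
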