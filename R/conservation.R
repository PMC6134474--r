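# Per-column conservation of a protein alignment, using the familiar
# Clustal notation: '*' identical, ':' strong group, '.' weak group.

#' Residue groups behind the ':' and '.' conservation notation
#'
#' The strong and weak amino-acid groups (Gonnet-matrix derived) that define
#' "conserved" and "semi-conserved" substitutions in Clustal-style alignment
#' annotation. Both can be overridden in [classify_columns()].
#'
#' @return A list with character-vector elements `strong` and `weak`; each
#'   element is a string of single-letter residue codes.
#' @export
clustal_groups <- function() {
  list(
    strong = c("STA", "NEQK", "NHQK", "NDEQ", "QHRK",
               "MILV", "MILF", "HY", "FYW"),
    weak = c("CSA", "ATV", "SAG", "STNK", "STPA", "SGND",
             "SNDEQK", "NDEQHK", "NEQHRK", "FVLIM", "HFY")
  )
}

#' Classify alignment columns by conservation
#'
#' Assigns every column of a protein alignment one category:
#' `identical` (one residue in all rows, no gap), `strong` / `weak` (all
#' residues fall inside one strong / weak group), or `none`. Any gap in a
#' column demotes it to `none` — a primer cannot span an indel. Also reports
#' the per-column fraction of the modal residue (gaps excluded from the
#' mode but counted in the denominator).
#'
#' @param aln A protein `marker_aln`.
#' @param groups Residue-group scheme, as returned by [clustal_groups()].
#' @return A data frame of class `conservation_profile` with columns
#'   `column`, `category` (factor), `identity_fraction`.
#' @export
classify_columns <- function(aln, groups = clustal_groups()) {
  aln <- as_alignment(aln)
  if (aln$moltype != "aa") {
    stop("classify_columns expects a protein alignment (moltype 'aa')")
  }
  if (aln_ntaxa(aln) == 0L || aln_ncol(aln) == 0L) stop("empty alignment")
  strong_sets <- strsplit(groups$strong, "")
  weak_sets <- strsplit(groups$weak, "")
  n <- aln_ntaxa(aln)
  L <- aln_ncol(aln)
  category <- character(L)
  identity_fraction <- numeric(L)
  for (j in seq_len(L)) {
    col <- aln$mat[, j]
    tab <- table(col[col != "-"])
    identity_fraction[j] <- if (length(tab)) max(tab) / n else 0
    u <- unique(col)
    if (any(u == "-")) {
      category[j] <- "none"
    } else if (length(u) == 1L) {
      category[j] <- "identical"
    } else if (any(vapply(strong_sets, function(g) all(u %in% g), logical(1)))) {
      category[j] <- "strong"
    } else if (any(vapply(weak_sets, function(g) all(u %in% g), logical(1)))) {
      category[j] <- "weak"
    } else {
      category[j] <- "none"
    }
  }
  out <- data.frame(
    column = seq_len(L),
    category = factor(category, levels = c("identical", "strong", "weak", "none")),
    identity_fraction = identity_fraction
  )
  attr(out, "consensus") <- apply(aln$mat, 2, function(col) {
    tab <- sort(table(col[col != "-"]), decreasing = TRUE)
    if (length(tab)) names(tab)[1] else "-"
  })
  class(out) <- c("conservation_profile", "data.frame")
  out
}

#' Locate conserved blocks suitable for primer design
#'
#' Scans a [classify_columns()] profile for maximal runs of columns whose
#' category is `identical` or `strong`, keeps runs at least `min_len`
#' columns long whose fraction of fully-identical columns is at least
#' `min_identical_frac`, and returns them sorted by start position.
#'
#' @param profile A `conservation_profile`.
#' @param min_len Minimum block length in columns (must be >= 4; shorter
#'   runs cannot seed a degenerate primer core).
#' @param min_identical_frac Minimum fraction of `identical` columns within
#'   the run.
#' @return Data frame with columns `block_id`, `start`, `end`, `consensus`,
#'   `mean_identity`, ranked columns-as-found (sorted by `start`).
#' @export
find_conserved_blocks <- function(profile, min_len = 8,
                                  min_identical_frac = 0.8) {
  if (!inherits(profile, "conservation_profile")) {
    stop("profile must come from classify_columns()")
  }
  if (min_len < 4) stop("min_len must be >= 4 (too short to seed a primer core)")
  keep <- profile$category %in% c("identical", "strong")
  runs <- rle(keep)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cons <- attr(profile, "consensus")
  blocks <- list()
  for (k in which(runs$values)) {
    s <- starts[k]; e <- ends[k]
    if (e - s + 1L < min_len) next
    ident_frac <- mean(profile$category[s:e] == "identical")
    if (ident_frac < min_identical_frac) next
    blocks[[length(blocks) + 1L]] <- data.frame(
      start = s, end = e,
      consensus = paste(cons[s:e], collapse = ""),
      mean_identity = mean(profile$identity_fraction[s:e])
    )
  }
  if (length(blocks) == 0L) {
    return(data.frame(block_id = integer(), start = integer(),
                      end = integer(), consensus = character(),
                      mean_identity = numeric()))
  }
  out <- do.call(rbind, blocks)
  out <- out[order(out$start), , drop = FALSE]
  out <- cbind(block_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Rank conserved blocks for primer design
#'
#' Orders blocks by `(mean_identity, length)` descending, the default
#' policy when more blocks are found than primers are needed.
#'
#' @param blocks Output of [find_conserved_blocks()].
#' @param n Number of blocks to keep (default all).
#' @export
rank_blocks <- function(blocks, n = nrow(blocks)) {
  len <- blocks$end - blocks$start + 1L
  ord <- order(-blocks$mean_identity, -len, blocks$start)
  blocks[ord[seq_len(min(n, nrow(blocks)))], , drop = FALSE]
}
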