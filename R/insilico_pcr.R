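# In-silico amplification: find IUPAC-compatible binding sites of a
# degenerate primer pair on concrete templates and pair them into products,
# replacing the bench PCR + gel step with a verifiable computation.

.encode_nt <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  code <- match(chars, c("A", "C", "G", "T"))
  if (anyNA(code)) {
    stop("template must be concrete A/C/G/T (found '",
         chars[which(is.na(code))[1]], "')")
  }
  code
}

# plen x 4 logical: allowed[j, b] = base b permitted at pattern position j.
.pattern_allowed <- function(pattern) {
  chars <- strsplit(toupper(pattern), "")[[1]]
  t(vapply(chars, function(ch) c("A", "C", "G", "T") %in% iub_expand(ch),
           logical(4)))
}

# Mismatch count of `pattern` at every plus-strand offset of the encoded
# template; returns integer vector of length L - plen + 1.
.slide_mismatches <- function(code, allowed) {
  plen <- nrow(allowed)
  n_off <- length(code) - plen + 1L
  if (n_off < 1L) return(integer(0))
  mm <- integer(n_off)
  offs <- seq_len(n_off)
  for (j in seq_len(plen)) {
    mm <- mm + !allowed[j, code[offs + j - 1L]]
  }
  mm
}

#' Find binding sites of a degenerate primer on a concrete template
#'
#' Scans the plus strand for windows where the primer (sense orientation)
#' or its reverse complement (antisense) is IUPAC-compatible with at most
#' `max_mismatch` mismatches, requiring the `anchor3` bases at the primer's
#' 3' terminus to match exactly. For an antisense primer the 3' terminus
#' corresponds to the low-coordinate end of the plus-strand window.
#'
#' @param primer A `degenerate_primer` (its `orientation` decides which
#'   strand is searched).
#' @param template A single named concrete nucleotide sequence (length-1
#'   `seq_set` or named character), or an unnamed string.
#' @param max_mismatch Maximum mismatches outside the anchor (default 2).
#' @param anchor3 Number of 3'-terminal bases that must match exactly
#'   (default 3).
#' @return Data frame with columns `template_id`, `primer_name`, `start`,
#'   `end` (plus-strand, 1-based inclusive), `strand` (`+`/`-`),
#'   `mismatches`.
#' @export
find_sites <- function(primer, template, max_mismatch = 2, anchor3 = 3) {
  if (!inherits(primer, "degenerate_primer")) stop("primer must be a degenerate_primer")
  tid <- if (!is.null(names(template))) names(template)[1] else "template"
  tseq <- unclass(template)[[1]]
  code <- .encode_nt(tseq)
  plen <- nchar(primer$seq)
  if (anchor3 > plen) stop("anchor3 exceeds primer length")
  if (primer$orientation == "sense") {
    pattern <- primer$seq
    anchor_pos <- (plen - anchor3 + 1L):plen  # written 3' end = high coords
    strand <- "+"
  } else {
    pattern <- revcomp(primer$seq)            # plus-strand representation
    anchor_pos <- seq_len(anchor3)            # written 3' end = low coords
    strand <- "-"
  }
  allowed <- .pattern_allowed(pattern)
  mm_all <- .slide_mismatches(code, allowed)
  anchor_allowed <- allowed[anchor_pos, , drop = FALSE]
  mm_anchor <- integer(length(mm_all))
  offs <- seq_along(mm_all)
  for (k in seq_along(anchor_pos)) {
    j <- anchor_pos[k]
    mm_anchor <- mm_anchor + !anchor_allowed[k, code[offs + j - 1L]]
  }
  hit <- which(mm_all <= max_mismatch & mm_anchor == 0L)
  data.frame(
    template_id = rep(tid, length(hit)),
    primer_name = rep(primer$name, length(hit)),
    start = hit,
    end = hit + plen - 1L,
    strand = rep(strand, length(hit)),
    mismatches = mm_all[hit]
  )
}

#' Predict PCR products of a primer pair on a template
#'
#' Pairs every forward (plus-strand) site with its nearest downstream
#' reverse (minus-strand) site — the dominant-product behaviour seen as a
#' single band on a gel — and keeps products whose length falls inside
#' `size_bounds`.
#'
#' @param pair A `primer_pair`.
#' @param template As in [find_sites()].
#' @param size_bounds Numeric `c(min, max)` product length in bases.
#' @inheritParams find_sites
#' @return Data frame with columns `template_id`, `start`, `end`,
#'   `product_len`, `fwd_mismatches`, `rev_mismatches`, `product_seq`
#'   (plus-strand substring spanning both sites inclusive). Zero rows when
#'   nothing amplifies.
#' @export
predict_amplicons <- function(pair, template, size_bounds = c(1000, 1600),
                              max_mismatch = 2, anchor3 = 3) {
  if (!inherits(pair, "primer_pair")) stop("pair must be a primer_pair")
  tid <- if (!is.null(names(template))) names(template)[1] else "template"
  tseq <- unclass(template)[[1]]
  fwd <- find_sites(pair$forward, template, max_mismatch, anchor3)
  rev <- find_sites(pair$reverse, template, max_mismatch, anchor3)
  out <- list()
  for (i in seq_len(nrow(fwd))) {
    cand <- rev[rev$start > fwd$end[i], , drop = FALSE]
    if (nrow(cand) == 0L) next
    j <- which.min(cand$start)
    len <- cand$end[j] - fwd$start[i] + 1L
    if (len < size_bounds[1] || len > size_bounds[2]) next
    out[[length(out) + 1L]] <- data.frame(
      template_id = tid,
      start = fwd$start[i], end = cand$end[j],
      product_len = len,
      fwd_mismatches = fwd$mismatches[i],
      rev_mismatches = cand$mismatches[j],
      product_seq = substr(tseq, fwd$start[i], cand$end[j])
    )
  }
  if (length(out) == 0L) {
    return(data.frame(template_id = character(), start = integer(),
                      end = integer(), product_len = integer(),
                      fwd_mismatches = integer(), rev_mismatches = integer(),
                      product_seq = character()))
  }
  do.call(rbind, out)
}

#' Predict amplicons across a set of templates
#'
#' @param pair A `primer_pair`.
#' @param templates A `seq_set` of concrete templates.
#' @inheritParams predict_amplicons
#' @return Row-bound data frame of per-template predictions.
#' @export
predict_amplicons_set <- function(pair, templates, size_bounds = c(1000, 1600),
                                  max_mismatch = 2, anchor3 = 3) {
  res <- lapply(names(templates), function(id) {
    predict_amplicons(pair, stats::setNames(unclass(templates)[id], id),
                      size_bounds, max_mismatch, anchor3)
  })
  do.call(rbind, res)
}
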