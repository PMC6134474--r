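# Consensus-clamp + degenerate-core ("CODEHOP"-style) primer construction.
# A primer is written 5'->3'; its 5' clamp is non-degenerate consensus taken
# verbatim from a reference CDS and its 3' core is the positionwise union of
# all codons for the conserved residues, compressed to IUPAC symbols.

# IUPAC nucleotide ambiguity alphabet, as base sets.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.iupac_by_key <- local({
  keys <- vapply(IUPAC_SETS, function(b) paste(sort(b), collapse = ""),
                 character(1))
  stats::setNames(names(IUPAC_SETS), keys)
})

#' IUPAC compression and expansion of base sets
#'
#' `iub_compress()` maps a non-empty subset of `{A,C,G,T}` to its single
#' IUPAC symbol (e.g. `{G,C,T}` to `B`); `iub_expand()` is its inverse.
#' Singleton sets map to the base itself and the full set to `N`.
#'
#' @param bases Character vector of concrete bases (a set).
#' @return `iub_compress()` a single symbol; `iub_expand()` the sorted base
#'   set of a symbol.
#' @examples
#' iub_compress(c("G", "C", "T"))  # "B"
#' iub_expand("V")                 # A G C
#' @export
iub_compress <- function(bases) {
  bases <- unique(toupper(bases))
  if (length(bases) == 0L) stop("empty base set")
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    stop("bases must be in {A,C,G,T}, got: ",
         paste(setdiff(bases, c("A", "C", "G", "T")), collapse = ","))
  }
  unname(.iupac_by_key[paste(sort(bases), collapse = "")])
}

#' @rdname iub_compress
#' @param symbol A single IUPAC symbol.
#' @export
iub_expand <- function(symbol) {
  symbol <- toupper(symbol)
  if (!symbol %in% names(IUPAC_SETS)) stop("not an IUPAC symbol: ", symbol)
  sort(IUPAC_SETS[[symbol]])
}

# Inverse genetic code: residue -> codon set, built once from the standard
# code (identical to the bacterial code over the 20 amino acids).
.codon_table <- local({
  tbl <- NULL
  function() {
    if (is.null(tbl)) {
      bases <- c("T", "C", "A", "G")
      codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
      aas <- vapply(codons, function(cd) {
        seqinr::translate(strsplit(cd, "")[[1]])
      }, character(1))
      tbl <<- split(codons, aas)
    }
    tbl
  }
})

#' Back-translate amino acids to a degenerate nucleotide string
#'
#' Each residue becomes three IUPAC symbols: the positionwise union of all
#' its codons under the standard genetic code, compressed with
#' [iub_compress()]. E.g. `D` (codons GAT, GAC) becomes `GAY`.
#'
#' @param residues Gap-free amino-acid string (single-letter codes).
#' @return A nucleotide string of length `3 * nchar(residues)` over the
#'   IUPAC alphabet.
#' @export
back_translate <- function(residues) {
  res <- strsplit(toupper(residues), "")[[1]]
  if (length(res) == 0L) stop("empty residue string")
  tbl <- .codon_table()
  out <- vapply(res, function(a) {
    if (!a %in% names(tbl) || a == "*") stop("unknown residue letter: ", a)
    codons <- strsplit(tbl[[a]], "")
    paste(vapply(1:3, function(p) {
      iub_compress(unique(vapply(codons, `[`, character(1), p)))
    }, character(1)), collapse = "")
  }, character(1))
  paste(out, collapse = "")
}

#' Degeneracy of an IUPAC primer sequence
#'
#' The number of concrete sequences the primer represents: the product over
#' positions of the IUPAC expansion sizes.
#'
#' @param seq IUPAC nucleotide string (or a `degenerate_primer`).
#' @return A positive integer.
#' @examples
#' primer_degeneracy("GAY")  # 2
#' @export
primer_degeneracy <- function(seq) {
  if (inherits(seq, "degenerate_primer")) seq <- seq$seq
  chars <- strsplit(toupper(seq), "")[[1]]
  prod(vapply(chars, function(ch) length(iub_expand(ch)), numeric(1)))
}

#' Enumerate all concrete expansions of a degenerate primer
#'
#' @param seq IUPAC nucleotide string (or a `degenerate_primer`).
#' @param cap Refuse to enumerate primers with degeneracy above this
#'   (default 4096).
#' @return Character vector of all concrete sequences, length equal to
#'   [primer_degeneracy()].
#' @export
expand_primer <- function(seq, cap = 4096) {
  if (inherits(seq, "degenerate_primer")) seq <- seq$seq
  deg <- primer_degeneracy(seq)
  if (deg > cap) {
    stop("degeneracy ", deg, " exceeds enumeration cap ", cap)
  }
  chars <- strsplit(toupper(seq), "")[[1]]
  sets <- lapply(chars, iub_expand)
  grid <- do.call(expand.grid, c(rev(sets), stringsAsFactors = FALSE))
  grid <- grid[, rev(seq_along(sets)), drop = FALSE]
  apply(grid, 1, paste, collapse = "")
}

#' Positionwise IUPAC compression of a set of concrete sequences
#'
#' Inverse of [expand_primer()]: compresses equal-length concrete sequences
#' back to a single IUPAC string.
#'
#' @param seqs Character vector of equal-length concrete sequences.
#' @export
compress_seqs <- function(seqs) {
  if (length(unique(nchar(seqs))) != 1L) stop("sequences must be equal length")
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  paste(apply(mat, 2, function(col) iub_compress(unique(col))), collapse = "")
}

#' Melting-temperature range of a degenerate primer
#'
#' Applies a GC-content formula to the most extreme expansions without
#' enumerating them: for primers longer than 14 nt,
#' `Tm = 64.9 + 41 * (GC - 16.4) / N`; for 10-14 nt the Wallace rule
#' `Tm = 2*(A+T) + 4*(G+C)`. The GC bounds come from counting positions
#' whose expansion is all-GC (minimum) or contains any G/C (maximum).
#'
#' @param seq IUPAC nucleotide string (or a `degenerate_primer`), length
#'   >= 10.
#' @return Numeric `c(tm_min, tm_max)` in degrees Celsius.
#' @export
melting_range <- function(seq) {
  if (inherits(seq, "degenerate_primer")) seq <- seq$seq
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  if (n < 10) stop("primer too short for a meaningful Tm (length < 10)")
  sets <- lapply(chars, iub_expand)
  gc_min <- sum(vapply(sets, function(b) all(b %in% c("G", "C")), logical(1)))
  gc_max <- sum(vapply(sets, function(b) any(b %in% c("G", "C")), logical(1)))
  tm <- function(gc) {
    if (n > 14) 64.9 + 41 * (gc - 16.4) / n else 2 * (n - gc) + 4 * gc
  }
  c(tm_min = tm(gc_min), tm_max = tm(gc_max))
}

#' Construct a degenerate primer record
#'
#' @param name Primer name.
#' @param seq IUPAC sequence written 5'->3' (for antisense primers, 5'->3'
#'   on the minus strand).
#' @param orientation `"sense"` or `"antisense"`.
#' @param clamp_len,core_len Lengths of the 5' consensus clamp and the 3'
#'   degenerate core; must sum to `nchar(seq)`, and the clamp must be
#'   non-degenerate.
#' @param ref_start,ref_end 1-based inclusive span on the reference plus
#'   strand. For antisense primers `ref_start` is the 3'-end position.
#' @return An object of class `degenerate_primer`.
#' @export
degenerate_primer <- function(name, seq, orientation = c("sense", "antisense"),
                              clamp_len, core_len,
                              ref_start = NA_integer_, ref_end = NA_integer_) {
  orientation <- match.arg(orientation)
  seq <- toupper(seq)
  if (clamp_len + core_len != nchar(seq)) {
    stop("clamp_len + core_len must equal primer length")
  }
  clamp <- substr(seq, 1, clamp_len)
  if (clamp_len > 0 && primer_degeneracy(clamp) != 1) {
    stop("clamp region must be non-degenerate")
  }
  if (!is.na(ref_start) && !is.na(ref_end)) {
    if (ref_start < 1 || ref_start > ref_end) stop("invalid reference span")
  }
  structure(list(name = name, seq = seq, orientation = orientation,
                 clamp_len = clamp_len, core_len = core_len,
                 ref_start = as.integer(ref_start),
                 ref_end = as.integer(ref_end),
                 degeneracy = primer_degeneracy(seq)),
            class = "degenerate_primer")
}

#' @export
print.degenerate_primer <- function(x, ...) {
  cat(sprintf("<degenerate_primer> %s (%s) %s\n  clamp %d nt + core %d nt, degeneracy %d, ref span %s-%s\n",
              x$name, x$orientation, x$seq, x$clamp_len, x$core_len,
              x$degeneracy, x$ref_start, x$ref_end))
  invisible(x)
}

#' Reverse complement (IUPAC-aware)
#' @param seq Nucleotide string, possibly degenerate.
#' @export
revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N", "-" = "-")
  chars <- rev(strsplit(toupper(seq), "")[[1]])
  paste(comp[chars], collapse = "")
}

# Map a reference-residue index to an alignment column, from the reference
# row of the protein alignment (gaps in the reference row consume no
# residue index).
.ref_residue_of_column <- function(aln, ref_id) {
  if (!ref_id %in% aln_labels(aln)) stop("reference id not in alignment: ", ref_id)
  row <- aln$mat[ref_id, ]
  idx <- cumsum(row != "-")
  idx[row == "-"] <- NA_integer_
  idx
}

#' Design a consensus-clamp / degenerate-core primer pair from two
#' conserved blocks
#'
#' The forward (sense) primer ends at the last codon of the upstream block:
#' its 3' `core_len` bases are the back-translated degenerate union of the
#' block residues and its 5' `clamp_len` bases are taken verbatim from the
#' reference CDS. The reverse (antisense) primer is built the same way on
#' the downstream block and written 5'->3' on the minus strand, so its
#' written 3' core corresponds to the low-coordinate end of its plus-strand
#' window. Reference spans are recorded 1-based inclusive on the plus
#' strand.
#'
#' @param blocks Data frame with at least two rows (columns `start`, `end`
#'   in alignment coordinates), as from [find_conserved_blocks()]; the two
#'   lowest-coordinate blocks are used in reference order.
#' @param aln The protein `marker_aln` the blocks were found in.
#' @param reference_cds Concrete nucleotide string of the reference coding
#'   sequence (no gaps), in frame with the reference protein.
#' @param ref_id Identifier of the reference row in `aln`.
#' @param clamp_len,core_len Primer architecture (defaults 22 + 12 nt).
#' @param product_range Admissible predicted product length (bases,
#'   inclusive) on the reference.
#' @return A list of class `primer_pair`: `forward`, `reverse`
#'   (`degenerate_primer`s) and `predicted_product_len`.
#' @export
design_primer_pair <- function(blocks, aln, reference_cds, ref_id,
                               clamp_len = 22, core_len = 12,
                               product_range = c(1000, 1600)) {
  if (nrow(blocks) < 2) stop("need two conserved blocks to design a pair")
  blocks <- blocks[order(blocks$start), , drop = FALSE]
  b1 <- blocks[1, ]; b2 <- blocks[nrow(blocks), ]
  reference_cds <- .normalise_seq(reference_cds)
  if (grepl("[^ACGT]", reference_cds)) stop("reference CDS must be concrete A/C/G/T")
  col2res <- .ref_residue_of_column(aln, ref_id)
  L <- clamp_len + core_len

  res_span <- function(b) {
    r <- col2res[b$start:b$end]
    if (anyNA(r)) stop("reference has gaps inside a conserved block")
    range(r)
  }
  r1 <- res_span(b1); r2 <- res_span(b2)
  n_core_res <- ceiling(core_len / 3)
  if (r1[2] - r1[1] + 1 < n_core_res || r2[2] - r2[1] + 1 < n_core_res) {
    stop("conserved block shorter than the residues needed for a ",
         core_len, "-nt core")
  }
  block_res <- function(lo, hi) {
    cols <- which(col2res >= lo & col2res <= hi & !is.na(col2res))
    paste(aln$mat[ref_id, cols], collapse = "")
  }

  # Forward: plus-strand window ending at the last base of block 1's last
  # codon; degenerate core = last core_len nt of the back-translated block.
  f_end <- 3L * r1[2]
  f_start <- f_end - L + 1L
  if (f_start < 1) stop("forward clamp would run off the 5' end of the reference")
  f_core_res <- block_res(r1[2] - n_core_res + 1L, r1[2])
  f_core_nt <- back_translate(f_core_res)
  f_core <- substr(f_core_nt, nchar(f_core_nt) - core_len + 1L, nchar(f_core_nt))
  f_clamp <- substr(reference_cds, f_start, f_end - core_len)
  forward <- degenerate_primer(
    name = "forward", seq = paste0(f_clamp, f_core), orientation = "sense",
    clamp_len = clamp_len, core_len = core_len,
    ref_start = f_start, ref_end = f_end
  )

  # Reverse: plus-strand window starting at the first base of block 2's
  # first codon; written primer = revcomp(window), clamp from the high end.
  s <- 3L * r2[1] - 2L
  r_end <- s + L - 1L
  if (r_end > nchar(reference_cds)) {
    stop("reverse clamp would run off the 3' end of the reference")
  }
  r_core_res <- block_res(r2[1], r2[1] + n_core_res - 1L)
  r_core_plus <- substr(back_translate(r_core_res), 1L, core_len)
  r_clamp_plus <- substr(reference_cds, s + core_len, r_end)
  reverse <- degenerate_primer(
    name = "reverse", seq = paste0(revcomp(r_clamp_plus), revcomp(r_core_plus)),
    orientation = "antisense",
    clamp_len = clamp_len, core_len = core_len,
    ref_start = s, ref_end = r_end
  )

  product_len <- reverse$ref_end - forward$ref_start + 1L
  if (product_len < product_range[1] || product_len > product_range[2]) {
    stop("predicted product length ", product_len,
         " outside allowed range [", product_range[1], ", ",
         product_range[2], "]")
  }
  if (forward$ref_end >= reverse$ref_start) stop("primer windows overlap")

  # By construction both primers must match the reference exactly under
  # IUPAC semantics; verify.
  stopifnot(
    iupac_mismatches(forward$seq,
                     substr(reference_cds, forward$ref_start, forward$ref_end)) == 0,
    iupac_mismatches(revcomp(reverse$seq),
                     substr(reference_cds, reverse$ref_start, reverse$ref_end)) == 0
  )
  structure(list(forward = forward, reverse = reverse,
                 predicted_product_len = product_len),
            class = "primer_pair")
}

#' Count IUPAC-compatibility mismatches between a pattern and a concrete
#' sequence of equal length
#'
#' A position matches when the template base is inside the IUPAC expansion
#' of the pattern symbol.
#'
#' @param pattern IUPAC string.
#' @param concrete Concrete A/C/G/T string of the same length.
#' @export
iupac_mismatches <- function(pattern, concrete) {
  p <- strsplit(toupper(pattern), "")[[1]]
  s <- strsplit(toupper(concrete), "")[[1]]
  if (length(p) != length(s)) stop("length mismatch")
  sum(!mapply(function(a, b) b %in% iub_expand(a), p, s))
}

#' @export
print.primer_pair <- function(x, ...) {
  cat("<primer_pair>\n")
  print(x$forward); print(x$reverse)
  cat("  predicted product:", x$predicted_product_len, "bp\n")
  invisible(x)
}
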