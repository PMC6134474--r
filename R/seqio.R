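# Internal alphabets. 'U' is normalised to 'T' on input and everything is
# case-folded to upper, so downstream code sees a single alphabet.
NT_LETTERS <- c("A", "C", "G", "T")
IUPAC_NT <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V", "N")
AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.valid_chars <- function(moltype) {
  if (moltype == "nt") c(IUPAC_NT, "-") else c(AA_LETTERS, "X", "-")
}

.normalise_seq <- function(s) {
  s <- toupper(s)
  gsub("U", "T", s, fixed = TRUE)
}

#' Read sequences from FASTA or Clustal files
#'
#' Returns the records in file order as a named character vector of class
#' `seq_set`. Sequences are upper-cased, `U` is converted to `T`, and gaps
#' (`-`) are retained. Identifiers are taken verbatim from the headers and
#' must be unique within a file.
#'
#' @param path Path to the input file.
#' @param format `"fasta"` or `"clustal"`.
#' @param moltype `"nt"`, `"aa"`, or `NULL` to guess from the residue
#'   composition (sequences composed almost entirely of `ACGTUN-` are taken
#'   as nucleotide).
#' @return A named character vector with class `seq_set` and attribute
#'   `moltype`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACGTACGTAC", ">b", "ACGTACGAAC"), fa)
#' read_sequences(fa)
#' @export
read_sequences <- function(path, format = c("fasta", "clustal"),
                           moltype = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "fasta") {
    lines <- readLines(path, warn = FALSE)
    nonblank <- which(nzchar(trimws(lines)))
    if (length(nonblank) == 0L) stop("parse error: empty FASTA file ", path)
    if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
      stop("parse error in ", path, " at line ", nonblank[1],
           ": expected '>' header")
    }
    recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                               forceDNAtolower = FALSE, set.attributes = FALSE)
    ids <- names(recs)
    seqs <- unlist(recs, use.names = FALSE)
  } else {
    rec <- .read_clustal(path)
    ids <- rec$ids
    seqs <- rec$seqs
  }
  seqs <- .normalise_seq(seqs)
  if (any(!nzchar(seqs))) {
    stop("parse error: empty sequence for id '", ids[!nzchar(seqs)][1], "'")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (is.null(moltype)) moltype <- .guess_moltype(seqs)
  .check_alphabet(seqs, ids, moltype)
  structure(stats::setNames(seqs, ids), moltype = moltype, class = "seq_set")
}

# Minimal Clustal block parser (header line, blocks of "name  sequence
# [position]", optional conservation lines starting with whitespace).
# Written here because the available readers mishandle single-block files.
.read_clustal <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !grepl("^CLUSTAL", lines[1])) {
    stop("parse error in ", path, " at line 1: expected CLUSTAL header")
  }
  body <- lines[-1]
  acc <- list()
  order_ids <- character(0)
  for (i in seq_along(body)) {
    ln <- body[i]
    if (!nzchar(trimws(ln))) next
    if (grepl("^\\s", ln)) next  # conservation line
    m <- regmatches(ln, regexec("^(\\S+)\\s+([A-Za-z.*-]+)(\\s+\\d+)?\\s*$", ln))[[1]]
    if (length(m) == 0L) {
      stop("parse error in ", path, " at line ", i + 1L,
           ": not a Clustal sequence line")
    }
    id <- m[2]
    if (!id %in% order_ids) order_ids <- c(order_ids, id)
    acc[[id]] <- paste0(if (is.null(acc[[id]])) "" else acc[[id]],
                        gsub(".", "-", m[3], fixed = TRUE))
  }
  if (length(acc) == 0L) stop("parse error: no sequence lines in ", path)
  lens <- vapply(order_ids, function(id) nchar(acc[[id]]), numeric(1))
  if (length(unique(lens)) != 1L) {
    stop("parse error in ", path, ": unequal alignment row lengths")
  }
  list(ids = order_ids, seqs = unlist(acc[order_ids], use.names = FALSE))
}

.guess_moltype <- function(seqs) {
  chars <- strsplit(paste(seqs, collapse = ""), "")[[1]]
  frac_nt <- mean(chars %in% c("A", "C", "G", "T", "U", "N", "-"))
  if (frac_nt >= 0.9) "nt" else "aa"
}

.check_alphabet <- function(seqs, ids, moltype) {
  ok <- .valid_chars(moltype)
  for (i in seq_along(seqs)) {
    chars <- unique(strsplit(seqs[[i]], "")[[1]])
    bad <- setdiff(chars, ok)
    if (length(bad) > 0L) {
      stop("invalid ", moltype, " character(s) ",
           paste(bad, collapse = ""), " in sequence '", ids[i], "'")
    }
  }
  invisible(TRUE)
}

#' Construct a sequence set in code
#'
#' @param x Named character vector of sequences.
#' @param moltype `"nt"` or `"aa"`.
#' @return A `seq_set`.
#' @export
seq_set <- function(x, moltype = c("nt", "aa")) {
  moltype <- match.arg(moltype)
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("all sequences must be named")
  }
  if (anyDuplicated(names(x))) stop("duplicate sequence id")
  x <- .normalise_seq(x)
  .check_alphabet(x, names(x), moltype)
  structure(x, moltype = moltype, class = "seq_set")
}

#' Write a sequence set as FASTA
#'
#' @param seqs A `seq_set` (or named character vector).
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Build an alignment from equal-length sequences
#'
#' @param x A `seq_set` or named character vector of gapped sequences, all
#'   the same length, or a character matrix (rows = taxa, one residue per
#'   cell).
#' @param moltype `"nt"` or `"aa"`; taken from `x` when it is a `seq_set`.
#' @return An object of class `marker_aln`: a list with `mat` (character
#'   matrix, rownames = ids) and `moltype`.
#' @export
as_alignment <- function(x, moltype = NULL) {
  if (inherits(x, "marker_aln")) return(x)
  if (is.matrix(x)) {
    if (is.null(moltype)) stop("moltype required for matrix input")
    if (is.null(rownames(x))) stop("matrix input must have rownames")
    aln <- structure(list(mat = x, moltype = moltype), class = "marker_aln")
    return(aln)
  }
  if (length(x) == 0L) stop("no sequences")
  if (is.null(moltype)) {
    moltype <- attr(x, "moltype")
    if (is.null(moltype)) moltype <- .guess_moltype(unclass(x))
  }
  lens <- nchar(x)
  if (length(unique(lens)) != 1L) {
    bad <- names(x)[lens != stats::median(lens)]
    if (length(bad) == 0L) bad <- names(x)
    stop("sequences have unequal lengths; offending ids: ",
         paste(bad, collapse = ", "))
  }
  mat <- do.call(rbind, strsplit(unclass(x), ""))
  rownames(mat) <- names(x)
  structure(list(mat = mat, moltype = moltype), class = "marker_aln")
}

#' @export
print.marker_aln <- function(x, ...) {
  cat(sprintf("<marker_aln> %d x %d (%s)\n",
              nrow(x$mat), ncol(x$mat), x$moltype))
  invisible(x)
}

#' Alignment dimensions and labels
#' @param aln A `marker_aln`.
#' @return `aln_ncol`/`aln_ntaxa` return integers; `aln_labels` the row ids.
#' @export
aln_ncol <- function(aln) ncol(aln$mat)

#' @rdname aln_ncol
#' @export
aln_ntaxa <- function(aln) nrow(aln$mat)

#' @rdname aln_ncol
#' @export
aln_labels <- function(aln) rownames(aln$mat)

#' Convert an alignment back to a `seq_set`
#' @param aln A `marker_aln`.
#' @export
aln_to_seqs <- function(aln) {
  seq_set(apply(aln$mat, 1, paste, collapse = ""), moltype = aln$moltype)
}

#' Subset alignment columns
#' @param aln A `marker_aln`.
#' @param cols Integer column indices (may repeat, as in bootstrapping).
#' @export
aln_subset_cols <- function(aln, cols) {
  structure(list(mat = aln$mat[, cols, drop = FALSE], moltype = aln$moltype),
            class = "marker_aln")
}

#' Write an alignment in Clustal format
#'
#' Minimal Clustal writer (60-column blocks, no conservation line) used for
#' round-trip interchange with tools that expect the format.
#'
#' @param aln A `marker_aln`.
#' @param path Output path.
#' @export
write_clustal <- function(aln, path) {
  seqs <- apply(aln$mat, 1, paste, collapse = "")
  ids <- rownames(aln$mat)
  pad <- max(nchar(ids)) + 3L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("CLUSTAL W (markerforge) multiple sequence alignment", con)
  writeLines("", con)
  len <- ncol(aln$mat)
  for (start in seq(1L, len, by = 60L)) {
    end <- min(start + 59L, len)
    for (i in seq_along(ids)) {
      writeLines(sprintf("%-*s%s", pad, ids[i], substr(seqs[i], start, end)),
                 con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Read and write Newick trees
#'
#' Thin wrappers over \pkg{ape} that enforce the package conventions:
#' internal-node labels, when present, are integer bootstrap percentages in
#' `[0, 100]`.
#'
#' @param path Path to a Newick file.
#' @return `read_tree` returns an \pkg{ape} `phylo`.
#' @export
read_tree <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("Newick parse error in ", path,
                                          ": ", conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error in ", path)
  tr
}

#' @rdname read_tree
#' @param tree A `phylo`.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
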