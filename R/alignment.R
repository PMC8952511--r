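# Alignment container and reference-anchored column bookkeeping.
#
# An aa_alignment is a character matrix (rows = sequences, columns = alignment
# columns) over the 20 amino-acid letters plus '-' (gap) and 'X' (unknown).
# Row names are the (unique) sequence identifiers. Columns are 0-based in
# nothing: all R-facing indices are 1-based; reference residue numbers follow
# the PDB convention (1-based along the ungapped reference).

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
GAP <- "-"
UNKNOWN <- "X"
ALPHABET <- c(AA20, GAP, UNKNOWN)

#' Construct an amino-acid alignment
#'
#' @param seqs Character vector of equal-length aligned sequences (gaps `-`),
#'   or a character matrix with one residue per cell.
#' @param ids Sequence identifiers; taken from `names(seqs)`/rownames if absent.
#' @return An `aa_alignment`: a character matrix with class attribute, rows
#'   named by sequence id, cells in the 20 AA letters, `-` or `X`.
#' @details Characters are upper-cased, `.` is normalised to `-`, and any
#'   letter outside the 20-letter amino-acid alphabet (`B`, `Z`, `J`, `U`,
#'   `O`, `*`, ...) is mapped to `X`. `X` is excluded from all frequency
#'   counts downstream.
#' @export
aa_alignment <- function(seqs, ids = NULL) {
  if (is.matrix(seqs)) {
    m <- seqs
    if (is.null(ids)) ids <- rownames(m)
  } else {
    if (is.null(ids)) ids <- names(seqs)
    if (length(seqs) == 0L) stop("empty alignment: no sequences")
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) {
      stop("alignment-shape error: sequences have unequal lengths (",
           paste(unique(lens), collapse = ", "), ")")
    }
    m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  }
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(m)))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    stop("identifier error: duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  m <- toupper(m)
  m[m == "."] <- GAP
  bad <- !(m %in% ALPHABET)
  if (any(bad)) m[bad] <- UNKNOWN
  dimnames(m) <- list(ids, NULL)
  class(m) <- c("aa_alignment", "matrix", "array")
  m
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat("aa_alignment: ", nrow(x), " sequences x ", ncol(x), " columns\n", sep = "")
  show <- utils::head(rownames(x), 5L)
  for (id in show) {
    s <- paste(x[id, seq_len(min(60L, ncol(x)))], collapse = "")
    cat(sprintf("  %-20s %s%s\n", id, s, if (ncol(x) > 60L) "..." else ""))
  }
  if (nrow(x) > 5L) cat("  ...\n")
  invisible(x)
}

#' Number of sequences / columns in an alignment
#' @param aln An `aa_alignment`.
#' @return Integer count.
#' @export
n_seqs <- function(aln) nrow(aln)

#' @rdname n_seqs
#' @export
n_cols <- function(aln) ncol(aln)

as_rows <- function(aln) {
  stats::setNames(apply(unclass(aln), 1L, paste, collapse = ""), rownames(aln))
}

#' Read an aligned FASTA file
#'
#' All records must have equal (gapped) length. Characters are normalised as
#' in [aa_alignment()].
#'
#' @param path Path to a FASTA file of aligned protein sequences.
#' @return An `aa_alignment`.
#' @export
read_fasta_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA format error in ", path, ": ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("FASTA format error: no records in ", path)
  seqs <- as.character(set)
  # FASTA descriptions: keep the first whitespace-delimited token as the id
  ids <- sub("\\s.*$", "", names(set))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("alignment-shape error: records in ", path,
         " have unequal lengths (", paste(sort(unique(lens)), collapse = ", "), ")")
  }
  aa_alignment(seqs, ids)
}

#' Write an alignment to FASTA
#' @param aln An `aa_alignment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  set <- Biostrings::BStringSet(as_rows(aln))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Per-column occupancy
#'
#' Fraction of non-gap characters in each column ('X' counts as occupied).
#'
#' @param aln An `aa_alignment`.
#' @return Numeric vector in `[0, 1]`, length `n_cols(aln)`.
#' @export
column_occupancy <- function(aln) {
  if (nrow(aln) == 0L) stop("empty alignment")
  colMeans(unclass(aln) != GAP)
}

#' Ungapped sequence lengths
#' @param aln An `aa_alignment`.
#' @return Named integer vector of residue counts per sequence.
#' @export
ungapped_lengths <- function(aln) {
  rowSums(unclass(aln) != GAP)
}

#' Map alignment columns to reference residue numbers
#'
#' The reference sequence (a structure-resolved member such as 1CZF chain A)
#' anchors the numbering: residue i of the ungapped reference sits in the i-th
#' non-gap column of its row.
#'
#' @param aln An `aa_alignment`.
#' @param reference_id Identifier of the reference row.
#' @return A `reference_map`: list with `reference_id`, `col_to_resnum`
#'   (integer vector over columns, `NA` where the reference is gapped) and
#'   `resnum_to_col` (integer vector over residue numbers).
#' @export
build_reference_map <- function(aln, reference_id) {
  if (!reference_id %in% rownames(aln)) {
    stop("lookup error: reference '", reference_id, "' not in alignment")
  }
  row <- unclass(aln)[reference_id, ]
  covered <- which(row != GAP)
  if (length(covered) == 0L) {
    stop("reference '", reference_id, "' is all-gap: empty reference map")
  }
  col_to_resnum <- rep(NA_integer_, ncol(aln))
  col_to_resnum[covered] <- seq_along(covered)
  structure(list(reference_id = reference_id,
                 col_to_resnum = col_to_resnum,
                 resnum_to_col = covered),
            class = "reference_map")
}

#' @export
print.reference_map <- function(x, ...) {
  cat("reference_map: '", x$reference_id, "', ", length(x$resnum_to_col),
      " residues over ", length(x$col_to_resnum), " columns\n", sep = "")
  invisible(x)
}

#' Trim an alignment to the reference-covered span
#'
#' Keeps columns from the first through the last column where the reference
#' has a residue (N-/C-terminal trimming anchored on the reference, the
#' stand-in for secondary-structure based end trimming).
#'
#' @param aln An `aa_alignment`.
#' @param refmap A `reference_map` built on `aln`.
#' @return Trimmed `aa_alignment`.
#' @export
trim_to_reference <- function(aln, refmap) {
  cov <- refmap$resnum_to_col
  if (length(cov) == 0L) stop("cannot trim: empty reference map")
  keep <- seq.int(cov[1L], cov[length(cov)])
  sub_alignment(aln, keep)
}

#' Drop columns where the reference is gapped
#'
#' Produces the pseudo-MSA used for reference-numbered reporting: output
#' column i corresponds to reference residue i.
#'
#' @inheritParams trim_to_reference
#' @return `aa_alignment` with `n_cols` equal to the ungapped reference length.
#' @export
drop_reference_gap_columns <- function(aln, refmap) {
  sub_alignment(aln, refmap$resnum_to_col)
}

#' Extract a column subset of an alignment
#' @param aln An `aa_alignment`.
#' @param cols Integer column indices to keep, in the order given.
#' @return `aa_alignment` restricted to `cols`.
#' @export
sub_alignment <- function(aln, cols) {
  m <- unclass(aln)[, cols, drop = FALSE]
  if (nrow(m) > 0L && ncol(m) == 0L) {
    # keep a valid zero-column alignment
    dimnames(m) <- list(rownames(aln), NULL)
  }
  class(m) <- c("aa_alignment", "matrix", "array")
  m
}

#' Extract a row (sequence) subset of an alignment
#' @param aln An `aa_alignment`.
#' @param ids Sequence identifiers or logical/integer row index.
#' @return `aa_alignment` restricted to the selected sequences.
#' @export
sub_sequences <- function(aln, ids) {
  m <- unclass(aln)[ids, , drop = FALSE]
  class(m) <- c("aa_alignment", "matrix", "array")
  m
}

#' Read a Newick tree
#'
#' Thin wrapper over [ape::read.tree()] that also accepts a degenerate
#' single-leaf string and validates the result.
#'
#' @param path Path to a Newick file.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  tr <- tryCatch(suppressWarnings(ape::read.tree(text = txt)),
                 error = function(e) NULL)
  if (!is.null(tr) && (length(tr$tip.label) == 0L || anyNA(tr$tip.label))) {
    tr <- NULL  # ape returns a malformed object for bare single-leaf strings
  }
  if (is.null(tr)) {
    name <- sub("^\\s*([^();,:]+?)\\s*;?\\s*$", "\\1", txt)
    if (nzchar(name) && !grepl("[();,]", name)) {
      # single-leaf degenerate tree
      tr <- structure(list(edge = matrix(c(2L, 1L), 1L, 2L),
                           tip.label = name, Nnode = 1L),
                      class = "phylo")
    } else {
      stop("Newick format error in ", path)
    }
  }
  if (is.null(tr$tip.label) || length(tr$tip.label) == 0L) {
    stop("Newick format error in ", path, ": no leaves")
  }
  tr
}

#' Integer-code an alignment for MI estimation
#'
#' Residues are coded 1..20 (alphabetical AA order), gap is 21. `X` is coded
#' as the gap symbol so estimators stay on a fixed 21-symbol space.
#'
#' @param aln An `aa_alignment`.
#' @return Integer matrix of the same shape.
#' @keywords internal
encode_alignment <- function(aln) {
  codes <- match(unclass(aln), AA20)
  codes[is.na(codes)] <- 21L
  matrix(codes, nrow = nrow(aln), ncol = ncol(aln),
         dimnames = list(rownames(aln), NULL))
}
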