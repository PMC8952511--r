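# Position-specific log-odds profiles.
#
# The profile is the package's stand-in for an HMMER profile: its contract is
# the ranking property (cluster members score above non-members), not
# bit-score compatibility. Columns are scored independently; gaps contribute
# nothing.

#' Build a position-specific log-odds profile from a sub-alignment
#'
#' Per column, the smoothed probability of residue `a` is
#' `(count(a) + alpha * bg(a)) / (n + alpha)` where `n` is the number of
#' residues observed in the column (gaps and `X` excluded), and the weight is
#' `log2(p / bg(a))` in bits.
#'
#' @param sub_aln An `aa_alignment` with at least one sequence.
#' @param alpha Pseudocount mass (default 1).
#' @param background Background amino-acid distribution over the 20 letters
#'   (default uniform 0.05). Must sum to 1.
#' @return An `aa_profile`: list with `weights` (20 x n_cols matrix, rows
#'   named by residue), `alpha`, `background`, `n_cols`.
#' @export
build_profile <- function(sub_aln, alpha = 1, background = rep(0.05, 20)) {
  if (nrow(sub_aln) == 0L) stop("cannot build profile from empty alignment")
  stopifnot(length(background) == 20L, abs(sum(background) - 1) < 1e-8)
  m <- unclass(sub_aln)
  nc <- ncol(m)
  counts <- matrix(0, nrow = 20L, ncol = nc, dimnames = list(AA20, NULL))
  for (a in seq_along(AA20)) counts[a, ] <- colSums(m == AA20[a])
  n <- colSums(counts)
  p <- sweep(counts + alpha * background, 2L, n + alpha, "/")
  weights <- log2(p / background)
  structure(list(weights = weights, alpha = alpha,
                 background = stats::setNames(background, AA20),
                 n_cols = nc),
            class = "aa_profile")
}

#' @export
print.aa_profile <- function(x, ...) {
  cat("aa_profile: ", x$n_cols, " columns, alpha = ", x$alpha, "\n", sep = "")
  invisible(x)
}

#' Score one aligned sequence against a profile
#'
#' Sum of the column weights at the sequence's non-gap positions, in bits.
#' `X` positions contribute nothing. An all-gap row scores 0.
#'
#' @param profile An `aa_profile`.
#' @param aligned_row Character vector of residues (one per profile column) or
#'   a single string.
#' @return Score in bits.
#' @export
score_sequence <- function(profile, aligned_row) {
  if (length(aligned_row) == 1L && nchar(aligned_row[1L]) > 1L) {
    aligned_row <- strsplit(aligned_row, "", fixed = TRUE)[[1L]]
  }
  if (length(aligned_row) != profile$n_cols) {
    stop("length mismatch: row has ", length(aligned_row),
         " positions, profile has ", profile$n_cols, " columns")
  }
  ai <- match(aligned_row, AA20)
  keep <- !is.na(ai)
  if (!any(keep)) return(0)
  sum(profile$weights[cbind(ai[keep], which(keep))])
}

#' Score every sequence of an alignment against a profile
#'
#' @param profile An `aa_profile`.
#' @param aln An `aa_alignment` with `n_cols` equal to the profile length.
#' @return Named numeric vector of scores in bits.
#' @export
score_alignment <- function(profile, aln) {
  if (ncol(aln) != profile$n_cols) {
    stop("length mismatch: alignment has ", ncol(aln),
         " columns, profile has ", profile$n_cols)
  }
  m <- unclass(aln)
  ai <- match(m, AA20)            # residue index or NA (gap / X)
  w <- matrix(0, nrow(m), ncol(m))
  keep <- !is.na(ai)
  colidx <- col(m)
  w[keep] <- profile$weights[cbind(ai[keep], colidx[keep])]
  stats::setNames(rowSums(w), rownames(m))
}
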