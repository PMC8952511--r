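# Column-column mutual information networks.
#
# All unordered column pairs get a plug-in MI (bits, gaps as a 21st symbol)
# and a permutation z-score: the null permutes the row order of the
# higher-index column. Edges are recorded for every pair, including those
# below the significance floor -- the random-ensemble step of the SDN needs
# z-scores for arbitrary node subsets.

#' Pairwise mutual information between all alignment columns
#'
#' @param aln An `aa_alignment` with at least 2 columns.
#' @return Symmetric `n_cols x n_cols` matrix of MI values in bits; the
#'   diagonal holds each column's entropy (`MI(X, X) = H(X)`).
#' @export
pairwise_mi <- function(aln) {
  if (ncol(aln) < 2L) stop("need at least 2 columns")
  pairwise_mi_cpp(encode_alignment(aln), 21L)
}

#' Mutual-information z-scores for all column pairs
#'
#' For each pair `(i, j)` with `i < j`, the null distribution is obtained by
#' permuting the rows of column `j` (`n_shuffle` shared permutations);
#' `z = (MI_obs - null_mean) / null_sd`, with `z = 0` where `null_sd = 0`.
#'
#' @param aln An `aa_alignment`.
#' @param n_shuffle Number of row permutations (default 200).
#' @param seed Integer seed.
#' @return An `mi_edge_set` data frame: `col_i`, `col_j` (`i < j`), `mi`, `z`,
#'   with attributes `n_cols` and `n_shuffle`.
#' @export
mi_zscores <- function(aln, n_shuffle = 200L, seed = 1L) {
  codes <- encode_alignment(aln)
  n <- nrow(codes)
  p <- ncol(codes)
  if (p < 2L) stop("need at least 2 columns")
  if (p > 5000L) {
    stop("alignment has ", p, " columns; the pipeline caps at 5000 - ",
         "trim to the reference span first (trim_to_reference)")
  }
  if (p > 1000L) {
    warning("alignment has ", p, " columns; all-pairs permutation nulls ",
            "scale quadratically and the pipeline is designed for <= 1000")
  }
  mi <- pairwise_mi_cpp(codes, 21L)
  perms <- local_seed(seed, {
    vapply(seq_len(n_shuffle), function(i) sample.int(n), integer(n))
  })
  null <- pairwise_mi_null_cpp(codes, 21L, perms)
  iu <- which(upper.tri(mi), arr.ind = TRUE)
  m <- null$mean[iu]
  s <- null$sd[iu]
  obs <- mi[iu]
  z <- ifelse(s > 0, (obs - m) / s, 0)
  out <- data.frame(col_i = iu[, 1L], col_j = iu[, 2L], mi = obs, z = z,
                    null_mean = m, null_sd = s, stringsAsFactors = FALSE)
  out <- out[order(out$col_i, out$col_j), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_cols") <- p
  attr(out, "n_shuffle") <- n_shuffle
  class(out) <- c("mi_edge_set", "data.frame")
  out
}
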