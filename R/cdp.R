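# Cluster Determining Positions: columns whose residue distribution carries
# significant mutual information about a subfamily partition.
#
# The statistic is plug-in MI (bits) between the column (21 symbols, gap is
# the 21st) and the partition labels; significance is a label-permutation
# z-score with the same permutations reused across columns, so a scan is
# deterministic given (seed, n_perm).

#' Plug-in mutual information between one column and a partition
#'
#' `sum p(a,g) log2( p(a,g) / (p(a) p(g)) )`, with gaps treated as a 21st
#' residue symbol. A single group gives 0 by definition.
#'
#' @param column Character vector of residues (one per sequence).
#' @param labels Group label per sequence (same length).
#' @return MI in bits.
#' @export
column_group_mi <- function(column, labels) {
  stopifnot(length(column) == length(labels))
  if (length(unique(labels)) < 2L) return(0)
  joint <- table(column, labels)
  n <- sum(joint)
  p <- joint / n
  pa <- rowSums(p)
  pg <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(pa, pg)[nz]))
}

#' Read / write partition labels (two-column TSV with header)
#'
#' @param path TSV file with columns `sequence_id` and `cluster_label`.
#' @return Named character vector id -> label.
#' @export
read_partition <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("partition TSV needs two columns (id, label)")
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' @rdname read_partition
#' @param partition Named character vector id -> label.
#' @export
write_partition <- function(partition, path) {
  utils::write.table(data.frame(sequence_id = names(partition),
                                cluster_label = unname(partition)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Scan an alignment for Cluster Determining Positions
#'
#' For every column, computes observed column-partition MI and a permutation
#' null (labels permuted over sequences; the same `n_perm` permutations are
#' reused for every column). `z = (MI_obs - null_mean) / null_sd`; columns
#' with `null_sd = 0` get `z = 0` (uninformative). A column is a CDP when
#' `z > z_threshold`.
#'
#' @param aln An `aa_alignment`.
#' @param partition Named character vector id -> group label covering every
#'   row of `aln`.
#' @param n_perm Number of label permutations (default 10000).
#' @param seed Integer seed for the permutations.
#' @param z_threshold CDP z cut (default 3.29, a one-sided normal
#'   p of about 5e-4).
#' @param refmap Optional `reference_map` used to annotate columns with
#'   reference residue numbers.
#' @return A `cdp_table` data frame: `col`, `resnum`, `mi`, `null_mean`,
#'   `null_sd`, `z`, `is_cdp`.
#' @export
cdp_scan <- function(aln, partition, n_perm = 10000L, seed = 1L,
                     z_threshold = 3.29, refmap = NULL) {
  ids <- rownames(aln)
  if (!all(ids %in% names(partition))) {
    stop("partition does not cover the alignment: missing ",
         paste(utils::head(setdiff(ids, names(partition))), collapse = ", "))
  }
  labels <- factor(partition[ids])
  k <- nlevels(labels)
  if (k < 2L) stop("need at least 2 groups for CDP detection")
  codes <- encode_alignment(aln)
  n <- nrow(codes)
  perms <- local_seed(seed, {
    vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
  })
  res <- column_group_mi_null_cpp(codes, as.integer(labels), 21L, k, perms)
  z <- ifelse(res$sd > 0, (res$mi - res$mean) / res$sd, 0)
  out <- data.frame(col = seq_len(ncol(aln)),
                    resnum = if (is.null(refmap)) NA_integer_
                             else refmap$col_to_resnum,
                    mi = res$mi, null_mean = res$mean, null_sd = res$sd,
                    z = z, is_cdp = z > z_threshold,
                    stringsAsFactors = FALSE)
  attr(out, "z_threshold") <- z_threshold
  attr(out, "n_perm") <- n_perm
  class(out) <- c("cdp_table", "data.frame")
  out
}

# Run an expression under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(list = ".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
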