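# End-to-end pipeline driver and reporting artifacts.
#
# A "design" is a named group-vs-group comparison over cluster labels (e.g.
# every cluster separately, or two pooled super-groups). All designs over the
# same alignment share one MI edge set, which is computed once.

#' Run the SDP-network pipeline over one or more comparison designs
#'
#' Stages: optional scrutiny -> partition (given, or tree clustering) ->
#' per-design CDP scan -> shared column-pair MI z-scores -> MIT scan ->
#' random-ensemble significance -> intersection of SDP sets across designs.
#'
#' @param aln An `aa_alignment`.
#' @param reference_id Reference row id for residue numbering.
#' @param partition Named id -> cluster label vector. Alternatively pass
#'   `tree` to cluster first.
#' @param tree Optional [ape::phylo] used to derive the partition via
#'   [cluster_tree()] when `partition` is `NULL`.
#' @param designs Named list of designs; each design is either `NULL` (every
#'   cluster its own group) or a named list mapping group label ->
#'   character vector of cluster labels to pool (clusters not mentioned are
#'   dropped from that design).
#' @param scrutinize_first Run [scrutinize()] before analysis (default TRUE).
#' @param cfg A [scrutiny_config()].
#' @param z_threshold CDP/edge z floor (default 3.29).
#' @param n_perm Label permutations per CDP scan (default 10000).
#' @param n_shuffle Row permutations per MI pair (default 200).
#' @param n_random Random networks for the significance test (default 1000).
#' @param seed Integer seed controlling every stochastic stage.
#' @param mics_denominator Passed to [scan_mit()].
#' @return List with `alignment` (post-scrutiny), `refmap`, `scrutiny`
#'   (report or NULL), `partition`, `edges`, per-design `analyses` (each with
#'   `cdp` and `sdn`), `shared` (a `shared_sdp_set` when >1 design) and
#'   `log` (parameters, seeds, per-stage counts).
#' @export
run_sdn_pipeline <- function(aln, reference_id, partition = NULL, tree = NULL,
                             designs = list(all_clusters = NULL),
                             scrutinize_first = TRUE,
                             cfg = scrutiny_config(),
                             z_threshold = 3.29, n_perm = 10000L,
                             n_shuffle = 200L, n_random = 1000L, seed = 1L,
                             mics_denominator = "global") {
  log <- list(params = list(z_threshold = z_threshold, n_perm = n_perm,
                            n_shuffle = n_shuffle, n_random = n_random,
                            seed = seed, mics_denominator = mics_denominator),
              stages = list())
  refmap <- build_reference_map(aln, reference_id)
  scrutiny <- NULL
  if (scrutinize_first) {
    sc <- scrutinize(aln, refmap, cfg)
    scrutiny <- sc$report
    log$stages$scrutiny <- list(input = nrow(aln), removed = nrow(sc$report),
                                kept = nrow(sc$alignment))
    aln <- sc$alignment
    refmap <- build_reference_map(aln, reference_id)
  }
  if (is.null(partition)) {
    if (is.null(tree)) stop("need either a partition or a tree")
    keep <- intersect(tree$tip.label, rownames(aln))
    cs <- cluster_tree(ape::keep.tip(tree, keep), aln)
    partition <- cluster_labels(cs)
    log$stages$clustering <- list(clusters = length(cs$clusters),
                                  unassigned = length(cs$unassigned))
  }
  partition <- partition[intersect(names(partition), rownames(aln))]
  aln_p <- sub_sequences(aln, names(partition))

  edges <- mi_zscores(aln_p, n_shuffle = n_shuffle, seed = seed)
  log$stages$mi <- list(n_pairs = nrow(edges))

  analyses <- list()
  for (d in seq_along(designs)) {
    dname <- names(designs)[d]
    spec <- designs[[d]]
    if (is.null(spec)) {
      labels <- partition
    } else {
      labels <- rep(NA_character_, length(partition))
      names(labels) <- names(partition)
      for (g in names(spec)) {
        labels[partition %in% spec[[g]]] <- g
      }
      labels <- labels[!is.na(labels)]
    }
    sub <- sub_sequences(aln_p, names(labels))
    sub_ref <- build_reference_map_or_null(sub, reference_id, refmap)
    cdp <- cdp_scan(sub, labels, n_perm = n_perm, seed = seed + d,
                    z_threshold = z_threshold, refmap = sub_ref)
    sdn <- suppressWarnings(scan_mit(cdp, edges, z_min = z_threshold,
                                     mics_denominator = mics_denominator))
    if (nrow(sdn$nodes) > 0L) {
      sdn <- ensemble_z(sdn, seq_len(ncol(sub)), edges,
                        n_random = n_random, seed = seed + 100L + d)
    }
    analyses[[dname]] <- list(cdp = cdp, sdn = sdn)
    log$stages[[paste0("design_", dname)]] <-
      list(groups = length(unique(labels)), n_seqs = length(labels),
           n_cdps = sum(cdp$is_cdp), n_sdn_nodes = nrow(sdn$nodes))
  }
  shared <- NULL
  if (length(analyses) > 1L) {
    shared <- intersect_sdps(lapply(analyses, `[[`, "sdn"), refmap)
  }
  list(alignment = aln, refmap = refmap, scrutiny = scrutiny,
       partition = partition, edges = edges, analyses = analyses,
       shared = shared, log = log)
}

# Designs can drop sequences but never columns, so the parent refmap stays
# column-compatible; rebuild only if the reference survived subsetting.
build_reference_map_or_null <- function(aln, reference_id, fallback) {
  if (reference_id %in% rownames(aln)) build_reference_map(aln, reference_id)
  else fallback
}

#' Extract the pseudo-MSA of SDP columns
#'
#' Restricts an alignment to an SDN's node columns, ordered by reference
#' residue number, for reference-numbered logo rendering.
#'
#' @param aln An `aa_alignment`.
#' @param sdn An `sdn`.
#' @param refmap A `reference_map` on `aln`.
#' @return An `aa_alignment` with one column per SDP.
#' @export
extract_sdp_pseudo_msa <- function(aln, sdn, refmap) {
  cols <- sdn$nodes$col
  if (length(cols) == 0L) {
    warning("empty SDN: empty pseudo-MSA")
    return(sub_alignment(aln, integer()))
  }
  rn <- refmap$col_to_resnum[cols]
  ord <- order(is.na(rn), rn, cols)
  sub_alignment(aln, cols[ord])
}

#' Per-column residue frequency matrices (logo input)
#'
#' Relative frequencies over the 21 symbols (20 residues + gap) per column,
#' pooled or split by group. `X` is excluded from the counts.
#'
#' @param sub_aln An `aa_alignment` (e.g. an SDP pseudo-MSA).
#' @param per_group Optional named id -> group vector; when given, one
#'   frequency matrix per group is returned.
#' @return A 21 x n_cols matrix (rows named by symbol), or a named list of
#'   such matrices when `per_group` is given. Columns sum to 1 (or 0 for a
#'   column of only `X`).
#' @export
logo_matrix <- function(sub_aln, per_group = NULL) {
  if (nrow(sub_aln) == 0L || ncol(sub_aln) == 0L) stop("empty alignment")
  one <- function(m) {
    syms <- c(AA20, GAP)
    counts <- vapply(syms, function(a) colSums(m == a),
                     numeric(ncol(m)))
    counts <- matrix(counts, ncol = length(syms),
                     dimnames = list(NULL, syms))
    tot <- rowSums(counts)
    freq <- counts / ifelse(tot > 0, tot, 1)
    t(freq)
  }
  if (is.null(per_group)) return(one(unclass(sub_aln)))
  ids <- rownames(sub_aln)
  stopifnot(all(ids %in% names(per_group)))
  groups <- split(ids, per_group[ids])
  lapply(groups, function(g) one(unclass(sub_sequences(sub_aln, g))))
}
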