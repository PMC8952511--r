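# Tree-guided clustering under the 100% precision-and-recall rule, and
# iterative profile-threshold classification of additional sequences.
#
# A cluster is accepted only when a profile built from its own members scores
# every member strictly above every non-member of the full alignment; the
# minimum member self-score becomes the cluster's inclusion threshold.

#' Test the 100% precision-and-recall certificate for a candidate cluster
#'
#' @param member_ids Sequence ids forming the candidate cluster.
#' @param aln The full `aa_alignment` (members plus non-members).
#' @param profile Optional pre-built `aa_profile` for the member
#'   sub-alignment; built here when `NULL`.
#' @return `TRUE` iff the minimum member score is strictly greater than the
#'   maximum non-member score under the cluster's own profile. When the
#'   cluster spans the whole alignment the certificate is vacuously `TRUE`
#'   (with a warning).
#' @export
is_100pr <- function(member_ids, aln, profile = NULL) {
  stopifnot(length(member_ids) >= 1L, all(member_ids %in% rownames(aln)))
  others <- setdiff(rownames(aln), member_ids)
  if (length(others) == 0L) {
    warning("cluster spans the whole alignment: 100% P&R holds vacuously")
    return(TRUE)
  }
  if (is.null(profile)) profile <- build_profile(sub_sequences(aln, member_ids))
  scores <- score_alignment(profile, aln)
  min(scores[member_ids]) > max(scores[others])
}

clade_children <- function(tree) {
  # list: node id -> integer vector of children (tips are 1..Ntip)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  kids <- vector("list", ntip + nnode)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]
    kids[[p]] <- c(kids[[p]], tree$edge[e, 2L])
  }
  kids
}

clade_tips <- function(node, kids, ntip, tip_labels) {
  if (node <= ntip) return(tip_labels[node])
  out <- character()
  for (ch in kids[[node]]) out <- c(out, clade_tips(ch, kids, ntip, tip_labels))
  out
}

#' Cluster an alignment by pre-order traversal of its phylogeny
#'
#' Starting at the root's children (the root clade has no non-members, so its
#' certificate would be vacuous), each clade is accepted as a cluster as soon
#' as it passes [is_100pr()]; accepted clades are not descended into. Leaves
#' that fail even as singletons become unassigned. Every accepted cluster is
#' monophyletic and carries the 100% P&R certificate.
#'
#' @param tree An [ape::phylo] tree whose leaf labels are alignment ids.
#' @param aln An `aa_alignment` containing (at least) the tree's leaves.
#' @return A `cluster_set`: list with `clusters` (each a list with `label`,
#'   `members`, `profile`, `threshold` = minimum member self-score) and
#'   `unassigned` (character ids).
#' @export
cluster_tree <- function(tree, aln) {
  stopifnot(all(tree$tip.label %in% rownames(aln)))
  ntip <- length(tree$tip.label)
  kids <- clade_children(tree)
  root <- ntip + 1L
  clusters <- list()
  unassigned <- character()

  visit <- function(node) {
    members <- clade_tips(node, kids, ntip, tree$tip.label)
    profile <- build_profile(sub_sequences(aln, members))
    ok <- suppressWarnings(is_100pr(members, aln, profile))
    if (ok) {
      scores <- score_alignment(profile, sub_sequences(aln, members))
      clusters[[length(clusters) + 1L]] <<- list(
        label = paste0("C", length(clusters) + 1L),
        members = members, profile = profile, threshold = min(scores))
    } else if (node <= ntip) {
      unassigned <<- c(unassigned, members)
    } else {
      for (ch in kids[[node]]) visit(ch)
    }
    invisible(NULL)
  }
  if (ntip == 1L) {
    visit(1L)
  } else {
    for (ch in kids[[root]]) visit(ch)
    if (length(clusters) == 0L) {
      # degenerate alignment (e.g. identical sequences): no clade below the
      # root separates, so the root clade itself is the only 100% P&R
      # cluster, vacuously
      members <- tree$tip.label
      profile <- build_profile(sub_sequences(aln, members))
      is_100pr(members, sub_sequences(aln, members), profile)  # warns
      scores <- score_alignment(profile, sub_sequences(aln, members))
      clusters <- list(list(label = "C1", members = members,
                            profile = profile, threshold = min(scores)))
      unassigned <- character()
    }
  }
  structure(list(clusters = clusters, unassigned = unassigned),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("cluster_set: ", length(x$clusters), " clusters, ",
      length(x$unassigned), " unassigned\n", sep = "")
  for (cl in x$clusters) {
    cat(sprintf("  %-4s %4d members  threshold %.2f\n",
                cl$label, length(cl$members), cl$threshold))
  }
  invisible(x)
}

#' Partition labels of a cluster set
#' @param cs A `cluster_set`.
#' @return Named character vector id -> cluster label (unassigned ids absent).
#' @export
cluster_labels <- function(cs) {
  out <- character()
  for (cl in cs$clusters) {
    out[cl$members] <- cl$label
  }
  out
}

#' Classify target sequences into existing clusters
#'
#' Iterative, dynamic classification: each round, every unassigned target is
#' scored against every cluster profile; a target is accepted into the cluster
#' where its score reaches that cluster's threshold and the margin over the
#' runner-up cluster is maximal. Profiles and thresholds are rebuilt after
#' each round and the 100% P&R certificate is re-verified against the
#' training-plus-accepted pool; a round's acceptances into a cluster are
#' rolled back (and the cluster frozen) if they break the certificate.
#'
#' @param cs A `cluster_set` from [cluster_tree()].
#' @param aln The training `aa_alignment` used to build `cs`.
#' @param targets An `aa_alignment` of target sequences in the same column
#'   frame (same `n_cols`).
#' @param max_iter Maximum classification rounds (default 10).
#' @return List with `assignments` (data frame `id`, `cluster` (`NA` when
#'   unclassified), `score`) and the updated `cluster_set`.
#' @export
classify_targets <- function(cs, aln, targets, max_iter = 10L) {
  stopifnot(ncol(targets) == ncol(aln))
  pool <- aa_alignment(rbind(unclass(aln), unclass(targets)))
  unclassified <- rownames(targets)
  assigned <- stats::setNames(rep(NA_character_, nrow(targets)), rownames(targets))
  final_score <- stats::setNames(rep(NA_real_, nrow(targets)), rownames(targets))
  frozen <- stats::setNames(rep(FALSE, length(cs$clusters)),
                            vapply(cs$clusters, `[[`, "", "label"))

  for (iter in seq_len(max_iter)) {
    if (length(unclassified) == 0L) break
    smat <- vapply(cs$clusters, function(cl) {
      score_alignment(cl$profile, sub_sequences(pool, unclassified))
    }, numeric(length(unclassified)))
    smat <- matrix(smat, nrow = length(unclassified),
                   dimnames = list(unclassified,
                                   vapply(cs$clusters, `[[`, "", "label")))
    thr <- vapply(cs$clusters, `[[`, 0, "threshold")
    batch <- list()
    for (id in unclassified) {
      s <- smat[id, ]
      eligible <- which(s >= thr & !frozen[colnames(smat)])
      if (length(eligible) == 0L) next
      if (length(s) > 1L) {
        margin <- vapply(eligible, function(k) s[k] - max(s[-k]), 0)
      } else {
        margin <- s[eligible]
      }
      k <- eligible[which.max(margin)]
      batch[[colnames(smat)[k]]] <- c(batch[[colnames(smat)[k]]], id)
    }
    if (length(batch) == 0L) break
    changed <- FALSE
    for (lab in names(batch)) {
      ki <- which(vapply(cs$clusters, `[[`, "", "label") == lab)
      cl <- cs$clusters[[ki]]
      new_members <- c(cl$members, batch[[lab]])
      new_profile <- build_profile(sub_sequences(pool, new_members))
      ok <- suppressWarnings(is_100pr(new_members, pool, new_profile))
      if (ok) {
        scores <- score_alignment(new_profile, sub_sequences(pool, new_members))
        cs$clusters[[ki]]$members <- new_members
        cs$clusters[[ki]]$profile <- new_profile
        cs$clusters[[ki]]$threshold <- min(scores)
        assigned[batch[[lab]]] <- lab
        final_score[batch[[lab]]] <- scores[batch[[lab]]]
        unclassified <- setdiff(unclassified, batch[[lab]])
        changed <- TRUE
      } else {
        frozen[lab] <- TRUE    # roll back: certificate would break
      }
    }
    if (!changed) break
  }
  list(assignments = data.frame(id = rownames(targets),
                                cluster = assigned[rownames(targets)],
                                score = final_score[rownames(targets)],
                                row.names = NULL, stringsAsFactors = FALSE),
       cluster_set = cs)
}
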