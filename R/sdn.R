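# The Specificity Determining Network.
#
# Candidate networks are built from CDP nodes and CDP-CDP MI edges above a
# Mutual Information Threshold (MIT). For a given MIT, with N the number of
# CDPs retaining at least one supra-threshold edge, each connected node i
# gets a Mutual Information Connectivity Score
#     MICS_i = (sum of its supra-threshold edge z-scores) / (N - 1)
# and the candidate scores
#     SNS = MIT * sum_i MICS_i .
# The scan walks every MIT at which the network can change (the 3.29 floor
# plus each distinct edge z below the maximum) and keeps the candidate with
# maximal SNS; significance is assessed against 1000 random same-size node
# subsets drawn from all alignment columns, scored at the same cut-offs.

#' Mutual Information Connectivity Scores at a given threshold
#'
#' Edges with `z` strictly above `mit` are kept. `N` is the number of CDP
#' nodes with at least one kept edge. Connected nodes get
#' `MICS = sum(kept z) / (N - 1)` (or, with
#' `mics_denominator = "degree"`, divided by the node's own kept degree);
#' unconnected nodes get 0.
#'
#' @param cdp_cols Integer vector of CDP column indices (the nodes).
#' @param edges Data frame with `col_i`, `col_j`, `z` (any superset; only
#'   CDP-CDP pairs are used).
#' @param mit The MI z-score threshold.
#' @param mics_denominator `"global"` (N - 1, the displayed-formula reading)
#'   or `"degree"` (per-node connection count).
#' @return Named numeric vector of MICS over `cdp_cols`.
#' @export
mics_scores <- function(cdp_cols, edges, mit,
                        mics_denominator = c("global", "degree")) {
  mics_denominator <- match.arg(mics_denominator)
  mics <- stats::setNames(numeric(length(cdp_cols)), as.character(cdp_cols))
  e <- edges[edges$col_i %in% cdp_cols & edges$col_j %in% cdp_cols &
               edges$z > mit, , drop = FALSE]
  if (nrow(e) == 0L) return(mics)
  zsum <- tapply(c(e$z, e$z), c(e$col_i, e$col_j), sum)
  deg <- tapply(rep(1, 2L * nrow(e)), c(e$col_i, e$col_j), sum)
  connected <- names(zsum)
  N <- length(connected)
  if (N <= 1L) return(mics)
  denom <- if (mics_denominator == "global") rep(N - 1, N) else deg[connected]
  mics[connected] <- as.numeric(zsum[connected]) / as.numeric(denom)
  mics
}

#' Specific Network Score
#'
#' `SNS = MIT * sum(MICS)` for a candidate network.
#'
#' @param mit The threshold the MICS map was computed at.
#' @param mics_map Output of [mics_scores()] at the same `mit`.
#' @return The SNS (non-negative real).
#' @export
sns <- function(mit, mics_map) {
  mit * sum(mics_map)
}

#' Select the Specificity Determining Network by scanning the MIT
#'
#' Candidate MITs are the floor `z_min` plus every distinct CDP-CDP edge
#' z-score strictly between `z_min` and the maximum (the SNS is piecewise
#' constant between edge weights, so the scan is exhaustive; at the maximal
#' edge z the network is empty by strictness). The candidate with maximal SNS
#' is returned; ties go to the smallest MIT (the largest network).
#'
#' @param cdp_table A `cdp_table` from [cdp_scan()] (or any data frame with
#'   `col`, `z` and optionally `is_cdp`, `resnum`).
#' @param edge_set An `mi_edge_set` from [mi_zscores()] covering the columns.
#' @param z_min Floor threshold (default 3.29).
#' @param mics_denominator Passed to [mics_scores()].
#' @return An `sdn`: list with `nodes` (data frame `col`, `resnum`, `cdp_z`,
#'   `mics`), `edges` (`col_i`, `col_j`, `z` above the selected MIT), `mit`,
#'   `sns`, `trace` (data frame of every candidate MIT with its SNS and node
#'   count) and `z_min`.
#' @export
scan_mit <- function(cdp_table, edge_set, z_min = 3.29,
                     mics_denominator = c("global", "degree")) {
  mics_denominator <- match.arg(mics_denominator)
  if (is.null(cdp_table$is_cdp)) cdp_table$is_cdp <- TRUE
  cdps <- cdp_table[cdp_table$is_cdp, , drop = FALSE]
  if (nrow(cdps) < 2L) {
    warning("fewer than 2 CDPs: empty SDN")
    return(empty_sdn(z_min))
  }
  cdp_cols <- cdps$col
  ce <- edge_set[edge_set$col_i %in% cdp_cols & edge_set$col_j %in% cdp_cols &
                   edge_set$z > z_min, , drop = FALSE]
  if (nrow(ce) == 0L) {
    warning("no CDP-CDP edge above the floor: empty SDN")
    return(empty_sdn(z_min))
  }
  zmax <- max(ce$z)
  candidates <- c(z_min, sort(unique(ce$z[ce$z > z_min & ce$z < zmax])))
  trace <- data.frame(mit = candidates, sns = NA_real_, n_nodes = NA_integer_)
  best <- NULL
  for (i in seq_along(candidates)) {
    mit <- candidates[i]
    mm <- mics_scores(cdp_cols, ce, mit, mics_denominator)
    s <- sns(mit, mm)
    trace$sns[i] <- s
    trace$n_nodes[i] <- sum(mm > 0)
    if (is.null(best) || s > best$sns + 1e-12) {
      best <- list(mit = mit, sns = s, mics = mm)
    }
  }
  kept <- ce[ce$z > best$mit, , drop = FALSE]
  node_cols <- cdp_cols[best$mics[as.character(cdp_cols)] > 0]
  nodes <- data.frame(
    col = node_cols,
    resnum = if (is.null(cdps$resnum)) NA_integer_
             else cdps$resnum[match(node_cols, cdps$col)],
    cdp_z = cdps$z[match(node_cols, cdps$col)],
    mics = as.numeric(best$mics[as.character(node_cols)]),
    stringsAsFactors = FALSE)
  structure(list(nodes = nodes,
                 edges = kept[, c("col_i", "col_j", "z")],
                 mit = best$mit, sns = best$sns, trace = trace,
                 z_min = z_min, mics_denominator = mics_denominator,
                 ensemble = NULL),
            class = "sdn")
}

empty_sdn <- function(z_min) {
  structure(list(nodes = data.frame(col = integer(), resnum = integer(),
                                    cdp_z = numeric(), mics = numeric()),
                 edges = data.frame(col_i = integer(), col_j = integer(),
                                    z = numeric()),
                 mit = z_min, sns = 0,
                 trace = data.frame(mit = numeric(), sns = numeric(),
                                    n_nodes = integer()),
                 z_min = z_min, mics_denominator = "global",
                 ensemble = NULL),
            class = "sdn")
}

#' @export
print.sdn <- function(x, ...) {
  cat("sdn: ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges, MIT = ", format(x$mit, digits = 4),
      ", SNS = ", format(x$sns, digits = 6), "\n", sep = "")
  if (!is.null(x$ensemble)) {
    cat("  ensemble: z = ", format(x$ensemble$z_score, digits = 5),
        " over ", x$ensemble$n_random, " random networks\n", sep = "")
  }
  invisible(x)
}

#' Significance of an SDN against random same-size networks
#'
#' Draws `n_random` uniform node subsets of the SDN's size from all alignment
#' columns (CDPs or not), scores each at the SDN's selected MIT (edges within
#' the subset with `z > mit`, MICS per the same formula) and reports
#' `z_score = (sns - mean_random) / sd_random`. With `sd_random = 0` the
#' z-score is `+Inf` (with a warning).
#'
#' @param sdn An `sdn` from [scan_mit()].
#' @param all_cols Integer vector of all alignment column indices.
#' @param edge_set An `mi_edge_set` covering all pairs of `all_cols`.
#' @param n_random Number of random networks (default 1000).
#' @param seed Integer seed.
#' @param rescan If `TRUE`, each random node set is re-scanned for its own
#'   SNS-maximising MIT instead of being scored at the SDN's MIT.
#' @return The `sdn` with an `ensemble` element: `n_random`, `mean`, `sd`,
#'   `z_score`, `sns_random` (the raw draws).
#' @export
ensemble_z <- function(sdn, all_cols, edge_set, n_random = 1000L, seed = 1L,
                       rescan = FALSE) {
  m <- nrow(sdn$nodes)
  if (m == 0L) stop("empty SDN: nothing to test")
  if (m > length(all_cols)) stop("SDN larger than the set of positions")
  supra <- edge_set[edge_set$z > sdn$mit, , drop = FALSE]
  floor_edges <- edge_set[edge_set$z > sdn$z_min, , drop = FALSE]
  draws <- local_seed(seed, {
    lapply(seq_len(n_random), function(i) sample(all_cols, m))
  })
  sns_random <- vapply(draws, function(subset) {
    if (rescan) {
      tab <- data.frame(col = subset, z = NA_real_, is_cdp = TRUE)
      e <- floor_edges[floor_edges$col_i %in% subset &
                         floor_edges$col_j %in% subset, , drop = FALSE]
      if (nrow(e) == 0L) return(0)
      suppressWarnings(scan_mit(tab, e, z_min = sdn$z_min,
                                mics_denominator = sdn$mics_denominator)$sns)
    } else {
      e <- supra[supra$col_i %in% subset & supra$col_j %in% subset, , drop = FALSE]
      if (nrow(e) == 0L) return(0)
      mm <- mics_scores(subset, e, sdn$mit, sdn$mics_denominator)
      sns(sdn$mit, mm)
    }
  }, numeric(1L))
  mu <- mean(sns_random)
  sdv <- stats::sd(sns_random)
  if (sdv == 0) {
    warning("random-network SNS has zero spread; ensemble z reported as +Inf")
    z <- Inf
  } else {
    z <- (sdn$sns - mu) / sdv
  }
  sdn$ensemble <- list(n_random = n_random, mean = mu, sd = sdv,
                       z_score = z, sns_random = sns_random)
  sdn
}

#' Intersect SDP sets across analyses
#'
#' Maps every SDN's nodes to reference residue numbers and returns the
#' positions present in all of them, with a per-analysis membership table.
#'
#' @param sdns Named list of `sdn` objects.
#' @param refmaps A single `reference_map` or a list of them (one per SDN),
#'   used where an SDN's nodes lack `resnum` annotation.
#' @return A `shared_sdp_set`: list with `resnums` (sorted integer vector)
#'   and `membership` (logical matrix, rows = residue numbers, columns =
#'   analyses).
#' @export
intersect_sdps <- function(sdns, refmaps = NULL) {
  if (is.null(names(sdns))) names(sdns) <- paste0("analysis", seq_along(sdns))
  get_resnums <- function(i) {
    sdn <- sdns[[i]]
    rn <- sdn$nodes$resnum
    if (all(is.na(rn)) && !is.null(refmaps)) {
      rm_i <- if (inherits(refmaps, "reference_map")) refmaps else refmaps[[i]]
      rn <- rm_i$col_to_resnum[sdn$nodes$col]
    }
    if (anyNA(rn)) {
      warning("analysis '", names(sdns)[i], "': ", sum(is.na(rn)),
              " node(s) not mappable to reference numbering; excluded")
      rn <- rn[!is.na(rn)]
    }
    sort(unique(rn))
  }
  per <- lapply(seq_along(sdns), get_resnums)
  names(per) <- names(sdns)
  all_rn <- sort(unique(unlist(per)))
  membership <- vapply(per, function(rn) all_rn %in% rn,
                       logical(length(all_rn)))
  membership <- matrix(membership, nrow = length(all_rn),
                       dimnames = list(all_rn, names(sdns)))
  shared <- all_rn[rowSums(membership) == length(sdns)]
  structure(list(resnums = shared, membership = membership),
            class = "shared_sdp_set")
}

#' @export
print.shared_sdp_set <- function(x, ...) {
  cat("shared_sdp_set: ", length(x$resnums), " positions shared by ",
      ncol(x$membership), " analyses\n", sep = "")
  if (length(x$resnums)) cat("  ", paste(x$resnums, collapse = ", "), "\n")
  invisible(x)
}

#' Induced subnetwork view of an SDN
#'
#' Restricts the SDN to a node subset at the same MIT; MICS values are
#' recomputed within the view (N counts only subset nodes that stay
#' connected).
#'
#' @param sdn An `sdn`.
#' @param node_cols Integer column indices, a subset of the SDN's nodes.
#' @return An `sdn`-classed view (no scan trace or ensemble).
#' @export
subnetwork <- function(sdn, node_cols) {
  stopifnot(all(node_cols %in% sdn$nodes$col))
  e <- sdn$edges[sdn$edges$col_i %in% node_cols &
                   sdn$edges$col_j %in% node_cols, , drop = FALSE]
  mm <- mics_scores(node_cols, e, sdn$mit, sdn$mics_denominator)
  keep <- node_cols[mm[as.character(node_cols)] > 0]
  nodes <- sdn$nodes[match(keep, sdn$nodes$col), , drop = FALSE]
  nodes$mics <- as.numeric(mm[as.character(keep)])
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = e, mit = sdn$mit,
                 sns = sns(sdn$mit, mm),
                 trace = NULL, z_min = sdn$z_min,
                 mics_denominator = sdn$mics_denominator, ensemble = NULL),
            class = "sdn")
}

#' Export an SDN to JSON
#'
#' @param sdn An `sdn`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sdn_json <- function(sdn, path) {
  payload <- list(nodes = sdn$nodes, edges = sdn$edges, mit = sdn$mit,
                  sns = sdn$sns, z_min = sdn$z_min,
                  mics_denominator = sdn$mics_denominator,
                  trace = sdn$trace,
                  ensemble = if (is.null(sdn$ensemble)) NULL else
                    sdn$ensemble[c("n_random", "mean", "sd", "z_score")])
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}
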