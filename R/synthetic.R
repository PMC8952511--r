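# Synthetic superfamily generator with planted ground truth.
#
# Emulates the statistical structure the SDP analysis assumes: globally
# conserved catalytic columns, subfamily-specifically conserved columns (the
# planted SDPs), coevolving column pairs driven by a hidden per-sequence
# state whose frequency differs between subfamilies, drifting background
# columns with a shared modal residue, and gap-rich columns. A companion
# corruption step plants the sequence pathologies the scrutiny filters are
# built to remove.

#' Generator configuration
#'
#' @param k_subfamilies Number of subfamilies (default 3).
#' @param n_per_subfamily Sequences per subfamily (default 60).
#' @param n_cols Alignment columns (default 250).
#' @param n_catalytic Globally conserved columns (default 5).
#' @param p_catalytic Conservation of catalytic columns (default 0.99).
#' @param n_sdp Planted SDP columns (default 12).
#' @param p_sdp Within-subfamily modal frequency at SDP columns (default
#'   0.95); each subfamily gets a distinct modal residue.
#' @param n_coevolving_pairs Column pairs driven by a hidden binary state
#'   (default 4); the per-subfamily state-1 frequencies are spread over
#'   `(0.1, 0.9)`.
#' @param p_coev Fidelity of the state-to-residue channel at coevolving
#'   columns (default 0.95, matching `p_sdp`): each column shows its state's
#'   residue with this probability and the opposite state's residue
#'   otherwise. A noise-free channel would make these two columns' mutual
#'   information an order of magnitude more extreme than any other planted
#'   signal, which no real covarying site pair attains.
#' @param p_bg Background conservation towards a per-column modal residue
#'   shared across subfamilies (default 0.60).
#' @param gap_col_frac Fraction of gap-rich columns (default 0.05; rows are
#'   gapped there with probability 0.7).
#' @param include_reference Designate the first subfamily-1 sequence as the
#'   numbering reference `REF` (modal residues, gapped at gap-rich columns).
#' @param seed Integer seed; generation is deterministic given the config.
#' @return A `generator_config` list.
#' @export
generator_config <- function(k_subfamilies = 3L, n_per_subfamily = 60L,
                             n_cols = 250L, n_catalytic = 5L,
                             p_catalytic = 0.99, n_sdp = 12L, p_sdp = 0.95,
                             n_coevolving_pairs = 4L, p_coev = 0.95,
                             p_bg = 0.60,
                             gap_col_frac = 0.05, include_reference = TRUE,
                             seed = 7L) {
  cfg <- list(k_subfamilies = as.integer(k_subfamilies),
              n_per_subfamily = as.integer(n_per_subfamily),
              n_cols = as.integer(n_cols),
              n_catalytic = as.integer(n_catalytic),
              p_catalytic = p_catalytic,
              n_sdp = as.integer(n_sdp), p_sdp = p_sdp,
              n_coevolving_pairs = as.integer(n_coevolving_pairs),
              p_coev = p_coev, p_bg = p_bg, gap_col_frac = gap_col_frac,
              include_reference = isTRUE(include_reference),
              seed = as.integer(seed))
  n_gap <- round(cfg$gap_col_frac * cfg$n_cols)
  need <- cfg$n_catalytic + cfg$n_sdp + 2L * cfg$n_coevolving_pairs + n_gap
  if (need > cfg$n_cols) {
    stop("config error: column budget exceeded (", need, " special columns, ",
         cfg$n_cols, " available)")
  }
  stopifnot(cfg$p_catalytic > 0, cfg$p_catalytic < 1,
            cfg$p_sdp > 0, cfg$p_sdp < 1, cfg$p_bg > 0, cfg$p_bg < 1,
            cfg$p_coev > 0.5, cfg$p_coev <= 1, cfg$k_subfamilies >= 2L)
  structure(cfg, class = "generator_config")
}

#' Generate a synthetic superfamily with known ground truth
#'
#' @param config A [generator_config()].
#' @return List with `alignment` (an `aa_alignment` of
#'   `k_subfamilies * n_per_subfamily` rows), `tree` (an [ape::phylo]:
#'   within-subfamily coalescent subtrees on long stem branches), `partition`
#'   (named id -> subfamily label) and `truth` (a `synthetic_truth` list:
#'   `subfamily`, `sdp_cols`, `coevolving_pairs` (two-column matrix),
#'   `catalytic_cols`, `gap_cols`, `reference_id`, `corrupted` (empty data
#'   frame here)).
#' @export
generate_superfamily <- function(config = generator_config()) {
  cfg <- config
  local_seed(cfg$seed, {
    K <- cfg$k_subfamilies
    n <- cfg$n_per_subfamily
    nc <- cfg$n_cols
    total <- K * n
    n_gap <- round(cfg$gap_col_frac * nc)

    roles <- rep("background", nc)
    shuffled <- sample.int(nc)
    take <- function(k) {
      out <- shuffled[seq_len(k)]
      shuffled <<- shuffled[-seq_len(k)]
      out
    }
    catalytic_cols <- sort(take(cfg$n_catalytic))
    sdp_cols <- sort(take(cfg$n_sdp))
    coev_cols <- take(2L * cfg$n_coevolving_pairs)
    coev_pairs <- matrix(sort(coev_cols), ncol = 2L, byrow = TRUE)
    gap_cols <- sort(take(n_gap))
    roles[catalytic_cols] <- "catalytic"
    roles[sdp_cols] <- "sdp"
    roles[c(coev_pairs)] <- "coevolving"
    roles[gap_cols] <- "gap_rich"

    subfam <- rep(paste0("SF", seq_len(K)), each = n)
    ids <- paste0(subfam, "_", rep(sprintf("%03d", seq_len(n)), K))
    m <- matrix(GAP, nrow = total, ncol = nc, dimnames = list(ids, NULL))

    draw_col <- function(modal, p) {
      # each row: modal residue with prob p, otherwise uniform over the rest
      hit <- stats::runif(total) < p
      out <- rep(modal, total)
      k <- sum(!hit)
      if (k) out[!hit] <- vapply(seq_len(k), function(i)
        sample(setdiff(AA20, modal), 1L), "")
      out
    }
    for (cc in catalytic_cols) {
      m[, cc] <- draw_col(sample(AA20, 1L), cfg$p_catalytic)
    }
    for (cc in sdp_cols) {
      modal <- sample(AA20, K)   # distinct modal residue per subfamily
      for (g in seq_len(K)) {
        rows <- which(subfam == paste0("SF", g))
        hit <- stats::runif(n) < cfg$p_sdp
        res <- rep(modal[g], n)
        k <- sum(!hit)
        if (k) res[!hit] <- vapply(seq_len(k), function(i)
          sample(setdiff(AA20, modal[g]), 1L), "")
        m[rows, cc] <- res
      }
    }
    # each subfamily sits predominantly in one joint state; an intermediate
    # frequency would add within-subfamily covariation far beyond what any
    # other planted signal produces
    state_freq <- rep(c(0.9, 0.1), length.out = K)
    for (pr in seq_len(nrow(coev_pairs))) {
      a <- coev_pairs[pr, 1L]; b <- coev_pairs[pr, 2L]
      res_a <- sample(AA20, 2L); res_b <- sample(AA20, 2L)
      state <- stats::runif(total) < state_freq[match(subfam, paste0("SF", seq_len(K)))]
      # noisy channel with the same error model as every other column type:
      # the state's residue with prob p_coev, otherwise uniform over the rest
      noisy <- function(res, which_state) {
        out <- ifelse(which_state, res[1L], res[2L])
        miss <- stats::runif(total) >= cfg$p_coev
        k <- sum(miss)
        if (k) out[miss] <- vapply(which(miss), function(r)
          sample(setdiff(AA20, out[r]), 1L), "")
        out
      }
      m[, a] <- noisy(res_a, state)
      m[, b] <- noisy(res_b, state)
    }
    for (cc in which(roles == "background")) {
      m[, cc] <- draw_col(sample(AA20, 1L), cfg$p_bg)
    }
    for (cc in gap_cols) {
      res <- draw_col(sample(AA20, 1L), cfg$p_bg)
      gap <- stats::runif(total) < 0.7
      res[gap] <- GAP
      m[, cc] <- res
    }

    reference_id <- NA_character_
    if (cfg$include_reference) {
      # first subfamily-1 row becomes the numbering reference: an ordinary
      # subfamily-1 draw (a consensus row would outscore other subfamilies'
      # weakest members under their own profiles and so break their 100% P&R
      # certificates), gapped at exactly the gap-rich columns
      reference_id <- "REF"
      ids[1L] <- reference_id
      rownames(m)[1L] <- reference_id
      m[1L, gap_cols] <- GAP
      ungapped <- setdiff(which(m[1L, ] == GAP), gap_cols)
      for (cc in ungapped) {
        tab <- table(m[subfam == "SF1", cc])
        tab <- tab[names(tab) != GAP]
        m[1L, cc] <- names(tab)[which.max(tab)]
      }
    }

    tree <- build_subfamily_tree(ids, subfam)
    partition <- stats::setNames(subfam, ids)
    truth <- structure(list(subfamily = partition,
                            sdp_cols = sdp_cols,
                            coevolving_pairs = coev_pairs,
                            catalytic_cols = catalytic_cols,
                            gap_cols = gap_cols,
                            reference_id = reference_id,
                            corrupted = data.frame(id = character(),
                                                   kind = character(),
                                                   source = character(),
                                                   stringsAsFactors = FALSE)),
                       class = "synthetic_truth")
    list(alignment = aa_alignment(m), tree = tree, partition = partition,
         truth = truth)
  })
}

# Star of within-subfamily coalescent subtrees on long stem branches.
build_subfamily_tree <- function(ids, subfam) {
  groups <- split(ids, subfam)
  subtrees <- lapply(groups, function(tips) {
    if (length(tips) == 1L) return(NULL)
    tr <- ape::rcoal(length(tips), tip.label = sample(tips))
    tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
    tr
  })
  K <- length(groups)
  # backbone star with long stems, subtrees bound at the tips
  backbone <- ape::stree(K, type = "star")
  backbone$tip.label <- names(groups)
  backbone$edge.length <- rep(10, nrow(backbone$edge))
  for (g in names(groups)) {
    if (is.null(subtrees[[g]])) {
      backbone$tip.label[backbone$tip.label == g] <- groups[[g]]
    } else {
      backbone <- ape::bind.tree(backbone, subtrees[[g]],
                                 where = which(backbone$tip.label == g))
    }
  }
  backbone
}

#' Append corrupted sequences to a synthetic alignment
#'
#' Plants the pathologies the scrutiny filters target, recording every
#' corrupted id and its kind in the truth object:
#' \describe{
#'   \item{truncate_to_half}{keeps the first 50% of a member's residues
#'     (below the 65% length rule).}
#'   \item{spurious_insert}{adds a 15-residue insert in a fresh all-gap
#'     column block (a unique insert).}
#'   \item{internal_deletion}{gaps a 40-column run inside the longest
#'     high-occupancy stretch (a long internal gap).}
#'   \item{shuffle}{permutes the member's residues in place (a profile-score
#'     outlier).}
#'   \item{tandem_repeat}{duplicates the member's row into an appended copy
#'     of the original columns (a repeat with two high-scoring windows).}
#' }
#' Insert and repeat blocks are appended after the existing columns, so
#' planted-truth column indices remain valid.
#'
#' @param aln An `aa_alignment` (clean).
#' @param truth Matching `synthetic_truth`.
#' @param kinds Subset of the five kinds above.
#' @param per_kind Corrupted copies per kind (default 5).
#' @param seed Integer seed.
#' @return List with `alignment` (clean + corrupted rows, possibly wider) and
#'   updated `truth`.
#' @export
corrupt_alignment <- function(aln, truth,
                              kinds = c("truncate_to_half", "spurious_insert",
                                        "internal_deletion", "shuffle",
                                        "tandem_repeat"),
                              per_kind = 5L, seed = 1L) {
  kinds <- match.arg(kinds, several.ok = TRUE)
  local_seed(seed, {
    m <- unclass(aln)
    nc0 <- ncol(m)
    clean_ids <- setdiff(rownames(m), truth$reference_id)
    occ <- column_occupancy(aln)

    new_rows <- list()
    recs <- list()
    extra_cols <- 0L
    inserts <- list()   # per new row: list(start (in appended frame), residues)
    repeats <- character()

    for (kind in kinds) {
      sources <- sample(clean_ids, per_kind)
      for (i in seq_len(per_kind)) {
        src <- sources[i]
        row <- m[src, ]
        id <- sprintf("CORRUPT_%s_%02d", kind, i)
        if (kind == "truncate_to_half") {
          res_pos <- which(row != GAP)
          drop <- res_pos[-seq_len(floor(length(res_pos) / 2))]
          row[drop] <- GAP
        } else if (kind == "spurious_insert") {
          ins_len <- 15L
          inserts[[id]] <- list(offset = extra_cols,
                                residues = sample(AA20, ins_len, replace = TRUE))
          extra_cols <- extra_cols + ins_len
        } else if (kind == "internal_deletion") {
          hot <- occ >= 0.8
          r <- rle(hot)
          ends <- cumsum(r$lengths)
          starts <- ends - r$lengths + 1L
          runs <- which(r$values)
          best <- runs[which.max(r$lengths[runs])]
          len <- min(40L, r$lengths[best])
          row[seq(starts[best], length.out = len)] <- GAP
        } else if (kind == "shuffle") {
          res_pos <- which(row != GAP)
          row[res_pos] <- row[sample(res_pos)]
        } else if (kind == "tandem_repeat") {
          repeats <- c(repeats, id)
        }
        new_rows[[id]] <- row
        recs[[id]] <- data.frame(id = id, kind = kind, source = src,
                                 stringsAsFactors = FALSE)
      }
    }

    n_new <- length(new_rows)
    rep_block <- if (length(repeats)) nc0 else 0L
    total_extra <- extra_cols + rep_block
    out <- rbind(m, do.call(rbind, new_rows))
    if (total_extra > 0L) {
      pad <- matrix(GAP, nrow = nrow(out), ncol = total_extra)
      rownames(pad) <- rownames(out)
      for (id in names(inserts)) {
        ins <- inserts[[id]]
        pad[id, ins$offset + seq_along(ins$residues)] <- ins$residues
      }
      for (id in repeats) {
        src <- recs[[id]]$source
        pad[id, extra_cols + seq_len(nc0)] <- m[src, ]
      }
      out <- cbind(out, pad)
    }
    truth$corrupted <- rbind(truth$corrupted, do.call(rbind, unname(recs)))
    rownames(truth$corrupted) <- NULL
    list(alignment = aa_alignment(out), truth = truth)
  })
}
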