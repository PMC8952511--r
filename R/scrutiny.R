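# Alignment scrutiny: removal of non-functional and misannotated sequences.
#
# Four iterated rules (short sequences; poorly represented inserts; long gaps
# in occupied columns; profile-score outliers) plus two standalone filters
# (repeat-bearing sequences; catalytic-residue check). The rules' intent
# follows published MSA-scrutiny practice; the numeric knobs for rules ii-iv
# are package defaults exposed in the config.

#' Scrutiny configuration
#'
#' @param min_length_frac Sequences shorter than this fraction of the
#'   reference's ungapped length are removed (rule i, default 0.65).
#' @param insert_occupancy_max A residue run counts as a unique insert when the
#'   columns' occupancy, excluding the sequence itself, is at most this
#'   (rule ii, default 0.10).
#' @param insert_min_len Minimum length (columns) of a unique-insert run
#'   (default 10).
#' @param gap_occupancy_min Columns at or above this occupancy count towards a
#'   long internal gap (rule iii, default 0.80).
#' @param gap_min_len Minimum length (columns) of a long gap run (default 30).
#' @param outlier_mad_k Modified z-score cut for low score outliers
#'   (rule iv, default 3.5).
#' @param max_rounds Maximum filter rounds before stopping (default 10).
#' @return A `scrutiny_config` list.
#' @export
scrutiny_config <- function(min_length_frac = 0.65,
                            insert_occupancy_max = 0.10,
                            insert_min_len = 10L,
                            gap_occupancy_min = 0.80,
                            gap_min_len = 30L,
                            outlier_mad_k = 3.5,
                            max_rounds = 10L) {
  stopifnot(min_length_frac > 0, min_length_frac < 1,
            insert_occupancy_max > 0, insert_occupancy_max < 1,
            gap_occupancy_min > 0, gap_occupancy_min < 1,
            insert_min_len >= 1, gap_min_len >= 1, max_rounds >= 1)
  structure(list(min_length_frac = min_length_frac,
                 insert_occupancy_max = insert_occupancy_max,
                 insert_min_len = as.integer(insert_min_len),
                 gap_occupancy_min = gap_occupancy_min,
                 gap_min_len = as.integer(gap_min_len),
                 outlier_mad_k = outlier_mad_k,
                 max_rounds = as.integer(max_rounds)),
            class = "scrutiny_config")
}

longest_run <- function(flags) {
  if (!any(flags)) return(0L)
  r <- rle(flags)
  max(r$lengths[r$values])
}

#' Remove very short sequences (rule i)
#'
#' Removes rows whose ungapped length is strictly below
#' `min_length_frac` times the reference's ungapped length. The reference
#' itself is never removed.
#'
#' @param aln An `aa_alignment`.
#' @param refmap A `reference_map` on `aln`.
#' @param cfg A [scrutiny_config()].
#' @return List with `alignment` (filtered) and `removed` (character ids).
#' @export
filter_short <- function(aln, refmap, cfg = scrutiny_config()) {
  lens <- ungapped_lengths(aln)
  ref_len <- length(refmap$resnum_to_col)
  bad <- names(lens)[lens < cfg$min_length_frac * ref_len]
  bad <- setdiff(bad, refmap$reference_id)
  list(alignment = sub_sequences(aln, setdiff(rownames(aln), bad)),
       removed = bad)
}

#' Remove sequences with unique inserts (rule ii)
#'
#' A sequence is removed when it has a run of at least `insert_min_len`
#' residues confined to columns whose occupancy, computed excluding that
#' sequence, is at most `insert_occupancy_max`: such runs instigate unique
#' gap blocks in every other row.
#'
#' @inheritParams filter_short
#' @param exempt Ids never removed (e.g. the reference).
#' @return List with `alignment` and `removed`.
#' @export
filter_unique_inserts <- function(aln, cfg = scrutiny_config(), exempt = character()) {
  m <- unclass(aln)
  nongap <- m != GAP
  tot <- colSums(nongap)
  n <- nrow(m)
  bad <- character()
  for (i in seq_len(n)) {
    occ_excl <- (tot - nongap[i, ]) / max(1L, n - 1L)
    flags <- nongap[i, ] & occ_excl <= cfg$insert_occupancy_max
    if (longest_run(flags) >= cfg$insert_min_len) bad <- c(bad, rownames(m)[i])
  }
  bad <- setdiff(bad, exempt)
  list(alignment = sub_sequences(aln, setdiff(rownames(aln), bad)),
       removed = bad)
}

#' Remove sequences with long gaps in occupied columns (rule iii)
#'
#' A sequence is removed when it is gapped over a run of at least
#' `gap_min_len` columns whose occupancy is at least `gap_occupancy_min`:
#' it lacks a subsequence present in most sequences.
#'
#' @inheritParams filter_unique_inserts
#' @return List with `alignment` and `removed`.
#' @export
filter_long_gaps <- function(aln, cfg = scrutiny_config(), exempt = character()) {
  m <- unclass(aln)
  occ <- column_occupancy(aln)
  hot <- occ >= cfg$gap_occupancy_min
  bad <- character()
  for (i in seq_len(nrow(m))) {
    flags <- (m[i, ] == GAP) & hot
    if (longest_run(flags) >= cfg$gap_min_len) bad <- c(bad, rownames(m)[i])
  }
  bad <- setdiff(bad, exempt)
  list(alignment = sub_sequences(aln, setdiff(rownames(aln), bad)),
       removed = bad)
}

#' Remove low-score outlier sequences (rule iv)
#'
#' Scores every sequence against a profile built from the current alignment
#' and removes those whose modified z-score
#' `(median - score) / (1.4826 * MAD)` exceeds `outlier_mad_k`. One-sided:
#' only low scores are outliers. With `MAD = 0` nothing is removed.
#'
#' @inheritParams filter_unique_inserts
#' @param profile An `aa_profile` built from `aln` (built here if `NULL`).
#' @return List with `alignment`, `removed` and the `scores` used.
#' @export
filter_score_outliers <- function(aln, profile = NULL, cfg = scrutiny_config(),
                                  exempt = character()) {
  if (is.null(profile)) profile <- build_profile(aln)
  scores <- score_alignment(profile, aln)
  med <- stats::median(scores)
  s <- stats::mad(scores)   # 1.4826 * MAD by default
  if (s == 0) {
    warning("MAD of profile scores is 0; no outliers removed")
    bad <- character()
  } else {
    z <- (med - scores) / s
    bad <- setdiff(names(scores)[z > cfg$outlier_mad_k], exempt)
  }
  list(alignment = sub_sequences(aln, setdiff(rownames(aln), bad)),
       removed = bad, scores = scores)
}

#' Flag repeat-bearing sequences
#'
#' Sequences containing repeats accumulate profile score from every copy and
#' end up scoring above any single-copy sequence. A sequence is flagged when
#' its total score strictly exceeds `ceiling` (the maximum profile score of a
#' designated training/reference subset) and it contains at least two disjoint
#' fixed-width windows each scoring above 50% of the ceiling.
#'
#' @param aln An `aa_alignment`.
#' @param profile An `aa_profile` over the same columns.
#' @param ceiling Maximum profile score among the training subset.
#' @param window_cols Window width in columns; defaults to half the alignment
#'   width. Pass the reference-covered span when the alignment carries extra
#'   low-occupancy blocks.
#' @return Character vector of flagged ids.
#' @export
flag_repeats <- function(aln, profile, ceiling, window_cols = NULL) {
  m <- unclass(aln)
  nc <- ncol(m)
  if (is.null(window_cols)) window_cols <- max(1L, nc %/% 2L)
  window_cols <- min(as.integer(window_cols), nc)
  ai <- match(m, AA20)
  w <- matrix(0, nrow(m), nc)
  keep <- !is.na(ai)
  w[keep] <- profile$weights[cbind(ai[keep], col(m)[keep])]
  total <- rowSums(w)
  flagged <- character()
  half <- ceiling / 2
  n_win <- nc - window_cols + 1L
  if (n_win < 2L) return(flagged)
  for (i in which(total > ceiling)) {
    cs <- c(0, cumsum(w[i, ]))
    starts <- seq_len(n_win)
    wsums <- cs[starts + window_cols] - cs[starts]
    # best pair of disjoint windows: prefix/suffix maxima of window sums
    best_upto <- cummax(wsums)                 # best window starting <= s
    best_from <- rev(cummax(rev(wsums)))       # best window starting >= s
    ok <- FALSE
    for (s in seq_len(n_win - window_cols)) {
      # window starting at s ends at s + window_cols - 1; next window may
      # start at s + window_cols
      if (best_upto[s] > half && best_from[s + window_cols] > half) {
        ok <- TRUE
        break
      }
    }
    if (ok) flagged <- c(flagged, rownames(m)[i])
  }
  flagged
}

#' Default catalytic-residue rules (GH28, 1CZF numbering)
#'
#' A sequence is considered catalytically competent when it has Asp at
#' reference position 180 and at least one of Asp201 / Asp-or-Glu202. Each
#' rule group is a named list `resnum -> allowed residues`; a sequence fails a
#' group only when it misses every position in the group.
#'
#' @return List of rule groups.
#' @export
default_catalytic_rules <- function() {
  list(list(`180` = "D"),
       list(`201` = "D", `202` = c("D", "E")))
}

#' Remove sequences lacking catalytic residues
#'
#' @param aln An `aa_alignment`.
#' @param refmap A `reference_map` on `aln`.
#' @param rules Rule groups as in [default_catalytic_rules()]: a sequence is
#'   removed if, for any group, it misses all of the group's positions.
#' @return List with `alignment` and `removed`.
#' @export
filter_catalytic <- function(aln, refmap, rules = default_catalytic_rules()) {
  m <- unclass(aln)
  bad <- rep(FALSE, nrow(m))
  for (group in rules) {
    miss_all <- rep(TRUE, nrow(m))
    for (rn in names(group)) {
      col <- refmap$resnum_to_col[as.integer(rn)]
      if (is.na(col) || length(col) == 0L) {
        stop("configuration error: reference residue ", rn, " is unmapped")
      }
      miss_all <- miss_all & !(m[, col] %in% group[[rn]])
    }
    bad <- bad | miss_all
  }
  bad_ids <- setdiff(rownames(m)[bad], refmap$reference_id)
  list(alignment = sub_sequences(aln, setdiff(rownames(aln), bad_ids)),
       removed = bad_ids)
}

#' Iterated alignment scrutiny (rules i-iv)
#'
#' Applies the four filters in order, recomputing occupancy and the profile
#' before each one, and repeats the round until no sequence is removed or
#' `max_rounds` is reached. The reference sequence is exempt throughout: it is
#' the numbering anchor.
#'
#' @param aln An `aa_alignment`.
#' @param refmap A `reference_map` on `aln`.
#' @param cfg A [scrutiny_config()].
#' @return List with `alignment` (the fixed point) and `report`, a data frame
#'   with columns `id`, `rule` (`short`, `unique_insert`, `long_gap`,
#'   `score_outlier`) and `round`.
#' @export
scrutinize <- function(aln, refmap, cfg = scrutiny_config()) {
  exempt <- refmap$reference_id
  report <- data.frame(id = character(), rule = character(), round = integer(),
                       stringsAsFactors = FALSE)
  note <- function(ids, rule, round) {
    if (length(ids)) rbind(report, data.frame(id = ids, rule = rule,
                                              round = round,
                                              stringsAsFactors = FALSE))
    else report
  }
  for (round in seq_len(cfg$max_rounds)) {
    n_before <- nrow(aln)

    r <- filter_short(aln, refmap, cfg)
    report <- note(r$removed, "short", round); aln <- r$alignment

    r <- filter_unique_inserts(aln, cfg, exempt = exempt)
    report <- note(r$removed, "unique_insert", round); aln <- r$alignment

    r <- filter_long_gaps(aln, cfg, exempt = exempt)
    report <- note(r$removed, "long_gap", round); aln <- r$alignment

    r <- suppressWarnings(filter_score_outliers(aln, NULL, cfg, exempt = exempt))
    report <- note(r$removed, "score_outlier", round); aln <- r$alignment

    if (nrow(aln) == 0L) stop("pipeline error: all sequences removed")
    if (nrow(aln) == n_before) break
  }
  list(alignment = aln, report = report)
}
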