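# The synthetic superfamily generator and its planted ground truth.

test_that("generation is deterministic and matches the configured shape", {
  cfg <- generator_config(seed = 7)
  g1 <- generate_superfamily(cfg)
  expect_equal(dim(unclass(g1$alignment)), c(180L, 250L))
  expect_length(g1$truth$sdp_cols, 12L)
  expect_equal(dim(g1$truth$coevolving_pairs), c(4L, 2L))
  expect_length(g1$truth$catalytic_cols, 5L)
  expect_setequal(g1$tree$tip.label, rownames(g1$alignment))

  g2 <- generate_superfamily(cfg)
  expect_identical(unclass(g1$alignment), unclass(g2$alignment))
  expect_identical(g1$truth, g2$truth)
  expect_identical(ape::write.tree(g1$tree), ape::write.tree(g2$tree))

  g3 <- generate_superfamily(generator_config(seed = 8))
  expect_false(identical(unclass(g1$alignment), unclass(g3$alignment)))
})

test_that("planted conservation levels are realised within tolerance", {
  g <- sim_default()
  m <- unclass(g$alignment)
  sf <- g$partition[rownames(m)]
  for (cc in g$truth$sdp_cols) {
    for (grp in unique(sf)) {
      col <- m[sf == grp, cc]
      modal_freq <- max(table(col)) / length(col)
      expect_gte(modal_freq, 0.95 - 0.05)
      expect_lte(modal_freq, 0.95 + 0.05)
    }
  }
  # distinct modal residues across subfamilies at SDP columns
  for (cc in g$truth$sdp_cols) {
    modals <- vapply(unique(sf), function(grp) {
      names(which.max(table(m[sf == grp, cc])))
    }, "")
    expect_equal(length(unique(modals)), length(unique(sf)))
  }
  # catalytic columns are globally conserved
  for (cc in g$truth$catalytic_cols) {
    expect_gte(max(table(m[, cc])) / nrow(m), 0.95)
  }
  # gap-rich columns are gap-dominated; others are fully occupied except REF
  occ <- column_occupancy(g$alignment)
  expect_true(all(occ[g$truth$gap_cols] < 0.5))
  expect_true(all(occ[-g$truth$gap_cols] > 0.9))
})

test_that("the reference row anchors numbering at exactly the gap columns", {
  g <- sim_default()
  expect_equal(g$truth$reference_id, "REF")
  rm <- build_reference_map(g$alignment, "REF")
  expect_setequal(which(is.na(rm$col_to_resnum)), g$truth$gap_cols)
})

test_that("corruptions have the planted pathologies and valid bookkeeping", {
  g <- sim_small()
  cor <- corrupt_alignment(g$alignment, g$truth, per_kind = 2, seed = 3)
  aln <- cor$alignment
  rec <- cor$truth$corrupted
  expect_equal(nrow(rec), 10L)
  expect_true(all(rec$id %in% rownames(aln)))
  expect_true(all(rec$source %in% rownames(g$alignment)))

  lens <- ungapped_lengths(aln)
  ref_len <- lens["REF"]
  for (i in which(rec$kind == "truncate_to_half")) {
    expect_lt(lens[rec$id[i]], 0.65 * ref_len)
    expect_equal(unname(lens[rec$id[i]]),
                 floor(unname(lens[rec$source[i]]) / 2))
  }
  # a tandem repeat is its source followed by its source
  m <- unclass(aln)
  nc0 <- n_cols(g$alignment)
  for (i in which(rec$kind == "tandem_repeat")) {
    first <- m[rec$id[i], seq_len(nc0)]
    second <- m[rec$id[i], (ncol(m) - nc0 + 1):ncol(m)]
    src <- m[rec$source[i], seq_len(nc0)]
    expect_equal(unname(first), unname(src))
    expect_equal(unname(second), unname(src))
  }
  # shuffles keep composition and gap pattern but not order
  for (i in which(rec$kind == "shuffle")) {
    a <- m[rec$id[i], seq_len(nc0)]
    b <- m[rec$source[i], seq_len(nc0)]
    expect_equal(sort(a), sort(b))
    expect_equal(a == "-", b == "-")
    expect_false(all(a == b))
  }
  # determinism
  cor2 <- corrupt_alignment(g$alignment, g$truth, per_kind = 2, seed = 3)
  expect_identical(unclass(cor$alignment), unclass(cor2$alignment))
})
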