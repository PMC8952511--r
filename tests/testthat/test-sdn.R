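# MICS / SNS arithmetic, the MIT scan, the random-network significance test
# and the shared-SDP intersection.

toy_edges <- function() {
  data.frame(col_i = c(1L, 1L), col_j = c(2L, 3L), z = c(10, 4))
}
toy_cdps <- function() {
  data.frame(col = 1:3, z = c(5, 5, 5), is_cdp = TRUE)
}

test_that("MICS follows the displayed formula at both toy thresholds", {
  mm <- mics_scores(1:3, toy_edges(), mit = 3.29)
  expect_equal(unname(mm[c("1", "2", "3")]), c(7, 5, 2))
  mm4 <- mics_scores(1:3, toy_edges(), mit = 4)
  expect_equal(unname(mm4[c("1", "2", "3")]), c(10, 10, 0))
  # degree denominator: node 1 has 2 connections at the floor
  mmd <- mics_scores(1:3, toy_edges(), mit = 3.29, mics_denominator = "degree")
  expect_equal(unname(mmd[c("1", "2", "3")]), c(7, 10, 4))
  # no edges above the threshold: all zero
  expect_equal(sum(mics_scores(1:3, toy_edges(), mit = 11)), 0)
})

test_that("SNS multiplies the MIT into the summed connectivity", {
  expect_equal(sns(3.29, mics_scores(1:3, toy_edges(), 3.29)), 46.06)
  expect_equal(sns(4, mics_scores(1:3, toy_edges(), 4)), 80)
  expect_equal(sns(5, numeric()), 0)
})

test_that("the MIT scan selects the maximal-SNS candidate on the toy graph", {
  sdn <- scan_mit(toy_cdps(), toy_edges())
  expect_equal(sdn$trace$mit, c(3.29, 4))
  expect_equal(sdn$trace$sns, c(46.06, 80), tolerance = 1e-9)
  expect_equal(sdn$mit, 4)
  expect_equal(sdn$sns, 80)
  expect_setequal(sdn$nodes$col, c(1L, 2L))
  expect_equal(nrow(sdn$edges), 1L)

  # single edge z = 6 between two CDPs: the floor is the only candidate
  one <- scan_mit(data.frame(col = 1:2, z = c(4, 4), is_cdp = TRUE),
                  data.frame(col_i = 1L, col_j = 2L, z = 6))
  expect_equal(one$mit, 3.29)
  expect_equal(one$sns, 3.29 * 12)
})

test_that("strictness forces the selected MIT below the maximal edge z", {
  set.seed(71)
  for (i in 1:50) {
    g <- random_cdp_graph(sample(3:12, 1))
    if (nrow(g$edges) == 0) next
    sdn <- suppressWarnings(scan_mit(data.frame(col = g$cols, z = 5,
                                                is_cdp = TRUE), g$edges))
    if (nrow(sdn$nodes) == 0) next
    expect_lt(sdn$mit, max(g$edges$z))
    # at the maximal edge z the network would be empty (strict '>')
    expect_equal(sum(mics_scores(g$cols, g$edges, max(g$edges$z))), 0)
  }
})

test_that("the scan agrees exactly with the brute-force oracle", {
  set.seed(81)
  for (i in 1:100) {
    g <- random_cdp_graph(sample(3:12, 1))
    sdn <- suppressWarnings(scan_mit(data.frame(col = g$cols, z = 5,
                                                is_cdp = TRUE), g$edges))
    oracle <- oracle_scan(g$cols, g$edges)
    expect_equal(sdn$mit, oracle$mit)
    expect_equal(sdn$sns, oracle$sns, tolerance = 1e-9)
    expect_equal(sort(sdn$nodes$col), oracle$nodes)
  }
})

test_that("the random-ensemble z is deterministic, ordered and degenerate-safe", {
  gen <- sim_small()
  cdp <- cdp_scan(gen$alignment, gen$partition, n_perm = 2000, seed = 5)
  es <- mi_zscores(gen$alignment, n_shuffle = 200, seed = 3)
  sdn <- scan_mit(cdp, es)
  expect_gt(nrow(sdn$nodes), 0)
  s1 <- ensemble_z(sdn, seq_len(n_cols(gen$alignment)), es,
                   n_random = 300, seed = 9)
  s2 <- ensemble_z(sdn, seq_len(n_cols(gen$alignment)), es,
                   n_random = 300, seed = 9)
  expect_identical(s1$ensemble, s2$ensemble)
  # random same-size subsets cannot beat the planted network on average
  expect_gte(s1$ensemble$mean, 0)
  expect_lte(s1$ensemble$mean, sdn$sns)
  expect_gt(s1$ensemble$z_score, 3.29)

  # SDN nodes = all positions: every random network identical -> sd 0, +Inf
  all_cols <- sdn$nodes$col
  expect_warning(deg <- ensemble_z(sdn, all_cols, es, n_random = 50, seed = 1),
                 "Inf")
  expect_equal(deg$ensemble$z_score, Inf)
})

test_that("SDP intersection equals brute-force set intersection", {
  mk <- function(resnums) {
    structure(list(nodes = data.frame(col = seq_along(resnums),
                                      resnum = resnums,
                                      cdp_z = 5, mics = 1),
                   edges = data.frame(col_i = integer(), col_j = integer(),
                                      z = numeric()),
                   mit = 3.29, sns = 1, z_min = 3.29,
                   mics_denominator = "global", ensemble = NULL),
              class = "sdn")
  }
  a <- mk(c(10, 20, 30, 40))
  b <- mk(c(20, 40, 50))
  cc <- mk(c(20, 40, 60))
  out <- intersect_sdps(list(x = a, y = b, z = cc))
  expect_equal(out$resnums, intersect(intersect(c(10, 20, 30, 40),
                                                c(20, 40, 50)),
                                      c(20, 40, 60)))
  expect_lte(length(out$resnums), min(4, 3, 3))
  # identity and disjoint cases
  expect_equal(intersect_sdps(list(a, a))$resnums, c(10, 20, 30, 40))
  expect_length(intersect_sdps(list(a, mk(c(70, 80))))$resnums, 0)
})

test_that("induced subnetworks match a brute-force edge filter", {
  sdn <- structure(list(
    nodes = data.frame(col = 1:4, resnum = 1:4, cdp_z = 5,
                       mics = c(7, 5, 2, 1)),
    edges = data.frame(col_i = c(1L, 1L, 2L, 3L), col_j = c(2L, 3L, 4L, 4L),
                       z = c(10, 4, 6, 5)),
    mit = 3.29, sns = 1, z_min = 3.29, mics_denominator = "global",
    ensemble = NULL), class = "sdn")

  full <- subnetwork(sdn, sdn$nodes$col)
  expect_setequal(full$nodes$col, sdn$nodes$col)
  expect_equal(full$edges, sdn$edges)

  sub <- subnetwork(sdn, c(1L, 2L, 3L))
  keep <- sdn$edges$col_i %in% 1:3 & sdn$edges$col_j %in% 1:3
  expect_equal(nrow(sub$edges), sum(keep))
  expect_equal(sub$edges$z, sdn$edges$z[keep])
  # MICS recomputed within the view: N = 3, edges 1-2 (10) and 1-3 (4)
  expect_equal(sub$nodes$mics[sub$nodes$col == 1], 7)
  expect_equal(sub$nodes$mics[sub$nodes$col == 2], 5)

  two <- subnetwork(sdn, c(1L, 2L))
  expect_equal(nrow(two$edges), 1L)
  expect_equal(two$edges$z, 10)
})
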