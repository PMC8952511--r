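# Scrutiny filters: short sequences, unique inserts, long gaps, score
# outliers, repeats, catalytic residues, and the iterated driver.

ref300 <- function() {
  # reference of 300 residues plus sequences of controlled ungapped length
  ref <- strrep("A", 300)
  len_seq <- function(k) paste0(strrep("A", k), strrep("-", 300 - k))
  make_aln(c(ref, len_seq(194), len_seq(195), ref),
           c("ref", "short194", "edge195", "dup"))
}

test_that("the 65% length rule removes strictly-shorter sequences only", {
  a <- ref300()
  rm <- build_reference_map(a, "ref")
  res <- filter_short(a, rm)
  expect_equal(res$removed, "short194")          # 194 < 0.65 * 300 = 195
  expect_true(all(c("edge195", "dup", "ref") %in% rownames(res$alignment)))
})

test_that("unique inserts are removed at the run-length boundary", {
  base <- strrep("A", 40)
  ins15 <- paste0(strrep("A", 10), strrep("C", 15), strrep("A", 15))
  ins5 <- paste0(strrep("A", 10), strrep("C", 5), strrep("A", 25))
  wide <- function(s) paste0(s, strrep("-", 0))
  # 99 plain rows with gaps where the insert sits
  plain <- paste0(strrep("A", 10), strrep("-", 15), strrep("A", 15))
  a <- make_aln(c(rep(plain, 99), ins15), c(paste0("p", 1:99), "bad"))
  res <- filter_unique_inserts(a)
  expect_equal(res$removed, "bad")

  b <- make_aln(c(rep(paste0(strrep("A", 10), strrep("-", 5), strrep("A", 25)), 99), ins5),
                c(paste0("p", 1:99), "ok"))
  expect_length(filter_unique_inserts(b)$removed, 0)
})

test_that("long gaps count only inside highly occupied columns", {
  core <- strrep("A", 100)
  gappy <- paste0(strrep("A", 30), strrep("-", 40), strrep("A", 30))
  a <- make_aln(c(rep(core, 19), gappy), c(paste0("p", 1:19), "bad"))
  expect_equal(filter_long_gaps(a)$removed, "bad")   # occupancy 0.95

  # same gap inside columns occupied by only 30% of rows
  sparse <- paste0(strrep("A", 30), strrep("-", 40), strrep("A", 30))
  lowocc <- c(rep(sparse, 13), rep(core, 6), gappy)
  b <- make_aln(lowocc, c(paste0("p", 1:19), "kept"))
  expect_length(filter_long_gaps(b)$removed, 0)
})

test_that("score outliers are detected one-sidedly and converge", {
  set.seed(9)
  base <- sample(sdpnet:::AA20, 120, replace = TRUE)
  seqs <- replicate(50, {
    s <- base
    idx <- sample(120, 6)          # near-identical: 5% mutations
    s[idx] <- sample(sdpnet:::AA20, 6, replace = TRUE)
    paste(s, collapse = "")
  })
  shuffled <- paste(sample(base), collapse = "")
  a <- make_aln(c(seqs, shuffled), c(paste0("m", 1:50), "shuf"))
  res <- filter_score_outliers(a)
  expect_equal(res$removed, "shuf")
  # re-running on the cleaned alignment removes nothing further
  res2 <- filter_score_outliers(res$alignment)
  expect_length(res2$removed, 0)

  ident <- make_aln(rep("ACDEFG", 10), paste0("i", 1:10))
  expect_warning(res3 <- filter_score_outliers(ident), "MAD")
  expect_length(res3$removed, 0)
})

test_that("repeat flagging needs both a ceiling break and two windows", {
  gen <- sim_small()
  cor <- corrupt_alignment(gen$alignment, gen$truth, kinds = "tandem_repeat",
                           per_kind = 3, seed = 2)
  aln <- cor$alignment
  prof <- build_profile(aln)
  training <- rownames(gen$alignment)
  ceiling_score <- max(score_alignment(prof, sub_sequences(aln, training)))
  span <- n_cols(gen$alignment)
  fl <- flag_repeats(aln, prof, ceiling_score, window_cols = span)
  expect_setequal(fl, cor$truth$corrupted$id)
  # ordinary members and the reference are never flagged: their totals are
  # bounded by the ceiling definition
  expect_false(any(training %in% fl))
})

test_that("the catalytic rule implements 'lacks 180 and/or both 201/202'", {
  # positions 2, 4 and 5 stand in for reference residues 180, 201, 202
  cases <- expand.grid(p180 = c("D", "N"), p201 = c("D", "N"),
                       p202 = c("E", "N"), stringsAsFactors = FALSE)
  seqs <- apply(cases, 1, function(r) paste0("A", r[1], "G", r[2], r[3]))
  a <- make_aln(c("ADGDE", seqs), c("ref", paste0("c", seq_len(nrow(cases)))))
  rm <- build_reference_map(a, "ref")
  rules <- list(list(`2` = "D"), list(`4` = "D", `5` = c("D", "E")))
  res <- filter_catalytic(a, rm, rules)
  expected_removed <- cases$p180 != "D" | (cases$p201 != "D" & cases$p202 != "E")
  expect_setequal(res$removed, paste0("c", which(expected_removed)))
  # spot checks forced by the rule
  keep <- rownames(res$alignment)
  expect_true(paste0("c", which(cases$p180 == "D" & cases$p201 == "D" &
                                  cases$p202 == "E")) %in% keep)
  expect_error(filter_catalytic(a, rm, list(list(`99` = "D"))), "unmapped")
})

test_that("scrutinize reaches a fixed point, conserves ids and labels rules", {
  gen <- sim_small()
  rm <- build_reference_map(gen$alignment, "REF")
  clean <- scrutinize(gen$alignment, rm)
  expect_equal(nrow(clean$report), 0L)
  expect_identical(unclass(clean$alignment), unclass(gen$alignment))

  cor <- corrupt_alignment(gen$alignment, gen$truth,
                           kinds = c("truncate_to_half", "spurious_insert",
                                     "internal_deletion", "shuffle"),
                           per_kind = 3, seed = 4)
  rm2 <- build_reference_map(cor$alignment, "REF")
  sc <- scrutinize(cor$alignment, rm2)
  # conservation: removed + kept = input
  expect_equal(sort(c(sc$report$id, rownames(sc$alignment))),
               sort(rownames(cor$alignment)))
  # every planted corruption is removed, with its matching rule
  planted <- cor$truth$corrupted
  expect_true(all(planted$id %in% sc$report$id))
  rule_of <- c(truncate_to_half = "short", spurious_insert = "unique_insert",
               internal_deletion = "long_gap", shuffle = "score_outlier")
  got <- sc$report$rule[match(planted$id, sc$report$id)]
  expect_equal(got, unname(rule_of[planted$kind]))
  # rules i-iii never remove clean sequences
  false_rm <- setdiff(sc$report$id, planted$id)
  expect_false(any(sc$report$rule[match(false_rm, sc$report$id)] %in%
                     c("short", "unique_insert", "long_gap")))
  # idempotence on its own output
  rm3 <- build_reference_map(sc$alignment, "REF")
  again <- scrutinize(sc$alignment, rm3)
  expect_equal(nrow(again$report), 0L)
})
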