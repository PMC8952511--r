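# Alignment container, FASTA/Newick I/O and reference-anchored bookkeeping.

test_that("alignment construction enforces shape, ids and alphabet", {
  a <- make_aln(c("AC-D", "AC-D"))
  expect_s3_class(a, "aa_alignment")
  expect_equal(n_cols(a), 4L)
  expect_equal(n_seqs(a), 2L)

  expect_error(make_aln(c("ACDE", "ACDEF")), "unequal lengths")
  expect_error(make_aln(c("ACD", "ACD"), ids = c("x", "x")), "duplicate")

  b <- make_aln("ac.dBzU")
  expect_equal(unname(unclass(b)[1, ]), c("A", "C", "-", "D", "X", "X", "X"))
})

test_that("FASTA write/read round-trips arbitrary alignments exactly", {
  set.seed(42)
  for (i in 1:5) {
    a <- random_alignment(sample(2:8, 1), sample(3:40, 1))
    path <- withr::local_tempfile(fileext = ".fasta")
    write_fasta_alignment(a, path)
    b <- read_fasta_alignment(path)
    expect_identical(unclass(a), unclass(b))
  }
  expect_error(read_fasta_alignment(withr::local_tempfile()), "not found|format")
  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(), empty)
  expect_error(read_fasta_alignment(empty), "format")
})

test_that("column occupancy counts non-gap fractions and conserves residues", {
  a <- make_aln(c("A-", "C-", "D-", "-A"))
  occ <- column_occupancy(a)
  expect_equal(occ, c(0.75, 0.25))

  set.seed(1)
  a <- random_alignment(10, 30)
  expect_equal(sum(column_occupancy(a)) * n_seqs(a),
               sum(unclass(a) != "-"))
})

test_that("reference map is monotone, invertible and anchored at residues", {
  a <- make_aln(c("--AC-D", "AAAAAA"), c("ref", "x"))
  rm <- build_reference_map(a, "ref")
  expect_equal(rm$resnum_to_col, c(3L, 4L, 6L))
  expect_equal(rm$col_to_resnum[c(3, 4, 6)], 1:3)
  expect_true(all(is.na(rm$col_to_resnum[c(1, 2, 5)])))
  # inverse on its domain
  dom <- which(!is.na(rm$col_to_resnum))
  expect_equal(rm$resnum_to_col[rm$col_to_resnum[dom]], dom)
  expect_true(all(diff(rm$resnum_to_col) > 0))

  expect_error(build_reference_map(a, "missing"), "lookup")
  g <- make_aln(c("----", "ACDE"), c("ref", "x"))
  expect_error(build_reference_map(g, "ref"), "all-gap")
})

test_that("reference trimming keeps the covered span and is idempotent", {
  a <- make_aln(c("--AC-D--", "EEEEEEEE"), c("ref", "x"))
  rm <- build_reference_map(a, "ref")
  t1 <- trim_to_reference(a, rm)
  expect_equal(n_cols(t1), 4L)
  expect_equal(unname(unclass(t1)["ref", ]), c("A", "C", "-", "D"))

  rm1 <- build_reference_map(t1, "ref")
  expect_identical(unclass(trim_to_reference(t1, rm1)), unclass(t1))

  full <- make_aln(c("ACDE", "EEEE"), c("ref", "x"))
  expect_identical(unclass(trim_to_reference(full, build_reference_map(full, "ref"))),
                   unclass(full))
})

test_that("dropping reference gap columns yields the pseudo-MSA", {
  a <- make_aln(c("A-CD", "EFGH"), c("ref", "x"))
  rm <- build_reference_map(a, "ref")
  p <- drop_reference_gap_columns(a, rm)
  expect_equal(n_cols(p), 3L)
  expect_equal(n_seqs(p), 2L)
  # output column i corresponds to reference residue i
  for (i in seq_len(3)) {
    expect_equal(unclass(p)["ref", i],
                 unclass(a)["ref", rm$resnum_to_col[i]])
  }
  gapfree <- make_aln(c("ACD", "EFG"), c("ref", "x"))
  expect_identical(unclass(drop_reference_gap_columns(
    gapfree, build_reference_map(gapfree, "ref"))), unclass(gapfree))
})

test_that("newick reading recovers leaf sets, including degenerate trees", {
  p <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,(B:1,C:1):1);", p)
  tr <- read_newick(p)
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  expect_equal(tr$Nnode, 2L)

  writeLines("A;", p)
  tr1 <- read_newick(p)
  expect_equal(tr1$tip.label, "A")

  # independent extraction oracle on a generated tree
  gen <- sim_small()
  writeLines(ape::write.tree(gen$tree), p)
  tr2 <- read_newick(p)
  names_oracle <- regmatches(ape::write.tree(gen$tree),
                             gregexpr("[A-Za-z0-9_]+(?=:)", ape::write.tree(gen$tree),
                                      perl = TRUE))[[1]]
  names_oracle <- setdiff(names_oracle, character())
  expect_setequal(tr2$tip.label, intersect(names_oracle, rownames(gen$alignment)))
})
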