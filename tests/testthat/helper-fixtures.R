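# Shared fixtures and independent oracles. Oracles are deliberately naive and
# separate from the package's code paths.

make_aln <- function(seqs, ids = NULL) {
  if (is.null(ids)) ids <- paste0("s", seq_along(seqs))
  aa_alignment(seqs, ids)
}

random_alignment <- function(n_seqs, n_cols, gap_frac = 0.1) {
  chars <- c(sdpnet:::AA20, "-")
  probs <- c(rep((1 - gap_frac) / 20, 20), gap_frac)
  m <- matrix(sample(chars, n_seqs * n_cols, replace = TRUE, prob = probs),
              nrow = n_seqs)
  aa_alignment(m, paste0("r", seq_len(n_seqs)))
}

# Plug-in MI oracle via explicit joint tables (independent of the C++ path).
oracle_mi <- function(x, y) {
  joint <- table(x, y)
  p <- joint / sum(joint)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(px, py)[nz]))
}

# Independent brute-force evaluation of the MICS / SNS / MIT-scan contract:
# naive loops, no shared helpers with the package.
oracle_scan <- function(cdp_cols, edges, z_min = 3.29) {
  ce <- edges[edges$col_i %in% cdp_cols & edges$col_j %in% cdp_cols &
                edges$z > z_min, , drop = FALSE]
  if (nrow(ce) == 0L) return(list(mit = z_min, sns = 0, nodes = integer()))
  zmax <- max(ce$z)
  cands <- c(z_min, sort(unique(ce$z[ce$z > z_min & ce$z < zmax])))
  eval_at <- function(mit) {
    kept <- ce[ce$z > mit, , drop = FALSE]
    sums <- numeric(0)
    for (nd in cdp_cols) {
      s <- 0
      for (r in seq_len(nrow(kept))) {
        if (kept$col_i[r] == nd || kept$col_j[r] == nd) s <- s + kept$z[r]
      }
      if (s > 0) sums[as.character(nd)] <- s
    }
    N <- length(sums)
    if (N <= 1L) return(list(sns = 0, nodes = integer()))
    list(sns = mit * sum(sums / (N - 1)),
         nodes = sort(as.integer(names(sums))))
  }
  best <- NULL
  for (mit in cands) {
    ev <- eval_at(mit)
    if (is.null(best) || ev$sns > best$sns + 1e-9) {
      best <- list(mit = mit, sns = ev$sns, nodes = ev$nodes)
    }
  }
  best
}

random_cdp_graph <- function(n_nodes, edge_prob = 0.5) {
  cols <- sort(sample(1:50, n_nodes))
  pairs <- t(combn(cols, 2))
  keep <- runif(nrow(pairs)) < edge_prob
  pairs <- pairs[keep, , drop = FALSE]
  edges <- data.frame(col_i = pairs[, 1], col_j = pairs[, 2],
                      z = round(runif(nrow(pairs), 0, 12), 2))
  list(cols = cols, edges = edges)
}

# Small default-structure superfamily, cached per test run.
sim_default <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_superfamily(generator_config(seed = 7))
    cache
  }
})

sim_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_superfamily(generator_config(
        n_per_subfamily = 25L, n_cols = 120L, n_sdp = 8L,
        n_coevolving_pairs = 2L, n_catalytic = 3L, seed = 11L))
    }
    cache
  }
})
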