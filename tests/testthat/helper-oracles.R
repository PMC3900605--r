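# Independent oracles used to validate the fast implementations.
#
# These are deliberately written with different algorithms from the package
# code: full dynamic programs and exhaustive enumeration, correct by
# construction and feasible only at test sizes.

# Optimal ungapped local alignment score between two DNA strings under a
# match/mismatch scheme, by exhaustive Kadane scan over every diagonal of the
# full DP matrix (both strands of the target).
oracle_best_ungapped_nt <- function(query, target, match = 1, mismatch = -2) {
  best_one <- function(q, t) {
    qv <- strsplit(q, "", fixed = TRUE)[[1]]
    tv <- strsplit(t, "", fixed = TRUE)[[1]]
    m <- length(qv); n <- length(tv)
    best <- 0
    for (d in (-(m - 1)):(n - 1)) {
      qi <- max(1, 1 - d); ti <- qi + d
      len <- min(m - qi, n - ti) + 1
      if (len < 1) next
      sc <- ifelse(qv[qi:(qi + len - 1)] == tv[ti:(ti + len - 1)],
                   match, mismatch)
      # max subarray via running cumulative minimum
      cs <- cumsum(sc)
      best <- max(best, max(cs - cummin(c(0, cs[-len]))))
    }
    best
  }
  max(best_one(query, target), best_one(query, revcomp(target)))
}

# Exact MAST size by enumerating leaf subsets in decreasing size and checking
# topological identity of the induced subtrees.
oracle_mast_size <- function(tree_a, tree_b) {
  shared <- intersect(tree_a$tip.label, tree_b$tip.label)
  same_topology <- function(keep) {
    if (length(keep) <= 3) return(TRUE)
    ta <- ape::unroot(ape::keep.tip(tree_a, keep))
    tb <- ape::unroot(ape::keep.tip(tree_b, keep))
    ape::dist.topo(ta, tb) == 0
  }
  for (size in rev(seq_len(length(shared)))) {
    subsets <- utils::combn(shared, size, simplify = FALSE)
    for (keep in subsets) if (same_topology(keep)) return(size)
  }
  0L
}

# Small deterministic community used by several test files (built once).
test_community <- local({
  com <- NULL
  function() {
    if (is.null(com)) {
      cfg <- community_config(n_groups = 2, genomes_per_group = 3,
                              outgroup = TRUE, seed = 42)
      com <<- simulate_phage_community(cfg)
    }
    com
  }
})
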