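#' Size of the maximum agreement subtree of two unrooted trees
#'
#' The maximum agreement subtree (MAST) of two trees is the largest set of
#' leaves on which the two trees induce the same topology. Computed exactly by
#' dynamic programming over pairs of directed edges (the rooted-MAST recursion
#' applied to every rooting of both trees, sharing subproblems), which runs in
#' O(E1 * E2) table entries for binary trees. Trees are first restricted to
#' their shared leaves; polytomies are not supported and at most 64 shared
#' leaves are allowed.
#'
#' @param tree_a,tree_b `ape::phylo` trees sharing at least four leaf labels.
#' @return integer MAST size (number of leaves).
#' @seealso [icong()]
#' @export
mast_size <- function(tree_a, tree_b) {
  prep <- prepare_mast_pair(tree_a, tree_b)
  cpp_mast_size(prep$edge_a, prep$leaf_a, prep$edge_b, prep$leaf_b)
}

prepare_mast_pair <- function(tree_a, tree_b) {
  stopifnot(inherits(tree_a, "phylo"), inherits(tree_b, "phylo"))
  shared <- intersect(tree_a$tip.label, tree_b$tip.label)
  if (length(shared) < 4) {
    stop("trees share fewer than 4 leaves", call. = FALSE)
  }
  if (length(shared) > 64) {
    stop("more than 64 shared leaves is not supported", call. = FALSE)
  }
  ta <- ape::unroot(ape::keep.tip(tree_a, shared))
  tb <- ape::unroot(ape::keep.tip(tree_b, shared))
  if (!ape::is.binary(ta) || !ape::is.binary(tb)) {
    stop("MAST requires fully resolved (binary) trees; resolve polytomies ",
         "first, e.g. with ape::multi2di()", call. = FALSE)
  }
  shared <- sort(shared)
  list(
    edge_a = ta$edge, leaf_a = node_labels(ta, shared),
    edge_b = tb$edge, leaf_b = node_labels(tb, shared)
  )
}

# per-node label vector: shared-leaf index for tips, 0 for internal nodes
node_labels <- function(tree, shared) {
  c(match(tree$tip.label, shared), integer(tree$Nnode))
}

#' Congruence index between two trees
#'
#' The congruence index I_cong is the observed MAST size divided by the mean
#' MAST size of the observed topology pair's null distribution, obtained by
#' comparing `null_reps` pairs of random binary topologies (uniform
#' edge-addition model) on the same leaf set. The reported p-value is the
#' fraction of null MAST sizes at least as large as the observed one, with the
#' usual +1 correction. Values of I_cong well above 1 (with small p) indicate
#' that the two trees agree far beyond chance.
#'
#' @param tree_a,tree_b `ape::phylo` trees sharing at least four leaf labels.
#' @param null_reps number of null topology pairs (default 1000).
#' @param seed random seed for the null draws.
#' @return a `congruence_result` list: `mast` (observed size), `n_leaves`
#'   (shared), `icong`, `p_value`, `null_mean`, `null_sd`, `null_sizes`,
#'   `null_reps`.
#' @export
icong <- function(tree_a, tree_b, null_reps = 1000, seed = NULL) {
  stopifnot(null_reps >= 1)
  prep <- prepare_mast_pair(tree_a, tree_b)
  observed <- cpp_mast_size(prep$edge_a, prep$leaf_a, prep$edge_b, prep$leaf_b)
  n <- max(prep$leaf_a)
  labels <- sort(as.character(seq_len(n)))
  null_sizes <- with_seed(seed, vapply(seq_len(null_reps), function(i) {
    ra <- random_pda_tree(labels)
    rb <- random_pda_tree(labels)
    cpp_mast_size(ra$edge, node_labels(ra, labels),
                  rb$edge, node_labels(rb, labels))
  }, integer(1)))
  structure(
    list(
      mast = observed,
      n_leaves = n,
      icong = observed / mean(null_sizes),
      p_value = (1 + sum(null_sizes >= observed)) / (null_reps + 1),
      null_mean = mean(null_sizes),
      null_sd = stats::sd(null_sizes),
      null_sizes = null_sizes,
      null_reps = null_reps
    ),
    class = "congruence_result"
  )
}

#' @export
print.congruence_result <- function(x, ...) {
  cat("<congruence_result> MAST ", x$mast, "/", x$n_leaves,
      " leaves, I_cong = ", round(x$icong, 2),
      " (null mean ", round(x$null_mean, 2), ", p = ",
      format.pval(x$p_value, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' @export
glance.congruence_result <- function(x, ...) {
  tibble::tibble(mast = x$mast, n_leaves = x$n_leaves, icong = x$icong,
                 p_value = x$p_value, null_mean = x$null_mean,
                 null_sd = x$null_sd, null_reps = x$null_reps)
}
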