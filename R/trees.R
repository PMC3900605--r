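#' Neighbor-joining tree from a distance matrix
#'
#' Wraps the canonical neighbor-joining algorithm and post-processes negative
#' branch lengths, which NJ can produce when the input distances are not
#' additive: a negative branch is clamped to zero and its length transferred to
#' the adjacent branch of the same split (the standard fix that preserves
#' patristic distances between tips as far as possible).
#'
#' @param distance a symmetric `distance_matrix` (or square numeric matrix with
#'   dimnames and zero diagonal) over at least three taxa.
#' @return an unrooted `ape::phylo` tree.
#' @seealso [patristic_matrix()], [group_separation()]
#' @export
nj_tree <- function(distance) {
  stopifnot(is.matrix(distance), nrow(distance) == ncol(distance),
            nrow(distance) >= 3, !is.null(rownames(distance)))
  d <- unclass(distance)
  if (any(!is.finite(d))) stop("distance matrix has non-finite entries",
                               call. = FALSE)
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric",
                                      call. = FALSE)
  tree <- ape::nj(stats::as.dist(d))
  fix_negative_branches(tree)
}

# clamp negative branch lengths to zero, transferring the deficit to the
# sibling edge sharing the child node so tip-to-tip path lengths are preserved
# where possible
fix_negative_branches <- function(tree) {
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    len <- tree$edge.length[e]
    child <- tree$edge[e, 2]
    down <- which(tree$edge[, 1] == child)
    if (length(down)) tree$edge.length[down] <- tree$edge.length[down] + len
    tree$edge.length[e] <- 0
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Patristic (tree path-length) distances between all tips
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @return symmetric numeric matrix of tip-to-tip path lengths along the tree.
#' @export
patristic_matrix <- function(tree) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  ape::cophenetic.phylo(tree)
}

#' Do predefined groups separate on a tree?
#'
#' A pair of groups is called separated when every between-group patristic
#' distance exceeds every within-group distance of both groups; this is the
#' tree-metric analogue of "each group forms its own tight cluster". Reported
#' per group pair together with the within/between summaries.
#'
#' @param distances symmetric distance matrix with taxon dimnames (patristic
#'   or raw).
#' @param groups tibble with columns `genome`, `group`; taxa absent from
#'   `distances` are dropped with a warning.
#' @return a `group_separation` list with `pairs` (tibble: `group_a`,
#'   `group_b`, `between_min`, `between_mean`, `within_max_a`, `within_max_b`,
#'   `separated`), `within` (per-group tibble) and `all_separated`.
#' @export
group_separation <- function(distances, groups) {
  stopifnot(is.matrix(distances), !is.null(rownames(distances)))
  groups <- tibble::as_tibble(groups)
  stopifnot(all(c("genome", "group") %in% names(groups)))
  missing <- setdiff(groups$genome, rownames(distances))
  if (length(missing)) {
    warning("dropping taxa absent from the distance matrix: ",
            paste(missing, collapse = ", "), call. = FALSE)
    groups <- dplyr::filter(groups, !.data$genome %in% missing)
  }
  split_g <- split(groups$genome, groups$group)

  within_tbl <- purrr::imap(split_g, function(members, g) {
    if (length(members) < 2) {
      return(tibble::tibble(group = g, n = length(members),
                            within_max = NA_real_, within_mean = NA_real_))
    }
    d <- distances[members, members]
    vals <- d[upper.tri(d)]
    tibble::tibble(group = g, n = length(members),
                   within_max = max(vals), within_mean = mean(vals))
  }) |>
    dplyr::bind_rows()

  gnames <- names(split_g)
  pairs <- if (length(gnames) >= 2) {
    cmb <- utils::combn(gnames, 2)
    purrr::map(seq_len(ncol(cmb)), function(k) {
      ga <- cmb[1, k]; gb <- cmb[2, k]
      between <- distances[split_g[[ga]], split_g[[gb]], drop = FALSE]
      wa <- within_tbl$within_max[within_tbl$group == ga]
      wb <- within_tbl$within_max[within_tbl$group == gb]
      # singleton groups have no within distances; only the other side binds
      wmax <- max(c(wa, wb), na.rm = TRUE)
      tibble::tibble(
        group_a = ga, group_b = gb,
        between_min = min(between), between_mean = mean(between),
        within_max_a = wa, within_max_b = wb,
        separated = is.finite(wmax) && min(between) > wmax ||
          !is.finite(wmax)
      )
    }) |>
      dplyr::bind_rows()
  } else {
    tibble::tibble(group_a = character(), group_b = character(),
                   between_min = numeric(), between_mean = numeric(),
                   within_max_a = numeric(), within_max_b = numeric(),
                   separated = logical())
  }

  structure(list(pairs = pairs, within = within_tbl,
                 all_separated = all(pairs$separated)),
            class = "group_separation")
}

#' @export
print.group_separation <- function(x, ...) {
  cat("<group_separation> ", nrow(x$within), " groups, ",
      sum(x$pairs$separated), "/", nrow(x$pairs),
      " pairs separated\n", sep = "")
  print(x$pairs)
  invisible(x)
}

#' @export
tidy.group_separation <- function(x, ...) x$pairs

#' @export
glance.group_separation <- function(x, ...) {
  tibble::tibble(n_groups = nrow(x$within),
                 n_pairs = nrow(x$pairs),
                 n_separated = sum(x$pairs$separated),
                 all_separated = x$all_separated)
}

#' Random binary tree topology under the uniform addition (PDA) model
#'
#' Grows a tree by attaching each successive leaf to an edge chosen uniformly
#' at random among the current edges, which yields the proportional-to-
#' distinguishable-arrangements distribution over binary topologies. Used as
#' the null model for tree-congruence testing. Branch lengths are set to 1.
#'
#' @param labels tip labels (at least 3).
#' @param seed random seed.
#' @return an unrooted binary `ape::phylo`.
#' @export
random_pda_tree <- function(labels, seed = NULL) {
  stopifnot(length(labels) >= 3, !anyDuplicated(labels))
  with_seed(seed, {
    tree <- ape::rtopology(length(labels), rooted = FALSE,
                           tip.label = sample(labels))
    tree$edge.length <- rep(1, nrow(tree$edge))
    tree
  })
}
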