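#' Similarity network with attraction weights from HSP P-values
#'
#' All-against-all nucleotide HSP search over a genome set; a pair of genomes
#' is connected when the best HSP of either direction has an E-value at or
#' below `e_ceiling`. The edge P-value is the smaller of the two directions'
#' best-HSP P-values, and the attraction weight maps it onto `(0, 1]` as
#' `min(1, -log10(p) / 200)` with p floored at 1e-200, so identical genomes
#' attract with weight 1 and marginal pairs barely at all.
#'
#' @param genomes named character vector of at least three genome sequences,
#'   or a `phage_community`.
#' @param e_ceiling E-value cut-off for keeping an edge (1e-5 for close
#'   relatives; 1e-2 casts a wider net across a family).
#' @param params nucleotide engine overrides (see [local_hsps()]).
#' @return an `attraction_graph`: list with `nodes` (genome ids), `edges`
#'   (tibble `from`, `to`, `log10_p`, `p_value`, `attraction`) and
#'   `e_ceiling`. A graph with no edges is returned with a warning.
#' @seealso [extract_clusters()], [layout_fr()]
#' @export
build_attraction_graph <- function(genomes, e_ceiling = 1e-5,
                                   params = list()) {
  if (inherits(genomes, "phage_community")) genomes <- genomes$genomes
  stopifnot(is.character(genomes), length(genomes) >= 3,
            !is.null(names(genomes)))
  ids <- names(genomes)
  pairs <- utils::combn(seq_along(ids), 2)
  edges <- purrr::map(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    lp <- c(best_hit_log10p(genomes[[i]], genomes[[j]], e_ceiling, params),
            best_hit_log10p(genomes[[j]], genomes[[i]], e_ceiling, params))
    if (is.null(lp)) return(NULL)
    l10p <- max(min(lp), -200)                     # floor at 1e-200
    tibble::tibble(from = ids[i], to = ids[j], log10_p = l10p,
                   p_value = 10^l10p,
                   attraction = pmin(1, -l10p / 200))
  }) |>
    dplyr::bind_rows()
  if (nrow(edges) == 0) {
    warning("no edges at e_ceiling = ", e_ceiling,
            "; all nodes are isolated", call. = FALSE)
    edges <- tibble::tibble(from = character(), to = character(),
                            log10_p = numeric(), p_value = numeric(),
                            attraction = numeric())
  }
  structure(list(nodes = ids, edges = edges, e_ceiling = e_ceiling),
            class = "attraction_graph")
}

#' @export
print.attraction_graph <- function(x, ...) {
  cat("<attraction_graph> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges (e-value ceiling ", format(x$e_ceiling), ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.attraction_graph <- function(x, ...) x$edges

#' Extract genome clusters from the attraction graph
#'
#' Clusters are the connected components of the subgraph of edges with
#' P-value at or below `p_cutoff`; nodes of degree zero at that cutoff are
#' flagged as singletons. Reading groups off the thresholded network (rather
#' than off layout coordinates) makes the assignment independent of the
#' stochastic embedding.
#'
#' @param graph an `attraction_graph`.
#' @param p_cutoff maximum edge P-value retained (default 1: every edge that
#'   survived the build-time E-value ceiling).
#' @return a `group_assignment` tibble: `node`, `cluster`, `singleton`.
#' @export
extract_clusters <- function(graph, p_cutoff = 1) {
  stopifnot(inherits(graph, "attraction_graph"))
  edges <- dplyr::filter(graph$edges, .data$log10_p <= log10(p_cutoff))
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = graph$nodes)
  )
  comp <- igraph::components(g)
  memb <- comp$membership[graph$nodes]
  out <- tibble::tibble(
    node = graph$nodes,
    cluster = sprintf("C%d", unname(memb)),
    singleton = comp$csize[memb] == 1
  )
  class(out) <- c("group_assignment", class(out))
  out
}

#' Force-directed layout of the attraction graph
#'
#' A standard Fruchterman-Reingold iteration: every pair of nodes repels with
#' force `k^2 / d`, every edge attracts with force `attraction * d^2 / k`
#' (`k` the ideal spring length `sqrt(1/n)`), displacements are capped by a
#' linearly cooling temperature, and initial positions are uniform random from
#' the seed. The per-iteration layout energy (repulsive potential plus
#' attractive potential) is recorded so the cooling behaviour can be audited.
#'
#' @param graph an `attraction_graph`.
#' @param dims 2 or 3 embedding dimensions.
#' @param iterations layout rounds (default 10000).
#' @param seed random seed; same graph and seed give identical coordinates.
#' @return an `fr_layout` tibble (`node`, `x`, `y` and `z` for 3-D) with the
#'   energy
#'   trace, seed and iteration count as attributes.
#' @export
layout_fr <- function(graph, dims = 2, iterations = 10000, seed = NULL) {
  stopifnot(inherits(graph, "attraction_graph"), dims %in% c(2, 3),
            iterations >= 1)
  n <- length(graph$nodes)
  ei <- match(graph$edges$from, graph$nodes)
  ej <- match(graph$edges$to, graph$nodes)
  w <- graph$edges$attraction
  k <- sqrt(1 / max(n, 1))
  pos <- with_seed(seed, matrix(stats::runif(n * dims, -0.5, 0.5), n, dims))
  t0 <- 0.1
  energy <- numeric(iterations)
  eps <- 1e-9
  for (it in seq_len(iterations)) {
    disp <- matrix(0, n, dims)
    if (n > 1) {
      # repulsion between all pairs
      d2 <- matrix(0, n, n)
      for (dim in seq_len(dims)) d2 <- d2 + outer(pos[, dim], pos[, dim], "-")^2
      dist <- sqrt(d2) + eps
      diag(dist) <- Inf
      rep_f <- k^2 / dist^2              # force / distance (for vector scaling)
      for (dim in seq_len(dims)) {
        delta <- outer(pos[, dim], pos[, dim], "-")
        disp[, dim] <- disp[, dim] + rowSums(rep_f * delta)
      }
      energy[it] <- -k^2 * sum(log(dist[upper.tri(dist)]))
    }
    if (length(ei)) {
      dvec <- pos[ei, , drop = FALSE] - pos[ej, , drop = FALSE]
      dl <- sqrt(rowSums(dvec^2)) + eps
      att <- w * dl / k                  # force / distance
      for (dim in seq_len(dims)) {
        f <- att * dvec[, dim]
        disp[, dim] <- disp[, dim] - tapply_add(f, ei, n) + tapply_add(f, ej, n)
      }
      energy[it] <- energy[it] + sum(w * dl^3) / (3 * k)
    }
    temp <- t0 * (1 - (it - 1) / iterations)
    dl <- sqrt(rowSums(disp^2)) + eps
    step <- pmin(dl, temp) / dl
    pos <- pos + disp * step
  }
  out <- tibble::as_tibble(as.data.frame(pos)) |>
    stats::setNames(c("x", "y", "z")[seq_len(dims)]) |>
    dplyr::mutate(node = graph$nodes, .before = 1)
  attr(out, "seed") <- seed
  attr(out, "iterations") <- iterations
  attr(out, "energy") <- energy
  class(out) <- c("fr_layout", class(out))
  out
}

tapply_add <- function(values, index, n) {
  out <- numeric(n)
  agg <- tapply(values, index, sum)
  out[as.integer(names(agg))] <- agg
  out
}
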