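#' End-to-end comparative genomics pipeline
#'
#' Runs the full comparative workflow on a set of genomes: fragmented
#' translated similarity, symmetric distance, neighbor-joining tree, patristic
#' distances, attraction network with force-directed layout, connected-
#' component clusters, and (when groups are supplied) group separation on the
#' patristic distances. With `marker_trees`, every pair of marker trees plus
#' every marker-against-genome-tree pair is scored with the congruence index.
#'
#' @param genomes named character vector of genome sequences, or a
#'   `phage_community` (whose group table is then used automatically).
#' @param groups optional tibble (`genome`, `group`) for separation testing.
#' @param marker_trees optional named list of `ape::phylo` trees for
#'   congruence testing against each other and the genome tree.
#' @param similarity_params,graph_params named lists forwarded to
#'   [fragmented_similarity()] and [build_attraction_graph()].
#' @param layout_iterations rounds for [layout_fr()] (default 10000).
#' @param congruence_reps null replicates per congruence test (default 1000).
#' @param seed random seed governing the layout and the congruence nulls.
#' @param out_dir optional directory; when given, all result tables and trees
#'   are written there (TSV, Newick, PHYLIP, JSON) together with a
#'   `provenance.json` listing each file's MD5 checksum, and reruns with the
#'   same inputs are byte-identical.
#' @return a `pipeline_result` list: `similarity`, `distance`, `tree`,
#'   `patristic`, `graph`, `layout`, `clusters`, `separation` (or NULL),
#'   `congruence` (tibble or NULL), `n_genomes`, `notices` (character).
#' @export
run_pipeline <- function(genomes, groups = NULL, marker_trees = NULL,
                         similarity_params = list(), graph_params = list(),
                         layout_iterations = 10000, congruence_reps = 1000,
                         seed = NULL, out_dir = NULL) {
  if (inherits(genomes, "phage_community")) {
    if (is.null(groups)) groups <- genomes$groups
    genomes <- genomes$genomes
  }
  stopifnot(is.character(genomes), !is.null(names(genomes)),
            length(genomes) >= 2)
  notices <- character()

  sim <- do.call(fragmented_similarity, c(list(genomes), similarity_params))
  dist <- to_distance(sim)

  tree <- graph <- layout <- clusters <- separation <- patristic <- NULL
  if (length(genomes) >= 3) {
    tree <- nj_tree(dist)
    patristic <- patristic_matrix(tree)
    graph <- do.call(build_attraction_graph, c(list(genomes), graph_params))
    layout <- layout_fr(graph, iterations = layout_iterations, seed = seed)
    clusters <- extract_clusters(graph)
    if (!is.null(groups)) separation <- group_separation(patristic, groups)
  } else {
    notices <- c(notices,
                 "fewer than 3 genomes: tree, network and clustering skipped")
    message(notices[length(notices)])
  }

  congruence <- NULL
  trees <- marker_trees
  if (!is.null(tree) && length(trees)) trees <- c(trees, list(genome = tree))
  if (length(trees) >= 2) {
    cmb <- utils::combn(names(trees), 2)
    congruence <- purrr::map(seq_len(ncol(cmb)), function(k) {
      a <- cmb[1, k]; b <- cmb[2, k]
      fit <- icong(trees[[a]], trees[[b]], null_reps = congruence_reps,
                   seed = if (is.null(seed)) NULL else seed + k)
      dplyr::mutate(glance(fit), tree_a = a, tree_b = b, .before = 1)
    }) |>
      dplyr::bind_rows()
  }

  result <- structure(
    list(similarity = sim, distance = dist, tree = tree,
         patristic = patristic, graph = graph, layout = layout,
         clusters = clusters, separation = separation,
         congruence = congruence, n_genomes = length(genomes),
         notices = notices),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_results(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", x$n_genomes, " genomes\n", sep = "")
  if (!is.null(x$clusters)) {
    cat("  clusters: ", length(unique(x$clusters$cluster)), " (",
        sum(x$clusters$singleton), " singletons)\n", sep = "")
  }
  if (!is.null(x$separation)) {
    cat("  group separation: ", sum(x$separation$pairs$separated), "/",
        nrow(x$separation$pairs), " pairs\n", sep = "")
  }
  if (!is.null(x$congruence)) {
    cat("  congruence tests: ", nrow(x$congruence), "\n", sep = "")
  }
  for (n in x$notices) cat("  note: ", n, "\n", sep = "")
  invisible(x)
}

write_pipeline_results <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(out_dir, f)
  written <- character()
  put_tsv <- function(tbl, f) {
    write_tsv_table(tbl, path(f)); written <<- c(written, f)
  }

  put_tsv(tidy(result$similarity), "similarity.tsv")
  write_phylip_distance(unclass(result$distance), path("distance.phy"))
  written <- c(written, "distance.phy")
  if (!is.null(result$tree)) {
    ape::write.tree(result$tree, path("tree.nwk"))
    written <- c(written, "tree.nwk")
  }
  if (!is.null(result$graph)) put_tsv(result$graph$edges, "network_edges.tsv")
  if (!is.null(result$layout)) {
    put_tsv(tibble::as_tibble(result$layout), "layout.tsv")
  }
  if (!is.null(result$clusters)) put_tsv(result$clusters, "clusters.tsv")
  if (!is.null(result$separation)) {
    put_tsv(result$separation$pairs, "group_separation.tsv")
  }
  if (!is.null(result$congruence)) put_tsv(result$congruence, "congruence.tsv")

  prov <- list(
    package = "phagephylo",
    version = as.character(utils::packageVersion("phagephylo")),
    n_genomes = result$n_genomes,
    files = lapply(stats::setNames(nm = sort(written)), function(f) {
      list(md5 = unname(tools::md5sum(path(f))))
    })
  )
  jsonlite::write_json(prov, path("provenance.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(out_dir)
}
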