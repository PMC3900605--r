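#' Configuration for a synthetic phage genome community
#'
#' Describes a community of modular phage genomes organised into groups that
#' mirror how related spounavirus-like phages are structured: conserved,
#' syntenic core modules (packaging, head, tail, replication) shared by all
#' genomes of a group, interleaved with mosaic accessory regions that turn over
#' rapidly, plus an optional unrelated outgroup singleton. Within-group
#' divergence is strictly smaller than between-group divergence, which is what
#' downstream clustering and tree building are expected to recover.
#'
#' @param n_groups number of related genome groups.
#' @param genomes_per_group genomes simulated per group.
#' @param module_plan a data frame with columns `module` (label), `length`
#'   (bp, each at least 300) and `core` (logical; core modules keep exact
#'   synteny, accessory modules are subject to turnover). The default plan has
#'   four core modules (P, H, T, R) of 1.2-1.8 kb and two 900 bp accessory
#'   slots, giving roughly 8 kb genomes - a scaled-down but structurally
#'   faithful rendition of a modular myovirus genome.
#' @param within_rate substitutions per site separating a group member from its
#'   group ancestor.
#' @param between_rate substitutions per site separating each group ancestor
#'   from the community root; must exceed `within_rate`.
#' @param accessory_turnover probability that an accessory module of a genome
#'   is replaced wholesale by unrelated random sequence.
#' @param outgroup add one unrelated singleton genome?
#' @param seed random seed (fixing it makes the output byte-identical).
#'
#' @return a `community_config` list.
#' @seealso [simulate_phage_community()]
#' @export
community_config <- function(n_groups = 3,
                             genomes_per_group = 4,
                             module_plan = default_module_plan(),
                             within_rate = 0.05,
                             between_rate = 0.45,
                             accessory_turnover = 0.3,
                             outgroup = TRUE,
                             seed = NULL) {
  module_plan <- tibble::as_tibble(module_plan)
  stopifnot(
    all(c("module", "length", "core") %in% names(module_plan)),
    n_groups >= 1, genomes_per_group >= 1,
    within_rate >= 0, accessory_turnover >= 0, accessory_turnover <= 1
  )
  if (any(module_plan$length < 300)) {
    stop("all module lengths must be at least 300 bp", call. = FALSE)
  }
  if (between_rate <= within_rate) {
    stop("between_rate must exceed within_rate", call. = FALSE)
  }
  structure(
    list(n_groups = n_groups, genomes_per_group = genomes_per_group,
         module_plan = module_plan, within_rate = within_rate,
         between_rate = between_rate, accessory_turnover = accessory_turnover,
         outgroup = outgroup, seed = seed),
    class = "community_config"
  )
}

#' @rdname community_config
#' @export
default_module_plan <- function() {
  tibble::tibble(
    module = c("P", "A1", "H", "T", "A2", "R"),
    length = c(1200L, 900L, 1800L, 1800L, 900L, 1500L),
    core   = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE)
  )
}

#' Simulate a community of modular phage genomes with known group structure
#'
#' Draws one community root genome (core modules with coding-like codon
#' structure, accessory modules uniform random), derives each group's ancestor
#' from the root at `between_rate` substitutions per site, then derives group
#' members from their ancestor at `within_rate`. Accessory modules are replaced
#' by fresh random sequence with probability `accessory_turnover` per genome.
#' Core module order is identical in every in-group genome (no indels), so the
#' synteny of the core is exact by construction. The optional outgroup genome
#' shares no ancestry with the rest.
#'
#' @param config a [community_config()].
#' @return a `phage_community` list with elements
#'   * `genomes`: named character vector of genome sequences,
#'   * `groups`: tibble with columns `genome`, `group` (ground truth),
#'   * `tree`: the generating tree (`phylo`) whose branch lengths are the
#'     configured substitution rates; usable with [simulate_marker_families()],
#'   * `config`: the configuration used.
#' @examples
#' com <- simulate_phage_community(community_config(
#'   n_groups = 2, genomes_per_group = 2, seed = 1))
#' names(com$genomes)
#' @export
simulate_phage_community <- function(config = community_config()) {
  stopifnot(inherits(config, "community_config"))
  with_seed(config$seed, {
    plan <- config$module_plan
    draw_root_module <- function(len, core) {
      if (core) rand_coding_dna(len) else rand_dna(len)
    }
    root <- purrr::map2_chr(plan$length, plan$core, draw_root_module)

    genomes <- list()
    groups <- list()
    for (g in seq_len(config$n_groups)) {
      ancestor <- vapply(root, mutate_seq, character(1),
                         rate = config$between_rate)
      for (m in seq_len(config$genomes_per_group)) {
        mods <- vapply(ancestor, mutate_seq, character(1),
                       rate = config$within_rate)
        turn <- !plan$core &
          stats::runif(nrow(plan)) < config$accessory_turnover
        if (any(turn)) {
          mods[turn] <- vapply(plan$length[turn], rand_dna, character(1))
        }
        id <- sprintf("G%d_%d", g, m)
        genomes[[id]] <- paste(mods, collapse = "")
        groups[[id]] <- sprintf("group_%d", g)
      }
    }
    if (config$outgroup) {
      genomes[["OUT"]] <- rand_dna(sum(plan$length))
      groups[["OUT"]] <- "outgroup"
    }

    out <- structure(
      list(
        genomes = unlist(genomes),
        groups = tibble::tibble(genome = names(groups),
                                group = unlist(unname(groups))),
        tree = community_tree(config),
        config = config
      ),
      class = "phage_community"
    )
    out
  })
}

# generating tree: groups are rakes hanging off the root; branch lengths are
# the configured per-site rates, with the outgroup on a long terminal branch
community_tree <- function(config) {
  grp <- function(g) {
    tips <- sprintf("G%d_%d:%g", g, seq_len(config$genomes_per_group),
                    config$within_rate)
    if (config$genomes_per_group == 1) {
      sprintf("G%d_1:%g", g, config$within_rate + config$between_rate)
    } else {
      sprintf("(%s):%g", paste(tips, collapse = ","), config$between_rate)
    }
  }
  parts <- vapply(seq_len(config$n_groups), grp, character(1))
  if (config$outgroup) {
    parts <- c(parts, sprintf("OUT:%g", 3 * config$between_rate))
  }
  ape::read.tree(text = paste0("(", paste(parts, collapse = ","), ");"))
}

#' @export
print.phage_community <- function(x, ...) {
  cat("<phage_community> ", length(x$genomes), " genomes, ",
      length(unique(x$groups$group)), " groups\n", sep = "")
  cat("  genome length: ", nchar(x$genomes[[1]]), " bp\n", sep = "")
  invisible(x)
}
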