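#' Fragmented whole-genome translated similarity matrix
#'
#' Whole-genome similarity in the style of fragmented translated comparison:
#' each genome is cut into overlapping fragments (default 50 bp at a step of
#' 25 bp), every fragment is scored against every other genome with the
#' translated HSP engine, and the similarity of genome A against genome B is
#'
#' \deqn{S_{AB} = 100 \times \frac{\sum_i \min(best_i(B), self_i)}{\sum_i self_i}}
#'
#' where `best_i(B)` is the best significant HSP raw score of fragment i
#' against B and `self_i` the best HSP score of fragment i against its own
#' genome of origin, so the diagonal is exactly 100 (the cap prevents
#' repeated matches from pushing similarity above 100). The matrix is
#' deliberately asymmetric: genomes of different sizes and variable content
#' score each other differently, because similarity is a fraction of *each*
#' genome's own fragments. Fragments shorter than 9 bp (under one codon of
#' context) are skipped with a notice, and fragments whose self-score cannot
#' reach the significance threshold are excluded from the normalisation.
#'
#' @param genomes named character vector of at least two genome sequences, or
#'   a `phage_community`.
#' @param fragment_size fragment length in bp (default 50).
#' @param step tiling step in bp (default 25; must not exceed
#'   `fragment_size`).
#' @param e_ceiling per-fragment E-value ceiling for a hit to count
#'   (default 1e-2).
#' @param xdrop,lambda,K translated engine parameters (see [local_hsps()]).
#' @return a `similarity_matrix`: an N x N numeric matrix of percent
#'   similarities in `[0, 100]` with a diagonal of 100, genome ids as
#'   dimnames, and the tiling parameters as attributes.
#' @seealso [to_distance()], [local_hsps()]
#' @export
fragmented_similarity <- function(genomes, fragment_size = 50, step = 25,
                                  e_ceiling = 1e-2, xdrop = 20,
                                  lambda = 0.3176, K = 0.134) {
  if (inherits(genomes, "phage_community")) genomes <- genomes$genomes
  stopifnot(is.character(genomes), length(genomes) >= 2,
            !is.null(names(genomes)), fragment_size >= step, step >= 1)
  ids <- names(genomes)
  n <- length(genomes)

  frags <- purrr::map(genomes, tile_fragments,
                      fragment_size = fragment_size, step = step)
  # self score of a fragment = the best the engine itself achieves for the
  # fragment against its genome of origin; normalising by this makes the
  # diagonal exactly 100 and keeps the cap consistent with the scorer
  selfs <- purrr::map2(frags, genomes, function(f, g) {
    cpp_fragment_best_scores(f, g, xdrop, 0)
  })

  values <- matrix(0, n, n, dimnames = list(ids, ids))
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      tlen <- nchar(genomes[[b]])
      # minimum raw score for E <= e_ceiling at this target size
      s_min <- (log(K * (fragment_size / 3) * (tlen / 3)) - log(e_ceiling)) /
        lambda
      usable <- selfs[[a]] >= s_min
      if (!any(usable)) { values[a, b] <- 0; next }
      best <- cpp_fragment_best_scores(frags[[a]][usable], genomes[[b]],
                                       xdrop, s_min)
      values[a, b] <- 100 * sum(pmin(best, selfs[[a]][usable])) /
        sum(selfs[[a]][usable])
    }
  }
  structure(values, class = c("similarity_matrix", "matrix", "array"),
            fragment_size = fragment_size, step = step,
            e_ceiling = e_ceiling)
}

tile_fragments <- function(genome, fragment_size, step) {
  len <- nchar(genome)
  starts <- seq(1, len, by = step)
  frags <- substr(rep(genome, length(starts)), starts,
                  pmin(starts + fragment_size - 1, len))
  short <- nchar(frags) < 9
  if (any(short)) {
    message(sum(short), " fragment(s) shorter than 9 bp skipped")
    frags <- frags[!short]
  }
  frags
}

#' Symmetric distance matrix from an asymmetric similarity matrix
#'
#' Averages the two directions of the percent-similarity matrix and converts
#' to a distance: `d(A, B) = 100 - (S_AB + S_BA) / 2`, with a forced zero
#' diagonal. This is the input for neighbor-joining tree building, where the
#' scale is percent dissimilarity in average translated score.
#'
#' @param matrix a `similarity_matrix` (or any square matrix with dimnames).
#' @return a symmetric `distance_matrix` with zero diagonal.
#' @export
to_distance <- function(matrix) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  d <- 100 - (matrix + t(matrix)) / 2
  diag(d) <- 0
  structure(unclass(d), class = c("distance_matrix", "matrix", "array"))
}

#' @export
tidy.similarity_matrix <- function(x, ...) {
  tibble::as_tibble(as.table(unclass(x)), .name_repair = "minimal") |>
    stats::setNames(c("query", "target", "similarity")) |>
    tibble::as_tibble()
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("<similarity_matrix> ", nrow(x), " genomes (fragment ",
      attr(x, "fragment_size"), " bp / step ", attr(x, "step"), " bp)\n",
      sep = "")
  print(round(unclass(x), 1))
  invisible(x)
}
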