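#' Simulate a collapsed assembly of a genome with long terminal repeats
#'
#' Linear phage genomes that carry identical long terminal repeats (LTRs)
#' assemble into an apparently circular sequence in which the two repeat copies
#' collapse onto one, doubling the read depth over the collapsed segment. This
#' generator builds such a linear genome, samples uniform shotgun reads from
#' it, maps them onto the collapsed circular representation and returns the
#' per-position depth profile together with the ground truth.
#'
#' Under uniform read sampling the expected in-repeat/out-of-repeat depth ratio
#' is 2 (every collapsed position receives reads from both repeat copies),
#' apart from a one-read-length ramp at the downstream repeat boundary.
#'
#' @param genome_length length of the linear genome in bp (repeat included
#'   twice); must exceed twice `ltr_length`.
#' @param ltr_length length of the terminal repeat in bp.
#' @param n_reads number of uniformly placed reads.
#' @param read_length read length in bp; must be smaller than `ltr_length`,
#'   otherwise reads could not be placed unambiguously within the repeat.
#' @param seed random seed.
#'
#' @return a `collapsed_assembly` list with elements `sequence` (the collapsed
#'   circular sequence, one repeat copy), `coverage` (tibble `pos`, `depth`
#'   over the collapsed sequence) and `truth` (repeat coordinates on the
#'   collapsed sequence, 1-based inclusive, plus the simulation parameters).
#' @examples
#' asm <- simulate_collapsed_assembly(30000, 2000, 2000, 400, seed = 1)
#' asm$truth$ltr_length
#' @export
simulate_collapsed_assembly <- function(genome_length, ltr_length, n_reads,
                                        read_length, seed = NULL) {
  stopifnot(genome_length > 0, ltr_length > 0, n_reads >= 0, read_length > 0)
  if (ltr_length >= genome_length / 2) {
    stop("ltr_length must be smaller than genome_length / 2", call. = FALSE)
  }
  if (read_length >= ltr_length) {
    stop("read_length must be smaller than ltr_length (reads spanning a full ",
         "repeat copy would map ambiguously)", call. = FALSE)
  }
  with_seed(seed, {
    unique_len <- genome_length - ltr_length
    collapsed <- rand_dna(unique_len)

    depth <- integer(unique_len)
    if (n_reads > 0) {
      starts <- sample.int(genome_length - read_length + 1L, n_reads,
                           replace = TRUE)
      s0 <- ((starts - 1L) %% unique_len) + 1L          # collapsed, circular
      e0 <- s0 + read_length - 1L
      # difference-array accumulation over the circle
      bump <- integer(unique_len + 1L)
      wrap <- e0 > unique_len
      add <- function(i, v) tabulate(i, nbins = unique_len + 1L) * v
      bump <- bump + add(s0, 1L) - add(pmin(e0, unique_len) + 1L, 1L)
      if (any(wrap)) {
        ew <- e0[wrap] - unique_len
        bump <- bump + add(rep(1L, sum(wrap)), 1L) - add(ew + 1L, 1L)
      }
      depth <- cumsum(bump[seq_len(unique_len)])
    }

    structure(
      list(
        sequence = collapsed,
        coverage = tibble::tibble(pos = seq_len(unique_len), depth = depth),
        truth = list(ltr_start = 1L, ltr_end = as.integer(ltr_length),
                     ltr_length = as.integer(ltr_length),
                     genome_length = as.integer(genome_length),
                     unique_length = as.integer(unique_len),
                     read_length = as.integer(read_length),
                     n_reads = as.integer(n_reads))
      ),
      class = "collapsed_assembly"
    )
  })
}

#' @export
print.collapsed_assembly <- function(x, ...) {
  cat("<collapsed_assembly> ", x$truth$unique_length, " bp collapsed (",
      x$truth$genome_length, " bp linear, ", x$truth$ltr_length,
      " bp terminal repeat), mean depth ",
      round(mean(x$coverage$depth), 1), "x\n", sep = "")
  invisible(x)
}
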