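#' Consensus CDS calls by voting across predictor tracks
#'
#' Gene callers agree well on the stop codon (and hence the reading frame) of a
#' coding sequence but disagree frequently on its start. Predictions from all
#' tracks are therefore grouped by `(strand, stop anchor)`, where the stop
#' anchor is the genomic coordinate of the stop codon's last base on the coding
#' strand (`end` on `+`, `start` on `-`). A group supported by at least
#' `min_support` distinct tracks yields one consensus feature whose start is
#' the most frequent 5' end among the group's members, ties broken in favour of
#' the longest CDS. Overlapping same-strand predictions with different stop
#' anchors remain distinct candidates; nothing is merged.
#'
#' @param tracks list of feature tibbles with columns `start`, `end`, `strand`
#'   (one per prediction tool).
#' @param min_support minimum number of distinct tracks that must contain a
#'   candidate (default 3).
#' @return a tibble of consensus features: `start`, `end`, `strand`,
#'   `stop_anchor`, `support`, sorted by `start`.
#' @examples
#' trk <- list(
#'   tibble::tibble(start = 1, end = 300, strand = "+"),
#'   tibble::tibble(start = 10, end = 300, strand = "+"),
#'   tibble::tibble(start = 1, end = 300, strand = "+")
#' )
#' consensus_cds(trk, min_support = 3)
#' @export
consensus_cds <- function(tracks, min_support = 3) {
  stopifnot(is.list(tracks), length(tracks) >= min_support, min_support >= 1)
  all <- purrr::imap(tracks, function(trk, i) {
    trk <- tibble::as_tibble(trk)
    stopifnot(all(c("start", "end", "strand") %in% names(trk)))
    dplyr::mutate(trk[c("start", "end", "strand")], .track = i)
  }) |>
    dplyr::bind_rows()
  if (nrow(all) == 0) {
    return(tibble::tibble(start = integer(), end = integer(),
                          strand = character(), stop_anchor = integer(),
                          support = integer()))
  }
  all |>
    dplyr::mutate(
      stop_anchor = ifelse(.data$strand == "+", .data$end, .data$start),
      five_prime = ifelse(.data$strand == "+", .data$start, .data$end),
      len = .data$end - .data$start + 1
    ) |>
    dplyr::group_by(.data$strand, .data$stop_anchor) |>
    dplyr::filter(dplyr::n_distinct(.data$.track) >= min_support) |>
    # consensus 5' end: majority vote, ties to the longest CDS
    dplyr::count(.data$five_prime, .data$len, name = "votes") |>
    dplyr::arrange(dplyr::desc(.data$votes), dplyr::desc(.data$len),
                   .by_group = TRUE) |>
    dplyr::slice_head(n = 1) |>
    dplyr::ungroup() |>
    dplyr::left_join(
      all |>
        dplyr::mutate(stop_anchor =
                        ifelse(.data$strand == "+", .data$end, .data$start)) |>
        dplyr::group_by(.data$strand, .data$stop_anchor) |>
        dplyr::summarise(support = dplyr::n_distinct(.data$.track),
                         .groups = "drop"),
      by = c("strand", "stop_anchor")
    ) |>
    dplyr::mutate(
      start = ifelse(.data$strand == "+", .data$five_prime, .data$stop_anchor),
      end = ifelse(.data$strand == "+", .data$stop_anchor, .data$five_prime)
    ) |>
    dplyr::select("start", "end", "strand", "stop_anchor", "support") |>
    dplyr::arrange(.data$start, .data$strand)
}
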