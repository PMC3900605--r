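#' Simulate gene-predictor tracks with controlled error
#'
#' Emulates the outputs of several independent CDS prediction tools run on the
#' same genome. Each tool reports every true CDS with its own sensitivity,
#' jitters the 5' start position by a multiple of 3 (tools disagree on starts
#' far more than on stops; the stop anchor and strand of true calls are always
#' preserved), and adds spurious calls at a per-kilobase false-positive rate
#' that are independent between tools.
#'
#' @param genome genome sequence (character scalar).
#' @param true_cds tibble of true features with columns `start`, `end`,
#'   `strand` (1-based inclusive, `"+"`/`"-"`).
#' @param sensitivities per-tool probability of reporting a true CDS.
#' @param fp_rate per-tool expected spurious calls per kb of genome.
#' @param start_jitter maximum 5'-start displacement in bp (rounded down to a
#'   multiple of 3).
#' @param seed random seed.
#'
#' @return a named list of tibbles (`start`, `end`, `strand`, `source`), one
#'   per tool.
#' @export
simulate_predictor_tracks <- function(genome, true_cds,
                                      sensitivities = c(1, 1, 1, 1),
                                      fp_rate = 0, start_jitter = 0,
                                      seed = NULL) {
  true_cds <- tibble::as_tibble(true_cds)
  stopifnot(all(c("start", "end", "strand") %in% names(true_cds)),
            all(sensitivities >= 0 & sensitivities <= 1),
            fp_rate >= 0, start_jitter >= 0)
  glen <- nchar(genome)
  j3 <- start_jitter %/% 3
  with_seed(seed, {
    tracks <- purrr::imap(
      stats::setNames(sensitivities,
                      sprintf("tool_%d", seq_along(sensitivities))),
      function(sens, tool) {
        keep <- true_cds[stats::runif(nrow(true_cds)) < sens, , drop = FALSE]
        if (nrow(keep) > 0 && j3 > 0) {
          shift <- 3L * sample(seq(-j3, j3), nrow(keep), replace = TRUE)
          plus <- keep$strand == "+"
          # jitter the 5' end only, clamped to keep a sane feature in bounds
          keep$start[plus] <- pmax(1L, pmin(keep$start[plus] + shift[plus],
                                            keep$end[plus] - 5L))
          keep$end[!plus] <- pmin(glen, pmax(keep$end[!plus] + shift[!plus],
                                             keep$start[!plus] + 5L))
        }
        n_fp <- stats::rpois(1, fp_rate * glen / 1000)
        if (n_fp > 0) {
          len <- 3L * sample(60:240, n_fp, replace = TRUE)
          st <- sample.int(glen, n_fp, replace = TRUE)
          fp <- tibble::tibble(
            start = pmax(1L, pmin(st, glen - len + 1L)),
            end = pmin(glen, st + len - 1L),
            strand = sample(c("+", "-"), n_fp, replace = TRUE)
          )
          keep <- dplyr::bind_rows(keep[, c("start", "end", "strand")], fp)
        }
        keep |>
          dplyr::select("start", "end", "strand") |>
          dplyr::arrange(.data$start) |>
          dplyr::mutate(source = tool)
      })
    tracks
  })
}
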