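#' Local high-scoring segment pairs between two sequences
#'
#' A seeded, ungapped local-alignment search. In nucleotide mode, exact word
#' seeds (default word size 7) are extended in both directions under a +1/-2
#' match/mismatch scheme with X-drop termination. In translated mode, all six
#' reading frames of both sequences are translated and 3-mer protein seeds are
#' extended under BLOSUM62; stop codons and ambiguous positions translate to X
#' and score -1 against everything, so genomic fragments are scored without
#' being truncated at stops. Significance follows Karlin-Altschul statistics
#' for ungapped alignments, `E = K * m * n * exp(-lambda * S)`, with the
#' standard published ungapped parameters for each scoring scheme (+1/-2:
#' lambda 1.28, K 0.46; BLOSUM62: lambda 0.3176, K 0.134), and
#' `P = 1 - exp(-E)`.
#'
#' @param query,target DNA sequences (character scalars).
#' @param mode `"nucleotide"` or `"translated"`.
#' @param params named list overriding the engine defaults: `word_size`,
#'   `match`, `mismatch`, `xdrop`, `e_ceiling`, `lambda`, `K` (nucleotide);
#'   `xdrop`, `e_ceiling`, `lambda`, `K` (translated). HSPs with E-value above
#'   `e_ceiling` (default 10) are discarded.
#' @return a tibble of HSPs sorted by decreasing raw score with 1-based
#'   inclusive coordinates on the plus strand of each sequence
#'   (`q_start`..`t_end`), `strand` or `q_frame`/`t_frame`, `raw_score`,
#'   `bit_score`, `e_value`, `p_value` and `log10_e` (kept separately because
#'   E-values of long identical sequences underflow doubles).
#' @examples
#' hits <- local_hsps(strrep("ACGT", 50), strrep("ACGT", 50))
#' hits[1, c("raw_score", "e_value")]
#' @export
local_hsps <- function(query, target, mode = c("nucleotide", "translated"),
                       params = list()) {
  mode <- match.arg(mode)
  check_sequence(query, "query")
  check_sequence(target, "target")
  if (mode == "nucleotide") {
    p <- utils::modifyList(
      list(word_size = 7, match = 1, mismatch = -2, xdrop = 30,
           e_ceiling = 10, lambda = 1.28, K = 0.46),
      params)
    df <- cpp_nt_hsps(query, target, p$word_size, p$match, p$mismatch,
                      p$xdrop, log10(p$e_ceiling), p$lambda, p$K)
  } else {
    p <- utils::modifyList(
      list(xdrop = 20, e_ceiling = 10, lambda = 0.3176, K = 0.134),
      params)
    df <- cpp_tx_hsps(query, target, p$xdrop, log10(p$e_ceiling),
                      p$lambda, p$K)
  }
  df <- tibble::as_tibble(df)
  df$bit_score <- (p$lambda * df$raw_score - log(p$K)) / log(2)
  df$e_value <- 10^df$log10_e
  df$p_value <- -expm1(-df$e_value)
  df
}

check_sequence <- function(x, what) {
  if (!is.character(x) || length(x) != 1 || nchar(x) == 0) {
    stop(what, " must be a single non-empty sequence", call. = FALSE)
  }
  frac_ambig <- 1 - mean(strsplit(toupper(x), "", fixed = TRUE)[[1]] %in%
                           DNA_BASES)
  if (frac_ambig > 0.5) {
    stop(what, " has more than 50% ambiguity codes", call. = FALSE)
  }
  invisible(x)
}

# log10 of the best (smallest) HSP p-value between two sequences, or NULL when
# nothing passes the ceiling; robust for p-values far below double underflow
best_hit_log10p <- function(query, target, e_ceiling, params = list()) {
  hits <- local_hsps(query, target, "nucleotide",
                     utils::modifyList(params, list(e_ceiling = e_ceiling)))
  if (nrow(hits) == 0) return(NULL)
  l10e <- min(hits$log10_e)
  if (l10e > -8) log10(-expm1(-10^l10e)) else l10e
}
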