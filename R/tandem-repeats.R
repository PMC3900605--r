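#' Find tandem repeats by direct periodicity scanning
#'
#' Reports maximal runs in which the sequence repeats a unit of length between
#' `unit_min` and `unit_max`, allowing a per-run mismatch fraction up to
#' `max_mismatch_frac` (default 0, i.e. exact repeats). A run is reported only
#' with its smallest generating unit: a homopolymer is a unit-1 repeat, never a
#' unit-2 or unit-4 one. Runs shorter than `min_total` bp, or spanning fewer
#' than two unit copies, are discarded.
#'
#' The scan compares the sequence with itself shifted by each candidate unit
#' length, so a position "matches" when `s[i] == s[i + u]`; a maximal run of
#' matching positions `a..b` corresponds to a repeat region `a..(b + u)`.
#' Mismatch tolerance is applied greedily while extending a run and runs never
#' end on a mismatch.
#'
#' @param sequence DNA sequence (character scalar).
#' @param unit_min,unit_max unit length bounds in bp.
#' @param min_total minimum total run length in bp.
#' @param max_mismatch_frac maximum fraction of mismatching positions within a
#'   run (0 = exact).
#' @return a tibble with columns `start`, `end` (1-based inclusive),
#'   `unit_length`, `copies` (possibly fractional), sorted by `start`.
#' @examples
#' find_tandem_repeats(strrep("AC", 10), unit_max = 4, min_total = 20)
#' @export
find_tandem_repeats <- function(sequence, unit_min = 1, unit_max = 10,
                                min_total = 20, max_mismatch_frac = 0) {
  stopifnot(unit_min >= 1, unit_max >= unit_min, min_total >= 2,
            max_mismatch_frac >= 0, max_mismatch_frac < 1)
  x <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  n <- length(x)
  out <- list()
  for (u in unit_min:unit_max) {
    if (n < 2 * u) break
    mism <- x[seq_len(n - u)] != x[(u + 1):n]
    runs <- mismatch_tolerant_runs(mism, max_mismatch_frac)
    if (nrow(runs) == 0) next
    runs$start <- runs$from
    runs$end <- runs$to + u
    keep <- (runs$end - runs$start + 1) >= max(min_total, 2 * u)
    runs <- runs[keep, , drop = FALSE]
    if (nrow(runs) == 0) next
    # smallest-unit rule: drop runs explainable by a proper divisor of u
    explained <- vapply(seq_len(nrow(runs)), function(i) {
      divs <- setdiff(which(u %% seq_len(u - 1) == 0), 0)
      any(vapply(divs, function(d) {
        repeats_with_unit(x, runs$start[i], runs$end[i], d, max_mismatch_frac)
      }, logical(1)))
    }, logical(1))
    runs <- runs[!explained, , drop = FALSE]
    if (nrow(runs) == 0) next
    out[[length(out) + 1]] <- tibble::tibble(
      start = runs$start, end = runs$end, unit_length = u,
      copies = (runs$end - runs$start + 1) / u
    )
  }
  if (!length(out)) {
    return(tibble::tibble(start = integer(), end = integer(),
                          unit_length = integer(), copies = numeric()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$start, .data$unit_length)
}

# maximal runs over a logical mismatch vector, allowing the running mismatch
# fraction to stay at or below `frac`; runs are trimmed to end on a match
mismatch_tolerant_runs <- function(mism, frac) {
  if (frac == 0) {
    r <- rle(mism)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- !r$values
    return(data.frame(from = starts[keep], to = ends[keep]))
  }
  from <- integer(); to <- integer()
  i <- 1L; n <- length(mism)
  while (i <= n) {
    if (mism[i]) { i <- i + 1L; next }
    start <- i; bad <- 0L; last_good <- i
    while (i <= n) {
      if (mism[i]) {
        if ((bad + 1L) / (i - start + 1L) > frac) break
        bad <- bad + 1L
      } else {
        last_good <- i
      }
      i <- i + 1L
    }
    from <- c(from, start); to <- c(to, last_good)
    i <- last_good + 1L
    while (i <= n && mism[i]) i <- i + 1L
  }
  data.frame(from = from, to = to)
}

repeats_with_unit <- function(x, start, end, u, frac) {
  if (end - start + 1 < 2 * u) return(FALSE)
  seg <- x[start:end]
  m <- seg[seq_len(length(seg) - u)] != seg[(u + 1):length(seg)]
  mean(m) <= frac
}
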