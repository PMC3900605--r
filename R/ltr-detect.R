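#' Detect a collapsed terminal-repeat segment from a coverage profile
#'
#' In a circular assembly of a linear genome with identical terminal repeats,
#' the collapsed repeat receives roughly twice the read depth of the rest of
#' the sequence. This detector smooths the per-position depth with a circular
#' moving average, thresholds it at `ratio_threshold` times the global median
#' of the smoothed profile, takes the longest contiguous (circular) segment
#' above threshold, and optionally refines each boundary to the best two-level
#' step position under a piecewise-constant depth model. Segments may wrap the
#' origin of the circular coordinate system.
#'
#' The threshold default of 1.5 sits midway between the background (1x) and
#' the collapsed-duplication expectation (2x). A profile with no position
#' above threshold yields a "not detected" result rather than an error; if
#' several disjoint segments exceed the threshold the longest is returned and
#' the total count reported.
#'
#' @param profile coverage as a numeric depth vector or a tibble with columns
#'   `pos` and `depth` (as produced by [simulate_collapsed_assembly()]).
#' @param smoothing_window circular moving-average window in bp (odd; default
#'   201).
#' @param ratio_threshold fold-change over the median smoothed depth required
#'   to call a position elevated.
#' @param refine refine boundaries by a two-level step fit? (default `TRUE`)
#' @param refine_window half-width of the boundary refinement window in bp;
#'   defaults to three smoothing windows.
#'
#' @return an `ltr_call` list: `detected`, `start`, `end`, `length` (circular
#'   span, 1-based inclusive; `start > end` means the segment wraps the
#'   origin), `coverage_ratio` (mean raw depth inside divided by mean depth
#'   outside, with positions within one smoothing window of either boundary
#'   excluded from both levels because depth transitions there rather than
#'   sitting at either level), `n_segments` (segments above threshold after gaps
#'   narrower than one smoothing window are filled), and `flank_repeats`
#'   (filled by [annotate_flank_repeats()]).
#' @seealso [linearize()], [annotate_flank_repeats()]
#' @examples
#' asm <- simulate_collapsed_assembly(30000, 2000, 5000, 400, seed = 1)
#' detect_elevated_segment(asm$coverage)
#' @export
detect_elevated_segment <- function(profile, smoothing_window = 201,
                                    ratio_threshold = 1.5, refine = TRUE,
                                    refine_window = NULL) {
  depth <- coverage_depth(profile)
  L <- length(depth)
  if (L < 10 * smoothing_window) {
    stop("profile must be at least 10 smoothing windows long", call. = FALSE)
  }
  if (is.null(refine_window)) refine_window <- 3 * smoothing_window

  sm <- as.numeric(stats::filter(depth, rep(1 / smoothing_window,
                                            smoothing_window),
                                 sides = 2, circular = TRUE))
  med <- stats::median(sm)
  above <- sm >= ratio_threshold * med & sm > 0
  if (!any(above) || all(above)) {
    return(ltr_call(detected = FALSE, L = L))
  }
  # below-threshold gaps narrower than the smoother's resolution cannot be
  # genuine low-coverage regions; fill them so one depth dip cannot split
  # the elevated segment
  above <- fill_short_gaps(above, smoothing_window)
  if (all(above)) {
    return(ltr_call(detected = FALSE, L = L))
  }

  # circular run extraction: rotate so the scan starts outside a segment
  i0 <- which(!above)[1]
  rot <- c(above[i0:L], above[seq_len(i0 - 1)])
  r <- rle(rot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  seg <- which(r$values)
  # map back to original circular coordinates
  to_orig <- function(i) ((i + i0 - 2) %% L) + 1
  seg_start <- to_orig(starts[seg])
  seg_end <- to_orig(ends[seg])
  seg_len <- r$lengths[seg]
  n_segments <- length(seg)
  best <- which.max(seg_len)
  s <- seg_start[best]; e <- seg_end[best]

  if (refine) {
    s <- refine_boundary(depth, s, refine_window, rising = TRUE)
    e <- refine_boundary(depth, e, refine_window, rising = FALSE)
  }
  len <- ((e - s) %% L) + 1

  # estimate the two coverage levels away from the boundaries: within one
  # smoothing window of a boundary the depth transitions between levels (read
  # ramps, smoothing), so those positions belong to neither level cleanly and
  # would bias the level estimates
  trim <- min(smoothing_window, len %/% 4)
  core <- circular_index(s + trim, max(len - 2L * trim, 1L), L)
  expanded <- circular_index(s - trim, min(len + 2L * trim, L - 1L), L)
  ratio <- mean(depth[core]) / mean(depth[-expanded])
  ltr_call(detected = TRUE, start = s, end = e, length = len,
           coverage_ratio = ratio, n_segments = n_segments, L = L)
}

coverage_depth <- function(profile) {
  if (is.data.frame(profile)) {
    stopifnot(all(c("pos", "depth") %in% names(profile)))
    depth <- profile$depth[order(profile$pos)]
  } else {
    depth <- as.numeric(profile)
  }
  if (any(depth < 0)) stop("depths must be non-negative", call. = FALSE)
  depth
}

circular_index <- function(start, len, L) {
  (((start - 1) + seq_len(len) - 1) %% L) + 1
}

# flip circular below-threshold runs shorter than `min_gap` when both values
# are present; rotation starts at a gap opening so no circular run is split
fill_short_gaps <- function(above, min_gap) {
  L <- length(above)
  g0 <- which(!above & c(above[L], above[-L]))[1] # gap start (prev is TRUE)
  rot <- c(above[g0:L], above[seq_len(g0 - 1)])
  r <- rle(rot)
  r$values[!r$values & r$lengths < min_gap] <- TRUE
  rot <- inverse.rle(r)
  out <- logical(L)
  out[c(g0:L, seq_len(g0 - 1))] <- rot
  out
}

# Slide a step-change position within +/- window of `pos` and keep the split
# that minimises the within-segment sum of squares of a two-level fit. For a
# rising boundary the elevated side is to the right of the split.
refine_boundary <- function(depth, pos, window, rising) {
  L <- length(depth)
  idx <- circular_index(pos - window, 2 * window + 1, L)
  y <- depth[idx]
  n <- length(y)
  cs <- cumsum(y); cs2 <- cumsum(y^2)
  # split after position i: left = 1..i, right = (i+1)..n
  i <- seq_len(n - 1)
  sse_left <- cs2[i] - cs[i]^2 / i
  nr <- n - i
  sr <- cs[n] - cs[i]
  sse_right <- (cs2[n] - cs2[i]) - sr^2 / nr
  split <- which.min(sse_left + sse_right)
  # boundary position: first (rising) or last (falling) elevated position
  off <- if (rising) split + 1 else split
  idx[min(off, n)]
}

ltr_call <- function(detected, start = NA_integer_, end = NA_integer_,
                     length = NA_integer_, coverage_ratio = NA_real_,
                     n_segments = 0L, flank_repeats = NULL, L = NA_integer_) {
  structure(
    list(detected = detected, start = start, end = end, length = length,
         coverage_ratio = coverage_ratio, n_segments = n_segments,
         flank_repeats = flank_repeats, sequence_length = L),
    class = "ltr_call"
  )
}

#' @export
print.ltr_call <- function(x, ...) {
  if (!x$detected) {
    cat("<ltr_call> no elevated segment detected\n")
  } else {
    cat("<ltr_call> ", x$length, " bp segment at ", x$start, "..", x$end,
        " (coverage ratio ", round(x$coverage_ratio, 2), "x, ",
        x$n_segments, " segment(s) above threshold)\n", sep = "")
  }
  invisible(x)
}

#' Attach nearby tandem repeats to a terminal-repeat call
#'
#' Scans a window around each boundary of the detected segment for tandem
#' repeats, mirroring the observation that repeats flank the physical ends of
#' the linear genome. The window extends `flank` bp beyond each boundary in
#' both directions.
#'
#' @param call an `ltr_call`.
#' @param sequence the collapsed circular sequence.
#' @param flank window half-width around each boundary (default 200 bp).
#' @param ... passed to [find_tandem_repeats()].
#' @return the call with its `flank_repeats` tibble filled in (coordinates on
#'   the full sequence).
#' @export
annotate_flank_repeats <- function(call, sequence, flank = 200, ...) {
  stopifnot(inherits(call, "ltr_call"))
  if (!call$detected) return(call)
  L <- nchar(sequence)
  scan_at <- function(b) {
    idx <- circular_index(b - flank, 2 * flank + 1, L)
    win <- paste(strsplit(sequence, "", fixed = TRUE)[[1]][idx], collapse = "")
    reps <- find_tandem_repeats(win, ...)
    if (nrow(reps)) {
      reps$start <- idx[reps$start]
      reps$end <- idx[reps$end]
    }
    reps
  }
  call$flank_repeats <- dplyr::bind_rows(
    dplyr::mutate(scan_at(call$start), boundary = "start"),
    dplyr::mutate(scan_at(call$end), boundary = "end")
  )
  call
}

#' Linearize a collapsed circular assembly at the terminal repeat
#'
#' Rotates the circular unique sequence so that position 1 is the first
#' nucleotide of the detected collapsed repeat. The complete linear genome
#' consists of the rotated unique sequence plus a second copy of the repeat,
#' so `total_length = unique_length + ltr_length` - the length accounting used
#' to report the full genome size from a collapsed assembly.
#'
#' @param collapsed the collapsed circular sequence (character scalar).
#' @param call an `ltr_call` with `detected = TRUE`.
#' @return a `linearized_genome` list: `sequence` (rotated unique sequence),
#'   `unique_length`, `ltr_length`, `total_length`.
#' @examples
#' asm <- simulate_collapsed_assembly(30000, 2000, 5000, 400, seed = 1)
#' call <- detect_elevated_segment(asm$coverage)
#' linearize(asm$sequence, call)
#' @export
linearize <- function(collapsed, call) {
  stopifnot(inherits(call, "ltr_call"))
  if (!call$detected) {
    stop("cannot linearize: no terminal repeat detected", call. = FALSE)
  }
  L <- nchar(collapsed)
  s <- call$start
  rotated <- if (s == 1) collapsed else {
    paste0(substr(collapsed, s, L), substr(collapsed, 1, s - 1))
  }
  structure(
    list(sequence = rotated,
         unique_length = L,
         ltr_length = call$length,
         total_length = L + call$length),
    class = "linearized_genome"
  )
}

#' @export
print.linearized_genome <- function(x, ...) {
  cat("<linearized_genome> unique ", x$unique_length, " bp + terminal repeat ",
      x$ltr_length, " bp = ", x$total_length, " bp total\n", sep = "")
  invisible(x)
}
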