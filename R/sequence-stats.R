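#' Genome sequence statistics over a set of CDS features
#'
#' Computes the summary numbers conventionally reported for a newly annotated
#' phage genome: GC content (ambiguity codes excluded from the denominator),
#' CDS counts per strand, the distribution of start codons (ATG/TTG/GTG/other)
#' and stop codons (TAA/TAG/TGA/other) read off the genome respecting strand,
#' and the CDS density as the fraction of the genome covered by the *union* of
#' CDS intervals (overlapping features are counted once).
#'
#' @param genome genome sequence (character scalar).
#' @param features tibble of CDS features with columns `start`, `end`,
#'   `strand` (1-based inclusive).
#' @return a `sequence_stats` list: `gc_percent`, `cds_count_forward`,
#'   `cds_count_reverse`, `start_codon_fractions`, `stop_codon_fractions`
#'   (named percentages to one decimal), `cds_density_percent`.
#' @examples
#' g <- strrep("ATGAAATAA", 10)
#' sequence_stats(g, tibble::tibble(start = 1, end = 9, strand = "+"))
#' @export
sequence_stats <- function(genome, features) {
  features <- tibble::as_tibble(features)
  stopifnot(all(c("start", "end", "strand") %in% names(features)))
  L <- nchar(genome)
  bad <- which(features$start < 1 | features$end > L |
                 features$start > features$end)
  if (length(bad)) {
    stop("feature out of bounds: row ", bad[1], " (",
         features$start[bad[1]], "..", features$end[bad[1]], " on a ",
         L, " bp genome)", call. = FALSE)
  }

  counts <- table(factor(strsplit(toupper(genome), "", fixed = TRUE)[[1]],
                         levels = c("A", "C", "G", "T")))
  gc <- round(100 * sum(counts[c("G", "C")]) / sum(counts), 1)

  plus <- features$strand == "+"
  codon_at <- function(i, which_end) {
    if (features$strand[i] == "+") {
      if (which_end == "start") {
        substr(genome, features$start[i], features$start[i] + 2)
      } else {
        substr(genome, features$end[i] - 2, features$end[i])
      }
    } else {
      if (which_end == "start") {
        revcomp(substr(genome, features$end[i] - 2, features$end[i]))
      } else {
        revcomp(substr(genome, features$start[i], features$start[i] + 2))
      }
    }
  }
  rows <- seq_len(nrow(features))
  first_codon <- vapply(rows, codon_at, character(1), which_end = "start")
  last_codon <- vapply(rows, codon_at, character(1), which_end = "stop")

  frac <- function(x, levels) {
    if (length(x) == 0) {
      return(stats::setNames(rep(0, length(levels) + 1), c(levels, "other")))
    }
    f <- factor(ifelse(toupper(x) %in% levels, toupper(x), "other"),
                levels = c(levels, "other"))
    round(100 * as.numeric(table(f)) / length(x), 1) |>
      stats::setNames(c(levels, "other"))
  }

  density <- if (nrow(features)) {
    covered <- sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(start = features$start, end = features$end))))
    round(100 * covered / L, 1)
  } else 0

  structure(
    list(
      gc_percent = as.numeric(gc),
      cds_count_forward = sum(plus),
      cds_count_reverse = sum(!plus),
      start_codon_fractions = frac(first_codon, c("ATG", "TTG", "GTG")),
      stop_codon_fractions = frac(last_codon, c("TAA", "TAG", "TGA")),
      cds_density_percent = as.numeric(density)
    ),
    class = "sequence_stats"
  )
}

#' @export
print.sequence_stats <- function(x, ...) {
  cat("<sequence_stats>\n")
  cat("  GC: ", x$gc_percent, "%   CDS: ", x$cds_count_forward, " forward, ",
      x$cds_count_reverse, " reverse   density: ", x$cds_density_percent,
      "%\n", sep = "")
  cat("  start codons:",
      paste(names(x$start_codon_fractions),
            paste0(x$start_codon_fractions, "%"), collapse = ", "), "\n")
  cat("  stop codons: ",
      paste(names(x$stop_codon_fractions),
            paste0(x$stop_codon_fractions, "%"), collapse = ", "), "\n")
  invisible(x)
}

#' @export
glance.sequence_stats <- function(x, ...) {
  tibble::tibble(
    gc_percent = x$gc_percent,
    cds_count_forward = x$cds_count_forward,
    cds_count_reverse = x$cds_count_reverse,
    cds_count_total = x$cds_count_forward + x$cds_count_reverse,
    cds_density_percent = x$cds_density_percent,
    start_atg_percent = x$start_codon_fractions[["ATG"]],
    stop_taa_percent = x$stop_codon_fractions[["TAA"]]
  )
}
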