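#' Read and write FASTA sequence files
#'
#' Thin wrappers around seqinr that present sequences the way the rest of the
#' package does: a named character vector of uppercase sequences.
#'
#' @param path file path.
#' @return `read_fasta()` returns a named character vector.
#' @export
read_fasta <- function(path) {
  recs <- seqinr::read.fasta(path, seqtype = "DNA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  stats::setNames(toupper(vapply(recs, function(r) r[[1]], character(1))),
                  names(recs))
}

#' @param sequences named character vector of sequences.
#' @param width line width for wrapping (default 70).
#' @rdname read_fasta
#' @export
write_fasta <- function(sequences, path, width = 70) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  seqinr::write.fasta(as.list(unname(sequences)), names(sequences), path,
                      nbchar = width)
  invisible(path)
}

#' Read and write CDS feature tables as GFF3
#'
#' Uses rtracklayer for parsing and serialisation; the package-side
#' representation is the feature tibble (`start`, `end`, `strand`, optional
#' `support`) used throughout.
#'
#' @param path file path.
#' @return `read_features_gff3()` returns a feature tibble with a `seqid`
#'   column.
#' @export
read_features_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  tibble::tibble(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' @param features feature tibble with columns `start`, `end`, `strand`.
#' @param seqid sequence identifier written to column 1.
#' @param source annotation source written to column 2.
#' @rdname read_features_gff3
#' @export
write_features_gff3 <- function(features, path, seqid = "genome",
                                source = "phagephylo") {
  features <- tibble::as_tibble(features)
  stopifnot(all(c("start", "end", "strand") %in% names(features)))
  gr <- GenomicRanges::GRanges(
    seqnames = seqid,
    ranges = IRanges::IRanges(start = features$start, end = features$end),
    strand = features$strand
  )
  gr$source <- source
  gr$type <- "CDS"
  gr$phase <- 0L # consensus features always start in frame
  if ("support" %in% names(features)) gr$support <- features$support
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write a distance matrix in relaxed PHYLIP format
#'
#' @param distance square numeric matrix with dimnames.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_phylip_distance <- function(distance, path) {
  stopifnot(is.matrix(distance), nrow(distance) == ncol(distance),
            !is.null(rownames(distance)))
  lines <- c(
    format(nrow(distance)),
    vapply(seq_len(nrow(distance)), function(i) {
      paste(c(rownames(distance)[i],
              formatC(distance[i, ], format = "f", digits = 6)),
            collapse = "  ")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read and write tab-separated result tables
#'
#' Plain TSV with a header row; `read_tsv_table()` returns a tibble.
#'
#' @param path file path.
#' @return `read_tsv_table()` returns a tibble.
#' @export
read_tsv_table <- function(path) {
  tibble::as_tibble(utils::read.delim(path, check.names = FALSE,
                                      stringsAsFactors = FALSE))
}

#' @param table a data frame.
#' @rdname read_tsv_table
#' @export
write_tsv_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
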