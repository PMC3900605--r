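#' Sequence utilities
#'
#' Small helpers for working with genomes stored as plain character strings:
#' reverse complement, random sequence generation and i.i.d. per-site mutation.
#' These underpin the synthetic-data generators.
#'
#' @param x a single DNA sequence (character scalar).
#' @return `revcomp()` returns the reverse complement as a character scalar.
#' @examples
#' revcomp("ACGTT")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  rawToChar(rev(charToRaw(chartr("ACGTacgt", "TGCAtgca", x))))
}

DNA_BASES <- c("A", "C", "G", "T")

seq_to_int <- function(x) {
  match(strsplit(toupper(x), "", fixed = TRUE)[[1]], DNA_BASES)
}

int_to_seq <- function(v) paste(DNA_BASES[v], collapse = "")

# uniform random DNA
rand_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# the 61 sense codons of the standard code
sense_codons <- function() {
  all <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1, paste,
               collapse = "")
  setdiff(all, c("TAA", "TAG", "TGA"))
}

# random DNA with a coding-like reading frame: in-frame codons are drawn from
# the sense codons so the + strand frame 1 is open end to end
rand_coding_dna <- function(n) {
  n_codons <- ceiling(n / 3)
  s <- paste(sample(sense_codons(), n_codons, replace = TRUE), collapse = "")
  substr(s, 1, n)
}

# i.i.d. per-site substitution: each site is replaced with probability `rate`
# by a uniformly chosen *different* base (no indels, so coordinates and synteny
# are preserved exactly)
mutate_seq <- function(x, rate) {
  if (rate <= 0) return(x)
  v <- seq_to_int(x)
  hit <- which(stats::runif(length(v)) < rate)
  if (length(hit)) {
    # new base = old base shifted by 1..3 (mod 4): uniform over the other three
    v[hit] <- ((v[hit] - 1L + sample.int(3L, length(hit), replace = TRUE)) %% 4L) + 1L
  }
  int_to_seq(v)
}

# fraction of identical sites between two equal-length sequences
site_identity <- function(a, b) {
  va <- seq_to_int(a); vb <- seq_to_int(b)
  stopifnot(length(va) == length(vb))
  mean(va == vb, na.rm = TRUE)
}

AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
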