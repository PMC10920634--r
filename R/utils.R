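#' Run code with a fixed RNG seed, restoring RNG state afterwards
#'
#' All stochastic operations in the package funnel through this helper so that
#' an identical seed gives byte-identical output and the caller's RNG stream
#' is never disturbed.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param code Code to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

#' Reverse-complement DNA strings
#'
#' @param x Character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp(c("ACGT", "TTAA"))
revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

#' Round half away from zero
#'
#' Percentages in reports are rounded half-up (2.5 -> 3), unlike base
#' [round()], which rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## Phred+33 helpers -----------------------------------------------------------

qual_to_int <- function(qual) {
  lapply(qual, function(q) as.integer(charToRaw(q)) - 33L)
}

int_to_qual <- function(q) {
  vapply(q, function(v) rawToChar(as.raw(v + 33L)), character(1))
}

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ file (optionally gzipped).
#' @return A `data.frame` with columns `id`, `seq`, `qual` (Phred+33 string).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(
    id = names(x),
    seq = as.character(x),
    qual = as.character(S4Vectors::mcols(x)$qualities),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Write a read table to FASTQ
#'
#' @param reads `data.frame` with columns `id`, `seq`, `qual`.
#' @param path Output path; `.gz` suffix triggers compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual),
    compress = grepl("\\.gz$", path)
  )
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  # keep only the first whitespace-delimited token as the name
  nm <- sub("\\s.*$", "", names(x))
  stats::setNames(as.character(x), nm)
}

#' Write named sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# flatten a character vector of sequences into per-base vectors
explode_seqs <- function(seqs) {
  chars <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  len <- nchar(seqs)
  list(
    chars = chars,
    frag = rep(seq_along(seqs), len),
    pos = sequence(len) - 1L,    # 0-based position within sequence
    len = rep(len, len)
  )
}

# rebuild sequences from an exploded representation
implode_seqs <- function(chars, frag, n) {
  out <- character(n)
  sp <- split(chars, factor(frag, levels = seq_len(n)))
  unname(vapply(sp, paste, character(1), collapse = ""))
}
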