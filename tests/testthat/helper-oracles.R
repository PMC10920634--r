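# Independent oracles and fixture builders used across the suite.

# Full-matrix affine-gap Smith-Waterman in plain R, written independently of
# the package's compiled implementation. Gap of length L costs
# gap_open + (L - 1) * gap_extend; N never matches. Returns the best score.
sw_oracle <- function(query, ref, match = 1, mismatch = -1,
                      gap_open = -2, gap_extend = -1) {
  q <- strsplit(query, "")[[1]]
  r <- strsplit(ref, "")[[1]]
  n <- length(q); m <- length(r)
  NEG <- -Inf
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)  # gap consuming ref
  F <- matrix(NEG, n + 1, m + 1)  # gap consuming query
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (q[i - 1] == r[j - 1] && q[i - 1] != "N") match else mismatch
      E[i, j] <- max(H[i, j - 1] + gap_open, E[i, j - 1] + gap_extend)
      F[i, j] <- max(H[i - 1, j] + gap_open, F[i - 1, j] + gap_extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

rand_dna <- function(len, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

make_reads <- function(seqs, qual = 37, ids = NULL) {
  if (is.null(ids)) ids <- paste0("r", seq_along(seqs))
  data.frame(id = ids, seq = seqs,
             qual = strrep(rawToChar(as.raw(qual + 33L)), nchar(seqs)),
             stringsAsFactors = FALSE)
}

# small fragment table in the layout the damage/snp modules expect
frag_table <- function(chrom, start, end, strand, seq, id = NULL) {
  if (is.null(id)) id <- paste0("f", seq_along(start))
  data.frame(id = id, chrom = chrom, start = start, end = end,
             strand = strand, seq = seq, stringsAsFactors = FALSE)
}
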