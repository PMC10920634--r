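#' Trim adapters and low-quality ends from reads
#'
#' Adapter removal: a full adapter occurrence anywhere in the read, or an
#' exact terminal overlap (>= `min_adapter_overlap` bases of the adapter
#' prefix at the read 3' end), truncates the read there. Quality trimming
#' then removes bases with Phred quality below `quality_cutoff` from both
#' ends inward until a base at or above the cutoff is met. Reads shorter
#' than `min_length` after trimming are discarded.
#'
#' @param reads `data.frame` with columns `id`, `seq`, `qual` (Phred+33).
#' @param adapter Adapter sequence (default [sequencing_adapter()]).
#' @param quality_cutoff Minimum base quality kept at read ends.
#' @param min_length Minimum retained read length.
#' @param min_adapter_overlap Minimum exact terminal adapter overlap.
#' @return A list with `reads` (trimmed, surviving reads with `trim5`,
#'   `trim3` columns) and `n_discarded`.
#' @export
trim_reads <- function(reads, adapter = sequencing_adapter(),
                       quality_cutoff = 20, min_length = 30,
                       min_adapter_overlap = 3) {
  if (!all(c("id", "seq", "qual") %in% names(reads))) {
    stop("reads must have id, seq and qual columns")
  }
  if (any(nchar(reads$seq) != nchar(reads$qual))) {
    bad <- reads$id[nchar(reads$seq) != nchar(reads$qual)][1]
    stop("malformed record (sequence/quality length mismatch): ", bad)
  }
  n <- nrow(reads)
  seqs <- reads$seq
  quals <- reads$qual

  # adapter: full internal occurrence
  hit <- regexpr(adapter, seqs, fixed = TRUE)
  cut_at <- ifelse(hit > 0, hit - 1L, nchar(seqs))  # bases kept
  # terminal partial overlap with adapter prefix (longest match wins, once)
  alen <- nchar(adapter)
  open <- hit <= 0  # reads without a full adapter occurrence
  for (k in seq(alen - 1L, min_adapter_overlap)) {
    pre <- substr(adapter, 1L, k)
    cand <- open & cut_at >= k & substr(seqs, cut_at - k + 1L, cut_at) == pre
    cut_at[cand] <- cut_at[cand] - k
    open <- open & !cand
  }
  seqs <- substr(seqs, 1L, cut_at)
  quals <- substr(quals, 1L, cut_at)

  qint <- qual_to_int(quals)
  trim5 <- integer(n); trim3 <- integer(n)
  out_seq <- character(n); out_qual <- character(n)
  for (i in seq_len(n)) {
    q <- qint[[i]]
    ok <- which(q >= quality_cutoff)
    if (!length(ok)) {
      out_seq[i] <- ""
      out_qual[i] <- ""
      trim5[i] <- length(q)
      next
    }
    a <- ok[1]; b <- ok[length(ok)]
    trim5[i] <- a - 1L
    trim3[i] <- length(q) - b
    out_seq[i] <- substr(seqs[i], a, b)
    out_qual[i] <- substr(quals[i], a, b)
  }
  keep <- nchar(out_seq) >= min_length
  res <- data.frame(id = reads$id[keep], seq = out_seq[keep],
                    qual = out_qual[keep], trim5 = trim5[keep],
                    trim3 = trim3[keep], stringsAsFactors = FALSE)
  list(reads = res, n_discarded = sum(!keep))
}

#' Merge a read pair by overlap
#'
#' The reverse complement of the second mate is scanned against the first
#' for the best inner overlap of at least `min_overlap` bases; overlaps with
#' mismatch density above `max_mismatch_density` are rejected. Overlapping
#' bases are resolved to the higher-quality call. The merged length is
#' `|r1| + |r2| - overlap`.
#'
#' @param seq1,qual1 First mate sequence and Phred+33 quality.
#' @param seq2,qual2 Second mate (as sequenced; reverse-complemented here).
#' @param min_overlap Minimum overlap length.
#' @param max_mismatch_density Maximum mismatches per overlap base.
#' @return A list with `merged` (logical); when merged, `seq` and `qual`.
#' @export
#' @examples
#' merge_pair("ACGTACGTACGTAC", strrep("F", 14),
#'            revcomp("ACGTACGTACGTAC"), strrep("F", 14))
merge_pair <- function(seq1, qual1, seq2, qual2,
                       min_overlap = 10, max_mismatch_density = 0.25) {
  rc2 <- revcomp(seq2)
  rq2 <- paste(rev(strsplit(qual2, "", fixed = TRUE)[[1]]), collapse = "")
  l1 <- nchar(seq1); l2 <- nchar(rc2)
  max_o <- min(l1, l2)
  if (max_o < min_overlap) return(list(merged = FALSE))

  c1 <- strsplit(seq1, "", fixed = TRUE)[[1]]
  c2 <- strsplit(rc2, "", fixed = TRUE)[[1]]
  best_o <- 0L; best_d <- Inf
  for (o in seq.int(min_overlap, max_o)) {
    mm <- sum(c1[(l1 - o + 1L):l1] != c2[1:o])
    d <- mm / o
    if (d <= max_mismatch_density && (d < best_d || (d == best_d && o > best_o))) {
      best_d <- d; best_o <- o
    }
  }
  if (best_o == 0L) return(list(merged = FALSE))

  o <- best_o
  q1 <- qual_to_int(qual1)[[1]]
  q2 <- qual_to_int(rq2)[[1]]
  ov1 <- (l1 - o + 1L):l1
  ov2 <- 1:o
  take2 <- q2[ov2] > q1[ov1]
  ov_chars <- c1[ov1]; ov_chars[take2] <- c2[ov2][take2]
  ov_q <- pmax(q1[ov1], q2[ov2])
  merged_seq <- paste0(substr(seq1, 1, l1 - o),
                       paste(ov_chars, collapse = ""),
                       substr(rc2, o + 1L, l2))
  merged_qual <- paste0(substr(qual1, 1, l1 - o),
                        int_to_qual(list(ov_q)),
                        substr(rq2, o + 1L, l2))
  list(merged = TRUE, seq = merged_seq, qual = merged_qual,
       overlap = o, mismatch_density = best_d)
}

#' Collapse exact duplicate sequences
#'
#' Keeps the first occurrence of each distinct sequence, in stable order
#' (zero-mismatch deduplication).
#'
#' @param reads Read `data.frame` with a `seq` column.
#' @return The deduplicated `data.frame`.
#' @export
deduplicate <- function(reads) {
  reads[!duplicated(reads$seq), , drop = FALSE]
}

# minimum normalized k-mer entropy over sliding windows of one sequence
min_window_entropy <- function(seq, k = 5, window = 50) {
  L <- nchar(seq)
  if (L < k) return(0)
  kmers <- substring(seq, 1:(L - k + 1L), k:L)
  n_k <- length(kmers)
  slots <- min(window, L) - k + 1L  # k-mers per window
  ent <- function(v) {
    tab <- table(v)
    p <- tab / sum(tab)
    -sum(p * log(p))
  }
  norm <- log(slots)
  if (norm == 0) return(0)
  if (n_k <= slots) return(ent(kmers) / norm)
  starts <- 1:(n_k - slots + 1L)
  min(vapply(starts, function(s) ent(kmers[s:(s + slots - 1L)]) / norm,
             numeric(1)))
}

#' Remove low-complexity reads by windowed k-mer entropy
#'
#' For each read, the Shannon entropy of k-mer counts is computed in every
#' sliding window and normalized by the log of the number of k-mer slots in
#' the window; a read is removed when any window falls below the threshold.
#'
#' @param reads Read `data.frame`.
#' @param entropy_threshold Normalized entropy threshold (default 0.7).
#' @param k K-mer size.
#' @param window Window length in bases.
#' @return The retained reads.
#' @export
entropy_filter <- function(reads, entropy_threshold = 0.7, k = 5, window = 50) {
  if (!nrow(reads)) return(reads)
  e <- vapply(reads$seq, min_window_entropy, numeric(1),
              k = k, window = window, USE.NAMES = FALSE)
  reads[e >= entropy_threshold, , drop = FALSE]
}

#' Run the full read-processing chain
#'
#' Stages, in order: adapter/quality trimming of both mates, pair merging,
#' exact deduplication, and entropy filtering, with exact per-stage read
#' accounting. Pairs that fail to merge are kept as two single-end reads
#' when `keep_unmerged` is `TRUE`.
#'
#' @param r1,r2 Paired read `data.frame`s (`id`, `seq`, `qual`) or FASTQ
#'   file paths. Files must be record-synchronized.
#' @param adapter Adapter sequence.
#' @param quality_cutoff,min_length Trimming parameters.
#' @param min_overlap,max_mismatch_density Merge parameters.
#' @param entropy_threshold,k,window Entropy-filter parameters.
#' @param keep_unmerged Keep unmerged pairs as single-end reads.
#' @return An object of class `readproc_result`: list with `reads` (the
#'   surviving processed reads) and `counts` (`data.frame`: `stage`,
#'   `n_in`, `n_out`).
#' @export
run_readproc <- function(r1, r2, adapter = sequencing_adapter(),
                         quality_cutoff = 20, min_length = 30,
                         min_overlap = 10, max_mismatch_density = 0.25,
                         entropy_threshold = 0.7, k = 5, window = 50,
                         keep_unmerged = TRUE) {
  if (is.character(r1)) r1 <- read_fastq(r1)
  if (is.character(r2)) r2 <- read_fastq(r2)
  if (nrow(r1) != nrow(r2) || any(r1$id != r2$id)) {
    stop("paired files are not record-synchronized")
  }
  n_pairs <- nrow(r1)

  t1 <- trim_reads(r1, adapter, quality_cutoff, min_length)
  t2 <- trim_reads(r2, adapter, quality_cutoff, min_length)
  n_trim_out <- nrow(t1$reads) + nrow(t2$reads)

  both <- intersect(t1$reads$id, t2$reads$id)
  only1 <- t1$reads[!(t1$reads$id %in% both), , drop = FALSE]
  only2 <- t2$reads[!(t2$reads$id %in% both), , drop = FALSE]
  m1 <- t1$reads[match(both, t1$reads$id), , drop = FALSE]
  m2 <- t2$reads[match(both, t2$reads$id), , drop = FALSE]

  merged <- vector("list", length(both))
  unmerged_idx <- logical(length(both))
  for (i in seq_along(both)) {
    m <- merge_pair(m1$seq[i], m1$qual[i], m2$seq[i], m2$qual[i],
                    min_overlap, max_mismatch_density)
    if (m$merged) {
      merged[[i]] <- data.frame(id = both[i], seq = m$seq, qual = m$qual,
                                merged = TRUE, stringsAsFactors = FALSE)
    } else {
      unmerged_idx[i] <- TRUE
    }
  }
  merged_df <- do.call(rbind, merged[!unmerged_idx])
  singles <- function(df, suffix) {
    if (!nrow(df)) return(NULL)
    data.frame(id = paste0(df$id, suffix), seq = df$seq, qual = df$qual,
               merged = FALSE, stringsAsFactors = FALSE)
  }
  un <- NULL
  if (keep_unmerged) {
    un <- rbind(
      singles(m1[unmerged_idx, , drop = FALSE], "/1"),
      singles(m2[unmerged_idx, , drop = FALSE], "/2"),
      singles(only1, "/1"), singles(only2, "/2")
    )
  }
  after_merge <- rbind(merged_df, un)
  if (is.null(after_merge)) {
    after_merge <- data.frame(id = character(0), seq = character(0),
                              qual = character(0), merged = logical(0),
                              stringsAsFactors = FALSE)
  }

  dedup <- deduplicate(after_merge)
  final <- entropy_filter(dedup, entropy_threshold, k, window)

  counts <- data.frame(
    stage = c("trim", "merge", "dedup", "entropy"),
    n_in = c(2L * n_pairs, n_trim_out, nrow(after_merge), nrow(dedup)),
    n_out = c(n_trim_out, nrow(after_merge), nrow(dedup), nrow(final)),
    stringsAsFactors = FALSE
  )
  structure(list(reads = final, counts = counts), class = "readproc_result")
}

#' @export
print.readproc_result <- function(x, ...) {
  cat("Read-processing result:", nrow(x$reads), "reads retained\n")
  print(x$counts, row.names = FALSE)
  invisible(x)
}
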