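#' Optimal local alignment score and locations
#'
#' Smith-Waterman local alignment with affine gap costs (a gap of length L
#' costs `gap_open + (L - 1) * gap_extend`); `N` matches nothing. All tied
#' optimal locations are reported via their reference start (and end)
#' coordinates.
#'
#' @param query,reference Sequences over `{A,C,G,T,N}`.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters.
#' @return A list with `score`, and `starts`/`ends` (1-based inclusive
#'   reference coordinates of all optimal-scoring alignments, deduplicated
#'   by start).
#' @export
#' @examples
#' align_local("ACGTACGT", "TTTTACGTACGTTTTT")
align_local <- function(query, reference, match = 1, mismatch = -1,
                        gap_open = -2, gap_extend = -1) {
  if (!nzchar(query)) stop("empty query")
  if (!nzchar(reference)) stop("empty reference")
  r <- .sw_local_cpp(query, reference, match, mismatch, gap_open, gap_extend)
  keep <- !duplicated(r$starts)
  list(score = r$score, starts = r$starts[keep], ends = r$ends[keep])
}

# best score of a query against one reference, both strands
best_score_both_strands <- function(query, reference, ...) {
  f <- align_local(query, reference, ...)
  r <- align_local(revcomp(query), reference, ...)
  max(f$score, r$score)
}

#' Prefilter reads against a focal reference genome
#'
#' A read is retained when its best local alignment score on either strand
#' of any focal record reaches `min_score_fraction` times the read length
#' (score surrogate for "aligned at least once" to the focal genome).
#'
#' @param reads Read `data.frame` (`id`, `seq`, ...) or character vector.
#' @param focal Named character vector of focal reference sequences, or a
#'   FASTA path.
#' @param min_score_fraction Fraction of read length the score must reach.
#' @param ... Scoring parameters passed to [align_local()].
#' @return The retained reads (same type as input), with the best scores in
#'   attribute `scores`.
#' @export
prefilter_focal <- function(reads, focal, min_score_fraction = 0.9, ...) {
  if (is.character(focal) && length(focal) == 1 && file.exists(focal)) {
    focal <- read_fasta(focal)
  }
  if (!length(focal) || any(!nzchar(focal))) stop("empty focal reference")
  seqs <- if (is.data.frame(reads)) reads$seq else reads
  sc <- vapply(seqs, function(s) {
    max(vapply(focal, function(ref) best_score_both_strands(s, ref, ...),
               numeric(1)))
  }, numeric(1), USE.NAMES = FALSE)
  keep <- sc >= min_score_fraction * nchar(seqs)
  out <- if (is.data.frame(reads)) reads[keep, , drop = FALSE] else reads[keep]
  attr(out, "scores") <- sc[keep]
  out
}

#' Best-hit taxonomic assignment of one read
#'
#' Scores the read against every record of a labelled multi-taxon database
#' on both strands and assigns the taxon of the maximal score. Exact score
#' ties between different taxa make the read ambiguous (assigned to none).
#'
#' @param read Read sequence (character scalar).
#' @param db Named character vector of reference sequences; `taxa` gives
#'   the taxon label of each record (defaults to record names).
#' @param taxa Taxon label per database record.
#' @param ... Scoring parameters passed to [align_local()].
#' @return A list (`hit_record`): `taxon` (NA when ambiguous), `best_score`,
#'   `runner_up` (best score in any other taxon), `ambiguous`.
#' @export
best_hit <- function(read, db, taxa = names(db), ...) {
  if (!length(db)) stop("empty taxon database")
  if (is.null(taxa)) stop("db records must carry taxon labels")
  scores <- vapply(db, function(ref) best_score_both_strands(read, ref, ...),
                   numeric(1), USE.NAMES = FALSE)
  by_taxon <- tapply(scores, taxa, max)
  ord <- order(by_taxon, decreasing = TRUE)
  best <- by_taxon[ord[1]]
  runner <- if (length(by_taxon) > 1) by_taxon[ord[2]] else -Inf
  amb <- length(by_taxon) > 1 && abs(best - runner) < 1e-9
  list(taxon = if (amb) NA_character_ else names(by_taxon)[ord[1]],
       best_score = unname(best),
       runner_up = unname(runner),
       ambiguous = amb)
}

#' Best-hit assignment for a set of reads
#'
#' @param reads Read `data.frame` (`id`, `seq`) or character vector.
#' @param db,taxa,... As in [best_hit()].
#' @return `data.frame` with `id`, `seq`, `taxon`, `best_score`,
#'   `runner_up`, `ambiguous`.
#' @export
best_hits <- function(reads, db, taxa = names(db), ...) {
  if (!is.data.frame(reads)) {
    reads <- data.frame(id = paste0("read", seq_along(reads)), seq = reads,
                        stringsAsFactors = FALSE)
  }
  hits <- lapply(reads$seq, best_hit, db = db, taxa = taxa, ...)
  data.frame(
    id = reads$id, seq = reads$seq,
    taxon = vapply(hits, `[[`, character(1), "taxon"),
    best_score = vapply(hits, `[[`, numeric(1), "best_score"),
    runner_up = vapply(hits, `[[`, numeric(1), "runner_up"),
    ambiguous = vapply(hits, `[[`, logical(1), "ambiguous"),
    stringsAsFactors = FALSE
  )
}

#' Per-item taxon presence call
#'
#' A taxon is called present when at least `min_distinct` *distinct*
#' first-hit sequences support it (distinctness by exact sequence identity;
#' ambiguous hits support no taxon).
#'
#' @param hits `data.frame` from [best_hits()] (columns `seq`, `taxon`,
#'   optionally `ambiguous`).
#' @param target_taxa Taxa to report; defaults to all observed plus these.
#' @param min_distinct Presence threshold on distinct first-hit sequences.
#' @param item_id Item identifier carried into the result.
#' @return An object of class `taxon_call`: `data.frame` with `item_id`,
#'   `taxon`, `n_distinct`, `positive`, `threshold`.
#' @export
#' @examples
#' h <- data.frame(seq = c("AA", "AC", "AG", "AT", "CA"),
#'                 taxon = "Theobroma cacao", ambiguous = FALSE)
#' call_presence(h, "Theobroma cacao")
call_presence <- function(hits, target_taxa = NULL, min_distinct = 5,
                          item_id = "item") {
  ok <- hits
  if ("ambiguous" %in% names(ok)) ok <- ok[!ok$ambiguous, , drop = FALSE]
  ok <- ok[!is.na(ok$taxon), , drop = FALSE]
  ok <- ok[!duplicated(ok$seq), , drop = FALSE]
  taxa <- union(unique(ok$taxon), target_taxa)
  counts <- vapply(taxa, function(tx) sum(ok$taxon == tx), integer(1))
  out <- data.frame(
    item_id = item_id, taxon = taxa, n_distinct = unname(counts),
    positive = unname(counts) >= min_distinct, threshold = min_distinct,
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("taxon_call", class(out))
  out
}
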