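#' Unique-mapping filter
#'
#' A fragment is retained only when its optimal local alignment score is
#' reached at exactly one location on the focal genome, pooling both
#' strands. Tied optimal start positions closer than the fragment length
#' are collapsed into one location.
#'
#' @param seq Fragment sequence (as sequenced).
#' @param genome Named character vector of focal chromosome sequences.
#' @param ... Scoring parameters passed to [align_local()].
#' @return A list: `keep` (logical), `n_locations`, `best_score`.
#' @export
unique_mapping_filter <- function(seq, genome, ...) {
  best <- -Inf
  locs <- list()
  for (ch in names(genome)) {
    for (st in c("+", "-")) {
      q <- if (st == "+") seq else revcomp(seq)
      a <- align_local(q, genome[[ch]], ...)
      if (a$score > best + 1e-9) {
        best <- a$score
        locs <- list(data.frame(chrom = ch, strand = st, start = a$starts))
      } else if (a$score > best - 1e-9) {
        locs <- c(locs, list(data.frame(chrom = ch, strand = st,
                                        start = a$starts)))
      }
    }
  }
  locs <- do.call(rbind, locs)
  # cluster starts within one fragment length on the same chrom/strand
  n_loc <- 0L
  for (key in unique(paste(locs$chrom, locs$strand))) {
    s <- sort(locs$start[paste(locs$chrom, locs$strand) == key])
    n_loc <- n_loc + 1L + sum(diff(s) >= nchar(seq))
  }
  list(keep = n_loc == 1L, n_locations = n_loc, best_score = best)
}

#' Extract SNP allele observations from aligned fragments
#'
#' For every panel locus covered by a fragment alignment, records the
#' observed base together with its distance to each read end. Distances and
#' the observed base are computed on the read as sequenced; for
#' reverse-strand fragments the locus allele pair is reverse-complemented
#' into read space alongside.
#'
#' @param fragments `data.frame` with `id`, `chrom`, `start`, `end`
#'   (0-based half-open, reference coordinates), `strand`, `seq` (observed,
#'   read orientation). Alignments are assumed gap-free across the locus.
#' @param loci Panel locus table (`id`, `chrom`, `pos`, `ref`, `alt`) or a
#'   `reference_panel`.
#' @return `data.frame` of class `allele_observations`: `locus_id`,
#'   `fragment_id`, `obs_read`, `obs_genome`, `ref`, `alt`, `pair_read_ref`,
#'   `pair_read_alt`, `d5`, `d3`, `strand`, `status` (all `"kept"`).
#' @export
extract_alleles <- function(fragments, loci) {
  if (inherits(loci, "reference_panel")) loci <- loci$loci
  out <- list()
  for (ch in unique(fragments$chrom)) {
    loc <- loci[loci$chrom == ch, , drop = FALSE]
    if (!nrow(loc)) next
    fr <- fragments[fragments$chrom == ch, , drop = FALSE]
    for (j in seq_len(nrow(fr))) {
      cov <- which(loc$pos >= fr$start[j] & loc$pos < fr$end[j])
      if (!length(cov)) next
      len <- fr$end[j] - fr$start[j]
      fwd <- fr$strand[j] == "+"
      readpos <- if (fwd) loc$pos[cov] - fr$start[j]
                 else fr$end[j] - 1L - loc$pos[cov]
      obs_read <- substring(fr$seq[j], readpos + 1L, readpos + 1L)
      obs_genome <- if (fwd) obs_read else chartr("ACGT", "TGCA", obs_read)
      pr <- if (fwd) loc$ref[cov] else chartr("ACGT", "TGCA", loc$ref[cov])
      pa <- if (fwd) loc$alt[cov] else chartr("ACGT", "TGCA", loc$alt[cov])
      out[[length(out) + 1L]] <- data.frame(
        locus_id = loc$id[cov], fragment_id = fr$id[j],
        obs_read = obs_read, obs_genome = obs_genome,
        ref = loc$ref[cov], alt = loc$alt[cov],
        pair_read_ref = pr, pair_read_alt = pa,
        d5 = readpos, d3 = len - 1L - readpos,
        strand = fr$strand[j], status = "kept",
        stringsAsFactors = FALSE
      )
    }
  }
  obs <- if (length(out)) do.call(rbind, out) else
    data.frame(locus_id = character(0), fragment_id = character(0),
               obs_read = character(0), obs_genome = character(0),
               ref = character(0), alt = character(0),
               pair_read_ref = character(0), pair_read_alt = character(0),
               d5 = integer(0), d3 = integer(0), strand = character(0),
               status = character(0), stringsAsFactors = FALSE)
  rownames(obs) <- NULL
  class(obs) <- c("allele_observations", class(obs))
  obs
}

#' Exclude terminal observations explainable by deamination
#'
#' Drops an observation only when it sits within `end_window` bases of a
#' read end *and* matches the damage signature there: an observed T at a
#' C/T locus near the 5' end, or an observed A at a G/A locus near the 3'
#' end (in read space). All other terminal observations are kept.
#'
#' @param obs `allele_observations` from [extract_alleles()].
#' @param end_window Window size in bases (default 5: distances 0..4).
#' @return The observations with `status` set to `"terminal_damage"` for
#'   dropped rows; subset with `status == "kept"` downstream.
#' @export
terminal_damage_filter <- function(obs, end_window = 5) {
  pair_is <- function(a, b, x, y) (a == x & b == y) | (a == y & b == x)
  drop5 <- obs$d5 < end_window & obs$obs_read == "T" &
    pair_is(obs$pair_read_ref, obs$pair_read_alt, "C", "T")
  drop3 <- obs$d3 < end_window & obs$obs_read == "A" &
    pair_is(obs$pair_read_ref, obs$pair_read_alt, "G", "A")
  obs$status[obs$status == "kept" & (drop5 | drop3)] <- "terminal_damage"
  obs
}

#' Discard observations matching neither panel allele
#'
#' Observed bases outside the locus `{ref, alt}` pair (in genome space) are
#' marked `"allele_mismatch"`; the mismatch fraction among evaluated
#' observations is attached as attribute `mismatch_fraction`.
#'
#' @param obs `allele_observations`.
#' @return The annotated observations.
#' @export
allele_match_filter <- function(obs) {
  consider <- obs$status == "kept"
  bad <- consider & !(obs$obs_genome == obs$ref | obs$obs_genome == obs$alt)
  obs$status[bad] <- "allele_mismatch"
  attr(obs, "mismatch_fraction") <-
    if (any(consider)) sum(bad) / sum(consider) else NA_real_
  obs
}

#' Aggregate filtered observations into an item genotype
#'
#' Per locus with at least one kept observation: dosage 0 when every read
#' shows the reference allele, 1 when every read shows the alternate, and
#' 0.5 when both are observed. Items with fewer than `min_loci` loci are
#' flagged ineligible for ancestry analysis.
#'
#' @param obs `allele_observations` (after filtering).
#' @param item_id Item identifier.
#' @param min_loci Minimum locus count for ancestry eligibility.
#' @return An object of class `item_genotype`: list with `item_id`,
#'   `genotype` (`data.frame`: `locus_id`, `dosage`, `n_ref`, `n_alt`),
#'   `n_loci`, `eligible`.
#' @export
aggregate_genotype <- function(obs, item_id = "item", min_loci = 20) {
  kept <- obs[obs$status == "kept", , drop = FALSE]
  if (nrow(kept)) {
    sp <- split(kept, kept$locus_id)
    rows <- lapply(sp, function(d) {
      n_ref <- sum(d$obs_genome == d$ref)
      n_alt <- sum(d$obs_genome == d$alt)
      dosage <- if (n_alt == 0) 0 else if (n_ref == 0) 1 else 0.5
      data.frame(locus_id = d$locus_id[1], dosage = dosage,
                 n_ref = n_ref, n_alt = n_alt, stringsAsFactors = FALSE)
    })
    geno <- do.call(rbind, rows)
    rownames(geno) <- NULL
  } else {
    geno <- data.frame(locus_id = character(0), dosage = numeric(0),
                       n_ref = integer(0), n_alt = integer(0),
                       stringsAsFactors = FALSE)
  }
  structure(
    list(item_id = item_id, genotype = geno, n_loci = nrow(geno),
         eligible = nrow(geno) >= min_loci, min_loci = min_loci),
    class = "item_genotype"
  )
}

#' @export
print.item_genotype <- function(x, ...) {
  cat(sprintf("Item genotype '%s': %d loci (%s for ancestry analysis)\n",
              x$item_id, x$n_loci,
              if (x$eligible) "eligible" else "INELIGIBLE"))
  invisible(x)
}
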