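#' Position-specific mis-incorporation profile
#'
#' Compares aligned fragments with the reference and tabulates the C-to-T
#' rate at 5' distances 0..`max_pos - 1` and the G-to-A rate at 3'
#' distances, after re-orienting reverse-strand fragments. A rate is `NA`
#' when no reference C (resp. G) was observed at that distance.
#'
#' @param fragments `data.frame` with columns `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `seq` (the observed fragment as
#'   sequenced).
#' @param genome Named character vector of reference chromosome sequences.
#' @param max_pos Number of terminal positions profiled from each end.
#' @return A list (`substitution_profile`): `ct5`, `ga3` (numeric vectors
#'   indexed by 0-based distance), `n_fragments`.
#' @export
substitution_profile <- function(fragments, genome, max_pos = 25) {
  refseq <- substring(genome[fragments$chrom], fragments$start + 1L,
                      fragments$end)
  rev <- fragments$strand == "-"
  refseq[rev] <- revcomp(refseq[rev])
  obs <- explode_seqs(fragments$seq)
  ref <- explode_seqs(unname(refseq))
  stopifnot(length(obs$chars) == length(ref$chars))
  d5 <- obs$pos
  d3 <- obs$len - 1L - obs$pos

  rate_at <- function(d, ref_base, obs_base) {
    vapply(0:(max_pos - 1L), function(i) {
      at <- d == i & ref$chars == ref_base
      n <- sum(at)
      if (n == 0) return(NA_real_)
      sum(obs$chars[at] == obs_base) / n
    }, numeric(1))
  }
  structure(
    list(ct5 = rate_at(d5, "C", "T"),
         ga3 = rate_at(d3, "G", "A"),
         n_fragments = nrow(fragments)),
    class = "substitution_profile"
  )
}

#' Base composition around fragment ends
#'
#' Base frequencies at genomic offsets -2, -1 (outside the fragment) and
#' +0, +1 (inside) around the 5' and 3' termini, in read orientation.
#' Offsets falling outside the contig are skipped (denominator adjusted).
#'
#' @inheritParams substitution_profile
#' @return A list with `comp` (data.frame: `end`, `offset`, `A`, `C`, `G`,
#'   `T`, rows summing to 1), `genome_purine` (background purine fraction),
#'   and `purine_enrichment_5p` (purine fraction at offset -1 of the 5' end
#'   divided by background).
#' @export
end_composition <- function(fragments, genome) {
  bases <- c("A", "C", "G", "T")
  get_base <- function(chrom, gpos, flip) {
    # gpos 0-based genomic; returns base in read orientation; NA off-contig
    L <- nchar(genome[chrom])
    ok <- gpos >= 0 & gpos < L
    b <- rep(NA_character_, length(gpos))
    b[ok] <- substring(genome[chrom[ok]], gpos[ok] + 1L, gpos[ok] + 1L)
    b[ok & flip] <- chartr("ACGT", "TGCA", b[ok & flip])
    b
  }
  rev <- fragments$strand == "-"
  rows <- list()
  for (end in c("5p", "3p")) {
    for (off in c(-2L, -1L, 0L, 1L)) {
      # genomic position of this offset, per fragment, in read orientation
      gpos <- ifelse(xor(rev, end == "3p"),
                     fragments$end - 1L - off,   # read end at genomic right
                     fragments$start + off)
      b <- get_base(fragments$chrom, gpos, rev)
      tab <- table(factor(b, levels = bases))
      tot <- sum(tab)
      rows[[paste(end, off)]] <- data.frame(
        end = end, offset = off, t(as.numeric(tab) / max(tot, 1)),
        stringsAsFactors = FALSE
      )
    }
  }
  comp <- do.call(rbind, rows)
  names(comp)[3:6] <- bases
  rownames(comp) <- NULL

  gchars <- unlist(strsplit(unname(genome), "", fixed = TRUE), use.names = FALSE)
  g_pur <- mean(gchars %in% c("A", "G"))
  at5m1 <- comp[comp$end == "5p" & comp$offset == -1L, bases]
  list(comp = comp, genome_purine = g_pur,
       purine_enrichment_5p = (at5m1$A + at5m1$G) / g_pur)
}

#' Fragment length statistics
#'
#' @param fragments `data.frame` with `start`/`end` columns, or a numeric
#'   vector of lengths.
#' @param probs Quantiles to report.
#' @return A list with `histogram` (named integer table), `mean`, `n`, and
#'   `quantiles`.
#' @export
length_stats <- function(fragments, probs = c(0.05, 0.25, 0.5, 0.75, 0.95)) {
  lens <- if (is.data.frame(fragments)) fragments$end - fragments$start
          else as.numeric(fragments)
  if (!length(lens)) stop("no fragments supplied")
  list(histogram = table(lens), mean = mean(lens), n = length(lens),
       quantiles = quantile(lens, probs))
}

#' Fraction of template molecules amplifiable at given amplicon lengths
#'
#' For each amplicon, the fraction of fragments at least as long as the
#' amplicon, with a predicted quantitative-PCR Ct shift relative to the
#' shortest amplicon of `-log2(fraction ratio)` (perfect doubling assumed).
#'
#' @param lengths Numeric vector of fragment lengths (or a `data.frame`
#'   with `start`/`end`).
#' @param amplicon_lengths Amplicon lengths in bp; defaults to the
#'   mitochondrial/cytochrome assay set 66, 197, 290, 543.
#' @return `data.frame` with `amplicon`, `fraction`, `delta_ct`.
#' @export
#' @examples
#' amplifiable_fraction(rep(100, 10))
amplifiable_fraction <- function(lengths,
                                 amplicon_lengths = c(66, 197, 290, 543)) {
  if (any(amplicon_lengths <= 0)) stop("amplicon lengths must be positive")
  if (is.data.frame(lengths)) lengths <- lengths$end - lengths$start
  frac <- vapply(amplicon_lengths, function(a) mean(lengths >= a), numeric(1))
  ref <- frac[which.min(amplicon_lengths)]
  data.frame(amplicon = amplicon_lengths, fraction = frac,
             delta_ct = ifelse(frac > 0, -log2(frac / ref), Inf))
}

#' Assemble a full damage profile
#'
#' Convenience wrapper combining [substitution_profile()],
#' [end_composition()] and [length_stats()] into the object consumed by
#' [authenticate()].
#'
#' @inheritParams substitution_profile
#' @return An object of class `damage_profile`.
#' @export
damage_profile <- function(fragments, genome, max_pos = 25) {
  sp <- substitution_profile(fragments, genome, max_pos)
  ec <- end_composition(fragments, genome)
  ls <- length_stats(fragments)
  structure(
    list(ct5 = sp$ct5, ga3 = sp$ga3, end_composition = ec$comp,
         genome_purine = ec$genome_purine,
         purine_enrichment_5p = ec$purine_enrichment_5p,
         length_histogram = ls$histogram, mean_length = ls$mean,
         n_fragments = ls$n),
    class = "damage_profile"
  )
}

#' @export
print.damage_profile <- function(x, ...) {
  cat(sprintf("aDNA damage profile over %d fragments\n", x$n_fragments))
  cat(sprintf("  terminal C->T: %.3f  terminal G->A: %.3f\n",
              x$ct5[1], x$ga3[1]))
  cat(sprintf("  mean length: %.2f bp  purine enrichment (5', -1): %.2f\n",
              x$mean_length, x$purine_enrichment_5p))
  invisible(x)
}

#' Estimate deamination parameters from a profile
#'
#' Weighted log-linear fit of the C-to-T rate over the first `n_pos`
#' 5' positions: `log(rate[i]) = log(delta0) + i * log(lambda)`.
#'
#' @param profile A `damage_profile` or `substitution_profile`.
#' @param n_pos Number of 5' positions used in the fit.
#' @return A list with `delta0` and `decay_lambda`.
#' @export
fit_deamination <- function(profile, n_pos = 10) {
  r <- profile$ct5[seq_len(n_pos)]
  i <- seq_len(n_pos) - 1
  ok <- !is.na(r) & r > 0
  if (sum(ok) < 2) stop("too few informative positions to fit")
  fit <- stats::lm(log(r[ok]) ~ i[ok], weights = r[ok])
  list(delta0 = exp(unname(stats::coef(fit)[1])),
       decay_lambda = exp(unname(stats::coef(fit)[2])))
}

#' Authenticity verdict from a damage profile
#'
#' Formalizes the three qualitative ancient-DNA authentication criteria as
#' a decision rule: elevated terminal C-to-T relative to the fragment
#' interior, purine enrichment just 5' of fragment starts, and short mean
#' fragment length.
#'
#' @param profile A `damage_profile`.
#' @param min_terminal_ratio Minimum ratio of the terminal C-to-T rate to
#'   the median interior rate (positions 10..24).
#' @param min_purine_enrichment Minimum purine enrichment at offset -1.
#' @param max_mean_length Maximum mean fragment length (bp).
#' @return An object of class `auth_verdict`: `authentic`, `evidence`
#'   (named numeric), `thresholds`, `inconclusive` (criteria that could not
#'   be evaluated).
#' @export
authenticate <- function(profile, min_terminal_ratio = 3,
                         min_purine_enrichment = 1.1,
                         max_mean_length = 120) {
  interior <- profile$ct5[11:min(25, length(profile$ct5))]
  interior_med <- median(interior, na.rm = TRUE)
  term <- profile$ct5[1]
  ratio <- if (is.na(term) || is.na(interior_med)) NA_real_
           else if (interior_med > 0) term / interior_med
           else if (term > 0) Inf
           else NA_real_   # no substitutions anywhere: elevation undefined
  evid <- c(terminal_ct_ratio = ratio,
            purine_enrichment = profile$purine_enrichment_5p,
            mean_length = profile$mean_length)
  inconclusive <- names(evid)[is.na(evid)]
  checks <- c(
    terminal_ct_ratio = !is.na(ratio) && ratio >= min_terminal_ratio,
    purine_enrichment = !is.na(evid[2]) && evid[2] >= min_purine_enrichment,
    mean_length = !is.na(evid[3]) && evid[3] <= max_mean_length
  )
  structure(
    list(authentic = all(checks) && !length(inconclusive),
         evidence = evid,
         checks = checks,
         thresholds = c(min_terminal_ratio = min_terminal_ratio,
                        min_purine_enrichment = min_purine_enrichment,
                        max_mean_length = max_mean_length),
         inconclusive = inconclusive),
    class = "auth_verdict"
  )
}

#' @export
print.auth_verdict <- function(x, ...) {
  cat("aDNA authentication:",
      if (x$authentic) "AUTHENTIC" else "not authenticated", "\n")
  for (nm in names(x$evidence)) {
    cat(sprintf("  %-20s %8.3f  [%s]\n", nm, x$evidence[[nm]],
                if (nm %in% x$inconclusive) "inconclusive"
                else if (isTRUE(x$checks[[nm]])) "pass" else "fail"))
  }
  invisible(x)
}
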