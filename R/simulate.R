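#' Post-mortem damage model for simulated ancient DNA
#'
#' Parameters of the generative model for degraded DNA fragments: terminal
#' cytosine deamination decaying geometrically into the fragment, a
#' right-skewed fragment-length law, purine-biased break points
#' (depurination), and a contamination fraction for non-target reads.
#'
#' @param delta0 Deamination probability at the terminal base, in `[0, 1]`.
#'   Default 0.05, matching terminal C-to-T rates of 4-5.5 percent observed
#'   in ceramic-residue cacao libraries.
#' @param decay_lambda Geometric decay per base of the deamination
#'   probability, in `(0, 1]`. A cytosine at 5' distance `i` is read as T
#'   with probability `delta0 * decay_lambda^i` (G-to-A mirrored at 3').
#' @param length_mean Mean fragment length in bp after truncation to
#'   `[30, L]`. Default 81.65 bp.
#' @param length_shape Log-scale standard deviation of the log-normal
#'   fragment-length law.
#' @param depurination_bias Odds multiplier (>= 1) for a purine (A/G) at the
#'   genomic position immediately 5' of a fragment start.
#' @param contamination_fraction Proportion of non-target read pairs, in
#'   `[0, 1)`.
#' @return An object of class `damage_model`.
#' @export
#' @examples
#' damage_model()
damage_model <- function(delta0 = 0.05, decay_lambda = 0.7,
                         length_mean = 81.65, length_shape = 0.35,
                         depurination_bias = 4,
                         contamination_fraction = 0) {
  if (delta0 < 0 || delta0 > 1) stop("delta0 must be in [0, 1]")
  if (decay_lambda <= 0 || decay_lambda > 1) stop("decay_lambda must be in (0, 1]")
  if (length_mean <= 30) stop("length_mean must exceed 30 bp")
  if (length_shape <= 0) stop("length_shape must be positive")
  if (depurination_bias < 1) stop("depurination_bias must be >= 1")
  if (contamination_fraction < 0 || contamination_fraction >= 1) {
    stop("contamination_fraction must be in [0, 1)")
  }
  structure(
    list(delta0 = delta0, decay_lambda = decay_lambda,
         length_mean = length_mean, length_shape = length_shape,
         depurination_bias = depurination_bias,
         contamination_fraction = contamination_fraction),
    class = "damage_model"
  )
}

#' @export
print.damage_model <- function(x, ...) {
  cat(sprintf(
    "aDNA damage model: delta0=%.3g lambda=%.3g length=%.4g bp (sdlog %.3g) purine bias=%.3g contamination=%.3g\n",
    x$delta0, x$decay_lambda, x$length_mean, x$length_shape,
    x$depurination_bias, x$contamination_fraction))
  invisible(x)
}

# meanlog of a log-normal with sdlog s whose [lo, hi]-truncated mean equals m
trunc_lnorm_meanlog <- function(m, s, lo = 30, hi = Inf) {
  tmean <- function(mu) {
    zlo <- (log(lo) - mu) / s
    zhi <- if (is.finite(hi)) (log(hi) - mu) / s else Inf
    num <- pnorm(zhi - s) - pnorm(zlo - s)
    den <- pnorm(zhi) - pnorm(zlo)
    exp(mu + s^2 / 2) * num / den
  }
  uniroot(function(mu) tmean(mu) - m,
          lower = log(lo), upper = log(m) + 3, tol = 1e-10)$root
}

#' Generate a random synthetic genome
#'
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param gc GC content in `(0, 1)`.
#' @param seed Integer seed.
#' @return Named character vector of chromosome sequences.
#' @export
synthetic_genome <- function(chrom_lengths, gc = 0.37, seed = NULL) {
  with_seed(seed, {
    vapply(chrom_lengths, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                   prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
            collapse = "")
    }, character(1))
  })
}

#' Genome carrying the panel reference alleles
#'
#' Builds a random genome sized to `panel$chrom_lengths` and writes the
#' reference allele of every panel locus at its position, so fragments drawn
#' from the genome carry the ref allele unless a genotype says otherwise.
#'
#' @param panel A `reference_panel` built by [build_panel()].
#' @param gc GC content of the background sequence.
#' @param seed Integer seed.
#' @return Named character vector of chromosome sequences.
#' @export
panel_genome <- function(panel, gc = 0.37, seed = NULL) {
  if (is.null(panel$chrom_lengths)) stop("panel carries no chromosome lengths")
  g <- synthetic_genome(panel$chrom_lengths, gc = gc, seed = seed)
  for (i in seq_len(nrow(panel$loci))) {
    ch <- panel$loci$chrom[i]
    p <- panel$loci$pos[i] + 1L  # to 1-based string index
    substr(g[ch], p, p) <- panel$loci$ref[i]
  }
  g
}

#' Fragment a genome with depurination-biased break points
#'
#' Fragment lengths follow a log-normal truncated to `[30, L]` whose mean is
#' calibrated to `model$length_mean`; start positions are weighted so the
#' genomic base immediately 5' of the start is a purine with odds multiplied
#' by `model$depurination_bias`.
#'
#' @param sequence A single chromosome sequence (character scalar).
#' @param model A [damage_model()].
#' @param n_fragments Number of fragments to draw (>= 1).
#' @param strand Strand the fragments will be sequenced from; the
#'   depurination bias is applied at the 5' flank of that strand.
#' @param seed Integer seed.
#' @return `data.frame` with 0-based half-open `start`, `end` columns.
#' @export
fragment_genome <- function(sequence, model, n_fragments, strand = "+",
                            seed = NULL) {
  L <- nchar(sequence)
  if (L < 30) stop("sequence must be at least 30 bp")
  if (L <= model$length_mean) stop("sequence must be longer than the mean fragment length")
  if (n_fragments < 1) stop("n_fragments must be >= 1")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")

  mu <- trunc_lnorm_meanlog(model$length_mean, model$length_shape, 30, L)
  base <- strsplit(sequence, "", fixed = TRUE)[[1]]
  # The break-point bias acts at the 5' flank of the sequenced strand:
  # for "+" fragments the genomic base at start-1 is a purine with boosted
  # odds; for "-" fragments the flank sits at the genomic *end* position and
  # is a purine on the minus strand iff the genomic base is a pyrimidine.
  if (strand == "+") {
    w <- rep(1, L)  # w[i+1] = weight of 0-based start position i
    purine_prev <- c(FALSE, base[-L] %in% c("A", "G"))  # position 0: no flank
    w[purine_prev] <- model$depurination_bias
  } else {
    w <- rep(1, L)  # w[e] = weight of exclusive end position e (1..L)
    flank_pyrimidine <- c(base[-1] %in% c("C", "T"), FALSE)  # end L: no flank
    w[flank_pyrimidine] <- model$depurination_bias
  }
  cw <- cumsum(w)
  tot <- cw[L]

  with_seed(seed, {
    draw_lengths <- function(n) {
      x <- round(rlnorm(n, mu, model$length_shape))
      bad <- x < 30 | x > L
      while (any(bad)) {
        x[bad] <- round(rlnorm(sum(bad), mu, model$length_shape))
        bad <- x < 30 | x > L
      }
      as.integer(x)
    }
    len <- draw_lengths(n_fragments)
    anchor <- integer(n_fragments)
    todo <- seq_len(n_fragments)
    while (length(todo)) {
      u <- runif(length(todo)) * tot
      a <- findInterval(u, cw) + 1L  # index into w (1..L)
      ok <- if (strand == "+") (a - 1L) + len[todo] <= L else a - len[todo] >= 0L
      anchor[todo[ok]] <- a[ok]
      todo <- todo[!ok]
    }
    if (strand == "+") {
      start <- anchor - 1L
      data.frame(start = start, end = start + len)
    } else {
      data.frame(start = anchor - len, end = anchor)
    }
  })
}

#' Apply terminal deamination damage to fragment sequences
#'
#' A cytosine at 0-based 5' distance `i` becomes T with probability
#' `delta0 * decay_lambda^i`; a guanine at 3' distance `j` becomes A with
#' probability `delta0 * decay_lambda^j`. No other changes are made.
#'
#' @param sequences Character vector of fragment sequences (as oriented for
#'   sequencing).
#' @param model A [damage_model()].
#' @param seed Integer seed.
#' @return A list with `sequences` (damaged) and `truth`, a `data.frame`
#'   with columns `fragment` (index into `sequences`), `pos` (0-based read
#'   position), `from`, `to`.
#' @export
#' @examples
#' apply_damage("CCCGGG", damage_model(delta0 = 1, decay_lambda = 1), seed = 1)
apply_damage <- function(sequences, model, seed = NULL) {
  if (length(sequences) == 0) {
    return(list(sequences = character(0),
                truth = data.frame(fragment = integer(0), pos = integer(0),
                                   from = character(0), to = character(0))))
  }
  ex <- explode_seqs(sequences)
  d5 <- ex$pos
  d3 <- ex$len - 1L - ex$pos
  p <- numeric(length(ex$chars))
  isC <- ex$chars == "C"
  isG <- ex$chars == "G"
  p[isC] <- model$delta0 * model$decay_lambda^d5[isC]
  p[isG] <- model$delta0 * model$decay_lambda^d3[isG]
  with_seed(seed, {
    hit <- runif(length(p)) < p
    from <- ex$chars[hit]
    newchars <- ex$chars
    newchars[hit & isC] <- "T"
    newchars[hit & isG] <- "A"
    list(
      sequences = implode_seqs(newchars, ex$frag, length(sequences)),
      truth = data.frame(
        fragment = ex$frag[hit], pos = ex$pos[hit],
        from = from, to = ifelse(from == "C", "T", "A"),
        stringsAsFactors = FALSE
      )
    )
  })
}

#' Adapter sequence appended when reads run through short fragments
#'
#' @return A fixed 33-mer adapter string.
#' @export
sequencing_adapter <- function() "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA"

#' Simulate a paired-end aDNA sequencing library for one item
#'
#' Draws damaged fragments from a target genome carrying an admixed genotype
#' at the panel loci, mixes in contaminant fragments from non-target genomes
#' at the model's contamination fraction, and renders 2 x `read_length`
#' paired reads that run through into a fixed adapter when the fragment is
#' shorter than the read.
#'
#' @param panel A `reference_panel`.
#' @param genome Named character vector of target chromosome sequences
#'   (see [panel_genome()]).
#' @param model A [damage_model()].
#' @param n_pairs Number of read pairs.
#' @param q Admixture proportions used to draw the item's genotype
#'   (ignored when `genotype` is supplied).
#' @param genotype Optional pre-drawn dosage vector (0/1/2) over panel loci.
#' @param contaminants Named character vector of contaminant genome
#'   sequences; names are taxon labels. Required when the model's
#'   contamination fraction is positive.
#' @param target_taxon Taxon label for target reads.
#' @param read_length Read length (default 150, paired).
#' @param base_quality Constant Phred quality for simulated bases.
#' @param item_id Item identifier used in read names.
#' @param seed Integer seed.
#' @return A list with `r1`, `r2` (read `data.frame`s with `id`, `seq`,
#'   `qual`), `truth` (one row per pair: `id`, `taxon`, `chrom`, `start`,
#'   `end`, `strand`, `length`, `n_damage`), `genotype`, and `fragments`
#'   (the damaged fragment sequences as oriented).
#' @export
simulate_library <- function(panel, genome, model, n_pairs,
                             q = NULL, genotype = NULL,
                             contaminants = NULL,
                             target_taxon = "Theobroma cacao",
                             read_length = 150, base_quality = 37,
                             item_id = "item", seed = NULL) {
  if (model$contamination_fraction > 0 && is.null(contaminants)) {
    stop("contaminants must be supplied when contamination_fraction > 0")
  }
  with_seed(seed, {
    if (is.null(genotype)) {
      if (is.null(q)) q <- c(1, rep(0, length(panel$groups) - 1))
      genotype <- sample_admixed_genotype(panel, q)
    }

    is_contam <- runif(n_pairs) < model$contamination_fraction
    n_t <- sum(!is_contam)
    n_c <- sum(is_contam)
    strand <- sample(c("+", "-"), n_pairs, replace = TRUE)

    frag_seq <- character(n_pairs)
    meta <- data.frame(
      id = sprintf("%s_read%06d", item_id, seq_len(n_pairs)),
      taxon = ifelse(is_contam, NA_character_, target_taxon),
      chrom = NA_character_, start = NA_integer_, end = NA_integer_,
      strand = strand, stringsAsFactors = FALSE
    )

    draw_from_genome <- function(gnm, n, strands) {
      chroms <- names(gnm)
      lens <- nchar(gnm)
      ch <- sample(chroms, n, replace = TRUE, prob = lens)
      out <- data.frame(chrom = ch, start = NA_integer_, end = NA_integer_,
                        stringsAsFactors = FALSE)
      for (c0 in unique(ch)) {
        for (st in c("+", "-")) {
          i <- which(ch == c0 & strands == st)
          if (!length(i)) next
          fr <- fragment_genome(gnm[[c0]], model, length(i), strand = st)
          out$start[i] <- fr$start
          out$end[i] <- fr$end
        }
      }
      out$seq <- substring(gnm[out$chrom], out$start + 1L, out$end)
      out
    }

    if (n_t > 0) {
      tf <- draw_from_genome(genome, n_t, strand[!is_contam])
      # impose the item's alleles at panel loci covered by each fragment
      for (c0 in unique(tf$chrom)) {
        loc <- panel$loci[panel$loci$chrom == c0, , drop = FALSE]
        if (!nrow(loc)) next
        fi <- which(tf$chrom == c0)
        for (j in fi) {
          cov <- which(loc$pos >= tf$start[j] & loc$pos < tf$end[j])
          for (l in cov) {
            d <- genotype[[loc$id[l]]]
            allele <- if (d == 0L) loc$ref[l]
                      else if (d == 2L) loc$alt[l]
                      else if (runif(1) < 0.5) loc$alt[l] else loc$ref[l]
            rp <- loc$pos[l] - tf$start[j] + 1L
            substr(tf$seq[j], rp, rp) <- allele
          }
        }
      }
      idx <- which(!is_contam)
      meta$chrom[idx] <- tf$chrom
      meta$start[idx] <- tf$start
      meta$end[idx] <- tf$end
      frag_seq[idx] <- tf$seq
    }
    if (n_c > 0) {
      taxa <- names(contaminants)
      pick <- sample(taxa, n_c, replace = TRUE)
      idx <- which(is_contam)
      for (tx in unique(pick)) {
        i <- idx[pick == tx]
        cf <- draw_from_genome(contaminants[tx], length(i), strand[i])
        meta$taxon[i] <- tx
        meta$chrom[i] <- cf$chrom
        meta$start[i] <- cf$start
        meta$end[i] <- cf$end
        frag_seq[i] <- cf$seq
      }
    }

    oriented <- ifelse(strand == "+", frag_seq, revcomp(frag_seq))

    dm <- apply_damage(oriented, model)
    damaged <- dm$sequences
    n_dam <- tabulate(dm$truth$fragment, nbins = n_pairs)

    adapter <- sequencing_adapter()
    render_read <- function(insert) {
      raw <- paste0(insert, adapter,
                    strrep("A", max(0, read_length - nchar(insert) - nchar(adapter))))
      substr(raw, 1, read_length)
    }
    r1seq <- vapply(damaged, render_read, character(1), USE.NAMES = FALSE)
    r2seq <- vapply(revcomp(damaged), render_read, character(1), USE.NAMES = FALSE)
    q1 <- strrep(rawToChar(as.raw(base_quality + 33L)), nchar(r1seq))

    meta$length <- meta$end - meta$start
    meta$n_damage <- n_dam
    list(
      r1 = data.frame(id = meta$id, seq = r1seq, qual = q1,
                      stringsAsFactors = FALSE),
      r2 = data.frame(id = meta$id, seq = r2seq, qual = q1,
                      stringsAsFactors = FALSE),
      truth = meta,
      genotype = genotype,
      fragments = damaged
    )
  })
}

#' Simulate methylxanthine measurements with a contamination background
#'
#' Negative items draw low-level background amounts (log-normal, truncated
#' below 200 pg/sample, emulating ambient museum contamination); positive
#' items draw high amounts (log-normal, truncated above 700 pg/sample).
#' Theobromine is always elevated in positive items; caffeine and
#' theophylline are elevated with fixed conditional probabilities
#' approximating their relative abundance in cacao.
#'
#' @param n_items Number of items (default 326, the survey scale).
#' @param positive_fraction Fraction of truly positive items.
#' @param background_scale Median background amount in pg/sample (< 200).
#' @param positive_scale Median positive amount in pg/sample (> 700).
#' @param p_caffeine,p_theophylline Probability that a positive item is also
#'   elevated for caffeine / theophylline.
#' @param seed Integer seed.
#' @return A list with `measurements` (`data.frame`: `item_id`,
#'   `theobromine`, `theophylline`, `caffeine`, pg/sample) and `truth`
#'   (`item_id`, `positive`). An attribute `overlap_warning` is set when the
#'   two scales are not separated.
#' @export
simulate_methylxanthine <- function(n_items = 326, positive_fraction = 0.37,
                                    background_scale = 50,
                                    positive_scale = 5000,
                                    p_caffeine = 0.85, p_theophylline = 0.25,
                                    seed = NULL) {
  if (background_scale <= 0 || positive_scale <= 0) stop("scales must be positive")
  if (background_scale >= 200) stop("background_scale must be below 200 pg/sample")
  if (positive_scale <= 700) stop("positive_scale must exceed 700 pg/sample")
  overlap <- positive_scale / background_scale < 10

  with_seed(seed, {
    rtrunc_lnorm <- function(n, meanlog, sdlog, lo = 0, hi = Inf) {
      x <- rlnorm(n, meanlog, sdlog)
      bad <- x <= lo | x >= hi
      while (any(bad)) {
        x[bad] <- rlnorm(sum(bad), meanlog, sdlog)
        bad <- x <= lo | x >= hi
      }
      x
    }
    bg <- function(n) rtrunc_lnorm(n, log(background_scale), 0.6, hi = 200)
    fg <- function(n) rtrunc_lnorm(n, log(positive_scale), 0.8, lo = 700)

    positive <- runif(n_items) < positive_fraction
    n <- n_items
    theobromine <- bg(n); caffeine <- bg(n); theophylline <- bg(n)
    np <- sum(positive)
    if (np > 0) {
      theobromine[positive] <- fg(np)
      caf_up <- positive & runif(n) < p_caffeine
      teo_up <- positive & runif(n) < p_theophylline
      caffeine[caf_up] <- fg(sum(caf_up))
      theophylline[teo_up] <- fg(sum(teo_up))
    }
    out <- list(
      measurements = data.frame(
        item_id = sprintf("P%03d", seq_len(n)),
        theobromine = theobromine, theophylline = theophylline,
        caffeine = caffeine, stringsAsFactors = FALSE
      ),
      truth = data.frame(item_id = sprintf("P%03d", seq_len(n)),
                         positive = positive, stringsAsFactors = FALSE)
    )
    attr(out, "overlap_warning") <- overlap
    out
  })
}
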