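#' Reference design of the modern cacao collection
#'
#' The 76-accession modern reference collection spans the 11 named
#' *Theobroma cacao* genetic groups. This helper returns the group labels and
#' per-group accession counts used as the default panel design.
#'
#' @return A list with elements `groups` (character) and `sizes` (integer),
#'   totalling 76 accessions.
#' @export
#' @examples
#' d <- cacao_reference_design()
#' sum(d$sizes)
cacao_reference_design <- function() {
  list(
    groups = c("Criollo", "Caqueta", "Curaray", "Nacional", "Purus",
               "Contamana", "Maranon", "Iquitos", "Amelonado", "Nanay",
               "Guiana"),
    sizes = c(8L, 8L, 8L, 8L, 7L, 4L, 7L, 7L, 4L, 8L, 7L)
  )
}

#' Build a synthetic SNP reference panel
#'
#' Generates biallelic SNP loci with hierarchically structured group allele
#' frequencies and labelled accession genotypes. Ancestral alternate-allele
#' frequencies are drawn from Uniform(0.05, 0.95); group-specific frequencies
#' follow a Balding-Nichols Beta distribution with FST equal to `divergence`;
#' accession genotypes are binomial draws from their group frequency.
#'
#' @param n_groups Number of genetic groups (>= 2).
#' @param n_loci Number of SNP loci (>= 20).
#' @param divergence FST-like differentiation between groups, in (0, 1).
#' @param group_sizes Integer vector of accessions per group; defaults to 8
#'   per group, or to the 76-accession design of [cacao_reference_design()]
#'   when `n_groups` is 11.
#' @param group_labels Optional group names.
#' @param n_chrom Number of synthetic chromosomes loci are spread over.
#' @param chrom_length Length (bp) of each synthetic chromosome.
#' @param seed Integer seed for reproducibility.
#' @return An object of class `reference_panel`: a list with elements
#'   `loci` (data.frame: `id`, `chrom`, `pos` 0-based, `ref`, `alt`),
#'   `groups`, `freqs` (loci x groups alternate-allele frequencies),
#'   `accessions` (loci x accessions dosage matrix, 0/1/2),
#'   `acc_groups` (group label per accession), and `chrom_lengths`.
#' @export
#' @examples
#' p <- build_panel(n_groups = 3, n_loci = 50, divergence = 0.15, seed = 1)
#' dim(p$freqs)
build_panel <- function(n_groups, n_loci, divergence,
                        group_sizes = NULL, group_labels = NULL,
                        n_chrom = 10, chrom_length = 1e5, seed = NULL) {
  if (n_groups < 2) stop("n_groups must be >= 2")
  if (n_loci < 20) stop("n_loci must be >= 20")
  if (divergence <= 0 || divergence >= 1) stop("divergence must be in (0, 1)")
  if (is.null(group_sizes)) {
    group_sizes <- if (n_groups == 11) cacao_reference_design()$sizes
                   else rep(8L, n_groups)
  }
  if (length(group_sizes) != n_groups || any(group_sizes < 1)) {
    stop("group_sizes must give a positive size for each group")
  }
  if (is.null(group_labels)) {
    group_labels <- if (n_groups == 11) cacao_reference_design()$groups
                    else paste0("G", seq_len(n_groups))
  }
  n_chrom <- min(n_chrom, n_loci)

  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    chrom <- paste0("chr", sample.int(n_chrom, n_loci, replace = TRUE))
    pos <- integer(n_loci)
    for (ch in unique(chrom)) {
      i <- chrom == ch
      pos[i] <- sort(sample.int(chrom_length - 2L, sum(i)))  # keep off edges
    }
    ref <- sample(bases, n_loci, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))

    p_anc <- runif(n_loci, 0.05, 0.95)
    f <- divergence
    shape_scale <- (1 - f) / f
    freqs <- vapply(seq_len(n_groups), function(k) {
      rbeta(n_loci, p_anc * shape_scale, (1 - p_anc) * shape_scale)
    }, numeric(n_loci))
    colnames(freqs) <- group_labels

    acc_groups <- rep(group_labels, group_sizes)
    acc_ids <- unlist(lapply(seq_len(n_groups), function(k) {
      paste0(group_labels[k], "_", seq_len(group_sizes[k]))
    }))
    accessions <- vapply(seq_along(acc_ids), function(a) {
      rbinom(n_loci, 2L, freqs[, acc_groups[a]])
    }, integer(n_loci))
    colnames(accessions) <- acc_ids

    loci <- data.frame(
      id = sprintf("L%05d", seq_len(n_loci)),
      chrom = chrom, pos = pos, ref = unname(ref), alt = unname(alt),
      stringsAsFactors = FALSE
    )
    rownames(freqs) <- loci$id
    rownames(accessions) <- loci$id

    structure(
      list(loci = loci, groups = group_labels, freqs = freqs,
           accessions = accessions, acc_groups = acc_groups,
           chrom_lengths = stats::setNames(rep(chrom_length, n_chrom),
                                           paste0("chr", seq_len(n_chrom)))),
      class = "reference_panel"
    )
  })
}

#' @export
print.reference_panel <- function(x, ...) {
  cat("Reference SNP panel:", nrow(x$loci), "loci,",
      length(x$groups), "groups,", ncol(x$accessions), "accessions\n")
  cat("Groups:", paste(x$groups, collapse = ", "), "\n")
  invisible(x)
}

#' Empirical group allele frequencies from accession genotypes
#'
#' @param panel A `reference_panel`, or a dosage matrix (loci x accessions)
#'   together with `acc_groups`.
#' @param acc_groups Group label per accession column (ignored for panels).
#' @return Matrix of alternate-allele frequencies, loci x groups.
#' @export
group_freqs_from_accessions <- function(panel, acc_groups = NULL) {
  if (inherits(panel, "reference_panel")) {
    geno <- panel$accessions
    acc_groups <- panel$acc_groups
  } else {
    geno <- panel
  }
  groups <- unique(acc_groups)
  out <- vapply(groups, function(g) {
    rowMeans(geno[, acc_groups == g, drop = FALSE], na.rm = TRUE) / 2
  }, numeric(nrow(geno)))
  colnames(out) <- groups
  out
}

#' Sample an admixed genotype from panel group frequencies
#'
#' Each of the two allele copies at a locus comes from group *k* with
#' probability `q[k]`, then is the alternate allele with probability equal to
#' that group's frequency at the locus.
#'
#' @param panel A `reference_panel` (or a loci x groups frequency matrix).
#' @param q Membership proportions over groups; non-negative, summing to 1.
#' @param seed Integer seed.
#' @return Integer vector of alternate-allele dosages (0/1/2), named by locus.
#' @export
#' @examples
#' p <- build_panel(3, 50, 0.15, seed = 1)
#' g <- sample_admixed_genotype(p, c(1, 0, 0), seed = 2)
sample_admixed_genotype <- function(panel, q, seed = NULL) {
  freqs <- if (inherits(panel, "reference_panel")) panel$freqs else panel
  if (length(q) != ncol(freqs)) stop("q must have one entry per group")
  if (any(q < 0) || abs(sum(q) - 1) > 1e-9) {
    stop("q must be non-negative and sum to 1")
  }
  n_loci <- nrow(freqs)
  with_seed(seed, {
    # group of origin for each of the 2*n_loci allele copies
    grp <- sample.int(length(q), 2L * n_loci, replace = TRUE, prob = q)
    p <- freqs[cbind(rep(seq_len(n_loci), 2L), grp)]
    alleles <- rbinom(2L * n_loci, 1L, p)
    dosage <- alleles[seq_len(n_loci)] + alleles[n_loci + seq_len(n_loci)]
    stats::setNames(as.integer(dosage), rownames(freqs))
  })
}

#' Write a reference panel to TSV
#'
#' Columns: `locus_id`, `chrom`, `pos` (1-based in the file), `ref`, `alt`,
#' one `freq_<group>` column per group, then one genotype column per
#' accession named `<group>__<accession>` (dosage 0/1/2, `.` for missing).
#'
#' @param panel A `reference_panel`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  geno <- panel$accessions
  geno_chr <- apply(geno, 2, function(v) ifelse(is.na(v), ".", as.character(v)))
  df <- data.frame(
    locus_id = panel$loci$id, chrom = panel$loci$chrom,
    pos = panel$loci$pos + 1L, ref = panel$loci$ref, alt = panel$loci$alt,
    stringsAsFactors = FALSE
  )
  fr <- as.data.frame(panel$freqs)
  names(fr) <- paste0("freq_", colnames(panel$freqs))
  gn <- as.data.frame(geno_chr, stringsAsFactors = FALSE)
  names(gn) <- paste0(panel$acc_groups, "__", colnames(geno))
  out <- cbind(df, fr, gn)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a reference panel from TSV
#'
#' @param path TSV written by [write_panel()].
#' @return A `reference_panel`.
#' @export
read_panel <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  fcols <- grep("^freq_", names(df), value = TRUE)
  gcols <- grep("__", names(df), value = TRUE, fixed = TRUE)
  loci <- data.frame(
    id = df$locus_id, chrom = df$chrom, pos = df$pos - 1L,
    ref = df$ref, alt = df$alt, stringsAsFactors = FALSE
  )
  freqs <- as.matrix(df[, fcols, drop = FALSE])
  colnames(freqs) <- sub("^freq_", "", fcols)
  rownames(freqs) <- loci$id
  geno <- as.matrix(df[, gcols, drop = FALSE])
  geno[geno == "."] <- NA
  storage.mode(geno) <- "integer"
  acc_groups <- sub("__.*$", "", gcols)
  colnames(geno) <- sub("^.*?__", "", gcols)
  rownames(geno) <- loci$id
  structure(
    list(loci = loci, groups = colnames(freqs), freqs = freqs,
         accessions = geno, acc_groups = acc_groups,
         chrom_lengths = NULL),
    class = "reference_panel"
  )
}
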