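#' Supervised admixture estimation by EM
#'
#' Maximum-likelihood membership proportions `q` of an item against labelled
#' group allele frequencies: each allele copy is modelled as drawn from
#' group *k* with probability `q_k`, then Bernoulli with that group's
#' frequency. The EM iteration computes per-copy group responsibilities and
#' averages them; the log-likelihood is concave in `q`, so EM converges to
#' the global optimum regardless of initialization and never decreases.
#'
#' @param genotype An `item_genotype`, or a named numeric vector of
#'   alternate-allele dosages on the 0/0.5/1 scale (fraction of the two
#'   copies that are alternate), named by locus id.
#' @param panel A `reference_panel`, or a loci x groups frequency matrix
#'   with rownames matching the genotype names.
#' @param group_sizes Accessions per group, used for the frequency clipping
#'   bound `eps_k = 1/(2 n_k + 1)` that keeps private alleles from
#'   producing infinite log-likelihoods. Default taken from the panel.
#' @param init Optional starting value for `q` (defaults to uniform); the
#'   optimum is unique, so this affects only the iteration path.
#' @param tol Convergence tolerance on the log-likelihood increase.
#' @param max_iter Maximum EM iterations.
#' @param min_loci Minimum locus count (default 20).
#' @param ambiguity_tol Log-likelihood change below which swapping two
#'   groups' proportions flags the pair as ambiguous.
#' @return An object of class `ancestry_estimate`: `q` (named, sums to 1),
#'   `loglik`, `ll_trace`, `n_loci`, `n_iter`, `converged`,
#'   `ambiguous_pairs` (`data.frame`: `group1`, `group2`, `delta_ll`).
#' @export
#' @examples
#' p <- build_panel(3, 100, 0.2, seed = 1)
#' g <- sample_admixed_genotype(p, c(1, 0, 0), seed = 2)
#' est <- admixture_em(g / 2, p)
#' est$q
admixture_em <- function(genotype, panel, group_sizes = NULL, init = NULL,
                         tol = 1e-8, max_iter = 1000, min_loci = 20,
                         ambiguity_tol = 2) {
  if (inherits(genotype, "item_genotype")) {
    g <- stats::setNames(genotype$genotype$dosage, genotype$genotype$locus_id)
  } else {
    g <- genotype
  }
  if (inherits(panel, "reference_panel")) {
    freqs <- panel$freqs
    if (is.null(group_sizes)) {
      group_sizes <- as.vector(table(panel$acc_groups)[colnames(freqs)])
    }
  } else {
    freqs <- panel
  }
  common <- intersect(names(g), rownames(freqs))
  if (length(common) == 0 && length(g) == nrow(freqs) && is.null(names(g))) {
    common <- rownames(freqs)
    names(g) <- rownames(freqs)
  }
  g <- g[common]
  g <- g[!is.na(g)]
  n_loci <- length(g)
  if (n_loci == 0) stop("no usable loci")
  if (n_loci < min_loci) {
    stop("item has ", n_loci, " loci; a minimum of ", min_loci,
         " SNP markers is required for ancestry analysis")
  }
  p <- freqs[names(g), , drop = FALSE]
  K <- ncol(p)
  if (is.null(group_sizes)) group_sizes <- rep(500, K)
  eps <- 1 / (2 * group_sizes + 1)
  # clip columnwise to [eps_k, 1 - eps_k]
  p <- sweep(p, 2, eps, pmax)
  p <- sweep(p, 2, 1 - eps, pmin)

  a <- round(2 * g)            # alternate-allele copies per locus (0/1/2)
  r <- 2 - a                   # reference copies
  ll_fun <- function(q) {
    sum(a * log(as.vector(p %*% q)) + r * log(as.vector((1 - p) %*% q)))
  }
  q <- if (is.null(init)) rep(1 / K, K) else {
    stopifnot(length(init) == K, all(init >= 0))
    init / sum(init)
  }
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    mix_alt <- as.vector(p %*% q)        # P(alt copy) per locus
    mix_ref <- as.vector((1 - p) %*% q)
    resp_alt <- sweep(p, 2, q, `*`) / mix_alt
    resp_ref <- sweep(1 - p, 2, q, `*`) / mix_ref
    q <- as.vector(a %*% resp_alt + r %*% resp_ref) / (2 * n_loci)
    q <- q / sum(q)
    ll <- ll_fun(q)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  names(q) <- colnames(p)

  pairs <- utils::combn(K, 2)
  amb <- list()
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    if (max(q[i1], q[i2]) < 0.1) next  # swap of two near-zero groups is vacuous
    qs <- q; qs[c(i1, i2)] <- q[c(i2, i1)]
    d <- ll_trace[length(ll_trace)] - ll_fun(qs)
    if (abs(d) < ambiguity_tol) {
      amb[[length(amb) + 1L]] <- data.frame(
        group1 = colnames(p)[i1], group2 = colnames(p)[i2], delta_ll = d,
        stringsAsFactors = FALSE)
    }
  }
  ambiguous_pairs <- if (length(amb)) do.call(rbind, amb) else
    data.frame(group1 = character(0), group2 = character(0),
               delta_ll = numeric(0), stringsAsFactors = FALSE)

  structure(
    list(q = q, loglik = ll_trace[length(ll_trace)], ll_trace = ll_trace,
         n_loci = n_loci, n_iter = length(ll_trace), converged = converged,
         ambiguous_pairs = ambiguous_pairs),
    class = "ancestry_estimate"
  )
}

#' @export
print.ancestry_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("Ancestry estimate over %d loci (logL %.2f, %d EM iterations)\n",
              x$n_loci, x$loglik, x$n_iter))
  print(round(sort(x$q, decreasing = TRUE), digits))
  if (nrow(x$ambiguous_pairs)) {
    cat("Ambiguous group pairs:",
        paste(x$ambiguous_pairs$group1, x$ambiguous_pairs$group2,
              sep = "/", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Nei (1978) unbiased genetic distance between two populations
#'
#' `D = -ln( Jxy / sqrt(Jx Jy) )` over shared biallelic loci, where the
#' within-population gene identities use the small-sample correction
#' `J = (2n * sum(p^2) - 1) / (2n - 1)` when a finite sample size is given.
#' Small negative distances arising from the sampling correction are
#' clamped to zero and flagged via attribute `clamped`.
#'
#' @param p_x,p_y Alternate-allele frequency vectors over the same loci.
#' @param n_x,n_y Number of diploid individuals behind each frequency
#'   vector; `Inf` disables the correction.
#' @return The distance (non-negative scalar).
#' @export
#' @examples
#' nei_distance(c(0.2, 0.8), c(0.9, 0.1))
nei_distance <- function(p_x, p_y, n_x = Inf, n_y = Inf) {
  ok <- !is.na(p_x) & !is.na(p_y)
  if (!any(ok)) stop("no overlapping loci")
  px <- p_x[ok]; py <- p_y[ok]
  raw_j <- function(p) p^2 + (1 - p)^2
  unbias <- function(j, n) if (is.finite(n)) (2 * n * j - 1) / (2 * n - 1) else j
  jx <- mean(unbias(raw_j(px), n_x))
  jy <- mean(unbias(raw_j(py), n_y))
  jxy <- mean(px * py + (1 - px) * (1 - py))
  d <- -log(jxy / sqrt(jx * jy))
  clamped <- d < 0
  structure(max(d, 0), clamped = clamped)
}

#' Nei distances between an item and every panel group
#'
#' The item is treated as a population of one pseudo-individual whose
#' allele frequencies are its dosages (0/0.5/1 scale), with `n = 1`.
#'
#' @param genotype An `item_genotype` or named dosage vector (0/0.5/1).
#' @param panel A `reference_panel`.
#' @return Named numeric vector of distances, ascending.
#' @export
nei_to_groups <- function(genotype, panel) {
  if (inherits(genotype, "item_genotype")) {
    g <- stats::setNames(genotype$genotype$dosage, genotype$genotype$locus_id)
  } else {
    g <- genotype
  }
  common <- intersect(names(g), rownames(panel$freqs))
  sizes <- table(panel$acc_groups)[panel$groups]
  d <- vapply(panel$groups, function(grp) {
    as.numeric(nei_distance(g[common], panel$freqs[common, grp],
                            n_x = 1, n_y = as.integer(sizes[[grp]])))
  }, numeric(1))
  sort(d)
}

#' Pairwise allele-sharing dissimilarity matrix
#'
#' `d(i, j) = mean over loci typed in both of |dosage_i - dosage_j| / 2`
#' on the 0/1/2 dosage scale (0 for identical genotypes, 1 for opposite
#' homozygotes at every locus).
#'
#' @param genotypes Dosage matrix (0/1/2, `NA` for missing), individuals in
#'   columns, loci in rows.
#' @return Symmetric matrix with zero diagonal and individuals as labels.
#' @export
dissimilarity_matrix <- function(genotypes) {
  n <- ncol(genotypes)
  if (n < 3) stop("at least 3 individuals required")
  labs <- colnames(genotypes)
  if (!anyNA(genotypes)) {
    d <- as.matrix(stats::dist(t(genotypes), method = "manhattan")) /
      (2 * nrow(genotypes))
    dimnames(d) <- list(labs, labs)
    return(d)
  }
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(genotypes[, i]) & !is.na(genotypes[, j])
      if (!any(ok)) {
        stop("individuals ", labs[i], " and ", labs[j], " share no typed loci")
      }
      d[i, j] <- d[j, i] <-
        mean(abs(genotypes[ok, i] - genotypes[ok, j])) / 2
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via \pkg{ape}); on an additive matrix the
#' generating tree is recovered exactly. Negative branch lengths are
#' clamped to zero and counted in attribute `clamped_edges`.
#'
#' @param d Symmetric distance matrix (or `dist`).
#' @return An \pkg{ape} `phylo` tree.
#' @export
neighbor_joining <- function(d) {
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
    d <- stats::as.dist(d)
  }
  tr <- ape::nj(d)
  neg <- tr$edge.length < 0
  tr$edge.length[neg] <- 0
  attr(tr, "clamped_edges") <- sum(neg)
  tr
}

#' Neighbor-joining tree with locus-bootstrap support
#'
#' Loci are resampled with replacement `n_replicates` times; the support of
#' each internal edge is the percentage of replicate trees containing the
#' same bipartition, written into the tree's node labels.
#'
#' @param genotypes Dosage matrix, individuals x loci are `ncol` x `nrow`
#'   as in [dissimilarity_matrix()] (loci in rows).
#' @param n_replicates Number of bootstrap replicates (0 skips supports).
#' @param seed Integer seed governing all replicates.
#' @return A `phylo` tree; when `n_replicates > 0`, node labels carry
#'   percent support and attribute `bootstrap` holds the numeric vector.
#' @export
bootstrap_support <- function(genotypes, n_replicates = 500, seed = NULL) {
  if (nrow(genotypes) < 10) stop("at least 10 loci required for bootstrap")
  tree_fun <- function(m) neighbor_joining(dissimilarity_matrix(t(m)))
  main <- tree_fun(t(genotypes))
  if (n_replicates == 0) return(main)
  with_seed(seed, {
    counts <- ape::boot.phylo(main, t(genotypes), tree_fun,
                              B = n_replicates, quiet = TRUE,
                              rooted = FALSE)
    support <- 100 * counts / n_replicates
    main$node.label <- as.character(round(support))
    attr(main, "bootstrap") <- support
    main
  })
}

#' Per-item ancestry report
#'
#' Combines admixture estimates and Nei distances to groups: for each item
#' the report lists the admixture argmax group, the two nearest groups by
#' Nei distance, a concordance flag (argmax among the two nearest), and any
#' ambiguous group pairs. Items failing the minimum-SNP rule are listed
#' separately with both possible attributions retained for ambiguous pairs.
#'
#' @param estimates Named list of `ancestry_estimate` (may contain `NULL`
#'   for ineligible items).
#' @param nei_dists Named list of distance vectors from [nei_to_groups()].
#' @return A list with `report` (`data.frame`) and `ineligible` (character
#'   vector of item ids).
#' @export
ancestry_report <- function(estimates, nei_dists) {
  items <- names(estimates)
  rows <- list()
  ineligible <- character(0)
  for (it in items) {
    est <- estimates[[it]]
    if (is.null(est)) { ineligible <- c(ineligible, it); next }
    nd <- nei_dists[[it]]
    top_adm <- names(est$q)[which.max(est$q)]
    nearest2 <- names(nd)[seq_len(min(2, length(nd)))]
    amb <- if (nrow(est$ambiguous_pairs)) {
      paste(est$ambiguous_pairs$group1, est$ambiguous_pairs$group2,
            sep = "/", collapse = "; ")
    } else ""
    rows[[it]] <- data.frame(
      item_id = it, n_loci = est$n_loci,
      admixture_top = top_adm, admixture_q = max(est$q),
      nei_nearest = nearest2[1],
      nei_second = if (length(nearest2) > 1) nearest2[2] else NA_character_,
      concordant = top_adm %in% nearest2,
      ambiguous_pairs = amb, stringsAsFactors = FALSE
    )
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(item_id = character(0))
  rownames(report) <- NULL
  list(report = report, ineligible = ineligible)
}
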