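test_that("build_panel validates inputs and is deterministic under a seed", {
  expect_error(build_panel(1, 50, 0.1), "n_groups")
  expect_error(build_panel(3, 10, 0.1), "n_loci")
  expect_error(build_panel(3, 50, 1.2), "divergence")
  expect_error(build_panel(3, 50, 0.1, group_sizes = c(2, 0, 3)), "positive")

  a <- build_panel(4, 40, 0.2, seed = 7)
  b <- build_panel(4, 40, 0.2, seed = 7)
  expect_identical(a, b)
  c <- build_panel(4, 40, 0.2, seed = 8)
  expect_false(identical(a$freqs, c$freqs))
})

test_that("the default 11-group panel matches the 76-accession collection", {
  p <- build_panel(11, 30, 0.15, seed = 1)
  expect_identical(p$groups, cacao_reference_design()$groups)
  expect_equal(ncol(p$accessions), 76)
  expect_equal(as.vector(table(p$acc_groups)[p$groups]),
               cacao_reference_design()$sizes)
})

test_that("panel invariants hold: biallelic loci, bounded frequencies,
           accession means consistent with group frequencies", {
  p <- build_panel(5, 400, 0.15, seed = 11)
  expect_true(all(p$loci$ref != p$loci$alt))
  expect_true(all(p$loci$ref %in% c("A", "C", "G", "T")))
  expect_true(all(p$freqs >= 0 & p$freqs <= 1))
  expect_true(all(p$loci$pos >= 0 & p$loci$pos < p$chrom_lengths[1]))

  # frequency conservation: empirical accession frequencies within 3
  # binomial SD of the generating group frequencies
  emp <- group_freqs_from_accessions(p)
  for (g in p$groups) {
    n <- sum(p$acc_groups == g)
    sd3 <- 3 * sqrt(p$freqs[, g] * (1 - p$freqs[, g]) / (2 * n))
    frac_ok <- mean(abs(emp[, g] - p$freqs[, g]) <= pmax(sd3, 1e-12))
    expect_gt(frac_ok, 0.98)
  }
})

test_that("no-divergence limit collapses between-group Nei distance", {
  lo <- build_panel(3, 500, 0.005, seed = 2)
  hi <- build_panel(3, 500, 0.4, seed = 2)
  d_lo <- as.numeric(nei_distance(lo$freqs[, 1], lo$freqs[, 2]))
  d_hi <- as.numeric(nei_distance(hi$freqs[, 1], hi$freqs[, 2]))
  expect_lt(d_lo, 0.01)
  expect_gt(d_hi, 10 * d_lo)
})

test_that("admixed genotypes follow the mixture law", {
  expect_error(sample_admixed_genotype(build_panel(3, 30, 0.1, seed = 1),
                                       c(0.5, 0.2)), "q")
  # degenerate frequencies: one-hot group with p = 1 everywhere -> dosage 2
  freqs <- cbind(G1 = rep(1, 30), G2 = rep(0.5, 30))
  rownames(freqs) <- paste0("L", 1:30)
  g <- sample_admixed_genotype(freqs, c(1, 0), seed = 3)
  expect_true(all(g == 2L))

  # q = (0.5, 0.5) with p1 = 0, p2 = 1 -> dosage ~ Binomial(2, 0.5)
  freqs2 <- cbind(G1 = rep(0, 10000), G2 = rep(1, 10000))
  rownames(freqs2) <- paste0("L", 1:10000)
  g2 <- sample_admixed_genotype(freqs2, c(0.5, 0.5), seed = 4)
  tab <- tabulate(g2 + 1L, 3) / 10000
  sd3 <- 3 * sqrt(c(0.25, 0.5, 0.25) * c(0.75, 0.5, 0.75) / 10000)
  expect_true(all(abs(tab - c(0.25, 0.5, 0.25)) <= sd3))

  # law of large numbers: mean alt fraction ~= sum_k q_k * mean_l p_kl
  p <- build_panel(4, 10000, 0.2, seed = 5)
  q <- c(0.4, 0.3, 0.2, 0.1)
  g3 <- sample_admixed_genotype(p, q, seed = 6)
  expected <- sum(q * colMeans(p$freqs))
  se <- sqrt(expected * (1 - expected) / (2 * 10000))
  expect_lt(abs(mean(g3) / 2 - expected), 3 * se)

  # determinism
  expect_identical(sample_admixed_genotype(p, q, seed = 6), g3)
})

test_that("fragment lengths are truncated, calibrated and right-skewed", {
  m <- damage_model()
  gen <- synthetic_genome(c(chr1 = 60000), seed = 1)
  expect_error(fragment_genome(strrep("A", 20), m, 5), "30")
  fr <- fragment_genome(gen[[1]], m, 10000, seed = 2)
  len <- fr$end - fr$start
  expect_true(all(len >= 30))
  expect_true(all(fr$start >= 0 & fr$end <= 60000))
  # calibrated mean: sample mean within 3 SE of the model mean
  expect_lt(abs(mean(len) - m$length_mean), 3 * sd(len) / sqrt(10000))
  expect_gt(mean(len > median(len) + 40), mean(len < median(len) - 40))
})

test_that("depurination bias shapes the base just 5' of fragment starts", {
  gen <- synthetic_genome(c(chr1 = 50000), gc = 0.5, seed = 3)
  base <- strsplit(gen[[1]], "")[[1]]

  flank_purine_frac <- function(fr) {
    flank <- base[fr$start]        # genomic base at start-1 (0-based start)
    flank <- flank[fr$start > 0]
    mean(flank %in% c("A", "G"))
  }
  # unbiased: flank composition matches the genome
  m1 <- damage_model(depurination_bias = 1)
  f1 <- fragment_genome(gen[[1]], m1, 8000, seed = 4)
  g_pur <- mean(base %in% c("A", "G"))
  expect_lt(abs(flank_purine_frac(f1) - g_pur),
            3 * sqrt(g_pur * (1 - g_pur) / 8000))
  # bias 4 on a balanced genome: odds 4:1 -> fraction ~ 0.8
  m4 <- damage_model(depurination_bias = 4)
  f4 <- fragment_genome(gen[[1]], m4, 8000, seed = 5)
  expect_lt(abs(flank_purine_frac(f4) - 0.8), 3 * sqrt(0.8 * 0.2 / 8000))
})

test_that("apply_damage is the identity at delta0 = 0 and closes over truth", {
  m0 <- damage_model(delta0 = 0)
  s <- replicate(50, rand_dna(60))
  d0 <- apply_damage(s, m0, seed = 1)
  expect_identical(d0$sequences, s)
  expect_equal(nrow(d0$truth), 0)

  # damage closure: every difference is a recorded C->T (5') or G->A (3')
  m <- damage_model(delta0 = 0.3, decay_lambda = 0.8)
  d <- apply_damage(s, m, seed = 2)
  diffs <- list()
  for (i in seq_along(s)) {
    a <- strsplit(s[i], "")[[1]]
    b <- strsplit(d$sequences[i], "")[[1]]
    w <- which(a != b)
    if (length(w)) diffs[[length(diffs) + 1L]] <-
      data.frame(fragment = i, pos = w - 1L, from = a[w], to = b[w])
  }
  diffs <- do.call(rbind, diffs)
  expect_equal(nrow(diffs), nrow(d$truth))
  got <- d$truth[order(d$truth$fragment, d$truth$pos), ]
  exp <- diffs[order(diffs$fragment, diffs$pos), ]
  rownames(got) <- rownames(exp) <- NULL
  expect_equal(got, exp)
  expect_true(all(d$truth$from %in% c("C", "G")))
  expect_true(all(ifelse(d$truth$from == "C", d$truth$to == "T",
                         d$truth$to == "A")))

  # determinism
  expect_identical(apply_damage(s, m, seed = 2)$sequences, d$sequences)
})

test_that("deamination rates decay geometrically into the fragment", {
  m <- damage_model(delta0 = 0.05, decay_lambda = 0.7)
  s <- rep(strrep("C", 40), 20000)
  d <- apply_damage(s, m, seed = 9)
  chars <- do.call(rbind, strsplit(d$sequences, ""))
  r <- colMeans(chars == "T")
  expect_lt(abs(r[1] - 0.05), 0.01)
  # ratio of consecutive positions ~ 1 / lambda
  expect_lt(abs(r[1] / r[2] - 1 / 0.7), 0.25)
})

test_that("simulate_library labels contamination truthfully", {
  p <- build_panel(3, 40, 0.2, n_chrom = 2, chrom_length = 20000, seed = 1)
  gen <- panel_genome(p, seed = 2)
  cont <- synthetic_genome(c(herrania_1 = 20000), gc = 0.42, seed = 3)

  m0 <- damage_model(contamination_fraction = 0)
  lib0 <- simulate_library(p, gen, m0, 200, q = c(1, 0, 0), seed = 4)
  expect_true(all(lib0$truth$taxon == "Theobroma cacao"))
  expect_equal(nrow(lib0$truth), 200)
  expect_equal(lib0$truth$length, lib0$truth$end - lib0$truth$start)

  m3 <- damage_model(contamination_fraction = 0.3)
  expect_error(simulate_library(p, gen, m3, 100, q = c(1, 0, 0), seed = 5),
               "contaminants")
  lib3 <- simulate_library(p, gen, m3, 5000, q = c(1, 0, 0),
                           contaminants = c(Herrania = unname(cont)),
                           seed = 5)
  n_c <- sum(lib3$truth$taxon == "Herrania")
  expect_lt(abs(n_c - 1500), 3 * sqrt(5000 * 0.3 * 0.7))

  # byte-identical under the same seed
  lib3b <- simulate_library(p, gen, m3, 5000, q = c(1, 0, 0),
                            contaminants = c(Herrania = unname(cont)),
                            seed = 5)
  expect_identical(lib3, lib3b)
})

test_that("read-through geometry recovers the fragment after processing", {
  p <- build_panel(3, 40, 0.2, n_chrom = 1, chrom_length = 20000, seed = 1)
  gen <- panel_genome(p, seed = 2)
  lib <- simulate_library(p, gen, damage_model(), 40, q = c(1, 0, 0),
                          seed = 6)
  res <- run_readproc(lib$r1, lib$r2)
  # every fragment is shorter than the read, so all pairs merge back to the
  # exact fragment sequence
  merged <- res$reads[res$reads$merged, ]
  expect_setequal(merged$seq, unique(lib$fragments))
})

test_that("methylxanthine simulation separates background from positives", {
  s0 <- simulate_methylxanthine(50, positive_fraction = 0, seed = 1)
  expect_true(all(s0$measurements$theobromine < 700))
  expect_false(any(s0$truth$positive))

  s <- simulate_methylxanthine(seed = 2)
  expect_equal(nrow(s$measurements), 326)
  flags <- call_positive(s$measurements)$flags
  expect_identical(unname(flags$theobromine), s$truth$positive)

  expect_error(simulate_methylxanthine(background_scale = 250), "200")
  expect_error(simulate_methylxanthine(positive_scale = 500), "700")
  expect_identical(simulate_methylxanthine(seed = 2), s)
})
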