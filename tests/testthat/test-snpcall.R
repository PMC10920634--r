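test_that("unique-mapping rule keeps single-copy fragments only", {
  set.seed(30)
  uniq <- rand_dna(2000)
  repeat_unit <- rand_dna(80)
  genome <- c(chr1 = paste0(uniq, repeat_unit, rand_dna(500), repeat_unit))

  single <- substr(uniq, 101, 180)
  u1 <- unique_mapping_filter(single, genome)
  expect_true(u1$keep)
  expect_equal(u1$n_locations, 1)

  u2 <- unique_mapping_filter(repeat_unit, genome)
  expect_false(u2$keep)
  expect_equal(u2$n_locations, 2)

  # reverse-complement palindromic double-count is not an issue for
  # ordinary fragments: a reverse-strand copy is one location
  u3 <- unique_mapping_filter(revcomp(single), genome)
  expect_true(u3$keep)

  # brute-force oracle: location count equals exact-match enumeration
  hits <- gregexpr(repeat_unit, genome[[1]], fixed = TRUE)[[1]]
  expect_equal(u2$n_locations, length(hits))
})

test_that("allele extraction computes read-space coordinates", {
  loci <- data.frame(id = c("L1", "L2"), chrom = "chr1",
                     pos = c(103, 160), ref = c("A", "C"), alt = c("G", "T"),
                     stringsAsFactors = FALSE)
  set.seed(31)
  gseq <- rand_dna(400)
  substr(gseq, 104, 104) <- "A"   # L1 at 0-based 103
  substr(gseq, 161, 161) <- "C"   # L2 at 0-based 160

  # forward fragment covering both loci; L1 at read position 3
  fr <- frag_table("chr1", 100, 180, "+", substr(gseq, 101, 180))
  obs <- extract_alleles(fr, loci)
  expect_equal(nrow(obs), 2)
  expect_equal(obs$d5[obs$locus_id == "L1"], 3)
  expect_equal(obs$d3[obs$locus_id == "L1"], 80 - 1 - 3)
  expect_identical(obs$obs_genome, c("A", "C"))

  # reverse-strand fragment: same genomic alleles, mirrored distances
  fr_rc <- frag_table("chr1", 100, 180, "-", revcomp(substr(gseq, 101, 180)))
  obs_rc <- extract_alleles(fr_rc, loci)
  expect_identical(obs_rc$obs_genome, c("A", "C"))
  expect_equal(obs_rc$d5[obs_rc$locus_id == "L1"], 76)
  expect_identical(obs_rc$pair_read_ref[obs_rc$locus_id == "L1"], "T")

  # a fragment not covering any locus produces no observation
  expect_equal(nrow(extract_alleles(frag_table("chr1", 300, 380, "+",
                                               substr(gseq, 301, 380)),
                                    loci)), 0)
})

test_that("terminal damage filter drops only damage-consistent calls", {
  base <- data.frame(
    locus_id = "L", fragment_id = "f", obs_genome = "T", ref = "C",
    alt = "T", strand = "+", status = "kept", stringsAsFactors = FALSE
  )
  mk <- function(obs_read, pr, pa, d5, d3) {
    o <- base
    o$obs_read <- obs_read; o$pair_read_ref <- pr; o$pair_read_alt <- pa
    o$d5 <- d5; o$d3 <- d3
    o
  }
  # T at 5' distance 2 at a C/T locus -> dropped
  expect_identical(terminal_damage_filter(mk("T", "C", "T", 2, 70))$status,
                   "terminal_damage")
  # T at 5' distance 7 (outside the window) -> kept
  expect_identical(terminal_damage_filter(mk("T", "C", "T", 7, 65))$status,
                   "kept")
  # G at 5' distance 2 at an A/G locus -> kept (not a 5' damage pattern)
  expect_identical(terminal_damage_filter(mk("G", "A", "G", 2, 70))$status,
                   "kept")
  # A at 3' distance 2 at a G/A locus -> dropped
  expect_identical(terminal_damage_filter(mk("A", "G", "A", 70, 2))$status,
                   "terminal_damage")
  # A at 3' distance 2 at a C/A locus -> kept (pair is not G/A)
  expect_identical(terminal_damage_filter(mk("A", "C", "A", 70, 2))$status,
                   "kept")
})

test_that("allele-match filter discards third alleles and reports the rate", {
  obs <- data.frame(
    locus_id = c("L1", "L1", "L2"), fragment_id = c("a", "b", "c"),
    obs_genome = c("A", "G", "T"), ref = c("A", "A", "C"),
    alt = c("G", "G", "G"), status = "kept", stringsAsFactors = FALSE
  )
  f <- allele_match_filter(obs)
  expect_identical(f$status, c("kept", "kept", "allele_mismatch"))
  expect_equal(attr(f, "mismatch_fraction"), 1 / 3)
})

test_that("filters commute: terminal-damage and allele-match are disjoint", {
  p <- build_panel(3, 60, 0.2, n_chrom = 2, chrom_length = 20000, seed = 32)
  gen <- panel_genome(p, seed = 33)
  m <- damage_model(delta0 = 0.3)
  lib <- simulate_library(p, gen, m, 400, q = c(1, 0, 0), seed = 34)
  frags <- frag_table(lib$truth$chrom, lib$truth$start, lib$truth$end,
                      lib$truth$strand, lib$fragments, lib$truth$id)
  obs <- extract_alleles(frags, p)
  a <- allele_match_filter(terminal_damage_filter(obs))
  b <- terminal_damage_filter(allele_match_filter(obs))
  key <- function(o) paste(o$locus_id, o$fragment_id)[o$status == "kept"]
  expect_setequal(key(a), key(b))
})

test_that("terminal filter removal rate grows with damage and is 0 without", {
  p <- build_panel(3, 300, 0.2, n_chrom = 1, chrom_length = 10000, seed = 35)
  # orient every locus so the damage product (T of a C/T pair, A of a G/A
  # pair) is the alternate allele; with an all-reference genotype no genuine
  # call can mimic damage, so the filter must remove nothing at delta0 = 0
  swap <- (p$loci$alt == "C" & p$loci$ref == "T") |
          (p$loci$alt == "G" & p$loci$ref == "A")
  tmp <- p$loci$ref[swap]
  p$loci$ref[swap] <- p$loci$alt[swap]
  p$loci$alt[swap] <- tmp
  gen <- panel_genome(p, seed = 36)
  geno0 <- stats::setNames(rep(0L, nrow(p$loci)), p$loci$id)
  removed_frac <- vapply(c(0, 0.1, 0.5), function(d0) {
    m <- damage_model(delta0 = d0)
    lib <- simulate_library(p, gen, m, 2000, genotype = geno0, seed = 37)
    obs <- extract_alleles(
      frag_table(lib$truth$chrom, lib$truth$start, lib$truth$end,
                 lib$truth$strand, lib$fragments, lib$truth$id), p)
    f <- terminal_damage_filter(obs)
    mean(f$status == "terminal_damage")
  }, numeric(1))
  expect_equal(removed_frac[1], 0)
  expect_gt(removed_frac[2], 0)
  expect_lt(removed_frac[2], removed_frac[3])
})

test_that("genotype aggregation applies the dosage and eligibility rules", {
  mk_obs <- function(locus, bases, ref = "A", alt = "G") {
    data.frame(locus_id = locus, fragment_id = paste0("f", seq_along(bases)),
               obs_genome = bases, ref = ref, alt = alt, status = "kept",
               stringsAsFactors = FALSE)
  }
  g1 <- aggregate_genotype(mk_obs("L1", c("A", "A", "A")))
  expect_equal(g1$genotype$dosage, 0)
  g2 <- aggregate_genotype(mk_obs("L1", c("A", "A", "G")))
  expect_equal(g2$genotype$dosage, 0.5)
  g3 <- aggregate_genotype(mk_obs("L1", c("G", "G")))
  expect_equal(g3$genotype$dosage, 1)

  # 19 loci -> ineligible for ancestry analysis
  obs19 <- do.call(rbind, lapply(1:19, function(i) mk_obs(paste0("L", i), "A")))
  expect_false(aggregate_genotype(obs19)$eligible)
  obs20 <- rbind(obs19, mk_obs("L20", "A"))
  expect_true(aggregate_genotype(obs20)$eligible)
})

test_that("damage-free pipeline recovers the simulated genotype exactly", {
  p <- build_panel(3, 100, 0.25, n_chrom = 1, chrom_length = 30000, seed = 38)
  gen <- panel_genome(p, seed = 39)
  m0 <- damage_model(delta0 = 0)
  geno <- stats::setNames(rep(c(0L, 2L), length.out = 100), p$loci$id)
  lib <- simulate_library(p, gen, m0, 800, genotype = geno, seed = 40)
  frags <- frag_table(lib$truth$chrom, lib$truth$start, lib$truth$end,
                      lib$truth$strand, lib$fragments, lib$truth$id)
  obs <- extract_alleles(frags, p)
  # observation count equals the truth coverage count over loci
  cov <- sum(vapply(seq_len(nrow(p$loci)), function(i) {
    sum(lib$truth$chrom == p$loci$chrom[i] &
          lib$truth$start <= p$loci$pos[i] & lib$truth$end > p$loci$pos[i])
  }, numeric(1)))
  expect_equal(nrow(obs), cov)

  obs <- allele_match_filter(terminal_damage_filter(obs))
  expect_equal(attr(obs, "mismatch_fraction"), 0)
  ig <- aggregate_genotype(obs, "item1")
  expect_true(ig$eligible)
  expect_true(all(ig$genotype$dosage ==
                    geno[ig$genotype$locus_id] / 2))
})
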