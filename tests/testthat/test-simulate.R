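test_that("simulateLocus: zero theta, argument errors, pi calibration", {
  set.seed(51)
  s0 <- simulateLocus(0, 10)
  expect_length(unique(s0), 1)             # no mutation, all identical
  expect_error(simulateLocus(0.01, 1), "n_sequences")
  expect_error(simulateLocus(-0.1, 10), "theta")
  # Monte-Carlo calibration of the configured diversity
  pis <- replicate(2000, {
    s <- simulateLocus(0.02, 40, 92, "neutral")
    locusPi(seqsToCalls(s), 92)
  })
  expect_lt(abs(mean(pis) - 0.02), 0.002)  # within 10% of 0.02
})

test_that("intermediate frequency mode yields positive Tajima's D", {
  set.seed(52)
  Ds <- replicate(500, {
    s <- simulateLocus(0.03, 40, 92, "intermediate")
    # site-wise D over the locus, via the Tajima oracle
    m <- do.call(rbind, strsplit(s, ""))
    S <- 0; ph <- 0
    for (j in seq_len(ncol(m))) {
      tab <- table(m[, j])
      if (length(tab) > 1) {
        S <- S + 1
        n <- sum(tab)
        ph <- ph + (n^2 - sum(tab^2)) / (n * (n - 1))
      }
    }
    if (S >= 5) tajimaD(S, ph, length(s)) else NA_real_
  })
  expect_gt(mean(Ds, na.rm = TRUE), 0)
})

test_that("dataset simulation is deterministic and honours its invariants", {
  cfg <- simConfig(n_chromosomes = 2, chrom_length = 1e6, seed = 99,
                   missing_rate = 0.25)
  a <- simulateDataset(cfg)
  b <- simulateDataset(cfg)
  expect_identical(haplotypeCalls(a$haplotypes), haplotypeCalls(b$haplotypes))
  expect_identical(a$snps, b$snps)
  expect_identical(a$gene_classes, b$gene_classes)
  # locus coordinates strictly increasing within chromosomes, inside bounds
  lo <- radLoci(a$haplotypes)
  for (ch in unique(lo$chrom))
    expect_false(is.unsorted(lo$pos[lo$chrom == ch], strictly = TRUE))
  expect_true(all(lo$pos + lo$length - 1 <= 1e6))
  # truth flags agree with planted coordinates (none planted here)
  expect_false(any(a$truth$locus_truth$in_planted_region))
})

test_that("complete selfing gives zero observed heterozygosity everywhere", {
  cfg <- simConfig(n_chromosomes = 1, chrom_length = 2e6, seed = 7,
                   missing_rate = 0,
                   groups = list(list(group_id = "S", n_populations = 4,
                                      n_individuals_per_pop = 4,
                                      inbreeding_F = 1)))
  sim <- simulateDataset(cfg)
  st <- locusStats(sim$haplotypes)
  expect_true(all(st$ho == 0))
  expect_true(all(individualHeterozygosity(sim$haplotypes) == 0))
})

test_that("observed heterozygosity decreases with the inbreeding coefficient", {
  meanHo <- function(F, seed) {
    cfg <- simConfig(n_chromosomes = 2, chrom_length = 7e6, seed = seed,
                     missing_rate = 0,
                     groups = list(list(group_id = "G", n_populations = 4,
                                        n_individuals_per_pop = 4,
                                        inbreeding_F = F)))
    st <- locusStats(simulateDataset(cfg)$haplotypes)
    mean(st$ho)
  }
  h0 <- meanHo(0, 3); h5 <- meanHo(0.5, 3); h9 <- meanHo(0.9, 3)
  expect_gt(h0, h5)
  expect_gt(h5, h9)
})

test_that("planted regions scale diversity by the configured multiplier", {
  cfg <- simConfig(n_chromosomes = 2, chrom_length = 8e6, seed = 31,
                   missing_rate = 0.1,
                   planted_regions = list(
                     list(chrom = "chr1", start = 1e6, end = 4.5e6,
                          diversity_multiplier = 3, fst_multiplier = 1,
                          frequency_mode = "neutral")))
  sim <- simulateDataset(cfg)
  st <- locusStats(sim$haplotypes)
  inr <- sim$truth$locus_truth$in_planted_region
  expect_gte(sum(inr), 250)                 # enough loci per stratum
  ratio <- mean(st$pi[inr], na.rm = TRUE) / mean(st$pi[!inr], na.rm = TRUE)
  expect_lt(abs(ratio - 3) / 3, 0.15)
})

test_that("two-group simulation recovers the divergence parameter", {
  cfg <- simConfig(n_chromosomes = 2, chrom_length = 3.1e7,
                   structure_Fst = 0.3, missing_rate = 0,
                   groups = list(list(group_id = "A", n_populations = 1,
                                      n_individuals_per_pop = 12,
                                      inbreeding_F = 0),
                                 list(group_id = "B", n_populations = 1,
                                      n_individuals_per_pop = 12,
                                      inbreeding_F = 0)),
                   seed = 5)
  sim <- simulateDataset(cfg)
  expect_gte(nLoci(sim$haplotypes), 5000)
  cl <- haplotypeCalls(sim$haplotypes)
  grp <- sampleInfo(sim$haplotypes)$group
  # mean per-locus AMOVA F_ST lands in the expected band
  fst <- vapply(seq_len(nrow(cl)), function(i) locusAmovaFst(cl[i, ], grp),
                numeric(1))
  m <- mean(fst, na.rm = TRUE)
  expect_gte(m, 0.2); expect_lte(m, 0.4)
  # multi-locus Weir-Cockerham recovers the parameter within 0.05
  pw <- pairwiseFst(sim$haplotypes, by = "group")
  expect_lt(abs(pw$fst["A", "B"] - 0.3), 0.05)
})

test_that("gene class assignment follows the planted probabilities", {
  genes <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(seq(1, 2e6, by = 1000), width = 500))
  genes$gene_id <- sprintf("G%05d", seq_along(genes))
  planted <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5e5, 1e6))
  set.seed(61)
  # degenerate probabilities
  z <- assignGeneClasses(genes, planted, 0, 0)
  expect_false(any(z$class == "candidate"))
  d <- assignGeneClasses(genes, planted, 1, 0)
  mids <- GenomicRanges::start(genes) + 249
  inr <- mids >= 5e5 & mids <= 1e6
  expect_true(all(d$class[inr] == "candidate"))
  expect_false(any(d$class[!inr] == "candidate"))
  expect_error(assignGeneClasses(genes, planted, 0.1, 0.5), "p_out")
  # realized in-region rate within exact binomial 99% bounds of 0.3
  cl <- assignGeneClasses(genes, planted, 0.3, 0.05)
  n_in <- sum(inr)
  k <- sum(cl$class[inr] == "candidate")
  ci <- qbinom(c(0.005, 0.995), n_in, 0.3)
  expect_gte(k, ci[1]); expect_lte(k, ci[2])
})

test_that("written datasets round-trip losslessly through the readers", {
  cfg <- simConfig(n_chromosomes = 1, chrom_length = 1.5e6, seed = 77,
                   missing_rate = 0.3,
                   planted_regions = list(
                     list(chrom = "chr1", start = 2e5, end = 6e5,
                          diversity_multiplier = 4, fst_multiplier = 0.5,
                          frequency_mode = "intermediate")))
  sim <- simulateDataset(cfg)
  d <- tempfile()
  p <- writeDataset(sim, d)
  hm <- readHaplotypeTable(p["haplotypes"], p["metadata"])
  expect_identical(haplotypeCalls(hm), haplotypeCalls(sim$haplotypes))
  # per-locus missing counts match what the simulator recorded
  expect_equal(rowSums(is.na(haplotypeCalls(hm))),
               rowSums(is.na(haplotypeCalls(sim$haplotypes))))
  snps <- readVcfSnps(p["vcf"])
  expect_equal(nrow(snps$sites), nrow(sim$snps$sites))
  g <- readGff3Genes(p["genes"], p["classes"])
  expect_equal(g$gene_class, sim$genes$gene_class)
  pl <- readIntervalsBed(p["planted"])
  expect_equal(GenomicRanges::start(pl),
               GenomicRanges::start(sim$truth$planted))
  expect_equal(GenomicRanges::end(pl), GenomicRanges::end(sim$truth$planted))
})

test_that("config invariants are enforced", {
  expect_error(simConfig(structure_Fst = 1), "structure_Fst")
  expect_error(simConfig(missing_rate = 1.2), "missing_rate")
  expect_error(simConfig(planted_regions = list(
    list(chrom = "chr1", start = 5e6, end = 2e7, diversity_multiplier = 2,
         fst_multiplier = 1, frequency_mode = "neutral"))), "bounds")
  expect_error(simConfig(planted_regions = list(
    list(chrom = "chr1", start = 1e5, end = 5e5, diversity_multiplier = 2,
         fst_multiplier = 1, frequency_mode = "neutral"),
    list(chrom = "chr1", start = 4e5, end = 8e5, diversity_multiplier = 2,
         fst_multiplier = 1, frequency_mode = "neutral"))), "overlap")
  expect_error(simConfig(planted_regions = list(
    list(chrom = "chr1", start = 1e5, end = 5e5, diversity_multiplier = 2,
         fst_multiplier = 1, frequency_mode = "weird"))), "frequency_mode")
})
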