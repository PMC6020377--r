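## Genealogy-free RAD-seq simulator with planted truth.
##
## Allele frequencies follow a Balding-Nichols (Beta) model around a global
## per-site frequency; haplotype sequences are built by placing Poisson
## numbers of mutations on independent sites of a 92-bp tag. Loci inside
## planted regions get theta x diversity_multiplier, a shrunken divergence
## parameter (structure_Fst x fst_multiplier) and optionally an
## intermediate-frequency site spectrum. Everything is deterministic given
## the config seed, with per-chromosome sub-streams.

#' Simulation configuration
#'
#' Builds and validates the configuration of \code{\link{simulateDataset}}.
#' Defaults emulate a RAD-seq scan sample group: 92-bp tags spaced 12 kbp
#' apart on average, eight outcrossing populations of four diploids, and a
#' Balding-Nichols divergence parameter of 0.1 among populations.
#'
#' @param n_chromosomes number of chromosomes
#' @param chrom_length chromosome length in bp
#' @param locus_spacing_mean mean inter-locus spacing in bp (exponential)
#' @param locus_length RAD tag length in bp (default 92)
#' @param groups list of lists(group_id, n_populations,
#'   n_individuals_per_pop, inbreeding_F)
#' @param background_theta expected per-bp pairwise diversity outside
#'   planted regions
#' @param structure_Fst Balding-Nichols divergence parameter in [0, 1)
#' @param planted_regions list of lists(chrom, start, end,
#'   diversity_multiplier, fst_multiplier, frequency_mode); regions must
#'   lie within chromosome bounds and not overlap
#' @param missing_rate per-(individual, locus) Bernoulli missingness
#' @param gene_length,gene_spacing gene model geometry in bp
#' @param candidate_class_prob_in,candidate_class_prob_out probability of
#'   the candidate class inside / outside planted regions
#' @param seed integer RNG seed
#' @return validated config list of class "SimConfig"
#' @export
simConfig <- function(n_chromosomes = 2, chrom_length = 1e7,
                      locus_spacing_mean = 12000, locus_length = 92,
                      groups = list(list(group_id = "OUT",
                                         n_populations = 8,
                                         n_individuals_per_pop = 4,
                                         inbreeding_F = 0)),
                      background_theta = 0.008, structure_Fst = 0.1,
                      planted_regions = list(), missing_rate = 0.2,
                      gene_length = 2000, gene_spacing = 6000,
                      candidate_class_prob_in = 0.3,
                      candidate_class_prob_out = 0.05, seed = 1L) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chrom_length = chrom_length,
              locus_spacing_mean = locus_spacing_mean,
              locus_length = as.integer(locus_length), groups = groups,
              background_theta = background_theta,
              structure_Fst = structure_Fst,
              planted_regions = planted_regions,
              missing_rate = missing_rate, gene_length = gene_length,
              gene_spacing = gene_spacing,
              candidate_class_prob_in = candidate_class_prob_in,
              candidate_class_prob_out = candidate_class_prob_out,
              seed = as.integer(seed))
  validateSimConfig(cfg)
  class(cfg) <- "SimConfig"
  cfg
}

validateSimConfig <- function(cfg) {
  stopifnot(cfg$n_chromosomes >= 1, cfg$chrom_length > 0,
            cfg$locus_spacing_mean > 0, cfg$locus_length >= 1,
            cfg$background_theta >= 0,
            cfg$structure_Fst >= 0, cfg$structure_Fst < 1,
            cfg$missing_rate >= 0, cfg$missing_rate <= 1,
            cfg$candidate_class_prob_in >= 0, cfg$candidate_class_prob_in <= 1,
            cfg$candidate_class_prob_out >= 0,
            cfg$candidate_class_prob_out <= 1,
            length(cfg$groups) >= 1)
  for (g in cfg$groups)
    stopifnot(g$n_populations >= 1, g$n_individuals_per_pop >= 1,
              g$inbreeding_F >= 0, g$inbreeding_F <= 1)
  prs <- cfg$planted_regions
  if (length(prs)) {
    for (r in prs) {
      if (r$start < 1 || r$end > cfg$chrom_length || r$start >= r$end)
        stop("planted region outside chromosome bounds")
      if (r$diversity_multiplier <= 0) stop("diversity_multiplier must be > 0")
      if (r$fst_multiplier <= 0 || r$fst_multiplier > 1)
        stop("fst_multiplier must be in (0, 1]")
      if (!r$frequency_mode %in% c("neutral", "intermediate"))
        stop("frequency_mode must be 'neutral' or 'intermediate'")
    }
    byc <- split(prs, vapply(prs, `[[`, character(1), "chrom"))
    for (rs in byc) {
      if (length(rs) < 2) next
      s <- vapply(rs, `[[`, numeric(1), "start")
      e <- vapply(rs, `[[`, numeric(1), "end")
      o <- order(s)
      if (any(s[o][-1] < e[o][-length(e)] ))
        stop("planted regions overlap")
    }
  }
  invisible(TRUE)
}

## deterministic sub-seed, kept below 2^31
.subSeed <- function(seed, k) (as.numeric(seed) * 48271 + k * 99991) %% 2147483629

.BASES <- c("A", "C", "G", "T")

## derived-site frequencies: neutral SFS (prob ~ 1/k over derived counts)
## or a symmetric Beta concentrated at 1/2 (intermediate spectra)
.siteFrequencies <- function(S, n, mode) {
  if (mode == "neutral") {
    k <- seq_len(n - 1)
    sample(k, S, replace = TRUE, prob = 1 / k) / n
  } else {
    stats::rbeta(S, 20, 20)
  }
}

## expected per-site pairwise-difference proportion under each mode, used
## to convert a target per-bp diversity into a Poisson site count
.sitePairwiseHet <- function(n, mode) {
  if (mode == "neutral") 1 / sum(1 / seq_len(n - 1)) * 1  # E[2p(1-p)] under 1/k SFS
  else 20 / (2 * 20 + 1)                                   # Beta(20,20)
}

.expectedSites <- function(theta, L, n, mode) theta * L / .sitePairwiseHet(n, mode)

## Carrier sets with complete within-locus linkage: each site's derived
## allele is carried by a contiguous block (of the site's derived count) of
## one fixed random circular ordering of the sequences, a crude stand-in
## genealogy. Per-site derived counts are exact, so the expected pairwise
## diversity is unchanged, but neighbouring sequences share mutations and
## the locus holds few distinct haplotype alleles, as a non-recombining
## 92-bp tag does.
.linkedCarriers <- function(S, n, freq) {
  perm <- sample.int(n)
  starts <- sample.int(n, S, replace = TRUE)
  carrier <- matrix(FALSE, S, n)
  ks <- pmin(pmax(1L, as.integer(round(freq * n))), n - 1L)
  for (s in seq_len(S)) {
    block <- ((starts[s] - 1L + seq_len(ks[s]) - 1L) %% n) + 1L
    carrier[s, perm[block]] <- TRUE
  }
  carrier
}

#' Simulate one RAD locus as a set of haplotype sequences
#'
#' Places Poisson(theta * L / E[site heterozygosity]) mutations on distinct
#' sites of a random reference tag, each carried by a contiguous block of a
#' fixed random ordering of the sequences (a crude star/clade genealogy
#' with complete within-locus linkage). Under "neutral" the derived-allele
#' count of each site follows the neutral (1/k) frequency spectrum, so the
#' expected per-bp pairwise diversity equals \code{theta_locus}; under
#' "intermediate" frequencies are drawn from Beta(20, 20) (concentrated
#' near 0.5), producing positive Tajima's D in expectation. Uses the
#' current RNG state.
#'
#' @param theta_locus expected per-bp pairwise diversity (>= 0)
#' @param n_sequences number of haplotype sequences (>= 2)
#' @param locus_length tag length in bp (default 92)
#' @param frequency_mode "neutral" or "intermediate"
#' @return character vector of n_sequences strings over A/C/G/T
#' @export
simulateLocus <- function(theta_locus, n_sequences, locus_length = 92,
                          frequency_mode = c("neutral", "intermediate")) {
  frequency_mode <- match.arg(frequency_mode)
  if (n_sequences < 2) stop("n_sequences must be >= 2")
  if (locus_length < 1) stop("locus_length must be >= 1")
  if (theta_locus < 0) stop("theta_locus must be >= 0")
  ref <- sample(.BASES, locus_length, replace = TRUE)
  S <- min(stats::rpois(1, .expectedSites(theta_locus, locus_length,
                                          n_sequences, frequency_mode)),
           locus_length)
  if (S == 0) return(rep(paste(ref, collapse = ""), n_sequences))
  sitepos <- sample.int(locus_length, S)
  freq <- .siteFrequencies(S, n_sequences, frequency_mode)
  carrier <- .linkedCarriers(S, n_sequences, freq)
  alt <- vapply(ref[sitepos], function(b) sample(setdiff(.BASES, b), 1),
                character(1))
  .buildSequences(ref, sitepos, alt, carrier)
}

## carrier: S x n logical; returns n strings
.buildSequences <- function(ref, sitepos, alt, carrier) {
  n <- ncol(carrier)
  S <- nrow(carrier)
  code <- if (S <= 30) as.vector(crossprod(carrier, 2^(seq_len(S) - 1)))
          else apply(carrier, 2, paste, collapse = "")
  u <- !duplicated(code)
  uidx <- which(u)
  seqs_u <- vapply(uidx, function(j) {
    s <- ref
    hit <- carrier[, j]
    s[sitepos[hit]] <- alt[hit]
    paste(s, collapse = "")
  }, character(1))
  seqs_u[match(code, code[uidx])]
}

#' Assign gene classes with planted enrichment
#'
#' Labels each gene "candidate" with probability p_in when its midpoint
#' lies inside a planted region and p_out otherwise; the control class is
#' then assigned uniformly at rate p_out among the remaining genes, and
#' everything else is "other". Uses the current RNG state.
#'
#' @param genes \code{GRanges} with gene_id column
#' @param planted \code{GRanges} of planted regions (may be empty)
#' @param p_in,p_out candidate probabilities (0 <= p_out <= p_in <= 1)
#' @return data.frame(gene_id, class)
#' @importFrom GenomicRanges mid ranges
#' @export
assignGeneClasses <- function(genes, planted, p_in, p_out) {
  if (!(p_out >= 0 && p_in >= p_out && p_in <= 1))
    stop("need 0 <= p_out <= p_in <= 1")
  n <- length(genes)
  mids <- GenomicRanges::start(genes) +
    floor((GenomicRanges::width(genes) - 1) / 2)
  midgr <- GenomicRanges::GRanges(GenomicRanges::seqnames(genes),
                                  IRanges::IRanges(mids, mids))
  inreg <- if (length(planted))
    GenomicRanges::countOverlaps(midgr, planted) > 0 else rep(FALSE, n)
  p <- ifelse(inreg, p_in, p_out)
  cand <- stats::runif(n) < p
  ctrl <- !cand & stats::runif(n) < p_out
  cls <- ifelse(cand, "candidate", ifelse(ctrl, "control", "other"))
  data.frame(gene_id = genes$gene_id, class = cls, stringsAsFactors = FALSE)
}

#' Simulate a full RAD-seq dataset with planted truth
#'
#' Generates the haplotype matrix, sample metadata, gene annotation with
#' class labels, per-site SNP genotypes and the truth set, all consistent
#' with one another: the SNP records are exactly the segregating sites of
#' the simulated haplotype loci. Deterministic given the config seed.
#'
#' @param config a \code{\link{simConfig}} object
#' @return list(haplotypes = HaplotypeMatrix, metadata, genes = GRanges,
#'   gene_classes, snps = list(sites, a1, a2), truth = list(planted =
#'   GRanges, locus_truth, gene_classes, chrom_lengths))
#' @export
simulateDataset <- function(config) {
  validateSimConfig(config)
  set.seed(config$seed)
  ## sample frame
  meta <- do.call(rbind, lapply(config$groups, function(g) {
    do.call(rbind, lapply(seq_len(g$n_populations), function(p) {
      popid <- sprintf("%s_P%02d", g$group_id, p)
      data.frame(individual = sprintf("%s_I%02d", popid,
                                      seq_len(g$n_individuals_per_pop)),
                 population = popid, group = g$group_id,
                 lat = stats::runif(1, 40, 65),
                 lon = stats::runif(1, -95, 25),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(meta) <- NULL
  n_ind <- nrow(meta)
  pop_of <- match(meta$population, unique(meta$population))
  n_pop <- max(pop_of)
  Fg <- unlist(lapply(config$groups, function(g)
    rep(g$inbreeding_F, g$n_populations * g$n_individuals_per_pop)))
  L <- config$locus_length
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  chrom_lengths <- stats::setNames(rep(config$chrom_length,
                                       config$n_chromosomes), chroms)
  planted <- .plantedGRanges(config)

  loci_list <- list(); calls_list <- list()
  snp_sites <- list(); snp_a1 <- list(); snp_a2 <- list()
  truth_flags <- list()
  lc <- 0L
  for (ci in seq_along(chroms)) {
    set.seed(.subSeed(config$seed, ci))
    ch <- chroms[ci]
    pos <- cumsum(ceiling(stats::rexp(ceiling(2.5 * config$chrom_length /
                                              config$locus_spacing_mean),
                                      1 / config$locus_spacing_mean)) + 1)
    pos <- pos[pos <= config$chrom_length - L]
    nl <- length(pos)
    if (!nl) next
    ## planted-region membership by locus start
    reg_id <- rep(0L, nl)
    if (length(planted)) {
      pch <- as.character(GenomicRanges::seqnames(planted))
      for (r in which(pch == ch)) {
        s <- GenomicRanges::start(planted)[r]
        e <- GenomicRanges::end(planted)[r]
        reg_id[pos >= s & pos <= e] <- r
      }
    }
    cl <- matrix(NA_character_, nl, n_ind)
    keep_sites <- list()
    for (li in seq_len(nl)) {
      inreg <- reg_id[li] > 0L
      mult <- if (inreg) planted$diversity_multiplier[reg_id[li]] else 1
      fmult <- if (inreg) planted$fst_multiplier[reg_id[li]] else 1
      mode <- if (inreg) planted$frequency_mode[reg_id[li]] else "neutral"
      theta <- config$background_theta * mult
      Feff <- config$structure_Fst * fmult
      sim <- .simulateLocusStructured(theta, L, mode, n_ind, pop_of, n_pop,
                                      Feff, Fg)
      miss <- stats::runif(n_ind) < config$missing_rate
      row <- sim$calls
      row[miss] <- NA_character_
      cl[li, ] <- row
      if (sim$S > 0) {
        a1 <- sim$der1; a2 <- sim$der2
        a1[, miss] <- NA_integer_; a2[, miss] <- NA_integer_
        keep_sites[[length(keep_sites) + 1L]] <- list(
          pos = pos[li] + sim$sitepos - 1L, ref = sim$refb, alt = sim$altb,
          a1 = a1, a2 = a2)
      }
    }
    ids <- sprintf("L%06d", lc + seq_len(nl))
    lc <- lc + nl
    loci_list[[ci]] <- data.frame(locus_id = ids, chrom = ch, pos = pos,
                                  length = L, stringsAsFactors = FALSE)
    calls_list[[ci]] <- cl
    truth_flags[[ci]] <- data.frame(locus_id = ids, chrom = ch, pos = pos,
                                    in_planted_region = reg_id > 0L,
                                    region_id = reg_id,
                                    stringsAsFactors = FALSE)
    if (length(keep_sites)) {
      snp_sites[[ci]] <- data.frame(
        chrom = ch,
        pos = unlist(lapply(keep_sites, `[[`, "pos")),
        ref = unlist(lapply(keep_sites, `[[`, "ref")),
        alt = unlist(lapply(keep_sites, `[[`, "alt")),
        stringsAsFactors = FALSE)
      snp_a1[[ci]] <- do.call(rbind, lapply(keep_sites, `[[`, "a1"))
      snp_a2[[ci]] <- do.call(rbind, lapply(keep_sites, `[[`, "a2"))
    }
  }
  loci <- do.call(rbind, loci_list)
  calls <- do.call(rbind, calls_list)
  hm <- HaplotypeMatrix(loci, meta, calls, canonicalize = FALSE)
  sites <- if (length(snp_sites)) do.call(rbind, snp_sites) else
    data.frame(chrom = character(), pos = numeric(), ref = character(),
               alt = character())
  a1 <- if (length(snp_a1)) do.call(rbind, snp_a1) else
    matrix(integer(), 0, n_ind)
  a2 <- if (length(snp_a2)) do.call(rbind, snp_a2) else
    matrix(integer(), 0, n_ind)
  colnames(a1) <- colnames(a2) <- meta$individual
  ## sort sites by (chrom, pos)
  if (nrow(sites)) {
    o <- order(sites$chrom, sites$pos)
    sites <- sites[o, , drop = FALSE]; rownames(sites) <- NULL
    a1 <- a1[o, , drop = FALSE]; a2 <- a2[o, , drop = FALSE]
  }
  ## genes + classes
  set.seed(.subSeed(config$seed, 1000L))
  genes <- .geneModel(chroms, config$chrom_length, config$gene_length,
                      config$gene_spacing)
  gene_classes <- assignGeneClasses(genes, planted,
                                    config$candidate_class_prob_in,
                                    config$candidate_class_prob_out)
  genes$gene_class <- gene_classes$class
  locus_truth <- do.call(rbind, truth_flags)
  list(haplotypes = hm, metadata = meta, genes = genes,
       gene_classes = gene_classes,
       snps = list(sites = sites, a1 = a1, a2 = a2),
       truth = list(planted = planted, locus_truth = locus_truth,
                    gene_classes = gene_classes,
                    chrom_lengths = chrom_lengths),
       config = config)
}

.plantedGRanges <- function(config) {
  prs <- config$planted_regions
  if (!length(prs)) return(GenomicRanges::GRanges())
  gr <- GenomicRanges::GRanges(
    vapply(prs, `[[`, character(1), "chrom"),
    IRanges::IRanges(vapply(prs, `[[`, numeric(1), "start"),
                     vapply(prs, `[[`, numeric(1), "end")))
  gr$diversity_multiplier <- vapply(prs, `[[`, numeric(1),
                                    "diversity_multiplier")
  gr$fst_multiplier <- vapply(prs, `[[`, numeric(1), "fst_multiplier")
  gr$frequency_mode <- vapply(prs, `[[`, character(1), "frequency_mode")
  gr
}

.geneModel <- function(chroms, chrom_length, gene_length, gene_spacing) {
  starts1 <- seq(1, chrom_length - gene_length, by = gene_spacing)
  df <- data.frame(chrom = rep(chroms, each = length(starts1)),
                   start = rep(starts1, length(chroms)))
  gr <- GenomicRanges::GRanges(df$chrom,
          IRanges::IRanges(df$start, df$start + gene_length - 1))
  gr$gene_id <- sprintf("G%05d", seq_along(gr))
  gr
}

## One locus under population structure. A virtual pool sample of
## n_virtual fully linked sequences defines the locus's distinct haplotype
## alleles and their global frequencies q; each population then draws its
## allele frequencies from the multiallelic Balding-Nichols model
## Dirichlet((1 - F)/F * q), so the haplotype-level F_ST equals the
## divergence parameter in expectation. Individuals sample two alleles
## from their population's frequencies; the second is an identical-by-
## descent copy of the first with probability inbreeding_F (selfing).
## Returns canonical "h1/h2" calls plus per-site derived indicators per
## haplotype (for the SNP table).
.simulateLocusStructured <- function(theta, L, mode, n_ind, pop_of, n_pop,
                                     Feff, Fg) {
  n_v <- max(2L * n_ind, 32L)
  S <- min(stats::rpois(1, .expectedSites(theta, L, n_v, mode)), L)
  ref <- sample(.BASES, L, replace = TRUE)
  refstr <- paste(ref, collapse = "")
  if (S == 0) {
    gt <- paste0(refstr, "/", refstr)
    return(list(calls = rep(gt, n_ind), S = 0L))
  }
  sitepos <- sort(sample.int(L, S))
  freq <- .siteFrequencies(S, n_v, mode)
  pool <- .linkedCarriers(S, n_v, freq)           # S x n_v logical
  ## distinct alleles of the pool and their global frequencies
  code <- if (S <= 30) as.vector(crossprod(pool, 2^(seq_len(S) - 1)))
          else apply(pool, 2, paste, collapse = "")
  uidx <- which(!duplicated(code))
  K <- length(uidx)
  q <- as.vector(table(factor(match(code, code[uidx]), seq_len(K)))) / n_v
  patt <- pool[, uidx, drop = FALSE]              # S x K
  ## per-population allele frequencies: Dirichlet((1-F)/F * q)
  if (Feff < 1e-9 || K == 1L) {
    pfreq <- matrix(q, K, n_pop)
  } else {
    C <- (1 - Feff) / Feff
    g <- matrix(stats::rgamma(K * n_pop, shape = rep(q * C, n_pop)), K, n_pop)
    zero <- colSums(g) == 0
    if (any(zero)) g[, zero] <- q                 # degenerate draw guard
    pfreq <- sweep(g, 2, colSums(g), "/")
  }
  ## two allele draws per individual, whole-locus IBD with prob F
  a1 <- integer(n_ind); a2 <- integer(n_ind)
  for (p in seq_len(n_pop)) {
    ii <- which(pop_of == p)
    if (!length(ii)) next
    dr <- sample.int(K, 2L * length(ii), replace = TRUE, prob = pfreq[, p])
    a1[ii] <- dr[seq_along(ii)]
    a2[ii] <- dr[length(ii) + seq_along(ii)]
  }
  ibd <- stats::runif(n_ind) < Fg
  a2[ibd] <- a1[ibd]
  refi <- match(ref[sitepos], .BASES)
  alt <- .BASES[((refi - 1L + sample.int(3L, S, replace = TRUE)) %% 4L) + 1L]
  useqs <- vapply(seq_len(K), function(j) {
    s <- ref
    hit <- patt[, j]
    s[sitepos[hit]] <- alt[hit]
    paste(s, collapse = "")
  }, character(1))
  s1 <- useqs[a1]; s2 <- useqs[a2]
  swap <- s2 < s1
  gt <- paste0(ifelse(swap, s2, s1), "/", ifelse(swap, s1, s2))
  pattI <- matrix(as.integer(patt), S, K)
  list(calls = gt, S = S, sitepos = sitepos, refb = ref[sitepos],
       altb = alt, der1 = pattI[, a1, drop = FALSE],
       der2 = pattI[, a2, drop = FALSE])
}

#' Write a simulated dataset to a directory
#'
#' Emits the haplotype table, sample metadata, GFF3 gene annotation,
#' gene-class table, minimal VCF, truth-set TSV and planted-region BED.
#'
#' @param sim output of \code{\link{simulateDataset}}
#' @param dir output directory (created if absent)
#' @return named vector of file paths
#' @export
writeDataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(haplotypes = file.path(dir, "haplotypes.tsv"),
             metadata = file.path(dir, "samples.tsv"),
             genes = file.path(dir, "genes.gff3"),
             classes = file.path(dir, "gene_classes.tsv"),
             vcf = file.path(dir, "snps.vcf"),
             truth = file.path(dir, "locus_truth.tsv"),
             planted = file.path(dir, "planted_regions.bed"))
  writeHaplotypeTable(sim$haplotypes, paths["haplotypes"])
  writeSampleMetadata(sim$metadata, paths["metadata"])
  writeGff3Genes(sim$genes, paths["genes"])
  writeGeneClasses(sim$gene_classes, paths["classes"])
  writeVcfSnps(sim$snps, paths["vcf"])
  con <- file(paths["truth"], "w")
  writeLines(paste0("#", paste(names(sim$truth$locus_truth), collapse = "\t")),
             con)
  utils::write.table(sim$truth$locus_truth, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  if (length(sim$truth$planted)) {
    writeIntervalsBed(sim$truth$planted, paths["planted"])
  } else {
    writeLines("#chrom\tstart\tend\tname\tscore", paths["planted"])
  }
  paths
}
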