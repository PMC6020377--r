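## Per-locus and per-window population-genetic estimators.
## Haplotype alleles (whole 92-bp RAD tags) are the unit for pi, He, Ho and
## AMOVA Fst; individual SNPs are the unit for Tajima's D.

## split a vector of canonical "h1/h2" calls into its genotype spectrum:
## unique genotypes, their counts, and the two alleles of each
.callSpectrum <- function(calls) {
  calls <- calls[!is.na(calls)]
  if (!length(calls))
    return(list(n_ind = 0L, gt = character(), count = integer(),
                a1 = character(), a2 = character()))
  tab <- table(calls)
  gt <- names(tab)
  parts <- strsplit(gt, "/", fixed = TRUE)
  a1 <- vapply(parts, `[`, character(1), 1L)
  a2 <- vapply(parts, function(p) p[length(p)], character(1))
  list(n_ind = length(calls), gt = gt, count = as.integer(tab),
       a1 = a1, a2 = a2)
}

## allele frequency spectrum over the 2n haplotypes
.alleleCounts <- function(sp) {
  al <- c(sp$a1, sp$a2)
  cnt <- c(sp$count, sp$count)
  u <- unique(al)
  k <- vapply(u, function(a) sum(cnt[al == a]), numeric(1))
  names(k) <- u
  k
}

## Hamming distance matrix between equal-length allele strings
.hammingMatrix <- function(alleles) {
  k <- length(alleles)
  raws <- lapply(alleles, charToRaw)
  d <- matrix(0, k, k)
  if (k >= 2) {
    for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
      d[i, j] <- d[j, i] <- sum(raws[[i]] != raws[[j]])
    }
  }
  d
}

#' Per-locus nucleotide diversity from haplotype calls
#'
#' Average number of nucleotide differences over all unordered pairs of the
#' 2n sampled haplotype sequences at one RAD locus, divided by the locus
#' length, i.e. pairwise nucleotide diversity with whole-tag haplotypes as
#' alleles. Monomorphic loci return 0.
#'
#' @param calls character vector of canonical "h1/h2" calls (NA = missing)
#' @param L locus length in bp (default 92, the classic RAD tag length)
#' @return per-bp nucleotide diversity, or NA if fewer than 2 sequences
#' @export
locusPi <- function(calls, L = 92L) {
  sp <- .callSpectrum(calls)
  if (sp$n_ind == 0L) return(NA_real_)
  k <- .alleleCounts(sp)
  n2 <- sum(k)
  if (n2 < 2L) return(NA_real_)
  if (length(k) < 2L) return(0)
  lens <- nchar(names(k))
  if (length(unique(lens)) != 1L)
    stop("haplotype alleles of unequal length at one locus")
  d <- .hammingMatrix(names(k))
  tot <- 0
  for (i in seq_len(length(k) - 1L)) for (j in seq.int(i + 1L, length(k)))
    tot <- tot + k[i] * k[j] * d[i, j]
  unname(tot / choose(n2, 2) / L)
}

#' Per-locus gene diversity (expected heterozygosity)
#'
#' With whole-tag haplotypes as alleles and frequencies p_k over the 2n
#' sampled sequences, He = (2n/(2n-1)) (1 - sum p_k^2); the leading factor
#' is Nei's small-sample correction and can be switched off.
#'
#' @param calls character vector of canonical "h1/h2" calls
#' @param unbiased apply the 2n/(2n-1) correction (default TRUE)
#' @return gene diversity in [0, 1], NA when no sequences
#' @export
locusGeneDiversity <- function(calls, unbiased = TRUE) {
  sp <- .callSpectrum(calls)
  if (sp$n_ind == 0L) return(NA_real_)
  k <- .alleleCounts(sp)
  n2 <- sum(k)
  if (length(k) < 2L) return(0)
  p <- k / n2
  h <- 1 - sum(p^2)
  if (unbiased && n2 > 1L) h <- h * n2 / (n2 - 1L)
  unname(h)
}

#' Per-locus observed heterozygosity
#'
#' Proportion of genotyped individuals carrying two distinct haplotype
#' alleles at the locus.
#'
#' @param calls character vector of canonical "h1/h2" calls
#' @return proportion in [0, 1], NA when no individuals genotyped
#' @export
locusObservedHet <- function(calls) {
  sp <- .callSpectrum(calls)
  if (sp$n_ind == 0L) return(NA_real_)
  unname(sum(sp$count[sp$a1 != sp$a2]) / sp$n_ind)
}

#' Filter loci by per-group presence
#'
#' Retains loci genotyped in at least ceil((1 - max_missing_frac) * n)
#' members of the given individual set, the presence filter applied before
#' any diversity scan (e.g. max_missing_frac = 0.5 keeps loci present in at
#' least half the group).
#'
#' @param hm a \code{\link{HaplotypeMatrix}}
#' @param individuals character vector of individual ids (default: all)
#' @param max_missing_frac maximum tolerated missing fraction in [0, 1]
#' @return list(matrix = filtered HaplotypeMatrix restricted to the group,
#'   retained, dropped, min_present)
#' @export
filterLociByPresence <- function(hm, individuals = NULL, max_missing_frac = 0.5) {
  if (is.null(individuals)) individuals <- sampleInfo(hm)$individual
  if (!length(individuals)) stop("empty individual set")
  if (max_missing_frac < 0 || max_missing_frac > 1)
    stop("max_missing_frac must be in [0, 1]")
  if (!all(individuals %in% sampleInfo(hm)$individual))
    stop("unknown individuals in group")
  sub <- hm[, individuals]
  present <- rowSums(!is.na(haplotypeCalls(sub)))
  need <- ceiling((1 - max_missing_frac) * length(individuals))
  keep <- present >= need
  list(matrix = sub[which(keep), ], retained = sum(keep),
       dropped = sum(!keep), min_present = need)
}

#' Per-locus diversity statistics for a sample group
#'
#' Computes, for every locus of the matrix, the number of genotyped
#' individuals, distinct haplotype alleles, nucleotide diversity (pi), gene
#' diversity (He) and observed heterozygosity (Ho) within the given group.
#'
#' @param hm a \code{\link{HaplotypeMatrix}} (already filtered/subset)
#' @param individuals individual ids to use (default: all columns)
#' @param group_id label stored in the output (default "all")
#' @param unbiased_he use the 2n/(2n-1) correction for He
#' @return data.frame(locus_id, chrom, pos, group, n_ind, n_alleles, pi,
#'   he, ho, is_polymorphic)
#' @export
locusStats <- function(hm, individuals = NULL, group_id = "all",
                       unbiased_he = TRUE) {
  if (is.null(individuals)) individuals <- sampleInfo(hm)$individual
  sub <- hm[, individuals]
  cl <- haplotypeCalls(sub)
  lo <- radLoci(sub)
  n <- nrow(lo)
  n_ind <- integer(n); n_alleles <- integer(n)
  pi <- numeric(n); he <- numeric(n); ho <- numeric(n)
  for (i in seq_len(n)) {
    sp <- .callSpectrum(cl[i, ])
    n_ind[i] <- sp$n_ind
    if (sp$n_ind == 0L) {
      n_alleles[i] <- 0L; pi[i] <- NA_real_; he[i] <- NA_real_; ho[i] <- NA_real_
      next
    }
    k <- .alleleCounts(sp)
    n_alleles[i] <- length(k)
    n2 <- sum(k)
    ho[i] <- sum(sp$count[sp$a1 != sp$a2]) / sp$n_ind
    if (length(k) < 2L) {
      pi[i] <- 0; he[i] <- 0
    } else {
      p <- k / n2
      h <- 1 - sum(p^2)
      he[i] <- if (unbiased_he) h * n2 / (n2 - 1L) else h
      d <- .hammingMatrix(names(k))
      tot <- 0
      for (a in seq_len(length(k) - 1L)) for (b in seq.int(a + 1L, length(k)))
        tot <- tot + k[a] * k[b] * d[a, b]
      pi[i] <- tot / choose(n2, 2) / lo$length[i]
    }
  }
  data.frame(locus_id = lo$locus_id, chrom = lo$chrom, pos = lo$pos,
             group = group_id, n_ind = n_ind, n_alleles = n_alleles,
             pi = pi, he = he, ho = ho,
             is_polymorphic = n_alleles >= 2L,
             stringsAsFactors = FALSE)
}

#' Per-individual heterozygosity
#'
#' Proportion of heterozygous loci per individual over a locus set that
#' includes monomorphic loci (the per-individual analogue of Ho).
#'
#' @param hm a \code{\link{HaplotypeMatrix}}
#' @param individuals individual ids (default: all)
#' @param loci locus ids (default: all loci of the matrix)
#' @return named numeric vector, NA for individuals with no genotyped loci
#' @export
individualHeterozygosity <- function(hm, individuals = NULL, loci = NULL) {
  if (is.null(individuals)) individuals <- sampleInfo(hm)$individual
  if (is.null(loci)) loci <- radLoci(hm)$locus_id
  cl <- haplotypeCalls(hm[loci, individuals])
  lens <- radLoci(hm[loci, individuals])$length
  het <- matrix(FALSE, nrow(cl), ncol(cl))
  ok <- !is.na(cl)
  if (any(ok)) {
    L <- lens[row(cl)[ok]]
    v <- cl[ok]
    het[ok] <- substr(v, 1L, L) != substr(v, L + 2L, 2L * L + 1L)
  }
  geno <- colSums(ok)
  out <- colSums(het) / geno
  out[geno == 0L] <- NA_real_
  names(out) <- individuals
  out
}

## ---- AMOVA haplotype Fst -------------------------------------------------

#' Per-locus AMOVA F_ST from haplotype calls
#'
#' Treats the whole-tag haplotypes as unordered alleles and partitions the
#' allelic variance of the 2n sampled sequences among versus within
#' populations (one-level AMOVA with a binary allele-mismatch distance).
#' F_ST = sigma2_among / (sigma2_among + sigma2_within); negative estimates
#' are returned unclipped.
#'
#' @param calls character vector of canonical "h1/h2" calls, one per
#'   individual (NA = missing)
#' @param pops factor/character of population (or group) labels, parallel
#'   to \code{calls}
#' @return F_ST estimate, or NA when fewer than 2 populations have data
#' @export
locusAmovaFst <- function(calls, pops) {
  stopifnot(length(calls) == length(pops))
  keep <- !is.na(calls)
  calls <- calls[keep]; pops <- as.character(pops)[keep]
  upops <- unique(pops)
  if (length(upops) < 2L) return(NA_real_)
  ## per-population allele counts over the 2n sequences
  counts <- lapply(upops, function(p) .alleleCounts(.callSpectrum(calls[pops == p])))
  alleles <- unique(unlist(lapply(counts, names)))
  C <- sapply(counts, function(k) {
    v <- numeric(length(alleles)); names(v) <- alleles
    v[names(k)] <- k; v
  })
  if (is.null(dim(C))) C <- matrix(C, nrow = length(alleles))
  Np <- colSums(C)                      # sequences per population
  if (sum(Np > 0) < 2L) return(NA_real_)
  C <- C[, Np > 0, drop = FALSE]; Np <- Np[Np > 0]
  N <- sum(Np); P <- length(Np)
  ctot <- rowSums(C)
  ssd_total <- (N^2 - sum(ctot^2)) / (2 * N)
  ssd_wp <- sum((Np^2 - colSums(C^2)) / (2 * Np))
  ssd_ap <- ssd_total - ssd_wp
  if (N - P <= 0) return(NA_real_)
  s2_w <- ssd_wp / (N - P)
  nc <- (N - sum(Np^2) / N) / (P - 1)
  s2_a <- (ssd_ap / (P - 1) - s2_w) / nc
  if (s2_a + s2_w == 0) return(NA_real_)
  unname(s2_a / (s2_a + s2_w))
}

## ---- Weir-Cockerham pairwise Fst ------------------------------------------

## Weir & Cockerham (1984) variance components for one locus, two or more
## populations, multiallelic, using genotypic (diploid) information.
## Returns c(a, b, c) summed over alleles.
.wcComponents <- function(calls, pops) {
  keep <- !is.na(calls)
  calls <- calls[keep]; pops <- as.character(pops)[keep]
  upops <- unique(pops)
  r <- length(upops)
  if (r < 2L) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  sps <- lapply(upops, function(p) .callSpectrum(calls[pops == p]))
  n_i <- vapply(sps, function(s) as.numeric(s$n_ind), numeric(1))
  if (any(n_i == 0)) {
    ok <- n_i > 0
    sps <- sps[ok]; n_i <- n_i[ok]; r <- sum(ok)
    if (r < 2L) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  }
  alleles <- unique(unlist(lapply(sps, function(s) c(s$a1, s$a2))))
  nbar <- mean(n_i)
  nC <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
  a <- b <- cc <- 0
  for (al in alleles) {
    p_i <- vapply(sps, function(s)
      sum(s$count * ((s$a1 == al) + (s$a2 == al))) / (2 * s$n_ind), numeric(1))
    h_i <- vapply(sps, function(s)
      sum(s$count * (xor(s$a1 == al, s$a2 == al))) / s$n_ind, numeric(1))
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    a <- a + (nbar / nC) *
      (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
    b <- b + (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- cc + hbar / 2
  }
  c(a = a, b = b, c = cc)
}

#' Pairwise population F_ST (Weir & Cockerham) over many loci
#'
#' Multi-locus Weir-Cockerham (1984) theta for every pair of populations:
#' the ratio of summed among-population variance components to summed total
#' components across loci and alleles, with whole-tag haplotypes as
#' alleles. Also returns the linearized distance F_ST / (1 - F_ST) used for
#' isolation-by-distance regressions (Inf where F_ST = 1).
#'
#' @param hm a \code{\link{HaplotypeMatrix}}
#' @param loci locus ids to use (default all)
#' @param by sample column defining the units ("population" or "group")
#' @return list(fst = symmetric matrix, linearized = F_ST/(1-F_ST) matrix)
#' @export
pairwiseFst <- function(hm, loci = NULL, by = "population") {
  sm <- sampleInfo(hm)
  pops <- sm[[by]]
  upop <- unique(pops)
  if (length(upop) < 2L) stop("need at least 2 populations")
  if (!is.null(loci)) hm <- hm[loci, ]
  cl <- haplotypeCalls(hm)
  k <- length(upop)
  fst <- matrix(0, k, k, dimnames = list(upop, upop))
  for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
    sel <- pops %in% c(upop[i], upop[j])
    A <- B <- Cc <- 0
    for (l in seq_len(nrow(cl))) {
      comp <- .wcComponents(cl[l, sel], pops[sel])
      if (!is.na(comp[1])) {
        A <- A + comp[1]; B <- B + comp[2]; Cc <- Cc + comp[3]
      }
    }
    fst[i, j] <- fst[j, i] <- if (A + B + Cc == 0) NA_real_ else A / (A + B + Cc)
  }
  lin <- fst / (1 - fst)
  lin[is.nan(lin)] <- NA_real_
  list(fst = fst, linearized = lin)
}

## ---- Tajima's D ------------------------------------------------------------

#' Tajima (1989) normalizing constants
#'
#' @param n number of sampled sequences (>= 4 for a finite variance)
#' @return list(n, a1, a2, b1, b2, c1, c2, e1, e2)
#' @export
tajimaConstants <- function(n) {
  if (n < 2) stop("n must be >= 2")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(n = n, a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = e1, e2 = e2)
}

#' Tajima's D from segregating sites and mean pairwise differences
#'
#' D = (pihat - S/a1) / sqrt(e1 S + e2 S (S - 1)) with the Tajima (1989)
#' constants for n sequences. Positive D indicates an excess of
#' intermediate-frequency variants (the balancing-selection signature);
#' singleton-heavy spectra push D negative.
#'
#' @param S number of segregating sites in the window (>= 1)
#' @param pihat sum over sites of the per-site pairwise difference
#'   proportion (absolute, not per bp)
#' @param n number of sequences
#' @return D, or NA when S < 1 or n < 4
#' @export
tajimaD <- function(S, pihat, n) {
  if (is.na(S) || is.na(n) || S < 1 || n < 4) return(NA_real_)
  ct <- tajimaConstants(n)
  denom <- sqrt(ct$e1 * S + ct$e2 * S * (S - 1))
  if (denom == 0) return(NA_real_)
  (pihat - S / ct$a1) / denom
}

## ---- Isolation by distance -------------------------------------------------

#' Matrix regression of linearized F_ST on great-circle distance
#'
#' Regresses the vectorized upper triangle of a genetic distance matrix
#' (F_ST / (1 - F_ST)) on pairwise great-circle distances between
#' population coordinates (haversine, Earth radius 6371 km). Significance
#' comes from permuting rows and columns of the genetic matrix together and
#' recomputing the regression F statistic, with add-one correction.
#'
#' @param genetic symmetric genetic distance matrix, zero diagonal
#' @param coords data.frame(population, lat, lon) in matrix row order
#' @param n_permutations number of matrix permutations (default 999)
#' @param seed optional RNG seed
#' @return list(slope, intercept, F, p, distances_km)
#' @importFrom geosphere distHaversine
#' @export
ibdRegression <- function(genetic, coords, n_permutations = 999, seed = NULL) {
  k <- nrow(genetic)
  if (k < 4L) stop("need >= 4 populations")
  stopifnot(nrow(coords) == k)
  if (!is.null(seed)) set.seed(seed)
  pts <- cbind(coords$lon, coords$lat)
  geo <- matrix(0, k, k)
  for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k))
    geo[i, j] <- geo[j, i] <-
      geosphere::distHaversine(pts[i, ], pts[j, ], r = 6371)
  ut <- upper.tri(geo)
  x <- geo[ut]
  if (stats::var(x) == 0)
    return(list(slope = NA_real_, intercept = NA_real_, F = NA_real_,
                p = NA_real_, distances_km = geo))
  fstat <- function(gmat) {
    y <- gmat[ut]
    fit <- stats::lm(y ~ x)
    s <- summary(fit)
    c(s$coefficients[2, 1], s$coefficients[1, 1], s$fstatistic[1])
  }
  obs <- fstat(genetic)
  cnt <- 0L
  for (b in seq_len(n_permutations)) {
    pidx <- sample.int(k)
    if (fstat(genetic[pidx, pidx])[3] >= obs[3]) cnt <- cnt + 1L
  }
  list(slope = unname(obs[1]), intercept = unname(obs[2]),
       F = unname(obs[3]), p = (1 + cnt) / (n_permutations + 1),
       distances_km = geo)
}
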