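# In-code fixtures and independent oracles used across the suite.

# tiny HaplotypeMatrix from a list of per-locus call vectors
makeHapMatrix <- function(calls_list, L = 4L, pos = NULL, chrom = "chr1",
                          pops = NULL, groups = NULL) {
  n_ind <- length(calls_list[[1]])
  n_loc <- length(calls_list)
  if (is.null(pos)) pos <- seq_len(n_loc) * 1000
  if (is.null(pops)) pops <- rep("P1", n_ind)
  if (is.null(groups)) groups <- rep("G1", n_ind)
  loci <- data.frame(locus_id = sprintf("L%03d", seq_len(n_loc)),
                     chrom = chrom, pos = pos, length = L)
  samples <- data.frame(individual = sprintf("I%02d", seq_len(n_ind)),
                        population = pops, group = groups,
                        lat = 50, lon = 0)
  calls <- do.call(rbind, calls_list)
  HaplotypeMatrix(loci, samples, calls)
}

# random call vector over a small allele pool (short haplotypes)
randomCalls <- function(n_ind, L = 4L, n_alleles = 3L, miss = 0.1) {
  pool <- unique(replicate(n_alleles,
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")))
  a1 <- sample(pool, n_ind, replace = TRUE)
  a2 <- sample(pool, n_ind, replace = TRUE)
  calls <- paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
  calls[runif(n_ind) < miss] <- NA
  calls
}

# expand "h1/h2" calls to the vector of 2n sequences
expandSeqs <- function(calls) {
  calls <- calls[!is.na(calls)]
  unlist(strsplit(calls, "/", fixed = TRUE))
}

hamming <- function(a, b) sum(charToRaw(a) != charToRaw(b))

# brute-force pi: enumerate every unordered sequence pair
bruteForcePi <- function(calls, L) {
  s <- expandSeqs(calls)
  n <- length(s)
  if (n < 2) return(NA_real_)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n))
    tot <- tot + hamming(s[i], s[j])
  tot / choose(n, 2) / L
}

bruteForceHe <- function(calls, unbiased = TRUE) {
  s <- expandSeqs(calls)
  if (!length(s)) return(NA_real_)
  p <- table(s) / length(s)
  h <- 1 - sum(p^2)
  if (length(p) < 2) return(0)
  if (unbiased) h <- h * length(s) / (length(s) - 1)
  h
}

bruteForceHo <- function(calls) {
  calls <- calls[!is.na(calls)]
  if (!length(calls)) return(NA_real_)
  parts <- strsplit(calls, "/", fixed = TRUE)
  mean(vapply(parts, function(p) p[1] != p[2], logical(1)))
}

# brute-force one-level AMOVA from the explicit pairwise mismatch matrix
bruteForceAmovaFst <- function(calls, pops) {
  keep <- !is.na(calls)
  calls <- calls[keep]; pops <- as.character(pops)[keep]
  seqs <- expandSeqs(calls)
  spop <- rep(pops, each = 2)
  N <- length(seqs); P <- length(unique(spop))
  if (P < 2) return(NA_real_)
  delta <- outer(seqs, seqs, FUN = Vectorize(function(a, b) as.numeric(a != b)))
  ssd_tot <- sum(delta[upper.tri(delta)]) / N
  ssd_wp <- 0
  for (p in unique(spop)) {
    ii <- which(spop == p)
    d <- delta[ii, ii, drop = FALSE]
    ssd_wp <- ssd_wp + sum(d[upper.tri(d)]) / length(ii)
  }
  Np <- table(spop)
  s2w <- (ssd_wp) / (N - P)
  nc <- (N - sum(Np^2) / N) / (P - 1)
  s2a <- ((ssd_tot - ssd_wp) / (P - 1) - s2w) / nc
  if (s2a + s2w == 0) return(NA_real_)
  s2a / (s2a + s2w)
}

# independent Weir-Cockerham theta via the nested ANOVA sums-of-squares
# route (allele indicators over gametes / individuals / populations)
bruteForceWcTheta <- function(calls, pops) {
  keep <- !is.na(calls)
  calls <- calls[keep]; pops <- as.character(pops)[keep]
  parts <- strsplit(calls, "/", fixed = TRUE)
  alleles <- unique(unlist(parts))
  upop <- unique(pops)
  r <- length(upop)
  n_i <- as.numeric(table(factor(pops, upop)))
  N <- sum(n_i)
  nc <- (N - sum(n_i^2) / N) / (r - 1)
  A <- B <- G <- 0
  for (al in alleles) {
    x <- t(vapply(parts, function(p) as.numeric(p == al), numeric(2)))
    xbar_ind <- rowMeans(x)
    p_i <- vapply(upop, function(pp) mean(xbar_ind[pops == pp]), numeric(1))
    pw <- sum(n_i * p_i) / N
    SSG <- sum((x - xbar_ind)^2)
    SSI <- 2 * sum((xbar_ind - p_i[match(pops, upop)])^2)
    SSP <- 2 * sum(n_i * (p_i - pw)^2)
    MSG <- SSG / N
    MSI <- SSI / (N - r)
    MSP <- SSP / (r - 1)
    s2a <- (MSP - MSI) / (2 * nc)
    s2b <- (MSI - MSG) / 2
    A <- A + s2a; B <- B + s2b; G <- G + MSG
  }
  A / (A + B + G)
}

# collapse simulated haplotype sequences into diploid calls
seqsToCalls <- function(s) {
  a1 <- s[seq(1, length(s) - 1, 2)]
  a2 <- s[seq(2, length(s), 2)]
  paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
}
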