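test_that("kernel smoothing: convexity, isolated locus, hand-weighted mean", {
  # constant values smooth to the constant
  pos <- seq(1000, 100000, by = 2000)
  sw <- smoothStatistic(rep("chr1", length(pos)), pos, rep(0.3, length(pos)),
                        sigma = 10000)
  expect_true(all(abs(windowTable(sw)$value - 0.3) < 1e-12))
  # single isolated locus keeps its own value
  sw1 <- smoothStatistic("chr1", 5000, 0.7, sigma = 1000)
  expect_equal(windowTable(sw1)$value, 0.7)
  expect_equal(windowTable(sw1)$n_loci, 1L)
  # locus exactly sigma away carries weight exp(-1/2)
  sw2 <- smoothStatistic(c("chr1", "chr1"), c(10000, 20000), c(1, 0),
                         sigma = 10000, centers = c(TRUE, FALSE))
  w <- exp(-0.5)
  expect_equal(windowTable(sw2)$value, (1 * 1 + 0 * w) / (1 + w),
               tolerance = 1e-12)
  # convex combination bound on random data, and 3-sigma truncation
  set.seed(4)
  pos <- sort(sample.int(5e5, 300))
  val <- rexp(300)
  sw3 <- smoothStatistic(rep("chr1", 300), pos, val, sigma = 8000)
  wt <- windowTable(sw3)
  for (k in seq_len(nrow(wt))) {
    idx <- sw3@contrib[[k]]$idx
    expect_true(all(abs(pos[idx] - wt$center[k]) <= 3 * 8000))
    expect_gte(wt$value[k], min(val[idx]) - 1e-12)
    expect_lte(wt$value[k], max(val[idx]) + 1e-12)
    expect_equal(max(sw3@contrib[[k]]$w), 1)
  }
})

test_that("bootstrap p-values behave at the degenerate extremes", {
  pos <- seq(1000, 50000, by = 1000)
  n <- length(pos)
  # constant pool: every pseudoreplicate ties the observed -> p = 1
  swc <- smoothStatistic(rep("chr1", n), pos, rep(0.5, n), sigma = 5000)
  swc <- bootstrapWindowPvalues(swc, rep(0.5, n), n_reps = 200, seed = 1)
  expect_true(all(windowTable(swc)$boot_p == 1))
  # observed above the pool maximum -> minimal p = 1/(n_reps+1)
  val <- c(rep(0, n - 1), 100)
  swx <- smoothStatistic(rep("chr1", n), pos, val, sigma = 300,
                         centers = seq_len(n) == n)
  swx <- bootstrapWindowPvalues(swx, rep(0.001, 500), n_reps = 500, seed = 2)
  expect_equal(windowTable(swx)$boot_p, 1 / 501)
  # observed below the pool minimum -> p = 1
  swl <- smoothStatistic(rep("chr1", n), pos, rep(0, n), sigma = 300,
                         centers = seq_len(n) == 1)
  swl <- bootstrapWindowPvalues(swl, runif(500, 1, 2), n_reps = 300, seed = 3)
  expect_equal(windowTable(swl)$boot_p, 1)
  expect_error(bootstrapWindowPvalues(swl, runif(500), n_reps = 50), "100")
})

test_that("single-locus outliers use nearest-rank threshold with ties", {
  v <- sample(seq_len(1000))            # 1000 distinct values
  out <- singleLocusOutliers(v, 0.99)
  expect_length(out, 10)
  expect_true(all(v[out] > 990))
  # all identical -> everything returned
  expect_length(singleLocusOutliers(rep(1, 50), 0.99), 50)
  expect_error(singleLocusOutliers(numeric(0)), "empty")
  # brute-force sort-and-slice on random input with ties
  set.seed(8)
  for (rep in 1:10) {
    x <- sample(1:40, 200, replace = TRUE)
    got <- sort(singleLocusOutliers(x, 0.95))
    thr <- sort(x, decreasing = TRUE)[10]   # top 5% of 200
    expect_equal(got, which(x >= thr))
  }
})

test_that("window merging follows the centre-gap < sigma rule and is idempotent", {
  # gap 60 kb < sigma=150 kb -> one region, clipped at the chromosome start
  w <- data.frame(chrom = "chr1", center = c(100000, 160000))
  r <- mergeWindowsToRegions(w, sigma = 150000)
  expect_length(r, 1)
  expect_equal(GenomicRanges::start(r), 1)
  expect_equal(GenomicRanges::end(r), 310000)
  # gap 300 kb >= sigma -> two regions
  w2 <- data.frame(chrom = "chr1", center = c(100000, 400000))
  expect_length(mergeWindowsToRegions(w2, sigma = 150000), 2)
  # brute-force union-find on random window sets + idempotence
  set.seed(17)
  for (rep in 1:10) {
    cen <- sort(sample.int(2e6, 40))
    sig <- 30000
    w3 <- data.frame(chrom = "chr1", center = cen)
    r3 <- mergeWindowsToRegions(w3, sig)
    grp <- cumsum(c(TRUE, diff(cen) >= sig))
    expect_length(r3, length(unique(grp)))
    # merging the merged regions' centres again changes nothing
    again <- mergeWindowsToRegions(
      data.frame(chrom = "chr1", center = cen), sig)
    expect_identical(as.data.frame(r3), as.data.frame(again))
  }
})

test_that("quantile window selection picks nearest-rank tails", {
  df <- data.frame(chrom = "chr1", center = seq_len(100) * 1000,
                   value = sample(seq_len(100)))
  lo <- quantileWindows(df, "lower", 0.05)
  hi <- quantileWindows(df, "upper", 0.05)
  expect_equal(nrow(lo), 5)
  expect_equal(nrow(hi), 5)
  expect_true(all(lo$value <= 5))
  expect_true(all(hi$value >= 96))
  # symmetric values -> equal tail sizes
  df2 <- data.frame(value = c(-(1:20), 1:20))
  expect_equal(nrow(quantileWindows(df2, "lower", 0.1)),
               nrow(quantileWindows(df2, "upper", 0.1)))
})

test_that("sliding D-window grid places sites in the right windows", {
  # one SNP at pos 115000 falls in the 10 windows starting 1..108001
  a1 <- matrix(c(0L, 1L, 0L, 1L), 1, 4)
  a2 <- matrix(c(0L, 0L, 1L, 1L), 1, 4)
  colnames(a1) <- colnames(a2) <- paste0("I", 1:4)
  snps <- list(sites = data.frame(chrom = "chr1", pos = 115000,
                                  ref = "A", alt = "T"), a1 = a1, a2 = a2)
  dw <- slidingTajimaD(snps, width = 120000, step = 12000,
                       chrom_lengths = c(chr1 = 130000))
  est <- dw[!is.na(dw$D), ]
  expect_equal(nrow(est), 10)
  expect_equal(est$start, seq(1, 108001, by = 12000))
  expect_true(all(est$S == 1))
  # D matches tajimaD applied to the window's (S, pihat, n) by hand
  expect_equal(unique(est$D), tajimaD(1, 2 * 4 * 4 / (8 * 7), 8))
  # no SNPs -> no estimable windows
  empty <- list(sites = data.frame(chrom = character(), pos = numeric(),
                                   ref = character(), alt = character()),
                a1 = matrix(integer(), 0, 4), a2 = matrix(integer(), 0, 4))
  expect_equal(nrow(slidingTajimaD(empty)), 0)
})

test_that("sliding D handles missing genotypes per site", {
  # site 1: complete; site 2: one individual missing -> n = 6
  a1 <- rbind(c(0L, 1L, 0L, 1L), c(0L, 1L, NA, 1L))
  a2 <- rbind(c(0L, 0L, 1L, 1L), c(0L, 0L, NA, 1L))
  colnames(a1) <- colnames(a2) <- paste0("I", 1:4)
  snps <- list(sites = data.frame(chrom = "chr1", pos = c(5000, 6000),
                                  ref = "A", alt = "T"), a1 = a1, a2 = a2)
  dw <- slidingTajimaD(snps, width = 12000, step = 12000,
                       chrom_lengths = c(chr1 = 12000))
  expect_equal(dw$S, 2L)
  expect_equal(dw$n, 7)                  # median of (8, 6) -> 7
  h1 <- 2 * 4 * 4 / (8 * 7)
  h2 <- 2 * 3 * 3 / (6 * 5)
  expect_equal(dw$D, tajimaD(2, h1 + h2, 7))
})

test_that("top-D selection sizes follow round(q * n) with genomic tie-break", {
  mk <- function(n) data.frame(chrom = "chr1",
                               start = seq_len(n) * 1000,
                               end = seq_len(n) * 1000 + 999,
                               S = 1L, n = 8, pihat = 0.5,
                               D = rnorm(n))
  set.seed(23)
  expect_equal(nrow(topDWindows(mk(14278), 0.05)), 714)
  expect_equal(nrow(topDWindows(mk(13679), 0.05)), 684)
  # brute-force sort-and-slice
  d <- mk(400)
  top <- topDWindows(d, 0.05)
  expect_equal(sort(top$D, decreasing = TRUE),
               sort(d$D, decreasing = TRUE)[1:20])
  # exact size under ties at the boundary, earlier windows kept
  d2 <- mk(100); d2$D <- rep(1, 100)
  top2 <- topDWindows(d2, 0.05)
  expect_equal(nrow(top2), 5)
  expect_equal(top2$start, (1:5) * 1000)
})

test_that("interval overlap counts and fractions match brute force", {
  A <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 100, 300),
                                                       c(50, 150, 400)))
  B <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(120, 500), c(130, 600)))
  ov <- intervalOverlap(A, B)
  expect_equal(ov$count, 1)
  expect_equal(ov$fraction, 1 / 3)
  # disjoint -> 0; nested -> 1
  expect_equal(suppressWarnings(intervalOverlap(A,
    GenomicRanges::GRanges("chr2", IRanges::IRanges(1, 10))))$fraction, 0)
  expect_equal(intervalOverlap(A, GenomicRanges::GRanges("chr1",
    IRanges::IRanges(1, 1000)))$fraction, 1)
  # random sets vs all-pairs brute force
  set.seed(31)
  for (rep in 1:10) {
    s1 <- sample.int(1e4, 30); s2 <- sample.int(1e4, 20)
    A <- GenomicRanges::GRanges("chr1", IRanges::IRanges(s1, s1 + 199))
    B <- GenomicRanges::GRanges("chr1", IRanges::IRanges(s2, s2 + 99))
    got <- intervalOverlap(A, B)$count
    brute <- sum(vapply(seq_along(s1), function(i)
      any(s1[i] <= s2 + 99 & s2 <= s1[i] + 199), logical(1)))
    expect_equal(got, brute)
  }
})

test_that("sigma helper hits the ~30 loci per window convention", {
  expect_equal(sigmaForLocusDensity(12000, 30), 60000)
  expect_equal(sigmaForLocusDensity(11595, 30), 57975)
})
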