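## Kernel-smoothed window scan, bootstrap significance, region merging,
## quantile window selection, sliding-window Tajima's D and interval overlap.

#' Smoothing scale for a target number of loci per window
#'
#' Each smoothed window is 6 sigma long, so with loci spaced
#' \code{mean_spacing} apart on average, a window holds about
#' 6 sigma / mean_spacing loci. Returns the sigma for which that count
#' equals \code{target_loci} (the convention is ~30 loci per window).
#'
#' @param mean_spacing mean inter-locus distance in bp
#' @param target_loci desired average loci per window (default 30)
#' @return sigma in bp
#' @export
sigmaForLocusDensity <- function(mean_spacing, target_loci = 30) {
  stopifnot(mean_spacing > 0, target_loci > 0)
  target_loci * mean_spacing / 6
}

#' Gaussian kernel smoothing of a per-locus statistic
#'
#' For every centre (a polymorphic RAD locus) the smoothed value is the
#' kernel-weighted mean of the per-locus statistic over all loci within
#' 3 sigma of the centre, with weights exp(-d^2 / (2 sigma^2)); the centre
#' locus carries weight 1. One window per centre.
#'
#' @param chrom chromosome per locus
#' @param pos position per locus (bp)
#' @param values per-locus statistic (NA values are dropped from every
#'   window they would contribute to)
#' @param sigma smoothing scale in bp
#' @param centers logical vector marking the centre loci (typically the
#'   polymorphic ones); default: all loci with non-NA value
#' @param stat name of the statistic, stored on the result
#' @return a \code{\link{SmoothedWindows}} object
#' @export
smoothStatistic <- function(chrom, pos, values, sigma, centers = NULL,
                            stat = "pi") {
  stopifnot(sigma > 0, length(chrom) == length(pos),
            length(pos) == length(values))
  if (is.null(centers)) centers <- !is.na(values)
  o <- order(chrom, pos)
  chrom <- chrom[o]; pos <- pos[o]; values <- values[o]
  centers <- centers[o]
  if (!any(centers & !is.na(values))) stop("no centre loci")
  win <- list(); contrib <- list()
  for (ch in unique(chrom)) {
    csel <- which(chrom == ch & !is.na(values))
    cp <- pos[csel]                      # usable loci, sorted
    cv <- values[csel]
    cens <- which(centers[csel])
    for (k in cens) {
      c0 <- cp[k]
      lo <- findInterval(c0 - 3 * sigma - 0.5, cp) + 1L
      hi <- findInterval(c0 + 3 * sigma, cp)
      idx <- seq.int(min(lo, k), max(hi, k))
      idx <- idx[abs(cp[idx] - c0) <= 3 * sigma]
      w <- exp(-(cp[idx] - c0)^2 / (2 * sigma^2))
      v <- sum(cv[idx] * w) / sum(w)
      win[[length(win) + 1L]] <-
        data.frame(chrom = ch, center = c0, value = v,
                   n_loci = length(idx), stringsAsFactors = FALSE)
      contrib[[length(contrib) + 1L]] <- list(idx = csel[idx], w = w)
    }
  }
  df <- do.call(rbind, win)
  rownames(df) <- NULL
  new("SmoothedWindows", stat = stat, sigma = sigma, windows = df,
      contrib = contrib)
}

#' Bootstrap p-values for elevated smoothed windows
#'
#' Tests each window for significantly higher smoothed value than expected
#' under the genome-wide per-locus distribution. Each pseudoreplicate
#' redraws the window's m contributing loci with replacement from the
#' genome-wide pool and recomputes the weighted mean with the window's own
#' kernel weights. The upper-tail p-value uses the add-one correction
#' p = (1 + #{pseudoreplicate >= observed}) / (n_reps + 1).
#'
#' @param sw a \code{\link{SmoothedWindows}} object
#' @param pool genome-wide per-locus values (NA dropped)
#' @param n_reps pseudoreplicates per window (>= 100; default 10000)
#' @param alpha significance level used for the \code{significant} flag
#' @param seed optional RNG seed
#' @return the \code{SmoothedWindows} with boot_p and significant columns
#' @export
bootstrapWindowPvalues <- function(sw, pool, n_reps = 10000, alpha = 0.05,
                                   seed = NULL) {
  pool <- pool[!is.na(pool)]
  if (length(pool) < 2L) stop("pool must hold at least 2 values")
  if (n_reps < 100) stop("n_reps must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  df <- sw@windows
  np <- length(pool)
  boot_p <- numeric(nrow(df))
  for (k in seq_len(nrow(df))) {
    w <- sw@contrib[[k]]$w
    m <- length(w)
    draws <- pool[sample.int(np, n_reps * m, replace = TRUE)]
    dim(draws) <- c(n_reps, m)
    stat <- as.vector(draws %*% w) / sum(w)
    ## tolerance so exact ties (degenerate pools) count as >=
    tol <- 1e-9 * (abs(df$value[k]) + 1e-12)
    boot_p[k] <- (1 + sum(stat >= df$value[k] - tol)) / (n_reps + 1)
  }
  df$boot_p <- boot_p
  df$significant <- boot_p < alpha
  attr(df, "alpha") <- alpha
  sw@windows <- df
  sw
}

#' Single-locus outliers by upper quantile
#'
#' Returns the loci in the top (1 - q) tail of the per-locus statistic:
#' the k = ceiling((1 - q) n) largest values define the threshold (the
#' k-th largest) and every locus with value >= threshold is returned, so
#' ties at the threshold are all included.
#'
#' @param values per-locus statistic (NA dropped from the ranking)
#' @param q quantile in (0, 1); default 0.99 (top 1 percent)
#' @return integer indices into \code{values}
#' @export
singleLocusOutliers <- function(values, q = 0.99) {
  if (!length(values)) stop("empty input")
  stopifnot(q > 0, q < 1)
  ok <- which(!is.na(values))
  v <- values[ok]
  k <- max(1L, as.integer(ceiling((1 - q) * length(v) - 1e-9)))
  thr <- sort(v, decreasing = TRUE)[k]
  ok[v >= thr]
}

#' Merge significant windows into genomic regions
#'
#' Consecutive significant windows on one chromosome whose centres are
#' separated by less than sigma collapse into one region spanning
#' [first centre - sigma, last centre + sigma], clipped at the chromosome
#' start (and end if chromosome lengths are supplied). Merging is
#' idempotent.
#'
#' @param windows data.frame with chrom and center columns (only the
#'   significant windows should be passed)
#' @param sigma smoothing scale in bp
#' @param chrom_lengths optional named vector of chromosome lengths
#' @return \code{GRanges} of regions with an \code{n_windows} column
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @export
mergeWindowsToRegions <- function(windows, sigma, chrom_lengths = NULL) {
  if (is(windows, "SmoothedWindows")) windows <- windowTable(windows)
  if (!nrow(windows))
    return(GenomicRanges::GRanges())
  windows <- windows[order(windows$chrom, windows$center), , drop = FALSE]
  out <- list()
  for (ch in unique(windows$chrom)) {
    cen <- windows$center[windows$chrom == ch]
    newgrp <- c(TRUE, diff(cen) >= sigma)
    grp <- cumsum(newgrp)
    for (g in unique(grp)) {
      cc <- cen[grp == g]
      s <- max(1, min(cc) - sigma)
      e <- max(cc) + sigma
      if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths))
        e <- min(e, chrom_lengths[[ch]])
      out[[length(out) + 1L]] <- data.frame(chrom = ch, start = s, end = e,
                                            n_windows = length(cc))
    }
  }
  df <- do.call(rbind, out)
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                         n_windows = df$n_windows)
}

#' Select windows in an extreme tail of the smoothed distribution
#'
#' Nearest-rank empirical quantile selection: the lower tail keeps windows
#' with value <= the k-th smallest value (k = ceiling(q n)); the upper tail
#' keeps windows with value >= the k-th largest. Ties at the threshold are
#' included.
#'
#' @param sw \code{\link{SmoothedWindows}} or a window data.frame with a
#'   value column
#' @param tail "lower" or "upper"
#' @param q tail mass (default 0.05)
#' @return data.frame of the selected windows
#' @export
quantileWindows <- function(sw, tail = c("lower", "upper"), q = 0.05) {
  tail <- match.arg(tail)
  df <- if (is(sw, "SmoothedWindows")) windowTable(sw) else sw
  v <- df$value
  ok <- !is.na(v)
  n <- sum(ok)
  if (n < 1L) stop("no windows")
  k <- max(1L, as.integer(ceiling(q * n - 1e-9)))
  if (tail == "lower") {
    thr <- sort(v[ok])[k]
    df[ok & v <= thr, , drop = FALSE]
  } else {
    thr <- sort(v[ok], decreasing = TRUE)[k]
    df[ok & v >= thr, , drop = FALSE]
  }
}

#' Sliding-window Tajima's D over SNP genotypes
#'
#' Fixed windows of the given width advancing by \code{step} along each
#' chromosome (grid anchored at coordinate 1), the classic 120 kbp / 12 kbp
#' layout. Per window, S counts the polymorphic sites and pihat sums the
#' per-site pairwise-difference proportions over the non-missing sequences;
#' D comes from \code{\link{tajimaD}} with n = the median per-site number
#' of non-missing sequences in the window. Windows without polymorphic
#' sites are reported with NA D (counted as not estimable).
#'
#' @param snps SNP set as returned by \code{\link{readVcfSnps}} or
#'   \code{\link{simulateDataset}}: list(sites, a1, a2) with allele
#'   matrices (sites x individuals, entries 0/1/NA)
#' @param individuals columns (individual ids) to use; default all
#' @param width window width in bp (default 120000)
#' @param step window shift in bp (default 12000)
#' @param chrom_lengths optional named vector bounding the grid
#' @return data.frame(chrom, start, end, S, n, pihat, D)
#' @export
slidingTajimaD <- function(snps, individuals = NULL, width = 120000,
                           step = 12000, chrom_lengths = NULL) {
  sites <- snps$sites
  if (is.null(sites) || !nrow(sites))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), S = integer(), n = numeric(),
                      pihat = numeric(), D = numeric()))
  a1 <- snps$a1; a2 <- snps$a2
  if (!is.null(individuals)) {
    j <- match(individuals, colnames(a1))
    if (anyNA(j)) stop("unknown individuals in SNP set")
    a1 <- a1[, j, drop = FALSE]; a2 <- a2[, j, drop = FALSE]
  }
  ## per-site derived count and non-missing sequence count
  ok1 <- !is.na(a1); ok2 <- !is.na(a2)
  nseq <- rowSums(ok1) + rowSums(ok2)
  der <- rowSums(a1, na.rm = TRUE) + rowSums(a2, na.rm = TRUE)
  poly <- der > 0 & der < nseq & nseq >= 2
  hsite <- ifelse(poly, 2 * der * (nseq - der) / (nseq * (nseq - 1)), 0)
  out <- list()
  for (ch in unique(sites$chrom)) {
    sel <- which(sites$chrom == ch)
    maxpos <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths))
      chrom_lengths[[ch]] else max(sites$pos[sel])
    starts <- seq(1, max(1, maxpos - 1), by = step)
    ## assign each site to every window containing it
    S <- integer(length(starts)); ph <- numeric(length(starts))
    nmed <- rep(NA_real_, length(starts))
    widx <- rep(list(integer()), length(starts))
    for (s in sel) {
      p <- sites$pos[s]
      k1 <- ceiling((p - width + 1 - 1) / step) + 1  # first window index
      k1 <- max(1L, as.integer(k1))
      k2 <- as.integer(floor((p - 1) / step) + 1)
      k2 <- min(k2, length(starts))
      if (k1 > k2) next
      for (k in k1:k2) {
        if (poly[s]) {
          S[k] <- S[k] + 1L
          ph[k] <- ph[k] + hsite[s]
          widx[[k]] <- c(widx[[k]], s)
        }
      }
    }
    D <- rep(NA_real_, length(starts))
    for (k in which(S > 0)) {
      nmed[k] <- round(stats::median(nseq[widx[[k]]]))
      D[k] <- tajimaD(S[k], ph[k], nmed[k])
    }
    out[[ch]] <- data.frame(chrom = ch, start = starts,
                            end = starts + width - 1, S = S, n = nmed,
                            pihat = ph, D = D, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Top Tajima's D windows
#'
#' Selects exactly round(q * n_estimable) windows with the highest D among
#' the estimable windows (S >= 1). Ties at the boundary are resolved by
#' genomic order, earlier windows kept, so the selection size is exact.
#'
#' @param dwin data.frame from \code{\link{slidingTajimaD}}
#' @param q tail mass (default 0.05)
#' @return data.frame of the selected windows
#' @export
topDWindows <- function(dwin, q = 0.05) {
  est <- dwin[!is.na(dwin$D), , drop = FALSE]
  n <- nrow(est)
  if (!n) return(est)
  k <- round(q * n)
  if (k < 1L) return(est[0, , drop = FALSE])
  o <- order(-est$D, est$chrom, est$start)
  est[sort(o[seq_len(min(k, n))]), , drop = FALSE]
}

#' Overlap between two interval sets
#'
#' Counts how many intervals of A intersect at least one interval of B and
#' returns the overlapping pairs. Smoothed windows are first expanded to
#' [center - sigma, center + sigma] with \code{\link{windowsAsRanges}}.
#'
#' @param A,B \code{GRanges}
#' @return list(pairs = data.frame(a, b), count, fraction = count / |A|)
#' @importFrom GenomicRanges findOverlaps
#' @importFrom S4Vectors queryHits subjectHits
#' @export
intervalOverlap <- function(A, B) {
  hits <- GenomicRanges::findOverlaps(A, B)
  qh <- S4Vectors::queryHits(hits)
  list(pairs = data.frame(a = qh, b = S4Vectors::subjectHits(hits)),
       count = length(unique(qh)),
       fraction = if (length(A)) length(unique(qh)) / length(A) else NA_real_)
}

#' Represent smoothed windows as +/- 1 sigma genomic intervals
#'
#' @param windows \code{\link{SmoothedWindows}} or a window data.frame
#' @param sigma smoothing scale (taken from the object when omitted)
#' @return \code{GRanges} of [center - sigma, center + sigma]
#' @export
windowsAsRanges <- function(windows, sigma = NULL) {
  if (is(windows, "SmoothedWindows")) {
    if (is.null(sigma)) sigma <- windows@sigma
    windows <- windowTable(windows)
  }
  if (is.null(sigma)) stop("sigma required for a plain window table")
  if (!nrow(windows)) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(windows$chrom,
    IRanges::IRanges(pmax(1, windows$center - sigma),
                     windows$center + sigma))
}

#' \code{GRanges} for fixed Tajima's D windows
#'
#' @param dwin data.frame from \code{\link{slidingTajimaD}}
#' @return \code{GRanges}
#' @export
dWindowsAsRanges <- function(dwin) {
  if (!nrow(dwin)) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(dwin$chrom, IRanges::IRanges(dwin$start, dwin$end))
}
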