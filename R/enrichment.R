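## Gene-level layer: gene counts per smoothed window, label-permutation
## enrichment of a gene class in high-diversity windows, region annotation
## and cross-group shared-candidate partitions.

#' Count class-member genes per smoothed window
#'
#' Counts, for every window, the genes of the given class whose interval
#' intersects the +/- 1 sigma window interval [center - sigma,
#' center + sigma]. A gene spanning several windows counts in each of them
#' (the density is per window, not a partition of the genes).
#'
#' @param windows \code{\link{SmoothedWindows}} or a window data.frame
#' @param genes \code{GRanges} with gene_class column
#' @param gene_class class to count (default "candidate"); NULL counts all
#' @param sigma smoothing scale (needed only for a plain data.frame)
#' @return integer vector, one count per window
#' @importFrom GenomicRanges countOverlaps
#' @export
geneCountsPerWindow <- function(windows, genes, gene_class = "candidate",
                                sigma = NULL) {
  gr <- windowsAsRanges(windows, sigma)
  if (!is.null(gene_class)) genes <- genes[genes$gene_class == gene_class]
  GenomicRanges::countOverlaps(gr, genes)
}

#' Label-permutation enrichment test for a gene class
#'
#' Tests whether windows labelled "high diversity" carry more class-member
#' genes per window than the remaining windows. The observed statistic is
#' mean(counts[high]) - mean(counts[other]); the null distribution comes
#' from permuting the high/not-high label vector without replacement
#' (preserving the class sizes) and recomputing the difference. One-sided
#' p with the add-one correction:
#' p = (1 + #(null >= observed)) / (n_permutations + 1).
#'
#' When the total number of distinct labelings choose(n, n_high) does not
#' exceed \code{exhaustive_limit}, the null is enumerated exhaustively and
#' p = #(null >= observed) / n_labelings (the observed labeling is one of
#' the enumerated ones).
#'
#' @param counts per-window gene counts
#' @param high logical vector: TRUE for high-diversity windows
#' @param n_permutations Monte-Carlo permutations (default 1000)
#' @param seed optional RNG seed
#' @param exhaustive_limit switch to exact enumeration at or below this
#'   many labelings (default 1e5; set 0 to force Monte-Carlo)
#' @return list with observed means, observed_diff, p_value, n_permutations,
#'   method, and null_summary (mean, sd, max)
#' @export
enrichmentPermutationTest <- function(counts, high, n_permutations = 1000,
                                      seed = NULL, exhaustive_limit = 1e5) {
  stopifnot(length(counts) == length(high))
  high <- as.logical(high)
  n <- length(counts)
  k <- sum(high)
  if (k == 0L || k == n) stop("both label classes must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  tot <- sum(counts)
  diff_for <- function(sum_high)
    sum_high / k - (tot - sum_high) / (n - k)
  obs <- diff_for(sum(counts[high]))
  ncomb <- choose(n, k)
  if (ncomb <= exhaustive_limit && exhaustive_limit > 0) {
    combs <- utils::combn(n, k)
    null <- apply(combs, 2, function(idx) diff_for(sum(counts[idx])))
    p <- sum(null >= obs) / length(null)
    method <- "exhaustive"
    nperm <- length(null)
  } else {
    null <- vapply(seq_len(n_permutations), function(b)
      diff_for(sum(counts[sample.int(n, k)])), numeric(1))
    p <- (1 + sum(null >= obs)) / (n_permutations + 1)
    method <- "monte-carlo"
    nperm <- n_permutations
  }
  list(n_high_windows = k, n_other_windows = n - k,
       mean_count_high = sum(counts[high]) / k,
       mean_count_other = (tot - sum(counts[high])) / (n - k),
       observed_diff = obs, p_value = p, n_permutations = nperm,
       method = method,
       null_summary = c(mean = mean(null), sd = stats::sd(null),
                        max = max(null)))
}

#' Annotate merged regions with gene content
#'
#' Per region: gene count and class-member gene ids (a gene belongs to a
#' region when its interval overlaps it). Totals include summed region
#' length (Mbp) and the class density per Mbp inside regions versus
#' genome-wide.
#'
#' @param regions \code{GRanges} of merged high-diversity regions
#' @param genes \code{GRanges} with gene_id and gene_class columns
#' @param gene_class class of interest (default "candidate")
#' @param genome_length total genome length in bp for the genome-wide
#'   density (default: sum of spans of the gene set's chromosomes)
#' @return list(per_region = data.frame, totals = list)
#' @importFrom GenomicRanges findOverlaps width seqnames
#' @export
annotateRegions <- function(regions, genes, gene_class = "candidate",
                            genome_length = NULL) {
  cls <- genes[genes$gene_class == gene_class]
  if (is.null(genome_length)) {
    spans <- tapply(GenomicRanges::end(genes),
                    as.character(GenomicRanges::seqnames(genes)), max)
    genome_length <- sum(spans)
  }
  n <- length(regions)
  if (n == 0L) {
    return(list(per_region = data.frame(chrom = character(),
                  start = numeric(), end = numeric(), n_genes = integer(),
                  n_class = integer(), class_ids = character()),
                totals = list(n_regions = 0L, total_length_mbp = 0,
                  n_genes = 0L, n_class = 0L,
                  class_density_in = NA_real_,
                  class_density_genome = length(cls) / (genome_length / 1e6))))
  }
  hits_all <- GenomicRanges::findOverlaps(regions, genes)
  hits_cls <- GenomicRanges::findOverlaps(regions, cls)
  n_genes <- tabulate(S4Vectors::queryHits(hits_all), n)
  n_class <- tabulate(S4Vectors::queryHits(hits_cls), n)
  ids <- vapply(seq_len(n), function(i) {
    j <- S4Vectors::subjectHits(hits_cls)[S4Vectors::queryHits(hits_cls) == i]
    paste(sort(cls$gene_id[j]), collapse = ",")
  }, character(1))
  per <- data.frame(chrom = as.character(GenomicRanges::seqnames(regions)),
                    start = GenomicRanges::start(regions),
                    end = GenomicRanges::end(regions),
                    n_genes = n_genes, n_class = n_class,
                    class_ids = ids, stringsAsFactors = FALSE)
  tot_len <- sum(GenomicRanges::width(regions))
  uniq_genes <- length(unique(S4Vectors::subjectHits(hits_all)))
  uniq_class <- length(unique(S4Vectors::subjectHits(hits_cls)))
  list(per_region = per,
       totals = list(n_regions = n, total_length_mbp = tot_len / 1e6,
                     n_genes = uniq_genes, n_class = uniq_class,
                     class_density_in = uniq_class / (tot_len / 1e6),
                     class_density_genome = length(cls) / (genome_length / 1e6)))
}

#' Shared candidate genes across sample groups (Venn partition)
#'
#' Exact set-algebra partition of per-group candidate gene-id sets into
#' disjoint cells (one per non-empty combination of groups). Cells are
#' disjoint and union to the union of the inputs; gene ids within each
#' cell are sorted.
#'
#' @param sets named list of character vectors (>= 2 groups)
#' @return list(cells = named list of id vectors, sizes = named integer)
#' @export
sharedCandidates <- function(sets) {
  if (length(sets) < 2L) stop("need >= 2 groups")
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("sets must be named by group")
  sets <- lapply(sets, unique)
  all_ids <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) all_ids %in% s,
                   logical(length(all_ids)))
  if (is.null(dim(member))) member <- matrix(member, nrow = length(all_ids))
  key <- apply(member, 1, function(r)
    paste(names(sets)[r], collapse = "&"))
  cells <- split(all_ids, key)
  cells <- lapply(cells, sort)
  ## present every possible combination, empty cells included
  combos <- unlist(lapply(seq_along(sets), function(m)
    utils::combn(names(sets), m, paste, collapse = "&", simplify = FALSE)),
    use.names = FALSE)
  out <- stats::setNames(vector("list", length(combos)), combos)
  for (cb in combos) out[[cb]] <- cells[[cb]] %||% character()
  list(cells = out, sizes = vapply(out, length, integer(1)))
}
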