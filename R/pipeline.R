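## End-to-end orchestration of the scan for one sample group, and the
## summary-table arithmetic (window category counts, proportions, top-D
## overlap percentages).

#' Scan configuration for one sample group
#'
#' @param group_id label of the sample group being scanned
#' @param individuals individual ids in the group (NULL = all)
#' @param populations sample column used as the F_ST stratification
#'   ("population" or "group")
#' @param max_missing_frac presence filter (0 = loci present in all group
#'   members, 0.5 = present in at least half)
#' @param sigma smoothing scale in bp (e.g. 60000 for ~30 loci per window
#'   at 12 kbp spacing; see \code{\link{sigmaForLocusDensity}})
#' @param alpha significance level for elevated-diversity windows
#' @param boot_reps bootstrap pseudoreplicates per window
#' @param d_width,d_step Tajima's D sliding-window geometry in bp
#' @param outlier_q single-locus outlier quantile (default 0.99)
#' @param tail_q window-tail quantile for F_ST and D (default 0.05)
#' @param seed RNG seed for bootstrap and permutations
#' @return config list of class "ScanConfig"
#' @export
scanConfig <- function(group_id = "all", individuals = NULL,
                       populations = "population", max_missing_frac = 0.5,
                       sigma = 60000, alpha = 0.05, boot_reps = 10000,
                       d_width = 120000, d_step = 12000, outlier_q = 0.99,
                       tail_q = 0.05, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, sigma > 0, boot_reps >= 100,
            d_width > 0, d_step > 0,
            outlier_q > 0, outlier_q < 1, tail_q > 0, tail_q < 1)
  structure(list(group_id = group_id, individuals = individuals,
                 populations = populations,
                 max_missing_frac = max_missing_frac, sigma = sigma,
                 alpha = alpha, boot_reps = boot_reps, d_width = d_width,
                 d_step = d_step, outlier_q = outlier_q, tail_q = tail_q,
                 seed = as.integer(seed)),
            class = "ScanConfig")
}

#' Run the full genome scan for one sample group
#'
#' Stages: presence filter; per-locus pi / He / Ho; kernel smoothing of pi
#' and He in windows centred on polymorphic loci; bootstrap significance
#' of elevated diversity; merging of significant windows into regions;
#' per-locus AMOVA F_ST smoothed on the same windows with bottom/top
#' quantile selection; sliding-window Tajima's D from the SNP records with
#' top-quantile selection; interval overlaps between the signature sets;
#' candidate/control gene counts and label-permutation enrichment; region
#' annotation; and the summary row. Deterministic given the config seed.
#'
#' @param hm a \code{\link{HaplotypeMatrix}}
#' @param config a \code{\link{scanConfig}}
#' @param snps optional SNP set (list(sites, a1, a2)) for Tajima's D
#' @param genes optional \code{GRanges} gene annotation with gene_class
#' @param chrom_lengths optional named chromosome lengths
#' @return list with filtered matrix, per-locus stats, smoothed windows
#'   (pi, he, fst), high-diversity window table, regions, outliers,
#'   F_ST tail windows, D windows, overlaps, enrichment results, region
#'   annotation and \code{summary}
#' @export
runPipeline <- function(hm, config, snps = NULL, genes = NULL,
                        chrom_lengths = NULL) {
  inds <- config$individuals
  if (is.null(inds)) inds <- sampleInfo(hm)$individual
  log <- list()
  ## 1. presence filter
  flt <- filterLociByPresence(hm, inds, config$max_missing_frac)
  fhm <- flt$matrix
  log$filter <- c(input = nLoci(hm), retained = flt$retained)
  ## 2. per-locus statistics
  st <- locusStats(fhm, group_id = config$group_id)
  poly <- st$is_polymorphic
  ## 3-4. smoothing + bootstrap for pi and He
  sw <- list()
  for (s in c("pi", "he")) {
    x <- smoothStatistic(st$chrom, st$pos, st[[s]], config$sigma,
                         centers = poly, stat = s)
    sw[[s]] <- bootstrapWindowPvalues(x, st[[s]], config$boot_reps,
                                      config$alpha,
                                      seed = config$seed + match(s, c("pi", "he")))
  }
  wt_pi <- windowTable(sw$pi); wt_he <- windowTable(sw$he)
  ## windows are centre-aligned across the two statistics
  high <- wt_pi$significant | wt_he$significant
  categories <- c(he_only = sum(wt_he$significant & !wt_pi$significant),
                  pi_only = sum(wt_pi$significant & !wt_he$significant),
                  both = sum(wt_pi$significant & wt_he$significant))
  highwin <- wt_pi[high, c("chrom", "center"), drop = FALSE]
  highwin$sig_pi <- wt_pi$significant[high]
  highwin$sig_he <- wt_he$significant[high]
  ## 5. merge into regions
  regions <- mergeWindowsToRegions(highwin, config$sigma, chrom_lengths)
  ## single-locus outliers
  outliers <- lapply(c(pi = "pi", he = "he", ho = "ho"), function(s)
    st$locus_id[singleLocusOutliers(st[[s]], config$outlier_q)])
  ## 6. F_ST smoothing + extreme windows
  sm <- sampleInfo(fhm)
  pops <- sm[[config$populations]]
  sw_fst <- NULL; fst_low <- fst_high <- NULL
  if (length(unique(pops)) >= 2L) {
    cl <- haplotypeCalls(fhm)
    fst <- vapply(seq_len(nrow(cl)), function(i)
      locusAmovaFst(cl[i, ], pops), numeric(1))
    sw_fst <- smoothStatistic(st$chrom, st$pos, fst, config$sigma,
                              centers = poly & !is.na(fst), stat = "fst")
    fst_low <- quantileWindows(sw_fst, "lower", config$tail_q)
    fst_high <- quantileWindows(sw_fst, "upper", config$tail_q)
  }
  ## 7. sliding Tajima's D + top windows
  dwin <- NULL; topd <- NULL
  if (!is.null(snps)) {
    dwin <- slidingTajimaD(snps, individuals = inds, width = config$d_width,
                           step = config$d_step,
                           chrom_lengths = chrom_lengths)
    topd <- topDWindows(dwin, config$tail_q)
  }
  ## 8. overlaps of signature sets with high-diversity windows
  high_gr <- windowsAsRanges(highwin, config$sigma)
  overlaps <- list()
  if (!is.null(topd)) {
    ov <- intervalOverlap(dWindowsAsRanges(topd), high_gr)
    overlaps$top_d <- c(count = ov$count,
                        percent = 100 * ov$count / max(1, nrow(topd)))
  }
  if (!is.null(fst_low)) {
    ovl <- intervalOverlap(windowsAsRanges(fst_low, config$sigma), high_gr)
    ovh <- intervalOverlap(windowsAsRanges(fst_high, config$sigma), high_gr)
    overlaps$fst_low <- c(count = ovl$count,
                          percent = 100 * ovl$fraction)
    overlaps$fst_high <- c(count = ovh$count,
                           percent = 100 * ovh$fraction)
  }
  ## 9. enrichment + annotation
  enrich <- NULL; annot <- NULL
  if (!is.null(genes) && sum(high) > 0 && sum(!high) > 0) {
    enrich <- lapply(c(candidate = "candidate", control = "control"),
      function(cls) {
        counts <- geneCountsPerWindow(sw$pi, genes, cls)
        enrichmentPermutationTest(counts, high, n_permutations = 1000,
                                  seed = config$seed + 11L)
      })
    annot <- annotateRegions(regions, genes)
  }
  total_sig <- sum(categories)
  summary <- list(group = config$group_id,
                  max_missing_frac = config$max_missing_frac,
                  sigma = config$sigma,
                  n_loci = flt$retained,
                  total_windows = nrow(wt_pi),
                  he_only = unname(categories["he_only"]),
                  pi_only = unname(categories["pi_only"]),
                  both = unname(categories["both"]),
                  total_significant = total_sig,
                  proportion_significant =
                    round(total_sig / nrow(wt_pi), 4),
                  n_regions = length(regions),
                  region_length_mbp =
                    sum(GenomicRanges::width(regions)) / 1e6,
                  n_estimable_d_windows =
                    if (!is.null(dwin)) sum(!is.na(dwin$D)) else NA_integer_,
                  top_d_windows = if (!is.null(topd)) nrow(topd) else NA_integer_,
                  top_d_overlap_count =
                    if (!is.null(topd)) unname(overlaps$top_d["count"]) else NA_real_,
                  top_d_overlap_percent =
                    if (!is.null(topd))
                      round(unname(overlaps$top_d["percent"]), 1) else NA_real_)
  list(filtered = fhm, locus_stats = st, windows = sw, fst_windows = sw_fst,
       high_windows = highwin, categories = categories, regions = regions,
       outliers = outliers, fst_low = fst_low, fst_high = fst_high,
       d_windows = dwin, top_d = topd, overlaps = overlaps,
       enrichment = enrich, annotation = annot, summary = summary,
       log = log, config = config)
}

#' Summary-row arithmetic for the scan report
#'
#' Checks the additivity of the window categories (He-only + pi-only +
#' both = total significant), and computes the proportion of significant
#' windows (4 decimals) and, when D-window counts are given, the top-D
#' selection size round(q * n_estimable) and the overlap percentage
#' 100 * overlap / size (1 decimal).
#'
#' @param he_only,pi_only,both window category counts
#' @param total_windows total smoothed windows
#' @param d_overlap_count overlapping top-D windows (optional)
#' @param n_estimable_d estimable D windows (optional)
#' @param tail_q D tail mass (default 0.05)
#' @return list(total_significant, proportion_significant, top_d_size,
#'   top_d_overlap_percent)
#' @export
reportSummary <- function(he_only, pi_only, both, total_windows,
                          d_overlap_count = NULL, n_estimable_d = NULL,
                          tail_q = 0.05) {
  total <- he_only + pi_only + both
  if (total > total_windows)
    stop("window categories exceed the total number of windows")
  out <- list(total_significant = total,
              proportion_significant = round(total / total_windows, 4))
  if (!is.null(d_overlap_count) && !is.null(n_estimable_d)) {
    size <- round(tail_q * n_estimable_d)
    out$top_d_size <- size
    out$top_d_overlap_percent <- round(100 * d_overlap_count / size, 1)
  }
  out
}
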