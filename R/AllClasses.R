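#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' HaplotypeMatrix: per-locus, per-individual RAD haplotype calls
#'
#' The central container of the package: an ordered table of RAD loci
#' (id, chromosome, position, locus length in bp), a sample table
#' (individual, population, group, lat, lon), and a loci x individuals
#' character matrix of genotype calls. Each call is either \code{NA}
#' (locus absent in that individual) or a string \code{"h1/h2"} holding the
#' two haplotype alleles of the diploid individual; the pair is stored in
#' canonical (lexicographic) order so that heterozygote representation is
#' unique and observed-heterozygosity counting is representation
#' independent.
#'
#' Positions are 1-based base pairs and strictly increasing within a
#' chromosome. All haplotype strings at a locus have the length declared in
#' the locus table (92 bp for classic RAD tags).
#'
#' @slot loci data.frame with columns locus_id, chrom, pos, length
#' @slot samples data.frame with columns individual, population, group,
#'   lat, lon
#' @slot calls character matrix, rows = loci, columns = individuals
#' @export
setClass("HaplotypeMatrix",
  representation(loci = "data.frame", samples = "data.frame",
                 calls = "matrix"))

setValidity("HaplotypeMatrix", function(object) {
  msg <- character()
  lo <- object@loci
  sm <- object@samples
  cl <- object@calls
  need <- c("locus_id", "chrom", "pos", "length")
  if (!all(need %in% names(lo)))
    msg <- c(msg, paste("loci must have columns", paste(need, collapse = ", ")))
  if (!all(c("individual", "population", "group") %in% names(sm)))
    msg <- c(msg, "samples must have columns individual, population, group")
  if (length(msg)) return(msg)
  if (nrow(cl) != nrow(lo)) msg <- c(msg, "nrow(calls) != nrow(loci)")
  if (ncol(cl) != nrow(sm)) msg <- c(msg, "ncol(calls) != nrow(samples)")
  if (anyDuplicated(lo$locus_id)) msg <- c(msg, "duplicated locus ids")
  if (anyDuplicated(sm$individual)) msg <- c(msg, "duplicated individual ids")
  if (any(lo$pos < 0)) msg <- c(msg, "negative locus positions")
  for (ch in unique(lo$chrom)) {
    p <- lo$pos[lo$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      msg <- c(msg, sprintf("positions not strictly increasing on %s", ch))
  }
  ok <- !is.na(cl)
  if (any(ok)) {
    nc <- nchar(cl[ok])
    exp_ok <- 2L * lo$length[row(cl)[ok]] + 1L
    if (any(nc != exp_ok))
      msg <- c(msg, "haplotype call length does not match declared locus length")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a HaplotypeMatrix
#'
#' @param loci data.frame(locus_id, chrom, pos, length)
#' @param samples data.frame(individual, population, group, lat, lon)
#' @param calls character matrix of "h1/h2" calls (NA = missing). A bare
#'   "h" is expanded to the homozygote "h/h".
#' @param canonicalize sort each haplotype pair lexicographically (set to
#'   FALSE only when the calls are known to be canonical already)
#' @return a \code{HaplotypeMatrix}
#' @export
HaplotypeMatrix <- function(loci, samples, calls, canonicalize = TRUE) {
  loci <- as.data.frame(loci)
  samples <- as.data.frame(samples)
  storage.mode(calls) <- "character"
  if (canonicalize) calls[] <- canonicalizeCalls(as.vector(calls))
  dimnames(calls) <- list(loci$locus_id, samples$individual)
  o <- order(loci$chrom, loci$pos)
  loci <- loci[o, , drop = FALSE]
  calls <- calls[o, , drop = FALSE]
  rownames(loci) <- NULL
  new("HaplotypeMatrix", loci = loci, samples = samples, calls = calls)
}

## canonical "h1/h2" with h1 <= h2 in C-locale order; bare "h" -> "h/h"
canonicalizeCalls <- function(x) {
  out <- x
  ok <- which(!is.na(x))
  if (!length(ok)) return(out)
  u <- unique(x[ok])
  parts <- strsplit(u, "/", fixed = TRUE)
  canon <- vapply(parts, function(p) {
    if (length(p) == 1L) p <- c(p, p)
    p <- sort(p[1:2], method = "radix")
    paste(p, collapse = "/")
  }, character(1))
  out[ok] <- canon[match(x[ok], u)]
  out
}

#' @export
setGeneric("radLoci", function(x) standardGeneric("radLoci"))
#' Locus table of a HaplotypeMatrix
#' @param x a HaplotypeMatrix
#' @return data.frame(locus_id, chrom, pos, length)
#' @export
setMethod("radLoci", "HaplotypeMatrix", function(x) x@loci)

#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))
#' Sample metadata of a HaplotypeMatrix
#' @param x a HaplotypeMatrix
#' @export
setMethod("sampleInfo", "HaplotypeMatrix", function(x) x@samples)

#' @export
setGeneric("haplotypeCalls", function(x) standardGeneric("haplotypeCalls"))
#' Call matrix (loci x individuals) of a HaplotypeMatrix
#' @param x a HaplotypeMatrix
#' @export
setMethod("haplotypeCalls", "HaplotypeMatrix", function(x) x@calls)

#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))
#' @export
setMethod("nLoci", "HaplotypeMatrix", function(x) nrow(x@loci))

#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))
#' @export
setMethod("nIndividuals", "HaplotypeMatrix", function(x) nrow(x@samples))

#' Subset a HaplotypeMatrix by loci (i) and/or individuals (j)
#'
#' @param x HaplotypeMatrix
#' @param i locus index (numeric/logical) or locus ids (character)
#' @param j individual index or individual ids
#' @param ... ignored
#' @param drop ignored
#' @export
setMethod("[", "HaplotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@loci))
  if (missing(j)) j <- seq_len(nrow(x@samples))
  if (is.character(i)) i <- match(i, x@loci$locus_id)
  if (is.character(j)) j <- match(j, x@samples$individual)
  lo <- x@loci[i, , drop = FALSE]; rownames(lo) <- NULL
  sm <- x@samples[j, , drop = FALSE]; rownames(sm) <- NULL
  new("HaplotypeMatrix", loci = lo, samples = sm,
      calls = x@calls[i, j, drop = FALSE])
})

setMethod("show", "HaplotypeMatrix", function(object) {
  cl <- object@calls
  miss <- if (length(cl)) mean(is.na(cl)) else NA_real_
  cat("HaplotypeMatrix:", nrow(object@loci), "loci x",
      nrow(object@samples), "individuals\n")
  cat("  chromosomes:", paste(unique(object@loci$chrom), collapse = ", "), "\n")
  cat("  groups:", paste(unique(object@samples$group), collapse = ", "), "\n")
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
})

#' SmoothedWindows: kernel-smoothed statistic centred on polymorphic loci
#'
#' One window per polymorphic RAD locus. Each window spans 3 smoothing
#' scales (sigma) either side of its centre; contributing loci are weighted
#' by a Gaussian kernel exp(-d^2 / (2 sigma^2)) so the centre locus carries
#' weight 1. \code{windows} holds one row per window (chrom, center, value,
#' n_loci, and, after \code{bootstrapWindowPvalues}, boot_p and
#' significance flags). \code{contrib} keeps the per-window contributing
#' locus indices and kernel weights so the bootstrap can reuse them.
#'
#' @slot stat name of the smoothed statistic ("pi", "he" or "fst")
#' @slot sigma smoothing scale in bp
#' @slot windows data.frame of per-window results
#' @slot contrib list of list(idx, w) per window
#' @export
setClass("SmoothedWindows",
  representation(stat = "character", sigma = "numeric",
                 windows = "data.frame", contrib = "list"))

setValidity("SmoothedWindows", function(object) {
  if (length(object@contrib) != nrow(object@windows))
    return("contrib length != number of windows")
  TRUE
})

#' @export
setGeneric("windowTable", function(x) standardGeneric("windowTable"))
#' Per-window results of a SmoothedWindows object
#' @param x SmoothedWindows
#' @return data.frame, one row per window
#' @export
setMethod("windowTable", "SmoothedWindows", function(x) x@windows)

setMethod("show", "SmoothedWindows", function(object) {
  cat("SmoothedWindows(", object@stat, "): ", nrow(object@windows),
      " windows, sigma = ", object@sigma, " bp\n", sep = "")
  if ("boot_p" %in% names(object@windows)) {
    cat("  significant (p <", attr(object@windows, "alpha") %||% 0.05, "):",
        sum(object@windows$significant), "\n")
  }
})

`%||%` <- function(a, b) if (is.null(a)) b else a
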