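## Readers/writers for the fixed text dialects the pipeline touches:
## haplotype-table TSV, sample metadata TSV, gene-class TSV, GFF3 (via
## rtracklayer), minimal GT-only VCF v4.2 (read via VariantAnnotation) and
## BED. GFF3 is 1-based inclusive, BED 0-based half-open; internal interval
## objects are GRanges (1-based closed) and conversion happens only here.

#' Read a sample metadata table
#'
#' Tab-separated with a '#'-prefixed header:
#' individual, population, group, lat, lon.
#'
#' @param path file path
#' @return data.frame
#' @export
readSampleMetadata <- function(path) {
  hdr <- sub("^#", "", readLines(path, n = 1L))
  df <- utils::read.table(path, sep = "\t", header = FALSE, skip = 1L,
                          col.names = strsplit(hdr, "\t")[[1]],
                          stringsAsFactors = FALSE, comment.char = "")
  need <- c("individual", "population", "group")
  if (!all(need %in% names(df)))
    stop("metadata must have columns individual, population, group")
  df
}

#' Write a sample metadata table
#' @param samples data.frame(individual, population, group, lat, lon)
#' @param path file path
#' @export
writeSampleMetadata <- function(samples, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(samples), collapse = "\t")), con)
  utils::write.table(samples, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a Stacks-style haplotype table
#'
#' Dialect (normative for this package): tab-separated; '#'-prefixed header
#' \code{locus_id chrom pos length} followed by one column per individual;
#' one row per RAD locus; cells are \code{"h1/h2"}, a bare \code{"h"}
#' (homozygote shorthand) or \code{"."} for missing. Haplotype pairs are
#' canonicalized (lexicographic) on read.
#'
#' @param path haplotype table path
#' @param metadata_path sample metadata path (every individual column must
#'   have a metadata row)
#' @return a \code{\link{HaplotypeMatrix}}
#' @export
readHaplotypeTable <- function(path, metadata_path) {
  meta <- readSampleMetadata(metadata_path)
  hdr <- strsplit(sub("^#", "", readLines(path, n = 1L)), "\t")[[1]]
  fixed <- c("locus_id", "chrom", "pos", "length")
  if (!identical(hdr[1:4], fixed))
    stop("haplotype table must start with columns ",
         paste(fixed, collapse = ", "))
  inds <- hdr[-(1:4)]
  unknown <- setdiff(inds, meta$individual)
  if (length(unknown))
    stop("individuals absent from metadata: ", paste(unknown, collapse = ", "))
  df <- utils::read.table(path, sep = "\t", header = FALSE, skip = 1L,
                          stringsAsFactors = FALSE, comment.char = "",
                          colClasses = c("character", "character", "numeric",
                                         "integer",
                                         rep("character", length(inds))))
  names(df) <- hdr
  calls <- as.matrix(df[, inds, drop = FALSE])
  calls[calls == "."] <- NA_character_
  loci <- df[, fixed]
  ## validate haplotype lengths against the declared locus length
  ok <- !is.na(calls)
  if (any(ok)) {
    lens <- nchar(gsub("/.*", "", calls[ok]))
    bad <- lens != loci$length[row(calls)[ok]]
    if (any(bad)) {
      r <- row(calls)[ok][which(bad)[1]]
      stop(sprintf("haplotype length mismatch at locus %s (row %d)",
                   loci$locus_id[r], r))
    }
  }
  meta <- meta[match(inds, meta$individual), , drop = FALSE]
  rownames(meta) <- NULL
  HaplotypeMatrix(loci, meta, calls, canonicalize = TRUE)
}

#' Write a haplotype table
#'
#' Inverse of \code{\link{readHaplotypeTable}} (same dialect; missing calls
#' written as ".").
#'
#' @param hm a \code{\link{HaplotypeMatrix}}
#' @param path output path
#' @export
writeHaplotypeTable <- function(hm, path) {
  lo <- radLoci(hm)
  cl <- haplotypeCalls(hm)
  cl[is.na(cl)] <- "."
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(c("locus_id", "chrom", "pos", "length",
                                 sampleInfo(hm)$individual),
                               collapse = "\t")), con)
  body <- cbind(lo$locus_id, lo$chrom, format(lo$pos, scientific = FALSE,
                                              trim = TRUE),
                lo$length, cl)
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene annotations from GFF3
#'
#' Imports a GFF3 file (1-based inclusive coordinates), keeps rows of type
#' "gene" only, and joins the gene class (candidate / control / other) from
#' an optional gene-class table; genes absent from the table get class
#' "other". Strand is parsed but ignored by all downstream interval
#' arithmetic.
#'
#' @param path GFF3 path
#' @param class_path optional gene-class TSV (see
#'   \code{\link{readGeneClasses}})
#' @return \code{GRanges} with gene_id and gene_class columns
#' @importFrom rtracklayer import
#' @export
readGff3Genes <- function(path, class_path = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  ids <- gr$ID
  if (is.null(ids)) ids <- gr$Name
  gr$gene_id <- as.character(ids)
  cls <- rep("other", length(gr))
  if (!is.null(class_path)) {
    ct <- readGeneClasses(class_path)
    m <- match(gr$gene_id, ct$gene_id)
    cls[!is.na(m)] <- ct$class[m[!is.na(m)]]
  }
  gr$gene_class <- cls
  S4Vectors::mcols(gr) <- S4Vectors::mcols(gr)[, c("gene_id", "gene_class")]
  gr
}

#' Write gene annotations as GFF3
#' @param genes \code{GRanges} with gene_id column
#' @param path output path
#' @importFrom rtracklayer export
#' @export
writeGff3Genes <- function(genes, path) {
  gr <- genes
  gr$type <- "gene"
  gr$source <- "balscan"
  gr$ID <- gr$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a gene-class table
#'
#' Tab-separated, '#'-prefixed header: gene_id, class (candidate, control
#' or other).
#'
#' @param path file path
#' @return data.frame(gene_id, class)
#' @export
readGeneClasses <- function(path) {
  hdr <- sub("^#", "", readLines(path, n = 1L))
  df <- utils::read.table(path, sep = "\t", header = FALSE, skip = 1L,
                          col.names = strsplit(hdr, "\t")[[1]],
                          stringsAsFactors = FALSE, comment.char = "")
  stopifnot(all(c("gene_id", "class") %in% names(df)))
  df
}

#' Write a gene-class table
#' @param classes data.frame(gene_id, class)
#' @param path output path
#' @export
writeGeneClasses <- function(classes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#gene_id\tclass", con)
  utils::write.table(classes[, c("gene_id", "class")], con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read biallelic SNP genotypes from a VCF
#'
#' Reads a VCF (v4.x, GT field required), keeps biallelic SNP records, and
#' expands every diploid genotype into two allele codes (0 = REF,
#' 1 = ALT, NA = missing). Half-missing genotypes are treated as fully
#' missing at that site. Multiallelic records are skipped with a warning
#' reporting the count.
#'
#' @param path VCF path
#' @return list(sites = data.frame(chrom, pos, ref, alt),
#'   a1, a2 = sites x individuals allele matrices,
#'   n_skipped = multiallelic records dropped)
#' @importFrom VariantAnnotation readVcf geno
#' @export
readVcfSnps <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- rr$ALT
  nalt <- S4Vectors::elementNROWS(alt)
  refch <- as.character(rr$REF)
  altch <- rep(NA_character_, length(rr))
  one <- nalt == 1L
  altch[one] <- as.character(unlist(alt[one]))
  keep <- one & nchar(refch) == 1L & !is.na(altch) & nchar(altch) == 1L
  nskip <- sum(nalt > 1L)
  if (nskip)
    warning(sprintf("skipped %d multiallelic record(s)", nskip))
  gt <- VariantAnnotation::geno(vcf)$GT[keep, , drop = FALSE]
  sites <- data.frame(chrom = as.character(GenomicRanges::seqnames(rr))[keep],
                      pos = GenomicRanges::start(rr)[keep],
                      ref = refch[keep], alt = altch[keep],
                      stringsAsFactors = FALSE)
  parse1 <- function(g, which) {
    a <- sub("^([^/|]*)[/|]([^/|]*)$", paste0("\\", which), g)
    a[!a %in% c("0", "1")] <- NA
    suppressWarnings(as.integer(a))
  }
  a1 <- apply(gt, 2, parse1, which = 1L)
  a2 <- apply(gt, 2, parse1, which = 2L)
  if (is.null(dim(a1))) { a1 <- matrix(a1, nrow = nrow(gt)); a2 <- matrix(a2, nrow = nrow(gt)) }
  ## half-missing -> fully missing
  halfmiss <- xor(is.na(a1), is.na(a2))
  a1[halfmiss] <- NA_integer_; a2[halfmiss] <- NA_integer_
  dimnames(a1) <- dimnames(a2) <- list(NULL, colnames(gt))
  list(sites = sites, a1 = a1, a2 = a2, n_skipped = nskip)
}

#' Write biallelic SNP genotypes as a minimal GT-only VCF v4.2
#'
#' @param snps list(sites, a1, a2) as returned by \code{\link{readVcfSnps}}
#'   or the simulator
#' @param path output path
#' @export
writeVcfSnps <- function(snps, path) {
  sites <- snps$sites
  inds <- colnames(snps$a1)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", inds), collapse = "\t")), con)
  if (nrow(sites)) {
    gt <- matrix(paste(ifelse(is.na(snps$a1), ".", snps$a1),
                       ifelse(is.na(snps$a2), ".", snps$a2), sep = "/"),
                 nrow(sites), length(inds))
    body <- cbind(sites$chrom, format(sites$pos, scientific = FALSE, trim = TRUE),
                  ".", sites$ref, sites$alt, ".", "PASS", ".", "GT", gt)
    utils::write.table(body, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write intervals as BED
#'
#' BED3 plus name and score columns, 0-based half-open, sorted by
#' (chrom, start), with a '#'-prefixed header line.
#'
#' @param intervals \code{GRanges} (1-based closed) or data.frame with
#'   chrom/start/end (already 0-based half-open)
#' @param path output path
#' @export
writeIntervalsBed <- function(intervals, path) {
  if (is(intervals, "GRanges")) {
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(intervals)),
                     start = GenomicRanges::start(intervals) - 1L,
                     end = GenomicRanges::end(intervals),
                     stringsAsFactors = FALSE)
    nm <- intervals$name
    df$name <- if (is.null(nm)) paste0("region_", seq_along(intervals)) else nm
    df$score <- if (is.null(intervals$score)) 0 else intervals$score
  } else {
    df <- as.data.frame(intervals)
    if (is.null(df$name)) df$name <- paste0("region_", seq_len(nrow(df)))
    if (is.null(df$score)) df$score <- 0
  }
  if (any(df$end <= df$start)) stop("intervals must satisfy end > start")
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tname\tscore", con)
  utils::write.table(format(df, scientific = FALSE, trim = TRUE), con,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a BED file written by \code{\link{writeIntervalsBed}}
#' @param path BED path
#' @return \code{GRanges} (converted back to 1-based closed)
#' @export
readIntervalsBed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  gr <- GenomicRanges::GRanges(df$chrom,
          IRanges::IRanges(df$start + 1L, df$end))
  if (ncol(df) >= 4) gr$name <- df[[4]]
  if (ncol(df) >= 5) gr$score <- df[[5]]
  gr
}
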