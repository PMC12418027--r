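#' Ploidy-aware variant matrix
#'
#' Container for biallelic SNPs with per-sample genotypes of sample-specific
#' ploidy (diploid `0/1`, tetraploid `0/0/0/1`, missing `./.` etc.) and
#' per-sample read depths.
#'
#' @param sites Data frame with columns `chrom`, `pos` (1-based),
#'   `ref`, `alt` (single nucleotides).
#' @param gt Character matrix, sites x samples, "/"-separated allele
#'   indices, `.` for a missing allele copy.
#' @param dp Integer matrix, sites x samples, read depths.
#' @param ploidy Integer vector per sample (2 or 4).
#' @return An object of class `variant_matrix`.
#' @export
variant_matrix <- function(sites, gt, dp, ploidy) {
  stopifnot(nrow(sites) == nrow(gt), nrow(gt) == nrow(dp),
            ncol(gt) == ncol(dp), ncol(gt) == length(ploidy))
  if (!all(ploidy %in% c(2L, 4L))) stop("ploidy must be 2 or 4")
  if (anyDuplicated(sites[, c("chrom", "pos")]))
    stop("duplicate site positions within a chromosome")
  if (is.null(colnames(gt))) colnames(gt) <- paste0("S", seq_len(ncol(gt)))
  colnames(dp) <- colnames(gt)
  names(ploidy) <- colnames(gt)
  structure(list(sites = sites, gt = gt, dp = dp,
                 ploidy = as.integer(ploidy)),
            class = "variant_matrix")
}

#' @export
print.variant_matrix <- function(x, ...) {
  cat(sprintf("variant_matrix: %d sites x %d samples (%d diploid, %d tetraploid)\n",
              nrow(x$sites), ncol(x$gt), sum(x$ploidy == 2),
              sum(x$ploidy == 4)))
  invisible(x)
}

#' @export
`[.variant_matrix` <- function(x, i) {
  variant_matrix(x$sites[i, , drop = FALSE], x$gt[i, , drop = FALSE],
                 x$dp[i, , drop = FALSE], x$ploidy)
}

#' Number of sites in a variant matrix
#' @param vm A [variant_matrix()].
#' @return Integer site count.
#' @export
n_sites <- function(vm) nrow(vm$sites)

# sites x samples matrices of alternate and non-missing allele-copy counts
allele_copy_counts <- function(vm) {
  split_gt <- strsplit(vm$gt, "/", fixed = TRUE)
  alt <- vapply(split_gt, function(a) sum(a == "1"), 0L)
  seen <- vapply(split_gt, function(a) sum(a != "."), 0L)
  dim(alt) <- dim(seen) <- dim(vm$gt)
  list(alt = alt, called = seen)
}

#' Read a VCF into a variant matrix
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}), keeping biallelic SNPs and the
#' per-sample GT and DP fields. Per-sample ploidy is inferred from the
#' number of allele slots in the first non-missing genotype.
#'
#' @param path VCF path (plain or gzipped).
#' @return A [variant_matrix()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  snp <- nchar(fix[, "REF"]) == 1 & nchar(fix[, "ALT"]) == 1 &
    !grepl(",", fix[, "ALT"], fixed = TRUE)
  if (!all(snp)) {
    fix <- fix[snp, , drop = FALSE]
    gt <- gt[snp, , drop = FALSE]
    dp <- dp[snp, , drop = FALSE]
  }
  gt <- gsub("|", "/", gt, fixed = TRUE)
  ploidy <- apply(gt, 2, function(col) {
    ok <- col[!is.na(col) & !grepl("^\\.", col)]
    if (!length(ok)) return(2L)
    length(strsplit(ok[1], "/", fixed = TRUE)[[1]])
  })
  # fully missing genotypes -> "." repeated to the sample's ploidy
  for (j in seq_len(ncol(gt))) {
    miss <- is.na(gt[, j]) | grepl("^\\.", gt[, j])
    gt[miss, j] <- paste(rep(".", ploidy[j]), collapse = "/")
  }
  dp[is.na(dp)] <- 0L
  sites <- data.frame(chrom = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      stringsAsFactors = FALSE)
  rownames(gt) <- rownames(dp) <- NULL
  variant_matrix(sites, gt, matrix(as.integer(dp), nrow(dp), ncol(dp),
                                   dimnames = dimnames(dp)), ploidy)
}

#' Write a variant matrix as VCF 4.2
#'
#' Emits a minimal VCF with GT:DP per sample; tetraploid genotypes carry
#' four allele slots (`0/0/0/1`).
#'
#' @param vm A [variant_matrix()].
#' @param path Output path.
#' @export
write_vcf <- function(vm, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=cytoniche",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(vm$gt)), collapse = "\t"))
  body <- vapply(seq_len(n_sites(vm)), function(i) {
    paste(c(vm$sites$chrom[i], vm$sites$pos[i], ".", vm$sites$ref[i],
            vm$sites$alt[i], ".", "PASS", ".", "GT:DP",
            paste0(vm$gt[i, ], ":", vm$dp[i, ])), collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read genomic intervals for region exclusion
#'
#' BED files are read as 0-based half-open intervals, GFF3 as 1-based
#' closed (only rows of the requested feature `type`, default CDS, are
#' kept). Both are returned as a `GRanges`.
#'
#' @param path BED or GFF(3) file path; format chosen by extension unless
#'   `format` is given.
#' @param format `"bed"` or `"gff"` (default: by extension).
#' @param type GFF feature type to keep (default `"CDS"`).
#' @return A [GenomicRanges::GRanges] object.
#' @export
read_intervals <- function(path, format = NULL, type = "CDS") {
  if (is.null(format)) {
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE))
      "bed" else "gff"
  }
  gr <- rtracklayer::import(path, format = format)
  if (format == "gff") {
    gr <- gr[S4Vectors::mcols(gr)$type %in% type]
  }
  if (any(GenomicRanges::width(gr) <= 0))
    stop("malformed interval: start >= end")
  gr
}

#' Write intervals as BED
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @export
write_bed <- function(gr, path) {
  d <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                  start = GenomicRanges::start(gr) - 1L,
                  end = GenomicRanges::end(gr))
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
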