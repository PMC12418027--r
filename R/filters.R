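#' Depth-window filter
#'
#' Retains sites whose total read depth (sum of per-sample depths, or the
#' per-sample mean with `mode = "per_sample"`) lies within
#' `[mean/low_divisor, high_factor * mean]`, both bounds inclusive, where
#' the mean is taken across all input sites. The default window, one third
#' to twice the mean, excludes low-confidence and likely-duplicated
#' regions.
#'
#' @param vm A [variant_matrix()] with depths.
#' @param low_divisor Lower bound = mean / `low_divisor` (default 3).
#' @param high_factor Upper bound = `high_factor` * mean (default 2).
#' @param mode `"site_total"` (default) or `"per_sample"` (mean of sample
#'   depths at the site).
#' @return A list: `vm` (surviving sites), `report` (one-stage
#'   [filter_report()] row), `mean_depth`.
#' @export
depth_filter <- function(vm, low_divisor = 3, high_factor = 2,
                         mode = c("site_total", "per_sample")) {
  mode <- match.arg(mode)
  if (n_sites(vm) == 0)
    return(list(vm = vm, report = stage_report("depth", 0L, 0L),
                mean_depth = NA_real_))
  if (!length(vm$dp) || all(vm$dp == 0))
    stop("no depth information")
  depth <- if (mode == "site_total") rowSums(vm$dp) else rowMeans(vm$dp)
  m <- mean(depth)
  keep <- depth >= m / low_divisor & depth <= high_factor * m
  list(vm = vm[keep],
       report = stage_report("depth", n_sites(vm), sum(keep)),
       mean_depth = m)
}

#' Exclude genic and repetitive regions
#'
#' Removes sites falling inside transposable-element intervals or inside
#' coding sequences expanded by `flank` bp on both sides, so surviving
#' SNPs are putatively neutral. Interval membership uses the BED
#' convention internally (0-based half-open); VCF positions are 1-based.
#'
#' @param vm A [variant_matrix()].
#' @param cds,te `GRanges` interval sets (either may be empty/NULL).
#' @param flank Flank in bp added to each CDS interval (default 2000).
#' @return A list: `vm`, `report`.
#' @export
region_exclude <- function(vm, cds = NULL, te = NULL, flank = 2000) {
  bad <- rep(FALSE, n_sites(vm))
  pts <- GenomicRanges::GRanges(vm$sites$chrom,
                                IRanges::IRanges(vm$sites$pos, width = 1))
  grow <- function(gr, by) {
    if (is.null(gr) || length(gr) == 0) return(NULL)
    if (any(GenomicRanges::width(gr) <= 0))
      stop("malformed interval: start >= end")
    if (by > 0) {
      gr <- GenomicRanges::resize(gr, GenomicRanges::width(gr) + 2 * by,
                                  fix = "center")
      gr <- GenomicRanges::trim(gr)
      GenomicRanges::start(gr) <- pmax(1L, GenomicRanges::start(gr))
    }
    gr
  }
  for (gr in list(grow(cds, flank), grow(te, 0))) {
    if (!is.null(gr))
      bad <- bad | IRanges::overlapsAny(pts, gr)
  }
  list(vm = vm[!bad],
       report = stage_report("region", n_sites(vm), sum(!bad)))
}

#' Singleton removal
#'
#' Counts minor-allele copies across all non-missing allele slots,
#' ploidy-aware (a tetraploid `0/0/0/1` contributes one alternate copy),
#' and removes sites whose minor allele occurs exactly once — whichever of
#' the two alleles is the minor one. Such singletons are the variants most
#' likely to be sequencing errors.
#'
#' @param vm A [variant_matrix()].
#' @return A list: `vm`, `report`.
#' @export
singleton_filter <- function(vm) {
  cc <- allele_copy_counts(vm)
  alt <- rowSums(cc$alt)
  tot <- rowSums(cc$called)
  minor <- pmin(alt, tot - alt)
  keep <- minor != 1L
  list(vm = vm[keep],
       report = stage_report("singleton", n_sites(vm), sum(keep)))
}

#' Linkage thinning by minimum inter-site distance
#'
#' Greedy left-to-right scan per chromosome: the first site is kept, then
#' each site at least `min_dist` bp from the last kept site. Unsorted
#' input is sorted internally with a warning.
#'
#' @param vm A [variant_matrix()].
#' @param min_dist Minimum spacing in bp (default 20000).
#' @return A list: `vm`, `report`.
#' @export
spacing_thin <- function(vm, min_dist = 20000) {
  ord <- order(vm$sites$chrom, vm$sites$pos)
  if (is.unsorted(ord)) {
    warning("sites not sorted by chromosome/position; sorting internally")
    vm <- vm[ord]
  }
  keep <- logical(n_sites(vm))
  for (ch in unique(vm$sites$chrom)) {
    idx <- which(vm$sites$chrom == ch)
    last <- -Inf
    for (i in idx) {
      if (vm$sites$pos[i] - last >= min_dist) {
        keep[i] <- TRUE
        last <- vm$sites$pos[i]
      }
    }
  }
  list(vm = vm[keep],
       report = stage_report("spacing", n_sites(vm), sum(keep)))
}

stage_report <- function(stage, n_in, n_out) {
  data.frame(stage = stage, n_input = n_in, n_removed = n_in - n_out,
             n_survivors = n_out, stringsAsFactors = FALSE)
}

#' Neutral-SNP filter cascade
#'
#' Runs the four filters in the fixed order depth window -> genic/TE
#' region exclusion -> singleton removal -> 20-kb linkage thinning, and
#' returns the surviving sites plus a per-stage report. Spacing runs last
#' so that sites removed for quality reasons never block a retained,
#' well-spaced neighbour.
#'
#' @param vm A [variant_matrix()].
#' @param cds,te `GRanges` interval sets (optional).
#' @param flank CDS flank in bp (default 2000).
#' @param min_dist Minimum inter-site distance in bp (default 20000).
#' @param low_divisor,high_factor,depth_mode Passed to [depth_filter()].
#' @param singleton Apply the singleton filter (default TRUE).
#' @return A list: `vm` (final survivors), `report` (data frame, one row
#'   per stage), `mean_depth`.
#' @export
filter_cascade <- function(vm, cds = NULL, te = NULL, flank = 2000,
                           min_dist = 20000, low_divisor = 3,
                           high_factor = 2, depth_mode = "site_total",
                           singleton = TRUE) {
  s1 <- depth_filter(vm, low_divisor, high_factor, depth_mode)
  s2 <- region_exclude(s1$vm, cds, te, flank)
  s3 <- if (singleton) singleton_filter(s2$vm) else
    list(vm = s2$vm, report = stage_report("singleton", n_sites(s2$vm),
                                           n_sites(s2$vm)))
  s4 <- spacing_thin(s3$vm, min_dist)
  list(vm = s4$vm,
       report = rbind(s1$report, s2$report, s3$report, s4$report),
       mean_depth = s1$mean_depth)
}
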