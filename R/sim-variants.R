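#' Configuration for the mixed-ploidy variant generator
#'
#' @param n_diploid,n_tetraploid Sample counts per cytotype.
#' @param chrom_lengths Named integer vector of chromosome lengths (bp).
#' @param n_sites Number of biallelic SNPs to place.
#' @param depth_mean Mean per-sample read depth (> 0).
#' @param depth_dispersion Negative-binomial dispersion of depths (0 =
#'   Poisson-like; larger = noisier).
#' @param depth_outlier_fraction Fraction of sites given coverage
#'   anomalies (half inflated ~4x, emulating collapsed repeats; half
#'   deflated ~0.15x, emulating poorly covered regions), the signal the
#'   depth window is designed to remove.
#' @param singleton_fraction Fraction of sites planted as singletons (one
#'   minor-allele copy in one sample).
#' @param missing_fraction Fraction of genotype cells set fully missing.
#' @param cds_density,te_density Fraction of each chromosome covered by
#'   CDS / TE intervals.
#' @param flank CDS flank (bp) the downstream filter will apply; recorded
#'   so truth bookkeeping matches.
#' @param min_dist Linkage-thinning distance (bp) for truth bookkeeping.
#' @param seed Integer seed.
#' @return A validated list of class `variant_sim_config`.
#' @export
variant_sim_config <- function(n_diploid = 6, n_tetraploid = 10,
                               chrom_lengths = c(chr1 = 2e6, chr2 = 1.5e6),
                               n_sites = 5000, depth_mean = 20,
                               depth_dispersion = 0.15,
                               depth_outlier_fraction = 0.08,
                               singleton_fraction = 0.1,
                               missing_fraction = 0.02,
                               cds_density = 0.25, te_density = 0.15,
                               flank = 2000, min_dist = 20000, seed = 1) {
  if (depth_mean <= 0) stop("depth_mean must be positive")
  if (n_diploid + n_tetraploid < 2) stop("need at least two samples")
  if (singleton_fraction < 0 || singleton_fraction > 1)
    stop("singleton_fraction must be in [0, 1]")
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  structure(as.list(environment()), class = "variant_sim_config")
}

# Random non-overlapping intervals (0-based half-open) covering roughly
# `density` of a chromosome.
random_intervals <- function(len, density, mean_len) {
  target <- density * len
  starts <- integer(0); ends <- integer(0); covered <- 0
  while (covered < target) {
    w <- max(200L, as.integer(stats::rexp(1, 1 / mean_len)))
    s <- as.integer(stats::runif(1, 0, len - w))
    starts <- c(starts, s); ends <- c(ends, s + w)
    covered <- covered + w
  }
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  # merge overlaps so coverage is a union
  ms <- starts[1]; me <- ends[1]; rs <- integer(0); re <- integer(0)
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= me) me <- max(me, ends[i])
    else { rs <- c(rs, ms); re <- c(re, me); ms <- starts[i]; me <- ends[i] }
  }
  data.frame(start = c(rs, ms), end = c(re, me))
}

in_intervals <- function(pos0, iv, flank = 0) {
  if (!nrow(iv)) return(rep(FALSE, length(pos0)))
  vapply(pos0, function(p)
    any(p >= iv$start - flank & p < iv$end + flank), TRUE)
}

#' Generate a synthetic mixed-ploidy variant dataset with filter truth
#'
#' Places biallelic SNPs on the configured chromosomes, draws per-sample
#' negative-binomial read depths, allele frequencies from a U-shaped Beta,
#' and binomial per-sample allele-copy counts at each sample's ploidy; a
#' configured fraction of sites is planted as singletons and a fraction of
#' genotype cells set missing. CDS and TE interval sets are generated
#' alongside. During generation the exact number of sites that should
#' survive each stage of the neutral-SNP filter cascade (depth window ->
#' CDS+flank/TE exclusion -> singleton removal -> linkage thinning) is
#' computed by independent plain-arithmetic bookkeeping, giving
#' ground-truth counts the pipeline must reproduce exactly.
#'
#' @param cfg A [variant_sim_config()].
#' @return A list: `vm` ([variant_matrix()]), `cds`, `te` (`GRanges`),
#'   `truth` (survivor count after each cumulative stage plus the planted
#'   singleton count and mean site depth).
#' @export
simulate_variants <- function(cfg) {
  set.seed(cfg$seed)
  n_samples <- cfg$n_diploid + cfg$n_tetraploid
  ploidy <- c(rep(2L, cfg$n_diploid), rep(4L, cfg$n_tetraploid))
  sample_names <- c(sprintf("dip%02d", seq_len(cfg$n_diploid)),
                    sprintf("tet%02d", seq_len(cfg$n_tetraploid)))

  # unique sorted positions per chromosome
  chrom <- sample(names(cfg$chrom_lengths), cfg$n_sites, replace = TRUE,
                  prob = cfg$chrom_lengths / sum(cfg$chrom_lengths))
  pos <- integer(cfg$n_sites)
  for (ch in names(cfg$chrom_lengths)) {
    idx <- which(chrom == ch)
    p <- unique(as.integer(stats::runif(length(idx) * 1.2, 1,
                                        cfg$chrom_lengths[[ch]])))
    while (length(p) < length(idx)) {
      p <- unique(c(p, as.integer(stats::runif(length(idx), 1,
                                               cfg$chrom_lengths[[ch]]))))
    }
    pos[idx] <- sort(sample(p, length(idx)))
  }
  o <- order(chrom, pos)
  chrom <- chrom[o]; pos <- pos[o]

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, cfg$n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")

  dp <- matrix(stats::rnbinom(cfg$n_sites * n_samples,
                              mu = cfg$depth_mean,
                              size = 1 / max(cfg$depth_dispersion, 1e-8)),
               cfg$n_sites, n_samples)
  n_out <- round(cfg$depth_outlier_fraction * cfg$n_sites)
  if (n_out > 0) {
    out_sites <- sample.int(cfg$n_sites, n_out)
    hi <- out_sites[seq_len(floor(n_out / 2))]
    lo <- setdiff(out_sites, hi)
    dp[hi, ] <- dp[hi, ] * 4L           # collapsed-repeat pile-ups
    dp[lo, ] <- as.integer(round(dp[lo, ] * 0.15))  # poorly covered
  }

  n_singleton <- round(cfg$singleton_fraction * cfg$n_sites)
  planted <- sample.int(cfg$n_sites, n_singleton)
  freq <- stats::rbeta(cfg$n_sites, 0.6, 0.6)
  altc <- matrix(0L, cfg$n_sites, n_samples)
  for (j in seq_len(n_samples))
    altc[, j] <- stats::rbinom(cfg$n_sites, ploidy[j], freq)
  # planted singletons: exactly one minor copy in one sample
  altc[planted, ] <- 0L
  carrier <- sample.int(n_samples, n_singleton, replace = TRUE)
  altc[cbind(planted, carrier)] <- 1L

  miss <- matrix(stats::runif(cfg$n_sites * n_samples) <
                   cfg$missing_fraction, cfg$n_sites, n_samples)
  altc_eff <- altc; altc_eff[miss] <- NA_integer_

  gt <- matrix("", cfg$n_sites, n_samples,
               dimnames = list(NULL, sample_names))
  for (j in seq_len(n_samples)) {
    k <- ploidy[j]
    gt[, j] <- vapply(seq_len(cfg$n_sites), function(i) {
      if (miss[i, j]) return(paste(rep(".", k), collapse = "/"))
      paste(c(rep("0", k - altc[i, j]), rep("1", altc[i, j])),
            collapse = "/")
    }, "")
  }

  cds_iv <- do.call(rbind, lapply(names(cfg$chrom_lengths), function(ch) {
    cbind(chrom = ch, random_intervals(cfg$chrom_lengths[[ch]],
                                       cfg$cds_density, 1500))
  }))
  te_iv <- do.call(rbind, lapply(names(cfg$chrom_lengths), function(ch) {
    cbind(chrom = ch, random_intervals(cfg$chrom_lengths[[ch]],
                                       cfg$te_density, 3000))
  }))

  # ---- truth bookkeeping: plain arithmetic, independent of the filter
  # implementations -------------------------------------------------------
  site_depth <- rowSums(dp)
  mean_depth <- mean(site_depth)
  ok_depth <- site_depth >= mean_depth / 3 & site_depth <= 2 * mean_depth

  ok_region <- logical(cfg$n_sites)
  for (ch in names(cfg$chrom_lengths)) {
    idx <- which(chrom == ch)
    cds_ch <- cds_iv[cds_iv$chrom == ch, , drop = FALSE]
    te_ch <- te_iv[te_iv$chrom == ch, , drop = FALSE]
    p0 <- pos[idx] - 1L  # VCF 1-based -> BED 0-based
    ok_region[idx] <- !(in_intervals(p0, cds_ch, cfg$flank) |
                          in_intervals(p0, te_ch, 0))
  }

  alt_total <- rowSums(altc_eff, na.rm = TRUE)
  called <- matrix(ploidy, cfg$n_sites, n_samples, byrow = TRUE)
  called[miss] <- 0L
  minor <- pmin(alt_total, rowSums(called) - alt_total)
  ok_singleton <- minor != 1L

  keep12 <- ok_depth & ok_region
  keep123 <- keep12 & ok_singleton
  keep_final <- logical(cfg$n_sites)
  for (ch in names(cfg$chrom_lengths)) {
    idx <- which(chrom == ch & keep123)
    last <- -Inf
    for (i in idx) {
      if (pos[i] - last >= cfg$min_dist) {
        keep_final[i] <- TRUE
        last <- pos[i]
      }
    }
  }
  truth <- list(n_input = cfg$n_sites,
                after_depth = sum(ok_depth),
                after_region = sum(keep12),
                after_singleton = sum(keep123),
                after_spacing = sum(keep_final),
                planted_singletons = n_singleton,
                mean_site_depth = mean_depth)

  vm <- variant_matrix(
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = unname(alt),
               stringsAsFactors = FALSE),
    gt, dp, ploidy)
  to_granges <- function(iv)
    GenomicRanges::GRanges(iv$chrom,
                           IRanges::IRanges(iv$start + 1L, iv$end))
  list(vm = vm, cds = to_granges(cds_iv), te = to_granges(te_iv),
       cds_df = cds_iv, te_df = te_iv, truth = truth)
}
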