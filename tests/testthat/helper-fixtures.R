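# Shared in-code fixtures for the test suite.

# One degree of latitude at the default earth radius, in km.
km_per_deg <- pi * 6371 / 180

# Occurrences laid out along a meridian at given distances (km) from 0.
meridian_occ <- function(species, dist_km, lon = 0) {
  occurrence_set(species, rep(lon, length(dist_km)), dist_km / km_per_deg)
}

# Minimal density_grid for hand-specified cell masses.
manual_grid <- function(mass, x = seq_len(nrow(mass)),
                        y = seq_len(ncol(mass))) {
  structure(list(mass = mass, x = x, y = y, bandwidth = c(1, 1)),
            class = "density_grid")
}

# Toy variant matrix: gt is a sites x samples character matrix; depths
# default to a constant 10.
toy_vm <- function(gt, ploidy, pos = seq_len(nrow(gt)), chrom = "chr1",
                   dp = NULL) {
  gt <- as.matrix(gt)
  if (is.null(dp)) dp <- matrix(10L, nrow(gt), ncol(gt))
  variant_matrix(
    data.frame(chrom = rep_len(chrom, nrow(gt)), pos = as.integer(pos),
               ref = rep("A", nrow(gt)), alt = rep("T", nrow(gt)),
               stringsAsFactors = FALSE),
    gt, dp, ploidy)
}

# Constant-sequence sample set with optional point substitutions.
flat_seqs <- function(samples, len, chrom = "chr1") {
  s <- stats::setNames(rep(list(stats::setNames(strrep("A", len), chrom)),
                           length(samples)), samples)
  lapply(s, unlist)
}
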