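#' Run the full climatic-niche comparison chain
#'
#' Orchestrates thin -> extract -> prune -> z-score -> PCA -> KDE ->
#' Schoener's D / Levins' B -> permutation test on an occurrence set and a
#' list of environmental layers. Rerunning with the same inputs and seed
#' reproduces identical reports.
#'
#' @param occ An [occurrence_set()] (or path to an occurrence CSV).
#' @param layers List of [env_layer()] (or paths to ASCII grids).
#' @param threshold_km Spatial thinning distance (default 1 km).
#' @param per_species Thin within species (default TRUE).
#' @param r_threshold Correlation pruning threshold (default 0.8).
#' @param keep Variables never pruned (e.g. a published retained list).
#' @param grid_size KDE grid cells per axis (default 100).
#' @param replicates Permutation replicates (default 1000).
#' @param seed Integer seed for the permutation null.
#' @param bandwidth KDE bandwidth rule or fixed value (default "scott").
#' @param out_dir Optional directory; when given, per-stage CSVs and a
#'   JSON summary are written there.
#' @return A list with `thinned`, `extraction`, `prune`, `pca`, `overlap`,
#'   and `summary` (the JSON-ready stage summary).
#' @export
run_niche_pipeline <- function(occ, layers, threshold_km = 1,
                               per_species = TRUE, r_threshold = 0.8,
                               keep = character(), grid_size = 100,
                               replicates = 1000, seed = 1,
                               bandwidth = "scott", out_dir = NULL) {
  if (is.character(occ)) occ <- read_occurrences(occ)
  if (is.character(layers)) layers <- lapply(layers, read_ascii_grid)
  thinned <- thin_occurrences(occ, threshold_km, per_species)
  ex <- extract_at_points(layers, thinned)
  pr <- prune_correlated(ex$env, r_threshold, keep)
  z <- zscore(pr$env)
  pca <- pca_fit(z, 2)
  ov <- permutation_overlap_test(pca$scores, ex$occ$species,
                                 grid_size = grid_size,
                                 replicates = replicates, seed = seed,
                                 bandwidth = bandwidth)
  summary <- list(
    n_input = nrow(occ),
    n_thinned = nrow(thinned),
    n_extracted = ex$report$n_retained,
    variables_retained = pr$retained,
    variables_pruned = pr$pruned$variable,
    var_explained_pct = round(100 * pca$var_explained, 4),
    schoeners_D = ov$D,
    levins_B = as.list(ov$B),
    p_value = ov$p_value,
    replicates = replicates,
    grid_size = grid_size,
    seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_occurrences(thinned, file.path(out_dir, "occurrences_thinned.csv"))
    utils::write.csv(
      data.frame(species = ex$occ$species, pca$scores),
      file.path(out_dir, "pca_scores.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(pca$loadings),
                     file.path(out_dir, "pca_loadings.csv"))
    jsonlite::write_json(summary, file.path(out_dir, "niche_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(thinned = thinned, extraction = ex, prune = pr, pca = pca,
       overlap = ov, summary = summary)
}

#' Run the neutral-SNP filter chain (and optional downstream emitters)
#'
#' Applies the filter cascade to a variant matrix or VCF file and
#' optionally writes the filtered VCF, a mixed-ploidy STRUCTURE matrix and
#' the per-stage JSON report.
#'
#' @param vm A [variant_matrix()] or a VCF path.
#' @param cds,te Interval `GRanges` or BED/GFF paths (optional).
#' @param flank,min_dist,low_divisor,high_factor,depth_mode,singleton
#'   Passed to [filter_cascade()].
#' @param structure Also build the STRUCTURE-coded matrix (default TRUE).
#' @param out_dir Optional output directory for `filtered.vcf`,
#'   `structure.txt` and `filter_report.json`.
#' @return A list with `vm` (survivors), `report`, `mean_depth`, and
#'   `structure` (matrix or NULL).
#' @export
run_variant_pipeline <- function(vm, cds = NULL, te = NULL, flank = 2000,
                                 min_dist = 20000, low_divisor = 3,
                                 high_factor = 2,
                                 depth_mode = "site_total",
                                 singleton = TRUE, structure = TRUE,
                                 out_dir = NULL) {
  if (is.character(vm)) vm <- read_vcf(vm)
  if (is.character(cds)) cds <- read_intervals(cds)
  if (is.character(te)) te <- read_intervals(te)
  res <- filter_cascade(vm, cds, te, flank, min_dist, low_divisor,
                        high_factor, depth_mode, singleton)
  str_mat <- if (structure && n_sites(res$vm) > 0)
    write_structure(res$vm) else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_vcf(res$vm, file.path(out_dir, "filtered.vcf"))
    if (!is.null(str_mat))
      write_structure(res$vm, file.path(out_dir, "structure.txt"))
    jsonlite::write_json(res$report,
                         file.path(out_dir, "filter_report.json"),
                         dataframe = "rows", pretty = TRUE)
  }
  list(vm = res$vm, report = res$report, mean_depth = res$mean_depth,
       structure = str_mat)
}
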