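test_that("all generators are deterministic under a fixed seed", {
  cfg <- niche_sim_config(seed = 4)
  a <- simulate_occurrences(cfg)
  b <- simulate_occurrences(cfg)
  expect_identical(a$occ, b$occ)
  expect_identical(a$layers[[1]]$values, b$layers[[1]]$values)
  expect_identical(simulate_traits(seed = 4), simulate_traits(seed = 4))
  vcfg <- variant_sim_config(n_sites = 300, seed = 4)
  va <- simulate_variants(vcfg)
  vb <- simulate_variants(vcfg)
  expect_identical(va$vm$gt, vb$vm$gt)
  expect_identical(va$truth, vb$truth)
  # different seed changes the draw
  expect_false(identical(a$occ,
                         simulate_occurrences(niche_sim_config(seed = 5))$occ))
})

test_that("config validation rejects degenerate settings", {
  expect_error(niche_sim_config(species = list(
    list(name = "A", mean = c(0, 0), cov = matrix(c(1, 2, 2, 1), 2), n = 10)),
    n_layers = 2), "positive-definite")
  expect_error(niche_sim_config(species = list(
    list(name = "A", mean = c(0, 0), cov = diag(2), n = 0)),
    n_layers = 2), "record counts")
  expect_error(niche_sim_config(cellsize = -1), "cellsize")
  expect_error(niche_sim_config(dup_fraction = 2), "dup_fraction")
  expect_error(variant_sim_config(depth_mean = 0), "depth_mean")
})

test_that("duplicate clustering plants close pairs; none are forced at 0", {
  cfg <- niche_sim_config(species = list(
    list(name = "A", mean = c(0, 0), cov = diag(0.3^2, 2), n = 100)),
    n_layers = 2, layer_cor = diag(2), dup_fraction = 0.3, seed = 6)
  sim <- simulate_occurrences(cfg)
  d_min <- vapply(71:100, function(i)
    min(haversine_km(sim$occ$lon[1:70], sim$occ$lat[1:70],
                     sim$occ$lon[i], sim$occ$lat[i])), 0)
  expect_true(all(d_min < 1))  # every resampled record sits within 1 km
  expect_equal(sim$truth$species$A$n_duplicates, 30)
  cfg0 <- niche_sim_config(species = cfg$species, n_layers = 2,
                           layer_cor = diag(2), dup_fraction = 0, seed = 6)
  expect_equal(simulate_occurrences(cfg0)$truth$species$A$n_duplicates, 0)
})

test_that("realized layer correlations reproduce the configured structure", {
  sim <- simulate_occurrences(niche_sim_config(seed = 8))
  r <- sim$truth$layer_cor_realized
  # the default design plants redundant pairs above the 0.8 threshold
  expect_gt(abs(r["ENV1", "ENV2"]), 0.8)
  expect_gt(abs(r["ENV4", "ENV5"]), 0.8)
  expect_lt(abs(r["ENV1", "ENV4"]), 0.3)
})

test_that("occurrence environments converge to the configured Gaussian", {
  tgt <- 0.35^2 * matrix(c(1, 0.4, 0.4, 1), 2)
  cfg <- niche_sim_config(species = list(
    list(name = "A", mean = c(0, 0), cov = tgt, n = 2000)),
    n_layers = 2, layer_cor = diag(2), dup_fraction = 0, seed = 2)
  sim <- simulate_occurrences(cfg)
  ex <- extract_at_points(sim$layers, sim$occ)
  emp <- stats::cov(ex$env)
  expect_lt(max(abs(emp - tgt)) / max(diag(tgt)), 0.1)
  expect_lt(max(abs(colMeans(ex$env))), 0.05)
})

test_that("trait generator honors its configured distributions", {
  cfg <- trait_sim_defaults()
  tr <- simulate_traits(cfg, seed = 10)
  # group means within 3 standard errors of the configured truth
  for (sp in cfg) {
    lv <- sp$leaves
    for (i in seq_len(nrow(lv))) {
      got <- tr$length_cm[tr$species == sp$name & tr$part == lv$class[i]]
      se <- lv$length_sd[i] / sqrt(lv$n[i])
      expect_lt(abs(mean(got) - lv$length_mean[i]), 3 * se + 1e-9)
    }
  }
  # ratio column is consistent
  leaf <- tr[tr$part %in% c("apical", "lateral", "basal"), ]
  expect_equal(leaf$ratio, leaf$length_cm / leaf$width_cm, tolerance = 1e-9)
  # SD 0 collapses to the configured means exactly
  cfg0 <- cfg
  cfg0[[1]]$leaves$length_sd[] <- 0
  tr0 <- simulate_traits(cfg0, seed = 10)
  ap <- tr0[tr0$species == cfg0[[1]]$name & tr0$part == "apical", ]
  expect_true(all(ap$length_cm == cfg0[[1]]$leaves$length_mean[1]))
  # negative counts rejected
  cfg_bad <- cfg
  cfg_bad[[1]]$flowers$n <- -1
  expect_error(simulate_traits(cfg_bad, seed = 1), "non-negative")
})

test_that("strong configured separation yields decisive rank-sum tests", {
  cfg <- list(
    list(name = "A",
         leaves = data.frame(class = "lateral", n = 30L,
                             length_mean = 10, length_sd = 1,
                             width_mean = 5, width_sd = 0.5),
         pairs = list(values = 3L, probs = 1, n = 5L),
         flowers = list(n = 5L, mean_mm = 5, sd_mm = 0.3)),
    list(name = "B",
         leaves = data.frame(class = "lateral", n = 30L,
                             length_mean = 15, length_sd = 1,  # 5 SD apart
                             width_mean = 5, width_sd = 0.5),
         pairs = list(values = 5L, probs = 1, n = 5L),
         flowers = list(n = 5L, mean_mm = 3, sd_mm = 0.3)))
  tr <- simulate_traits(cfg, seed = 12)
  x <- tr$length_cm[tr$species == "A" & tr$part == "lateral"]
  y <- tr$length_cm[tr$species == "B" & tr$part == "lateral"]
  expect_lt(wilcoxon_rank_sum(x, y)$p_value, 0.001)
})

test_that("variant truth bookkeeping matches the filter cascade exactly", {
  sim <- simulate_variants(variant_sim_config(n_sites = 1500, seed = 14))
  res <- filter_cascade(sim$vm, sim$cds, sim$te)
  expect_equal(res$report$n_survivors,
               c(sim$truth$after_depth, sim$truth$after_region,
                 sim$truth$after_singleton, sim$truth$after_spacing))
  expect_equal(res$mean_depth, sim$truth$mean_site_depth)
})

test_that("singleton fraction 1 leaves no polymorphic site behind", {
  sim <- simulate_variants(variant_sim_config(
    n_sites = 300, singleton_fraction = 1, missing_fraction = 0,
    seed = 16))
  kept <- singleton_filter(sim$vm)$vm
  expect_equal(n_sites(kept), 0)
  expect_equal(sim$truth$planted_singletons, 300)
})
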