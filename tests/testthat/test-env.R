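test_that("extraction reads the containing cell, no interpolation", {
  # constant raster
  const <- env_layer(matrix(7, 10, 10), xll = 0, yll = 0, cellsize = 1,
                     name = "c")
  occ <- occurrence_set("sp", 4.5, 4.5)
  expect_equal(unname(extract_at_points(list(const), occ)$env[1, 1]), 7)

  # analytic field: value of cell (r, c) known in closed form
  f <- function(lon, lat) 3 * lon - 2 * lat
  lon_c <- 0.5 + 0:9; lat_c <- 9.5 - 0:9
  vals <- outer(lat_c, lon_c, function(la, lo) f(lo, la))
  lay <- env_layer(vals, 0, 0, 1, name = "f")
  set.seed(3)
  pts <- occurrence_set(rep("sp", 25), runif(25, 0, 10), runif(25, 0, 10))
  got <- extract_at_points(list(lay), pts)$env[, 1]
  want <- f(floor(pts$lon) + 0.5, floor(pts$lat) + 0.5)
  expect_equal(unname(got), want, tolerance = 1e-12)
})

test_that("records outside the extent or on nodata are dropped and reported", {
  v <- matrix(1, 5, 5); v[3, 3] <- NA
  lay <- env_layer(v, 0, 0, 1, name = "x")
  occ <- occurrence_set(rep("sp", 3), c(2.5, 2.5, 50), c(2.5, 4.0, 4))
  ex <- extract_at_points(list(lay), occ)
  # point 1 hits the NA cell (row 3, col 3), point 3 is outside
  expect_equal(ex$report$n_retained, 1)
  expect_equal(ex$report$dropped$index, c(1L, 3L))
  expect_equal(nrow(ex$occ), 1)
  expect_error(extract_at_points(list(), occ), "layer")
})

test_that("extraction is independent of record order", {
  set.seed(9)
  lay <- env_layer(matrix(rnorm(100), 10, 10), 0, 0, 1, name = "r")
  occ <- occurrence_set(rep("sp", 30), runif(30, 0, 10), runif(30, 0, 10))
  perm <- sample(30)
  a <- extract_at_points(list(lay), occ)$env
  b <- extract_at_points(list(lay),
                         occurrence_set(occ$species[perm], occ$lon[perm],
                                        occ$lat[perm]))$env
  expect_equal(a[perm, , drop = FALSE], b, ignore_attr = TRUE)
})

test_that("ascii grid I/O round-trips values and geotransform", {
  set.seed(5)
  v <- matrix(round(rnorm(30), 6), 5, 6); v[2, 2] <- NA
  lay <- env_layer(v, -10, 40, 0.25, name = "BIO1")
  p <- tempfile(fileext = ".asc")
  write_ascii_grid(lay, p)
  back <- read_ascii_grid(p, name = "BIO1")
  expect_equal(back$values, v, tolerance = 1e-9)
  expect_equal(back$xll, -10)
  expect_equal(back$yll, 40)
  expect_equal(back$cellsize, 0.25)
})

test_that("correlation pruning removes redundant variables", {
  set.seed(11)
  x <- rnorm(200)
  m <- cbind(a = x, b = x + rnorm(200, sd = 1e-6), c = rnorm(200))
  pr <- prune_correlated(m, 0.8)
  expect_equal(sum(c("a", "b") %in% pr$retained), 1)
  expect_true("c" %in% pr$retained)
  # mutually independent columns all survive
  ind <- matrix(rnorm(600), 200, 3, dimnames = list(NULL, c("p", "q", "r")))
  expect_equal(prune_correlated(ind, 0.8)$retained, c("p", "q", "r"))
})

test_that("pruned set matches the exhaustive-subset oracle", {
  sigma <- matrix(c(1, 0.9, 0.85, 0.2,
                    0.9, 1, 0.6, 0.1,
                    0.85, 0.6, 1, 0.1,
                    0.2, 0.1, 0.1, 1), 4, 4,
                  dimnames = list(NULL, c("v1", "v2", "v3", "v4")))
  set.seed(21)
  m <- MASS::mvrnorm(300, rep(0, 4), sigma, empirical = TRUE)
  colnames(m) <- colnames(sigma)
  pr <- prune_correlated(m, 0.8)
  # oracle: largest subset with all pairwise |r| <= 0.8
  best <- character(0)
  for (k in 4:1) {
    subs <- utils::combn(colnames(m), k, simplify = FALSE)
    ok <- Filter(function(s) {
      r <- abs(stats::cor(m[, s, drop = FALSE])); diag(r) <- 0
      all(r <= 0.8)
    }, subs)
    if (length(ok)) { best <- ok; break }
  }
  expect_equal(length(best), 1)  # unique maximal set in this design
  expect_setequal(pr$retained, best[[1]])
})

test_that("keep list protects variables and provenance is recorded", {
  set.seed(13)
  x <- rnorm(100)
  m <- cbind(A = x, B = x + rnorm(100, sd = 0.05), C = rnorm(100))
  pr <- prune_correlated(m, 0.8, keep = "B")
  expect_true("B" %in% pr$retained)
  expect_equal(pr$pruned$variable, "A")
  expect_gt(pr$pruned$max_abs_r, 0.8)
  # constant column goes first, with a warning
  m2 <- cbind(m, K = rep(1, 100))
  expect_warning(pr2 <- prune_correlated(m2, 0.8), "constant")
  expect_false("K" %in% pr2$retained)
})

test_that("no retained pair exceeds the threshold (property)", {
  set.seed(17)
  for (rep in 1:5) {
    p <- sample(4:8, 1)
    L <- matrix(rnorm(p * 2), p, 2)
    sigma <- stats::cov2cor(L %*% t(L) + diag(p))
    m <- MASS::mvrnorm(150, rep(0, p), sigma)
    colnames(m) <- paste0("V", 1:p)
    pr <- prune_correlated(m, 0.7)
    if (length(pr$retained) > 1) {
      r <- abs(stats::cor(pr$env)); diag(r) <- 0
      expect_lte(max(r), 0.7)
    }
  }
})

test_that("z-scoring gives exact mean 0 / SD 1 and is idempotent", {
  expect_equal(unname(zscore(cbind(x = c(1, 2, 3)))[, 1]), c(-1, 0, 1))
  set.seed(19)
  m <- matrix(rnorm(200, 5, 3), 50, 4, dimnames = list(NULL, letters[1:4]))
  z <- zscore(m)
  expect_true(all(abs(colMeans(z)) < 1e-9))
  expect_equal(unname(apply(z, 2, sd)), rep(1, 4), tolerance = 1e-12)
  z2 <- zscore(z)
  expect_equal(z2, z, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(zscore(cbind(k = rep(2, 10))), "constant")
})
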