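# Multivariate normal density via Cholesky; small enough to keep local.
dmvnorm_log <- function(x, mean, sigma) {
  ch <- tryCatch(chol(sigma),
                 error = function(e) stop("covariance not positive-definite"))
  z <- backsolve(ch, t(x) - mean, transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) -
    0.5 * ncol(sigma) * log(2 * pi)
}

#' Configuration for the niche-scenario generator
#'
#' Defines a two-species study system: a widespread, broad-niched
#' tetraploid and a narrow-niched diploid with a distinct climatic
#' optimum, sampled over a subtropical-China-sized extent. Layers are
#' unit-variance standardized environmental fields; species optima are
#' expressed in those units. The default inter-layer correlation structure
#' contains a pair above |r| = 0.8 so the pruning stage is exercised.
#'
#' @param species List of per-species settings; each element a list with
#'   `name`, `mean` (length `n_layers` optimum), `cov` (niche covariance,
#'   symmetric positive-definite), `n` (records).
#' @param extent_lon,extent_lat Extent in degrees (WGS84).
#' @param cellsize Raster cell size in degrees (default 0.05).
#' @param n_layers Number of environmental layers (default 5).
#' @param layer_cor Target inter-layer correlation matrix
#'   (`n_layers` x `n_layers`); realized correlations are its closest
#'   rank-2-plus-diagonal approximation, since the spatial fields live on
#'   two latent gradients.
#' @param dup_fraction Share of records resampled within 1 km of another
#'   record, emulating clustered duplicate collections (default 0.1).
#' @param wiggle Amplitude of the low-frequency sinusoidal warp added to
#'   the latent gradients (default 0.03; 0 gives exactly linear fields).
#' @param seed Integer seed.
#' @return A validated config list of class `niche_sim_config`.
#' @export
niche_sim_config <- function(species = NULL,
                             extent_lon = c(104, 120),
                             extent_lat = c(24, 32),
                             cellsize = 0.05, n_layers = 5,
                             layer_cor = NULL, dup_fraction = 0.1,
                             wiggle = 0.03, seed = 1) {
  if (is.null(layer_cor)) {
    # two blocks of mutually redundant layers (within-block r = 0.85)
    layer_cor <- diag(n_layers)
    blockA <- seq_len(ceiling(n_layers / 2))
    blockB <- setdiff(seq_len(n_layers), blockA)
    layer_cor[blockA, blockA] <- 0.85
    if (length(blockB)) layer_cor[blockB, blockB] <- 0.85
    diag(layer_cor) <- 1
  }
  if (is.null(species)) {
    eg <- eigen(layer_cor, symmetric = TRUE)
    M <- eg$vectors[, 1:2] %*% diag(sqrt(eg$values[1:2]))
    species <- list(
      list(name = "C. paliurus", mean = as.numeric(M %*% c(0.7, -0.2)),
           cov = diag(0.85^2, n_layers), n = 300),
      list(name = "C. serrata", mean = as.numeric(M %*% c(-1.1, 0.5)),
           cov = diag(0.45^2, n_layers), n = 120))
  }
  for (sp in species) {
    if (sp$n < 1) stop("record counts must be >= 1")
    if (length(sp$mean) != n_layers)
      stop("species mean length must equal n_layers")
    ev <- eigen(sp$cov, symmetric = TRUE, only.values = TRUE)$values
    if (!isSymmetric(unname(sp$cov)) || any(ev <= 0))
      stop("covariance not symmetric positive-definite")
  }
  if (cellsize <= 0) stop("cellsize must be positive")
  if (dup_fraction < 0 || dup_fraction > 1)
    stop("dup_fraction must be in [0, 1]")
  structure(list(species = species, extent_lon = extent_lon,
                 extent_lat = extent_lat, cellsize = cellsize,
                 n_layers = n_layers, layer_cor = layer_cor,
                 dup_fraction = dup_fraction, wiggle = wiggle,
                 seed = seed),
            class = "niche_sim_config")
}

# Smooth unit-variance spatial basis over the cell grid: two warped
# linear gradients plus independent low-frequency sinusoid fields, all
# centered and orthogonalized over cells.
latent_fields <- function(lon, lat, cfg, n_noise) {
  rlon <- diff(range(lon)); rlat <- diff(range(lat))
  u <- (lon - mean(lon)) / rlon
  v <- (lat - mean(lat)) / rlat
  b1 <- u + cfg$wiggle * sin(2 * pi * v)
  b2 <- v + cfg$wiggle * sin(2 * pi * u)
  noise <- vapply(seq_len(n_noise), function(k) {
    f <- stats::runif(2, 1, 3)          # low spatial frequency
    ph <- stats::runif(2, 0, 2 * pi)
    sin(2 * pi * f[1] * u + ph[1]) + sin(2 * pi * f[2] * v + ph[2])
  }, numeric(length(u)))
  m <- cbind(b1, b2, noise)
  m <- sweep(m, 2, colMeans(m))
  q <- qr.Q(qr(m))
  # orthonormal columns -> rescale to unit sample variance over cells
  q * sqrt(nrow(m) - 1)
}

#' Generate a synthetic niche scenario
#'
#' Builds `n_layers` smooth environmental rasters realizing the configured
#' inter-layer correlation structure (linear combinations of two latent
#' spatial gradients plus independent smooth noise), then places each
#' species' occurrence records by density-weighted inversion of the
#' environment-to-space mapping: grid cells are sampled with probability
#' proportional to the species' Gaussian niche density at the cell's
#' environmental values, and points are jittered uniformly within their
#' cell. A configured fraction of records is then resampled within 1 km
#' of another record to emulate clustered duplicate collections.
#'
#' Same config (including seed) reproduces identical output.
#'
#' @param cfg A [niche_sim_config()].
#' @return A list: `occ` ([occurrence_set()]), `layers` (list of
#'   [env_layer()], named ENV1..ENVk), `truth` (per-species configured
#'   mean/covariance/latent optimum and duplicate counts, plus the
#'   realized inter-layer correlation over cells).
#' @export
simulate_occurrences <- function(cfg) {
  set.seed(cfg$seed)
  nc <- floor(round(diff(cfg$extent_lon) / cfg$cellsize))
  nr <- floor(round(diff(cfg$extent_lat) / cfg$cellsize))
  lon_c <- cfg$extent_lon[1] + (seq_len(nc) - 0.5) * cfg$cellsize
  lat_c <- cfg$extent_lat[2] - (seq_len(nr) - 0.5) * cfg$cellsize # row 1 = N
  grid_lon <- rep(lon_c, each = nr)
  grid_lat <- rep(lat_c, times = nc)
  # column-major over (row, col): index = (col-1)*nr + row
  basis <- latent_fields(grid_lon, grid_lat, cfg, n_noise = cfg$n_layers)
  eg <- eigen(cfg$layer_cor, symmetric = TRUE)
  M <- eg$vectors[, 1:2, drop = FALSE] %*% diag(sqrt(eg$values[1:2]), 2)
  resid <- pmax(0, 1 - rowSums(M^2))
  env_cells <- basis[, 1:2, drop = FALSE] %*% t(M) +
    sweep(basis[, 2 + seq_len(cfg$n_layers), drop = FALSE],
          2, sqrt(resid), "*")
  colnames(env_cells) <- paste0("ENV", seq_len(cfg$n_layers))
  layers <- lapply(seq_len(cfg$n_layers), function(j) {
    env_layer(matrix(env_cells[, j], nrow = nr, ncol = nc),
              xll = cfg$extent_lon[1], yll = cfg$extent_lat[1],
              cellsize = cfg$cellsize, name = colnames(env_cells)[j])
  })
  names(layers) <- colnames(env_cells)

  species <- character(0); lon <- numeric(0); lat <- numeric(0)
  truth_sp <- list()
  for (sp in cfg$species) {
    lw <- dmvnorm_log(env_cells, sp$mean, sp$cov)
    w <- exp(lw - max(lw))
    cells <- sample.int(length(w), sp$n, replace = TRUE, prob = w)
    row <- ((cells - 1) %% nr) + 1
    col <- ((cells - 1) %/% nr) + 1
    x <- cfg$extent_lon[1] + (col - 1 + stats::runif(sp$n)) * cfg$cellsize
    y <- cfg$extent_lat[2] - (row - 1 + stats::runif(sp$n)) * cfg$cellsize
    n_dup <- floor(cfg$dup_fraction * sp$n)
    if (n_dup > 0 && sp$n - n_dup >= 1) {
      anchors <- sample.int(sp$n - n_dup, n_dup, replace = TRUE)
      dist_km <- stats::runif(n_dup, 0, 0.95)
      theta <- stats::runif(n_dup, 0, 2 * pi)
      idx <- (sp$n - n_dup + 1):sp$n
      y[idx] <- y[anchors] + dist_km * sin(theta) / 111.1949
      x[idx] <- x[anchors] + dist_km * cos(theta) /
        (111.1949 * cos(y[anchors] * pi / 180))
    } else {
      n_dup <- 0
    }
    species <- c(species, rep(sp$name, sp$n))
    lon <- c(lon, x); lat <- c(lat, y)
    truth_sp[[sp$name]] <- list(mean = sp$mean, cov = sp$cov, n = sp$n,
                                n_duplicates = n_dup)
  }
  list(occ = occurrence_set(species, lon, lat), layers = layers,
       truth = list(species = truth_sp,
                    layer_cor_realized = stats::cor(env_cells),
                    seed = cfg$seed))
}

#' Configuration for the trait-table generator
#'
#' Defaults emulate the study system's measurement design: a diploid with
#' narrow, elongated leaflets (higher length-to-width ratio), small male
#' flowers and 4-6 leaflet pairs, against a tetraploid with broader
#' leaflets, larger flowers and 2-4 pairs; leaf and flower sample sizes
#' follow the published measurement counts (38/104/37 vs 47/92/46
#' apical/lateral/basal leaflets; 72 male flowers; 38 vs 47 compound
#' leaves for pair counts).
#'
#' @return A list of per-species trait settings usable by
#'   [simulate_traits()].
#' @export
trait_sim_defaults <- function() {
  list(
    list(name = "C. paliurus",
         leaves = data.frame(
           class = c("apical", "lateral", "basal"),
           n = c(47L, 92L, 46L),
           length_mean = c(12.1, 10.95, 6.35), length_sd = c(1.8, 1.8, 1.2),
           width_mean = c(5.3, 4.5, 2.75), width_sd = c(0.7, 0.6, 0.45)),
         pairs = list(values = c(2L, 3L, 4L), probs = c(3, 23, 21) / 47,
                      n = 47L),
         flowers = list(n = 36L, mean_mm = 5.11, sd_mm = 0.33)),
    list(name = "C. serrata",
         leaves = data.frame(
           class = c("apical", "lateral", "basal"),
           n = c(38L, 104L, 37L),
           length_mean = c(8.8, 10.15, 6.05), length_sd = c(1.3, 1.5, 1.1),
           width_mean = c(3.75, 3.35, 1.95), width_sd = c(0.5, 0.45, 0.3)),
         pairs = list(values = c(4L, 5L, 6L), probs = c(13, 20, 5) / 38,
                      n = 38L),
         flowers = list(n = 36L, mean_mm = 3.35, sd_mm = 0.26)))
}

#' Generate a synthetic morphometric trait table
#'
#' Draws leaflet dimensions and flower diameters from per-species normal
#' distributions and leaflet-pair counts from per-species discrete
#' distributions. The result is a long table: leaflet rows (`part` in
#' apical/lateral/basal) carry `length_cm`, `width_cm` and their ratio;
#' `part == "leaf"` rows carry `leaflet_pairs`; `part == "flower"` rows
#' carry `flower_diameter_mm`.
#'
#' @param config Per-species settings, see [trait_sim_defaults()].
#' @param seed Integer seed.
#' @return A data frame with columns `species`, `part`, `length_cm`,
#'   `width_cm`, `ratio`, `leaflet_pairs`, `flower_diameter_mm`.
#' @export
simulate_traits <- function(config = trait_sim_defaults(), seed = 1) {
  set.seed(seed)
  rows <- list()
  for (sp in config) {
    lv <- sp$leaves
    if (any(lv$n < 0) || sp$pairs$n < 0 || sp$flowers$n < 0)
      stop("counts must be non-negative")
    if (any(c(lv$length_sd, lv$width_sd, sp$flowers$sd_mm) < 0))
      stop("SDs must be non-negative")
    for (i in seq_len(nrow(lv))) {
      len <- pmax(stats::rnorm(lv$n[i], lv$length_mean[i], lv$length_sd[i]),
                  0.05)
      wid <- pmax(stats::rnorm(lv$n[i], lv$width_mean[i], lv$width_sd[i]),
                  0.05)
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp$name, part = lv$class[i], length_cm = len,
        width_cm = wid, ratio = len / wid, leaflet_pairs = NA_integer_,
        flower_diameter_mm = NA_real_)
    }
    pairs <- sp$pairs$values[sample.int(length(sp$pairs$values),
                                        sp$pairs$n, replace = TRUE,
                                        prob = sp$pairs$probs)]
    rows[[length(rows) + 1L]] <- data.frame(
      species = sp$name, part = "leaf", length_cm = NA_real_,
      width_cm = NA_real_, ratio = NA_real_,
      leaflet_pairs = as.integer(pairs), flower_diameter_mm = NA_real_)
    dia <- pmax(stats::rnorm(sp$flowers$n, sp$flowers$mean_mm,
                             sp$flowers$sd_mm), 0.05)
    rows[[length(rows) + 1L]] <- data.frame(
      species = sp$name, part = "flower", length_cm = NA_real_,
      width_cm = NA_real_, ratio = NA_real_, leaflet_pairs = NA_integer_,
      flower_diameter_mm = dia)
  }
  do.call(rbind, rows)
}
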