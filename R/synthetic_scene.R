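#' Configuration for the synthetic landscape generator
#'
#' Bundles every knob of the seeded synthetic scene: grid geometry, the
#' elevation range of the mountain block (default 280-1662 m, the relief of
#' an isolated desert sierra), the four cover classes, per-class mean
#' reflectance spectra with a common noise standard deviation, per-class
#' NDVI target intervals, the logistic truth model that places pine as a
#' function of terrain ruggedness (TRI), vector ruggedness (VRM) and mean
#' temperature of the warmest month (MTWM), the coarseness of the climate
#' grids, and the stratified reference-sample allocation. Below the pine
#' floor the landscape grades from bare desert floor (below ~500 m, after
#' dithering) through scrub into chaparral (above ~900 m).
#'
#' The default truth-model coefficients (intercept 22.0, TRI +0.178,
#' MTWM -1.159, VRM +28.476) give pine occurrence probabilities that rise
#' with ruggedness and fall as the warm-month temperature climbs across its
#' 23.5-25.2 degC range, so rugged, cooler, higher ground carries most of
#' the pine. The synthetic DEM compresses a whole sierra's relief into a
#' small grid and therefore runs somewhat more rugged cell-to-cell than
#' real 15-m terrain; the intercept is set so that, with the ruggedness and
#' temperature slopes at their field magnitudes, the eligible-zone linear
#' predictor centres near zero and occurrence probabilities stay well away
#' from saturation. Pine is only eligible above `pine_floor` (default 1,010 m);
#' below it the landscape grades from bare desert floor through scrub into
#' chaparral by elevation bands with seeded dithering.
#'
#' @param grid_rows,grid_cols Grid dimensions (positive integers).
#' @param cell_size Cell edge, metres.
#' @param elevation_range `c(min, max)` elevation in metres, min < max.
#' @param class_names Ordered cover-class names; code `i` in categorical
#'   grids refers to `class_names[i]`.
#' @param class_spectra Numeric matrix (class x band) of mean reflectances
#'   in `[0, 1]`; rows named by class, columns by band.
#' @param spectral_noise_sd Gaussian noise sd added per band and cell.
#' @param ndvi_targets Named list of `c(low, high)` NDVI intervals per class.
#' @param truth_model Named numeric vector with elements `intercept`,
#'   `TRI`, `MTWM`, `VRM`: logistic coefficients generating pine presence.
#' @param pine_floor Minimum elevation (m) at which pine is eligible.
#' @param band_dither_sd Sd (m) of the seeded elevation dither used when
#'   assigning the non-pine classes to elevation bands.
#' @param mtwm_range `c(min, max)` degC of the warm-month temperature grid.
#' @param climate_noise_sd Sd (degC) of block-level climate noise.
#' @param climate_block_cells Coarseness factor: climate values are constant
#'   within square blocks of this many cells, mimicking an 800-m climate
#'   surface draped over a 10-m scene.
#' @param n_bumps,bump_width_frac,dem_noise_amp Shape controls of the DEM:
#'   number of Gaussian bumps, their width range as a fraction of the short
#'   grid side, and the relative amplitude of the added smooth noise.
#' @param samples_per_class Stratified reference-sample allocation: either a
#'   single count or a named vector per class. The default mirrors a
#'   2,143-point survey (pine 536, scrub 764, chaparral 405, nap 438).
#' @param coarse_band_factor Bands flagged as 20-m are aggregated by this
#'   factor before being resampled back, reproducing the mixed 10/20-m
#'   band structure; `1` disables it.
#' @param seed Integer root seed; every generator draw derives from it.
#' @return A validated list of class `scene_config`.
#' @export
scene_config <- function(grid_rows = 150L, grid_cols = 150L, cell_size = 10,
                         elevation_range = c(280, 1662),
                         class_names = c("pine", "scrub", "chaparral", "nap"),
                         class_spectra = default_class_spectra(),
                         spectral_noise_sd = 0.006,
                         ndvi_targets = list(
                           pine = c(0.30, 0.41), chaparral = c(0.24, 0.28),
                           scrub = c(0.10, 0.15), nap = c(-0.05, 0.08)),
                         truth_model = c(intercept = 22.0, TRI = 0.178,
                                         MTWM = -1.159, VRM = 28.476),
                         pine_floor = 1010,
                         band_dither_sd = 60,
                         mtwm_range = c(23.5, 25.2),
                         climate_noise_sd = 0.05,
                         climate_block_cells = 8L,
                         n_bumps = 8L,
                         bump_width_frac = c(0.20, 0.45),
                         dem_noise_amp = 0.01,
                         samples_per_class = c(pine = 536L, scrub = 764L,
                                               chaparral = 405L, nap = 438L),
                         coarse_band_factor = 2L,
                         seed = 1L) {
  cfg <- list(grid_rows = as.integer(grid_rows),
              grid_cols = as.integer(grid_cols),
              cell_size = cell_size, elevation_range = elevation_range,
              class_names = class_names, class_spectra = class_spectra,
              spectral_noise_sd = spectral_noise_sd,
              ndvi_targets = ndvi_targets, truth_model = truth_model,
              pine_floor = pine_floor, band_dither_sd = band_dither_sd,
              mtwm_range = mtwm_range, climate_noise_sd = climate_noise_sd,
              climate_block_cells = as.integer(climate_block_cells),
              n_bumps = as.integer(n_bumps),
              bump_width_frac = bump_width_frac,
              dem_noise_amp = dem_noise_amp,
              samples_per_class = samples_per_class,
              coarse_band_factor = as.integer(coarse_band_factor),
              seed = as.integer(seed))
  class(cfg) <- "scene_config"
  validate_scene_config(cfg)
}

validate_scene_config <- function(cfg) {
  if (cfg$grid_rows < 1L || cfg$grid_cols < 1L) {
    stop("configuration error: grid dimensions must be positive",
         call. = FALSE)
  }
  if (length(cfg$elevation_range) != 2L ||
      !(cfg$elevation_range[1] < cfg$elevation_range[2])) {
    stop("configuration error: elevation_range must satisfy min < max",
         call. = FALSE)
  }
  sp <- cfg$class_spectra
  if (!is.matrix(sp) || !all(cfg$class_names %in% rownames(sp))) {
    stop("configuration error: class_spectra must cover every class",
         call. = FALSE)
  }
  if (any(!is.finite(sp)) || any(sp < 0) || any(sp > 1)) {
    stop("configuration error: class_spectra must lie in [0, 1]",
         call. = FALSE)
  }
  if (any(cfg$samples_per_class < 1L)) {
    stop("configuration error: samples_per_class must be >= 1",
         call. = FALSE)
  }
  if (cfg$climate_block_cells < 1L) {
    stop("configuration error: climate_block_cells must be >= 1",
         call. = FALSE)
  }
  cfg
}

#' Default per-class mean reflectance spectra
#'
#' Ten bands (B2, B3, B4, B5, B6, B7, B8, B8A, B11, B12). The red (B4) and
#' near-infrared (B8) means are chosen so the noise-free NDVI of each class
#' sits at the centre of its target interval: pine 0.354, chaparral 0.261,
#' scrub 0.126, bare ground (nap) 0.021. The remaining bands follow the
#' broad shape of vegetation spectra (low blue, red-edge ramp, SWIR rising
#' with bare soil fraction) without attempting realism.
#'
#' @return Matrix (4 classes x 10 bands) of mean reflectances.
#' @export
default_class_spectra <- function() {
  bands <- c("B2", "B3", "B4", "B5", "B6", "B7", "B8", "B8A", "B11", "B12")
  m <- rbind(
    pine      = c(0.030, 0.055, 0.143, 0.170, 0.230, 0.280, 0.300, 0.310, 0.190, 0.110),
    scrub     = c(0.060, 0.090, 0.194, 0.210, 0.230, 0.245, 0.250, 0.260, 0.300, 0.230),
    chaparral = c(0.040, 0.070, 0.164, 0.190, 0.230, 0.260, 0.280, 0.290, 0.240, 0.160),
    nap       = c(0.110, 0.150, 0.211, 0.220, 0.225, 0.228, 0.220, 0.230, 0.380, 0.320))
  colnames(m) <- bands
  m
}

#' Generate a synthetic DEM
#'
#' Superimposes seeded Gaussian bumps (count and width from the config) plus
#' a low-amplitude smooth noise field, then rescales the surface affinely so
#' its minimum and maximum equal `elevation_range`. Deterministic given the
#' config seed.
#'
#' @param config A [scene_config()].
#' @return A continuous [grid] of elevations in metres.
#' @export
generate_dem <- function(config) {
  config <- validate_scene_config(config)
  nr <- config$grid_rows; nc <- config$grid_cols
  er <- config$elevation_range
  z <- withr::with_seed(stage_seed(config$seed, "dem"), {
    X <- matrix(rep(seq_len(nc), each = nr), nr, nc)
    Y <- matrix(rep(seq_len(nr), times = nc), nr, nc)
    cx <- stats::runif(config$n_bumps, 1, nc)
    cy <- stats::runif(config$n_bumps, 1, nr)
    w <- stats::runif(config$n_bumps, config$bump_width_frac[1],
                      config$bump_width_frac[2]) * min(nr, nc)
    a <- stats::runif(config$n_bumps, -1, 1)
    z <- matrix(0, nr, nc)
    for (k in seq_len(config$n_bumps)) {
      z <- z + a[k] * exp(-((X - cx[k])^2 + (Y - cy[k])^2) / (2 * w[k]^2))
    }
    # smooth low-amplitude noise: a few high-frequency bumps
    nb <- max(4L, config$n_bumps)
    cx2 <- stats::runif(nb, 1, nc); cy2 <- stats::runif(nb, 1, nr)
    w2 <- stats::runif(nb, 0.02, 0.05) * min(nr, nc)
    a2 <- stats::runif(nb, -1, 1) * config$dem_noise_amp * max(diff(range(z)), 1e-12)
    for (k in seq_len(nb)) {
      z <- z + a2[k] * exp(-((X - cx2[k])^2 + (Y - cy2[k])^2) / (2 * w2[k]^2))
    }
    z
  })
  rng <- range(z)
  if (diff(rng) < .Machine$double.eps) {
    z[] <- mean(er)
  } else {
    z <- er[1] + (z - rng[1]) / diff(rng) * diff(er)
  }
  grid(z, cell_size = config$cell_size, kind = "continuous")
}

#' Generate coarse climate covariate grids
#'
#' Produces a warm-month mean temperature (MTWM) grid as a lapse-rate
#' transform of block-mean elevation -- higher blocks are cooler -- plus
#' seeded block-level noise, held constant within
#' `climate_block_cells x climate_block_cells` blocks to mimic the
#' resolution mismatch between an ~800-m climate surface and a 10-m scene.
#' Values are clipped to `mtwm_range`. Two pure-noise covariates
#' (`noise1`, `noise2`) are included for screening tests.
#'
#' @param dem DEM [grid] from [generate_dem()].
#' @param config A [scene_config()].
#' @return Named list of [grid]s: `MTWM`, `noise1`, `noise2`.
#' @export
generate_covariates <- function(dem, config) {
  check_grid(dem)
  config <- validate_scene_config(config)
  nr <- nrow(dem$values); nc <- ncol(dem$values)
  f <- config$climate_block_cells
  er <- config$elevation_range; tr <- config$mtwm_range
  bm <- block_means(dem$values, f)
  out <- withr::with_seed(stage_seed(config$seed, "covariates"), {
    tb <- tr[2] - (bm - er[1]) / diff(er) * diff(tr)
    tb <- tb + stats::rnorm(length(tb), sd = config$climate_noise_sd)
    tb <- pmin(pmax(tb, tr[1]), tr[2])
    mtwm <- expand_blocks(tb, f, nr, nc)
    n1 <- matrix(stats::rnorm(nr * nc), nr, nc)
    n2 <- matrix(stats::rnorm(nr * nc), nr, nc)
    list(MTWM = mtwm, noise1 = n1, noise2 = n2)
  })
  lapply(out, grid, cell_size = config$cell_size, kind = "continuous")
}

#' Generate the cover-truth map
#'
#' Cells at or above `pine_floor` are pine-eligible; each eligible cell is
#' drawn Bernoulli with probability
#' `plogis(intercept + b_TRI*TRI + b_MTWM*MTWM + b_VRM*VRM)` from the
#' config's `truth_model`. Remaining cells are assigned bare ground (nap),
#' scrub or chaparral by elevation bands (below 500 m, 500-900 m, above
#' 900 m) after adding seeded Gaussian dither to the elevation, which mixes
#' the band edges the way real ecotones interdigitate.
#'
#' @param dem DEM [grid].
#' @param terrain Named list containing `tri` and `vrm` [grid]s (see
#'   [compute_tri()], [compute_vrm()]).
#' @param covariates Named list containing an `MTWM` [grid].
#' @param config A [scene_config()].
#' @return A categorical [grid] with levels `config$class_names`.
#' @export
generate_cover_truth <- function(dem, terrain, covariates, config) {
  check_grid(dem)
  config <- validate_scene_config(config)
  tm <- config$truth_model
  need <- c("intercept", "TRI", "MTWM", "VRM")
  if (!all(need %in% names(tm))) {
    stop("configuration error: truth_model missing coefficient(s): ",
         paste(setdiff(need, names(tm)), collapse = ", "), call. = FALSE)
  }
  if (!all(c("tri", "vrm") %in% names(terrain))) {
    stop("terrain must contain `tri` and `vrm` grids", call. = FALSE)
  }
  if (!"MTWM" %in% names(covariates)) {
    stop("covariates must contain an `MTWM` grid", call. = FALSE)
  }
  z <- dem$values
  lp <- tm[["intercept"]] + tm[["TRI"]] * terrain$tri$values +
    tm[["MTWM"]] * covariates$MTWM$values + tm[["VRM"]] * terrain$vrm$values
  p <- inv_logit(lp)
  eligible <- !is.na(z) & z >= config$pine_floor
  nr <- nrow(z); nc <- ncol(z)
  cover <- withr::with_seed(stage_seed(config$seed, "cover"), {
    u <- matrix(stats::runif(nr * nc), nr, nc)
    pine <- eligible & !is.na(p) & u < p
    zd <- z + matrix(stats::rnorm(nr * nc, sd = config$band_dither_sd), nr, nc)
    k <- matrix(NA_real_, nr, nc)
    k[!is.na(z)] <- 2          # scrub default
    k[!is.na(zd) & zd < 500] <- 4   # nap: desert floor
    k[!is.na(zd) & zd >= 900] <- 3  # chaparral
    k[pine] <- 1
    k
  })
  grid(cover, cell_size = config$cell_size, kind = "categorical",
       levels = config$class_names)
}

#' Generate reflectance band grids for a cover map
#'
#' Each cell's reflectance in each band is its class mean (from
#' `class_spectra`) plus seeded Gaussian noise with sd
#' `spectral_noise_sd`, clipped to `[0, 1]`.
#'
#' @param cover Categorical cover [grid].
#' @param config A [scene_config()].
#' @return Named list of continuous band [grid]s, one per spectra column.
#' @export
generate_spectra <- function(cover, config) {
  check_grid(cover)
  config <- validate_scene_config(config)
  sp <- config$class_spectra[config$class_names, , drop = FALSE]
  codes <- cover$values
  used <- sort(unique(codes[!is.na(codes)]))
  if (length(used) && any(used < 1 | used > nrow(sp))) {
    stop("configuration error: cover contains class codes without spectra",
         call. = FALSE)
  }
  nr <- nrow(codes); nc <- ncol(codes)
  idx <- as.vector(codes)
  withr::with_seed(stage_seed(config$seed, "spectra"), {
    out <- lapply(colnames(sp), function(b) {
      v <- sp[idx, b]
      v <- v + stats::rnorm(length(v), sd = config$spectral_noise_sd)
      v <- pmin(pmax(v, 0), 1)
      v[is.na(idx)] <- NA_real_
      grid(matrix(v, nr, nc), cell_size = config$cell_size)
    })
    names(out) <- colnames(sp)
    out
  })
}

#' Draw a stratified random reference sample
#'
#' Samples, without replacement and per class, the number of cells given by
#' `config$samples_per_class` (a single count applied to every class or a
#' named per-class allocation). Deterministic given the config seed.
#'
#' @param cover Categorical cover [grid] to stratify on (truth, or a
#'   predicted map when building an accuracy-assessment sample).
#' @param config A [scene_config()].
#' @param counts Optional override of the per-class allocation.
#' @return Data frame with columns `row`, `col`, `true_class` (the class of
#'   the stratifying grid at the sampled cell).
#' @export
sample_reference <- function(cover, config, counts = NULL) {
  check_grid(cover)
  config <- validate_scene_config(config)
  cls <- if (!is.null(cover$levels)) cover$levels else config$class_names
  if (is.null(counts)) counts <- config$samples_per_class
  if (length(counts) == 1L && is.null(names(counts))) {
    counts <- stats::setNames(rep(as.integer(counts), length(cls)), cls)
  }
  if (!all(cls %in% names(counts))) {
    stop("sampling error: counts must name every class", call. = FALSE)
  }
  v <- cover$values
  withr::with_seed(stage_seed(config$seed, "sample"), {
    rows <- lapply(seq_along(cls), function(k) {
      cells <- which(v == k)
      nk <- counts[[cls[k]]]
      if (length(cells) < nk) {
        stop(sprintf(
          "sampling error: class '%s' has %d cells but %d were requested",
          cls[k], length(cells), nk), call. = FALSE)
      }
      picked <- sample(cells, nk)
      ij <- arrayInd(picked, dim(v))
      data.frame(row = ij[, 1], col = ij[, 2],
                 true_class = cls[k], stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
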