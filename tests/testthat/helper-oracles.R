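# Independent brute-force oracles and small fixture builders used across
# the suite. The oracles are deliberately naive double loops, sharing no
# code with the package kernels.

mgrid <- function(m, cell = 10, ...) pinyon::grid(m, cell_size = cell, ...)

pad_edge <- function(m, n = 1L) {
  for (k in seq_len(n)) {
    m <- rbind(m[1, ], m, m[nrow(m), ])
    m <- cbind(m[, 1], m, m[, ncol(m)])
  }
  m
}

# Horn slope/aspect, scalar arithmetic per cell
naive_slope_aspect <- function(m, cell) {
  nr <- nrow(m); nc <- ncol(m)
  p <- pad_edge(m)
  slope <- matrix(NA_real_, nr, nc); aspect <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      a <- p[r, c];     b <- p[r, c + 1]; cc <- p[r, c + 2]
      d <- p[r + 1, c];                   f <- p[r + 1, c + 2]
      g <- p[r + 2, c]; h <- p[r + 2, c + 1]; i <- p[r + 2, c + 2]
      gx <- ((cc + 2 * f + i) - (a + 2 * d + g)) / (8 * cell)
      gy <- ((a + 2 * b + cc) - (g + 2 * h + i)) / (8 * cell)
      slope[r, c] <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
      if (gx != 0 || gy != 0) {
        aspect[r, c] <- (atan2(-gx, -gy) * 180 / pi) %% 360
      }
    }
  }
  list(slope = slope, aspect = aspect)
}

naive_tri <- function(m, variant = "riley_sqrt_sum_squares") {
  nr <- nrow(m); nc <- ncol(m)
  p <- pad_edge(m)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      z0 <- m[r, c]
      diffs <- c()
      for (dr in 0:2) for (dc in 0:2) {
        if (dr == 1 && dc == 1) next
        diffs <- c(diffs, p[r + dr, c + dc] - z0)
      }
      out[r, c] <- switch(variant,
        riley_sqrt_sum_squares = sqrt(sum(diffs^2)),
        sum_abs = sum(abs(diffs)),
        mean_abs = mean(abs(diffs)))
    }
  }
  out
}

naive_vrm <- function(m, cell, window = 3L) {
  sa <- naive_slope_aspect(m, cell)
  nr <- nrow(m); nc <- ncol(m)
  s <- sa$slope * pi / 180; a <- sa$aspect * pi / 180
  xn <- matrix(0, nr, nc); yn <- matrix(0, nr, nc); zn <- matrix(1, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (s[r, c] > 0) {
      xn[r, c] <- sin(s[r, c]) * sin(a[r, c])
      yn[r, c] <- sin(s[r, c]) * cos(a[r, c])
      zn[r, c] <- cos(s[r, c])
    }
  }
  h <- (window - 1L) %/% 2L
  px <- pad_edge(xn, h); py <- pad_edge(yn, h); pz <- pad_edge(zn, h)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    sx <- 0; sy <- 0; sz <- 0; n <- 0
    for (dr in 0:(window - 1)) for (dc in 0:(window - 1)) {
      sx <- sx + px[r + dr, c + dc]
      sy <- sy + py[r + dr, c + dc]
      sz <- sz + pz[r + dr, c + dc]
      n <- n + 1
    }
    out[r, c] <- 1 - sqrt(sx^2 + sy^2 + sz^2) / n
  }
  out
}

# small full scene used by classifier/pipeline tests
build_small_scene <- function(seed = 1, rows = 60, cols = 60,
                              noise = 0.006, spc = 80L, ...) {
  sc <- scene_config(grid_rows = rows, grid_cols = cols,
                     spectral_noise_sd = noise,
                     samples_per_class = spc, seed = seed, ...)
  dem <- generate_dem(sc)
  terrain <- compute_terrain(dem)
  covariates <- generate_covariates(dem, sc)
  cover <- generate_cover_truth(dem, terrain, covariates, sc)
  bands <- generate_spectra(cover, sc)
  stack <- stack_scene(bands, compute_ndvi(bands$B8, bands$B4))
  list(config = sc, dem = dem, terrain = terrain,
       covariates = covariates, cover = cover, stack = stack)
}

table3_fixture <- function() {
  system.file("extdata", "table3_error_matrix.csv", package = "pinyon")
}

table3_em <- function() read_error_matrix_csv(table3_fixture())
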