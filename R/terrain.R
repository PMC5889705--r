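# Terrain derivatives: slope/aspect (Horn), TRI, VRM.
#
# All kernels keep the output the same shape as the input. The default
# border policy replicates edge cells; `border = "nodata"` marks the
# outermost ring nodata instead.

# shifted neighbour matrices of a padded matrix: offsets (dr, dc)
shift_mat <- function(p, dr, dc, nr, nc) {
  p[(1 + dr):(nr + dr), (1 + dc):(nc + dc), drop = FALSE]
}

apply_border <- function(v, border) {
  if (border == "nodata") {
    v[1, ] <- NA_real_; v[nrow(v), ] <- NA_real_
    v[, 1] <- NA_real_; v[, ncol(v)] <- NA_real_
  }
  v
}

#' Slope and aspect from a DEM
#'
#' Horn's 3x3 finite-difference gradients. Slope is `atan(|grad z|)` in
#' degrees; aspect is the compass direction of the downslope vector,
#' degrees clockwise from north in `[0, 360)`. Cells with zero gradient
#' (flat) get nodata aspect. Borders are handled by edge replication (or
#' marked nodata with `border = "nodata"`).
#'
#' @param dem Elevation [grid], at least 3x3, with a known cell size.
#' @param border `"replicate"` (default) or `"nodata"`.
#' @return List with `slope` and `aspect` [grid]s (degrees).
#' @export
compute_slope_aspect <- function(dem, border = c("replicate", "nodata")) {
  check_grid(dem)
  border <- match.arg(border)
  v <- dem$values
  nr <- nrow(v); nc <- ncol(v)
  if (nr < 3L || nc < 3L) stop("DEM must be at least 3x3", call. = FALSE)
  cs <- dem$cell_size
  if (!is.finite(cs) || cs <= 0) stop("unknown cell size", call. = FALSE)
  p <- pad_replicate(v)
  nw <- shift_mat(p, 0L, 0L, nr, nc); n_ <- shift_mat(p, 0L, 1L, nr, nc)
  ne <- shift_mat(p, 0L, 2L, nr, nc); w_ <- shift_mat(p, 1L, 0L, nr, nc)
  e_ <- shift_mat(p, 1L, 2L, nr, nc); sw <- shift_mat(p, 2L, 0L, nr, nc)
  s_ <- shift_mat(p, 2L, 1L, nr, nc); se <- shift_mat(p, 2L, 2L, nr, nc)
  gx <- ((ne + 2 * e_ + se) - (nw + 2 * w_ + sw)) / (8 * cs)  # d z / d east
  gy <- ((nw + 2 * n_ + ne) - (sw + 2 * s_ + se)) / (8 * cs)  # d z / d north
  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  aspect <- (atan2(-gx, -gy) * 180 / pi) %% 360
  flat <- !is.na(gx) & !is.na(gy) & gx == 0 & gy == 0
  aspect[flat] <- NA_real_
  aspect[is.na(gx) | is.na(gy)] <- NA_real_
  slope[is.na(v)] <- NA_real_; aspect[is.na(v)] <- NA_real_
  slope <- apply_border(slope, border); aspect <- apply_border(aspect, border)
  list(slope = grid(slope, cell_size = cs),
       aspect = grid(aspect, cell_size = cs))
}

#' Terrain ruggedness index
#'
#' Summarises the elevation change between each cell and its eight
#' neighbours. Three formulations are available:
#' `riley_sqrt_sum_squares` (default) is `sqrt(sum((z_k - z_0)^2))`;
#' `sum_abs` is `sum(|z_k - z_0|)`; `mean_abs` divides that sum by the
#' number of usable neighbours (the GDAL/QGIS convention). Nodata
#' neighbours are excluded with count adjustment; a nodata centre stays
#' nodata. Borders by edge replication (or nodata via `border`).
#'
#' @param dem Elevation [grid], at least 3x3.
#' @param variant One of `"riley_sqrt_sum_squares"`, `"sum_abs"`,
#'   `"mean_abs"`.
#' @param border `"replicate"` or `"nodata"`.
#' @return A [grid] of TRI values (metres).
#' @export
compute_tri <- function(dem,
                        variant = c("riley_sqrt_sum_squares", "sum_abs",
                                    "mean_abs"),
                        border = c("replicate", "nodata")) {
  check_grid(dem)
  variant <- match.arg(variant)
  border <- match.arg(border)
  v <- dem$values
  nr <- nrow(v); nc <- ncol(v)
  if (nr < 3L || nc < 3L) stop("DEM must be at least 3x3", call. = FALSE)
  p <- pad_replicate(v)
  offs <- expand.grid(dr = 0:2, dc = 0:2)
  offs <- offs[!(offs$dr == 1 & offs$dc == 1), ]
  ssq <- matrix(0, nr, nc); sab <- matrix(0, nr, nc)
  cnt <- matrix(0, nr, nc)
  for (k in seq_len(nrow(offs))) {
    nb <- shift_mat(p, offs$dr[k], offs$dc[k], nr, nc)
    d <- nb - v
    ok <- !is.na(d)
    ssq[ok] <- ssq[ok] + d[ok]^2
    sab[ok] <- sab[ok] + abs(d[ok])
    cnt <- cnt + ok
  }
  out <- switch(variant,
    riley_sqrt_sum_squares = sqrt(ssq),
    sum_abs = sab,
    mean_abs = sab / pmax(cnt, 1))
  out[is.na(v) | cnt == 0] <- NA_real_
  out <- apply_border(out, border)
  grid(out, cell_size = dem$cell_size)
}

#' Vector ruggedness measure
#'
#' Measures the three-dimensional dispersion of unit vectors normal to the
#' local surface over a square moving window. Each cell's normal is built
#' from its slope `s` and aspect `a`:
#' `(sin s sin a, sin s cos a, cos s)`; flat cells contribute `(0, 0, 1)`.
#' With resultant length `|R|` over the `n` window cells,
#' `VRM = 1 - |R|/n`, which is 0 on any plane and approaches 1 for
#' maximally dispersed normals.
#'
#' @param dem Elevation [grid], at least `window x window`.
#' @param window Odd window edge length, >= 3 (default 3).
#' @param border `"replicate"` or `"nodata"`.
#' @return A [grid] of VRM values in `[0, 1]`.
#' @export
compute_vrm <- function(dem, window = 3L, border = c("replicate", "nodata")) {
  check_grid(dem)
  border <- match.arg(border)
  w <- as.integer(window)
  if (w < 3L || w %% 2L == 0L) {
    stop("`window` must be an odd integer >= 3", call. = FALSE)
  }
  v <- dem$values
  nr <- nrow(v); nc <- ncol(v)
  if (nr < w || nc < w) stop("DEM smaller than window", call. = FALSE)
  sa <- compute_slope_aspect(dem, border = "replicate")
  s <- sa$slope$values * pi / 180
  a <- sa$aspect$values * pi / 180
  xn <- sin(s) * sin(a); yn <- sin(s) * cos(a); zn <- cos(s)
  flat <- !is.na(s) & s == 0
  xn[flat] <- 0; yn[flat] <- 0; zn[flat] <- 1
  bad <- is.na(v)
  xn[bad] <- NA; yn[bad] <- NA; zn[bad] <- NA
  h <- (w - 1L) %/% 2L
  px <- pad_replicate(xn, h); py <- pad_replicate(yn, h); pz <- pad_replicate(zn, h)
  sx <- matrix(0, nr, nc); sy <- matrix(0, nr, nc); sz <- matrix(0, nr, nc)
  cnt <- matrix(0, nr, nc)
  for (dr in 0:(w - 1L)) {
    for (dc in 0:(w - 1L)) {
      cx <- shift_mat(px, dr, dc, nr, nc)
      cy <- shift_mat(py, dr, dc, nr, nc)
      cz <- shift_mat(pz, dr, dc, nr, nc)
      ok <- !is.na(cx)
      sx[ok] <- sx[ok] + cx[ok]
      sy[ok] <- sy[ok] + cy[ok]
      sz[ok] <- sz[ok] + cz[ok]
      cnt <- cnt + ok
    }
  }
  res <- sqrt(sx^2 + sy^2 + sz^2)
  out <- 1 - res / pmax(cnt, 1)
  out <- pmin(pmax(out, 0), 1)
  out[bad | cnt == 0] <- NA_real_
  out <- apply_border(out, border)
  grid(out, cell_size = dem$cell_size)
}

#' Full terrain derivative set
#'
#' Convenience wrapper computing slope, aspect, TRI and VRM from one DEM.
#'
#' @param dem Elevation [grid].
#' @param tri_variant Passed to [compute_tri()].
#' @param vrm_window Passed to [compute_vrm()].
#' @param border Border policy for all metrics.
#' @return Named list of grids: `slope`, `aspect`, `tri`, `vrm`, with the
#'   TRI variant recorded in the `tri_variant` attribute.
#' @export
compute_terrain <- function(dem, tri_variant = "riley_sqrt_sum_squares",
                            vrm_window = 3L,
                            border = c("replicate", "nodata")) {
  border <- match.arg(border)
  sa <- compute_slope_aspect(dem, border = border)
  out <- list(slope = sa$slope, aspect = sa$aspect,
              tri = compute_tri(dem, variant = tri_variant, border = border),
              vrm = compute_vrm(dem, window = vrm_window, border = border))
  attr(out, "tri_variant") <- tri_variant
  attr(out, "vrm_window") <- vrm_window
  out
}
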