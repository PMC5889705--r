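#' Resample a grid to a finer resolution
#'
#' Upsamples a grid by an integer factor, either by nearest-neighbour block
#' replication or by bilinear interpolation between cell centres with edge
#' clamping. The output has `factor` times as many rows and columns and a
#' correspondingly smaller cell size. Nodata propagates to every output
#' cell whose interpolation support touches a nodata input cell.
#'
#' @param coarse Input [grid].
#' @param factor Integer upsampling factor, >= 1.
#' @param method `"nearest"` or `"bilinear"`.
#' @return A [grid] of shape `dim(coarse) * factor`.
#' @export
resample_to_fine <- function(coarse, factor, method = c("bilinear", "nearest")) {
  check_grid(coarse)
  method <- match.arg(method)
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 ||
      factor != round(factor)) {
    stop("`factor` must be an integer >= 1", call. = FALSE)
  }
  f <- as.integer(factor)
  v <- coarse$values
  nr <- nrow(v); nc <- ncol(v)
  if (method == "nearest") {
    out <- v[rep(seq_len(nr), each = f), rep(seq_len(nc), each = f),
             drop = FALSE]
  } else {
    ax <- function(n) {
      # fine-cell centres in coarse-centre coordinates (centres at 1..n)
      u <- (seq_len(n * f) - 0.5) / f + 0.5
      k0 <- floor(u)
      frac <- u - k0
      i0 <- pmin(pmax(k0, 1), n)
      i1 <- pmin(pmax(k0 + 1, 1), n)
      i1[frac == 0] <- i0[frac == 0]  # exact centre: support is one cell
      list(i0 = i0, i1 = i1, w = frac)
    }
    r <- ax(nr); cc <- ax(nc)
    v00 <- v[r$i0, cc$i0, drop = FALSE]; v01 <- v[r$i0, cc$i1, drop = FALSE]
    v10 <- v[r$i1, cc$i0, drop = FALSE]; v11 <- v[r$i1, cc$i1, drop = FALSE]
    wr <- matrix(r$w, nr * f, nc * f)
    wc <- matrix(cc$w, nr * f, nc * f, byrow = TRUE)
    out <- (1 - wr) * ((1 - wc) * v00 + wc * v01) +
      wr * ((1 - wc) * v10 + wc * v11)
    out[is.na(v00) | is.na(v01) | is.na(v10) | is.na(v11)] <- NA_real_
  }
  grid(out, cell_size = coarse$cell_size / f, kind = coarse$kind,
       levels = coarse$levels)
}

#' Aggregate a grid to a coarser resolution by block means
#'
#' The companion of [resample_to_fine()]: averages `factor x factor` blocks
#' (requires the grid dimensions to be multiples of `factor`), yielding a
#' grid with a correspondingly larger cell size. Used to emulate bands
#' acquired at a coarser native resolution.
#'
#' @param fine Input [grid].
#' @param factor Integer aggregation factor, >= 1.
#' @return A [grid] of shape `dim(fine) / factor`.
#' @export
aggregate_to_coarse <- function(fine, factor) {
  check_grid(fine)
  f <- as.integer(factor)
  if (f < 1L) stop("`factor` must be an integer >= 1", call. = FALSE)
  v <- fine$values
  if (nrow(v) %% f != 0L || ncol(v) %% f != 0L) {
    stop("grid dimensions must be multiples of `factor`", call. = FALSE)
  }
  grid(block_means(v, f), cell_size = fine$cell_size * f, kind = fine$kind)
}

#' Normalized difference vegetation index
#'
#' Computes `(NIR - R) / (NIR + R)` cellwise. Cells where `NIR + R == 0`
#' become nodata rather than fabricating a vegetation signal; nodata in
#' either input propagates.
#'
#' @param nir Near-infrared band [grid] (B8).
#' @param red Red band [grid] (B4).
#' @return A continuous [grid] of NDVI values.
#' @export
compute_ndvi <- function(nir, red) {
  check_grid(nir); check_grid(red)
  if (!identical(dim(nir$values), dim(red$values))) {
    stop("`nir` and `red` must share shape", call. = FALSE)
  }
  s <- nir$values + red$values
  out <- (nir$values - red$values) / s
  out[!is.na(s) & s == 0] <- NA_real_
  grid(out, cell_size = nir$cell_size, kind = "continuous")
}

#' Band roster of the ten-band scene
#' @return Character vector of required band names, in stack order.
#' @export
scene_band_names <- function() {
  c("B2", "B3", "B4", "B5", "B6", "B7", "B8", "B8A", "B11", "B12")
}

#' Stack bands and NDVI into a fixed-order feature stack
#'
#' Assembles the ten reflectance bands plus NDVI into a `scene_stack` whose
#' feature order is fixed (B2...B12, NDVI appended last as the 11th
#' feature) so trained models are portable across runs. All member grids
#' must share shape and cell size.
#'
#' @param bands Named list of the ten band [grid]s (may already include an
#'   `NDVI` element, in which case `ndvi` can be omitted).
#' @param ndvi NDVI [grid] from [compute_ndvi()].
#' @return An object of class `scene_stack`.
#' @export
stack_scene <- function(bands, ndvi = NULL) {
  if (!is.null(ndvi)) bands <- c(bands, list(NDVI = ndvi))
  need <- c(scene_band_names(), "NDVI")
  missing <- setdiff(need, names(bands))
  if (length(missing)) {
    stop("missing required band(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bands <- bands[need]
  lapply(bands, check_grid)
  d <- dim(bands[[1]]$values); cs <- bands[[1]]$cell_size
  for (b in names(bands)) {
    if (!identical(dim(bands[[b]]$values), d) ||
        !isTRUE(all.equal(bands[[b]]$cell_size, cs))) {
      stop("band `", b, "` does not share the common grid", call. = FALSE)
    }
  }
  structure(list(bands = bands), class = "scene_stack")
}

#' @export
print.scene_stack <- function(x, ...) {
  d <- dim(x$bands[[1]]$values)
  cat(sprintf("<scene_stack> %d features on a %d x %d grid: %s\n",
              length(x$bands), d[1], d[2],
              paste(names(x$bands), collapse = ", ")))
  invisible(x)
}

#' Feature matrix of a scene stack
#'
#' Flattens a stack into an `ncell x nfeature` matrix (column-major cell
#' order), one column per band in stack order.
#'
#' @param stack A `scene_stack`.
#' @return Numeric matrix with one row per cell.
#' @export
feature_matrix <- function(stack) {
  stopifnot(inherits(stack, "scene_stack"))
  sapply(stack$bands, function(g) as.vector(g$values))
}
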