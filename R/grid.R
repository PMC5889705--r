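#' Raster grid container
#'
#' A `grid` is the package's lightweight raster: a numeric matrix of cell
#' values (row 1 is the northern edge), a cell size in metres, and a kind
#' flag distinguishing continuous fields (elevation, reflectance, indices)
#' from categorical maps (cover classes stored as integer codes). Nodata
#' cells are carried as `NA`.
#'
#' @param values Numeric matrix of cell values; `NA` marks nodata.
#' @param cell_size Cell edge length in metres (single positive number).
#' @param kind `"continuous"` or `"categorical"`.
#' @param levels For categorical grids, the class names corresponding to
#'   integer codes `1..length(levels)`.
#' @return An object of class `grid`.
#' @examples
#' g <- grid(matrix(runif(12), 3, 4), cell_size = 10)
#' nodata_mask(g)
#' @export
grid <- function(values, cell_size = 10, kind = c("continuous", "categorical"),
                 levels = NULL) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("grid dimensions must be positive", call. = FALSE)
  }
  if (!is.numeric(cell_size) || length(cell_size) != 1L ||
      !is.finite(cell_size) || cell_size <= 0) {
    stop("`cell_size` must be a single positive number", call. = FALSE)
  }
  if (kind == "categorical") {
    v <- values[!is.na(values)]
    if (length(v) && any(v != round(v))) {
      stop("categorical grids may contain only integer class codes or NA",
           call. = FALSE)
    }
  }
  structure(list(values = values, cell_size = cell_size, kind = kind,
                 levels = levels),
            class = "grid")
}

#' @export
dim.grid <- function(x) dim(x$values)

#' Nodata mask of a grid
#'
#' @param x A [grid].
#' @return Logical matrix, `TRUE` where the cell is nodata.
#' @export
nodata_mask <- function(x) {
  stopifnot(inherits(x, "grid"))
  is.na(x$values)
}

#' @export
print.grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<grid> %d x %d cells, %.6g m cell size, %s\n",
              d[1], d[2], x$cell_size, x$kind))
  if (!is.null(x$levels)) {
    cat("  classes:", paste(x$levels, collapse = ", "), "\n")
  }
  rng <- suppressWarnings(range(x$values, na.rm = TRUE))
  if (all(is.finite(rng))) {
    cat(sprintf("  range: [%.6g, %.6g], %d nodata cells\n",
                rng[1], rng[2], sum(is.na(x$values))))
  } else {
    cat("  all cells nodata\n")
  }
  invisible(x)
}

#' Write a grid as an ESRI ASCII raster
#'
#' Grids are stored in the ESRI ASCII grid format (plain text, readable by
#' GDAL/QGIS): a six-line header followed by one line of values per raster
#' row, north first. Nodata is written as -9999. Categorical grids are
#' written as integer codes; class names are not stored in the file.
#'
#' @param x A [grid].
#' @param path Output file path (conventionally `.asc`).
#' @param xllcorner,yllcorner Placeholder origin of the lower-left corner.
#' @return `path`, invisibly.
#' @export
write_grid <- function(x, path, xllcorner = 0, yllcorner = 0) {
  stopifnot(inherits(x, "grid"))
  v <- x$values
  v[is.na(v)] <- -9999
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.6f", xllcorner),
    sprintf("yllcorner %.6f", yllcorner),
    sprintf("cellsize %.6f", x$cell_size),
    "NODATA_value -9999"
  ), con)
  fmt <- if (x$kind == "categorical") "%d" else "%.10g"
  apply_fmt <- function(row) paste(sprintf(fmt, row), collapse = " ")
  writeLines(vapply(seq_len(nrow(v)), function(i) apply_fmt(v[i, ]), ""), con)
  invisible(path)
}

#' Read an ESRI ASCII raster as a grid
#'
#' @param path File written by [write_grid()] (or any ESRI ASCII grid).
#' @param kind `"continuous"` or `"categorical"`.
#' @param levels Optional class names for categorical grids.
#' @return A [grid].
#' @export
read_grid <- function(path, kind = c("continuous", "categorical"),
                      levels = NULL) {
  kind <- match.arg(kind)
  lines <- readLines(path)
  if (length(lines) < 7L) stop("not an ESRI ASCII grid: ", path, call. = FALSE)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[`, "", 1L))
  vals <- vapply(hdr, `[`, "", 2L)
  h <- stats::setNames(as.numeric(vals), keys)
  nr <- as.integer(h[["nrows"]]); nc <- as.integer(h[["ncols"]])
  nodata <- if ("nodata_value" %in% keys) h[["nodata_value"]] else -9999
  body <- scan(text = lines[-(1:6)], what = numeric(), quiet = TRUE)
  if (length(body) != nr * nc) {
    stop("grid body has ", length(body), " values, expected ", nr * nc,
         call. = FALSE)
  }
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  grid(m, cell_size = h[["cellsize"]], kind = kind, levels = levels)
}
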