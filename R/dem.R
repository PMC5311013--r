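#' Create a DEM raster
#'
#' A minimal single-band elevation raster: a numeric matrix of ground
#' elevations on a regular grid.  Rows index y (south to north), columns
#' index x (west to east); `origin` is the lower-left corner of the
#' lower-left cell.  Cell centres are at
#' `origin + (index - 0.5) * resolution`.
#'
#' @param elevation Numeric matrix of elevations (m); `elevation[i, j]` is
#'   the cell in row i (y) and column j (x).
#' @param origin Numeric length-2: x, y of the lower-left grid corner (m).
#' @param resolution Cell size (m), default 1.
#' @param nodata Value marking missing cells in `elevation`
#'   (converted to `NA` internally), default -9999.
#' @return An object of class `dem_raster`.
#' @examples
#' dem <- dem_raster(matrix(0, 50, 50), origin = c(0, 0))
#' @export
dem_raster <- function(elevation, origin = c(0, 0), resolution = 1,
                       nodata = -9999) {
  if (!is.matrix(elevation) || !is.numeric(elevation)) {
    abort("`elevation` must be a numeric matrix.")
  }
  check_number(resolution, "resolution", positive = TRUE)
  elevation[elevation == nodata] <- NA_real_
  structure(
    list(
      elevation = elevation,
      origin = as.numeric(origin),
      resolution = resolution,
      nodata = nodata
    ),
    class = "dem_raster"
  )
}

#' @export
print.dem_raster <- function(x, ...) {
  cat(sprintf(
    "<dem_raster> %d x %d cells @ %g m, origin (%g, %g), %d nodata\n",
    nrow(x$elevation), ncol(x$elevation), x$resolution,
    x$origin[1], x$origin[2], sum(is.na(x$elevation))
  ))
  invisible(x)
}

dem_extent <- function(dem) {
  c(
    dem$origin[1], dem$origin[2],
    dem$origin[1] + ncol(dem$elevation) * dem$resolution,
    dem$origin[2] + nrow(dem$elevation) * dem$resolution
  )
}

#' Sample ground elevation from a DEM
#'
#' Bilinear interpolation between the four surrounding cell centres
#' (default), or nearest-neighbour cell lookup.  Bilinear sampling is exact
#' for planar surfaces.  Query points must lie within the DEM extent;
#' beyond the outermost cell centres the interpolation clamps to the edge
#' cells.
#'
#' @param dem A [dem_raster()].
#' @param x,y Query coordinates (m), equal length.
#' @param method `"bilinear"` or `"nearest"`.
#' @return Numeric vector of elevations; `NA` where a contributing cell is
#'   nodata.
#' @export
sample_dem <- function(dem, x, y, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  stopifnot(inherits(dem, "dem_raster"), length(x) == length(y))
  ext <- dem_extent(dem)
  outside <- x < ext[1] | x > ext[3] | y < ext[2] | y > ext[4]
  if (any(outside)) {
    abort(sprintf(
      "%d query point(s) fall outside the DEM extent.", sum(outside)
    ))
  }
  res <- dem$resolution
  el <- dem$elevation
  nr <- nrow(el)
  nc <- ncol(el)
  # fractional cell-centre coordinates
  fx <- (x - dem$origin[1]) / res - 0.5
  fy <- (y - dem$origin[2]) / res - 0.5
  if (method == "nearest") {
    j <- pmin(pmax(round(fx), 0), nc - 1) + 1
    i <- pmin(pmax(round(fy), 0), nr - 1) + 1
    return(el[cbind(i, j)])
  }
  j0 <- pmin(pmax(floor(fx), 0), nc - 1)
  i0 <- pmin(pmax(floor(fy), 0), nr - 1)
  j1 <- pmin(j0 + 1, nc - 1)
  i1 <- pmin(i0 + 1, nr - 1)
  tx <- pmin(pmax(fx - j0, 0), 1)
  ty <- pmin(pmax(fy - i0, 0), 1)
  z00 <- el[cbind(i0 + 1, j0 + 1)]
  z01 <- el[cbind(i0 + 1, j1 + 1)]
  z10 <- el[cbind(i1 + 1, j0 + 1)]
  z11 <- el[cbind(i1 + 1, j1 + 1)]
  (1 - ty) * ((1 - tx) * z00 + tx * z01) + ty * ((1 - tx) * z10 + tx * z11)
}

#' Read and write rasters as Esri ASCII grid
#'
#' Plain-text single-band raster interchange (`.asc`): a six-line header
#' (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed by
#' rows of values from the north down.  Used for both DEMs and canopy
#' height models.
#'
#' @param dem A [dem_raster()] (for writing).
#' @param path File path.
#' @return `read_ascii_grid()` returns a `dem_raster`;
#'   `write_ascii_grid()` returns `path` invisibly.
#' @export
write_ascii_grid <- function(dem, path) {
  stopifnot(inherits(dem, "dem_raster"))
  el <- dem$elevation
  el[is.na(el)] <- dem$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(el)),
    sprintf("nrows %d", nrow(el)),
    sprintf("xllcorner %.10g", dem$origin[1]),
    sprintf("yllcorner %.10g", dem$origin[2]),
    sprintf("cellsize %.10g", dem$resolution),
    sprintf("NODATA_value %.10g", dem$nodata)
  ), con)
  # ASCII grid rows run north -> south; our matrix rows run south -> north.
  for (i in rev(seq_len(nrow(el)))) {
    writeLines(paste(format(el[i, ], trim = TRUE, digits = 10),
                     collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- hdr$nrows
  nc <- hdr$ncols
  if (length(vals) != nr * nc) {
    abort(sprintf("ASCII grid body has %d values, expected %d.",
                  length(vals), nr * nc))
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m <- m[rev(seq_len(nr)), , drop = FALSE] # back to south -> north rows
  dem_raster(
    m,
    origin = c(hdr$xllcorner, hdr$yllcorner),
    resolution = hdr$cellsize,
    nodata = hdr$nodata_value %||% -9999
  )
}
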