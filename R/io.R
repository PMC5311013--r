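#' Read a point cloud from disk
#'
#' Supports two dialects: `"xyz"`, a plain CSV with header `x,y,z,class`
#' ('.' decimal, UTF-8; `class` optional and defaulting to 1), and
#' `"las"`, the binary LAS exchange format (version 1.0-1.2, point record
#' format 0; coordinates and classification are read, other attributes
#' ignored).  All coordinates are assumed to share one planar metric CRS.
#'
#' @param path File path.
#' @param format `"las"` or `"xyz"`; default guesses from the extension.
#' @return A tibble with columns `x`, `y`, `z` (m) and `class` (integer
#'   ASPRS-style classification; 2 = ground, 5 = high vegetation).  An
#'   empty file yields an empty cloud with a warning.
#' @seealso [write_point_cloud()]
#' @export
read_point_cloud <- function(path, format = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (is.null(format)) {
    format <- if (grepl("\\.las$", path, ignore.case = TRUE)) "las" else "xyz"
  }
  switch(format,
    xyz = read_xyz_csv(path),
    las = read_las(path),
    abort(sprintf("Unknown point-cloud format '%s' (use 'las' or 'xyz').",
                  format))
  )
}

#' Write a point cloud to disk
#'
#' @param cloud Tibble with columns `x`, `y`, `z` (or `h`, treated as z)
#'   and optionally `class`.
#' @param path Output path.
#' @param format `"las"` or `"xyz"` (default from extension).
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(cloud, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.las$", path, ignore.case = TRUE)) "las" else "xyz"
  }
  cloud <- normalize_cloud_columns(cloud)
  switch(format,
    xyz = {
      utils::write.csv(
        data.frame(x = cloud$x, y = cloud$y, z = cloud$z,
                   class = cloud$class),
        path, row.names = FALSE, quote = FALSE
      )
    },
    las = write_las(cloud, path),
    abort(sprintf("Unknown point-cloud format '%s'.", format))
  )
  invisible(path)
}

normalize_cloud_columns <- function(cloud) {
  if (!is.data.frame(cloud)) abort("`cloud` must be a data frame.")
  if (!"z" %in% names(cloud) && "h" %in% names(cloud)) {
    cloud$z <- cloud$h
  }
  missing <- setdiff(c("x", "y", "z"), names(cloud))
  if (length(missing)) {
    abort(paste0("Cloud is missing columns: ", paste(missing, collapse = ", ")))
  }
  if (!"class" %in% names(cloud)) cloud$class <- 1L
  cloud
}

read_xyz_csv <- function(path) {
  if (file.size(path) == 0) {
    warn(sprintf("Empty point-cloud file: %s", path))
    return(tibble(x = numeric(), y = numeric(), z = numeric(),
                  class = integer()))
  }
  df <- tryCatch(
    utils::read.csv(path, header = TRUE, colClasses = NA),
    error = function(e) abort(sprintf("Cannot parse '%s': %s",
                                      path, conditionMessage(e)))
  )
  names(df) <- tolower(names(df))
  missing <- setdiff(c("x", "y", "z"), names(df))
  if (length(missing)) {
    abort(paste0("CSV '", path, "' lacks required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  for (col in c("x", "y", "z")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad)) {
      abort(sprintf("Malformed numeric value in '%s', column %s, record %d.",
                    path, col, bad[1]))
    }
    if (anyNA(v)) {
      abort(sprintf("Missing coordinate in '%s', column %s, record %d.",
                    path, col, which(is.na(v))[1]))
    }
    df[[col]] <- v
  }
  cls <- if ("class" %in% names(df)) as.integer(df$class) else 1L
  tibble(x = df$x, y = df$y, z = df$z,
         class = rep_len(cls, nrow(df)))
}

# --- minimal LAS 1.2 (point data record format 0) -------------------------
# 227-byte public header block; 20-byte point records holding scaled int32
# coordinates, return byte, classification.  Enough for round-tripping the
# simulator's clouds; multi-return structure is not modelled.

LAS_HEADER_SIZE <- 227L
LAS_RECORD_LENGTH <- 20L

write_las <- function(cloud, path, scale = 0.001) {
  n <- nrow(cloud)
  off <- if (n) c(min(cloud$x), min(cloud$y), min(cloud$z)) else c(0, 0, 0)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("LASF", con, nchars = 4, eos = NULL)
  writeBin(0L, con, size = 2)                         # file source id
  writeBin(0L, con, size = 2)                         # global encoding
  writeBin(raw(16), con)                              # project GUID
  writeBin(c(1L, 2L), con, size = 1)                  # version 1.2
  writeChar(formatC("lidarbiomass", width = 32, flag = "-"), con,
            nchars = 32, eos = NULL)                  # system identifier
  writeChar(formatC("lidarbiomass R", width = 32, flag = "-"), con,
            nchars = 32, eos = NULL)                  # generating software
  writeBin(c(1L, 2026L), con, size = 2)               # day / year
  writeBin(LAS_HEADER_SIZE, con, size = 2)
  writeBin(LAS_HEADER_SIZE, con, size = 4)            # offset to point data
  writeBin(0L, con, size = 4)                         # number of VLRs
  writeBin(0L, con, size = 1)                         # point data format 0
  writeBin(LAS_RECORD_LENGTH, con, size = 2)
  writeBin(n, con, size = 4)
  writeBin(c(n, 0L, 0L, 0L, 0L), con, size = 4)       # points by return
  writeBin(rep(scale, 3), con, size = 8)              # x/y/z scale
  writeBin(off, con, size = 8)                        # x/y/z offset
  rng <- function(v) if (n) range(v) else c(0, 0)
  writeBin(c(rng(cloud$x)[2], rng(cloud$x)[1],
             rng(cloud$y)[2], rng(cloud$y)[1],
             rng(cloud$z)[2], rng(cloud$z)[1]), con, size = 8)
  if (n) {
    xi <- as.integer(round((cloud$x - off[1]) / scale))
    yi <- as.integer(round((cloud$y - off[2]) / scale))
    zi <- as.integer(round((cloud$z - off[3]) / scale))
    # return number 1 of 1: bits 0-2 = 1, bits 3-5 = 1
    retbyte <- as.integer(1L + bitwShiftL(1L, 3))
    cls <- as.integer(cloud$class)
    # assemble records columnwise as a raw matrix for speed
    xyz <- writeBin(as.vector(rbind(xi, yi, zi)), raw(), size = 4)
    xyzm <- matrix(xyz, nrow = 12)
    intens <- writeBin(integer(n), raw(), size = 2)
    intm <- matrix(intens, nrow = 2)
    flags <- as.raw(rep(retbyte, n))
    clsr <- as.raw(cls)
    tailbytes <- matrix(as.raw(0), nrow = 4, ncol = n) # angle,user,psid(2)
    recm <- rbind(xyzm, intm, matrix(flags, nrow = 1),
                  matrix(clsr, nrow = 1), tailbytes)
    writeBin(as.vector(recm), con)
  }
  invisible(path)
}

read_las <- function(path) {
  sz <- file.size(path)
  if (sz == 0) {
    warn(sprintf("Empty point-cloud file: %s", path))
    return(tibble(x = numeric(), y = numeric(), z = numeric(),
                  class = integer()))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  sig <- readChar(con, 4, useBytes = TRUE)
  if (!identical(sig, "LASF")) abort(sprintf("'%s' is not a LAS file.", path))
  seek(con, 24)
  ver <- readBin(con, "integer", n = 2, size = 1)
  if (ver[1] != 1L) {
    abort(sprintf("Unsupported LAS version %d.%d.", ver[1], ver[2]))
  }
  seek(con, 94)
  readBin(con, "integer", n = 1, size = 2)            # header size
  offset_to_points <- readBin(con, "integer", n = 1, size = 4)
  n_vlr <- readBin(con, "integer", n = 1, size = 4)
  fmt <- readBin(con, "integer", n = 1, size = 1)
  reclen <- readBin(con, "integer", n = 1, size = 2)
  npts <- readBin(con, "integer", n = 1, size = 4)
  readBin(con, "integer", n = 5, size = 4)
  scl <- readBin(con, "numeric", n = 3, size = 8)
  off <- readBin(con, "numeric", n = 3, size = 8)
  if (fmt > 3L) abort(sprintf("Unsupported LAS point format %d.", fmt))
  seek(con, offset_to_points)
  body <- readBin(con, "raw", n = npts * reclen)
  recm <- matrix(body, nrow = reclen)
  ints <- readBin(as.vector(recm[1:12, , drop = FALSE]), "integer",
                  n = 3L * npts, size = 4)
  xi <- ints[seq(1, length(ints), by = 3)]
  yi <- ints[seq(2, length(ints), by = 3)]
  zi <- ints[seq(3, length(ints), by = 3)]
  cls <- as.integer(recm[16, ])
  tibble(
    x = xi * scl[1] + off[1],
    y = yi * scl[2] + off[2],
    z = zi * scl[3] + off[3],
    class = cls
  )
}
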