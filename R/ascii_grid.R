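#' Read a single-band ESRI ASCII grid
#'
#' Parses the plain-text `.asc` raster format: a six-line header
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by `nrows` whitespace-separated rows of
#' values, first row = northernmost (origin upper-left).
#'
#' @param path Path to an `.asc` file.
#' @return A numeric matrix (rows x cols, row 1 = top) with cells equal
#'   to the declared nodata value set to `NA`, and attributes
#'   `transform` (list with `xllcorner`, `yllcorner`, `cellsize`) and
#'   `nodata_value`.
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7L) stop("not an ASCII grid (too short): ", path)
  hdr <- list()
  for (k in 1:6) {
    parts <- strsplit(trimws(lines[k]), "\\s+")[[1]]
    if (length(parts) != 2L) stop("malformed header line ", k, " in ", path)
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(need %in% names(hdr))) {
    stop("missing header fields in ", path, ": ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  }
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  body <- paste(lines[-(1:6)], collapse = " ")
  vals <- as.numeric(strsplit(trimws(body), "\\s+")[[1]])
  if (length(vals) != nr * nc) {
    stop("ASCII grid ", path, ": expected ", nr * nc, " values, found ",
         length(vals))
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  attr(m, "transform") <- list(xllcorner = hdr$xllcorner,
                               yllcorner = hdr$yllcorner,
                               cellsize = hdr$cellsize)
  attr(m, "nodata_value") <- hdr$nodata_value
  m
}

#' Write a single-band ESRI ASCII grid
#'
#' @param x Numeric matrix, row 1 = northernmost row. `NA` cells are
#'   written as `nodata_value`.
#' @param path Output path.
#' @param transform List with `xllcorner`, `yllcorner`, `cellsize`.
#' @param nodata_value Sentinel written for `NA` cells (default -9999).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(x, path,
                             transform = list(xllcorner = 0, yllcorner = 0,
                                              cellsize = 1),
                             nodata_value = -9999) {
  stopifnot(is.matrix(x))
  if (any(is.finite(x) & x == nodata_value)) {
    stop("data contain the nodata sentinel ", nodata_value)
  }
  xx <- x
  xx[is.na(xx)] <- nodata_value
  hdr <- c(
    paste("ncols", ncol(x)),
    paste("nrows", nrow(x)),
    paste("xllcorner", format(transform$xllcorner, scientific = FALSE)),
    paste("yllcorner", format(transform$yllcorner, scientific = FALSE)),
    paste("cellsize", format(transform$cellsize, scientific = FALSE)),
    paste("NODATA_value", nodata_value)
  )
  rows <- apply(xx, 1L, function(r) paste(format(r, digits = 17, trim = TRUE,
                                                 scientific = TRUE),
                                          collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
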