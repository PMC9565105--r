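#' Annual raster time-series cube
#'
#' The pixel-level container used throughout the package: a 3-D array of
#' one variable (NDVI, air temperature in degrees C, or precipitation in
#' mm) indexed `[year, row, col]`, with the grid geometry and a shared
#' nodata mask. All per-pixel statistics assume gap-free series, so a
#' pixel that is nodata in any year is masked in every year.
#'
#' @param values 3-D numeric array, dimension `(n_years, nrow, ncol)`.
#' @param years Integer vector of years; must be strictly increasing
#'   consecutive integers matching `dim(values)[1]`.
#' @param transform Grid geometry: list with `xllcorner`, `yllcorner`,
#'   `cellsize` (the ASCII-grid affine convention; origin upper-left,
#'   row-major).
#' @param nodata_mask Logical matrix `(nrow, ncol)`; `TRUE` marks an
#'   excluded pixel. Defaults to pixels with any non-finite value.
#' @return An object of class `annual_cube`.
#' @export
annual_cube <- function(values, years,
                        transform = list(xllcorner = 0, yllcorner = 0,
                                         cellsize = 1),
                        nodata_mask = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("values must be a 3-D array (year x row x col)")
  }
  years <- as.integer(years)
  if (length(years) != dim(values)[1]) {
    stop("length(years) [", length(years), "] != first dimension of values [",
         dim(values)[1], "]")
  }
  if (length(years) > 1 && any(diff(years) != 1L)) {
    stop("years must be strictly increasing consecutive integers")
  }
  nr <- dim(values)[2]; nc <- dim(values)[3]
  any_na <- apply(values, c(2, 3), function(v) any(!is.finite(v)))
  if (is.null(nodata_mask)) {
    nodata_mask <- any_na
  } else {
    stopifnot(is.logical(nodata_mask), all(dim(nodata_mask) == c(nr, nc)))
    nodata_mask <- nodata_mask | any_na
  }
  # keep masked pixels NA across all years (gap-free-or-absent rule)
  if (any(nodata_mask)) {
    idx <- which(nodata_mask)
    for (t in seq_along(years)) {
      layer <- values[t, , ]
      layer[idx] <- NA_real_
      values[t, , ] <- layer
    }
  }
  structure(list(values = values, years = years, transform = transform,
                 nodata_mask = nodata_mask),
            class = "annual_cube")
}

#' @export
print.annual_cube <- function(x, ...) {
  d <- dim(x$values)
  cat("annual_cube:", d[1], "years (", x$years[1], "-", x$years[d[1]],
      "), grid ", d[2], "x", d[3], ", ", sum(x$nodata_mask),
      " nodata pixel(s)\n", sep = "")
  invisible(x)
}

#' @export
dim.annual_cube <- function(x) dim(x$values)

#' Write an annual cube as one ASCII grid per year
#'
#' @param cube An [annual_cube()].
#' @param dir Output directory (created if absent).
#' @param prefix File-name prefix; files are `<prefix>_<year>.asc`.
#' @return Character vector of paths, invisibly.
#' @export
write_annual_cube <- function(cube, dir, prefix = "layer") {
  stopifnot(inherits(cube, "annual_cube"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, sprintf("%s_%d.asc", prefix, cube$years))
  for (t in seq_along(cube$years)) {
    write_ascii_grid(cube$values[t, , ], paths[t], transform = cube$transform)
  }
  invisible(paths)
}

#' Read an annual cube from per-year raster files
#'
#' All rasters must share shape and geometry. A pixel that is nodata in
#' any year is masked in the returned cube for every year.
#'
#' @param paths Ordered character vector of single-band `.asc` files.
#' @param years Integer vector, one year per path.
#' @return An [annual_cube()].
#' @export
read_annual_cube <- function(paths, years) {
  if (length(paths) != length(years)) {
    stop("paths (", length(paths), ") and years (", length(years),
         ") differ in length")
  }
  layers <- vector("list", length(paths))
  ref_tr <- NULL; ref_dim <- NULL
  for (k in seq_along(paths)) {
    m <- read_ascii_grid(paths[k])
    tr <- attr(m, "transform")
    if (k == 1L) {
      ref_tr <- tr; ref_dim <- dim(m)
    } else {
      if (!identical(dim(m), ref_dim)) {
        stop("grid shape of ", paths[k], " (", nrow(m), "x", ncol(m),
             ") does not match ", paths[1], " (", ref_dim[1], "x",
             ref_dim[2], ")")
      }
      if (!isTRUE(all.equal(unlist(ref_tr), unlist(tr)))) {
        stop("grid geometry of ", paths[k], " does not match ", paths[1])
      }
    }
    layers[[k]] <- m
  }
  values <- array(NA_real_, c(length(paths), ref_dim[1], ref_dim[2]))
  for (k in seq_along(layers)) values[k, , ] <- layers[[k]]
  annual_cube(values, years, transform = ref_tr)
}

#' Composite sub-annual NDVI layers into growing-season annual means
#'
#' Averages, for each calendar year, the layers whose acquisition date
#' falls in the April 1 - October 31 growing-season window (inclusive);
#' layers outside the window are ignored. The composite is the unweighted
#' arithmetic mean, and is invariant to the ordering of input layers.
#'
#' @param layers 3-D numeric array `(n_layers, nrow, ncol)` of dated
#'   sub-annual composites (e.g. 16-day NDVI).
#' @param dates `Date` vector (or coercible), one acquisition date per layer.
#' @param months Integer window of growing-season months, default `4:10`.
#' @param transform Grid geometry passed to [annual_cube()].
#' @return An [annual_cube()] of growing-season annual means. Every year
#'   spanned by `dates` must have at least one in-window layer; a gap is
#'   an error because downstream statistics need gap-free series.
#' @export
composite_growing_season <- function(layers, dates, months = 4:10,
                                     transform = list(xllcorner = 0,
                                                      yllcorner = 0,
                                                      cellsize = 1)) {
  if (!is.array(layers) || length(dim(layers)) != 3L) {
    stop("layers must be a 3-D array (layer x row x col)")
  }
  dates <- as.Date(dates)
  if (length(dates) != dim(layers)[1]) stop("one date per layer required")
  yr <- as.integer(format(dates, "%Y"))
  mo <- as.integer(format(dates, "%m"))
  in_window <- mo %in% months
  years <- seq(min(yr), max(yr))
  nr <- dim(layers)[2]; nc <- dim(layers)[3]
  values <- array(NA_real_, c(length(years), nr, nc))
  for (k in seq_along(years)) {
    sel <- which(yr == years[k] & in_window)
    if (length(sel) == 0L) {
      stop("year ", years[k], " has no layers inside the growing-season ",
           "window (months ", min(months), "-", max(months),
           "); cube must be gap-free")
    }
    sub <- layers[sel, , , drop = FALSE]
    values[k, , ] <- apply(sub, c(2, 3), mean)
  }
  annual_cube(values, years, transform = transform)
}

#' Build the valid-pixel mask from a growing-season NDVI cube
#'
#' Sparse or barren surfaces are excluded: a pixel is valid iff its
#' multi-year mean growing-season NDVI is at or above `threshold`
#' (default 0.1, boundary inclusive) and it is not nodata. Using the
#' period mean (rather than a per-year rule) keeps the retained series
#' gap-free. Set `rule = "every_year"` to require every year to clear
#' the threshold instead.
#'
#' @param ndvi_cube An [annual_cube()] of growing-season annual mean NDVI.
#' @param threshold Minimum NDVI (default 0.1).
#' @param rule `"mean"` (default) or `"every_year"`.
#' @return Logical matrix; `TRUE` = valid pixel.
#' @export
build_valid_mask <- function(ndvi_cube, threshold = 0.1,
                             rule = c("mean", "every_year")) {
  stopifnot(inherits(ndvi_cube, "annual_cube"))
  rule <- match.arg(rule)
  if (rule == "mean") {
    stat <- apply(ndvi_cube$values, c(2, 3), mean)
    ok <- stat >= threshold
  } else {
    ok <- apply(ndvi_cube$values, c(2, 3), function(v) all(v >= threshold))
  }
  ok[is.na(ok)] <- FALSE
  valid <- ok & !ndvi_cube$nodata_mask
  if (!any(valid)) warning("no valid pixels (all below NDVI threshold or nodata)")
  valid
}

#' Categorical zone mask
#'
#' @param labels Integer matrix of zone ids (e.g. ecological-restoration
#'   project areas: GRP, GTGP, NFPP, NPA, none).
#' @param legend Named character vector mapping id (as name) to zone name.
#' @return An object of class `zone_mask`.
#' @export
zone_mask <- function(labels, legend) {
  stopifnot(is.matrix(labels))
  storage.mode(labels) <- "integer"
  ids <- sort(unique(labels[!is.na(labels)]))
  if (!all(as.character(ids) %in% names(legend))) {
    stop("legend does not cover zone ids: ",
         paste(setdiff(as.character(ids), names(legend)), collapse = ", "))
  }
  structure(list(labels = labels, legend = legend), class = "zone_mask")
}

#' Zonal summary of a raster layer
#'
#' Summarises a 2-D layer within each zone of a categorical mask:
#' per-zone mean, per-zone class fractions of a categorical layer, or a
#' per-zone histogram of a numeric layer with stated bin edges
#' (left-closed bins, last bin closed on both sides).
#'
#' @param layer 2-D numeric or character/factor matrix.
#' @param zones A [zone_mask()] on the same grid.
#' @param statistic One of `"mean"`, `"class_fraction"`, `"histogram"`.
#' @param breaks Numeric bin edges, required for `"histogram"`.
#' @param valid_mask Optional logical matrix restricting the summary to
#'   valid pixels; `NA` layer cells are always dropped.
#' @return A data.frame keyed by zone. For `"class_fraction"` the
#'   fractions sum to 1 within every zone that has at least one valid
#'   pixel; zones with no valid pixels get an `NA` row.
#' @export
zonal_summary <- function(layer, zones,
                          statistic = c("mean", "class_fraction", "histogram"),
                          breaks = NULL, valid_mask = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(zones, "zone_mask"))
  if (!all(dim(zones$labels) == dim(layer))) {
    stop("layer and zone mask grids differ in shape")
  }
  keep <- !is.na(zones$labels) & !is.na(layer)
  if (!is.null(valid_mask)) keep <- keep & valid_mask
  ids <- sort(unique(zones$labels[!is.na(zones$labels)]))
  zname <- unname(zones$legend[as.character(ids)])

  if (statistic == "mean") {
    rows <- lapply(seq_along(ids), function(k) {
      v <- layer[keep & zones$labels == ids[k]]
      data.frame(zone_id = ids[k], zone = zname[k], n = length(v),
                 mean = if (length(v)) mean(v) else NA_real_)
    })
    return(do.call(rbind, rows))
  }

  if (statistic == "class_fraction") {
    classes <- sort(unique(as.vector(layer[keep])))
    rows <- lapply(seq_along(ids), function(k) {
      v <- layer[keep & zones$labels == ids[k]]
      cnt <- vapply(classes, function(cl) sum(v == cl), 0L)
      data.frame(zone_id = ids[k], zone = zname[k], class = classes,
                 count = cnt,
                 fraction = if (length(v)) cnt / length(v) else NA_real_)
    })
    return(do.call(rbind, rows))
  }

  # histogram
  if (is.null(breaks) || length(breaks) < 2L || is.unsorted(breaks)) {
    stop("histogram statistic requires increasing bin edges in 'breaks'")
  }
  nb <- length(breaks) - 1L
  rows <- lapply(seq_along(ids), function(k) {
    v <- layer[keep & zones$labels == ids[k]]
    bin <- findInterval(v, breaks, rightmost.closed = TRUE)
    bin <- bin[bin >= 1L & bin <= nb]
    cnt <- tabulate(bin, nbins = nb)
    data.frame(zone_id = ids[k], zone = zname[k],
               bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
               count = if (length(v)) cnt else NA_integer_)
  })
  do.call(rbind, rows)
}
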