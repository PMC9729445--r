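# Yearly climate rasters, 5-year window means, rates of change, and the
# between-region warming contrast.

#' Construct a georeferenced climate grid
#'
#' Values are stored as a matrix with row 1 the northernmost row (the ESRI
#' ASCII grid layout); `NA` marks nodata cells and is excluded from every
#' statistic.
#'
#' @param values numeric matrix (`nrows` x `ncols`), `NA` = nodata.
#' @param xll,yll lower-left corner of the grid (decimal degrees).
#' @param cellsize cell edge length (degrees).
#' @param nodata sentinel written to file for `NA` cells.
#' @param variable,label optional variable name and year/window label.
#' @return an object of class `climate_grid`.
#' @export
climate_grid <- function(values, xll, yll, cellsize, nodata = -9999,
                         variable = NA_character_, label = NA_character_) {
  values <- as.matrix(values)
  if (cellsize <= 0) stop("cellsize must be > 0")
  structure(list(values = values, ncols = ncol(values), nrows = nrow(values),
                 xll = xll, yll = yll, cellsize = cellsize, nodata = nodata,
                 variable = variable, label = label),
            class = "climate_grid")
}

#' @export
print.climate_grid <- function(x, ...) {
  cat(sprintf("climate_grid %s%s: %d x %d cells, cellsize %g deg, origin (%g, %g)\n",
              if (is.na(x$variable)) "" else x$variable,
              if (is.na(x$label)) "" else paste0(" [", x$label, "]"),
              x$nrows, x$ncols, x$cellsize, x$xll, x$yll))
  invisible(x)
}

.same_georef <- function(a, b) {
  isTRUE(all.equal(c(a$ncols, a$nrows, a$xll, a$yll, a$cellsize),
                   c(b$ncols, b$nrows, b$xll, b$yll, b$cellsize),
                   tolerance = 1e-9))
}

# cell-centre coordinates; row 1 is the northern edge
.cell_centres <- function(grid) {
  list(lon = grid$xll + (seq_len(grid$ncols) - 0.5) * grid$cellsize,
       lat = grid$yll + (grid$nrows - seq_len(grid$nrows) + 0.5) * grid$cellsize)
}

#' Read an ESRI ASCII grid
#'
#' @param path `.asc` file with the standard 6-line header
#'   (`ncols nrows xllcorner yllcorner cellsize NODATA_value`).
#' @return a [climate_grid()] (nodata cells as `NA`).
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2)
      stop("malformed header at line ", i, " of ", path)
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  req <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
           "nodata_value")
  if (!all(req %in% names(hdr)))
    stop("ASCII grid header missing keys: ",
         paste(setdiff(req, names(hdr)), collapse = ", "))
  body <- strsplit(trimws(paste(lines[-(1:6)], collapse = " ")), "\\s+")[[1]]
  vals <- as.numeric(body)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ASCII grid body has ", length(vals), " values, header implies ",
         hdr$ncols * hdr$nrows)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  climate_grid(m, xll = hdr$xllcorner, yll = hdr$yllcorner,
               cellsize = hdr$cellsize, nodata = hdr$nodata_value,
               variable = sub("_[0-9]+\\.asc$", "", basename(path)))
}

#' Write an ESRI ASCII grid
#'
#' @param grid a [climate_grid()].
#' @param path output `.asc` path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path) {
  stopifnot(inherits(grid, "climate_grid"))
  m <- grid$values
  m[is.na(m)] <- grid$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", grid$ncols),
               paste("nrows", grid$nrows),
               paste("xllcorner", format(grid$xll, digits = 12)),
               paste("yllcorner", format(grid$yll, digits = 12)),
               paste("cellsize", format(grid$cellsize, digits = 12)),
               paste("NODATA_value", grid$nodata)), con)
  writeLines(apply(m, 1, function(r)
    paste(format(r, digits = 12, trim = TRUE, scientific = FALSE),
          collapse = " ")), con)
  invisible(path)
}

#' Cellwise mean over a window of yearly grids
#'
#' @param stack named list of [climate_grid()]s, names = years.
#' @param years inclusive year range `c(first, last)` (the study uses 5-year
#'   windows).
#' @return a `climate_grid` of cellwise means; a cell is nodata if masked in
#'   any contributing year.
#' @export
window_mean <- function(stack, years) {
  yrs <- seq(years[1], years[2])
  missing_y <- setdiff(as.character(yrs), names(stack))
  if (length(missing_y))
    stop("missing year(s) in stack: ", paste(missing_y, collapse = ", "))
  gs <- stack[as.character(yrs)]
  for (g in gs[-1]) if (!.same_georef(gs[[1]], g))
    stop("georeferencing differs across years")
  arr <- vapply(gs, function(g) g$values, gs[[1]]$values)
  m <- apply(arr, c(1, 2), function(v) if (anyNA(v)) NA_real_ else mean(v))
  dimnames(m) <- NULL
  out <- gs[[1]]
  out$values <- m
  out$label <- paste0(years[1], "-", years[2])
  out
}

#' Per-year rate of change between two window means
#'
#' `rate = (end - start) / interval_years`, cellwise; defined only where both
#' windows are defined.
#'
#' @param mean_start,mean_end [climate_grid()] window means.
#' @param interval_years elapsed years between window end years (> 0); the
#'   study's convention is end-window final year minus start-window final year
#'   (e.g. 2016 - 1980 = 36).
#' @return a `climate_grid` of rates (class also `rate_grid`) in variable
#'   units per year.
#' @export
rate_of_change <- function(mean_start, mean_end, interval_years) {
  stopifnot(inherits(mean_start, "climate_grid"),
            inherits(mean_end, "climate_grid"))
  if (!.same_georef(mean_start, mean_end))
    stop("window means have mismatched georeferencing")
  if (interval_years <= 0) stop("interval_years must be > 0")
  out <- mean_start
  out$values <- (mean_end$values - mean_start$values) / interval_years
  out$label <- paste0(mean_start$label, " to ", mean_end$label, " (",
                      interval_years, " yr)")
  class(out) <- c("rate_grid", "climate_grid")
  out
}

#' Mask cells within a buffer of sample sites
#'
#' @param grid a [climate_grid()].
#' @param sites data frame with `lon`, `lat` (one row per site).
#' @param radius_deg buffer radius in degrees (Euclidean in degrees,
#'   default 0.5, roughly 55 km).
#' @return logical matrix, `TRUE` for cells whose centre lies within
#'   `radius_deg` of any site.
#' @export
buffer_cells <- function(grid, sites, radius_deg = 0.5) {
  stopifnot(inherits(grid, "climate_grid"))
  if (nrow(sites) == 0) stop("`sites` is empty")
  cc <- .cell_centres(grid)
  mask <- matrix(FALSE, grid$nrows, grid$ncols)
  for (k in seq_len(nrow(sites))) {
    d2 <- outer((cc$lat - sites$lat[k])^2, (cc$lon - sites$lon[k])^2, `+`)
    mask <- mask | (d2 <= radius_deg^2 + 1e-12)
  }
  mask
}

#' Regional contrast of change rates
#'
#' Percent difference of the mean rate in region A relative to region B:
#' `100 * (mean_A - mean_B) / mean_B`. A value of 50 reads "region A has
#' warmed 50% more than region B".
#'
#' @param rateA,rateB rate grids ([rate_of_change()]).
#' @param maskA,maskB logical cell masks (e.g. [buffer_cells()]).
#' @return list with `contrast_pct`, `mean_A`, `mean_B`.
#' @export
regional_contrast <- function(rateA, maskA, rateB, maskB) {
  mA <- mean(rateA$values[maskA], na.rm = TRUE)
  mB <- mean(rateB$values[maskB], na.rm = TRUE)
  if (!is.finite(mA) || !is.finite(mB))
    stop("a regional mean is undefined (empty mask or all nodata)")
  if (mB == 0) stop("reference region mean rate is zero; contrast undefined")
  list(contrast_pct = 100 * (mA - mB) / mB, mean_A = mA, mean_B = mB)
}

#' Histogram of change rates within a mask
#'
#' @param rate a rate grid.
#' @param mask logical cell mask.
#' @param bin_width histogram bin width (variable units per year).
#' @return data frame with half-open bins `[lo, hi)` and counts.
#' @export
rate_histogram <- function(rate, mask, bin_width) {
  v <- rate$values[mask]
  v <- v[!is.na(v)]
  if (!length(v)) stop("no unmasked, defined cells")
  lo <- floor(min(v) / bin_width) * bin_width
  breaks <- seq(lo, max(v) + bin_width, by = bin_width)
  idx <- findInterval(v, breaks, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(breaks) - 1)
  data.frame(lo = breaks[-length(breaks)], hi = breaks[-1], count = counts)
}
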