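#' Preset month windows and variable sets
#'
#' `reproductiveWindow()` is May-July (months 5-7), the egg-laying /
#' gestation period of *Zootoca vivipara*; `annualWindow()` is the full
#' year. `reproductiveVars()` and `annualVars()` are the default
#' non-redundant variable sets for the two analyses: seven variables for
#' the reproductive period (BIO2, BIO3, BIO4, BIO6, BIO15, minTmax,
#' meanTmin) and six for the annual one (BIO1 replacing the two
#' window-specific extremes).
#'
#' @return integer month vector / character variable vector.
#' @export
reproductiveWindow <- function() 5:7

#' @rdname reproductiveWindow
#' @export
annualWindow <- function() 1:12

#' @rdname reproductiveWindow
#' @export
reproductiveVars <- function() c("BIO2", "BIO3", "BIO4", "BIO6", "BIO15", "minTmax", "meanTmin")

#' @rdname reproductiveWindow
#' @export
annualVars <- function() c("BIO1", "BIO2", "BIO3", "BIO4", "BIO6", "BIO15")

#' Derive window-specific bioclimatic variables
#'
#' Computes per-pixel bioclimatic variables from monthly `tmin`, `tmax`
#' and `prec` layers over a window of calendar months. With monthly mean
#' temperature `tavg_m = (tmin_m + tmax_m) / 2` and the window months `m`:
#'
#' * `BIO1` — mean of `tavg_m` (degC; the window mean temperature).
#' * `BIO2` — mean diurnal range, `mean(tmax_m - tmin_m)` (degC).
#' * `BIO3` — isothermality, `100 * BIO2 / (max(tmax_m) - min(tmin_m))` (%).
#' * `BIO4` — temperature seasonality, `100 * sd(tavg_m)` (sample SD).
#' * `BIO6` — minimum temperature of the coldest window month (degC).
#' * `BIO15` — precipitation seasonality,
#'   `100 * sd(prec_m) / (1 + mean(prec_m))` (CV %, ANUCLIM +1 convention).
#' * `minTmax` — minimum over window months of monthly `tmax` (degC).
#' * `meanTmin` — mean over window months of monthly `tmin` (degC).
#'
#' Standard deviations are sample SDs (denominator `n - 1`), so the window
#' must contain at least two months. `NA` (nodata) pixels propagate; pixels
#' whose window temperature range is zero get `BIO3 = NA` with a warning.
#'
#' @param stack a [MonthlyClimateStack].
#' @param window integer vector of calendar months (1-12), e.g.
#'   [reproductiveWindow()].
#' @param vars character vector of variables to keep (default: all eight).
#' @return a [BioclimSet].
#' @examples
#' stk <- generateMonthlyStack(scenarioPreset("null", gridDim = c(40, 40)), seed = 1)
#' bio <- deriveBioclim(stk, reproductiveWindow(), reproductiveVars())
#' layerNames(bio)
#' @export
deriveBioclim <- function(stack, window = annualWindow(), vars = NULL) {
  stopifnot(is(stack, "MonthlyClimateStack"))
  window <- as.integer(window)
  if (!length(window) || anyDuplicated(window) || any(window < 1L | window > 12L))
    stop("'window' must be a non-empty set of unique months in 1..12")
  k <- length(window)
  if (k < 2L)
    stop("'window' must contain at least two months (sample SD is undefined for one)")

  Tn <- stack@tmin[window]
  Tx <- stack@tmax[window]
  P <- stack@prec[window]
  tavg <- Map(function(a, b) (a + b) / 2, Tn, Tx)

  meanTavg <- Reduce(`+`, tavg) / k
  sdTavg <- sqrt(Reduce(`+`, lapply(tavg, function(m) (m - meanTavg)^2)) / (k - 1))
  bio2 <- Reduce(`+`, Map(`-`, Tx, Tn)) / k
  maxTx <- Reduce(pmax, Tx)
  minTn <- Reduce(pmin, Tn)
  rangeW <- maxTx - minTn
  bio3 <- 100 * bio2 / rangeW
  zeroRange <- !is.na(rangeW) & rangeW == 0
  if (any(zeroRange)) {
    warning(sum(zeroRange), " pixel(s) with zero window temperature range; BIO3 set to nodata")
    bio3[zeroRange] <- NA_real_
  }
  meanP <- Reduce(`+`, P) / k
  sdP <- sqrt(Reduce(`+`, lapply(P, function(m) (m - meanP)^2)) / (k - 1))

  layers <- list(
    BIO1 = meanTavg,
    BIO2 = bio2,
    BIO3 = bio3,
    BIO4 = 100 * sdTavg,
    BIO6 = minTn,
    BIO15 = 100 * sdP / (1 + meanP),
    minTmax = Reduce(pmin, Tx),
    meanTmin = Reduce(`+`, Tn) / k
  )
  if (!is.null(vars)) {
    unknown <- setdiff(vars, names(layers))
    if (length(unknown))
      stop("unknown bioclim variable(s): ", paste(unknown, collapse = ", "))
    layers <- layers[vars]
  }
  new("BioclimSet", grid = stack@grid, window = window, layers = layers,
      convention = list(sd = "sample (n-1)", bio15 = "100*sd/(1+mean)"))
}

#' Extract bioclim values at point locations
#'
#' Looks up each derived layer at the pixel containing each lon/lat point
#' (pixel-is-area, floor convention). Points outside the raster extent are
#' an error naming the offending points; rows hitting nodata pixels are
#' kept but flagged in the `"nodata"` attribute so callers can drop them
#' with a log message.
#'
#' @param bioclim a [BioclimSet].
#' @param points a 2-column matrix/data.frame of lon, lat.
#' @return numeric matrix, one row per point, columns in layer order, with
#'   attribute `"nodata"` (logical per row).
#' @export
extractAtPoints <- function(bioclim, points) {
  stopifnot(is(bioclim, "BioclimSet"))
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  grid <- bioclim@grid
  out <- !insideExtent(grid, pts[, 1], pts[, 2])
  if (any(out))
    stop("point(s) outside raster extent: ",
         paste(sprintf("(%g, %g)", pts[out, 1], pts[out, 2]), collapse = ", "))
  rc <- rowcolFromXY(grid, pts[, 1], pts[, 2])
  vals <- vapply(bioclim@layers, function(m) m[rc], numeric(nrow(pts)))
  if (nrow(pts) == 1L) vals <- matrix(vals, nrow = 1, dimnames = list(NULL, names(bioclim@layers)))
  attr(vals, "nodata") <- apply(is.na(vals), 1L, any)
  vals
}

#' Read and write rasters as ESRI ASCII grids
#'
#' Plain-text raster interchange: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by the
#' values row by row from the top. `NA` values are written as the grid's
#' nodata sentinel and read back as `NA`.
#'
#' @param x matrix of values (rows top to bottom).
#' @param grid the [GeoGrid] describing `x`.
#' @param file path to the `.asc` file.
#' @return `readAsciiGrid` returns `list(values = matrix, grid = GeoGrid)`.
#' @export
writeAsciiGrid <- function(x, grid, file) {
  stopifnot(identical(dim(x), dim(grid)))
  header <- c(
    sprintf("ncols %d", grid@ncol),
    sprintf("nrows %d", grid@nrow),
    sprintf("xllcorner %.10g", grid@xmin),
    sprintf("yllcorner %.10g", grid@ymax - grid@nrow * grid@res),
    sprintf("cellsize %.10g", grid@res),
    sprintf("NODATA_value %.10g", grid@nodata)
  )
  x[is.na(x)] <- grid@nodata
  body <- apply(x, 1L, function(r) paste(format(r, trim = TRUE, digits = 10), collapse = " "))
  writeLines(c(header, body), file)
  invisible(file)
}

#' @rdname writeAsciiGrid
#' @export
readAsciiGrid <- function(file) {
  lines <- readLines(file)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[`, character(1), 1L))
  vals <- as.numeric(vapply(hdr, `[`, character(1), 2L))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(need %in% keys)) stop("malformed ASCII grid header in ", file)
  nr <- as.integer(vals["nrows"]); nc <- as.integer(vals["ncols"])
  nodata <- vals["nodata_value"]
  dat <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(dat) != nr * nc) stop("expected ", nr * nc, " values in ", file)
  m <- matrix(dat, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  grid <- GeoGrid(nrow = nr, ncol = nc, xmin = vals["xllcorner"],
                  ymax = vals["yllcorner"] + nr * vals["cellsize"],
                  res = vals["cellsize"], nodata = nodata)
  list(values = m, grid = grid)
}

#' Read and write a monthly climate stack as ASCII grids
#'
#' A stack directory holds 36 files named `tmin_01.asc` .. `prec_12.asc`.
#' `scale` supports the classic integer-storage dialect in which
#' temperatures are stored as degC x 10: values are divided by `scale` on
#' read (temperature layers only).
#'
#' @param stack a [MonthlyClimateStack].
#' @param dir directory of `.asc` files.
#' @param scale temperature storage scale factor on read (default 1).
#' @return `readClimateStack` returns a [MonthlyClimateStack].
#' @export
writeClimateStack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in 1:12) {
    writeAsciiGrid(stack@tmin[[m]], stack@grid, file.path(dir, sprintf("tmin_%02d.asc", m)))
    writeAsciiGrid(stack@tmax[[m]], stack@grid, file.path(dir, sprintf("tmax_%02d.asc", m)))
    writeAsciiGrid(stack@prec[[m]], stack@grid, file.path(dir, sprintf("prec_%02d.asc", m)))
  }
  invisible(dir)
}

#' @rdname writeClimateStack
#' @export
readClimateStack <- function(dir, scale = 1) {
  rd <- function(var, m) readAsciiGrid(file.path(dir, sprintf("%s_%02d.asc", var, m)))
  first <- rd("tmin", 1)
  grid <- first$grid
  tmin <- c(list(first$values / scale), lapply(2:12, function(m) rd("tmin", m)$values / scale))
  tmax <- lapply(1:12, function(m) rd("tmax", m)$values / scale)
  prec <- lapply(1:12, function(m) rd("prec", m)$values)
  MonthlyClimateStack(grid, tmin, tmax, prec)
}

#' Read and write occurrence records
#'
#' Occurrence CSVs have the header `lon,lat,clade,parity`. Clades are
#' labels A-F; parity is a function of clade (A, B oviparous; C-F
#' viviparous) and is validated on read.
#'
#' @param file CSV path.
#' @param occurrences data.frame with columns lon, lat, clade, parity.
#' @return `readOccurrences` returns the validated data.frame.
#' @export
readOccurrences <- function(file) {
  occ <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("lon", "lat", "clade", "parity")
  if (!all(need %in% names(occ)))
    stop("occurrence CSV must have columns ", paste(need, collapse = ", "))
  validateOccurrences(occ)
}

#' @rdname readOccurrences
#' @export
writeOccurrences <- function(occurrences, file) {
  utils::write.csv(validateOccurrences(occurrences)[, c("lon", "lat", "clade", "parity")],
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname readOccurrences
#' @export
parityOfClade <- function(clade) {
  bad <- !clade %in% LETTERS[1:6]
  if (any(bad)) stop("unknown clade label(s): ", paste(unique(clade[bad]), collapse = ", "))
  ifelse(clade %in% c("A", "B"), "oviparous", "viviparous")
}

validateOccurrences <- function(occ) {
  expected <- parityOfClade(occ$clade)
  bad <- occ$parity != expected
  if (any(bad))
    stop(sum(bad), " record(s) with parity inconsistent with clade ",
         "(A,B are oviparous; C-F viviparous)")
  occ
}
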