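#' Convex-hull study extent
#'
#' The analysis extent is the convex hull of the occurrence coordinates:
#' the mask is TRUE for pixels whose centers fall inside or on the hull
#' polygon. Needs at least three non-collinear points.
#'
#' @param lon,lat occurrence coordinates (degrees).
#' @param grid a [GeoGrid].
#' @return logical matrix with the grid's dimensions.
#' @export
convexHullMask <- function(lon, lat, grid) {
  pts <- unique(cbind(lon, lat))
  if (nrow(pts) < 3L) stop("need at least 3 distinct points for a convex hull")
  h <- grDevices::chull(pts[, 1], pts[, 2])
  if (length(h) < 3L) stop("occurrence points are collinear; convex hull is degenerate")
  hx <- pts[h, 1]; hy <- pts[h, 2]
  # signed polygon area fixes the orientation of the edge tests
  n <- length(hx)
  nxt <- c(2:n, 1)
  orient <- sign(sum(hx * hy[nxt] - hx[nxt] * hy))
  X <- matrix(cellCentersX(grid), nrow = grid@nrow, ncol = grid@ncol, byrow = TRUE)
  Y <- matrix(cellCentersY(grid), nrow = grid@nrow, ncol = grid@ncol)
  tol <- 1e-9 * max(diff(range(hx)), diff(range(hy)))
  inside <- matrix(TRUE, grid@nrow, grid@ncol)
  for (i in seq_len(n)) {
    j <- nxt[i]
    cross <- (hx[j] - hx[i]) * (Y - hy[i]) - (hy[j] - hy[i]) * (X - hx[i])
    inside <- inside & (orient * cross >= -tol)
  }
  inside
}

#' Sample background pixels inside the study extent
#'
#' Uniform sampling without replacement of `n` pixels from the TRUE cells
#' of a mask (the PCA-env environmental background; the study used 20,000
#' pixels inside the occurrence convex hull).
#'
#' @param mask logical matrix (e.g. from [convexHullMask]).
#' @param grid the matching [GeoGrid].
#' @param n number of pixels to draw.
#' @param seed RNG seed (draw is reproducible for a fixed seed).
#' @return data.frame with columns `row`, `col`, `lon`, `lat`.
#' @export
sampleBackground <- function(mask, grid, n, seed = 1L) {
  idx <- which(mask)
  if (n > length(idx))
    stop("requested ", n, " background pixels but only ", length(idx), " are available")
  sel <- if (n == length(idx)) idx else withSeed(seed, sample(idx, n))
  rc <- arrayInd(sel, dim(mask))
  data.frame(row = rc[, 1], col = rc[, 2],
             lon = cellCentersX(grid)[rc[, 2]],
             lat = cellCentersY(grid)[rc[, 1]])
}

#' Fit the environmental PCA (PCA-env)
#'
#' Correlation-matrix PCA (center + unit-variance scale) on the pooled
#' calibration set of background and occurrence climate rows. Axis signs
#' are fixed so each axis's largest-magnitude loading is positive.
#'
#' @param x numeric matrix of calibration rows (background + occurrences),
#'   columns named by variable.
#' @return an [OrdinationModel].
#' @export
fitPcaEnv <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("need at least 2 variables")
  if (anyNA(x)) stop("calibration rows must not contain nodata values")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance variable(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  rot <- p$rotation
  for (j in seq_len(ncol(rot))) {
    if (rot[which.max(abs(rot[, j])), j] < 0) rot[, j] <- -rot[, j]
  }
  new("OrdinationModel", center = p$center, scale = p$scale,
      rotation = rot, sdev = p$sdev, varnames = colnames(x))
}

#' @describeIn fitPcaEnv fraction of variance explained per axis
#'   (sums to 1).
#' @param model an [OrdinationModel].
#' @export
explainedVariance <- function(model) {
  v <- model@sdev^2
  v / sum(v)
}

#' Project climate rows into the ordination space
#'
#' Standardizes rows with the model's center/scale and applies the
#' loadings. Columns must match the model's variables.
#'
#' @param model an [OrdinationModel].
#' @param rows numeric matrix with the model's variables as columns.
#' @param naxes number of axes to return (default all).
#' @return score matrix (rows x axes).
#' @export
projectScores <- function(model, rows, naxes = ncol(model@rotation)) {
  rows <- as.matrix(rows)
  if (ncol(rows) != length(model@varnames))
    stop("variable-count mismatch: model has ", length(model@varnames),
         ", rows have ", ncol(rows))
  if (!is.null(colnames(rows)) && !identical(colnames(rows), model@varnames))
    stop("variable order mismatch: expected ", paste(model@varnames, collapse = ", "))
  z <- sweep(sweep(rows, 2L, model@center), 2L, model@scale, `/`)
  (z %*% model@rotation)[, seq_len(naxes), drop = FALSE]
}

# Gaussian product-kernel density evaluated on a grid of cell centers.
# Returns f[i, j] = density at (xgrid[i], ygrid[j]); h are kernel SDs.
kernelDensity2d <- function(x, y, xgrid, ygrid, h) {
  n <- length(x)
  kx <- stats::dnorm(outer(xgrid, x, "-") / h[1]) / h[1]
  ky <- stats::dnorm(outer(ygrid, y, "-") / h[2]) / h[2]
  (kx %*% t(ky)) / n
}

# Silverman rule-of-thumb bandwidth with a fallback for degenerate inputs.
silvermanBandwidth <- function(v, extent) {
  if (length(v) >= 2L && stats::sd(v) > 0) stats::bw.nrd0(v) else extent / 20
}

#' Lay the ordination-space grid and background availability
#'
#' Builds the shared grid over the first two PCA axes: extents are the
#' min/max of the pooled background scores expanded by `margin` on each
#' side (so kernels are not clipped), with `gridSize` cell centers per
#' axis. The background kernel density `e` (environmental availability)
#' is evaluated once and shared by all clade surfaces.
#'
#' @param bgScores background score matrix (first two columns used).
#' @param gridSize cells per axis (default 100).
#' @param margin fractional extent expansion (default 0.05).
#' @param bwMult scalar multiplier on the Silverman bandwidths.
#' @return a [NicheSpace].
#' @export
nicheSpace <- function(bgScores, gridSize = 100L, margin = 0.05, bwMult = 1) {
  s <- as.matrix(bgScores)[, 1:2, drop = FALSE]
  rx <- range(s[, 1]); ry <- range(s[, 2])
  px <- margin * diff(rx); py <- margin * diff(ry)
  xgrid <- seq(rx[1] - px, rx[2] + px, length.out = gridSize)
  ygrid <- seq(ry[1] - py, ry[2] + py, length.out = gridSize)
  h <- bwMult * c(silvermanBandwidth(s[, 1], diff(range(xgrid))),
                  silvermanBandwidth(s[, 2], diff(range(ygrid))))
  e <- kernelDensity2d(s[, 1], s[, 2], xgrid, ygrid, h)
  new("NicheSpace", xgrid = xgrid, ygrid = ygrid, e = e, bw = h)
}

#' Kernel occupancy surface of a clade
#'
#' Gaussian product-kernel density of the clade's occurrence scores on the
#' shared grid, turned into an occupancy surface `z` normalized to sum 1.
#' Mode `"corrected"` (the PCA-env default) divides the occurrence density
#' `o` by the background availability `e` where `e` exceeds
#' `eps = 1e-12 * max(e)` (cells at or below `eps` get `z = 0`), so
#' occupancy reflects preference rather than availability; mode `"raw"`
#' normalizes `o` directly.
#'
#' @param space a [NicheSpace].
#' @param scores occurrence score matrix (first two columns used).
#' @param clade clade label to attach.
#' @param mode `"corrected"` (default) or `"raw"`.
#' @param bwMult scalar multiplier on the Silverman bandwidths of the
#'   occurrence scores.
#' @return a [NicheSurface].
#' @export
occupancySurface <- function(space, scores, clade = "", mode = c("corrected", "raw"),
                             bwMult = 1) {
  mode <- match.arg(mode)
  s <- as.matrix(scores)
  if (!nrow(s)) stop("empty occurrence score set")
  s <- s[, 1:2, drop = FALSE]
  h <- bwMult * c(silvermanBandwidth(s[, 1], diff(range(space@xgrid))),
                  silvermanBandwidth(s[, 2], diff(range(space@ygrid))))
  o <- kernelDensity2d(s[, 1], s[, 2], space@xgrid, space@ygrid, h)
  if (mode == "corrected") {
    eps <- 1e-12 * max(space@e)
    z <- ifelse(space@e > eps, o / space@e, 0)
  } else {
    z <- o
  }
  tot <- sum(z)
  if (tot <= 0) stop("all cells have background availability below eps; cannot normalize")
  new("NicheSurface", xgrid = space@xgrid, ygrid = space@ygrid,
      o = o, z = z / tot, clade = as.character(clade), bw = h, mode = mode)
}

#' Schoener's D niche overlap
#'
#' `D = 1 - 0.5 * sum(|z1 - z2|)` over the shared grid; 0 for disjoint
#' occupancies, 1 for identical surfaces. Symmetric in its arguments.
#'
#' @param s1,s2 [NicheSurface] objects on the same grid.
#' @return numeric D in `[0, 1]`.
#' @export
schoenerD <- function(s1, s2) {
  if (!isTRUE(all.equal(s1@xgrid, s2@xgrid)) || !isTRUE(all.equal(s1@ygrid, s2@ygrid)))
    stop("surfaces are on different grids/extents")
  d <- 1 - 0.5 * sum(abs(s1@z - s2@z))
  min(max(d, 0), 1)
}

#' Clade centroid in ordination space
#'
#' Arithmetic mean of the scores on the first two axes.
#'
#' @param scores score matrix (rows = occurrences).
#' @return named numeric `c(PC1, PC2)`.
#' @export
cladeCentroid <- function(scores) {
  s <- as.matrix(scores)
  if (!nrow(s)) stop("no scores")
  stats::setNames(colMeans(s[, 1:2, drop = FALSE]), c("PC1", "PC2"))
}

#' Pairwise Schoener's D matrix
#'
#' @param surfaces named list of [NicheSurface] objects on one grid.
#' @return symmetric numeric matrix of D values (diagonal 1).
#' @export
overlapMatrix <- function(surfaces) {
  k <- length(surfaces)
  D <- matrix(1, k, k, dimnames = list(names(surfaces), names(surfaces)))
  if (k < 2) return(D)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    D[i, j] <- D[j, i] <- schoenerD(surfaces[[i]], surfaces[[j]])
  }
  D
}
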