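#' @import methods
NULL

#' Regular geographic grid
#'
#' Describes a regular lon/lat raster grid: pixel counts, the upper-left
#' corner, the pixel size in degrees and the nodata sentinel used on disk
#' (values are held as `NA` in memory). All layers sharing a `GeoGrid` are
#' index-aligned; row 1 is the top (northernmost) row.
#'
#' @slot nrow,ncol integer pixel counts.
#' @slot xmin numeric, longitude of the left edge (degrees).
#' @slot ymax numeric, latitude of the top edge (degrees).
#' @slot res numeric, pixel size in degrees (pixel-is-area convention).
#' @slot crs character tag; geographic lon/lat is assumed throughout.
#' @slot nodata numeric sentinel written to / read from disk.
#'
#' @examples
#' g <- GeoGrid(nrow = 10L, ncol = 20L, xmin = 0, ymax = 50, res = 0.5)
#' dim(g)
#' @export
setClass("GeoGrid",
  representation(
    nrow = "integer", ncol = "integer",
    xmin = "numeric", ymax = "numeric",
    res = "numeric", crs = "character", nodata = "numeric"
  ),
  prototype(crs = "lonlat", nodata = -9999)
)

setValidity("GeoGrid", function(object) {
  msg <- character()
  if (length(object@res) != 1 || !is.finite(object@res) || object@res <= 0)
    msg <- c(msg, "'res' must be a single positive number")
  if (object@nrow < 1L || object@ncol < 1L)
    msg <- c(msg, "'nrow' and 'ncol' must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname GeoGrid-class
#' @param nrow,ncol,xmin,ymax,res,crs,nodata see slots.
#' @export
GeoGrid <- function(nrow, ncol, xmin = 0, ymax = nrow * res, res = 1,
                    crs = "lonlat", nodata = -9999) {
  new("GeoGrid", nrow = as.integer(nrow), ncol = as.integer(ncol),
      xmin = as.numeric(xmin), ymax = as.numeric(ymax),
      res = as.numeric(res), crs = crs, nodata = as.numeric(nodata))
}

#' @describeIn GeoGrid-class grid dimensions as `c(nrow, ncol)`.
#' @param x a `GeoGrid`.
#' @export
setMethod("dim", "GeoGrid", function(x) c(x@nrow, x@ncol))

setMethod("show", "GeoGrid", function(object) {
  cat(sprintf("GeoGrid: %d x %d pixels, res %g deg, x [%g, %g], y [%g, %g]\n",
              object@nrow, object@ncol, object@res,
              object@xmin, object@xmin + object@ncol * object@res,
              object@ymax - object@nrow * object@res, object@ymax))
})

#' Monthly climate raster stack
#'
#' Holds twelve monthly layers each of minimum temperature, maximum
#' temperature (degrees Celsius) and precipitation (mm), index-aligned on a
#' shared [GeoGrid]. Layers are matrices with `NA` marking nodata.
#'
#' @slot grid a [GeoGrid].
#' @slot tmin,tmax,prec lists of 12 matrices (January..December).
#' @export
setClass("MonthlyClimateStack",
  representation(grid = "GeoGrid", tmin = "list", tmax = "list", prec = "list")
)

setValidity("MonthlyClimateStack", function(object) {
  msg <- character()
  d <- dim(object@grid)
  for (nm in c("tmin", "tmax", "prec")) {
    lay <- slot(object, nm)
    if (length(lay) != 12L) msg <- c(msg, sprintf("'%s' must have 12 monthly layers", nm))
    if (!all(vapply(lay, function(m) identical(dim(m), d), logical(1))))
      msg <- c(msg, sprintf("'%s' layers must match the grid dimensions", nm))
  }
  if (!length(msg)) {
    for (m in 1:12) {
      bad <- object@tmax[[m]] < object@tmin[[m]]
      if (any(bad, na.rm = TRUE))
        msg <- c(msg, sprintf("tmax < tmin at %d pixel(s) in month %d", sum(bad, na.rm = TRUE), m))
      if (any(object@prec[[m]] < 0, na.rm = TRUE))
        msg <- c(msg, sprintf("negative precipitation in month %d", m))
    }
  }
  if (length(msg)) msg else TRUE
})

#' @rdname MonthlyClimateStack-class
#' @param grid a [GeoGrid].
#' @param tmin,tmax,prec lists of 12 matrices.
#' @export
MonthlyClimateStack <- function(grid, tmin, tmax, prec) {
  new("MonthlyClimateStack", grid = grid, tmin = tmin, tmax = tmax, prec = prec)
}

setMethod("show", "MonthlyClimateStack", function(object) {
  cat("MonthlyClimateStack with 12 months of tmin/tmax/prec on:\n")
  show(object@grid)
})

#' Derived bioclimatic variable set
#'
#' Per-pixel bioclimatic variables derived from a [MonthlyClimateStack]
#' over a month window (see [deriveBioclim]). `layers` is a named list of
#' matrices; `window` records the calendar months used; `convention`
#' records the statistical conventions (sample SD, the +1 in the
#' precipitation CV denominator).
#'
#' @slot grid a [GeoGrid].
#' @slot window integer vector of calendar months (1-12).
#' @slot layers named list of matrices.
#' @slot convention named list of convention flags.
#' @export
setClass("BioclimSet",
  representation(grid = "GeoGrid", window = "integer",
                 layers = "list", convention = "list")
)

setValidity("BioclimSet", function(object) {
  msg <- character()
  w <- object@window
  if (!length(w) || anyDuplicated(w) || any(w < 1L | w > 12L))
    msg <- c(msg, "'window' must be unique months in 1..12")
  d <- dim(object@grid)
  if (is.null(names(object@layers)) || any(names(object@layers) == ""))
    msg <- c(msg, "'layers' must be named")
  if (!all(vapply(object@layers, function(m) identical(dim(m), d), logical(1))))
    msg <- c(msg, "all layers must match the grid dimensions")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BioclimSet", function(object) {
  cat(sprintf("BioclimSet [%s] over months {%s} on:\n",
              paste(names(object@layers), collapse = ", "),
              paste(object@window, collapse = ",")))
  show(object@grid)
})

#' @describeIn BioclimSet-class names of the derived variables.
#' @param object a `BioclimSet`.
#' @export
layerNames <- function(object) names(object@layers)

#' @describeIn BioclimSet-class extract one derived layer as a matrix.
#' @param name variable name.
#' @export
getLayer <- function(object, name) {
  if (!name %in% names(object@layers))
    stop("no layer '", name, "' (available: ",
         paste(names(object@layers), collapse = ", "), ")")
  object@layers[[name]]
}

#' Environmental PCA ordination model
#'
#' Correlation-matrix PCA calibrated on background + occurrence climate
#' rows (the PCA-env calibration set). Axis signs are fixed so that the
#' largest-magnitude loading of each axis is positive.
#'
#' @slot center,scale named numeric vectors used for standardization.
#' @slot rotation loadings matrix (variables x axes).
#' @slot sdev per-axis standard deviations (sqrt of eigenvalues).
#' @slot varnames variable names in calibration order.
#' @export
setClass("OrdinationModel",
  representation(center = "numeric", scale = "numeric",
                 rotation = "matrix", sdev = "numeric", varnames = "character")
)

setMethod("show", "OrdinationModel", function(object) {
  ev <- explainedVariance(object)
  cat(sprintf("OrdinationModel on %d variables; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              length(object@varnames), 100 * ev[1], 100 * ev[2]))
})

#' Shared ordination-space grid with background availability
#'
#' The 2-D grid laid over the first two PCA axes, with extents taken from
#' the pooled background scores expanded by a margin, plus the kernel
#' density of the environmental background (availability, `e`) evaluated
#' on the cell centers. All clade surfaces in a run share one `NicheSpace`.
#'
#' @slot xgrid,ygrid cell-center coordinates along PC1 and PC2.
#' @slot e background (availability) kernel density matrix, `e[i, j]`
#'   at `(xgrid[i], ygrid[j])`.
#' @slot bw bandwidths (kernel SDs) used for `e`.
#' @export
setClass("NicheSpace",
  representation(xgrid = "numeric", ygrid = "numeric",
                 e = "matrix", bw = "numeric")
)

setMethod("show", "NicheSpace", function(object) {
  cat(sprintf("NicheSpace: %d x %d cells, PC1 [%.3g, %.3g], PC2 [%.3g, %.3g]\n",
              length(object@xgrid), length(object@ygrid),
              min(object@xgrid), max(object@xgrid),
              min(object@ygrid), max(object@ygrid)))
})

#' Kernel occupancy surface of one clade
#'
#' Normalized occupancy grid of a clade in PC1 x PC2 space: `o` is the
#' occurrence kernel density, `z` the occupancy (availability-corrected in
#' mode `"corrected"`, raw density in mode `"raw"`), normalized so that
#' `sum(z) == 1`.
#'
#' @slot xgrid,ygrid cell-center coordinates (shared across clades).
#' @slot o occurrence kernel density matrix.
#' @slot z normalized occupancy matrix (sums to 1).
#' @slot clade clade label.
#' @slot bw kernel bandwidths (SD per axis) used for `o`.
#' @slot mode `"corrected"` or `"raw"`.
#' @export
setClass("NicheSurface",
  representation(xgrid = "numeric", ygrid = "numeric",
                 o = "matrix", z = "matrix",
                 clade = "character", bw = "numeric", mode = "character")
)

setValidity("NicheSurface", function(object) {
  msg <- character()
  if (any(object@z < 0)) msg <- c(msg, "z must be non-negative")
  if (abs(sum(object@z) - 1) > 1e-9) msg <- c(msg, "z must sum to 1")
  if (!identical(dim(object@z), c(length(object@xgrid), length(object@ygrid))))
    msg <- c(msg, "z dimensions must match the grid")
  if (length(msg)) msg else TRUE
})

setMethod("show", "NicheSurface", function(object) {
  cat(sprintf("NicheSurface (clade %s, mode %s): %d x %d cells, sum(z) = %g\n",
              object@clade, object@mode,
              length(object@xgrid), length(object@ygrid), sum(object@z)))
})

#' Classification tree for parity mode
#'
#' Binary Gini classification tree with surrogate splits, grown by
#' recursive partitioning (see [growTree]). `root` is a nested node list
#' (class counts, primary split, surrogates, children); `cv` holds the
#' 10-fold cross-validation profile once [crossValidate] has run.
#'
#' @slot root nested node list.
#' @slot covariates covariate names offered to the tree.
#' @slot levels the two class labels (first = "left"/reference class).
#' @slot x training covariate matrix.
#' @slot y training class factor.
#' @slot params growth parameters (cp, minsplit, minbucket, maxSurrogate).
#' @slot cv data.frame cross-validation profile (may be empty).
#' @slot pruned logical, TRUE after [prune1SE]/[pruneAt].
#' @export
setClass("ParityTree",
  representation(root = "list", covariates = "character", levels = "character",
                 x = "matrix", y = "factor", params = "list",
                 cv = "data.frame", pruned = "logical"),
  prototype(cv = data.frame(), pruned = FALSE)
)

setMethod("show", "ParityTree", function(object) {
  cat(sprintf("ParityTree: %d leaves (%d splits), %d training rows, %s\n",
              countLeaves(object@root), countLeaves(object@root) - 1L,
              nrow(object@x), if (object@pruned) "pruned" else "unpruned"))
  cat(treeLines(object@root, object@levels), sep = "\n")
})

#' Synthetic study scenario
#'
#' Defines a synthetic world: grid size and extent, occurrences per clade
#' (defaults mirror the six-clade, 185-record study design: A 37, B 41,
#' C 19, D 26, E 47, F 15; A and B oviparous), the reproductive month
#' window, Gaussian-random-field parameters for the monthly climate, and
#' the per-clade niche targets (standardized centroid offsets in chosen
#' bioclimatic variables).
#'
#' @slot name scenario/preset name.
#' @slot grid a [GeoGrid] for the synthetic world.
#' @slot nPerClade named integer vector of occurrences per clade.
#' @slot window reproductive-period months.
#' @slot targets list of niche targets; each a list with elements
#'   `variable`, `period` ("reproductive"/"annual"), `offset` (named by
#'   clade, standardized units) and `width` (suitability SD).
#' @slot fields named list of field parameters for the climate generator.
#' @export
setClass("SyntheticScenario",
  representation(name = "character", grid = "GeoGrid",
                 nPerClade = "integer", window = "integer",
                 targets = "list", fields = "list")
)

setMethod("show", "SyntheticScenario", function(object) {
  cat(sprintf("SyntheticScenario '%s': %d x %d grid, %d occurrences, %d niche target(s)\n",
              object@name, object@grid@nrow, object@grid@ncol,
              sum(object@nPerClade), length(object@targets)))
})
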