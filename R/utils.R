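# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# x-coordinates (longitudes) of pixel centers, one per column.
cellCentersX <- function(grid) grid@xmin + (seq_len(grid@ncol) - 0.5) * grid@res

# y-coordinates (latitudes) of pixel centers, one per row (top to bottom).
cellCentersY <- function(grid) grid@ymax - (seq_len(grid@nrow) - 0.5) * grid@res

# Map lon/lat to 1-based (row, col); pixel-is-area, floor convention.
rowcolFromXY <- function(grid, lon, lat) {
  col <- floor((lon - grid@xmin) / grid@res) + 1
  row <- floor((grid@ymax - lat) / grid@res) + 1
  # points exactly on the right/bottom edge belong to the last pixel
  col[lon == grid@xmin + grid@ncol * grid@res] <- grid@ncol
  row[lat == grid@ymax - grid@nrow * grid@res] <- grid@nrow
  cbind(row = as.integer(row), col = as.integer(col))
}

# TRUE for points inside the grid extent.
insideExtent <- function(grid, lon, lat) {
  lon >= grid@xmin & lon <= grid@xmin + grid@ncol * grid@res &
    lat >= grid@ymax - grid@nrow * grid@res & lat <= grid@ymax
}

# Percent correct at the 1-decimal reporting precision used in tables.
#' Percent correctly classified
#'
#' `100 * correct / total`, rounded to one decimal as reported in
#' classification tables.
#'
#' @param correct,total counts (vectorized).
#' @return numeric percentage(s), one decimal.
#' @examples
#' percentCorrect(c(54, 99), c(78, 107))
#' @export
percentCorrect <- function(correct, total) {
  stopifnot(all(correct <= total), all(total > 0))
  round(100 * correct / total, 1)
}
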