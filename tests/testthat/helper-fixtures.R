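# Fixture builders and independent brute-force oracles used across tests.

# small grid helper
testGrid <- function(nr = 4, nc = 5, res = 1, xmin = 0, ymax = nr * res) {
  GeoGrid(nrow = nr, ncol = nc, xmin = xmin, ymax = ymax, res = res)
}

# monthly stack from per-month scalar (or matrix) values
makeStack <- function(grid, tminVals, tmaxVals, precVals) {
  asLayer <- function(v) if (is.matrix(v)) v else matrix(v, grid@nrow, grid@ncol)
  MonthlyClimateStack(grid,
    tmin = lapply(tminVals, asLayer),
    tmax = lapply(tmaxVals, asLayer),
    prec = lapply(precVals, asLayer))
}

# random smooth-ish stack with per-pixel variation, reproducible
randomStack <- function(grid, seed = 1) {
  set.seed(seed)
  nr <- grid@nrow; nc <- grid@ncol
  base <- matrix(rnorm(nr * nc, 10, 3), nr, nc)
  lst <- function(f) lapply(1:12, f)
  makeStack(grid,
    tminVals = lst(function(m) base + 3 * cos(2 * pi * (m - 7) / 12) +
                     matrix(rnorm(nr * nc, 0, 1), nr, nc) - 4),
    tmaxVals = lst(function(m) base + 3 * cos(2 * pi * (m - 7) / 12) +
                     matrix(abs(rnorm(nr * nc, 5, 1)), nr, nc)),
    precVals = lst(function(m) matrix(rexp(nr * nc, 1 / 50), nr, nc)))
}

# brute-force per-pixel bioclim recomputation (scalar loops, sample SD)
bruteBioclim <- function(stack, window) {
  nr <- stack@grid@nrow; nc <- stack@grid@ncol
  out <- list()
  vars <- c("BIO1", "BIO2", "BIO3", "BIO4", "BIO6", "BIO15", "minTmax", "meanTmin")
  for (v in vars) out[[v]] <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    tn <- vapply(window, function(m) stack@tmin[[m]][i, j], numeric(1))
    tx <- vapply(window, function(m) stack@tmax[[m]][i, j], numeric(1))
    pr <- vapply(window, function(m) stack@prec[[m]][i, j], numeric(1))
    ta <- (tn + tx) / 2
    out$BIO1[i, j] <- mean(ta)
    out$BIO2[i, j] <- mean(tx - tn)
    rng <- max(tx) - min(tn)
    out$BIO3[i, j] <- if (rng == 0) NA_real_ else 100 * mean(tx - tn) / rng
    out$BIO4[i, j] <- 100 * sd(ta)
    out$BIO6[i, j] <- min(tn)
    out$BIO15[i, j] <- 100 * sd(pr) / (1 + mean(pr))
    out$minTmax[i, j] <- min(tx)
    out$meanTmin[i, j] <- mean(tn)
  }
  out
}

# brute-force point-in-convex-polygon via barycentric fan triangulation
brutePointInHull <- function(px, py, hx, hy) {
  n <- length(hx)
  inTri <- function(x, y, x1, y1, x2, y2, x3, y3) {
    d1 <- (x - x3) * (y1 - y3) - (x1 - x3) * (y - y3)
    d2 <- (x - x1) * (y2 - y1) - (x2 - x1) * (y - y1)
    d3 <- (x - x2) * (y3 - y2) - (x3 - x2) * (y - y2)
    tol <- 1e-9
    (d1 >= -tol & d2 >= -tol & d3 >= -tol) | (d1 <= tol & d2 <= tol & d3 <= tol)
  }
  res <- rep(FALSE, length(px))
  for (k in 2:(n - 1)) {
    res <- res | inTri(px, py, hx[1], hy[1], hx[k], hy[k], hx[k + 1], hy[k + 1])
  }
  res
}

# exhaustive best-split oracle: all variables x all midpoints
bruteBestSplit <- function(x, y, minbucket = 1) {
  y1 <- as.integer(factor(y)) - 1
  gini <- function(v) { if (!length(v)) return(0); p <- mean(v); 2 * p * (1 - p) }
  best <- NULL
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    us <- sort(unique(v))
    if (length(us) < 2) next
    for (t in (us[-1] + us[-length(us)]) / 2) {
      L <- v < t
      if (sum(L) < minbucket || sum(!L) < minbucket) next
      dG <- gini(y1) - (sum(L) * gini(y1[L]) + sum(!L) * gini(y1[!L])) / length(v)
      if (is.null(best) || dG > best$decrease + 1e-12) {
        best <- list(var = colnames(x)[j], threshold = t, decrease = dG)
      }
    }
  }
  if (!is.null(best) && best$decrease <= 1e-12) best <- NULL
  best
}

# enumerate all pruned subtrees of a ParityTree root: list of (R, leaves)
enumerateSubtrees <- function(node) {
  collapse <- list(list(R = node$rlocal, leaves = 1L))
  if (is.null(node$split)) return(collapse)
  l <- enumerateSubtrees(node$left)
  r <- enumerateSubtrees(node$right)
  keep <- list()
  for (a in l) for (b in r) {
    keep[[length(keep) + 1L]] <- list(R = a$R + b$R, leaves = a$leaves + b$leaves)
  }
  c(collapse, keep)
}

# best (R, leaves) minimizing R + cp * leaves, ties to fewest leaves
bruteOptimalSubtree <- function(root, cp) {
  subs <- enumerateSubtrees(root)
  cost <- vapply(subs, function(s) s$R + cp * s$leaves, numeric(1))
  leaves <- vapply(subs, `[[`, integer(1), "leaves")
  minCost <- min(cost)
  cand <- which(cost <= minCost + 1e-12)
  best <- cand[which.min(leaves[cand])]
  subs[[best]]
}

# standard two-clade labelled covariate fixture for tree tests
cartFixture <- function(n = 120, p = 3, seed = 1, signal = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  colnames(x) <- paste0("v", seq_len(p))
  y <- factor(ifelse(x[, 1] * signal + rnorm(n, 0, 0.8) > 0, "oviparous", "viviparous"),
              levels = c("oviparous", "viviparous"))
  list(x = x, y = y)
}
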