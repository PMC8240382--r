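test_that("convex hull mask agrees with a brute-force point-in-polygon oracle", {
  grid <- testGrid(20, 20, res = 0.5)
  set.seed(4)
  lon <- runif(25, 1, 9); lat <- runif(25, 1, 9)
  mask <- convexHullMask(lon, lat, grid)
  h <- grDevices::chull(lon, lat)
  X <- matrix(parityNiche:::cellCentersX(grid), 20, 20, byrow = TRUE)
  Y <- matrix(parityNiche:::cellCentersY(grid), 20, 20)
  oracle <- matrix(brutePointInHull(as.vector(X), as.vector(Y), lon[h], lat[h]), 20, 20)
  expect_equal(mask, oracle)
  # independent cross-check with mgcv's in/out test on strictly interior cells
  bnd <- list(x = c(lon[h], lon[h][1]), y = c(lat[h], lat[h][1]))
  io <- matrix(mgcv::in.out(cbind(bnd$x, bnd$y), cbind(as.vector(X), as.vector(Y))), 20, 20)
  expect_true(all(mask[io]))  # everything mgcv calls inside, we call inside
})

test_that("hull mask contains the occurrence pixels and rejects degenerate input", {
  grid <- testGrid(10, 10)
  lon <- c(2.5, 7.5, 7.5, 2.5); lat <- c(2.5, 2.5, 7.5, 7.5)
  mask <- convexHullMask(lon, lat, grid)
  rc <- parityNiche:::rowcolFromXY(grid, lon, lat)
  expect_true(all(mask[rc]))
  expect_true(mask[5, 5])           # interior
  expect_false(mask[1, 1])          # outside the square
  expect_error(convexHullMask(c(1, 2), c(1, 2), grid), "at least 3")
  expect_error(convexHullMask(c(1, 2, 3), c(1, 2, 3), grid), "collinear")
})

test_that("background sampling is uniform, exact and reproducible", {
  grid <- testGrid(6, 6)
  mask <- matrix(FALSE, 6, 6)
  mask[2:5, 2:5] <- TRUE
  all16 <- sampleBackground(mask, grid, 16, seed = 1)
  expect_equal(nrow(all16), 16)
  expect_setequal(paste(all16$row, all16$col), paste(rep(2:5, 4), rep(2:5, each = 4)))
  expect_error(sampleBackground(mask, grid, 17), "only 16 are available")
  s1 <- sampleBackground(mask, grid, 5, seed = 42)
  s2 <- sampleBackground(mask, grid, 5, seed = 42)
  expect_identical(s1, s2)
  # Monte-Carlo uniformity: single-pixel draws from a 4-pixel mask
  m4 <- matrix(FALSE, 6, 6); m4[1, 1:4] <- TRUE
  draws <- vapply(1:10000, function(i) sampleBackground(m4, grid, 1, seed = i)$col, numeric(1))
  freq <- table(factor(draws, levels = 1:4)) / 10000
  expect_true(all(abs(freq - 0.25) < 3 * sqrt(0.25 * 0.75 / 10000) + 0.005))
})

test_that("correlation PCA matches an independent eigendecomposition", {
  set.seed(11)
  X <- matrix(rnorm(50 * 5), 50, 5)
  colnames(X) <- paste0("b", 1:5)
  m <- fitPcaEnv(X)
  e <- eigen(cor(X), symmetric = TRUE)
  expect_equal(m@sdev^2, e$values, tolerance = 1e-9)
  L <- e$vectors
  for (j in 1:5) if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  expect_equal(unname(m@rotation), L, tolerance = 1e-9)
  expect_equal(sum(explainedVariance(m)), 1)
  # sign convention: largest-magnitude loading positive on every axis
  for (j in 1:5) expect_gt(m@rotation[which.max(abs(m@rotation[, j])), j], 0)
})

test_that("PCA degenerate and error cases behave as specified", {
  set.seed(2)
  a <- rnorm(30)
  two <- cbind(p = a, q = 2 * a + 5)   # perfectly correlated
  m <- fitPcaEnv(two)
  expect_equal(explainedVariance(m)[1], 1, tolerance = 1e-12)
  const <- cbind(p = a, q = rep(1, 30))
  expect_error(fitPcaEnv(const), "zero-variance variable.*q")
  expect_error(fitPcaEnv(cbind(a)), "at least 2 variables")
  expect_error(fitPcaEnv(cbind(p = a, q = c(NA, a[-1]))), "nodata")
})

test_that("projection reproduces PCA geometry on the calibration set", {
  set.seed(12)
  X <- matrix(rnorm(80 * 4), 80, 4)
  colnames(X) <- paste0("b", 1:4)
  m <- fitPcaEnv(X)
  sc <- projectScores(m, X)
  # mean row projects to the origin
  expect_equal(as.numeric(projectScores(m, matrix(m@center, 1,
    dimnames = list(NULL, m@varnames)))), rep(0, 4), tolerance = 1e-12)
  # score variances equal the eigenvalues, axes uncorrelated
  expect_equal(apply(sc, 2, var), m@sdev^2, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_lt(abs(cov(sc[, 1], sc[, 2])), 1e-9)
  expect_error(projectScores(m, X[, 1:3]), "variable-count mismatch")
})

test_that("occupancy surfaces normalize, localize and match MASS::kde2d", {
  set.seed(5)
  bg <- cbind(rnorm(400), rnorm(400))
  sp <- nicheSpace(bg, gridSize = 50)
  occ <- cbind(rnorm(30, 1, 0.3), rnorm(30, -0.5, 0.3))
  s <- occupancySurface(sp, occ, clade = "A")
  expect_equal(sum(s@z), 1, tolerance = 1e-9)
  expect_true(all(s@z >= 0))
  # the raw occurrence density equals kde2d with 4x bandwidths
  ref <- MASS::kde2d(occ[, 1], occ[, 2], h = 4 * s@bw, n = 50,
                     lims = c(range(sp@xgrid), range(sp@ygrid)))
  expect_equal(s@o, ref$z, tolerance = 1e-9)
  # single occurrence peaks at its own cell
  one <- occupancySurface(sp, cbind(0.7, 0.2), mode = "raw")
  pk <- which(one@z == max(one@z), arr.ind = TRUE)
  expect_equal(as.integer(pk[1, ]),
               c(which.min(abs(sp@xgrid - 0.7)), which.min(abs(sp@ygrid - 0.2))))
  expect_error(occupancySurface(sp, occ[0, , drop = FALSE]), "empty occurrence")
})

test_that("corrected and raw occupancy agree over a uniform background", {
  # dense uniform background grid: availability is flat where occurrences sit
  g <- as.matrix(expand.grid(seq(-4, 4, length.out = 60), seq(-4, 4, length.out = 60)))
  sp <- nicheSpace(g, gridSize = 40, bwMult = 1)
  set.seed(6)
  occ <- cbind(rnorm(40, 0, 0.4), rnorm(40, 0, 0.4))   # well interior
  zc <- occupancySurface(sp, occ, mode = "corrected")@z
  zr <- occupancySurface(sp, occ, mode = "raw")@z
  expect_lt(max(abs(zc - zr)), 1e-6)
})

test_that("Schoener's D has its defining values, symmetry and bandwidth monotonicity", {
  sp <- nicheSpace(cbind(c(-2, 2, -2, 2), c(-2, -2, 2, 2)), gridSize = 30)
  mk <- function(z) new("NicheSurface", xgrid = sp@xgrid, ygrid = sp@ygrid,
                        o = z, z = z / sum(z), clade = "x", bw = c(1, 1), mode = "raw")
  z1 <- matrix(0, 30, 30); z1[5, 5] <- 0.6; z1[20, 20] <- 0.4
  z2 <- matrix(0, 30, 30); z2[5, 5] <- 0.4; z2[20, 20] <- 0.6
  a <- mk(z1); b <- mk(z2)
  expect_equal(schoenerD(a, b), 0.8)            # 1 - 0.5 * (0.2 + 0.2)
  expect_equal(schoenerD(a, a), 1)
  disjoint <- matrix(0, 30, 30); disjoint[1, 1] <- 1
  expect_equal(schoenerD(a, mk(disjoint)), 0)
  expect_identical(schoenerD(a, b), schoenerD(b, a))
  other <- nicheSpace(cbind(c(-3, 3), c(-3, 3)), gridSize = 25)
  c25 <- new("NicheSurface", xgrid = other@xgrid, ygrid = other@ygrid,
             o = matrix(1 / 625, 25, 25), z = matrix(1 / 625, 25, 25),
             clade = "y", bw = c(1, 1), mode = "raw")
  expect_error(schoenerD(a, c25), "different grids")

  # widening kernels makes two separated clouds overlap more
  set.seed(7)
  bg <- cbind(rnorm(300, 0, 2), rnorm(300, 0, 2))
  spc <- nicheSpace(bg, gridSize = 60)
  c1 <- cbind(rnorm(25, -0.6, 0.5), rnorm(25, 0, 0.5))
  c2 <- cbind(rnorm(25, 0.6, 0.5), rnorm(25, 0, 0.5))
  ds <- vapply(c(0.5, 1, 2, 4), function(mult) {
    schoenerD(occupancySurface(spc, c1, mode = "raw", bwMult = mult),
              occupancySurface(spc, c2, mode = "raw", bwMult = mult))
  }, numeric(1))
  expect_true(all(diff(ds) > 0))
})

test_that("surfaces and overlap are invariant to occurrence order", {
  set.seed(8)
  bg <- cbind(rnorm(200), rnorm(200))
  sp <- nicheSpace(bg, gridSize = 40)
  occ <- cbind(rnorm(20), rnorm(20))
  s1 <- occupancySurface(sp, occ)
  s2 <- occupancySurface(sp, occ[sample(20), ])
  expect_equal(s1@z, s2@z)
})

test_that("clade centroids are plain coordinate means", {
  expect_equal(cladeCentroid(cbind(2, 3)), c(PC1 = 2, PC2 = 3))
  expect_equal(cladeCentroid(rbind(c(-1, 2), c(1, -2))), c(PC1 = 0, PC2 = 0))
  set.seed(9)
  sc <- matrix(rnorm(20), 10, 2)
  expect_equal(cladeCentroid(sc), c(PC1 = sum(sc[, 1]) / 10, PC2 = sum(sc[, 2]) / 10))
  expect_error(cladeCentroid(sc[0, ]), "no scores")
})
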