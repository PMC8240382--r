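#' Permutation p-value against a null distribution of overlaps
#'
#' Add-one convention, so p is never 0:
#' `p_lo = (1 + #\{D_sim <= D_obs\}) / (n + 1)`, `p_hi` analogously, and
#' the two-tailed p is `min(1, 2 * min(p_lo, p_hi))`.
#'
#' @param dObs observed overlap.
#' @param dSim numeric vector of simulated overlaps.
#' @param tail `"two"`, `"lower"` or `"upper"`.
#' @return p-value in `(0, 1]`.
#' @export
compareToNull <- function(dObs, dSim, tail = c("two", "lower", "upper")) {
  tail <- match.arg(tail)
  if (!length(dSim)) stop("empty null distribution")
  n <- length(dSim)
  pLo <- (1 + sum(dSim <= dObs)) / (n + 1)
  pHi <- (1 + sum(dSim >= dObs)) / (n + 1)
  switch(tail,
    lower = pLo,
    upper = pHi,
    two = min(1, 2 * min(pLo, pHi))
  )
}

#' Significance code for overlap-test tables
#'
#' `"**"` for p <= 0.01, `"*"` for p < 0.05, `"NS"` otherwise.
#'
#' @param p p-value(s).
#' @return character vector of codes.
#' @export
significanceCode <- function(p) {
  ifelse(p <= 0.01, "**", ifelse(p < 0.05, "*", "NS"))
}

#' Translate an occupancy surface by whole cells
#'
#' Shifts `z` by `(dx, dy)` grid cells (positive = towards larger PC
#' values); mass shifted outside the grid is dropped and the surface
#' renormalized (a surface shifted fully off the grid keeps z = 0).
#'
#' @param surface a [NicheSurface].
#' @param dx,dy integer cell offsets along PC1 and PC2.
#' @return a [NicheSurface] with the translated, renormalized `z`.
#' @export
shiftSurface <- function(surface, dx, dy) {
  z <- surface@z
  nx <- nrow(z); ny <- ncol(z)
  out <- matrix(0, nx, ny)
  xs <- intersect(seq_len(nx), seq_len(nx) + dx)
  ys <- intersect(seq_len(ny), seq_len(ny) + dy)
  if (length(xs) && length(ys)) out[xs, ys] <- z[xs - dx, ys - dy]
  tot <- sum(out)
  if (tot > 0) out <- out / tot
  s <- surface
  s@z <- out
  # bypass the sum-to-1 validity check for the all-dropped edge case
  if (tot > 0) validObject(s)
  s
}

# density-weighted centroid of a surface, in cell indices
surfaceCentroidCell <- function(surface) {
  z <- surface@z
  c(round(sum(row(z) * z)), round(sum(col(z) * z)))
}

# bounding box (in cell indices) of the background-supported region
supportBox <- function(space) {
  eps <- 1e-12 * max(space@e)
  sup <- space@e > eps
  if (!any(sup)) stop("background support is empty")
  idx <- which(sup, arr.ind = TRUE)
  list(x = range(idx[, 1]), y = range(idx[, 2]))
}

#' Niche similarity test (surface-shift permutation)
#'
#' Per replicate, the occupancy surface of each clade is translated by an
#' independent uniform random cell offset: a target position for the
#' surface's density-weighted centroid is drawn uniformly within the
#' bounding box of the background-supported extent, mass shifted off the
#' grid is dropped and the surface renormalized. Schoener's D between the
#' two shifted surfaces gives `D_sim`; the test is two-tailed (add-one
#' convention). With `shiftBoth = FALSE` only the second clade's surface
#' is shifted.
#'
#' For exact symmetry in the clade order, the two random offsets of a
#' replicate are assigned to the clades in sorted label order.
#'
#' @param surfA,surfB [NicheSurface] objects on the shared grid.
#' @param space the shared [NicheSpace].
#' @param nReps number of permutations (default 1000).
#' @param seed base seed; replicate r uses seed + r.
#' @param shiftBoth shift both surfaces (default, as in the study) or
#'   only the second.
#' @return list of class `"overlapTest"`: clades, `dObs`, `dSim`, `p`,
#'   `tail`, `nReps`, `seed`.
#' @export
similarityTest <- function(surfA, surfB, space, nReps = 1000L, seed = 1L,
                           shiftBoth = TRUE) {
  stopifnot(nReps >= 1L)
  dObs <- schoenerD(surfA, surfB)
  box <- supportBox(space)
  surfs <- list(surfA, surfB)
  ord <- order(c(surfA@clade, surfB@clade))
  cents <- lapply(surfs, surfaceCentroidCell)
  dSim <- vapply(seq_len(nReps), function(r) {
    off <- withSeed(seed + r, {
      lapply(1:2, function(k) c(
        sample(box$x[1]:box$x[2], 1L),
        sample(box$y[1]:box$y[2], 1L)
      ))
    })
    # offsets drawn in sorted-label order so swapping arguments is a no-op
    tgt <- list(); tgt[ord] <- off
    shifted <- lapply(1:2, function(k) {
      if (k == 1L && !shiftBoth) return(surfs[[k]])
      shiftSurface(surfs[[k]], tgt[[k]][1] - cents[[k]][1], tgt[[k]][2] - cents[[k]][2])
    })
    schoenerD(shifted[[1]], shifted[[2]])
  }, numeric(1))
  structure(list(clades = c(surfA@clade, surfB@clade), dObs = dObs, dSim = dSim,
                 p = compareToNull(dObs, dSim, "two"), tail = "two_tailed_similarity",
                 nReps = as.integer(nReps), seed = as.integer(seed)),
            class = "overlapTest")
}

#' Niche equivalency test (occurrence-reassignment permutation)
#'
#' The pooled occurrence scores of the two clades are randomly
#' re-partitioned into groups of the original sizes; both occupancy
#' surfaces are rebuilt from scratch (bandwidths re-estimated from the
#' permuted groups) and `D_sim` recorded. The test is lower-tailed: it
#' rejects when `D_obs` is smaller than expected by chance,
#' `p = (1 + #\{D_sim <= D_obs\}) / (nReps + 1)`.
#'
#' The partition of a replicate is drawn for the clade pair in sorted
#' label order, so swapping the arguments changes neither `D_obs` nor p.
#'
#' @param scoresA,scoresB occurrence score matrices of the two clades.
#' @param space the shared [NicheSpace].
#' @param clades labels of the two clades.
#' @param nReps number of permutations (default 1000).
#' @param seed base seed; replicate r uses seed + r.
#' @param mode,bwMult passed to [occupancySurface].
#' @return an `"overlapTest"` list (see [similarityTest]).
#' @export
equivalencyTest <- function(scoresA, scoresB, space, clades = c("A", "B"),
                            nReps = 1000L, seed = 1L,
                            mode = "corrected", bwMult = 1) {
  scoresA <- as.matrix(scoresA)[, 1:2, drop = FALSE]
  scoresB <- as.matrix(scoresB)[, 1:2, drop = FALSE]
  nA <- nrow(scoresA); nB <- nrow(scoresB)
  if (nA < 1L || nB < 1L || nA + nB < 2L) stop("need at least one occurrence per clade")
  build <- function(s) occupancySurface(space, s, mode = mode, bwMult = bwMult)
  dObs <- schoenerD(build(scoresA), build(scoresB))
  # pool and subset sizes in sorted clade-label order, so swapping the
  # arguments reproduces the identical null distribution
  if (order(clades)[1] == 1L) {
    pool <- rbind(scoresA, scoresB); nFirst <- nA
  } else {
    pool <- rbind(scoresB, scoresA); nFirst <- nB
  }
  dSim <- vapply(seq_len(nReps), function(r) {
    idx <- withSeed(seed + r, sample(nA + nB, nFirst))
    schoenerD(build(pool[idx, , drop = FALSE]), build(pool[-idx, , drop = FALSE]))
  }, numeric(1))
  structure(list(clades = clades, dObs = dObs, dSim = dSim,
                 p = compareToNull(dObs, dSim, "lower"),
                 tail = "lower_tailed_equivalency",
                 nReps = as.integer(nReps), seed = as.integer(seed)),
            class = "overlapTest")
}

#' @export
print.overlapTest <- function(x, ...) {
  cat(sprintf("Niche overlap test (%s): clades %s-%s\n  D_obs = %.4f, p = %.4g (%d permutations) %s\n",
              x$tail, x$clades[1], x$clades[2], x$dObs, x$p, x$nReps,
              significanceCode(x$p)))
  invisible(x)
}

#' Pairwise overlap and test matrix
#'
#' Runs Schoener's D plus the similarity and equivalency tests for every
#' clade pair and assembles the table layout used for reporting: `D_obs`
#' (with similarity significance asterisks) below the diagonal and
#' equivalency significance codes above it.
#'
#' @param scoresByClade named list of occurrence score matrices.
#' @param space the shared [NicheSpace].
#' @param nReps permutations per test.
#' @param seed base seed; pair (i, j) uses an offset seed ladder.
#' @param mode,bwMult passed to [occupancySurface].
#' @return list with `D` (numeric matrix), `similarityP`, `equivalencyP`
#'   (numeric matrices), `table` (character matrix in the report layout)
#'   and `tests` (nested list of `"overlapTest"` objects).
#' @export
pairwiseNicheTests <- function(scoresByClade, space, nReps = 1000L, seed = 1L,
                               mode = "corrected", bwMult = 1) {
  clades <- names(scoresByClade)
  k <- length(clades)
  surfaces <- lapply(clades, function(cl)
    occupancySurface(space, scoresByClade[[cl]], clade = cl, mode = mode, bwMult = bwMult))
  names(surfaces) <- clades
  D <- overlapMatrix(surfaces)
  simP <- eqP <- matrix(NA_real_, k, k, dimnames = list(clades, clades))
  tests <- list()
  pair <- 0L
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    pair <- pair + 1L
    base <- seed + 2L * (pair - 1L) * nReps
    st <- similarityTest(surfaces[[i]], surfaces[[j]], space, nReps = nReps, seed = base)
    et <- equivalencyTest(scoresByClade[[i]], scoresByClade[[j]], space,
                          clades = c(clades[i], clades[j]),
                          nReps = nReps, seed = base + nReps,
                          mode = mode, bwMult = bwMult)
    simP[i, j] <- simP[j, i] <- st$p
    eqP[i, j] <- eqP[j, i] <- et$p
    tests[[paste(clades[i], clades[j], sep = "-")]] <- list(similarity = st, equivalency = et)
  }
  tab <- matrix("-", k, k, dimnames = list(clades, clades))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    star <- if (simP[i, j] < 0.05) "*" else ""
    tab[j, i] <- sprintf("%.3f%s", D[i, j], star)
    tab[i, j] <- significanceCode(eqP[i, j])
  }
  list(D = D, similarityP = simP, equivalencyP = eqP, table = tab, tests = tests)
}
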