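#' Run the niche-comparison analysis for one period
#'
#' Orchestrates one full analysis window: derive the bioclim variables,
#' build the convex-hull extent and background sample, fit the PCA-env
#' ordination, build per-clade occupancy surfaces, run the pairwise
#' similarity and equivalency tests, fit / cross-validate / prune the
#' parity classification tree, and map the result onto the parity-mode
#' hypotheses. All randomness flows from `seed`.
#'
#' @param stack a [MonthlyClimateStack].
#' @param occurrences data.frame with `lon`, `lat`, `clade`, `parity`.
#' @param window calendar months of the analysis window.
#' @param vars bioclim variables to use (defaults: seven-variable
#'   reproductive set for a sub-annual window, six-variable annual set
#'   otherwise).
#' @param bgN background pixels to sample (study default 20000).
#' @param gridSize ordination grid cells per axis (default 100).
#' @param nReps permutations per overlap test (study default 1000).
#' @param cartParams list of tree parameters (minsplit, minbucket).
#' @param mode occupancy mode, `"corrected"` or `"raw"`.
#' @param seed base RNG seed.
#' @return list of class `"nicheRun"`: bioclim metadata, PCA model and
#'   scores, surfaces, overlap tables, trees, importance, confusion and
#'   hypothesis report.
#' @export
runPeriodAnalysis <- function(stack, occurrences, window = reproductiveWindow(),
                              vars = NULL, bgN = 20000L, gridSize = 100L,
                              nReps = 1000L,
                              cartParams = list(minsplit = 20L, minbucket = 7L),
                              mode = "corrected", seed = 1L) {
  occurrences <- validateOccurrences(occurrences)
  if (is.null(vars))
    vars <- if (length(window) < 12L) reproductiveVars() else annualVars()
  bio <- deriveBioclim(stack, window, vars)
  grid <- stack@grid

  mask <- convexHullMask(occurrences$lon, occurrences$lat, grid)
  bg <- sampleBackground(mask, grid, bgN, seed = seed)
  xBg <- extractAtPoints(bio, bg[, c("lon", "lat")])
  xOcc <- extractAtPoints(bio, occurrences[, c("lon", "lat")])
  dropBg <- attr(xBg, "nodata"); dropOcc <- attr(xOcc, "nodata")
  if (any(dropBg)) message(sum(dropBg), " background pixel(s) on nodata dropped")
  if (any(dropOcc)) message(sum(dropOcc), " occurrence record(s) on nodata dropped")
  xBg <- xBg[!dropBg, , drop = FALSE]
  xOcc <- xOcc[!dropOcc, , drop = FALSE]
  occKept <- occurrences[!dropOcc, , drop = FALSE]

  model <- fitPcaEnv(rbind(xBg, xOcc))
  bgScores <- projectScores(model, xBg, naxes = 2L)
  occScores <- projectScores(model, xOcc, naxes = 2L)
  space <- nicheSpace(bgScores, gridSize = gridSize)

  clades <- sort(unique(occKept$clade))
  scoresByClade <- lapply(clades, function(cl)
    occScores[occKept$clade == cl, , drop = FALSE])
  names(scoresByClade) <- clades
  surfaces <- lapply(clades, function(cl)
    occupancySurface(space, scoresByClade[[cl]], clade = cl, mode = mode))
  names(surfaces) <- clades
  centroids <- t(vapply(scoresByClade, cladeCentroid, numeric(2)))
  overlap <- pairwiseNicheTests(scoresByClade, space, nReps = nReps,
                                seed = seed, mode = mode)

  y <- factor(occKept$parity, levels = c("oviparous", "viviparous"))
  fullTree <- growTree(xOcc, y, cp = 0,
                       minsplit = cartParams$minsplit,
                       minbucket = cartParams$minbucket)
  profile <- crossValidate(fullTree, seed = seed)
  prunedTree <- prune1SE(fullTree, profile)
  importance <- variableImportance(prunedTree, "global")
  perSplit <- lapply(seq_len(countLeaves(prunedTree@root) - 1L),
                     function(k) variableImportance(prunedTree, k))
  confusion <- classificationSummary(prunedTree, clades = occKept$clade)
  report <- hypothesisReport(prunedTree)

  structure(list(
    window = window, vars = vars, seed = seed,
    model = model, explained = explainedVariance(model),
    space = space, surfaces = surfaces, centroids = centroids,
    overlap = overlap,
    fullTree = fullTree, cv = profile, tree = prunedTree,
    importance = importance, importancePerSplit = perSplit,
    confusion = confusion, hypothesis = report,
    occurrences = occKept
  ), class = "nicheRun")
}

#' @export
print.nicheRun <- function(x, ...) {
  cat(sprintf("nicheRun over months {%s} with %d variables\n",
              paste(x$window, collapse = ","), length(x$vars)))
  cat(sprintf("  PC1 %.1f%%, PC2 %.1f%% of climatic variance\n",
              100 * x$explained[1], 100 * x$explained[2]))
  cat(sprintf("  pruned tree: %d leaves; overall %.1f%% correct\n",
              countLeaves(x$tree@root), x$confusion$overall$percent))
  cat(sprintf("  hypothesis combination %d: %s\n", x$hypothesis$combination,
              paste(x$hypothesis$hypotheses, collapse = ", ")))
  invisible(x)
}

#' Run the paired annual + reproductive analyses
#'
#' The two configured runs share the occurrence set and the climate stack
#' and differ only in the month window and variable list.
#'
#' @param stack a [MonthlyClimateStack].
#' @param occurrences occurrence data.frame.
#' @param bgN,gridSize,nReps,cartParams,mode,seed see [runPeriodAnalysis].
#' @return list with elements `reproductive` and `annual` (both
#'   `"nicheRun"`), and `config`.
#' @export
runParityPipeline <- function(stack, occurrences, bgN = 20000L, gridSize = 100L,
                              nReps = 1000L,
                              cartParams = list(minsplit = 20L, minbucket = 7L),
                              mode = "corrected", seed = 1L) {
  config <- list(bgN = bgN, gridSize = gridSize, nReps = nReps,
                 cartParams = cartParams, mode = mode, seed = seed)
  list(
    reproductive = runPeriodAnalysis(stack, occurrences,
                                     window = reproductiveWindow(),
                                     vars = reproductiveVars(),
                                     bgN = bgN, gridSize = gridSize, nReps = nReps,
                                     cartParams = cartParams, mode = mode, seed = seed),
    annual = runPeriodAnalysis(stack, occurrences,
                               window = annualWindow(), vars = annualVars(),
                               bgN = bgN, gridSize = gridSize, nReps = nReps,
                               cartParams = cartParams, mode = mode, seed = seed),
    config = config
  )
}

#' Write the output bundle of a run
#'
#' Emits, per period: PCA explained variance and loadings (CSV), the
#' pairwise overlap table with significance codes (CSV, D below the
#' diagonal and equivalency codes above), the clade centroids, the
#' cross-validation profile, the pruned tree dump (text), the importance
#' tables per scope (CSV), the confusion summary (CSV) and the hypothesis
#' report (JSON). Output is deterministic: re-running the same config
#' rewrites identical files.
#'
#' @param run a `"nicheRun"` object.
#' @param dir output directory (created).
#' @return invisibly, the paths written.
#' @export
writeRunOutputs <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  wcsv <- function(x, name, rn = FALSE) {
    p <- file.path(dir, name)
    utils::write.csv(x, p, row.names = rn, quote = FALSE)
    paths <<- c(paths, p)
  }
  wcsv(data.frame(axis = paste0("PC", seq_along(run$explained)),
                  explained_pct = 100 * run$explained), "pca_variance.csv")
  wcsv(as.data.frame(run$model@rotation), "pca_loadings.csv", rn = TRUE)
  wcsv(as.data.frame(run$centroids), "clade_centroids.csv", rn = TRUE)
  wcsv(as.data.frame(run$overlap$table), "overlap_table.csv", rn = TRUE)
  wcsv(as.data.frame(run$overlap$D), "overlap_D.csv", rn = TRUE)
  wcsv(run$cv, "cv_profile.csv")
  wcsv(run$importance, "importance_global.csv")
  for (k in seq_along(run$importancePerSplit))
    wcsv(run$importancePerSplit[[k]], sprintf("importance_split%d.csv", k))
  conf <- run$confusion
  wcsv(rbind(
    data.frame(group = "overall", correct = conf$overall$correct,
               total = conf$overall$total, percent = conf$overall$percent),
    conf$byParity, if (!is.null(conf$byClade)) conf$byClade
  ), "confusion.csv")
  treePath <- file.path(dir, "tree.txt")
  writeLines(treeLines(run$tree@root, run$tree@levels), treePath)
  paths <- c(paths, treePath)
  jsonPath <- file.path(dir, "hypothesis.json")
  jsonlite::write_json(run$hypothesis, jsonPath, auto_unbox = TRUE, pretty = TRUE)
  paths <- c(paths, jsonPath)
  invisible(paths)
}
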