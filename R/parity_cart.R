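# Binary Gini classification tree with surrogate splits, weakest-link
# cost-complexity pruning, stratified 10-fold cross-validation and
# impurity-based variable importance.

gini2 <- function(n1, n) {
  if (n == 0) return(0)
  p <- n1 / n
  2 * p * (1 - p)
}

#' Best single Gini split for a node
#'
#' Scans every covariate and every midpoint of consecutive distinct sorted
#' values, maximizing the Gini impurity decrease
#' `dG = G(parent) - (nL/n) G(L) - (nR/n) G(R)` (computed on rows where
#' the covariate is known, weighted by the known fraction when covariates
#' differ in missingness). Ties within a covariate go to the smaller
#' threshold; ties across covariates to the first covariate. Cases with
#' `value < threshold` go left.
#'
#' @param x covariate matrix (rows of one node).
#' @param y two-level factor of class labels.
#' @param minbucket minimum child size (default 1).
#' @return `NULL` when no admissible split exists, else a list with
#'   `var`, `threshold`, `decrease` (per-case Gini decrease) and
#'   `improveN` (decrease times the number of informative cases, the
#'   importance credit).
#' @export
bestSplit <- function(x, y, minbucket = 1L) {
  x <- as.matrix(x)
  y1 <- as.integer(y) - 1L  # second level coded 1
  best <- NULL
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    ok <- !is.na(v)
    nm <- sum(ok)
    if (nm < 2L * minbucket) next
    vv <- v[ok]; yy <- y1[ok]
    ord <- order(vv)
    vs <- vv[ord]; ys <- yy[ord]
    tot1 <- sum(ys)
    gParent <- gini2(tot1, nm)
    if (gParent == 0) next
    cum1 <- cumsum(ys)
    i <- seq_len(nm - 1L)
    cand <- i[vs[i] < vs[i + 1L] & i >= minbucket & (nm - i) >= minbucket]
    if (!length(cand)) next
    nL <- cand; n1L <- cum1[cand]
    pL <- n1L / nL; pR <- (tot1 - n1L) / (nm - nL)
    imp <- (nL * 2 * pL * (1 - pL) + (nm - nL) * 2 * pR * (1 - pR)) / nm
    dG <- gParent - imp
    k <- which.max(dG)  # first max = smallest threshold on ties
    if (dG[k] <= 1e-12) next
    improveN <- dG[k] * nm
    if (is.null(best) || improveN > best$improveN + 1e-12) {
      best <- list(var = colnames(x)[j], j = j,
                   threshold = (vs[cand[k]] + vs[cand[k] + 1L]) / 2,
                   decrease = dG[k], improveN = improveN)
    }
  }
  best
}

# Surrogate splits mimicking a primary left/right assignment.
# goLeft: logical (NA where the primary covariate is missing).
surrogateSplits <- function(x, goLeft, primaryJ, maxSurrogate) {
  if (maxSurrogate < 1L) return(list())
  out <- list()
  known <- !is.na(goLeft)
  totL <- sum(goLeft[known]); nK <- sum(known)
  if (nK == 0L) return(list())
  baseline <- max(totL, nK - totL) / nK
  for (j in seq_len(ncol(x))) {
    if (j == primaryJ) next
    v <- x[, j]
    ok <- known & !is.na(v)
    n <- sum(ok)
    if (n < 2L) next
    vv <- v[ok]; LL <- goLeft[ok]
    ord <- order(vv)
    vs <- vv[ord]; Ls <- LL[ord]
    tL <- sum(Ls)
    cumL <- cumsum(Ls)
    i <- seq_len(n - 1L)
    cand <- i[vs[i] < vs[i + 1L]]
    if (!length(cand)) next
    agreeLow <- 2 * cumL[cand] + n - cand - tL      # value < thr -> left
    agreeHigh <- n - agreeLow                        # value < thr -> right
    kL <- which.max(agreeLow); kH <- which.max(agreeHigh)
    if (agreeLow[kL] >= agreeHigh[kH]) {
      k <- kL; lowToLeft <- TRUE; agree <- agreeLow[kL]
    } else {
      k <- kH; lowToLeft <- FALSE; agree <- agreeHigh[kH]
    }
    agreement <- agree / n
    if (agreement > baseline + 1e-12) {
      out[[length(out) + 1L]] <- list(var = colnames(x)[j], j = j,
                                      threshold = (vs[cand[k]] + vs[cand[k] + 1L]) / 2,
                                      lowToLeft = lowToLeft, agreement = agreement,
                                      # gain over the blind majority rule; the
                                      # importance weight (raw agreement would
                                      # credit uninformative covariates with
                                      # about the majority share)
                                      adjAgreement = (agreement - baseline) / (1 - baseline))
    }
  }
  if (!length(out)) return(list())
  out[order(-vapply(out, `[[`, numeric(1), "agreement"))][seq_len(min(length(out), maxSurrogate))]
}

# route cases left/right through a split, using surrogates then the
# majority direction for rows whose primary covariate is missing
routeLeft <- function(x, split) {
  v <- x[, split$j]
  goLeft <- v < split$threshold
  miss <- is.na(goLeft)
  if (any(miss)) {
    for (s in split$surrogates) {
      if (!any(miss)) break
      sv <- x[, s$j]
      use <- miss & !is.na(sv)
      if (any(use)) {
        goLeft[use] <- if (s$lowToLeft) sv[use] < s$threshold else !(sv[use] < s$threshold)
        miss <- is.na(goLeft)
      }
    }
    goLeft[miss] <- split$majorityLeft
  }
  goLeft
}

#' Grow a classification tree for parity mode
#'
#' Recursive partitioning with the Gini impurity: each node takes the
#' best admissible split (see [bestSplit]) until it is pure, smaller than
#' `minsplit`, or no split leaves both children with at least `minbucket`
#' cases. With `cp = 0` (the default, as used for the study's full tree)
#' every impurity-decreasing split is kept; pruning is done afterwards
#' ([prune1SE]). Up to `maxSurrogate` surrogate splits per node (default:
#' number of covariates minus one) are retained when they agree with the
#' primary split better than the blind majority-direction rule; they route
#' missing values and earn importance credit.
#'
#' @param x covariate matrix with column names.
#' @param y class labels (two-level factor or character).
#' @param cp complexity parameter: minimum per-case impurity decrease,
#'   relative to the training size, for a split to be kept (default 0).
#' @param minsplit minimum node size to attempt a split (default 20).
#' @param minbucket minimum child size (default 7).
#' @param maxSurrogate maximum surrogates per split.
#' @param maxdepth depth cap (default 30).
#' @return a [ParityTree].
#' @export
growTree <- function(x, y, cp = 0, minsplit = 20L, minbucket = 7L,
                     maxSurrogate = ncol(x) - 1L, maxdepth = 30L) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  y <- factor(y)
  if (nlevels(y) > 2L) stop("parity trees are binary; got ", nlevels(y), " classes")
  if (nlevels(y) < 2L) {
    warning("only one class present; returning a single-leaf tree")
    y <- factor(y, levels = c(levels(y), ".other"))
  }
  N <- nrow(x)
  id <- 0L
  build <- function(rows, depth) {
    id <<- id + 1L
    cnt <- table(factor(y[rows], levels = levels(y)))
    counts <- as.integer(cnt)
    pred <- levels(y)[which.max(counts)]
    node <- list(id = id, n = length(rows), counts = counts, pred = pred,
                 gini = gini2(counts[2], sum(counts)),
                 rlocal = (length(rows) - max(counts)) / N,
                 rows = rows, split = NULL, left = NULL, right = NULL)
    if (length(rows) < minsplit || node$gini == 0 || depth >= maxdepth) return(node)
    s <- bestSplit(x[rows, , drop = FALSE], y[rows], minbucket = minbucket)
    if (is.null(s) || s$improveN / N <= cp) return(node)
    v <- x[rows, s$j]
    goLeft <- v < s$threshold
    s$surrogates <- surrogateSplits(x[rows, , drop = FALSE], goLeft, s$j, maxSurrogate)
    s$majorityLeft <- sum(goLeft, na.rm = TRUE) >= sum(!goLeft, na.rm = TRUE)
    node$split <- s
    goLeft <- routeLeft(x[rows, , drop = FALSE], s)
    node$left <- build(rows[goLeft], depth + 1L)
    node$right <- build(rows[!goLeft], depth + 1L)
    node
  }
  root <- build(seq_len(N), 0L)
  root <- numberSplits(root)
  new("ParityTree", root = root, covariates = colnames(x),
      levels = levels(y)[1:2], x = x, y = y,
      params = list(cp = cp, minsplit = as.integer(minsplit),
                    minbucket = as.integer(minbucket),
                    maxSurrogate = as.integer(maxSurrogate),
                    maxdepth = as.integer(maxdepth)))
}

# breadth-first split numbering (split 1 = root), as in reported trees
numberSplits <- function(root) {
  k <- 0L
  queue <- list(root)
  ids <- integer()
  while (length(queue)) {
    node <- queue[[1]]; queue <- queue[-1]
    if (!is.null(node$split)) {
      k <- k + 1L
      ids[as.character(node$id)] <- k
      queue <- c(queue, list(node$left), list(node$right))
    }
  }
  assign_ <- function(node) {
    if (is.null(node$split)) return(node)
    node$splitIndex <- ids[[as.character(node$id)]]
    node$left <- assign_(node$left)
    node$right <- assign_(node$right)
    node
  }
  assign_(root)
}

countLeaves <- function(node) {
  if (is.null(node$split)) 1L else countLeaves(node$left) + countLeaves(node$right)
}

# indented text dump: counts are (first level, second level)
treeLines <- function(node, levels, indent = "") {
  lab <- sprintf("n=%d (%d %s, %d %s) -> %s", node$n,
                 node$counts[1], levels[1], node$counts[2], levels[2], node$pred)
  if (is.null(node$split)) return(paste0(indent, "leaf: ", lab))
  c(sprintf("%ssplit %d: %s < %.4g  [%s]", indent, node$splitIndex,
            node$split$var, node$split$threshold, lab),
    treeLines(node$left, levels, paste0(indent, "  ")),
    treeLines(node$right, levels, paste0(indent, "  ")))
}

#' Predict parity mode
#'
#' Routes rows down the tree; rows missing the primary split covariate
#' use the surrogate splits in agreement order, then the majority
#' direction.
#'
#' @param tree a [ParityTree].
#' @param newx covariate matrix (training matrix by default).
#' @return factor of predicted classes.
#' @export
predictParity <- function(tree, newx = tree@x) {
  newx <- as.matrix(newx)
  preds <- character(nrow(newx))
  walk <- function(node, rows) {
    if (!length(rows)) return()
    if (is.null(node$split)) {
      preds[rows] <<- node$pred
      return()
    }
    goLeft <- routeLeft(newx[rows, , drop = FALSE], node$split)
    walk(node$left, rows[goLeft])
    walk(node$right, rows[!goLeft])
  }
  walk(tree@root, seq_len(nrow(newx)))
  factor(preds, levels = tree@levels)
}

# ---- cost-complexity pruning ------------------------------------------

# collect (id, g) for internal nodes of the tree restricted to `collapsed`
ccWalk <- function(node, collapsed) {
  if (is.null(node$split) || node$id %in% collapsed)
    return(list(R = node$rlocal, leaves = 1L, glist = list()))
  l <- ccWalk(node$left, collapsed)
  r <- ccWalk(node$right, collapsed)
  R <- l$R + r$R
  leaves <- l$leaves + r$leaves
  g <- (node$rlocal - R) / (leaves - 1L)
  list(R = R, leaves = leaves,
       glist = c(l$glist, r$glist, list(list(id = node$id, g = g))))
}

#' Weakest-link cost-complexity sequence
#'
#' For each internal node, `g = (R(node) - R(branch)) / (leaves - 1)` with
#' `R` the resubstitution misclassification cost (as a fraction of all
#' training rows). Nodes with minimal `g` are collapsed iteratively,
#' giving the nested subtree sequence indexed by increasing cp; the
#' sequence starts at the cp = 0 optimum (zero-gain branches already
#' collapsed) and ends at the root-only tree.
#'
#' @param tree a [ParityTree].
#' @return data.frame with columns `cp` and `nleaf`.
#' @export
costComplexitySequence <- function(tree) {
  # start from the cp = 0 optimum: branches that do not reduce the
  # misclassification cost (g <= 0) are collapsed immediately, so every
  # row of the sequence is the subtree pruneAt() returns at that cp
  collapsed <- integer()
  repeat {
    w <- ccWalk(tree@root, collapsed)
    if (!length(w$glist)) break
    gs <- vapply(w$glist, `[[`, numeric(1), "g")
    if (min(gs) > 1e-12) break
    collapsed <- c(collapsed, vapply(w$glist, `[[`, integer(1), "id")[gs <= min(gs) + 1e-12])
  }
  cp <- 0; nleaf <- w$leaves
  while (length(w$glist)) {
    gs <- vapply(w$glist, `[[`, numeric(1), "g")
    gmin <- min(gs)
    collapsed <- c(collapsed, vapply(w$glist, `[[`, integer(1), "id")[gs <= gmin + 1e-12])
    w <- ccWalk(tree@root, collapsed)
    cp <- c(cp, max(gmin, 0))
    nleaf <- c(nleaf, w$leaves)
  }
  data.frame(cp = cp, nleaf = nleaf)
}

# rebuild the tree with every node in `collapsed` turned into a leaf
collapseNodes <- function(node, collapsed) {
  if (is.null(node$split)) return(node)
  if (node$id %in% collapsed) {
    node$splitIndex <- NULL
    # keep the elements present (assigning NULL would drop them and let
    # `$split` partial-match `splitIndex`)
    node["split"] <- list(NULL)
    node["left"] <- list(NULL)
    node["right"] <- list(NULL)
    return(node)
  }
  node$left <- collapseNodes(node$left, collapsed)
  node$right <- collapseNodes(node$right, collapsed)
  node
}

#' Prune a tree at a complexity value
#'
#' Collapses weakest links while the minimal `g` does not exceed `cp`,
#' yielding the optimal subtree for that complexity penalty.
#'
#' @param tree a [ParityTree].
#' @param cp complexity value (same units as [costComplexitySequence]).
#' @return the pruned [ParityTree].
#' @export
pruneAt <- function(tree, cp) {
  collapsed <- integer()
  repeat {
    w <- ccWalk(tree@root, collapsed)
    if (!length(w$glist)) break
    gs <- vapply(w$glist, `[[`, numeric(1), "g")
    if (min(gs) > cp + 1e-12) break
    collapsed <- c(collapsed, vapply(w$glist, `[[`, integer(1), "id")[gs <= min(gs) + 1e-12])
  }
  out <- tree
  out@root <- numberSplits(collapseNodes(tree@root, collapsed))
  out@pruned <- TRUE
  out
}

#' Stratified 10-fold cross-validation profile
#'
#' Folds are stratified by class. For each cp in the master
#' cost-complexity sequence of the full tree (evaluated at the geometric
#' means of consecutive cp values), a tree is grown on each training fold,
#' pruned, and scored on the held-out fold. `xerror` is the
#' cross-validated misclassification count relative to the error of the
#' root (majority) rule; `xstd` its binomial standard error on the same
#' scale. Folds in which a training set loses a class entirely are
#' redrawn (bounded retries).
#'
#' @param tree a [ParityTree] grown with `cp = 0`.
#' @param nfolds number of folds (default 10).
#' @param seed RNG seed for the fold draw.
#' @return data.frame with columns `cp`, `nleaf`, `xerror`, `xstd`.
#' @export
crossValidate <- function(tree, nfolds = 10L, seed = 1L) {
  x <- tree@x; y <- tree@y
  N <- nrow(x)
  if (N < nfolds) stop("need at least as many rows as folds")
  cnt <- table(y)
  rootErr <- N - max(cnt)
  if (rootErr == 0) stop("cross-validation needs both classes present")
  cc <- costComplexitySequence(tree)
  alphas <- cc$cp
  K <- length(alphas)
  betas <- if (K == 1L) alphas else
    c(sqrt(alphas[-K] * alphas[-1L]), alphas[K])
  drawFolds <- function(s) {
    withSeed(s, {
      fold <- integer(N)
      for (lv in levels(y)) {
        idx <- sample(which(y == lv))
        fold[idx] <- rep_len(seq_len(nfolds), length(idx))
      }
      fold
    })
  }
  fold <- NULL
  for (try in 0:49) {
    f <- drawFolds(seed + 1000L * try)
    okAll <- all(vapply(seq_len(nfolds), function(k)
      nlevels(droplevels(y[f != k])) == 2L, logical(1)))
    if (okAll) { fold <- f; break }
  }
  if (is.null(fold)) stop("could not draw folds with both classes in every training set")
  err <- numeric(K)
  p <- tree@params
  for (k in seq_len(nfolds)) {
    tr <- fold != k
    sub <- growTree(x[tr, , drop = FALSE], y[tr], cp = 0,
                    minsplit = p$minsplit, minbucket = p$minbucket,
                    maxSurrogate = p$maxSurrogate, maxdepth = p$maxdepth)
    for (b in seq_len(K)) {
      pt <- pruneAt(sub, betas[b])
      pred <- predictParity(pt, x[!tr, , drop = FALSE])
      err[b] <- err[b] + sum(pred != y[!tr])
    }
  }
  data.frame(cp = alphas, nleaf = cc$nleaf,
             xerror = err / rootErr,
             xstd = sqrt(err * (1 - err / N)) / rootErr)
}

#' Prune with the 1-SE rule
#'
#' Selects the smallest subtree whose cross-validated error does not
#' exceed `min(xerror) + xstd[argmin]`, and prunes the full tree at that
#' cp. The profile is stored in the returned tree's `cv` slot.
#'
#' @param tree the full [ParityTree].
#' @param profile a profile from [crossValidate] (computed if missing).
#' @param seed passed to [crossValidate] when the profile is computed.
#' @return the pruned [ParityTree].
#' @export
prune1SE <- function(tree, profile = NULL, seed = 1L) {
  if (is.null(profile)) profile <- crossValidate(tree, seed = seed)
  i0 <- which.min(profile$xerror)
  thr <- profile$xerror[i0] + profile$xstd[i0]
  cand <- which(profile$xerror <= thr + 1e-12)
  pick <- cand[which.min(profile$nleaf[cand])]
  out <- pruneAt(tree, profile$cp[pick])
  out@cv <- profile
  out
}

# flat list of split nodes, ordered by splitIndex
collectSplits <- function(node) {
  if (is.null(node$split)) return(list())
  out <- c(list(node), collectSplits(node$left), collectSplits(node$right))
  out[order(vapply(out, `[[`, integer(1), "splitIndex"))]
}

#' Impurity-based variable importance
#'
#' Every split credits its primary variable with the split's impurity
#' improvement (Gini decrease times informative cases) and each retained
#' surrogate with the improvement weighted by its adjusted agreement,
#' `(agreement - baseline) / (1 - baseline)` with baseline the blind
#' majority-direction rule (so a surrogate no better than guessing earns
#' nothing). Credits are
#' summed over all splits (`scope = "global"`) or restricted to one split
#' (`scope = k`), and normalized to percent. A variable is flagged
#' significant when its share exceeds `100 / (number of covariates)`. The
#' `direction` column tags the sign of the Spearman correlation between
#' each covariate and the scope's main variable (the split's primary
#' variable, or the top-importance variable globally) on the relevant
#' cases.
#'
#' @param tree a [ParityTree].
#' @param scope `"global"` or a split number.
#' @return data.frame with columns `variable`, `credit`, `importance`
#'   (percent), `significant`, `direction`.
#' @export
variableImportance <- function(tree, scope = "global") {
  splits <- collectSplits(tree@root)
  vars <- tree@covariates
  credit <- stats::setNames(numeric(length(vars)), vars)
  if (!length(splits)) {
    return(data.frame(variable = vars, credit = 0, importance = 0,
                      significant = FALSE, direction = NA_character_))
  }
  if (!identical(scope, "global")) {
    k <- as.integer(scope)
    keep <- vapply(splits, `[[`, integer(1), "splitIndex") == k
    if (!any(keep)) stop("no split numbered ", k)
    splits <- splits[keep]
  }
  for (node in splits) {
    s <- node$split
    base <- s$improveN
    credit[s$var] <- credit[s$var] + base
    for (sur in s$surrogates)
      credit[sur$var] <- credit[sur$var] + sur$adjAgreement * base
  }
  importance <- 100 * credit / sum(credit)
  significant <- importance > 100 / length(vars)
  if (identical(scope, "global")) {
    mainVar <- vars[which.max(importance)]
    rows <- seq_len(nrow(tree@x))
  } else {
    mainVar <- splits[[1]]$split$var
    rows <- splits[[1]]$rows
  }
  direction <- vapply(vars, function(v) {
    if (v == mainVar) return("positive")
    rho <- suppressWarnings(stats::cor(tree@x[rows, v], tree@x[rows, mainVar],
                                       method = "spearman", use = "complete.obs"))
    if (!is.finite(rho)) NA_character_ else if (rho < 0) "negative" else "positive"
  }, character(1))
  out <- data.frame(variable = vars, credit = as.numeric(credit),
                    importance = as.numeric(importance),
                    significant = significant, direction = direction,
                    row.names = NULL)
  attr(out, "scope") <- scope
  attr(out, "mainVariable") <- mainVar
  out
}

#' Confusion summary by parity mode and clade
#'
#' Resubstitution (or supplied) predictions summarized as correct counts,
#' totals and percent correct (one decimal) per parity mode, per clade and
#' overall.
#'
#' @param tree a [ParityTree].
#' @param x,y data to score (training data by default).
#' @param clades optional clade label per row.
#' @return a `"confusionSummary"` list with elements `overall`,
#'   `byParity` and (if clades given) `byClade`.
#' @export
classificationSummary <- function(tree, x = tree@x, y = tree@y, clades = NULL) {
  summarizeConfusion(predictParity(tree, x), factor(y, levels = tree@levels), clades)
}

#' @rdname classificationSummary
#' @param pred,truth prediction and truth label vectors.
#' @export
summarizeConfusion <- function(pred, truth, clades = NULL) {
  ok <- pred == truth
  tab <- function(g) {
    agg <- data.frame(group = sort(unique(g)))
    agg$correct <- vapply(agg$group, function(l) sum(ok[g == l]), numeric(1))
    agg$total <- vapply(agg$group, function(l) sum(g == l), numeric(1))
    agg$percent <- percentCorrect(agg$correct, agg$total)
    agg
  }
  out <- list(
    overall = list(correct = sum(ok), total = length(ok),
                   percent = percentCorrect(sum(ok), length(ok))),
    byParity = tab(as.character(truth))
  )
  if (!is.null(clades)) out$byClade <- tab(as.character(clades))
  structure(out, class = "confusionSummary")
}

#' @export
print.confusionSummary <- function(x, ...) {
  cat(sprintf("Overall: %d/%d correct (%.1f%%)\n",
              x$overall$correct, x$overall$total, x$overall$percent))
  cat("By parity mode:\n")
  print(x$byParity, row.names = FALSE)
  if (!is.null(x$byClade)) {
    cat("By clade:\n")
    print(x$byClade, row.names = FALSE)
  }
  invisible(x)
}
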