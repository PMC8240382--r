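test_that("bestSplit matches the exhaustive brute-force oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- 30 + 10 * seed
    x <- matrix(sample(seq(-3, 3, 0.5), n * 3, replace = TRUE), n, 3)
    colnames(x) <- c("a", "b", "c")
    y <- factor(sample(c("oviparous", "viviparous"), n, replace = TRUE))
    got <- bestSplit(x, y)
    want <- bruteBestSplit(x, y)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$var, want$var)
      expect_equal(got$threshold, want$threshold)
      expect_equal(got$decrease, want$decrease, tolerance = 1e-12)
    }
  }
})

test_that("bestSplit contract cases: pure nodes, separation, tie-breaking", {
  x <- cbind(v = c(1, 2, 3, 4))
  expect_null(bestSplit(x, factor(rep("oviparous", 4), levels = c("oviparous", "viviparous"))))
  # perfectly separable: children pure, decrease equals parent Gini
  y <- factor(c("o", "o", "v", "v"))
  s <- bestSplit(x, y)
  expect_equal(s$threshold, 2.5)
  expect_equal(s$decrease, 0.5)   # parent Gini 2*0.5*0.5
  # two equally good thresholds: the smaller one wins
  ytie <- factor(c("o", "v", "v", "o"))
  stie <- bestSplit(x, ytie)
  expect_equal(stie$threshold, 1.5)
})

test_that("grown trees conserve counts, fit separable data and handle one class", {
  fx <- cartFixture(n = 150, seed = 3)
  tr <- growTree(fx$x, fx$y, minsplit = 10, minbucket = 4)
  checkConservation <- function(node) {
    if (is.null(node$split)) return(invisible())
    expect_equal(node$left$counts + node$right$counts, node$counts)
    checkConservation(node$left); checkConservation(node$right)
  }
  checkConservation(tr@root)
  # linearly separable labels are fit perfectly at cp = 0
  ysep <- factor(ifelse(fx$x[, 2] > 0.1, "oviparous", "viviparous"))
  tsep <- growTree(fx$x, ysep, minsplit = 4, minbucket = 1)
  expect_equal(mean(predictParity(tsep) == ysep), 1)
  expect_warning(t1 <- growTree(fx$x, rep("viviparous", 150)), "only one class")
  expect_null(t1@root$split)
  expect_equal(as.character(unique(predictParity(t1))), "viviparous")
})

test_that("tree agrees with rpart on root split and resubstitution accuracy", {
  for (seed in c(2, 5)) {
    fx <- cartFixture(n = 130, p = 4, seed = seed)
    tr <- growTree(fx$x, fx$y, minsplit = 20, minbucket = 7)
    rp <- rpart::rpart(y ~ ., data = data.frame(fx$x, y = fx$y), method = "class",
                       parms = list(split = "gini"),
                       control = rpart::rpart.control(cp = 0, minsplit = 20,
                                                      minbucket = 7, xval = 0))
    expect_equal(tr@root$split$var, as.character(rp$frame$var[1]))
    expect_equal(tr@root$split$threshold, unname(rp$splits[1, "index"]),
                 tolerance = 1e-9)
    expect_equal(mean(predictParity(tr) == fx$y),
                 mean(predict(rp, type = "class") == fx$y))
  }
})

test_that("cost-complexity sequence matches exhaustive subtree enumeration", {
  fx <- cartFixture(n = 90, p = 3, seed = 7, signal = 0.6)
  tr <- growTree(fx$x, fx$y, minsplit = 10, minbucket = 4)
  expect_gt(parityNiche:::countLeaves(tr@root), 3)  # non-trivial tree
  cc <- costComplexitySequence(tr)
  # the sequence starts at the cp = 0 optimum (zero-gain branches collapsed)
  expect_equal(cc$nleaf[1], parityNiche:::countLeaves(pruneAt(tr, 0)@root))
  expect_lte(cc$nleaf[1], parityNiche:::countLeaves(tr@root))
  expect_equal(cc$nleaf[nrow(cc)], 1)
  expect_true(all(diff(cc$cp) >= 0))
  expect_true(all(diff(cc$nleaf) < 0))
  # at every cp (and between breakpoints) pruning is optimal for R + cp|T|
  probes <- sort(unique(c(cc$cp, cc$cp + 1e-4, seq(0, max(cc$cp) * 1.5, length.out = 9))))
  for (cp in probes) {
    pruned <- pruneAt(tr, cp)
    want <- bruteOptimalSubtree(tr@root, cp)
    expect_equal(parityNiche:::countLeaves(pruned@root), want$leaves,
                 info = paste("cp =", cp))
    expect_equal(parityNiche:::ccWalk(pruned@root, integer())$R, want$R,
                 tolerance = 1e-12, info = paste("cp =", cp))
  }
  # extremes: infinite penalty prunes to the root
  expect_equal(parityNiche:::countLeaves(pruneAt(tr, Inf)@root), 1)
  # single-split tree has a length-2 sequence
  one <- growTree(cbind(v = c(1, 2, 3, 4, 5, 6)),
                  factor(c("o", "o", "o", "v", "v", "v")),
                  minsplit = 2, minbucket = 1)
  expect_equal(nrow(costComplexitySequence(one)), 2)
})

test_that("training error never increases with tree size along the pruning path", {
  fx <- cartFixture(n = 140, p = 3, seed = 9, signal = 0.7)
  tr <- growTree(fx$x, fx$y, minsplit = 10, minbucket = 4)
  cc <- costComplexitySequence(tr)
  errs <- vapply(cc$cp, function(cp)
    mean(predictParity(pruneAt(tr, cp)) != fx$y), numeric(1))
  expect_true(all(diff(errs) >= -1e-12))   # bigger cp (smaller tree) => no better fit
})

test_that("cross-validation is deterministic, exact at the root, and near 1 under the null", {
  fx <- cartFixture(n = 100, seed = 13)
  tr <- growTree(fx$x, fx$y)
  p1 <- crossValidate(tr, seed = 5)
  p2 <- crossValidate(tr, seed = 5)
  expect_identical(p1, p2)
  expect_true(all(p1$xstd >= 0))
  expect_true(all(is.finite(p1$xerror)))
  # separable labels cross-validate to (near) zero error at cp = 0
  ysep <- factor(ifelse(fx$x[, 1] > 0, "oviparous", "viviparous"))
  tsep <- growTree(fx$x, ysep, minsplit = 10, minbucket = 3)
  psep <- crossValidate(tsep, seed = 2)
  expect_lt(psep$xerror[1], 0.2)
  # labels independent of the covariates: relative error stays near 1
  set.seed(31)
  xe <- replicate(60, {
    x <- matrix(rnorm(60 * 2), 60, 2); colnames(x) <- c("a", "b")
    y <- factor(rep(c("oviparous", "viviparous"), times = c(35, 25)))
    t0 <- growTree(x, y, minsplit = 10, minbucket = 4)
    pr <- crossValidate(t0, seed = 1)
    c(pr$xerror[1], pr$xerror[nrow(pr)])
  })
  expect_lt(abs(mean(xe[1, ]) - 1), 0.15)   # overgrown tree end
  # a marginal extra split can only hurt on noise, so the near-root end
  # sits at or slightly above 1
  expect_lt(abs(mean(xe[2, ]) - 1), 0.25)

})

test_that("the 1-SE rule selects the smallest tree within one SE of the minimum", {
  fx <- cartFixture(n = 120, seed = 17, signal = 0.8)
  tr <- growTree(fx$x, fx$y, minsplit = 10, minbucket = 4)
  cc <- costComplexitySequence(tr)
  k <- nrow(cc)
  # flat profile: everything within 1 SE -> root-only tree
  flat <- data.frame(cp = cc$cp, nleaf = cc$nleaf,
                     xerror = rep(0.8, k), xstd = rep(0.05, k))
  expect_equal(parityNiche:::countLeaves(prune1SE(tr, flat)@root), 1)
  # monotone decreasing profile with tiny SEs keeps the full tree
  dec <- data.frame(cp = cc$cp, nleaf = cc$nleaf,
                    xerror = seq(0.5, 1.5, length.out = k), xstd = rep(1e-6, k))
  expect_equal(parityNiche:::countLeaves(prune1SE(tr, dec)@root), cc$nleaf[1])
  # hand-computed pick: minimum in the middle, neighbour inside the band
  if (k >= 3) {
    xerr <- rep(1.2, k); xerr[2] <- 0.6
    xstd <- rep(0.1, k); xerr[k] <- 0.65    # last (smallest tree) within 0.6 + 0.1
    prof <- data.frame(cp = cc$cp, nleaf = cc$nleaf, xerror = xerr, xstd = xstd)
    expect_equal(parityNiche:::countLeaves(prune1SE(tr, prof)@root), cc$nleaf[k])
  }
})

test_that("importance bookkeeping matches independent recomputation and sums to 100", {
  fx <- cartFixture(n = 160, p = 4, seed = 19, signal = 0.7)
  tr <- growTree(fx$x, fx$y, minsplit = 15, minbucket = 5)
  expect_gt(parityNiche:::countLeaves(tr@root), 2)
  imp <- variableImportance(tr, "global")
  expect_equal(sum(imp$importance), 100, tolerance = 1e-6)
  # independent credit walk over the stored split records
  credit <- setNames(numeric(4), colnames(fx$x))
  walk <- function(node) {
    if (is.null(node$split)) return(invisible())
    credit[node$split$var] <<- credit[node$split$var] + node$split$improveN
    for (s in node$split$surrogates)
      credit[s$var] <<- credit[s$var] + s$adjAgreement * node$split$improveN
    walk(node$left); walk(node$right)
  }
  walk(tr@root)
  expect_equal(imp$importance, as.numeric(100 * credit / sum(credit)), tolerance = 1e-12)
  expect_equal(imp$significant, imp$importance > 25)
  # per-split scopes partition the global credit
  splits <- parityNiche:::collectSplits(tr@root)
  perSplit <- lapply(seq_along(splits), function(k) variableImportance(tr, k))
  totals <- Reduce(`+`, lapply(perSplit, `[[`, "credit"))
  expect_equal(totals, imp$credit, tolerance = 1e-12)
  # a single split with no surrogates gives its primary variable 100%
  oneVar <- growTree(cbind(v = c(1, 2, 3, 4, 5, 6)),
                     factor(c("o", "o", "o", "v", "v", "v")),
                     minsplit = 2, minbucket = 1)
  impOne <- variableImportance(oneVar)
  expect_equal(impOne$importance, 100)
})

test_that("a duplicated covariate is a perfect surrogate and shares credit equally", {
  fx <- cartFixture(n = 100, seed = 23)
  x <- cbind(fx$x[, 1, drop = FALSE], twin = fx$x[, 1], other = fx$x[, 2])
  colnames(x)[1] <- "v1"
  tr <- growTree(x, fx$y, minsplit = 20, minbucket = 7)
  s <- tr@root$split
  expect_equal(s$var, "v1")   # tie broken by column order
  twin <- Filter(function(z) z$var == "twin", s$surrogates)[[1]]
  expect_equal(twin$agreement, 1)
  expect_equal(twin$adjAgreement, 1)
  imp <- variableImportance(tr)
  expect_equal(imp$importance[imp$variable == "v1"],
               imp$importance[imp$variable == "twin"])
  # rows missing the primary covariate are routed identically via the twin
  xm <- x
  xm[1:20, "v1"] <- NA
  expect_equal(predictParity(tr, xm), predictParity(tr, x))
})

test_that("confusion summaries report counts and one-decimal percentages", {
  pred <- factor(c("o", "o", "v", "v", "v"), levels = c("o", "v"))
  truth <- factor(c("o", "v", "v", "v", "o"), levels = c("o", "v"))
  cs <- summarizeConfusion(pred, truth, clades = c("A", "A", "C", "C", "B"))
  expect_equal(cs$overall$correct, 3)
  expect_equal(cs$overall$percent, 60)
  expect_equal(cs$byParity$correct[cs$byParity$group == "v"], 2)
  expect_equal(cs$byClade$total, c(2, 1, 2))
  # all-correct case
  all100 <- summarizeConfusion(truth, truth, clades = rep("A", 5))
  expect_equal(all100$overall$percent, 100)
  expect_true(all(all100$byParity$percent == 100))
  # tree-based summary is the resubstitution summary
  fx <- cartFixture(n = 80, seed = 29)
  tr <- growTree(fx$x, fx$y)
  cs2 <- classificationSummary(tr)
  expect_equal(cs2$overall$correct, sum(predictParity(tr) == fx$y))
})
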