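#' Variable classes for the hypothesis mapping
#'
#' Bioclimatic covariates are classed as *variability*-type (diurnal and
#' seasonal variability: BIO2, BIO3, BIO4, BIO15) or *average
#' temperature*-type (BIO1, BIO6, minTmax, meanTmin) for the mapping of
#' tree results onto the parity-mode hypotheses.
#'
#' @return named character vector `variable -> class`.
#' @export
variableClasses <- function() {
  c(BIO2 = "variability", BIO3 = "variability", BIO4 = "variability",
    BIO15 = "variability",
    BIO1 = "average", BIO6 = "average", minTmax = "average",
    meanTmin = "average")
}

#' The nine difference-pattern combinations and their supported hypotheses
#'
#' Each row pairs a direction of the viviparous-oviparous difference in
#' variability-type variables with one in average-temperature variables
#' and lists the hypotheses (with their prediction labels) that such a
#' pattern supports: CCH = cold-climate, MMH = maternal-manipulation,
#' SMH = selfish-mother hypothesis. Directions: `up_vivi` (viviparous >
#' oviparous), `down_vivi` (viviparous < oviparous), `none`. Footnotes:
#' (a) a hypothesis predicting only average temperature is not supported
#' by patterns that also involve variability differences; (b) supported if
#' the cost of higher variability is outweighed by the warmer average;
#' (c) supported if the cost of the colder average is outweighed by the
#' lower variability.
#'
#' @return data.frame with columns `combination`, `variability`,
#'   `meanTemp`, `hypotheses`, `predictions`, `footnote`.
#' @export
hypothesisCombinations <- function() {
  data.frame(
    combination = 1:9,
    variability = c("none", "none", "none", "up_vivi", "up_vivi", "up_vivi",
                    "down_vivi", "down_vivi", "down_vivi"),
    meanTemp = c("none", "down_vivi", "up_vivi", "none", "down_vivi", "up_vivi",
                 "none", "down_vivi", "up_vivi"),
    hypotheses = c("none", "CCH;MMH", "MMH;SMH", "MMH", "MMH", "MMH;SMH",
                   "SMH", "SMH", "SMH"),
    predictions = c("", "CCP_1;MMP_1", "MMP_2;SMP_2", "MMP_3", "MMP_1;MMP_3",
                    "MMP_2;MMP_3;SMP_2", "SMP_1", "SMP_1", "SMP_1;SMP_2"),
    footnote = c("", "", "", "", "", "b", "", "c", ""),
    stringsAsFactors = FALSE
  )
}

#' Direction of association of each covariate with viviparity
#'
#' Standardized mean difference (viviparous minus oviparous, in pooled-SD
#' units) per covariate: negative means viviparous records sit at lower
#' values (`down_vivi`).
#'
#' @param x covariate matrix.
#' @param parity parity label per row (`"oviparous"`/`"viviparous"`).
#' @return data.frame with `variable`, `smd` and `direction`.
#' @export
parityDirections <- function(x, parity) {
  x <- as.matrix(x)
  vivi <- parity == "viviparous"
  if (!any(vivi) || all(vivi)) stop("need both parity modes")
  smd <- vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    sdp <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(sdp) || sdp == 0) return(0)
    (mean(v[vivi], na.rm = TRUE) - mean(v[!vivi], na.rm = TRUE)) / sdp
  }, numeric(1))
  data.frame(variable = colnames(x), smd = smd,
             direction = ifelse(smd < 0, "down_vivi", ifelse(smd > 0, "up_vivi", "none")),
             row.names = NULL)
}

#' Classify the observed difference pattern
#'
#' Takes the pruned tree's global importance table and the per-covariate
#' associations with viviparity, and derives the difference pattern: for
#' each variable class (variability / average temperature), the majority
#' direction over the *significant* covariates of that class (importance
#' above 100/n); an exact conflict yields `none` with a warning; no
#' significant covariate yields `none`.
#'
#' @param importance a table from [variableImportance] (global scope).
#' @param directions a table from [parityDirections].
#' @param classes variable classing (default [variableClasses()]).
#' @return list with elements `variability` and `meanTemp`, each one of
#'   `"up_vivi"`, `"down_vivi"`, `"none"`.
#' @export
classifyPattern <- function(importance, directions, classes = variableClasses()) {
  sig <- importance$variable[importance$significant]
  dirOf <- stats::setNames(directions$direction, directions$variable)
  vote <- function(klass) {
    vars <- intersect(sig, names(classes)[classes == klass])
    if (!length(vars)) return("none")
    d <- dirOf[vars]
    nUp <- sum(d == "up_vivi"); nDown <- sum(d == "down_vivi")
    if (nUp == nDown) {
      if (nUp > 0)
        warning("conflicting directions among significant ", klass,
                " variables; pattern set to 'none'")
      return("none")
    }
    if (nUp > nDown) "up_vivi" else "down_vivi"
  }
  list(variability = vote("variability"), meanTemp = vote("average"))
}

#' Look up the hypotheses supported by a difference pattern
#'
#' Exact lookup in the nine-row combination table
#' ([hypothesisCombinations]).
#'
#' @param pattern list with `variability` and `meanTemp` (from
#'   [classifyPattern]).
#' @return one-row data.frame of the matching combination.
#' @export
supportedHypotheses <- function(pattern) {
  tab <- hypothesisCombinations()
  row <- tab[tab$variability == pattern$variability & tab$meanTemp == pattern$meanTemp, ]
  if (nrow(row) != 1L)
    stop("invalid pattern: ", pattern$variability, " / ", pattern$meanTemp)
  row
}

#' Full hypothesis report for a fitted tree
#'
#' Combines importance, directions, pattern and combination lookup into a
#' JSON-serializable report.
#'
#' @param tree a pruned [ParityTree].
#' @param parity parity label per training row (defaults to the tree's
#'   class labels).
#' @return list with `pattern`, `combination`, `hypotheses`,
#'   `predictions`, `footnote`, `significantVariables` and `directions`
#'   (a named list, so JSON serialization keeps the variable names).
#' @export
hypothesisReport <- function(tree, parity = as.character(tree@y)) {
  imp <- variableImportance(tree, "global")
  dirs <- parityDirections(tree@x, parity)
  pattern <- classifyPattern(imp, dirs)
  row <- supportedHypotheses(pattern)
  list(
    pattern = pattern,
    combination = row$combination,
    hypotheses = strsplit(row$hypotheses, ";")[[1]],
    predictions = if (nzchar(row$predictions)) strsplit(row$predictions, ";")[[1]] else character(),
    footnote = row$footnote,
    significantVariables = imp$variable[imp$significant],
    directions = as.list(stats::setNames(dirs$direction, dirs$variable))
  )
}
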