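# Synthetic study worlds: smooth monthly climate fields plus
# clade-structured occurrences with controllable niche differences.

# stationary Gaussian random field on a torus via spectral smoothing of
# white noise; standardized to mean 0, sd 1
gaussianRandomField <- function(nr, nc, corLen) {
  noise <- matrix(stats::rnorm(nr * nc), nr, nc)
  dx <- outer(pmin(0:(nr - 1), nr - (0:(nr - 1)))^2,
              pmin(0:(nc - 1), nc - (0:(nc - 1)))^2, `+`)
  kern <- exp(-dx / (2 * corLen^2))
  f <- Re(stats::fft(stats::fft(noise) * stats::fft(kern), inverse = TRUE)) / (nr * nc)
  (f - mean(f)) / stats::sd(f)
}

defaultNPerClade <- function() c(A = 37L, B = 41L, C = 19L, D = 26L, E = 47L, F = 15L)

defaultFieldParams <- function() list(
  baseMean = 11, baseSd = 4,     # spatial mean temperature field (degC)
  ampMean = 8, ampSd = 2,        # annual temperature cycle amplitude (degC)
  wSd = 3,                       # within-reproductive-window spread field (degC)
  drMean = 10, drSd = 2,         # diurnal temperature range field (degC)
  noiseSd = 0.2,                 # iid monthly temperature noise (degC)
  precLogMean = log(60), precLogSd = 0.4,   # log precipitation level
  precAmpMean = 0.7, precAmpSd = 0.35,      # log-scale seasonal modulation
  corLenFrac = 0.125             # GRF correlation length, fraction of grid side
)

# symmetric parity-mode centroid offsets: viviparous - oviparous = diff
parityOffsets <- function(diff) {
  off <- ifelse(names(defaultNPerClade()) %in% c("A", "B"), -diff / 2, diff / 2)
  stats::setNames(off, names(defaultNPerClade()))
}

#' Synthetic scenario presets
#'
#' Named study conditions for the synthetic world. All presets share the
#' six-clade design (A, B oviparous; C-F viviparous; 185 occurrences) on
#' a 200 x 200 grid with the May-July reproductive window; they differ in
#' the niche targets (centroid offsets in standardized bioclim units,
#' suitability width 0.5 SD):
#'
#' * `null` — all clades share one (uniform) niche; no climatic
#'   difference between parity modes.
#' * `smh_reproductive` — viviparous clades sit 1.5 SD lower in
#'   reproductive-window BIO4 and BIO15 (lower temperature and
#'   precipitation seasonality, the selfish-mother pattern).
#' * `cch_cold` — viviparous clades sit 1.5 SD lower in window meanTmin
#'   and BIO6 (colder, the cold-climate pattern).
#' * `mmh_variable` — viviparous clades sit 1.5 SD higher in window BIO4
#'   and BIO15 (more variable temperature and precipitation, the
#'   maternal-manipulation pattern).
#' * `annual_reversal` — viviparous clades sit 1.5 SD lower in
#'   reproductive-window BIO4 but 1.5 SD higher in annual BIO4,
#'   reproducing the qualitative reproductive-vs-annual sign flip.
#'
#' @param name preset name.
#' @param gridDim grid dimensions `c(nrow, ncol)` (default 200 x 200).
#' @param nPerClade named occurrences per clade (defaults above).
#' @param fields named overrides of the climate field parameters.
#' @return a [SyntheticScenario].
#' @export
scenarioPreset <- function(name = c("null", "smh_reproductive", "cch_cold",
                                    "mmh_variable", "annual_reversal"),
                           gridDim = c(200L, 200L),
                           nPerClade = defaultNPerClade(),
                           fields = list()) {
  name <- tryCatch(match.arg(name), error = function(e)
    stop("unknown preset '", name[1], "'; available: null, smh_reproductive, ",
         "cch_cold, mmh_variable, annual_reversal"))
  tgt <- function(variable, period, diff, width = 0.5)
    list(variable = variable, period = period, offset = parityOffsets(diff), width = width)
  targets <- switch(name,
    null = list(),
    smh_reproductive = list(tgt("BIO4", "reproductive", -1.5),
                            tgt("BIO15", "reproductive", -1.5)),
    cch_cold = list(tgt("meanTmin", "reproductive", -1.5),
                    tgt("BIO6", "reproductive", -1.5)),
    mmh_variable = list(tgt("BIO4", "reproductive", 1.5),
                        tgt("BIO15", "reproductive", 1.5)),
    annual_reversal = list(tgt("BIO4", "reproductive", -1.5),
                           tgt("BIO4", "annual", 1.5))
  )
  fp <- defaultFieldParams()
  fp[names(fields)] <- fields
  grid <- GeoGrid(nrow = gridDim[1], ncol = gridDim[2], xmin = 0, ymax = 50,
                  res = 10 / gridDim[2])
  new("SyntheticScenario", name = name, grid = grid,
      nPerClade = stats::setNames(as.integer(nPerClade), names(nPerClade)),
      window = 5:7, targets = targets, fields = fp)
}

#' Generate a synthetic monthly climate stack
#'
#' Builds spatially smooth monthly temperature and precipitation fields
#' from low-frequency Gaussian random fields: per pixel, monthly mean
#' temperature follows an annual cosine cycle
#' `T(m) = base + amp * cos(2 pi (m - 7) / 12)` peaking in July, plus a
#' window-spread field that adds an independent within-May-July trend
#' (so reproductive-window seasonality decorrelates from annual
#' seasonality), plus iid monthly noise. Diurnal range is a smooth
#' positive field with a mild annual cycle; precipitation is log-normal
#' with a smooth seasonal modulation. The result is bit-identical for a
#' fixed seed.
#'
#' @param scenario a [SyntheticScenario].
#' @param seed RNG seed.
#' @return a [MonthlyClimateStack].
#' @export
generateMonthlyStack <- function(scenario, seed = 1L) {
  fp <- scenario@fields
  g <- scenario@grid
  nr <- g@nrow; nc <- g@ncol
  corLen <- max(2, fp$corLenFrac * min(nr, nc))
  withSeed(seed, {
    base <- fp$baseMean + fp$baseSd * gaussianRandomField(nr, nc, corLen)
    amp <- if (fp$ampSd > 0 || fp$ampMean > 0)
      pmax(0, fp$ampMean + fp$ampSd * gaussianRandomField(nr, nc, corLen)) else
      matrix(0, nr, nc)
    w <- if (fp$wSd > 0) fp$wSd * gaussianRandomField(nr, nc, corLen) else matrix(0, nr, nc)
    dr <- pmax(0.5, fp$drMean + fp$drSd * gaussianRandomField(nr, nc, corLen))
    lp <- fp$precLogMean + fp$precLogSd * gaussianRandomField(nr, nc, corLen)
    pa <- fp$precAmpMean + fp$precAmpSd * gaussianRandomField(nr, nc, corLen)
    wseas <- c(0, 0, 0, 0, -1, 0, 1, 0, 0, 0, 0, 0)
    tmin <- tmax <- prec <- vector("list", 12L)
    for (m in 1:12) {
      tavg <- base + amp * cos(2 * pi * (m - 7) / 12) + w * wseas[m]
      if (fp$noiseSd > 0)
        tavg <- tavg + matrix(stats::rnorm(nr * nc, sd = fp$noiseSd), nr, nc)
      drm <- dr * (1 + 0.15 * cos(2 * pi * (m - 1) / 12))
      tmin[[m]] <- tavg - drm / 2
      tmax[[m]] <- tavg + drm / 2
      prec[[m]] <- exp(lp + pa * cos(2 * pi * (m - 8) / 12) +
                         matrix(stats::rnorm(nr * nc, sd = 0.1), nr, nc))
    }
    MonthlyClimateStack(g, tmin, tmax, prec)
  })
}

#' Sample clade-structured occurrences from a synthetic world
#'
#' Each clade samples pixels without replacement with probability
#' proportional to a Gaussian suitability around the clade's niche
#' centroid in the scenario's target variables (standardized over the
#' whole grid). With no targets (the `null` preset) all clades sample
#' uniformly, so their niches are exchangeable. Occurrence coordinates
#' are the pixel centers.
#'
#' @param scenario a [SyntheticScenario].
#' @param stack the matching [MonthlyClimateStack] (generated if missing).
#' @param seed RNG seed (also used for the stack when it is generated).
#' @return data.frame with columns `lon`, `lat`, `clade`, `parity`.
#' @export
generateOccurrences <- function(scenario, stack = NULL, seed = 1L) {
  if (is.null(stack)) stack <- generateMonthlyStack(scenario, seed = seed)
  g <- scenario@grid
  periods <- unique(vapply(scenario@targets, `[[`, character(1), "period"))
  bio <- list()
  if ("reproductive" %in% periods) bio$reproductive <- deriveBioclim(stack, scenario@window)
  if ("annual" %in% periods) bio$annual <- deriveBioclim(stack, 1:12)
  zfields <- lapply(scenario@targets, function(t) {
    f <- getLayer(bio[[t$period]], t$variable)
    (f - mean(f, na.rm = TRUE)) / stats::sd(as.vector(f), na.rm = TRUE)
  })
  clades <- names(scenario@nPerClade)
  nCells <- g@nrow * g@ncol
  lonC <- cellCentersX(g); latC <- cellCentersY(g)
  withSeed(seed + 1L, {
    out <- lapply(clades, function(cl) {
      n <- scenario@nPerClade[[cl]]
      if (length(scenario@targets)) {
        ls <- matrix(0, g@nrow, g@ncol)
        for (k in seq_along(scenario@targets)) {
          t <- scenario@targets[[k]]
          ls <- ls - 0.5 * ((zfields[[k]] - t$offset[[cl]]) / t$width)^2
        }
        suit <- exp(ls - max(ls))
        if (sum(suit > 1e-12) < n)
          stop("suitability mass for clade ", cl, " is (near) zero: the niche ",
               "centroid is unreachable in this world; relax the scenario ",
               "offsets or widths")
        cells <- sample.int(nCells, n, prob = as.vector(suit))
      } else {
        cells <- sample.int(nCells, n)
      }
      rc <- arrayInd(cells, c(g@nrow, g@ncol))
      data.frame(lon = lonC[rc[, 2]], lat = latC[rc[, 1]],
                 clade = cl, parity = parityOfClade(cl))
    })
    do.call(rbind, out)
  })
}
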