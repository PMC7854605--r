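# Cohort-level statistics: Wilcoxon signed-rank for paired region areas,
# simple linear regression (Pearson), multiple linear regression on z-scored
# variables with standardized coefficients and 95% CIs, and bidirectional
# stepwise selection. Also the parametric per-eye cohort generator used for
# statistical validation.

.morphometricVars <- c("maxHeightMm", "pedAreaMm2", "pedVolumeMm3",
                       "slopeAreaRatio")

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided test on paired differences. Zero differences are dropped;
#' tied absolute differences receive mid-ranks. The exact null distribution
#' is used for n <= 25 without ties, otherwise the normal approximation with
#' continuity correction. When every difference is zero the test is
#' undefined: the p-value is returned as NA with \code{flag} set.
#'
#' @param x,y equal-length paired samples.
#' @return list(statistic, p, n, exact, flag).
#' @export
wilcoxonSignedRank <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = NA_real_, p = NA_real_, n = 0L, exact = FALSE,
                flag = "all differences zero: test undefined"))
  ties <- any(duplicated(abs(d)))
  exact <- n <= 25L && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(d, exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p = ht$p.value, n = n,
       exact = exact, flag = NA_character_)
}

#' Simple linear regression with Pearson correlation
#'
#' @param x predictor, \code{y} response; n >= 3 with nonzero variance.
#' @param y response.
#' @return list(r, p, slope, intercept, n): Pearson r with the two-sided
#'   t-distributed p-value, and the OLS line on the original scales.
#' @export
simpleLinreg <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 3L) stopf("n >= 3 required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("zero variance in x or y: correlation undefined")
  ct <- stats::cor.test(x, y)
  fit <- stats::lm(y ~ x)
  list(r = unname(ct$estimate), p = ct$p.value,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), n = length(x))
}

.zscore <- function(m) {
  s <- apply(m, 2, stats::sd)
  if (any(s == 0))
    stopf("zero-variance column(s): %s",
          paste(colnames(m)[s == 0], collapse = ", "))
  scale(m)
}

.stdCoefTable <- function(Xz, yz, terms) {
  df <- data.frame(yz = yz, Xz[, terms, drop = FALSE], check.names = FALSE)
  fit <- stats::lm(yz ~ ., data = df)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stopf("rank-deficient design: collinear column(s) %s",
          paste(names(cf)[is.na(cf)], collapse = ", "))
  ci <- stats::confint(fit, level = 0.95)           # t-based, df = n - p - 1
  p <- summary(fit)$coefficients[, 4]
  keep <- setdiff(names(cf), "(Intercept)")
  list(fit = fit,
       table = data.frame(term = sub("^`|`$", "", keep),
                          beta = unname(cf[keep]),
                          ciLow = unname(ci[keep, 1]),
                          ciHigh = unname(ci[keep, 2]),
                          p = unname(p[keep]),
                          stringsAsFactors = FALSE))
}

#' Multiple linear regression with standardized coefficients
#'
#' Ordinary least squares on z-scored predictors and response. Coefficients
#' are therefore standardized betas (for a single predictor, beta equals the
#' Pearson correlation); 95% CIs come from the t distribution with
#' n - p - 1 degrees of freedom.
#'
#' @param X numeric matrix or data.frame of predictors (named columns).
#' @param y numeric response.
#' @param response response name for reporting.
#' @return a \linkS4class{RegressionReport} with identical selected and
#'   full-model tables.
#' @export
multipleLinregStandardized <- function(X, y, response = "y") {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) <= ncol(X) + 1L) stopf("n > p + 1 required")
  Xz <- .zscore(X)
  yz <- as.vector(scale(y))
  full <- .stdCoefTable(Xz, yz, colnames(Xz))
  new("RegressionReport", response = response, coefficients = full$table,
      fullCoefficients = full$table, selected = colnames(Xz),
      path = character(0), criterion = "none")
}

#' Stepwise multiple linear regression (standardized)
#'
#' Bidirectional stepwise selection on z-scored variables. With
#' \code{criterion = "p"} (default), predictors enter while their partial
#' two-sided p-value is below \code{pEnter} (0.05) and are removed when it
#' rises above \code{pStay} (0.10); with \code{criterion = "AIC"},
#' \code{stats::step} drives the search. The report carries the refit
#' selected model and, alongside it, the full all-predictor covariance table
#' (the two can answer different questions and both are reported). If no
#' predictor enters, the intercept-only model is reported with an empty
#' coefficient table.
#'
#' @param X predictor matrix/data.frame (named columns).
#' @param y response.
#' @param criterion "p" or "AIC".
#' @param pEnter,pStay entry/stay p-value thresholds for criterion "p".
#' @param response response name for reporting.
#' @return a \linkS4class{RegressionReport}.
#' @export
stepwiseSelect <- function(X, y, criterion = c("p", "AIC"),
                           pEnter = 0.05, pStay = 0.10, response = "y") {
  criterion <- match.arg(criterion)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) <= ncol(X) + 1L) stopf("n > p + 1 required")
  Xz <- .zscore(X)
  yz <- as.vector(scale(y))
  vars <- colnames(Xz)
  full <- .stdCoefTable(Xz, yz, vars)
  path <- character(0)

  if (criterion == "AIC") {
    df <- data.frame(yz = yz, Xz, check.names = FALSE)
    fit0 <- stats::lm(yz ~ 1, data = df)
    sc <- stats::step(fit0, scope = stats::reformulate(vars, "yz"),
                      direction = "both", trace = 0)
    selected <- setdiff(all.vars(stats::formula(sc)), "yz")
    path <- paste0("+", selected)
  } else {
    selected <- character(0)
    repeat {
      changed <- FALSE
      # forward: best candidate by partial p
      cands <- setdiff(vars, selected)
      if (length(cands)) {
        ps <- vapply(cands, function(v) {
          tab <- .stdCoefTable(Xz, yz, c(selected, v))$table
          tab$p[tab$term == v]
        }, numeric(1))
        if (min(ps) < pEnter) {
          add <- cands[which.min(ps)]
          selected <- c(selected, add)
          path <- c(path, paste0("+", add))
          changed <- TRUE
        }
      }
      # backward: worst included by partial p
      if (length(selected)) {
        tab <- .stdCoefTable(Xz, yz, selected)$table
        if (max(tab$p) > pStay) {
          drop <- tab$term[which.max(tab$p)]
          selected <- setdiff(selected, drop)
          path <- c(path, paste0("-", drop))
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  selTable <- if (length(selected)) .stdCoefTable(Xz, yz, selected)$table
    else full$table[0, ]
  new("RegressionReport", response = response, coefficients = selTable,
      fullCoefficients = full$table, selected = selected, path = path,
      criterion = criterion)
}

#' Generate a synthetic per-eye cohort table
#'
#' Draws per-eye morphometric PED parameters and RPE_70 lesion quantities
#' from a parametric model of a serous-PED cohort: lognormal maximum height
#' and PED area (matching the cohort means and dispersions of such a
#' population: height 0.288 +/- 0.202 mm, area 7.345 +/- 7.378 mm^2),
#' PED volume proportional to area x height with lognormal shape noise,
#' slope area ratio ~ truncated Normal(0.713, 0.097), and a planted linear
#' effect of PED volume on the whole-PED RPE_70 area (correlation set by
#' \code{effectR}, default 0.873) split between slope and peak regions with
#' a slope-dominant Beta fraction.
#'
#' @param nEyes number of eyes (default 26).
#' @param seed RNG seed.
#' @param effectR planted Pearson correlation between PED volume and
#'   whole-PED RPE_70 area.
#' @param slopeShare mean fraction of lesion area in the slope region
#'   (default 0.74).
#' @return data.frame with one row per eye: the four morphometric
#'   parameters, RPE_70 areas and RPE_70 area ratios (whole/peak/slope).
#' @export
generateCohortTable <- function(nEyes = 26L, seed = 1L, effectR = 0.873,
                                slopeShare = 0.74) {
  stopifnot(nEyes >= 3L, effectR > 0, effectR < 1)
  withSeed(seed, {
    lnPars <- function(m, s) {
      sdlog <- sqrt(log(1 + (s / m)^2))
      c(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
    }
    hp <- lnPars(0.288, 0.202)
    ap <- lnPars(7.345, 7.378)
    h <- stats::rlnorm(nEyes, hp[1], hp[2])
    a <- stats::rlnorm(nEyes, ap[1], ap[2])
    vol <- 0.66 * a * h * stats::rlnorm(nEyes, 0, 0.25)  # dome shape factor ~2/3
    sar <- pmin(pmax(stats::rnorm(nEyes, 0.713, 0.097), 0.30), 0.95)
    # planted volume -> lesion-area effect at the requested correlation
    sdv <- stats::sd(vol)
    targetSd <- 0.108
    b <- effectR * targetSd / sdv
    eps <- stats::rnorm(nEyes, 0, targetSd * sqrt(1 - effectR^2))
    # baseline 0.055 calibrated so the cohort mean slope-region lesion-area
    # ratio lands at its 0.011 target after the zero-truncation below
    whole <- pmax(0.055 + b * (vol - mean(vol)) + eps, 0)
    f <- stats::rbeta(nEyes, slopeShare * 12, (1 - slopeShare) * 12)
    slopeA <- whole * f
    peakA <- whole - slopeA
    peakRegion <- (1 - sar) * a
    slopeRegion <- sar * a
    data.frame(maxHeightMm = h, pedAreaMm2 = a, pedVolumeMm3 = vol,
               slopeAreaRatio = sar,
               rpe70AreaWholeMm2 = whole, rpe70AreaPeakMm2 = peakA,
               rpe70AreaSlopeMm2 = slopeA,
               rpe70RatioWhole = whole / a,
               rpe70RatioPeak = peakA / peakRegion,
               rpe70RatioSlope = slopeA / slopeRegion)
  })
}

#' Run the full statistical battery on a cohort table
#'
#' Reproduces the study-style analysis: descriptive summary of every column,
#' the paired Wilcoxon signed-rank test of slope- vs peak-region RPE_70
#' areas, simple linear regressions of each RPE_70 area and area ratio
#' against each morphometric parameter, and stepwise multiple linear
#' regressions (with the full-model covariance tables alongside). Two-sided
#' tests throughout; no multiplicity correction is applied (noted in the
#' output).
#'
#' @param cohort data.frame as from \code{\link{generateCohortTable}} (or
#'   assembled from per-eye pipeline results).
#' @param criterion stepwise criterion, "p" (default) or "AIC".
#' @return list with elements \code{summary}, \code{wilcoxonSlopeVsPeak},
#'   \code{simple} (data.frame of r and p per response/predictor pair),
#'   \code{stepwise} (list of \linkS4class{RegressionReport}), and
#'   \code{notes}.
#' @export
analyzeCohort <- function(cohort, criterion = c("p", "AIC")) {
  criterion <- match.arg(criterion)
  needed <- c(.morphometricVars, "rpe70AreaWholeMm2", "rpe70AreaPeakMm2",
              "rpe70AreaSlopeMm2", "rpe70RatioWhole", "rpe70RatioPeak",
              "rpe70RatioSlope")
  miss <- setdiff(needed, names(cohort))
  if (length(miss)) stopf("cohort table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (anyNA(cohort[needed])) stopf("cohort table contains missing values")

  summ <- do.call(rbind, lapply(needed, function(v) {
    x <- cohort[[v]]
    data.frame(parameter = v, mean = mean(x), sd = stats::sd(x),
               min = min(x), max = max(x))
  }))
  wil <- wilcoxonSignedRank(cohort$rpe70AreaSlopeMm2, cohort$rpe70AreaPeakMm2)
  responses <- c("rpe70AreaWholeMm2", "rpe70AreaPeakMm2", "rpe70AreaSlopeMm2",
                 "rpe70RatioWhole", "rpe70RatioPeak", "rpe70RatioSlope")
  simple <- do.call(rbind, lapply(responses, function(resp) {
    do.call(rbind, lapply(.morphometricVars, function(pred) {
      fit <- simpleLinreg(cohort[[pred]], cohort[[resp]])
      data.frame(response = resp, predictor = pred, r = fit$r, p = fit$p)
    }))
  }))
  X <- as.matrix(cohort[.morphometricVars])
  stepw <- lapply(stats::setNames(responses, responses), function(resp)
    stepwiseSelect(X, cohort[[resp]], criterion = criterion, response = resp))
  list(summary = summ, wilcoxonSlopeVsPeak = wil, simple = simple,
       stepwise = stepw,
       notes = "Two-sided tests; no multiplicity correction applied; eyes treated as independent.")
}
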