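# Cohort statistics: Wilcoxon signed-rank, simple and multiple linear
# regression with standardized coefficients, stepwise selection, and the
# parametric cohort generator.

# Exact two-sided signed-rank p by enumerating all sign patterns of ranks
# 1..n (independent oracle for small n, no ties).
enumSignedRankP <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vnull <- signs %*% seq_len(n)
  pLow <- mean(Vnull <= V)
  pHigh <- mean(Vnull >= V)
  min(1, 2 * min(pLow, pHigh))
}

test_that("signed-rank p matches exhaustive enumeration for small samples", {
  # n = 6, all differences positive: the extreme pattern
  x <- c(2, 4, 6, 8, 10, 12); y <- c(1, 2, 3, 4, 5, 6)
  res <- wilcoxonSignedRank(x, y)
  expect_true(res$exact)
  expect_equal(res$p, 0.03125)
  expect_equal(res$p, enumSignedRankP(x - y))

  # a mixed-sign pattern, still tie-free
  set.seed(8)
  for (i in 1:5) {
    d <- sample(c(-1, 1), 8, TRUE) * sample(seq(0.5, 8, by = 0.5), 8)
    res <- wilcoxonSignedRank(d, rep(0, 8))
    expect_equal(res$p, enumSignedRankP(d), tolerance = 1e-12)
  }
})

test_that("signed-rank handles zeros, ties and symmetry as specified", {
  allZero <- wilcoxonSignedRank(1:5, 1:5)
  expect_true(is.na(allZero$p))
  expect_match(allZero$flag, "undefined")

  # zero differences dropped before ranking
  res <- wilcoxonSignedRank(c(1, 2, 3, 4, 5, 6, 7), c(1, 1, 1, 1, 1, 1, 7))
  expect_equal(res$n, 5L)

  # tied magnitudes force the normal approximation
  resTie <- wilcoxonSignedRank(c(3, 3, 5, 5, 8, 9), rep(0, 6))
  expect_false(resTie$exact)
  expect_true(resTie$p > 0 && resTie$p <= 1)

  # p symmetric under swapping the paired samples
  set.seed(2)
  x <- rnorm(12); y <- rnorm(12)
  expect_equal(wilcoxonSignedRank(x, y)$p, wilcoxonSignedRank(y, x)$p)
})

test_that("simple regression returns Pearson r with its t-test p", {
  x <- 1:10
  expect_equal(simpleLinreg(x, 2 * x)$r, 1)
  expect_equal(simpleLinreg(x, 2 * x)$slope, 2)

  # hand-check oracle on a fixed 5-point table
  xt <- c(1, 2, 3, 4, 5); yt <- c(2, 1, 4, 3, 5)
  rOracle <- sum((xt - 3) * (yt - 3)) /
    sqrt(sum((xt - 3)^2) * sum((yt - 3)^2))
  fit <- simpleLinreg(xt, yt)
  expect_equal(fit$r, rOracle, tolerance = 1e-12)
  tStat <- rOracle * sqrt(3 / (1 - rOracle^2))
  expect_equal(fit$p, 2 * stats::pt(-abs(tStat), 3), tolerance = 1e-12)

  # affine invariance of r
  set.seed(4)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(simpleLinreg(5 - 2 * a, b)$r, -simpleLinreg(a, b)$r,
               tolerance = 1e-12)
  expect_error(simpleLinreg(rep(1, 5), 1:5), "zero variance")
  expect_error(simpleLinreg(1:2, 1:2), "n >= 3")
})

test_that("standardized beta of a single predictor equals Pearson r", {
  set.seed(13)
  for (i in 1:5) {
    x <- rnorm(26); y <- 0.5 * x + rnorm(26)
    rep1 <- multipleLinregStandardized(matrix(x, ncol = 1,
                                              dimnames = list(NULL, "x")), y)
    expect_equal(rep1@coefficients$beta, unname(cor(x, y)), tolerance = 1e-10)
  }
})

test_that("orthogonal predictors recover their marginal correlations as betas", {
  set.seed(19)
  n <- 40
  # columns orthogonal to each other AND to the intercept (mean zero), so
  # z-scoring preserves orthogonality and betas equal marginal correlations
  base <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n, 3))))[, 2:4]
  X <- base %*% diag(c(2, 5, 0.3))
  colnames(X) <- c("a", "b", "c")
  y <- rnorm(n)
  rep1 <- multipleLinregStandardized(X, y)
  marg <- vapply(1:3, function(j) cor(X[, j], y), numeric(1))
  expect_equal(rep1@coefficients$beta, marg, tolerance = 1e-10)
  # CI brackets beta and p in range (validity-checked on construction)
  expect_true(all(rep1@coefficients$ciLow <= rep1@coefficients$beta))
})

test_that("collinear designs are rejected naming the offending column", {
  set.seed(23)
  x <- rnorm(20)
  X <- cbind(a = x, b = 2 * x, c = rnorm(20))
  expect_error(multipleLinregStandardized(X, rnorm(20)), "collinear.*b")
})

test_that("a planted single-predictor effect is covered by the 95% CI at the nominal rate", {
  set.seed(101)
  n <- 26; reps <- 200
  hits <- 0L
  for (r in seq_len(reps)) {
    X <- matrix(rnorm(n * 3), n, 3,
                dimnames = list(NULL, c("vol", "h", "a")))
    yz <- 1.0 * scale(X[, "vol"])[, 1] + rnorm(n, 0, 0.5)
    rep1 <- multipleLinregStandardized(X, yz)
    cf <- rep1@coefficients
    i <- cf$term == "vol"
    # population standardized effect: 1 / sd(y) with sd(y) = sqrt(1 + 0.25)
    beta0 <- 1.0 / sqrt(1.25)
    if (cf$ciLow[i] <= beta0 && beta0 <= cf$ciHigh[i]) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.90)
})

test_that("stepwise selection finds a strong predictor and is reproducible", {
  set.seed(37)
  found <- 0L
  for (r in 1:50) {
    n <- 26
    X <- matrix(rnorm(n * 4), n, 4,
                dimnames = list(NULL, c("s", "n1", "n2", "n3")))
    y <- X[, "s"] + rnorm(n, 0, 0.4)
    sel <- stepwiseSelect(X, y)@selected
    if ("s" %in% sel) found <- found + 1L
  }
  expect_gte(found / 50, 0.95)

  # deterministic given the data
  X <- matrix(rnorm(26 * 4), 26, 4, dimnames = list(NULL, letters[1:4]))
  y <- rnorm(26)
  r1 <- stepwiseSelect(X, y); r2 <- stepwiseSelect(X, y)
  expect_identical(r1@selected, r2@selected)
  expect_identical(r1@path, r2@path)
})

test_that("all-noise predictors mostly yield an empty selection", {
  # with four independent noise predictors and p_entry 0.05, the chance that
  # none enters is about 0.95^4 ~ 0.81; assert the analytic rate with a
  # binomial margin
  set.seed(53)
  empty <- 0L
  for (r in 1:100) {
    X <- matrix(rnorm(26 * 4), 26, 4, dimnames = list(NULL, letters[1:4]))
    if (length(stepwiseSelect(X, rnorm(26))@selected) == 0L) empty <- empty + 1L
  }
  expect_gte(empty / 100, 0.70)
  # intercept-only report: empty coefficient table, full table intact
  Xn <- matrix(rnorm(26 * 2), 26, 2, dimnames = list(NULL, c("u", "v")))
  set.seed(71)
  repEmpty <- NULL
  for (k in 1:20) {
    cand <- stepwiseSelect(Xn, rnorm(26))
    if (length(cand@selected) == 0L) { repEmpty <- cand; break }
  }
  expect_false(is.null(repEmpty))
  expect_equal(nrow(repEmpty@coefficients), 0L)
  expect_equal(nrow(repEmpty@fullCoefficients), 2L)
})

test_that("AIC criterion is available and returns a valid report", {
  set.seed(61)
  X <- matrix(rnorm(30 * 3), 30, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- X[, "a"] + rnorm(30, 0, 0.5)
  rep1 <- stepwiseSelect(X, y, criterion = "AIC")
  expect_true("a" %in% rep1@selected)
  expect_s4_class(rep1, "RegressionReport")
})

test_that("the cohort generator reproduces the target population moments", {
  big <- generateCohortTable(nEyes = 2000L, seed = 5L)
  expect_lt(abs(mean(big$maxHeightMm) - 0.288) / 0.288, 0.10)
  expect_lt(abs(mean(big$pedAreaMm2) - 7.345) / 7.345, 0.10)
  expect_lt(abs(mean(big$slopeAreaRatio) - 0.713) / 0.713, 0.05)
  # planted volume -> lesion-area correlation near its target
  expect_gt(cor(big$pedVolumeMm3, big$rpe70AreaWholeMm2), 0.75)
  # mean slope-region lesion area ratio lands near the design target 0.011
  m <- mean(generateCohortTable(nEyes = 200L, seed = 9L)$rpe70RatioSlope)
  expect_lt(abs(m - 0.011) / 0.011, 0.20)
})

test_that("slope-region lesion areas dominate peak areas in the generated cohorts", {
  co <- generateCohortTable(nEyes = 26L, seed = 11L)
  res <- wilcoxonSignedRank(co$rpe70AreaSlopeMm2, co$rpe70AreaPeakMm2)
  expect_lt(res$p, 0.05)
})

test_that("analyzeCohort produces the full battery on a generated cohort", {
  co <- generateCohortTable(nEyes = 26L, seed = 21L)
  an <- analyzeCohort(co)
  expect_equal(nrow(an$summary), 10L)
  expect_equal(nrow(an$simple), 24L)                 # 6 responses x 4 predictors
  expect_length(an$stepwise, 6L)
  expect_s4_class(an$stepwise$rpe70AreaWholeMm2, "RegressionReport")
  expect_true(is.numeric(an$wilcoxonSlopeVsPeak$p))
  co$maxHeightMm[3] <- NA
  expect_error(analyzeCohort(co), "missing values")
})
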