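test_that("mutationRates follows the log-link formula", {
  fit <- tinyFit(lambda = c(g1 = 0))
  lens <- c(g1 = 1)
  expect_equal(unname(mutationRates(fit, lens, mu = 0)["g1", "other"]), 1)
  expect_equal(unname(mutationRates(fit, lens, mu = 1)["g1", "other"]),
               exp(1))

  # multiplying the length by c and subtracting log(c) from lambda leaves
  # the rate unchanged
  fit2 <- tinyFit(lambda = c(g1 = 0.7 - log(5)))
  fitb <- tinyFit(lambda = c(g1 = 0.7))
  expect_equal(mutationRates(fit2, c(g1 = 5000), mu = -2),
               mutationRates(fitb, c(g1 = 1000), mu = -2))
})

test_that("negativeLogLikelihood matches hand-computed cell values", {
  # one cell, m = 0, phi = 1: NLL = phi - m log phi = 1
  x <- tinyExperiment(matrix(0L, 1, 1), lengths = c(g1 = 1))
  fit <- tinyFit(lambda = c(g1 = 0), nu = c(other = 0),
                 eta = matrix(0, 1, 1), mu = c(s1 = 0))
  expect_equal(negativeLogLikelihood(fit, x), 1)

  # one cell, m = 2, phi = e: NLL = e - 2
  x2 <- tinyExperiment(matrix(2L, 1, 1), lengths = c(g1 = 1))
  fit2 <- tinyFit(lambda = c(g1 = 0), nu = c(other = 0),
                  eta = matrix(0, 1, 1), mu = c(s1 = 1))
  expect_equal(negativeLogLikelihood(fit2, x2), exp(1) - 2)

  # empty cell subset contributes nothing
  mask <- list(other = matrix(0, 1, 1))
  expect_equal(negativeLogLikelihood(fit2, x2, cellMask = mask), 0)

  # negative / non-integer counts are rejected at the container boundary
  expect_error(tinyExperiment(matrix(-1, 1, 1), lengths = c(g1 = 1)),
               "non-negative integers")
})

test_that("unpenalized fit matches a brute-force optimizer on a 3x4x2 case", {
  set.seed(5)
  other <- matrix(rpois(12, 6), 4, 4 - 1)
  indel <- matrix(rpois(12, 2), 4, 3)
  x <- tinyExperiment(other, indel,
                      lengths = setNames(c(800, 1500, 400, 2500),
                                         sprintf("g%d", 1:4)))
  fit <- fitGenerativeModel(x, kappa1 = 0,
                            config = fitConfig(tol = 1e-12, maxIter = 5000))
  oracle <- oracleNLLFit(x, kappa1 = 0)
  ours <- negativeLogLikelihood(fit, x)
  expect_lt(abs(ours - oracle$value), 1e-5 * abs(oracle$value))
  expect_lte(ours, oracle$value + 1e-6)  # we never do worse than BFGS
})

test_that("full shrinkage recovers the two-factor model exactly", {
  set.seed(8)
  other <- matrix(rpois(30, 5), 6, 5)
  indel <- matrix(rpois(30, 1), 6, 5)
  x <- tinyExperiment(other, indel,
                      lengths = setNames(500 + 200 * (1:6),
                                         sprintf("g%d", 1:6)))
  fit <- fitGenerativeModel(x, kappa1 = 1e6,
                            config = fitConfig(tol = 1e-12, maxIter = 5000))
  expect_true(all(fit@lambda == 0))
  expect_true(all(fit@eta == 0))
  oracle <- oracleNLLFit(x, lambdaEta = FALSE)
  expect_equal(unname(fit@mu), unname(oracle$mu), tolerance = 1e-4)
  expect_equal(unname(fit@nu["indel"]), unname(oracle$nu["indel"]),
               tolerance = 1e-4)
})

test_that("null gene effects are zeroed exactly, never merely small", {
  cfg <- syntheticConfig(nSamples = 80, nGenes = 40, lambdaSparsity = 0,
                         etaSparsity = 0, seed = 13)
  model <- sampleParams(cfg)
  x <- sampleCounts(model@params, model@geneLengths, seed = 14)
  cv <- crossValidateKappa1(x, fitConfig(gridLength = 10, nFolds = 5))

  # above the full-shrinkage bound the null model is recovered exactly
  fitHi <- fitGenerativeModel(x, kappa1 = 1.2 * max(cv@kappa1Grid))
  expect_true(all(fitHi@lambda == 0) && all(fitHi@eta == 0))
  expect_equal(unname(sparsityReport(fitHi)), c(1, 1))

  # at the CV-selected penalty on null data the estimates are overwhelmingly
  # exact zeros (soft-thresholding), with only small noise survivors
  fitCV <- fitGenerativeModel(x, kappa1 = cv@selectedKappa1)
  expect_gte(mean(fitCV@lambda == 0), 0.8)
  expect_true(all(abs(fitCV@lambda) < 0.25))
  expect_gte(mean(fitCV@eta[, "indel"] == 0), 0.8)
})

test_that("penalized objective is non-increasing across sweeps", {
  co <- smallSyntheticCohort(nSamples = 30, nGenes = 25, seed = 17)
  for (k in c(0, 5, 50)) {
    fit <- fitGenerativeModel(co$counts, kappa1 = k)
    tr <- fit@convergence$objective
    expect_true(all(diff(tr) <= 1e-8 * (abs(tr[-length(tr)]) + 1)))
  }
})

test_that("fitted coordinates satisfy the soft-threshold KKT conditions", {
  co <- smallSyntheticCohort(nSamples = 50, nGenes = 30, seed = 19)
  kappa1 <- 8
  fit <- fitGenerativeModel(co$counts, kappa1 = kappa1,
                            config = fitConfig(tol = 1e-12, maxIter = 2000))
  # partial objective in lambda_g has the form a*e^x - b*x + kappa|x|
  lens <- geneLengths(co$counts)
  b <- rowSums(assay(co$counts, "other")) + rowSums(assay(co$counts, "indel"))
  emu <- exp(fit@mu)
  a <- lens * exp(fit@nu["other"] + fit@eta[, "other"]) * sum(emu) +
    lens * exp(fit@nu["indel"] + fit@eta[, "indel"]) * sum(emu)
  grad <- a * exp(fit@lambda) - b
  zero <- fit@lambda == 0
  expect_true(any(zero) && any(!zero))
  expect_true(all(abs(grad[zero]) <= kappa1 + 1e-4))
  expect_true(all(abs(grad[!zero] + kappa1 * sign(fit@lambda[!zero]))
                  <= 1e-4 * (abs(b[!zero]) + 1)))
})

test_that("cell-wise cross-validation partitions cells and selects kappa1", {
  co <- smallSyntheticCohort(nSamples = 30, nGenes = 20, seed = 23)
  cfg <- fitConfig(kappa1Grid = c(40, 10, 2), nFolds = 5, seed = 2)
  cv <- crossValidateKappa1(co$counts, cfg)
  # partition contract: every cell in exactly one fold, sizes within 1
  expect_equal(sum(cv@foldSizes), 30 * 20 * 2)
  expect_lte(diff(range(cv@foldSizes)), 1L)
  expect_true(cv@selectedKappa1 %in% cv@kappa1Grid)
  expect_equal(cv@selectedKappa1,
               cv@kappa1Grid[which.min(cv@meanDeviance)])

  # single-value grid is selected trivially
  cv1 <- crossValidateKappa1(co$counts,
                             fitConfig(kappa1Grid = 3, nFolds = 4))
  expect_equal(cv1@selectedKappa1, 3)

  # deterministic under the seed
  cv2 <- crossValidateKappa1(co$counts, cfg)
  expect_identical(cv@meanDeviance, cv2@meanDeviance)
})

test_that("strong sparse signal pulls the selected penalty off the bound", {
  cfg <- syntheticConfig(nSamples = 60, nGenes = 50, lambdaSparsity = 0.2,
                         lambdaScale = 1.5, seed = 29)
  model <- sampleParams(cfg)
  x <- sampleCounts(model@params, model@geneLengths, seed = 30)
  cv <- crossValidateKappa1(x, fitConfig(gridLength = 8, nFolds = 5))
  expect_lt(cv@selectedKappa1, max(cv@kappa1Grid))
})

test_that("sparsity report counts exact zeros", {
  fit <- tinyFit(lambda = c(g1 = 0, g2 = 1.2, g3 = 0, g4 = -0.5))
  expect_equal(unname(sparsityReport(fit)["lambda"]), 0.5)
  fit0 <- tinyFit(lambda = c(g1 = 0, g2 = 0))
  expect_equal(unname(sparsityReport(fit0)), c(1, 1))
})

test_that("generative fits round-trip through JSON", {
  co <- smallSyntheticCohort(nSamples = 10, nGenes = 8, seed = 31)
  fit <- fitGenerativeModel(co$counts, kappa1 = 2)
  path <- withr::local_tempfile(fileext = ".json")
  writeGenerativeFit(fit, path)
  back <- readGenerativeFit(path)
  expect_equal(back@mu, fit@mu)
  expect_equal(back@lambda, fit@lambda)
  expect_equal(back@nu, fit@nu)
  expect_equal(back@eta, fit@eta)
  expect_equal(back@kappa1, fit@kappa1)
})

test_that("degenerate inputs are clipped or refused with diagnostics", {
  x0 <- tinyExperiment(matrix(0L, 3, 2), matrix(0L, 3, 2))
  expect_warning(fit <- fitGenerativeModel(x0, kappa1 = 1), "floor")
  expect_true(all(is.finite(fit@mu)))

  co <- smallSyntheticCohort(nSamples = 6, nGenes = 5, seed = 37)
  mask <- list(other = matrix(1, 5, 6), indel = matrix(0, 5, 6))
  expect_error(fitGenerativeModel(co$counts, kappa1 = 1, cellMask = mask),
               "no cells")
})
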