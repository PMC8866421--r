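test_that("normalizedRates rescales expected rates to unit target mass", {
  # flat parameters, equal lengths: uniform over all cells
  fit <- tinyFit(lambda = setNames(rep(0, 4), sprintf("g%d", 1:4)),
                 nu = c(other = 0, indel = 0),
                 eta = matrix(0, 4, 2))
  lens <- setNames(rep(1000, 4), sprintf("g%d", 1:4))
  r <- normalizedRates(fit, lens, tmbSpec())
  expect_equal(unname(r@p), matrix(1 / 8, 4, 2), tolerance = 1e-12)

  # two genes with lengths 1 and 2, one group: p = (1/3, 2/3)
  fit1 <- tinyFit(lambda = c(g1 = 0, g2 = 0), nu = c(other = 0),
                  eta = matrix(0, 2, 1))
  r1 <- normalizedRates(fit1, c(g1 = 1, g2 = 2),
                        BiomarkerSpec("T", "other"))
  expect_equal(unname(r1@p[, 1]), c(1 / 3, 2 / 3))

  # normalization holds for arbitrary parameters, and is mu-free
  fx <- panelFixture(seed = 11, nGenes = 12)
  expect_equal(sum(fx$rates@p[, fx$rates@targetGroups]), 1)
  expect_gt(min(fx$rates@p), 0)
  # TIB rates renormalize over the indel column only
  rTib <- normalizedRates(fx$fit, fx$lens, tibSpec())
  expect_equal(sum(rTib@p[, "indel"]), 1)
})

test_that("biasPenaltyK scales as exp(mu0) and honours the Inf sentinel", {
  fx <- panelFixture()
  K1 <- biasPenaltyK(fx$fit, fx$lens, fx$spec, mu0 = 0.3)
  K2 <- biasPenaltyK(fx$fit, fx$lens, fx$spec, mu0 = 0.3 + log(2))
  expect_equal(K2, 2 * K1)
  expect_identical(biasPenaltyK(fx$fit, fx$lens, fx$spec, Inf), Inf)
  # K(mu0) is the expected biomarker of a sample with that background rate
  base <- mutationRates(fx$fit, fx$lens, mu = 0.3)
  expect_equal(K1, sum(base[, fx$spec@targetGroups]))
})

test_that("recommendedK equals K at the max training pseudo-MLE", {
  co <- smallSyntheticCohort(seed = 41)
  fit <- fitGenerativeModel(co$counts, kappa1 = 3)
  spec <- tmbSpec()
  lens <- co$model@geneLengths
  Ti <- biomarkerValues(co$counts, spec)
  muHat <- pseudoMleMu(Ti, fit, lens, spec)
  expect_equal(recommendedK(fit, co$counts, lens, spec),
               biasPenaltyK(fit, lens, spec, max(muHat)))
})

test_that("objectiveF matches its exact identities and the MSE rescaling", {
  fx <- panelFixture()
  p <- fx$rates@p
  wIdent <- matrix(0, nrow(p), ncol(p), dimnames = dimnames(p))
  wIdent[, fx$spec@targetGroups] <- 1
  expect_equal(objectiveF(wIdent, fx$rates), 0)
  w0 <- wIdent * 0
  expect_equal(objectiveF(w0, fx$rates), 1 + fx$K)

  # second implementation path: f(w) = model MSE / K at matching mu0
  set.seed(2)
  w <- matrix(rnorm(length(p)), nrow(p), dimnames = dimnames(p))
  f <- objectiveF(w, fx$rates)
  mse <- modelMSE(w, fx$fit, fx$lens, fx$spec, mu0 = 1.5)
  expect_equal(f, mse / fx$K, tolerance = 1e-10)
})

test_that("firstFit solves the exact zero-penalty and full-shrinkage cases", {
  fx <- panelFixture()
  ident <- firstFit(fx$rates, fx$lens, kappa2 = 0)
  wIdent <- matrix(0, 5, 2, dimnames = dimnames(fx$rates@p))
  wIdent[, fx$spec@targetGroups] <- 1
  expect_equal(ident@weights, wIdent, tolerance = 1e-6)

  km <- kappa2Max(fx$rates, fx$lens)
  shrunk <- firstFit(fx$rates, fx$lens, kappa2 = km * 1.01)
  expect_true(all(shrunk@weights == 0))
  expect_equal(length(panelGenes(panelOf(shrunk, fx$lens))), 0L)
  notQuite <- firstFit(fx$rates, fx$lens, kappa2 = km * 0.8)
  expect_gt(sum(abs(notQuite@weights)), 0)
})

test_that("firstFit agrees with a brute-force proximal-gradient oracle", {
  fx <- panelFixture()
  km <- kappa2Max(fx$rates, fx$lens)
  for (k2 in km * c(0.5, 0.1, 0.01)) {
    ours <- firstFit(fx$rates, fx$lens, kappa2 = k2)
    oracle <- oracleGroupLasso(fx$rates, fx$lens, kappa2 = k2)
    expect_lt(abs(ours@objective - oracle$objective),
              1e-6 * (abs(oracle$objective) + 1e-12))
  }
})

test_that("include genes escape the penalty and exclude genes are pinned", {
  fx <- panelFixture()
  km <- kappa2Max(fx$rates, fx$lens)
  ft <- firstFit(fx$rates, fx$lens, kappa2 = km * 0.3,
                 include = "g2", exclude = "g4")
  expect_true(all(ft@weights["g4", ] == 0))
  expect_gt(sqrt(sum(ft@weights["g2", ]^2)), 0)
  expect_error(firstFit(fx$rates, fx$lens, 1, include = "g1",
                        exclude = "g1"), "disjoint")

  # augmentation consistency: a huge penalty shrinks the panel to exactly P0
  ftBig <- firstFit(fx$rates, fx$lens, kappa2 = km * 50, include = "g2")
  expect_equal(panelGenes(panelOf(ftBig, fx$lens)), "g2")
})

test_that("first-fit solutions are unique across warm starts", {
  fx <- panelFixture(seed = 9, nGenes = 8)
  km <- kappa2Max(fx$rates, fx$lens)
  set.seed(1)
  init <- matrix(rnorm(16, 0, 2), 8, 2, dimnames = dimnames(fx$rates@p))
  a <- firstFit(fx$rates, fx$lens, kappa2 = km * 0.2)
  b <- firstFit(fx$rates, fx$lens, kappa2 = km * 0.2, init = init)
  expect_lt(max(abs(a@weights - b@weights)), 1e-6)
})

test_that("panelOf extracts the support and its length", {
  lens <- c(g1 = 100, g2 = 200, g3 = 300)
  w <- matrix(0, 3, 2, dimnames = list(names(lens), c("other", "indel")))
  expect_equal(length(panelGenes(panelOf(w, lens))), 0L)
  expect_equal(panelLength(panelOf(w, lens)), 0)
  w["g1", "other"] <- 0.5
  w["g3", "indel"] <- -0.1
  pan <- panelOf(w, lens)
  expect_setequal(panelGenes(pan), c("g1", "g3"))
  expect_equal(panelLength(pan), 400)
  # panel length is the group-support cost norm by construction
  expect_equal(panelLength(pan),
               sum(lens * (sqrt(rowSums(w^2)) > 0)))
})

test_that("refitWeights attains the restricted optimum in closed form", {
  fx <- panelFixture()
  # full panel recovers the identity weights and f = 0
  full <- refitWeights(fx$rates, GenePanel(names(fx$lens), fx$lens))
  wIdent <- matrix(0, 5, 2, dimnames = dimnames(fx$rates@p))
  wIdent[, fx$spec@targetGroups] <- 1
  expect_equal(full@weights, wIdent, tolerance = 1e-12)
  expect_equal(full@objective, 0, tolerance = 1e-12)

  expect_warning(empty <- refitWeights(fx$rates, GenePanel(character(),
                                                           fx$lens)),
                 "empty panel")
  expect_true(all(empty@weights == 0))
  expect_equal(empty@objective, 1 + fx$K)

  # 3-gene support: per-coordinate agreement with a generic optimizer of f
  pan <- GenePanel(c("g1", "g3", "g5"), fx$lens)
  rf <- refitWeights(fx$rates, pan)
  sel <- rownames(fx$rates@p) %in% panelGenes(pan)
  obj <- function(v) {
    w <- matrix(0, 5, 2, dimnames = dimnames(fx$rates@p))
    w[sel, ] <- v
    objectiveF(w, fx$rates)
  }
  opt <- optim(rep(0, 6), obj, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 2000))
  expect_equal(as.numeric(rf@weights[sel, ]), opt$par, tolerance = 1e-4)
  expect_lte(rf@objective, opt$value + 1e-10)

  # KKT: gradient of f vanishes on the support
  g <- fGradient(rf@weights, fx$rates)
  expect_lt(max(abs(g[sel, ])), 1e-8)
})

test_that("refit never increases f and the K = Inf refit is unbiased", {
  fx <- panelFixture(seed = 13, nGenes = 10)
  km <- kappa2Max(fx$rates, fx$lens)
  ft <- firstFit(fx$rates, fx$lens, kappa2 = km * 0.1)
  pan <- panelOf(ft, fx$lens)
  rf <- refitWeights(fx$rates, pan)
  expect_lte(objectiveF(rf@weights, fx$rates),
             objectiveF(ft@weights, fx$rates) + 1e-12)

  ratesInf <- normalizedRates(fx$fit, fx$lens, fx$spec, K = Inf)
  rfInf <- refitWeights(ratesInf, pan)
  expect_lt(abs(sum(ratesInf@p * rfInf@weights) - 1), 1e-10)
})

test_that("kappa2ForLength maps budgets to panels within the grid rule", {
  fx <- panelFixture(seed = 19, nGenes = 12)
  lensTotal <- sum(fx$lens)
  grid <- kappa2Grid(fx$rates, fx$lens, gridLength = 40L)

  # zero budget: empty panel at the largest grid value
  sel0 <- kappa2ForLength(fx$rates, fx$lens, L = 0, grid = grid)
  expect_equal(length(panelGenes(sel0$panel)), 0L)
  expect_equal(sel0$kappa2, max(sel0$path$kappa2))

  # unconstrained budget with a deep grid: the full panel is reached and
  # the selection settles on the largest penalty attaining it
  deepGrid <- kappa2Grid(fx$rates, fx$lens, gridLength = 40L,
                         gridDecades = 8)
  selAll <- kappa2ForLength(fx$rates, fx$lens, L = lensTotal,
                            grid = deepGrid)
  expect_equal(panelLength(selAll$panel), lensTotal)

  # half budget: within budget, and no better grid value exists
  selHalf <- kappa2ForLength(fx$rates, fx$lens, L = lensTotal / 2,
                             grid = grid)
  expect_lte(panelLength(selHalf$panel), lensTotal / 2)
  path <- selHalf$path
  inBudget <- path$panelLength <= lensTotal / 2
  expect_equal(panelLength(selHalf$panel), max(path$panelLength[inBudget]))
  # tie rule: among maximal in-budget lengths, the largest penalty wins
  best <- path$kappa2[inBudget &
                        path$panelLength == max(path$panelLength[inBudget])]
  expect_equal(selHalf$kappa2, max(best))

  # the reported panel-length path is non-decreasing as the penalty drops
  expect_true(all(diff(path$panelLength) >= 0))

  # budgets below the mandatory panel are refused
  expect_error(kappa2ForLength(fx$rates, fx$lens, L = 1, include = "g1"),
               "mandatory")
})

test_that("panels write to gene lists and BED", {
  lens <- c(TP53 = 1182, KRAS = 567)
  pan <- GenePanel(c("TP53", "KRAS"), lens)
  path <- withr::local_tempfile(fileext = ".txt")
  writePanel(pan, path)
  expect_equal(panelGenes(readPanel(path, lens)), c("TP53", "KRAS"))

  coords <- data.frame(gene = c("TP53", "KRAS"), chrom = c("chr17", "chr12"),
                       start = c(7668402, 25205246), end = c(7687550, 25250929))
  bed <- withr::local_tempfile(fileext = ".bed")
  writePanelBed(pan, coords, bed)
  out <- read.table(bed, sep = "\t")
  expect_equal(out$V2, coords$start[match(out$V4, coords$gene)] - 1L)
  expect_equal(out$V3, coords$end[match(out$V4, coords$gene)])
})
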