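## Fixture builders and independent oracles shared by the test files.
## Everything is generated in code; no binary fixtures.

suppressPackageStartupMessages(library(SummarizedExperiment))

# A tiny MutationExperiment from explicit per-group count matrices.
tinyExperiment <- function(other, indel = NULL, lengths = NULL,
                           genes = NULL, samples = NULL) {
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(other)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(other)))
  dimnames(other) <- list(genes, samples)
  counts <- list(other = other)
  if (!is.null(indel)) {
    dimnames(indel) <- list(genes, samples)
    counts$indel <- indel
  }
  if (is.null(lengths)) lengths <- setNames(rep(1000, length(genes)), genes)
  MutationExperiment(counts, lengths, referenceGroup = "other")
}

# A deterministic GenerativeFit with explicit parameters.
tinyFit <- function(lambda, nu = c(other = 0, indel = 0),
                    eta = NULL, mu = c(s1 = 0),
                    genes = names(lambda), referenceGroup = "other") {
  if (is.null(names(lambda))) {
    genes <- sprintf("g%d", seq_along(lambda))
    names(lambda) <- genes
  }
  if (is.null(eta)) {
    eta <- matrix(0, length(lambda), length(nu),
                  dimnames = list(genes, names(nu)))
  } else {
    dimnames(eta) <- list(genes, names(nu))
  }
  new("GenerativeFit",
    mu = mu, lambda = lambda, nu = nu, eta = eta,
    referenceGroup = referenceGroup, kappa1 = NA_real_, convergence = list()
  )
}

# The three-row MAF fixture: two missense and one frameshift deletion in
# gene GA of sample S1 (plus a header).
writeThreeRowMAF <- function(path, extraRows = NULL) {
  rows <- data.frame(
    Hugo_Symbol = c("GA", "GA", "GA"),
    Tumor_Sample_Barcode = c("S1", "S1", "S1"),
    Variant_Classification = c("Missense_Mutation", "Missense_Mutation",
                               "Frame_Shift_Del"),
    stringsAsFactors = FALSE
  )
  if (!is.null(extraRows)) rows <- rbind(rows, extraRows)
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Independent oracle for the group lasso: plain (unaccelerated) proximal
# gradient with a fixed 1/L step, run to a tiny successive-change gap.
# Deliberately shares no code with firstFit().
oracleGroupLasso <- function(rates, geneLengths, kappa2,
                             include = character(), exclude = character(),
                             gap = 1e-10, maxIter = 2e5) {
  p <- rates@p
  K <- rates@K
  tmat <- matrix(0, nrow(p), ncol(p), dimnames = dimnames(p))
  tmat[, rates@targetGroups] <- 1
  lens <- geneLengths[rownames(p)]
  pen <- ifelse(rownames(p) %in% include, 0, lens)
  excl <- rownames(p) %in% exclude
  step <- 1 / (2 * max(p) + 2 * K * sum(p^2))
  w <- matrix(0, nrow(p), ncol(p), dimnames = dimnames(p))
  obj <- function(w) {
    sum(p * (w - tmat)^2) + K * (1 - sum(p * w))^2 +
      kappa2 * sum(pen * sqrt(rowSums(w^2)))
  }
  Fprev <- obj(w)
  for (it in seq_len(maxIter)) {
    g <- 2 * p * (w - tmat) + 2 * K * (sum(p * w) - 1) * p
    w <- w - step * g
    w[excl, ] <- 0
    nrm <- sqrt(rowSums(w^2))
    sh <- ifelse(nrm > 0, pmax(0, 1 - step * kappa2 * pen / nrm), 0)
    sh[pen == 0] <- 1
    w <- w * sh
    Fnew <- obj(w)
    if (abs(Fprev - Fnew) <= gap * (abs(Fprev) + 1e-15)) break
    Fprev <- Fnew
  }
  list(weights = w, objective = Fnew)
}

# Brute-force minimizer of the (optionally penalized) Poisson NLL via a
# generic smooth optimizer on the identifiable parameter vector.  Only
# valid for kappa1 = 0 (smooth) or as the unpenalized two-factor model
# when lambdaEta = FALSE.
oracleNLLFit <- function(x, kappa1 = 0, lambdaEta = TRUE, reltol = 1e-12) {
  groups <- variantGroups(x)
  ref <- referenceGroup(x)
  free <- setdiff(groups, ref)
  M <- lapply(groups, function(s) SummarizedExperiment::assay(x, s))
  names(M) <- groups
  lens <- geneLengths(x)
  n <- ncol(x); G <- nrow(x)
  unpack <- function(par) {
    mu <- par[seq_len(n)]
    k <- n
    nuv <- setNames(rep(0, length(groups)), groups)
    nuv[free] <- par[k + seq_along(free)]; k <- k + length(free)
    if (lambdaEta) {
      lam <- par[k + seq_len(G)]; k <- k + G
      eta <- matrix(0, G, length(groups), dimnames = list(rownames(x), groups))
      for (s in free) { eta[, s] <- par[k + seq_len(G)]; k <- k + G }
    } else {
      lam <- rep(0, G)
      eta <- matrix(0, G, length(groups), dimnames = list(rownames(x), groups))
    }
    list(mu = mu, nu = nuv, lambda = lam, eta = eta)
  }
  fn <- function(par) {
    pp <- unpack(par)
    val <- 0
    for (s in groups) {
      lphi <- outer(log(lens) + pp$lambda + pp$nu[s] + pp$eta[, s], pp$mu, `+`)
      val <- val + sum(exp(lphi)) - sum(M[[s]] * lphi)
    }
    val + kappa1 * (sum(abs(pp$lambda)) + sum(abs(pp$eta)))
  }
  npar <- n + length(free) + if (lambdaEta) G * length(groups) else 0
  opt <- optim(rep(0, npar), fn, method = "BFGS",
               control = list(maxit = 5000, reltol = reltol))
  c(unpack(opt$par), value = opt$value)
}

# Model-based expected squared error computed term by term from the
# variance/bias decomposition (independent of modelMSE's single formula).
oracleMSEDecomposition <- function(w, fit, geneLengths, spec, mu0) {
  phi <- mutationRates(fit, geneLengths, mu = mu0)
  tg <- spec@targetGroups
  varTw <- sum(w^2 * phi)
  varT <- sum(phi[, tg, drop = FALSE])
  covTwT <- sum(w[, tg, drop = FALSE] * phi[, tg, drop = FALSE])
  bias <- sum(w * phi) - sum(phi[, tg, drop = FALSE])
  varTw + varT - 2 * covTwT + bias^2
}

# Gradient of the estimator objective f on a refit support (for KKT checks).
fGradient <- function(w, rates) {
  tmat <- matrix(0, nrow(rates@p), ncol(rates@p), dimnames = dimnames(rates@p))
  tmat[, rates@targetGroups] <- 1
  2 * rates@p * (w - tmat) + 2 * rates@K * (sum(rates@p * w) - 1) * rates@p
}

# A reusable small fitted panel-selection instance: nGenes genes, 2 groups.
panelFixture <- function(seed = 3, nGenes = 5) {
  set.seed(seed)
  genes <- sprintf("g%d", seq_len(nGenes))
  lens <- setNames(round(runif(nGenes, 300, 3000)), genes)
  fit <- tinyFit(
    lambda = setNames(rnorm(nGenes, 0, 0.8), genes),
    nu = c(other = 0, indel = -2),
    eta = matrix(c(rep(0, nGenes), rnorm(nGenes, 0, 0.5)), nGenes, 2),
    mu = c(s1 = 4)
  )
  spec <- tmbSpec()
  K <- biasPenaltyK(fit, lens, spec, mu0 = 1.5)
  list(fit = fit, lens = lens, spec = spec,
       rates = normalizedRates(fit, lens, spec, K = K), K = K)
}

# Small synthetic model + counts shared by several files (cheap).
smallSyntheticCohort <- function(nSamples = 40, nGenes = 60, seed = 7) {
  cfg <- syntheticConfig(nSamples = nSamples, nGenes = nGenes, seed = seed)
  model <- sampleParams(cfg)
  counts <- sampleCounts(model@params, model@geneLengths, seed = seed + 1L)
  list(model = model, counts = counts)
}
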