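#' @include AllClasses.R AllGenerics.R mutation-data.R utils.R
NULL

#' Cross-validation result for the generative-model penalty
#'
#' @slot kappa1Grid decreasing penalty grid.
#' @slot foldDeviance folds x grid matrix of mean held-out Poisson deviance
#'   per cell.
#' @slot meanDeviance per-grid-value mean deviance across folds.
#' @slot selectedKappa1 grid value attaining the minimum (ties go to the
#'   larger penalty).
#' @slot foldSizes number of held-out cells per fold (a uniform partition:
#'   sizes differ by at most one).
#' @slot nFolds,seed fold count and RNG seed of the cell partition.
#' @export
setClass("CVResult",
  representation(
    kappa1Grid = "numeric",
    foldDeviance = "matrix",
    meanDeviance = "numeric",
    selectedKappa1 = "numeric",
    foldSizes = "integer",
    nFolds = "integer",
    seed = "integer"
  )
)

setMethod("show", "CVResult", function(object) {
  cat(sprintf(
    "CVResult: %d-fold cell-wise CV over %d kappa1 values; selected %.4g\n",
    object@nFolds, length(object@kappa1Grid), object@selectedKappa1
  ))
})

#' Fit configuration for the penalized Poisson model
#'
#' @param kappa1Grid decreasing positive penalty grid, or `NULL` to build a
#'   log-spaced grid from the full-shrinkage threshold down `gridDecades`
#'   decades.
#' @param gridLength,gridDecades size and span of the automatic grid.
#' @param nFolds folds for cell-wise cross-validation (>= 2).
#' @param seed RNG seed for the fold partition.
#' @param tol relative objective-change convergence tolerance.
#' @param maxIter coordinate-descent sweep cap.
#' @param muFloor lower clip for unpenalized log-rate parameters whose
#'   unconstrained optimum is -Inf (zero observed counts).
#' @return a validated configuration list.
#' @export
fitConfig <- function(kappa1Grid = NULL, gridLength = 50L, gridDecades = 4,
                      nFolds = 10L, seed = 1L, tol = 1e-8, maxIter = 500L,
                      muFloor = -30) {
  if (!is.null(kappa1Grid)) {
    stopIfNot(length(kappa1Grid) >= 1L && all(kappa1Grid >= 0) &&
                !is.unsorted(rev(kappa1Grid)),
              "kappa1Grid must be a decreasing non-negative sequence")
  }
  stopIfNot(nFolds >= 2L, "nFolds must be at least 2")
  list(
    kappa1Grid = kappa1Grid, gridLength = as.integer(gridLength),
    gridDecades = gridDecades, nFolds = as.integer(nFolds),
    seed = as.integer(seed), tol = tol, maxIter = as.integer(maxIter),
    muFloor = muFloor
  )
}

## ---- internal fitting engine ---------------------------------------------
## All matrices are genes x samples, one per variant group, matching the
## MutationExperiment assay layout. `W` is an optional 0/1 cell mask of the
## same shape (1 = cell participates in the fit).

.tensorPieces <- function(x, cellMask = NULL) {
  groups <- variantGroups(x)
  M <- lapply(groups, function(s) assay(x, s))
  names(M) <- groups
  if (is.null(cellMask)) {
    W <- lapply(M, function(m) matrix(1, nrow(m), ncol(m)))
  } else {
    stopIfNot(identical(sort(names(cellMask)), sort(groups)),
              "cellMask must have one matrix per variant group")
    W <- cellMask[groups]
  }
  for (s in groups) {
    m <- M[[s]]
    if (any(m < 0) || any(m != round(m))) {
      stop("counts must be non-negative integers")
    }
  }
  list(
    M = M, W = W, groups = groups, lens = geneLengths(x),
    genes = rownames(x), samples = colnames(x),
    refGroup = referenceGroup(x)
  )
}

# exact block-coordinate descent on NLL + kappa1*(sum|lambda| + sum|eta|)
# with nu[ref] = 0, eta[, ref] = 0.  Each block's partial objective has the
# form a*exp(x) - b*x (+ kappa|x|), minimized in closed form.
.fitEngine <- function(tp, kappa1, tol = 1e-8, maxIter = 500L,
                       muFloor = -30, init = NULL) {
  M <- tp$M; W <- tp$W; groups <- tp$groups; lens <- tp$lens
  nG <- length(tp$genes); nS <- length(groups); n <- length(tp$samples)
  ref <- tp$refGroup
  free <- setdiff(groups, ref)

  bMu <- rep(0, n); bLam <- rep(0, nG)
  bNu <- numeric(0); bEta <- list()
  for (s in groups) {
    wm <- W[[s]] * M[[s]]
    bMu <- bMu + colSums(wm)
    bLam <- bLam + rowSums(wm)
    bEta[[s]] <- rowSums(wm)
    bNu[s] <- sum(wm)
  }
  wTot <- vapply(W, sum, numeric(1))
  if (any(colSums(Reduce(`+`, W)) == 0)) {
    stop("a sample has no cells in the fitting set; mu is not estimable")
  }
  if (any(wTot == 0)) {
    stop("a variant group has no cells in the fitting set; nu is not estimable")
  }

  if (is.null(init)) {
    mu <- rep(0, n); lambda <- rep(0, nG)
    nu <- stats::setNames(rep(0, nS), groups)
    eta <- matrix(0, nG, nS, dimnames = list(tp$genes, groups))
  } else {
    mu <- init$mu; lambda <- init$lambda; nu <- init$nu; eta <- init$eta
  }

  rmat <- function() {
    out <- matrix(0, nG, nS, dimnames = list(tp$genes, groups))
    for (s in groups) out[, s] <- lens * exp(lambda + nu[s] + eta[, s])
    out
  }
  objective <- function(r) {
    nll <- 0
    for (s in groups) {
      lp <- log(r[, s]) # + mu per column
      nll <- nll + sum(W[[s]] * (r[, s] %o% exp(mu))) -
        sum((W[[s]] * M[[s]]) * outer(lp, mu, `+`))
    }
    nll + kappa1 * (sum(abs(lambda)) + sum(abs(eta)))
  }

  r <- rmat()
  trace <- objective(r)
  converged <- FALSE
  flooredAny <- FALSE
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    ## mu block
    aMu <- rep(0, n)
    for (s in groups) aMu <- aMu + colSums(W[[s]] * r[, s])
    mu <- log(bMu / aMu)
    if (any(mu < muFloor)) { flooredAny <- TRUE; mu[mu < muFloor] <- muFloor }
    emu <- exp(mu)
    cgs <- vapply(groups, function(s) as.numeric(W[[s]] %*% emu),
                  numeric(nG))
    colnames(cgs) <- groups
    ## nu block (reference pinned at 0)
    for (s in free) {
      aNu <- sum(cgs[, s] * lens * exp(lambda + eta[, s]))
      nu[s] <- max(log(bNu[s] / aNu), muFloor)
    }
    ## lambda block
    aLam <- rep(0, nG)
    for (s in groups) aLam <- aLam + cgs[, s] * lens * exp(nu[s] + eta[, s])
    lambda <- softLogRatio(aLam, bLam, kappa1)
    if (any(lambda < muFloor)) {
      flooredAny <- TRUE; lambda[lambda < muFloor] <- muFloor
    }
    ## eta block (reference column pinned at 0)
    for (s in free) {
      aEta <- cgs[, s] * lens * exp(lambda + nu[s])
      e <- softLogRatio(aEta, bEta[[s]], kappa1)
      e[e < muFloor] <- muFloor
      eta[, s] <- e
    }
    r <- rmat()
    obj <- objective(r)
    trace <- c(trace, obj)
    prev <- trace[length(trace) - 1L]
    if (abs(prev - obj) <= tol * (abs(prev) + 1e-12)) {
      converged <- TRUE
      break
    }
  }
  if (flooredAny) {
    warning("some log-rate parameters hit the floor (", muFloor,
            "); zero observed counts in their cells")
  }
  if (!converged) {
    warning("coordinate descent stopped at maxIter = ", maxIter,
            " without meeting tol")
  }
  names(mu) <- tp$samples; names(lambda) <- tp$genes
  list(mu = mu, lambda = lambda, nu = nu, eta = eta,
       iterations = it, converged = converged, trace = trace)
}

# full-shrinkage threshold: smallest kappa1 at which lambda = eta = 0 solves
# the penalized problem (max |NLL gradient| over the penalized coordinates at
# the two-factor null fit).
.kappa1Max <- function(tp, tol = 1e-10, maxIter = 2000L, muFloor = -30) {
  groups <- tp$groups; lens <- tp$lens
  nG <- length(tp$genes); n <- length(tp$samples)
  ref <- tp$refGroup; free <- setdiff(groups, ref)
  M <- tp$M; W <- tp$W
  bMu <- rep(0, n); bNu <- numeric(0)
  for (s in groups) {
    wm <- W[[s]] * M[[s]]
    bMu <- bMu + colSums(wm); bNu[s] <- sum(wm)
  }
  mu <- rep(0, n); nu <- stats::setNames(rep(0, length(groups)), groups)
  for (it in seq_len(maxIter)) {
    aMu <- rep(0, n)
    for (s in groups) aMu <- aMu + colSums(W[[s]] * (lens * exp(nu[s])))
    muNew <- pmax(log(bMu / aMu), muFloor)
    emu <- exp(muNew)
    nuNew <- nu
    for (s in free) {
      aNu <- sum((W[[s]] %*% emu) * lens)
      nuNew[s] <- max(log(bNu[s] / aNu), muFloor)
    }
    if (max(abs(c(muNew - mu, nuNew - nu))) < tol) {
      mu <- muNew; nu <- nuNew; break
    }
    mu <- muNew; nu <- nuNew
  }
  emu <- exp(mu)
  grad <- numeric(0)
  aLam <- rep(0, nG); bLam <- rep(0, nG)
  for (s in groups) {
    cg <- as.numeric(W[[s]] %*% emu)
    a <- cg * lens * exp(nu[s])
    b <- rowSums(W[[s]] * M[[s]])
    aLam <- aLam + a; bLam <- bLam + b
    if (s != ref) grad <- c(grad, abs(a - b))
  }
  grad <- c(grad, abs(aLam - bLam))
  list(kappaMax = max(grad), mu = mu, nu = nu)
}

.autoGrid <- function(tp, config) {
  km <- .kappa1Max(tp, muFloor = config$muFloor)$kappaMax
  km <- max(km, .Machine$double.eps)
  exp(seq(log(km * 1.0001), log(km) - config$gridDecades * log(10),
          length.out = config$gridLength))
}

## ---- exported operations --------------------------------------------------

#' Fit the penalized Poisson generative model
#'
#' Minimizes the Poisson negative log-likelihood plus
#' \eqn{\kappa_1(\sum_g|\lambda_g| + \sum_{g,s}|\eta_{gs}|)} over the
#' identifiable parameterization (`nu` and `eta` pinned to zero at the
#' reference group; `mu`, `nu` unpenalized), by exact block-coordinate
#' descent. If `kappa1` is `NULL`, it is chosen by cell-wise
#' cross-validation ([crossValidateKappa1()]) and the model refitted on all
#' cells at the selected value.
#'
#' @param x a [MutationExperiment-class].
#' @param kappa1 L1 penalty level (>= 0), or `NULL` to cross-validate.
#' @param config a [fitConfig()] list.
#' @param cellMask optional named list (one genes-by-samples 0/1 matrix per
#'   group) restricting the fit to a subset of cells.
#' @param init optional warm start (a [GenerativeFit-class] or a list with
#'   `mu`, `lambda`, `nu`, `eta`).
#' @return a [GenerativeFit-class]; if cross-validation ran, its
#'   [CVResult-class] is stored in `convergence(fit)$cv`.
#' @export
fitGenerativeModel <- function(x, kappa1 = NULL, config = fitConfig(),
                               cellMask = NULL, init = NULL) {
  tp <- .tensorPieces(x, cellMask)
  cv <- NULL
  if (is.null(kappa1)) {
    cv <- crossValidateKappa1(x, config, cellMask = cellMask)
    kappa1 <- cv@selectedKappa1
  }
  stopIfNot(kappa1 >= 0, "kappa1 must be non-negative")
  if (is(init, "GenerativeFit")) {
    init <- list(mu = init@mu, lambda = init@lambda, nu = init@nu,
                 eta = init@eta)
  }
  res <- .fitEngine(tp, kappa1, tol = config$tol, maxIter = config$maxIter,
                    muFloor = config$muFloor, init = init)
  conv <- list(iterations = res$iterations, converged = res$converged,
               objective = res$trace)
  if (!is.null(cv)) conv$cv <- cv
  new("GenerativeFit",
    mu = res$mu, lambda = res$lambda, nu = res$nu, eta = res$eta,
    referenceGroup = tp$refGroup, kappa1 = kappa1, convergence = conv
  )
}

#' Poisson rates implied by a fit
#'
#' \eqn{\phi_{igs} = \exp(\mu_i + \log\ell_g + \lambda_g + \nu_s +
#' \eta_{gs})}. With `mu = NULL` the per-sample factor is omitted and the
#' genes-by-groups matrix \eqn{\ell_g e^{\lambda_g+\nu_s+\eta_{gs}}} is
#' returned.
#'
#' @param fit a [GenerativeFit-class].
#' @param geneLengths named numeric of coding lengths for the fitted genes.
#' @param mu optional scalar or per-sample vector of background log-rates.
#' @return genes x groups matrix (`mu` scalar/`NULL`), or a list of such
#'   matrices for vector `mu`.
#' @export
mutationRates <- function(fit, geneLengths, mu = NULL) {
  genes <- names(fit@lambda)
  stopIfNot(all(genes %in% names(geneLengths)),
            "geneLengths must cover every fitted gene")
  lens <- geneLengths[genes]
  base <- matrix(0, length(genes), length(fit@nu),
                 dimnames = list(genes, names(fit@nu)))
  for (s in names(fit@nu)) {
    base[, s] <- lens * exp(fit@lambda + fit@nu[s] + fit@eta[, s])
  }
  if (is.null(mu)) return(base)
  if (length(mu) == 1L) return(base * exp(mu))
  lapply(mu, function(m) base * exp(m))
}

#' Negative log-likelihood of the generative model
#'
#' \eqn{\sum (\phi_{igs} - m_{igs}\log\phi_{igs})} over the included cells;
#' the \eqn{\log m!} terms are constant in the parameters and omitted.
#'
#' @param fit a [GenerativeFit-class] (its `mu` must cover the samples of
#'   `x`).
#' @param x a [MutationExperiment-class].
#' @param cellMask optional 0/1 cell mask as in [fitGenerativeModel()].
#' @return a number.
#' @export
negativeLogLikelihood <- function(fit, x, cellMask = NULL) {
  tp <- .tensorPieces(x, cellMask)
  stopIfNot(all(tp$samples %in% names(fit@mu)),
            "fit does not contain mu for every sample in x")
  base <- mutationRates(fit, tp$lens)
  mu <- fit@mu[tp$samples]
  nll <- 0
  for (s in tp$groups) {
    phi <- base[tp$genes, s] %o% exp(mu)
    lp <- outer(log(base[tp$genes, s]), mu, `+`)
    nll <- nll + sum(tp$W[[s]] * phi) - sum((tp$W[[s]] * tp$M[[s]]) * lp)
  }
  nll
}

#' Cell-wise cross-validation of the L1 penalty
#'
#' Partitions the full cell set \eqn{\{(i,g,s)\}} (not the samples) uniformly
#' at random into folds. For each fold the model is fitted on the complement
#' over the penalty grid (warm-started large to small) and scored by mean
#' held-out Poisson deviance \eqn{2[m\log(m/\hat\phi) - (m - \hat\phi)]}
#' per cell (with \eqn{0\log 0 = 0} and \eqn{\hat\phi} floored at 1e-12).
#' The selected penalty minimizes the fold-averaged deviance; ties break
#' toward the larger (sparser) value.
#'
#' @inheritParams fitGenerativeModel
#' @return a [CVResult-class].
#' @export
crossValidateKappa1 <- function(x, config = fitConfig(), cellMask = NULL) {
  tp <- .tensorPieces(x, cellMask)
  grid <- config$kappa1Grid
  if (is.null(grid)) grid <- .autoGrid(tp, config)
  groups <- tp$groups
  nCells <- sum(vapply(tp$W, sum, numeric(1)))
  stopIfNot(nCells >= config$nFolds,
            "fewer cells (%d) than folds (%d)", nCells, config$nFolds)

  ## seeded uniform fold assignment over the active cells
  folds <- withSeed(config$seed, {
    lab <- sample(rep(seq_len(config$nFolds), length.out = nCells))
    out <- list(); k <- 0L
    for (s in groups) {
      f <- matrix(0L, nrow(tp$W[[s]]), ncol(tp$W[[s]]))
      act <- which(tp$W[[s]] > 0)
      f[act] <- lab[k + seq_along(act)]
      k <- k + length(act)
      out[[s]] <- f
    }
    out
  })

  dev <- matrix(NA_real_, config$nFolds, length(grid))
  for (f in seq_len(config$nFolds)) {
    Wtr <- lapply(groups, function(s) (folds[[s]] != f) * tp$W[[s]])
    names(Wtr) <- groups
    tpf <- tp; tpf$W <- Wtr
    init <- NULL
    for (j in seq_along(grid)) {
      res <- .fitEngine(tpf, grid[j], tol = config$tol,
                        maxIter = config$maxIter, muFloor = config$muFloor,
                        init = init)
      init <- res[c("mu", "lambda", "nu", "eta")]
      ## held-out deviance
      tot <- 0; cnt <- 0
      emu <- exp(res$mu)
      for (s in groups) {
        ho <- folds[[s]] == f
        if (!any(ho)) next
        r <- tp$lens * exp(res$lambda + res$nu[s] + res$eta[, s])
        phi <- pmax(r %o% emu, 1e-12)
        m <- tp$M[[s]]
        d <- -(m - phi)
        pos <- ho & m > 0
        d[pos] <- d[pos] + m[pos] * log(m[pos] / phi[pos])
        tot <- tot + 2 * sum(d[ho])
        cnt <- cnt + sum(ho)
      }
      dev[f, j] <- tot / cnt
    }
  }
  meanDev <- colMeans(dev)
  sel <- grid[which.min(meanDev)]  # grid decreasing: first min = largest
  sizes <- rep(0L, config$nFolds)
  for (s in groups) {
    tab <- tabulate(folds[[s]][folds[[s]] > 0], nbins = config$nFolds)
    sizes <- sizes + tab
  }
  new("CVResult",
    kappa1Grid = grid, foldDeviance = dev, meanDeviance = meanDev,
    selectedKappa1 = sel, foldSizes = sizes, nFolds = config$nFolds,
    seed = config$seed
  )
}

#' @describeIn GenerativeFit-class fractions of exactly-zero `lambda` and
#'   (non-reference) `eta` entries.
#' @export
setMethod("sparsityReport", "GenerativeFit", function(x, ...) {
  free <- setdiff(colnames(x@eta), x@referenceGroup)
  c(
    lambda = mean(x@lambda == 0),
    eta = mean(x@eta[, free, drop = FALSE] == 0)
  )
})

setMethod("show", "GenerativeFit", function(object) {
  sp <- sparsityReport(object)
  cat(sprintf(
    paste0("GenerativeFit: %d samples, %d genes, groups {%s}; kappa1 = %.4g",
           "; sparsity lambda %.1f%%, eta %.1f%%\n"),
    length(object@mu), length(object@lambda),
    paste(names(object@nu), collapse = ", "), object@kappa1,
    100 * sp["lambda"], 100 * sp["eta"]
  ))
})

## JSON round trip for fitted parameters

#' Serialize / restore a generative fit
#'
#' @param fit a [GenerativeFit-class].
#' @param path JSON file path.
#' @return `writeGenerativeFit()`: `path` invisibly; `readGenerativeFit()`:
#'   the restored [GenerativeFit-class].
#' @export
writeGenerativeFit <- function(fit, path) {
  jsonlite::write_json(
    list(
      mu = as.list(fit@mu), lambda = as.list(fit@lambda),
      nu = as.list(fit@nu),
      eta = apply(fit@eta, 2L, as.list),
      genes = names(fit@lambda), groups = names(fit@nu),
      referenceGroup = fit@referenceGroup, kappa1 = fit@kappa1,
      convention = "nu and eta are zero at referenceGroup"
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname writeGenerativeFit
#' @export
readGenerativeFit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  eta <- do.call(cbind, lapply(obj$groups, function(s) unlist(obj$eta[[s]])))
  dimnames(eta) <- list(obj$genes, obj$groups)
  new("GenerativeFit",
    mu = unlist(obj$mu), lambda = unlist(obj$lambda), nu = unlist(obj$nu),
    eta = eta, referenceGroup = obj$referenceGroup, kappa1 = obj$kappa1,
    convergence = list()
  )
}
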