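#' @include AllClasses.R AllGenerics.R generative-model.R
NULL

## ---- panels ---------------------------------------------------------------

#' Construct a gene panel
#'
#' @param genes character vector of gene identifiers.
#' @param geneLengths named numeric of coding lengths covering `genes`.
#' @return a [GenePanel-class].
#' @export
GenePanel <- function(genes, geneLengths) {
  genes <- unique(as.character(genes))
  stopIfNot(all(genes %in% names(geneLengths)),
            "every panel gene needs a length in geneLengths")
  new("GenePanel", genes = genes,
      totalLength = sum(unname(geneLengths[genes])))
}

#' @describeIn GenePanel-class member gene identifiers.
#' @export
setMethod("panelGenes", "GenePanel", function(x, ...) x@genes)

#' @describeIn GenePanel-class total coding length in bases.
#' @export
setMethod("panelLength", "GenePanel", function(x, ...) x@totalLength)

setMethod("show", "GenePanel", function(object) {
  cat(sprintf("GenePanel: %d genes, %.3g Mb\n", length(object@genes),
              object@totalLength / 1e6))
})

#' Read / write a panel as a plain gene list
#'
#' One gene symbol per line.
#'
#' @param panel a [GenePanel-class].
#' @param path file path.
#' @param geneLengths named numeric of coding lengths (for reading).
#' @return `writePanel()`: `path` invisibly; `readPanel()`: a
#'   [GenePanel-class].
#' @export
writePanel <- function(panel, path) {
  writeLines(panelGenes(panel), path)
  invisible(path)
}

#' @rdname writePanel
#' @export
readPanel <- function(path, geneLengths) {
  GenePanel(readLines(path), geneLengths)
}

#' Write a panel as BED
#'
#' Emits 0-based half-open intervals for the panel genes, given a
#' coordinates table with 1-based inclusive `start`/`end` columns.
#'
#' @param panel a [GenePanel-class].
#' @param coords data frame with columns `gene`, `chrom`, `start`, `end`.
#' @param path BED file path.
#' @return `path`, invisibly.
#' @export
writePanelBed <- function(panel, coords, path) {
  for (col in c("gene", "chrom", "start", "end")) {
    stopIfNot(col %in% names(coords),
              "coordinates table is missing column '%s'", col)
  }
  sub <- coords[coords$gene %in% panelGenes(panel), , drop = FALSE]
  missing <- setdiff(panelGenes(panel), sub$gene)
  if (length(missing)) {
    warning("no coordinates for panel gene(s): ",
            paste(utils::head(missing, 10L), collapse = ", "))
  }
  bed <- data.frame(chrom = sub$chrom, start = sub$start - 1L,
                    end = sub$end, name = sub$gene)
  bed <- bed[order(bed$chrom, bed$start), , drop = FALSE]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ---- estimator objective --------------------------------------------------

#' Normalized expected rates for the estimator objective
#'
#' \eqn{p_{gs} = \ell_g e^{\hat\lambda_g+\hat\nu_s+\hat\eta_{gs}} /
#' \sum_{g',s'\in\bar S} \ell_{g'} e^{\hat\lambda_{g'}+\hat\nu_{s'}+
#' \hat\eta_{g's'}}} — the model's expected share of the biomarker falling in
#' each (gene, group) cell, independent of the background rate. Computed in
#' log space to guard against overflow.
#'
#' @param fit a [GenerativeFit-class].
#' @param geneLengths named numeric of coding lengths.
#' @param spec a [BiomarkerSpec-class] (defines the target groups).
#' @param K bias-penalty weight to store (may be `NA` and set later via
#'   [biasPenaltyK()]).
#' @return a [NormalizedRates-class].
#' @export
normalizedRates <- function(fit, geneLengths, spec, K = NA_real_) {
  genes <- names(fit@lambda)
  lens <- geneLengths[genes]
  lb <- matrix(0, length(genes), length(fit@nu),
               dimnames = list(genes, names(fit@nu)))
  for (s in names(fit@nu)) {
    lb[, s] <- log(lens) + fit@lambda + fit@nu[s] + fit@eta[, s]
  }
  tg <- spec@targetGroups
  stopIfNot(all(tg %in% colnames(lb)),
            "biomarker target groups must be fitted variant groups")
  m <- max(lb[, tg, drop = FALSE])
  denom <- sum(exp(lb[, tg, drop = FALSE] - m))
  p <- exp(lb - m) / denom
  new("NormalizedRates", p = p, K = K, targetGroups = tg)
}

#' Bias penalty weight K
#'
#' \eqn{K(\mu_0) = e^{\mu_0}\sum_{g,s\in\bar S}\ell_g
#' e^{\hat\lambda_g+\hat\nu_s+\hat\eta_{gs}}} — the expected biomarker value
#' of a sample with background log-rate `mu0`. `mu0 = Inf` marks the
#' exact-unbiasedness constraint (\eqn{\sum p_{gs} w_{gs} = 1}) for the
#' refitting step.
#'
#' @param fit a [GenerativeFit-class].
#' @param geneLengths named numeric of coding lengths.
#' @param spec a [BiomarkerSpec-class].
#' @param mu0 background log-rate of the (hypothetical) target sample, or
#'   `Inf` for the unbiased limit.
#' @return a non-negative number (possibly `Inf`).
#' @seealso [recommendedK()] for the data-driven default
#'   \eqn{K(\max_i \hat\mu_i)}.
#' @export
biasPenaltyK <- function(fit, geneLengths, spec, mu0) {
  if (is.infinite(mu0) && mu0 > 0) return(Inf)
  base <- mutationRates(fit, geneLengths)
  exp(mu0) * sum(base[, spec@targetGroups, drop = FALSE])
}

#' Estimator objective f(w)
#'
#' \eqn{f(w) = \sum_{g,s\in\bar S} p_{gs}(1-w_{gs})^2 +
#' \sum_{g,s\notin\bar S} p_{gs} w_{gs}^2 +
#' K(1 - \sum_{g,s} p_{gs} w_{gs})^2}, the rescaled model-based expected
#' squared error of the weighted-count estimator \eqn{T(w)}.
#'
#' @param w gene x group weight matrix (dimnames matching the rates).
#' @param rates a [NormalizedRates-class] with `K` set. With `K = Inf` the
#'   bias term is treated as a hard constraint: the value is the quadratic
#'   part when \eqn{\sum p w = 1} (to 1e-8) and `Inf` otherwise.
#' @return a number.
#' @export
objectiveF <- function(w, rates) {
  p <- rates@p
  stopIfNot(!is.na(rates@K), "rates@K is unset; see biasPenaltyK()")
  tmat <- .targetMatrix(rates)
  quad <- sum(p * (w - tmat)^2)
  bias <- 1 - sum(p * w)
  if (is.infinite(rates@K)) {
    if (abs(bias) <= 1e-8) quad else Inf
  } else {
    quad + rates@K * bias^2
  }
}

.targetMatrix <- function(rates) {
  tmat <- matrix(0, nrow(rates@p), ncol(rates@p), dimnames = dimnames(rates@p))
  tmat[, rates@targetGroups] <- 1
  tmat
}

## ---- first fit: length-weighted group lasso -------------------------------

#' Group-lasso first fit
#'
#' Minimizes \eqn{f(w) + \kappa_2 \sum_{g \notin P_0} \ell_g \|w_g\|_2} over
#' \eqn{\{w : w_g = 0 \ \forall g \in Q_0\}} by accelerated proximal
#' gradient (FISTA with monotone restart) on the smooth quadratic \eqn{f}
#' with the exact group soft-threshold prox. The Lipschitz constant uses the
#' diagonal-plus-rank-one structure of the Hessian
#' (\eqn{2\max p + 2K\|p\|^2}). First-order conditions are checked at exit.
#'
#' @param rates a [NormalizedRates-class] with finite `K`.
#' @param geneLengths named numeric of coding lengths.
#' @param kappa2 group-lasso penalty (>= 0).
#' @param include genes exempt from the penalty (mandatory panel
#'   \eqn{P_0}).
#' @param exclude genes forced to zero weight (\eqn{Q_0}); must be disjoint
#'   from `include`.
#' @param tol relative objective-change stopping tolerance (a relative
#'   weight-change criterion of the same order must hold simultaneously).
#' @param maxIter iteration cap.
#' @param kktTol first-order residual (relative to the gradient scale at
#'   the origin) above which hitting `maxIter` is an error.
#' @param init optional warm-start weight matrix.
#' @return a [PanelFit-class].
#' @export
firstFit <- function(rates, geneLengths, kappa2, include = character(),
                     exclude = character(), tol = 1e-10, maxIter = 20000L,
                     kktTol = 1e-6, init = NULL) {
  stopIfNot(kappa2 >= 0, "kappa2 must be non-negative")
  stopIfNot(length(intersect(include, exclude)) == 0L,
            "include and exclude panels must be disjoint")
  stopIfNot(is.finite(rates@K), "firstFit needs finite K; K = Inf is only
    meaningful for the constrained refit")
  p <- rates@p
  genes <- rownames(p)
  lens <- geneLengths[genes]
  tmat <- .targetMatrix(rates)
  K <- rates@K
  penWeight <- lens
  penWeight[genes %in% include] <- 0
  isExcl <- genes %in% exclude

  Lip <- 2 * max(p) + 2 * K * sum(p^2)
  step <- 1 / Lip
  thresh <- step * kappa2 * penWeight

  fval <- function(w) {
    sum(p * (w - tmat)^2) + K * (1 - sum(p * w))^2
  }
  gradf <- function(w) {
    2 * p * (w - tmat) + 2 * K * (sum(p * w) - 1) * p
  }
  prox <- function(w) {
    w[isExcl, ] <- 0
    nrm <- sqrt(rowSums(w^2))
    shrink <- ifelse(nrm > 0, pmax(0, 1 - thresh / nrm), 0)
    shrink[thresh == 0] <- 1
    w * shrink
  }
  penalty <- function(w) kappa2 * sum(penWeight * sqrt(rowSums(w^2)))

  w <- if (is.null(init)) matrix(0, nrow(p), ncol(p), dimnames = dimnames(p))
       else init
  w <- prox(w)
  y <- w
  tAcc <- 1
  Fprev <- fval(w) + penalty(w)
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    wNew <- prox(y - step * gradf(y))
    Fnew <- fval(wNew) + penalty(wNew)
    if (Fnew > Fprev) {        # monotone restart
      y <- w
      tAcc <- 1
      wNew <- prox(y - step * gradf(y))
      Fnew <- fval(wNew) + penalty(wNew)
    }
    tNew <- (1 + sqrt(1 + 4 * tAcc^2)) / 2
    y <- wNew + ((tAcc - 1) / tNew) * (wNew - w)
    done <- abs(Fprev - Fnew) <= tol * (abs(Fprev) + 1e-15) &&
      max(abs(wNew - w)) <= 1e-8 * (1 + max(abs(wNew)))
    w <- wNew
    tAcc <- tNew
    Fprev <- Fnew
    if (done) break
  }

  gradScale <- max(sqrt(rowSums((2 * p * tmat + 2 * K * p)^2)), 1e-15)
  kkt <- .firstFitKKT(w, gradf(w), kappa2, penWeight, isExcl) / gradScale
  if (it >= maxIter && kkt > kktTol) {
    stop(sprintf(
      "group-lasso solver did not converge in %d iterations (relative KKT residual %.3g)",
      maxIter, kkt
    ))
  }
  new("PanelFit",
    weights = w, kappa2 = kappa2, objective = Fprev,
    iterations = it, kktResidual = kkt,
    include = as.character(include), exclude = as.character(exclude)
  )
}

# max violation of the first-order conditions of f(w) + kappa2*sum(pen*||w_g||)
.firstFitKKT <- function(w, grad, kappa2, penWeight, isExcl) {
  res <- 0
  nrm <- sqrt(rowSums(w^2))
  gn <- sqrt(rowSums(grad^2))
  for (g in seq_len(nrow(w))) {
    if (isExcl[g]) next
    if (nrm[g] > 0) {
      v <- grad[g, ] + kappa2 * penWeight[g] * w[g, ] / nrm[g]
      res <- max(res, sqrt(sum(v^2)))
    } else {
      res <- max(res, max(0, gn[g] - kappa2 * penWeight[g]))
    }
  }
  res
}

#' Full-shrinkage penalty bound
#'
#' The smallest \eqn{\kappa_2} at which the all-zero weight matrix solves
#' the first fit (no mandatory genes):
#' \eqn{\max_g \|\nabla_g f(0)\|_2 / \ell_g}.
#'
#' @inheritParams firstFit
#' @return a positive number.
#' @export
kappa2Max <- function(rates, geneLengths, include = character(),
                      exclude = character()) {
  p <- rates@p
  tmat <- .targetMatrix(rates)
  grad0 <- -2 * p * tmat - 2 * rates@K * p
  lens <- geneLengths[rownames(p)]
  free <- !(rownames(p) %in% c(include, exclude))
  stopIfNot(any(free), "no penalized genes left")
  max(sqrt(rowSums(grad0^2))[free] / lens[free])
}

#' Log-spaced penalty grid for panel selection
#'
#' @inheritParams firstFit
#' @param gridLength number of grid points.
#' @param gridDecades decades spanned below the full-shrinkage bound.
#' @return decreasing numeric vector.
#' @export
kappa2Grid <- function(rates, geneLengths, include = character(),
                       exclude = character(), gridLength = 100L,
                       gridDecades = 4) {
  km <- kappa2Max(rates, geneLengths, include, exclude)
  exp(seq(log(km * 1.0001), log(km) - gridDecades * log(10),
          length.out = gridLength))
}

## ---- panel extraction and refit ------------------------------------------

#' Panel selected by a weight matrix
#'
#' Genes with non-zero group norm \eqn{\|w_g\|_2 > 0}; the panel's total
#' length equals the cost norm \eqn{\|w\|_{G,0}}.
#'
#' @param w gene x group weight matrix or a [PanelFit-class].
#' @param geneLengths named numeric of coding lengths.
#' @return a [GenePanel-class].
#' @export
panelOf <- function(w, geneLengths) {
  if (is(w, "PanelFit")) w <- w@weights
  sel <- rownames(w)[sqrt(rowSums(w^2)) > 0]
  GenePanel(sel, geneLengths)
}

#' Refit the estimator weights on a fixed panel
#'
#' Minimizes \eqn{f(w)} over weight matrices supported on the panel genes.
#' The stationarity conditions force \eqn{w_{gs} = t_{gs} + c} on every
#' support cell with a common offset \eqn{c = K(1-q)/(1+K P_s)}, where
#' \eqn{q} is the panel's share of the target-group mass and \eqn{P_s} its
#' total mass, so the solve is closed-form. With `K = Inf` the offset is
#' \eqn{(1-q)/P_s}, giving the exactly unbiased constrained least-squares
#' solution (\eqn{\sum p_{gs} w_{gs} = 1}).
#'
#' @param rates a [NormalizedRates-class] with `K` set (finite or `Inf`).
#' @param panel a [GenePanel-class].
#' @return a [PanelFit-class] with `kappa2 = NA`.
#' @export
refitWeights <- function(rates, panel) {
  p <- rates@p
  stopIfNot(!is.na(rates@K), "rates@K is unset; see biasPenaltyK()")
  tmat <- .targetMatrix(rates)
  w <- matrix(0, nrow(p), ncol(p), dimnames = dimnames(p))
  sel <- rownames(p) %in% panelGenes(panel)
  if (!any(sel)) {
    warning("empty panel: returning zero weights (f = 1 + K)")
  } else {
    q <- sum(p[sel, rates@targetGroups, drop = FALSE])
    Ps <- sum(p[sel, , drop = FALSE])
    cOff <- if (is.infinite(rates@K)) (1 - q) / Ps
            else rates@K * (1 - q) / (1 + rates@K * Ps)
    w[sel, ] <- tmat[sel, ] + cOff
  }
  obj <- if (is.infinite(rates@K) && !any(sel)) Inf else objectiveF(w, rates)
  new("PanelFit",
    weights = w, kappa2 = NA_real_, objective = obj,
    iterations = 0L, kktResidual = 0,
    include = character(), exclude = character()
  )
}

#' @describeIn PanelFit-class the fitted weight matrix.
#' @export
setMethod("panelWeights", "PanelFit", function(x, ...) x@weights)

setMethod("show", "PanelFit", function(object) {
  nz <- sum(sqrt(rowSums(object@weights^2)) > 0)
  cat(sprintf(
    "PanelFit: %d of %d genes selected; kappa2 = %.4g, objective = %.6g\n",
    nz, nrow(object@weights), object@kappa2, object@objective
  ))
})

## ---- length-budget search -------------------------------------------------

#' Map a panel length budget to a penalty level
#'
#' Walks the penalty grid from large to small with warm starts, recording
#' each first-fit panel (always including the mandatory genes). Among grid
#' values whose panel length does not exceed the budget `L`, the one with
#' the longest panel is returned; exact length ties go to the larger
#' penalty (sparsest weights). This enforces a within-budget selection even
#' if the raw support path is locally non-monotone (any non-monotone step is
#' recorded in the returned path table).
#'
#' @inheritParams firstFit
#' @param L panel length budget in bases; must cover the mandatory genes.
#' @param grid decreasing penalty sequence (default [kappa2Grid()]).
#' @return list with elements `kappa2`, `panel` ([GenePanel-class]), `fit`
#'   ([PanelFit-class]) and `path` (data frame kappa2 / panelLength).
#' @export
kappa2ForLength <- function(rates, geneLengths, L, grid = NULL,
                            include = character(), exclude = character(),
                            tol = 1e-10, maxIter = 20000L) {
  if (length(include)) {
    lenP0 <- sum(geneLengths[include])
    stopIfNot(L >= lenP0,
              "budget L = %g is below the mandatory panel length %g",
              L, lenP0)
  }
  if (is.null(grid)) {
    grid <- kappa2Grid(rates, geneLengths, include, exclude)
  }
  fits <- vector("list", length(grid))
  lenPath <- numeric(length(grid))
  init <- NULL
  for (j in seq_along(grid)) {
    ft <- firstFit(rates, geneLengths, grid[j], include = include,
                   exclude = exclude, tol = tol, maxIter = maxIter,
                   init = init)
    init <- ft@weights
    pan <- unique(c(include, panelGenes(panelOf(ft, geneLengths))))
    fits[[j]] <- ft
    lenPath[j] <- sum(geneLengths[pan])
  }
  ok <- which(lenPath <= L)
  stopIfNot(length(ok) > 0L,
            "no grid value produces a panel within the budget %g", L)
  best <- ok[lenPath[ok] == max(lenPath[ok])][1L]  # ties -> largest kappa2
  pan <- GenePanel(
    unique(c(include, panelGenes(panelOf(fits[[best]], geneLengths)))),
    geneLengths
  )
  list(
    kappa2 = grid[best], panel = pan, fit = fits[[best]],
    path = data.frame(kappa2 = grid, panelLength = lenPath)
  )
}
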