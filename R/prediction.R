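#' @include AllClasses.R AllGenerics.R panel-selection.R
NULL

#' Assemble a biomarker estimator
#'
#' Bundles refitted weights, the rates and generative fit they came from,
#' the biomarker definition and the selected panel into a deployable
#' estimator object.
#'
#' @param weights gene x group weight matrix (or a [PanelFit-class]).
#' @param rates a [NormalizedRates-class].
#' @param fit a [GenerativeFit-class].
#' @param spec a [BiomarkerSpec-class].
#' @param panel a [GenePanel-class].
#' @param geneLengths named numeric of coding lengths.
#' @return a [BiomarkerEstimator-class].
#' @export
BiomarkerEstimator <- function(weights, rates, fit, spec, panel,
                               geneLengths) {
  if (is(weights, "PanelFit")) weights <- weights@weights
  new("BiomarkerEstimator",
    weights = weights, rates = rates, fit = fit, spec = spec,
    panel = panel, geneLengths = geneLengths
  )
}

#' Fit the whole panel-design pipeline
#'
#' Convenience wrapper: normalized rates from a generative fit, data-driven
#' bias penalty \eqn{K(\max_i\hat\mu_i)}, budgeted group-lasso panel
#' selection (optionally around mandatory / excluded gene sets), and refit
#' on the selected support.
#'
#' @param fit a [GenerativeFit-class] from the training data.
#' @param train the training [MutationExperiment-class] (used for the
#'   data-driven `K`).
#' @param geneLengths named numeric of coding lengths.
#' @param spec a [BiomarkerSpec-class].
#' @param budget panel length budget in bases, or `NULL` to use a fixed
#'   panel.
#' @param panel fixed [GenePanel-class] to refit on (used when `budget` is
#'   `NULL`).
#' @param include,exclude mandatory / excluded gene sets for selection.
#' @param K bias penalty; default [recommendedK()]. Use `Inf` for the
#'   exactly unbiased refit.
#' @param grid optional [kappa2Grid()] override.
#' @return a [BiomarkerEstimator-class].
#' @export
buildEstimator <- function(fit, train, geneLengths, spec, budget = NULL,
                           panel = NULL, include = character(),
                           exclude = character(), K = NULL, grid = NULL) {
  if (is.null(K)) K <- recommendedK(fit, train, geneLengths, spec)
  rates <- normalizedRates(fit, geneLengths, spec, K = K)
  if (is.null(budget)) {
    stopIfNot(!is.null(panel), "supply either a budget or a fixed panel")
  } else {
    selRates <- if (is.infinite(K)) {
      normalizedRates(fit, geneLengths, spec,
                      K = recommendedK(fit, train, geneLengths, spec))
    } else {
      rates
    }
    sel <- kappa2ForLength(selRates, geneLengths, budget, grid = grid,
                           include = include, exclude = exclude)
    panel <- sel$panel
  }
  refit <- refitWeights(rates, panel)
  BiomarkerEstimator(refit, rates, fit, spec, panel, geneLengths)
}

#' @describeIn BiomarkerEstimator-class the selected panel.
#' @export
setMethod("panelGenes", "BiomarkerEstimator", function(x, ...)
  panelGenes(x@panel))

#' @describeIn BiomarkerEstimator-class total panel length (bases).
#' @export
setMethod("panelLength", "BiomarkerEstimator", function(x, ...)
  panelLength(x@panel))

#' @describeIn BiomarkerEstimator-class the refitted weight matrix.
#' @export
setMethod("panelWeights", "BiomarkerEstimator", function(x, ...) x@weights)

setMethod("show", "BiomarkerEstimator", function(object) {
  cat(sprintf(
    "BiomarkerEstimator for %s: panel of %d genes (%.3g Mb), K = %.4g\n",
    object@spec@name, length(panelGenes(object@panel)),
    panelLength(object@panel) / 1e6, object@rates@K
  ))
})

#' Predict biomarker values for new samples
#'
#' \eqn{\hat T_0 = \sum_{g,s} w_{gs} M_{0gs}}; only counts of panel genes
#' enter the sum, so `newdata` need only cover the panel.
#'
#' @param object a [BiomarkerEstimator-class].
#' @param newdata a [MutationExperiment-class] whose genes include every
#'   panel gene and whose groups match the estimator's.
#' @param ... ignored.
#' @return named numeric of per-sample estimates.
#' @export
setMethod("predict", "BiomarkerEstimator", function(object, newdata, ...) {
  w <- object@weights
  missing <- setdiff(panelGenes(object@panel), rownames(newdata))
  if (length(missing)) {
    stop("test counts are missing panel gene(s): ",
         paste(utils::head(missing, 10L), collapse = ", "))
  }
  groups <- colnames(w)
  stopIfNot(all(groups %in% variantGroups(newdata)),
            "test counts lack variant group(s) used by the estimator")
  sel <- intersect(rownames(w)[sqrt(rowSums(w^2)) > 0], rownames(newdata))
  est <- rep(0, ncol(newdata))
  for (s in groups) {
    est <- est + colSums(assay(newdata, s)[sel, , drop = FALSE] *
                           w[sel, s])
  }
  names(est) <- colnames(newdata)
  est
})

#' Model-based mean squared error of a weighted-count estimator
#'
#' \eqn{\sum_{g,s\in\bar S}(1-w_{gs})^2\phi_{0gs} +
#' \sum_{g,s\notin\bar S} w_{gs}^2\phi_{0gs} +
#' (\sum_{g,s} w_{gs}\phi_{0gs} - \sum_{g,s\in\bar S}\phi_{0gs})^2}
#' with \eqn{\phi_{0gs}} the model rate at background log-rate `mu0`
#' (variance plus squared bias of \eqn{T(w)} under the Poisson model).
#'
#' @param w gene x group weight matrix.
#' @param fit a [GenerativeFit-class].
#' @param geneLengths named numeric of coding lengths.
#' @param spec a [BiomarkerSpec-class].
#' @param mu0 background log-rate of the target sample.
#' @return a non-negative number.
#' @export
modelMSE <- function(w, fit, geneLengths, spec, mu0) {
  stopIfNot(is.finite(mu0), "mu0 must be finite")
  phi <- mutationRates(fit, geneLengths, mu = mu0)
  tg <- spec@targetGroups
  other <- setdiff(colnames(phi), tg)
  varTerm <- sum((1 - w[, tg, drop = FALSE])^2 * phi[, tg, drop = FALSE]) +
    sum(w[, other, drop = FALSE]^2 * phi[, other, drop = FALSE])
  bias <- sum(w * phi) - sum(phi[, tg, drop = FALSE])
  varTerm + bias^2
}

#' Pseudo-maximum-likelihood background rate
#'
#' \eqn{\hat\mu_i = \log(T_i / \sum_{g,s\in\bar S}\ell_g
#' e^{\hat\lambda_g+\hat\nu_s+\hat\eta_{gs}})}: the background log-rate at
#' which the model's expected biomarker equals the observed value
#' \eqn{T_i}. Zero observed burdens are floored at 0.5 before the log so
#' the estimate stays finite. Set `allGroups = TRUE` to normalize by the
#' full variant-type total instead of the biomarker's target groups.
#'
#' @param T observed biomarker value(s).
#' @param fit a [GenerativeFit-class].
#' @param geneLengths named numeric of coding lengths.
#' @param spec a [BiomarkerSpec-class].
#' @param allGroups sum the denominator over all of \eqn{S} instead of
#'   \eqn{\bar S}.
#' @return numeric of the same length as `T`.
#' @export
pseudoMleMu <- function(T, fit, geneLengths, spec, allGroups = FALSE) {
  base <- mutationRates(fit, geneLengths)
  cols <- if (allGroups) colnames(base) else spec@targetGroups
  denom <- sum(base[, cols, drop = FALSE])
  if (any(T <= 0)) {
    warning("non-positive biomarker value(s) floored at 0.5 before the log")
  }
  log(pmax(T, 0.5) / denom)
}

#' Data-driven bias penalty recommendation
#'
#' \eqn{K(\max_i\hat\mu_i)} over the training samples, with \eqn{\hat\mu_i}
#' the pseudo-MLE background rates of the observed training biomarkers.
#'
#' @param fit a [GenerativeFit-class].
#' @param train training [MutationExperiment-class].
#' @param geneLengths named numeric of coding lengths.
#' @param spec a [BiomarkerSpec-class].
#' @return a positive number.
#' @export
recommendedK <- function(fit, train, geneLengths, spec) {
  Ti <- biomarkerValues(train, spec)
  muHat <- pseudoMleMu(Ti, fit, geneLengths, spec)
  biasPenaltyK(fit, geneLengths, spec, max(muHat))
}

#' Heuristic Markov-bound prediction intervals
#'
#' For each point estimate \eqn{\hat T}, the plug-in mean squared error is
#' evaluated at the pseudo-MLE background rate implied by \eqn{\hat T}
#' itself, and Markov's inequality applied to \eqn{(\hat T - T)^2} gives
#' \eqn{t_\alpha = \mathrm{MSE}/\alpha} and the conservative interval
#' \eqn{[\hat T - \sqrt{t_\alpha},\ \hat T + \sqrt{t_\alpha}]}, floored at 0
#' since the biomarker is a count.
#'
#' @param model a [BiomarkerEstimator-class].
#' @param estimates per-sample point estimates from [predict()].
#' @param alpha miscoverage level in (0, 1\]; `alpha = 1` gives the plain
#'   root-MSE half-width.
#' @return data frame with columns `sample`, `estimate`, `lower`, `upper`,
#'   `alpha`.
#' @export
predictionInterval <- function(model, estimates, alpha = 0.1) {
  stopIfNot(alpha > 0 && alpha <= 1, "alpha must lie in (0, 1]")
  mu0 <- suppressWarnings(
    pseudoMleMu(estimates, model@fit, model@geneLengths, model@spec)
  )
  half <- vapply(mu0, function(m) {
    sqrt(modelMSE(model@weights, model@fit, model@geneLengths,
                  model@spec, m) / alpha)
  }, numeric(1))
  data.frame(
    sample = if (is.null(names(estimates))) seq_along(estimates)
             else names(estimates),
    estimate = unname(estimates),
    lower = pmax(0, unname(estimates) - half),
    upper = unname(estimates) + half,
    alpha = alpha,
    row.names = NULL
  )
}
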