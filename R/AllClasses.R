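#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assays assay
#'   assayNames rowData colData
NULL

#' Variant classification catalogue
#'
#' Maps raw variant-classification labels (as found in a MAF file) onto the
#' small set of variant groups \eqn{S} used by the generative model, and
#' singles out one group as the reference for identifiability. Synonymous
#' classes map to a sentinel "excluded" group that never enters \eqn{S}.
#'
#' @slot classes ordered character vector of raw classification labels.
#' @slot groups named character vector: raw class -> group label. The value
#'   `excludedLabel` marks classes that are dropped from all counts.
#' @slot referenceGroup the group \eqn{s_1} whose gene-by-type effects are
#'   pinned to zero.
#' @slot excludedLabel sentinel group label for excluded (synonymous) classes.
#'
#' @seealso [VariantCatalog()] for the constructor and
#'   [defaultVariantCatalog()] for the standard two-group (indel / other)
#'   catalogue.
#' @export
setClass("VariantCatalog",
  representation(
    classes = "character",
    groups = "character",
    referenceGroup = "character",
    excludedLabel = "character"
  )
)

setValidity("VariantCatalog", function(object) {
  msg <- character()
  if (length(object@excludedLabel) != 1L) {
    msg <- c(msg, "excludedLabel must be a single string")
  }
  if (is.null(names(object@groups)) || anyDuplicated(names(object@groups))) {
    msg <- c(msg, "groups must be uniquely named by raw class")
  }
  if (!all(object@classes %in% names(object@groups))) {
    msg <- c(msg, "every raw class must map to exactly one group")
  }
  live <- setdiff(unique(unname(object@groups)), object@excludedLabel)
  if (length(object@referenceGroup) != 1L ||
      !(object@referenceGroup %in% live)) {
    msg <- c(msg, "referenceGroup must be one of the non-excluded groups")
  }
  if (length(msg)) msg else TRUE
})

#' Biomarker definition
#'
#' An exome-wide count biomarker is a sum of mutation counts over all genes
#' and a target subset \eqn{\bar S \subseteq S} of variant groups, with a
#' clinical high/low threshold (e.g. TMB >= 300 exome mutations, TIB >= 10
#' indels).
#'
#' @slot name label, e.g. `"TMB"` or `"TIB"`.
#' @slot targetGroups non-empty subset of the variant groups.
#' @slot threshold non-negative high/low classification cutoff (inclusive).
#' @export
setClass("BiomarkerSpec",
  representation(
    name = "character",
    targetGroups = "character",
    threshold = "numeric"
  )
)

setValidity("BiomarkerSpec", function(object) {
  msg <- character()
  if (length(object@targetGroups) < 1L) {
    msg <- c(msg, "targetGroups must be non-empty")
  }
  if (length(object@threshold) != 1L || is.na(object@threshold) ||
      object@threshold < 0) {
    msg <- c(msg, "threshold must be a single non-negative number")
  }
  if (length(msg)) msg else TRUE
})

#' Mutation count experiment
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding the mutation count
#' tensor \eqn{M_{igs}}: one assay per variant group \eqn{s}, each a
#' genes-by-samples matrix of non-negative integer counts, with coding gene
#' lengths (bases) in `rowData(x)$length`. The variant grouping and reference
#' group are carried in `metadata(x)$variantGroups` /
#' `metadata(x)$referenceGroup`.
#'
#' @seealso [MutationExperiment()] and [aggregateCounts()]; `biomarkerValues()`
#'   computes biomarkers from the counts.
#' @export
setClass("MutationExperiment", contains = "SummarizedExperiment")

setValidity("MutationExperiment", function(object) {
  msg <- character()
  if (length(assays(object)) < 1L) {
    msg <- c(msg, "at least one variant-group assay is required")
  }
  if (is.null(assayNames(object)) || anyDuplicated(assayNames(object))) {
    msg <- c(msg, "assays must be uniquely named by variant group")
  }
  for (nm in assayNames(object)) {
    a <- assay(object, nm)
    if (any(is.na(a)) || any(a < 0) || any(a != round(a))) {
      msg <- c(msg, sprintf("assay '%s' must hold non-negative integers", nm))
      break
    }
  }
  len <- rowData(object)$length
  if (is.null(len) || any(is.na(len)) || any(len <= 0)) {
    msg <- c(msg, "rowData(x)$length must hold strictly positive gene lengths")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object))) {
    msg <- c(msg, "rownames (gene identifiers) must be present and unique")
  }
  if (is.null(colnames(object)) || anyDuplicated(colnames(object))) {
    msg <- c(msg, "colnames (sample identifiers) must be present and unique")
  }
  if (length(msg)) msg else TRUE
})

#' Fitted generative model parameters
#'
#' Parameters of the penalized Poisson model
#' \eqn{\log\phi_{igs} = \mu_i + \log\ell_g + \lambda_g + \nu_s + \eta_{gs}}:
#' per-sample background log-rates `mu`, per-gene effects `lambda`, per-group
#' effects `nu` and gene-by-group effects `eta`. For identifiability
#' `eta[, referenceGroup] == 0` and `nu[referenceGroup] == 0` (the global
#' level is absorbed into `mu`).
#'
#' @slot mu named numeric, one per training sample.
#' @slot lambda named numeric, one per gene.
#' @slot nu named numeric, one per variant group.
#' @slot eta numeric matrix, genes x groups.
#' @slot referenceGroup the pinned group \eqn{s_1}.
#' @slot kappa1 the L1 penalty the fit was obtained at.
#' @slot convergence list: iterations, objective trace, converged flag.
#' @export
setClass("GenerativeFit",
  representation(
    mu = "numeric",
    lambda = "numeric",
    nu = "numeric",
    eta = "matrix",
    referenceGroup = "character",
    kappa1 = "numeric",
    convergence = "list"
  )
)

setValidity("GenerativeFit", function(object) {
  msg <- character()
  if (!all(is.finite(object@mu))) msg <- c(msg, "mu must be finite")
  if (!all(is.finite(object@lambda))) msg <- c(msg, "lambda must be finite")
  if (!all(is.finite(object@nu))) msg <- c(msg, "nu must be finite")
  if (!all(is.finite(object@eta))) msg <- c(msg, "eta must be finite")
  grp <- colnames(object@eta)
  if (is.null(grp) || !identical(sort(grp), sort(names(object@nu)))) {
    msg <- c(msg, "eta columns and nu must be named by the same groups")
  }
  s1 <- object@referenceGroup
  if (length(s1) != 1L || !(s1 %in% names(object@nu))) {
    msg <- c(msg, "referenceGroup must be one of the groups")
  } else {
    if (any(object@eta[, s1] != 0)) {
      msg <- c(msg, "eta[, referenceGroup] must be identically zero")
    }
    if (object@nu[s1] != 0) {
      msg <- c(msg, "nu[referenceGroup] must be zero")
    }
  }
  if (!identical(rownames(object@eta), names(object@lambda))) {
    msg <- c(msg, "eta rows and lambda must be named by the same genes")
  }
  if (length(msg)) msg else TRUE
})

#' Normalized expected mutation rates
#'
#' The gene-by-group matrix \eqn{p_{gs} \propto \ell_g
#' \exp(\hat\lambda_g + \hat\nu_s + \hat\eta_{gs})}, rescaled so the entries
#' over the biomarker's target groups sum to one, together with the bias
#' penalty weight \eqn{K} of the estimator objective \eqn{f(w)}. `K` may be
#' `Inf` (exact-unbiasedness constraint) or `NA` (not yet set).
#'
#' @slot p positive gene x group matrix.
#' @slot K non-negative number, `Inf`, or `NA_real_`.
#' @slot targetGroups the biomarker's target groups \eqn{\bar S}.
#' @export
setClass("NormalizedRates",
  representation(p = "matrix", K = "numeric", targetGroups = "character")
)

setValidity("NormalizedRates", function(object) {
  msg <- character()
  if (any(object@p <= 0) || any(!is.finite(object@p))) {
    msg <- c(msg, "all p entries must be positive and finite")
  }
  if (!all(object@targetGroups %in% colnames(object@p))) {
    msg <- c(msg, "targetGroups must be columns of p")
  } else {
    tot <- sum(object@p[, object@targetGroups, drop = FALSE])
    if (abs(tot - 1) > 1e-8) {
      msg <- c(msg, "p must sum to 1 over the target groups")
    }
  }
  if (length(object@K) != 1L || (!is.na(object@K) && object@K < 0)) {
    msg <- c(msg, "K must be a single non-negative number, Inf, or NA")
  }
  if (length(msg)) msg else TRUE
})

#' Targeted gene panel
#'
#' A subset of genes together with its total coding length in bases
#' (the sequencing cost proxy).
#'
#' @slot genes character vector of member gene identifiers.
#' @slot totalLength sum of member coding lengths (bases).
#' @export
setClass("GenePanel",
  representation(genes = "character", totalLength = "numeric")
)

setValidity("GenePanel", function(object) {
  msg <- character()
  if (anyDuplicated(object@genes)) msg <- c(msg, "panel genes must be unique")
  if (length(object@totalLength) != 1L || is.na(object@totalLength) ||
      object@totalLength < 0) {
    msg <- c(msg, "totalLength must be a single non-negative number")
  }
  if (length(msg)) msg else TRUE
})

#' Group-lasso panel fit
#'
#' Result of the length-weighted group-lasso minimization of the estimator
#' objective: the weight matrix, the penalty it was solved at, the attained
#' penalized objective, and solver diagnostics (iterations, KKT residual).
#'
#' @slot weights gene x group weight matrix.
#' @slot kappa2 group-lasso penalty level (`NA` for an unpenalized refit).
#' @slot objective attained penalized objective value.
#' @slot iterations proximal-gradient iterations used.
#' @slot kktResidual max first-order-condition violation at exit.
#' @slot include genes exempt from the penalty (mandatory panel
#'   \eqn{P_0}).
#' @slot exclude genes constrained to zero weight (\eqn{Q_0}).
#' @export
setClass("PanelFit",
  representation(
    weights = "matrix",
    kappa2 = "numeric",
    objective = "numeric",
    iterations = "integer",
    kktResidual = "numeric",
    include = "character",
    exclude = "character"
  )
)

#' Biomarker estimator
#'
#' The deployable object: refitted weights supported on a selected panel,
#' the normalized rates and generative fit they were derived from, and the
#' biomarker definition. `predict()` on new mutation counts gives per-sample
#' point estimates; [predictionInterval()] adds Markov-bound intervals.
#'
#' @slot weights gene x group weight matrix, non-zero only on panel genes.
#' @slot rates the [NormalizedRates-class] used to build the estimator.
#' @slot fit the underlying [GenerativeFit-class].
#' @slot spec the [BiomarkerSpec-class] being estimated.
#' @slot panel the selected [GenePanel-class].
#' @slot geneLengths named numeric of coding lengths for all modelled genes.
#' @export
setClass("BiomarkerEstimator",
  representation(
    weights = "matrix",
    rates = "NormalizedRates",
    fit = "GenerativeFit",
    spec = "BiomarkerSpec",
    panel = "GenePanel",
    geneLengths = "numeric"
  )
)

setValidity("BiomarkerEstimator", function(object) {
  msg <- character()
  norms <- sqrt(rowSums(object@weights^2))
  support <- rownames(object@weights)[norms > 0]
  if (!all(support %in% object@panel@genes)) {
    msg <- c(msg, "weights must be supported only on panel genes")
  }
  if (!all(object@spec@targetGroups %in% colnames(object@weights))) {
    msg <- c(msg, "weight columns must cover the biomarker target groups")
  }
  if (length(msg)) msg else TRUE
})
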