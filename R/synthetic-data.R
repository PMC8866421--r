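#' @include AllClasses.R AllGenerics.R generative-model.R mutation-data.R
NULL

#' Synthetic cohort model
#'
#' Ground-truth parameters for simulating mutation-count cohorts from the
#' Poisson generative model, together with the background-rate law used to
#' draw fresh samples.
#'
#' @slot params true [GenerativeFit-class] parameters (its `mu` holds the
#'   base cohort's draws).
#' @slot geneLengths named numeric of simulated coding lengths.
#' @slot muCenter,muSd normal law of per-sample background log-rates.
#' @slot catalog the [VariantCatalog-class] in force.
#' @slot config the generating configuration.
#' @export
setClass("SyntheticModel",
  representation(
    params = "GenerativeFit",
    geneLengths = "numeric",
    muCenter = "numeric",
    muSd = "numeric",
    catalog = "VariantCatalog",
    config = "list"
  )
)

setMethod("show", "SyntheticModel", function(object) {
  cat(sprintf(
    "SyntheticModel: %d genes, %d base samples, mean burden target %.4g\n",
    length(object@geneLengths), length(object@params@mu),
    object@config$meanTMB
  ))
})

#' Synthetic cohort configuration
#'
#' Defaults describe a desk-scale cohort shaped like a high-burden lung
#' cancer study: 200 samples, 500 genes, two variant groups, mean total
#' burden about 250 with a mean indel burden about 10, heavy-tailed
#' per-sample burdens (log-normal background rates with unit log-scale
#' spread), log-normal coding lengths around 1.3 kb, and sparse gene
#' effects (5% of genes off the background rate at |effect| = 1 on the log
#' scale).
#'
#' @param nSamples,nGenes cohort dimensions.
#' @param lambdaSparsity,lambdaScale fraction and log-scale magnitude of
#'   non-zero per-gene effects (drawn at +/- `lambdaScale`).
#' @param etaSparsity,etaScale likewise for gene-by-group effects
#'   (non-reference groups).
#' @param meanTMB,meanTIB target expected total and indel burden per
#'   sample; the group effect `nu` and the background-rate center are
#'   calibrated so the cohort means match these.
#' @param muSd standard deviation of the per-sample background log-rate.
#' @param lengthMeanlog,lengthSdlog log-normal law of coding lengths
#'   (bases).
#' @param seed RNG seed fixing the entire draw.
#' @param catalog a [VariantCatalog-class]; burden calibration assumes the
#'   default two-group (other/indel) catalogue.
#' @return a configuration list for [sampleParams()].
#' @export
syntheticConfig <- function(nSamples = 200L, nGenes = 500L,
                            lambdaSparsity = 0.05, lambdaScale = 1,
                            etaSparsity = 0.05, etaScale = 1,
                            meanTMB = 250, meanTIB = 10, muSd = 1,
                            lengthMeanlog = log(1300), lengthSdlog = 0.6,
                            seed = 1L, catalog = defaultVariantCatalog()) {
  stopIfNot(nSamples >= 1L && nGenes >= 1L,
            "nSamples and nGenes must be at least 1")
  stopIfNot(lambdaSparsity >= 0 && lambdaSparsity <= 1 &&
              etaSparsity >= 0 && etaSparsity <= 1,
            "sparsities must lie in [0, 1]")
  stopIfNot(meanTIB < meanTMB, "meanTIB must be below meanTMB")
  list(
    nSamples = as.integer(nSamples), nGenes = as.integer(nGenes),
    lambdaSparsity = lambdaSparsity, lambdaScale = lambdaScale,
    etaSparsity = etaSparsity, etaScale = etaScale,
    meanTMB = meanTMB, meanTIB = meanTIB, muSd = muSd,
    lengthMeanlog = lengthMeanlog, lengthSdlog = lengthSdlog,
    seed = as.integer(seed), catalog = catalog
  )
}

#' Exome-scale cohort configuration
#'
#' An exome-scale profile (800 samples, 17,358 genes). Fitting at this size
#' takes minutes to hours; it is provided for full-scale experiments, not
#' for routine testing.
#'
#' @param ... overrides passed to [syntheticConfig()].
#' @return a configuration list.
#' @export
cohortScaleConfig <- function(...) {
  args <- utils::modifyList(
    list(nSamples = 800L, nGenes = 17358L, meanTMB = 252, meanTIB = 9.25),
    list(...)
  )
  do.call(syntheticConfig, args)
}

#' Draw ground-truth generative parameters
#'
#' Coding lengths are log-normal (rounded up to at least one base);
#' per-gene effects `lambda` and gene-by-group effects `eta` are sparse
#' with the configured non-zero fraction, each non-zero drawn at plus or
#' minus the configured scale with equal probability; the non-reference
#' group effect `nu` is calibrated so the expected indel share matches
#' `meanTIB / meanTMB`; background log-rates are normal with the center
#' calibrated so the expected total burden equals `meanTMB`.
#'
#' @param config a [syntheticConfig()] list.
#' @return a [SyntheticModel-class].
#' @export
sampleParams <- function(config = syntheticConfig()) {
  groups <- variantGroups(config$catalog)
  ref <- referenceGroup(config$catalog)
  free <- setdiff(groups, ref)
  stopIfNot(length(groups) == 2L && identical(free, "indel"),
            "burden calibration expects the two-group other/indel catalogue")
  withSeed(config$seed, {
    genes <- sprintf("g%05d", seq_len(config$nGenes))
    lens <- pmax(1, round(stats::rlnorm(config$nGenes,
                                        config$lengthMeanlog,
                                        config$lengthSdlog)))
    names(lens) <- genes

    lambda <- numeric(config$nGenes)
    on <- stats::runif(config$nGenes) < config$lambdaSparsity
    lambda[on] <- config$lambdaScale *
      sample(c(-1, 1), sum(on), replace = TRUE)
    names(lambda) <- genes

    eta <- matrix(0, config$nGenes, 2L, dimnames = list(genes, groups))
    onE <- stats::runif(config$nGenes) < config$etaSparsity
    eta[onE, "indel"] <- config$etaScale *
      sample(c(-1, 1), sum(onE), replace = TRUE)

    ## calibrate nu["indel"] to the target indel share, then the mu center
    ## to the target total burden
    aOther <- sum(lens * exp(lambda))                    # eta/nu zero at ref
    aIndel <- sum(lens * exp(lambda + eta[, "indel"]))
    rho <- config$meanTIB / (config$meanTMB - config$meanTIB)
    nu <- stats::setNames(c(0, log(rho * aOther / aIndel)), groups)
    totalBase <- aOther + exp(nu["indel"]) * aIndel
    muCenter <- log(config$meanTMB) - log(totalBase) - config$muSd^2 / 2

    mu <- stats::rnorm(config$nSamples, muCenter, config$muSd)
    names(mu) <- sprintf("s%04d", seq_len(config$nSamples))

    params <- new("GenerativeFit",
      mu = mu, lambda = lambda, nu = nu, eta = eta,
      referenceGroup = ref, kappa1 = NA_real_,
      convergence = list(source = "synthetic ground truth")
    )
    new("SyntheticModel",
      params = params, geneLengths = lens,
      muCenter = unname(muCenter), muSd = config$muSd,
      catalog = config$catalog, config = config
    )
  })
}

#' Draw a mutation-count tensor from the generative model
#'
#' Each cell is an independent Poisson draw at rate
#' \eqn{\phi_{igs} = e^{\mu_i}\ell_g e^{\lambda_g+\nu_s+\eta_{gs}}}.
#'
#' @param params a [GenerativeFit-class] holding the true parameters.
#' @param geneLengths named numeric of coding lengths.
#' @param seed RNG seed.
#' @param mu per-sample background log-rates (defaults to `params@mu`).
#' @param sampleNames optional sample identifiers.
#' @param referenceGroup identifiability reference recorded in the output.
#' @return a [MutationExperiment-class].
#' @export
sampleCounts <- function(params, geneLengths, seed = 1L, mu = params@mu,
                         sampleNames = names(mu),
                         referenceGroup = params@referenceGroup) {
  base <- mutationRates(params, geneLengths)     # genes x groups
  if (is.null(sampleNames)) sampleNames <- sprintf("s%04d", seq_along(mu))
  maxRate <- max(base) * max(exp(mu))
  stopIfNot(maxRate <= 1e9,
    "per-cell rates up to %.3g exceed 1e9; lower mu or the effect scales",
    maxRate)
  genes <- rownames(base)
  withSeed(seed, {
    counts <- lapply(colnames(base), function(s) {
      phi <- base[, s] %o% exp(mu)
      m <- matrix(stats::rpois(length(phi), phi), nrow(phi), ncol(phi))
      dimnames(m) <- list(genes, sampleNames)
      m
    })
    names(counts) <- colnames(base)
    MutationExperiment(counts, geneLengths[genes],
                       referenceGroup = referenceGroup)
  })
}

#' Draw a fresh cohort from a synthetic model
#'
#' Background log-rates for the new samples are drawn from the model's
#' calibrated normal law, then counts from the Poisson model.
#'
#' @param model a [SyntheticModel-class].
#' @param nSamples cohort size (default: the configured size).
#' @param seed RNG seed.
#' @param prefix sample-name prefix.
#' @return list with `counts` (a [MutationExperiment-class]), `mu` (the
#'   drawn background log-rates) and `truth` (per-sample expected burdens
#'   are implied by `mu`; observed biomarkers come from the counts).
#' @export
sampleCohort <- function(model, nSamples = NULL, seed = 1L,
                         prefix = "t") {
  if (is.null(nSamples)) nSamples <- model@config$nSamples
  mu <- withSeed(seed, stats::rnorm(nSamples, model@muCenter, model@muSd))
  names(mu) <- sprintf("%s%04d", prefix, seq_len(nSamples))
  counts <- sampleCounts(model@params, model@geneLengths, seed = seed + 1L,
                         mu = mu)
  list(counts = counts, mu = mu)
}

#' Expand a count tensor into a MAF-style fixture
#'
#' Writes one MAF row per mutation, using the first raw classification
#' label mapping to each variant group, so the MAF reader and aggregation
#' paths can be exercised end-to-end on simulated data.
#'
#' @param x a [MutationExperiment-class].
#' @param path output TSV path.
#' @param catalog the [VariantCatalog-class] supplying raw class labels.
#' @return `path`, invisibly.
#' @export
writeMAF <- function(x, path, catalog = defaultVariantCatalog()) {
  rows <- list()
  for (s in variantGroups(x)) {
    cls <- names(catalog@groups)[catalog@groups == s][1L]
    stopIfNot(!is.na(cls), "catalogue has no raw class for group '%s'", s)
    m <- assay(x, s)
    idx <- which(m > 0, arr.ind = TRUE)
    if (!nrow(idx)) next
    rows[[s]] <- data.frame(
      Hugo_Symbol = rep(rownames(m)[idx[, 1L]], m[idx]),
      Tumor_Sample_Barcode = rep(colnames(m)[idx[, 2L]], m[idx]),
      Variant_Classification = cls,
      stringsAsFactors = FALSE
    )
  }
  maf <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(Hugo_Symbol = character(),
               Tumor_Sample_Barcode = character(),
               Variant_Classification = character())
  }
  maf <- maf[order(maf$Tumor_Sample_Barcode, maf$Hugo_Symbol), , drop = FALSE]
  utils::write.table(maf, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
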