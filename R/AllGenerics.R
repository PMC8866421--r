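#' @include AllClasses.R
NULL

#' @export
setGeneric("variantGroups", function(x, ...) standardGeneric("variantGroups"))

#' @export
setGeneric("referenceGroup", function(x, ...) standardGeneric("referenceGroup"))

#' @export
setGeneric("geneLengths", function(x, ...) standardGeneric("geneLengths"))

#' @export
setGeneric("panelGenes", function(x, ...) standardGeneric("panelGenes"))

#' @export
setGeneric("panelLength", function(x, ...) standardGeneric("panelLength"))

#' @export
setGeneric("panelWeights", function(x, ...) standardGeneric("panelWeights"))

#' @export
setGeneric("biomarkerValues", function(x, spec, ...)
  standardGeneric("biomarkerValues"))

#' @export
setGeneric("sparsityReport", function(x, ...) standardGeneric("sparsityReport"))
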