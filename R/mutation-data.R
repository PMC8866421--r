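#' @include AllClasses.R AllGenerics.R
NULL

## ---- variant catalogue ----------------------------------------------------

#' Construct a variant classification catalogue
#'
#' @param groups named character vector mapping raw variant-classification
#'   labels to group labels; classes mapped to `excludedLabel` are dropped
#'   from all counts.
#' @param referenceGroup group used as the identifiability reference
#'   \eqn{s_1}; defaults to the first non-excluded group.
#' @param excludedLabel sentinel label for excluded classes.
#' @return a [VariantCatalog-class] object.
#' @examples
#' vc <- VariantCatalog(c(Missense_Mutation = "other",
#'                        Frame_Shift_Del = "indel",
#'                        Silent = "excluded"))
#' variantGroups(vc)
#' @export
VariantCatalog <- function(groups, referenceGroup = NULL,
                           excludedLabel = "excluded") {
  live <- setdiff(unique(unname(groups)), excludedLabel)
  if (is.null(referenceGroup)) referenceGroup <- live[1L]
  new("VariantCatalog",
    classes = names(groups), groups = groups,
    referenceGroup = referenceGroup, excludedLabel = excludedLabel
  )
}

#' Default two-group catalogue for TMB/TIB work
#'
#' Frameshift insertions and deletions form the `"indel"` group; the other
#' non-synonymous classes (missense, nonsense, splice site, in-frame
#' insertion/deletion, nonstop, translation start site) form `"other"`, which
#' is also the identifiability reference. Silent mutations are excluded.
#' In-frame indels sit in `"other"` because the indel-burden biomarker counts
#' frameshift events only; remap them if a different convention is needed.
#'
#' @param inFrameAsIndel if `TRUE`, count in-frame insertions/deletions in the
#'   `"indel"` group instead.
#' @return a [VariantCatalog-class].
#' @export
defaultVariantCatalog <- function(inFrameAsIndel = FALSE) {
  inframe <- if (inFrameAsIndel) "indel" else "other"
  VariantCatalog(
    c(
      Missense_Mutation = "other",
      Nonsense_Mutation = "other",
      Frame_Shift_Del = "indel",
      Frame_Shift_Ins = "indel",
      Splice_Site = "other",
      In_Frame_Del = inframe,
      In_Frame_Ins = inframe,
      Nonstop_Mutation = "other",
      Translation_Start_Site = "other",
      Silent = "excluded"
    ),
    referenceGroup = "other"
  )
}

#' @describeIn VariantCatalog-class ordered non-excluded groups, reference
#'   first.
#' @export
setMethod("variantGroups", "VariantCatalog", function(x, ...) {
  live <- setdiff(unique(unname(x@groups)), x@excludedLabel)
  c(x@referenceGroup, setdiff(live, x@referenceGroup))
})

#' @describeIn VariantCatalog-class the identifiability reference group.
#' @export
setMethod("referenceGroup", "VariantCatalog", function(x, ...)
  x@referenceGroup)

setMethod("show", "VariantCatalog", function(object) {
  cat("VariantCatalog with", length(object@classes), "raw classes ->",
      paste(variantGroups(object), collapse = ", "),
      sprintf("(reference: %s)\n", object@referenceGroup))
})

## ---- biomarker specs ------------------------------------------------------

#' Construct a biomarker specification
#'
#' @param name biomarker label.
#' @param targetGroups variant groups summed by the biomarker (\eqn{\bar S}).
#' @param threshold inclusive high/low classification cutoff.
#' @return a [BiomarkerSpec-class].
#' @export
BiomarkerSpec <- function(name, targetGroups, threshold = 0) {
  new("BiomarkerSpec",
    name = name, targetGroups = targetGroups,
    threshold = as.numeric(threshold)
  )
}

#' Standard biomarker specifications
#'
#' `tmbSpec()` is tumour mutation burden: all non-synonymous mutations, high
#' class at 300 or more exome mutations (about 10 Mut/Mb). `tibSpec()` is
#' tumour indel burden: frameshift indels only, high class at ten or more.
#'
#' @param catalog a [VariantCatalog-class] providing the group labels.
#' @return a [BiomarkerSpec-class].
#' @export
tmbSpec <- function(catalog = defaultVariantCatalog()) {
  BiomarkerSpec("TMB", variantGroups(catalog), threshold = 300)
}

#' @rdname tmbSpec
#' @export
tibSpec <- function(catalog = defaultVariantCatalog()) {
  BiomarkerSpec("TIB", "indel", threshold = 10)
}

setMethod("show", "BiomarkerSpec", function(object) {
  cat(sprintf("BiomarkerSpec '%s': sum over groups {%s}, high class >= %g\n",
              object@name, paste(object@targetGroups, collapse = ", "),
              object@threshold))
})

## ---- gene lengths ---------------------------------------------------------

#' Read a gene-length table
#'
#' Expects a tab-separated file with columns `gene` and `length_bases`
#' (maximum coding sequence length in bases).
#'
#' @param path file path.
#' @return named numeric vector of lengths.
#' @export
readGeneLengths <- function(path) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE)
  for (col in c("gene", "length_bases")) {
    stopIfNot(col %in% names(tab),
              "gene-length table is missing required column '%s'", col)
  }
  stopIfNot(!anyDuplicated(tab$gene), "duplicate gene identifiers in '%s'",
            path)
  len <- as.numeric(tab$length_bases)
  stopIfNot(all(is.finite(len)) && all(len > 0),
            "gene lengths must be strictly positive")
  names(len) <- tab$gene
  len
}

#' Write a gene-length table
#' @param lengths named numeric vector of coding lengths.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGeneLengths <- function(lengths, path) {
  utils::write.table(
    data.frame(gene = names(lengths), length_bases = unname(lengths)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

## ---- MAF ingestion --------------------------------------------------------

#' Read MAF-style annotated mutation calls
#'
#' Reads a tab-separated MAF file, keeping only the sample, gene and
#' variant-classification columns, and tags each row with its variant group.
#' Rows whose class maps to the excluded (synonymous) group, or is absent
#' from the catalogue, are retained but flagged `excluded` so they never enter
#' counts. Malformed rows (empty sample or gene) are dropped with a warning
#' naming their line numbers.
#'
#' @param path MAF file path.
#' @param catalog a [VariantCatalog-class].
#' @param columns named character vector giving the column names to use for
#'   `sample`, `gene` and `class`.
#' @return a `data.frame` with columns `sample`, `gene`, `variantClass`,
#'   `group`, `excluded`.
#' @export
readMAF <- function(path, catalog = defaultVariantCatalog(),
                    columns = c(sample = "Tumor_Sample_Barcode",
                                gene = "Hugo_Symbol",
                                class = "Variant_Classification")) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE, colClasses = "character")
  for (role in c("sample", "gene", "class")) {
    stopIfNot(columns[[role]] %in% names(tab),
              "MAF file is missing required column '%s' (%s)",
              columns[[role]], role)
  }
  if (nrow(tab) == 0L) {
    warning("MAF file '", path, "' has no data rows")
    return(data.frame(sample = character(), gene = character(),
                      variantClass = character(), group = character(),
                      excluded = logical()))
  }
  rec <- data.frame(
    sample = tab[[columns[["sample"]]]],
    gene = tab[[columns[["gene"]]]],
    variantClass = tab[[columns[["class"]]]],
    stringsAsFactors = FALSE
  )
  bad <- is.na(rec$sample) | rec$sample == "" | is.na(rec$gene) | rec$gene == ""
  if (any(bad)) {
    warning("dropping ", sum(bad), " malformed MAF row(s) at line(s) ",
            paste(utils::head(which(bad) + 1L, 20L), collapse = ", "))
    rec <- rec[!bad, , drop = FALSE]
  }
  grp <- unname(catalog@groups[rec$variantClass])
  unknown <- is.na(grp)
  if (any(unknown)) {
    warning(sum(unknown), " row(s) with unrecognised variant class (",
            paste(unique(rec$variantClass[unknown]), collapse = ", "),
            ") treated as excluded")
    grp[unknown] <- catalog@excludedLabel
  }
  rec$group <- grp
  rec$excluded <- grp == catalog@excludedLabel
  rownames(rec) <- NULL
  rec
}

## ---- aggregation ----------------------------------------------------------

#' Build a MutationExperiment
#'
#' Low-level constructor from per-group count matrices.
#'
#' @param counts named list of genes-by-samples integer matrices, one per
#'   variant group (identical dimnames).
#' @param geneLengths named numeric of coding lengths covering all genes.
#' @param referenceGroup identifiability reference group; defaults to the
#'   first assay.
#' @return a [MutationExperiment-class].
#' @export
MutationExperiment <- function(counts, geneLengths,
                               referenceGroup = names(counts)[1L]) {
  stopIfNot(is.list(counts) && !is.null(names(counts)),
            "counts must be a named list of matrices (one per group)")
  genes <- rownames(counts[[1L]])
  stopIfNot(all(genes %in% names(geneLengths)),
            "every gene must have a length in geneLengths")
  se <- SummarizedExperiment(
    assays = counts,
    rowData = DataFrame(length = as.numeric(geneLengths[genes]),
                        row.names = genes)
  )
  obj <- new("MutationExperiment", se)
  metadata(obj)$variantGroups <- names(counts)
  metadata(obj)$referenceGroup <- referenceGroup
  obj
}

#' Aggregate mutation records into a count tensor
#'
#' Counts non-excluded records per (sample, gene, group) cell. Genes come
#' from `geneLengths` (zero rows are kept so the model's rates are defined for
#' every gene); set `observedOnly = TRUE` to restrict to genes with at least
#' one record. Samples are ordered by first appearance unless `samples` is
#' given.
#'
#' @param records data frame from [readMAF()].
#' @param geneLengths named numeric of coding lengths.
#' @param catalog the [VariantCatalog-class] used to read the records.
#' @param samples optional explicit sample ordering (may include samples with
#'   no records).
#' @param unknownGenes `"drop"` (default, with a warning) or `"error"` for
#'   records naming genes absent from `geneLengths`.
#' @param observedOnly keep only genes with at least one counted record.
#' @return a [MutationExperiment-class].
#' @export
aggregateCounts <- function(records, geneLengths,
                            catalog = defaultVariantCatalog(),
                            samples = NULL,
                            unknownGenes = c("drop", "error"),
                            observedOnly = FALSE) {
  unknownGenes <- match.arg(unknownGenes)
  rec <- records[!records$excluded, , drop = FALSE]
  missing <- !(rec$gene %in% names(geneLengths))
  if (any(missing)) {
    if (unknownGenes == "error") {
      stop("records name gene(s) absent from the gene catalogue: ",
           paste(utils::head(unique(rec$gene[missing]), 10L), collapse = ", "))
    }
    warning("dropping ", sum(missing),
            " record(s) for gene(s) absent from the gene catalogue")
    rec <- rec[!missing, , drop = FALSE]
  }
  if (is.null(samples)) samples <- unique(records$sample)
  stopIfNot(all(rec$sample %in% samples),
            "records contain samples outside the supplied sample list")
  groups <- variantGroups(catalog)
  genes <- if (observedOnly) {
    intersect(names(geneLengths), unique(rec$gene))
  } else {
    names(geneLengths)
  }
  counts <- lapply(groups, function(s) {
    sub <- rec[rec$group == s, , drop = FALSE]
    m <- matrix(0L, nrow = length(genes), ncol = length(samples),
                dimnames = list(genes, samples))
    if (nrow(sub)) {
      tab <- table(factor(sub$gene, levels = genes),
                   factor(sub$sample, levels = samples))
      m[] <- as.integer(tab)
    }
    m
  })
  names(counts) <- groups
  MutationExperiment(counts, geneLengths,
                     referenceGroup = referenceGroup(catalog))
}

## ---- accessors & biomarkers ----------------------------------------------

#' @describeIn MutationExperiment-class variant group labels (assay names).
#' @export
setMethod("variantGroups", "MutationExperiment", function(x, ...)
  assayNames(x))

#' @describeIn MutationExperiment-class identifiability reference group.
#' @export
setMethod("referenceGroup", "MutationExperiment", function(x, ...)
  metadata(x)$referenceGroup)

#' @describeIn MutationExperiment-class named coding lengths of the genes.
#' @export
setMethod("geneLengths", "MutationExperiment", function(x, ...) {
  len <- rowData(x)$length
  names(len) <- rownames(x)
  len
})

#' @describeIn MutationExperiment-class per-sample biomarker values
#'   \eqn{T_i = \sum_g \sum_{s \in \bar S} M_{igs}}.
#' @param spec a [BiomarkerSpec-class].
#' @export
setMethod("biomarkerValues", "MutationExperiment", function(x, spec, ...) {
  bad <- setdiff(spec@targetGroups, variantGroups(x))
  if (length(bad)) {
    stop("biomarker target group(s) not present in the counts: ",
         paste(bad, collapse = ", "))
  }
  vals <- rep(0, ncol(x))
  for (s in spec@targetGroups) vals <- vals + colSums(assay(x, s))
  names(vals) <- colnames(x)
  vals
})

setMethod("show", "MutationExperiment", function(object) {
  cat(sprintf(
    "MutationExperiment: %d genes x %d samples, groups {%s}, %d mutations\n",
    nrow(object), ncol(object),
    paste(variantGroups(object), collapse = ", "),
    sum(vapply(assays(object), sum, numeric(1)))
  ))
})

## ---- sample splitting -----------------------------------------------------

#' Split samples into training / validation / test sets
#'
#' Random, seeded, exhaustive and disjoint. Split sizes are the
#' largest-remainder apportionment of `fractions`, with ties resolved in
#' split order (training first).
#'
#' @param samples character vector of sample identifiers.
#' @param fractions positive numeric of length 3 summing to 1
#'   (train, validation, test).
#' @param seed integer RNG seed.
#' @return named list of character vectors `train`, `validation`, `test`.
#' @export
splitSamples <- function(samples, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  stopIfNot(length(fractions) == 3L && all(fractions >= 0) &&
              abs(sum(fractions) - 1) < 1e-8,
            "fractions must be three non-negative numbers summing to 1")
  n <- length(samples)
  sizes <- floor(n * fractions)
  rem <- n - sum(sizes)
  if (rem > 0) {
    frac <- n * fractions - sizes
    extra <- order(-frac)[seq_len(rem)]  # order() breaks ties train-first
    sizes[extra] <- sizes[extra] + 1L
  }
  stopIfNot(all(sizes[fractions > 0] >= 1L),
            "too few samples (%d) for the requested non-empty splits", n)
  perm <- withSeed(seed, sample(samples))
  ends <- cumsum(sizes)
  list(
    train = sort(perm[seq_len(sizes[1L])]),
    validation = sort(perm[seq_len(sizes[2L]) + ends[1L]]),
    test = sort(perm[seq_len(sizes[3L]) + ends[2L]])
  )
}

## ---- serialization --------------------------------------------------------

#' Write / read the count tensor as long-format TSV
#'
#' `writeCounts()` writes the non-zero cells as a `sample`, `gene`, `group`,
#' `count` TSV, plus a JSON index sidecar (`<path>.index.json`) recording the
#' full sample/gene/group ordering, gene lengths and reference group, so the
#' round trip reproduces the tensor exactly, zero rows included.
#'
#' @param x a [MutationExperiment-class].
#' @param path TSV path.
#' @return `writeCounts()`: `path`, invisibly. `readCounts()`: the
#'   reconstructed [MutationExperiment-class].
#' @export
writeCounts <- function(x, path) {
  cells <- do.call(rbind, lapply(variantGroups(x), function(s) {
    m <- assay(x, s)
    idx <- which(m > 0, arr.ind = TRUE)
    data.frame(
      sample = colnames(m)[idx[, 2L]],
      gene = rownames(m)[idx[, 1L]],
      group = rep(s, nrow(idx)),
      count = m[idx],
      stringsAsFactors = FALSE
    )
  }))
  cells <- cells[order(cells$sample, cells$gene, cells$group), , drop = FALSE]
  utils::write.table(cells, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(
      samples = colnames(x), genes = rownames(x),
      lengths = unname(geneLengths(x)), groups = variantGroups(x),
      referenceGroup = referenceGroup(x)
    ),
    paste0(path, ".index.json")
  )
  invisible(path)
}

#' @rdname writeCounts
#' @export
readCounts <- function(path) {
  idx <- jsonlite::read_json(paste0(path, ".index.json"),
                             simplifyVector = TRUE)
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE)
  lengths <- idx$lengths
  names(lengths) <- idx$genes
  counts <- lapply(idx$groups, function(s) {
    m <- matrix(0L, nrow = length(idx$genes), ncol = length(idx$samples),
                dimnames = list(idx$genes, idx$samples))
    sub <- tab[tab$group == s, , drop = FALSE]
    if (nrow(sub)) m[cbind(sub$gene, sub$sample)] <- as.integer(sub$count)
    m
  })
  names(counts) <- idx$groups
  MutationExperiment(counts, lengths, referenceGroup = idx$referenceGroup)
}
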