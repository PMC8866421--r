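#' @include AllClasses.R AllGenerics.R mutation-data.R panel-selection.R
NULL

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - \sum_i (t_i - \hat t_i)^2 / \sum_i (t_i - \bar t)^2};
#' can be arbitrarily negative for estimators worse than the mean.
#'
#' @param truth numeric vector of true biomarker values.
#' @param pred numeric vector of predictions, same length.
#' @return a number, at most 1.
#' @export
rSquared <- function(truth, pred) {
  stopIfNot(length(truth) == length(pred) && length(truth) >= 2L,
            "truth and pred must have equal length of at least 2")
  sst <- sum((truth - mean(truth))^2)
  stopIfNot(sst > 0, "truth values are all equal; R^2 is undefined")
  1 - sum((truth - pred)^2) / sst
}

#' Precision-recall curve and AUPRC
#'
#' Classifies a sample high if its score is at least the threshold \eqn{t}.
#' Sweeping \eqn{t} over the distinct scores (plus an all-negative
#' sentinel), precision \eqn{p(t)} and recall \eqn{r(t)} are the usual
#' indicator ratios; thresholds with zero predicted positives are dropped
#' (0/0 precision). The area is the step integral
#' \eqn{\sum_k (r_k - r_{k-1}) p_k} over decreasing thresholds; tied scores
#' move between classes together.
#'
#' @param scores numeric scores (higher means more likely high class).
#' @param labels logical or 0/1 true class labels; at least one positive.
#' @return list with `curve` (data frame `threshold`, `recall`,
#'   `precision`) and `auprc`.
#' @export
prCurve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopIfNot(length(scores) == length(labels),
            "scores and labels must have equal length")
  stopIfNot(any(labels), "at least one positive label is required")
  nPos <- sum(labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- cumsum(vapply(
    thr, function(t) sum(labels[scores == t]), numeric(1)
  ))
  npred <- cumsum(vapply(
    thr, function(t) sum(scores == t), numeric(1)
  ))
  curve <- data.frame(
    threshold = thr,
    recall = tp / nPos,
    precision = tp / npred
  )
  rPrev <- 0
  auprc <- 0
  for (k in seq_len(nrow(curve))) {
    auprc <- auprc + (curve$recall[k] - rPrev) * curve$precision[k]
    rPrev <- curve$recall[k]
  }
  list(curve = curve, auprc = auprc)
}

#' @rdname prCurve
#' @export
auprc <- function(scores, labels) prCurve(scores, labels)$auprc

#' ROC curve and area
#'
#' `rocAuc()` is computed as the normalized Mann-Whitney U statistic (ties
#' count one half), which equals the trapezoidal area under the ROC curve;
#' `rocCurve()` returns the (FPR, TPR) sweep.
#'
#' @param scores numeric scores.
#' @param labels logical or 0/1 labels; both classes must be present.
#' @return `rocAuc()`: a number in \[0, 1\]; `rocCurve()`: a data frame
#'   with columns `threshold`, `fpr`, `tpr`.
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopIfNot(any(labels) && any(!labels),
            "both classes must be present for ROC analysis")
  pos <- scores[labels]
  neg <- scores[!labels]
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' @rdname rocAuc
#' @export
rocCurve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopIfNot(any(labels) && any(!labels),
            "both classes must be present for ROC analysis")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) mean(scores[!labels] >= t), numeric(1)),
    tpr = vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))
  )
}

#' Count-rescaling baseline estimator
#'
#' \eqn{(\ell_G/\ell_P) \sum_{g\in P}\sum_{s\in\bar S} M_{0gs}}: the
#' panel's target-group burden scaled up by the exome-to-panel length
#' ratio.
#'
#' @param x test [MutationExperiment-class].
#' @param panel a non-empty [GenePanel-class].
#' @param geneLengths named numeric of coding lengths over the full gene
#'   set \eqn{G}.
#' @param spec a [BiomarkerSpec-class].
#' @return named numeric of per-sample estimates.
#' @export
countEstimator <- function(x, panel, geneLengths, spec) {
  stopIfNot(length(panelGenes(panel)) > 0L,
            "count estimator needs a non-empty panel")
  scale <- sum(geneLengths) / panelLength(panel)
  sel <- intersect(panelGenes(panel), rownames(x))
  est <- rep(0, ncol(x))
  for (s in spec@targetGroups) {
    est <- est + colSums(assay(x, s)[sel, , drop = FALSE])
  }
  stats::setNames(scale * est, colnames(x))
}

#' Indel-burden count baseline
#'
#' Rescales the panel's total non-synonymous burden by the exome-to-panel
#' length ratio and by the training-set relative frequency of indel
#' mutations among all non-synonymous mutations:
#' \eqn{(\ell_G/\ell_P)\,\hat\rho\,\sum_{g\in P}\sum_{s\in S} M_{0gs}}.
#'
#' @param x test [MutationExperiment-class].
#' @param train training [MutationExperiment-class] (supplies
#'   \eqn{\hat\rho}).
#' @param panel a non-empty [GenePanel-class].
#' @param geneLengths named numeric over the full gene set.
#' @param indelGroups variant group(s) forming the indel burden.
#' @return named numeric of per-sample estimates.
#' @export
tibCountEstimator <- function(x, train, panel, geneLengths,
                              indelGroups = "indel") {
  tot <- sum(vapply(variantGroups(train),
                    function(s) sum(assay(train, s)), numeric(1)))
  stopIfNot(tot > 0, "training counts contain no mutations")
  ind <- sum(vapply(indelGroups, function(s) sum(assay(train, s)),
                    numeric(1)))
  rho <- ind / tot
  scale <- sum(geneLengths) / panelLength(panel)
  sel <- intersect(panelGenes(panel), rownames(x))
  est <- rep(0, ncol(x))
  for (s in variantGroups(x)) {
    est <- est + colSums(assay(x, s)[sel, , drop = FALSE])
  }
  stats::setNames(scale * rho * est, colnames(x))
}

#' Ordinary least-squares baseline
#'
#' Regresses the training biomarker on the per-gene total mutation counts
#' of the panel genes (summed over all variant groups), with an intercept.
#' A rank-deficient design falls back to the minimum-norm solution with a
#' warning. An empty panel gives the intercept-only model.
#'
#' @param train training [MutationExperiment-class].
#' @param trainT numeric of training biomarker values (one per training
#'   sample, in column order).
#' @param panel a [GenePanel-class].
#' @return an object of class `burdenLinearModel` with a `predict` method
#'   taking a [MutationExperiment-class].
#' @export
linearBaseline <- function(train, trainT, panel) {
  genes <- intersect(panelGenes(panel), rownames(train))
  X <- .geneTotals(train, genes)
  n <- nrow(X)
  stopIfNot(length(trainT) == n,
            "trainT must have one value per training sample")
  Xd <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(Xd)
  if (qrX$rank < ncol(Xd)) {
    warning("rank-deficient design; using the minimum-norm OLS solution")
    beta <- as.numeric(MASS::ginv(Xd) %*% trainT)
  } else {
    beta <- as.numeric(qr.coef(qrX, trainT))
  }
  names(beta) <- colnames(Xd)
  structure(
    list(coefficients = beta, genes = genes),
    class = "burdenLinearModel"
  )
}

.geneTotals <- function(x, genes) {
  out <- matrix(0, ncol(x), length(genes),
                dimnames = list(colnames(x), genes))
  for (s in variantGroups(x)) {
    out <- out + t(assay(x, s)[genes, , drop = FALSE])
  }
  out
}

#' @export
predict.burdenLinearModel <- function(object, newdata, ...) {
  missing <- setdiff(object$genes, rownames(newdata))
  stopIfNot(length(missing) == 0L,
            "test counts are missing model gene(s): %s",
            paste(utils::head(missing, 10L), collapse = ", "))
  X <- .geneTotals(newdata, object$genes)
  est <- as.numeric(cbind(1, X) %*% object$coefficients)
  stats::setNames(est, colnames(newdata))
}

#' Regression and classification summary
#'
#' Bundles \eqn{R^2}, AUPRC and AUROC for predictions of a thresholded
#' biomarker.
#'
#' @param truth true biomarker values.
#' @param pred predicted values (used as classification scores).
#' @param threshold inclusive high-class cutoff on `truth`.
#' @return data frame with columns `r2`, `auprc`, `auroc`, `n`,
#'   `prevalence`.
#' @export
evaluatePredictions <- function(truth, pred, threshold) {
  labels <- truth >= threshold
  data.frame(
    r2 = rSquared(truth, pred),
    auprc = if (any(labels)) auprc(pred, labels) else NA_real_,
    auroc = if (any(labels) && any(!labels)) rocAuc(pred, labels)
            else NA_real_,
    n = length(truth),
    prevalence = mean(labels)
  )
}
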