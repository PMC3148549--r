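## ROC/AUC machinery. The AUC is the Mann-Whitney rank statistic
## P(score_case > score_control) + 0.5 * P(tie), which equals the
## trapezoidal area under the ROC curve with tied scores grouped at one
## threshold.

.checkScores <- function(scores, labels) {
  labels <- as.integer(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  if (!any(labels == 1L) || !any(labels == 0L))
    stop("both classes must be present; the curve/AUC is undefined")
  list(scores = scores, labels = labels)
}

#' ROC curve by exhaustive threshold sweep
#'
#' Sweeps every distinct score value as a threshold (ties grouped), with
#' samples scoring at or above the threshold called positive. The curve
#' starts at (FPR, TPR) = (0, 0) (threshold above all scores) and ends at
#' (1, 1).
#'
#' @param scores Numeric prediction scores (higher = more case-like).
#' @param labels Binary 0/1 outcome, 1 = case.
#' @return data.frame of class \code{"ROCCurve"}: threshold, fpr, tpr.
#' @export
rocCurve <- function(scores, labels) {
  d <- .checkScores(scores, labels)
  ord <- order(d$scores, decreasing = TRUE)
  s <- d$scores[ord]; y <- d$labels[ord]
  n1 <- sum(y); n0 <- length(y) - n1
  grp <- !duplicated(s)
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- c(which(grp[-1L]) , length(s))  # last index of each tied block
  curve <- data.frame(threshold = c(Inf, s[last]),
                      fpr = c(0, fp[last] / n0),
                      tpr = c(0, tp[last] / n1))
  class(curve) <- c("ROCCurve", "data.frame")
  curve
}

## Trapezoidal area under an ROC curve.
.rocArea <- function(curve) {
  sum(diff(curve$fpr) * (utils::head(curve$tpr, -1L) + utils::tail(curve$tpr, -1L)) / 2)
}

#' Rank-statistic AUC with standard error and significance vs chance
#'
#' AUC = P(case score > control score) + 0.5 P(tie), computed from the
#' Mann-Whitney rank sum. The standard error of the estimate is
#' Hanley-McNeil; the two-sided p-value against AUC = 0.5 uses the normal
#' approximation with the null-hypothesis variance of the Mann-Whitney
#' statistic (tie-corrected).
#'
#' @inheritParams rocCurve
#' @return An \linkS4class{AUCResult}.
#' @export
aucScore <- function(scores, labels) {
  d <- .checkScores(scores, labels)
  n1 <- sum(d$labels); n0 <- length(d$labels) - n1
  r <- rank(d$scores)  # midranks: ties get half credit
  auc <- (sum(r[d$labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ## Hanley-McNeil SE of the estimate
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt(max(0, auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                   (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  new("AUCResult", auc = auc, se = se,
      pValue = .aucNormalP(auc, n1, n0, d$scores),
      nCases = as.integer(n1), nControls = as.integer(n0))
}

## Null-variance normal approximation, with tie correction as in the
## normal approximation to the Wilcoxon rank-sum test.
.aucNormalP <- function(auc, n1, n0, scores = NULL) {
  n <- n1 + n0
  v <- (n + 1) / (12 * n1 * n0)
  if (!is.null(scores)) {
    ties <- table(scores)
    v <- v - sum(ties^3 - ties) / (12 * n1 * n0 * n * (n - 1))
  }
  if (v <= 0) return(1)
  ## continuity correction: half a step of the discrete Mann-Whitney count
  z <- max(0, abs(auc - 0.5) - 1 / (2 * n1 * n0)) / sqrt(v)
  min(1, 2 * stats::pnorm(-z))
}

#' p-value for an AUC differing from 0.5
#'
#' \code{method = "normal"} uses the null-variance normal approximation of
#' the Mann-Whitney statistic. \code{method = "permutation"} permutes the
#' case/control labels: exhaustively when the number of distinct label
#' assignments is small (at most \code{maxExact}), otherwise by Monte-Carlo
#' sampling, and compares |AUC - 0.5| against the permutation distribution.
#'
#' @inheritParams rocCurve
#' @param method "normal" or "permutation".
#' @param nPermutations Monte-Carlo sample size when exhaustive enumeration
#'   is infeasible.
#' @param maxExact Enumeration budget (number of case-index combinations).
#' @param seed Seed for Monte-Carlo permutations.
#' @return A single p-value in (0, 1].
#' @export
aucPvalue <- function(scores, labels, method = c("normal", "permutation"),
                      nPermutations = 10000L, maxExact = 200000L,
                      seed = 1L) {
  method <- match.arg(method)
  d <- .checkScores(scores, labels)
  n1 <- sum(d$labels); n0 <- length(d$labels) - n1
  obs <- aucStat(d$scores, d$labels)
  if (method == "normal")
    return(.aucNormalP(obs, n1, n0, d$scores))
  n <- n1 + n0
  dev <- abs(obs - 0.5) - 1e-12
  if (choose(n, n1) <= maxExact) {
    combs <- utils::combn(n, n1)
    hits <- 0L
    for (i in seq_len(ncol(combs))) {
      y <- integer(n); y[combs[, i]] <- 1L
      if (abs(aucStat(d$scores, y) - 0.5) >= dev) hits <- hits + 1L
    }
    hits / ncol(combs)
  } else {
    perm <- withSeed(seed, vapply(seq_len(nPermutations), function(i) {
      aucStat(d$scores, sample(d$labels))
    }, 0))
    (1 + sum(abs(perm - 0.5) >= dev)) / (nPermutations + 1)
  }
}

#' Bare AUC point estimate
#'
#' The rank-statistic AUC without standard error or p-value; convenient in
#' tight loops (permutation nulls, property checks).
#'
#' @inheritParams rocCurve
#' @return AUC in [0, 1].
#' @export
aucStat <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Predictive values at an ROC operating point
#'
#' Applies Bayes' rule at a threshold characterised by its sensitivity and
#' specificity, for a given disease prevalence:
#' PPV = sens * prev / (sens * prev + (1 - spec)(1 - prev)),
#' NPV = spec * (1 - prev) / (spec * (1 - prev) + (1 - sens) * prev).
#'
#' @param sensitivity,specificity,prevalence Values in [0, 1].
#' @return A list of class \code{"OperatingPoint"} with fields sensitivity,
#'   specificity, prevalence, ppv, npv.
#' @examples
#' op <- operatingPoint(0.2, 0.95, 0.3)
#' round(op$npv, 2)
#' @export
operatingPoint <- function(sensitivity, specificity, prevalence) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1,
            prevalence >= 0, prevalence <= 1)
  ppvDen <- sensitivity * prevalence + (1 - specificity) * (1 - prevalence)
  npvDen <- specificity * (1 - prevalence) + (1 - sensitivity) * prevalence
  if (ppvDen == 0)
    stop("PPV undefined: no positive calls at this operating point ",
         "(sensitivity and 1 - specificity both zero, or degenerate prevalence)")
  if (npvDen == 0)
    stop("NPV undefined: no negative calls at this operating point")
  structure(list(sensitivity = sensitivity, specificity = specificity,
                 prevalence = prevalence,
                 ppv = sensitivity * prevalence / ppvDen,
                 npv = specificity * (1 - prevalence) / npvDen),
            class = "OperatingPoint")
}

#' @export
print.OperatingPoint <- function(x, ...) {
  cat(sprintf("Operating point: sens %.2f, spec %.2f @ prevalence %.2f -> PPV %.3f, NPV %.3f\n",
              x$sensitivity, x$specificity, x$prevalence, x$ppv, x$npv))
  invisible(x)
}
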