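#' Model specification: which SNPs, and whether clinical traits enter
#'
#' @param snpIds Ordered character vector of SNP ids (possibly empty for a
#'   clinical-only model).
#' @param includeClinical Include the four clinical covariates (age, sex,
#'   FEV1 percent predicted, treatment group) as predictors.
#' @return A list of class \code{"ModelSpec"}.
#' @export
modelSpec <- function(snpIds = character(0), includeClinical = TRUE) {
  if (!length(snpIds) && !includeClinical)
    stop("model must use at least one predictor (SNPs and/or clinical traits)")
  structure(list(snpIds = as.character(snpIds),
                 includeClinical = isTRUE(includeClinical)),
            class = "ModelSpec")
}

## Assemble the feature frame for a model spec. Sex and treatment are
## categorical codes and enter as fixed-level factors; age and FEV1% are
## numeric.
.assembleFeatures <- function(cohort, spec) {
  parts <- list()
  if (length(spec$snpIds)) {
    X <- encodeAdditive(cohort)
    absent <- setdiff(spec$snpIds, colnames(X))
    if (length(absent))
      stop("SNP(s) not on the genotype panel: ",
           paste(utils::head(absent, 5L), collapse = ", "))
    parts$snp <- as.data.frame(X[, spec$snpIds, drop = FALSE])
  }
  if (spec$includeClinical) {
    cv <- covariates(cohort)
    if (is.null(cv))
      stop("model spec includes clinical traits but the cohort has no covariates attached")
    parts$clin <- data.frame(age = as.numeric(cv$age),
                             sex = factor(cv$sex, levels = c(1L, 2L)),
                             fev1_pct_pred = as.numeric(cv$fev1_pct_pred),
                             treatment = factor(cv$treatment, levels = 1:3),
                             row.names = sampleIds(cohort))
  }
  df <- do.call(cbind, unname(parts))
  rownames(df) <- sampleIds(cohort)
  df
}

#' Impute missing genotypes from control genotype frequencies
#'
#' Every missing call is replaced by a random draw from \{0, 1, 2\} with
#' probabilities equal to that SNP's observed genotype frequency
#' distribution among the non-missing calls of the control (non-case)
#' samples of the training cohort. Non-missing calls are never touched.
#' A SNP with zero non-missing control calls falls back to the pooled
#' frequencies across all training samples (with a warning), and to a
#' uniform draw if even those are absent.
#'
#' @param target \linkS4class{GwasCohort} whose missing calls are imputed.
#' @param controls \linkS4class{GwasCohort} of training control samples (or
#'   a full training cohort: samples with \code{outcome == 0} are used and,
#'   for the fallback, all of its samples).
#' @param seed Integer seed; draws are deterministic given it.
#' @return The target cohort with no missing genotype calls.
#' @export
imputeMissingFromControls <- function(target, controls, seed = 1L) {
  gt <- genotypes(target)
  if (!anyNA(gt)) return(target)
  if (!identical(rownames(gt), rownames(genotypes(controls))))
    stop("target and control SNP panels are not aligned")
  gc <- genotypes(controls)
  yc <- outcome(controls)
  ctrl <- if (!is.null(yc) && any(yc == 0L, na.rm = TRUE))
    gc[, !is.na(yc) & yc == 0L, drop = FALSE] else gc
  freqOf <- function(m, j) {
    v <- m[j, ]
    v <- v[!is.na(v)]
    if (!length(v)) return(NULL)
    tabulate(v + 1L, 3L) / length(v)
  }
  withSeed(seed, {
    for (j in which(rowSums(is.na(gt)) > 0L)) {
      pr <- freqOf(ctrl, j)
      if (is.null(pr)) {
        pr <- freqOf(gc, j)
        warning("SNP ", rownames(gt)[j],
                ": no non-missing control calls; falling back to pooled training frequencies")
        if (is.null(pr)) pr <- rep(1 / 3, 3L)
      }
      miss <- which(is.na(gt[j, ]))
      gt[j, miss] <- sample(0:2, length(miss), replace = TRUE, prob = pr)
    }
  })
  assay(target, "genotype") <- gt
  target
}

#' Build a top-k SNP + clinical-trait prediction forest
#'
#' Fits one forest on the selected SNP columns (additively coded) plus,
#' when requested, the four clinical covariates, with \code{ntree} trees
#' (study default 1,500) and default \code{mtry} over the realized feature
#' count. Training data must be imputed and carry both outcome classes.
#'
#' @param train Training \linkS4class{GwasCohort}.
#' @param spec A \code{\link{modelSpec}}.
#' @param rfCtrl An \code{\link{rfControl}}.
#' @param seed Seed for the fit (default \code{rfCtrl$seed}).
#' @return A list of class \code{"PredictionModel"} (forest + spec).
#' @export
buildPredictionModel <- function(train, spec, rfCtrl = rfControl(),
                                 seed = rfCtrl$seed) {
  feats <- .assembleFeatures(train, spec)
  y <- outcome(train)
  if (is.null(y) || anyNA(y)) stop("training cohort must carry a complete outcome")
  forest <- fitForest(feats, y, rfCtrl, seed = seed)
  structure(list(forest = forest, spec = spec,
                 featureNames = colnames(feats), ntree = rfCtrl$ntree),
            class = "PredictionModel")
}

#' @export
print.PredictionModel <- function(x, ...) {
  cat("PredictionModel:", length(x$spec$snpIds), "SNPs",
      if (x$spec$includeClinical) "+ 4 clinical traits" else "(no clinical traits)",
      "|", x$ntree, "trees\n")
  invisible(x)
}

#' Vote-fraction scores for a cohort
#'
#' The prediction score of a sample is the fraction of trees voting "case";
#' it lies in [0, 1] with granularity 1/ntree.
#'
#' @param model A \code{\link{buildPredictionModel}} fit.
#' @param cohort Cohort to score; must be imputed and carry the same
#'   feature columns as training.
#' @return Named numeric vector of scores.
#' @export
predictScores <- function(model, cohort) {
  feats <- .assembleFeatures(cohort, model$spec)
  if (!identical(colnames(feats), model$featureNames))
    stop("feature columns do not match the trained model")
  if (anyNA(feats))
    stop("features contain missing values; impute first (see imputeMissingFromControls)")
  pr <- stats::predict(model$forest, newdata = feats, type = "prob")
  stats::setNames(as.numeric(pr[, "1"]), rownames(feats))
}

#' Internal cross-validation on the training cohort
#'
#' One random 90/10 split, stratified by outcome so the hold-out fold
#' contains both classes: the model is fitted on 90% of the training
#' samples and the AUC measured on the held-out 10%.
#'
#' @param train Training \linkS4class{GwasCohort} (imputed).
#' @param spec A \code{\link{modelSpec}}.
#' @param rfCtrl An \code{\link{rfControl}}.
#' @param seed Seed controlling the split and the fit.
#' @param repeats Number of independent splits; the returned AUCResult is
#'   from the first split when \code{repeats = 1}, otherwise the
#'   per-repeat AUCs are averaged (SE and p from the pooled mean are not
#'   defined and returned as NA).
#' @return An \linkS4class{AUCResult} (single split), or a list with
#'   \code{mean_auc} and per-repeat results when \code{repeats > 1}.
#' @export
internalCrossValidation <- function(train, spec, rfCtrl = rfControl(),
                                    seed = rfCtrl$seed, repeats = 1L) {
  y <- outcome(train)
  oneSplit <- function(s) {
    hold <- withSeed(deriveSeed(s, 17L), {
      unlist(lapply(split(seq_along(y), y), function(idx)
        sample(idx, max(1L, round(0.1 * length(idx))))))
    })
    fitC <- train[, -hold]
    holdC <- train[, hold]
    model <- buildPredictionModel(fitC, spec, rfCtrl, seed = deriveSeed(s, 18L))
    aucScore(predictScores(model, holdC), outcome(holdC))
  }
  if (repeats == 1L) return(oneSplit(seed))
  res <- lapply(seq_len(repeats), function(r) oneSplit(deriveSeed(seed, r)))
  list(mean_auc = mean(vapply(res, function(a) a@auc, 0)), results = res)
}

#' Independent replication on the Stage 2 cohort
#'
#' Missing Stage 2 genotypes are imputed from the Stage 1 control genotype
#' frequencies (the same rule fills any Stage 1 training missingness), the
#' model is fitted on all Stage 1 samples, and AUC, its standard error and
#' the p-value against AUC = 0.5 are computed from the Stage 2 vote
#' fractions.
#'
#' @param train Stage 1 \linkS4class{GwasCohort}.
#' @param test Stage 2 \linkS4class{GwasCohort}.
#' @param spec A \code{\link{modelSpec}}.
#' @param rfCtrl An \code{\link{rfControl}}.
#' @param seed Seed (imputation and fit streams derive from it).
#' @return An \linkS4class{AUCResult}; the scores are attached as
#'   attribute \code{"scores"}.
#' @export
independentReplication <- function(train, test, spec, rfCtrl = rfControl(),
                                   seed = rfCtrl$seed) {
  yTest <- outcome(test)
  if (is.null(yTest) || length(unique(stats::na.omit(yTest))) < 2L)
    stop("replication outcome must contain both classes; AUC is undefined")
  train <- imputeMissingFromControls(train, train, deriveSeed(seed, 31L))
  test <- imputeMissingFromControls(test, train, deriveSeed(seed, 32L))
  model <- buildPredictionModel(train, spec, rfCtrl, seed = deriveSeed(seed, 33L))
  sc <- predictScores(model, test)
  res <- aucScore(sc, yTest)
  attr(res, "scores") <- sc
  res
}

#' Run the SNP-count ladder
#'
#' For each model size k in \code{screenCtrl$selectionSizes} (plus the
#' clinical-only model, k = 0, when clinical traits are included) the top-k
#' stage-2 SNPs are taken, and three AUCs are computed: training
#' (resubstitution on Stage 1), internal 90/10 cross-validation, and
#' independent replication on Stage 2. Setting
#' \code{includeClinical = FALSE} gives the SNPs-alone variant.
#'
#' @param train,test Stage 1 / Stage 2 \linkS4class{GwasCohort}s.
#' @param records Stage-2 importance records (\code{\link{rerankTop}}).
#' @param screenCtrl A \code{\link{screenControl}}.
#' @param rfCtrl An \code{\link{rfControl}}.
#' @param includeClinical Include the clinical covariates in every model.
#' @param seed Master seed for the ladder.
#' @return data.frame with one row per k: n_snps, n_features, train_auc,
#'   cv_auc, replication_auc, replication_se, replication_p.
#' @export
runSnpLadder <- function(train, test, records, screenCtrl = screenControl(),
                         rfCtrl = rfControl(), includeClinical = TRUE,
                         seed = rfCtrl$seed) {
  poolSize <- sum(!is.na(records$stage2_rank))
  ks <- screenCtrl$selectionSizes
  if (any(ks > poolSize)) {
    warning("selection size(s) exceed the stage-2 pool (", poolSize,
            "); clipping")
    ks <- pmin(ks, poolSize)
  }
  ks <- unique(ks)
  if (includeClinical) ks <- c(0L, ks)
  train <- imputeMissingFromControls(train, train, deriveSeed(seed, 31L))
  test <- imputeMissingFromControls(test, train, deriveSeed(seed, 32L))
  rows <- lapply(seq_along(ks), function(i) {
    k <- ks[i]
    spec <- modelSpec(if (k > 0L) selectTop(records, k) else character(0),
                      includeClinical)
    kSeed <- deriveSeed(seed, 100L + i)
    model <- buildPredictionModel(train, spec, rfCtrl, seed = kSeed)
    trainAuc <- aucScore(predictScores(model, train), outcome(train))@auc
    cvAuc <- internalCrossValidation(train, spec, rfCtrl, seed = kSeed)@auc
    rep <- aucScore(predictScores(model, test), outcome(test))
    data.frame(n_snps = k,
               n_features = k + if (includeClinical) 4L else 0L,
               train_auc = trainAuc, cv_auc = cvAuc,
               replication_auc = rep@auc, replication_se = rep@se,
               replication_p = rep@pValue)
  })
  do.call(rbind, rows)
}
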