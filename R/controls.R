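## Null controls for the prediction pipeline. Both are iterated (study
## protocol: 10 times) and return the per-iteration replication AUCs plus
## their mean.

#' Permutation control
#'
#' Per iteration the training outcome labels are permuted uniformly at
#' random among samples (predictors keep their association with the
#' samples), the whole pipeline — two-stage SNP selection and model
#' building — is re-run on the permuted labels, and the resulting model is
#' scored on the unpermuted replication set. Re-running selection inside
#' each iteration is the default, so selection bias cannot leak signal into
#' the null; \code{reuseSelection = TRUE} instead reuses a fixed ranking
#' (cheaper, but a weaker null).
#'
#' @param train,test Stage 1 / Stage 2 \linkS4class{GwasCohort}s (imputed
#'   or imputable; missing calls are filled from training controls).
#' @param k Number of top-ranked SNPs per model.
#' @param nIterations Number of permutation iterations (default 10).
#' @param rfCtrl An \code{\link{rfControl}}.
#' @param screenCtrl A \code{\link{screenControl}}.
#' @param includeClinical Include the clinical covariates in the models.
#' @param reuseSelection Reuse \code{records} instead of re-running
#'   selection under each permutation.
#' @param records Stage-2 importance records; required when
#'   \code{reuseSelection = TRUE}.
#' @param seed Master seed.
#' @return A list of class \code{"ControlResult"}: \code{results}
#'   (data.frame iteration/auc), \code{mean_auc}, and \code{selections}
#'   (list of per-iteration selected SNP id sets).
#' @export
permutationControl <- function(train, test, k, nIterations = 10L,
                               rfCtrl = rfControl(),
                               screenCtrl = screenControl(),
                               includeClinical = TRUE,
                               reuseSelection = FALSE, records = NULL,
                               seed = rfCtrl$seed) {
  stopifnot(nIterations >= 1L)
  if (reuseSelection && is.null(records))
    stop("reuseSelection = TRUE requires precomputed importance records")
  train <- imputeMissingFromControls(train, train, deriveSeed(seed, 31L))
  test <- imputeMissingFromControls(test, train, deriveSeed(seed, 32L))
  y <- outcome(train)
  aucs <- numeric(nIterations)
  selections <- vector("list", nIterations)
  for (it in seq_len(nIterations)) {
    itSeed <- deriveSeed(seed, 1000L + it)
    permTrain <- train
    outcome(permTrain) <- withSeed(itSeed, sample(y))
    ids <- if (reuseSelection) {
      selectTop(records, k)
    } else {
      itRf <- rfCtrl
      itRf$seed <- deriveSeed(itSeed, 1L)
      rec <- chunkedImportanceScan(permTrain, itRf, screenCtrl)
      rec <- rerankTop(rec, permTrain, itRf, screenCtrl)
      selectTop(rec, k)
    }
    selections[[it]] <- ids
    model <- buildPredictionModel(permTrain, modelSpec(ids, includeClinical),
                                  rfCtrl, seed = deriveSeed(itSeed, 2L))
    aucs[it] <- aucScore(predictScores(model, test), outcome(test))@auc
  }
  structure(list(results = data.frame(iteration = seq_len(nIterations),
                                      auc = aucs),
                 mean_auc = mean(aucs), selections = selections,
                 control_type = "permutation"),
            class = "ControlResult")
}

#' Random-SNP control
#'
#' Per iteration, k SNP ids are sampled uniformly without replacement from
#' the full panel (regardless of association with the phenotype), a model
#' is built on them (plus clinical traits when requested) with the true
#' training labels, and scored on the replication set.
#'
#' @inheritParams permutationControl
#' @return A \code{"ControlResult"} list as for
#'   \code{\link{permutationControl}}.
#' @export
randomSnpControl <- function(train, test, k, nIterations = 10L,
                             rfCtrl = rfControl(), includeClinical = TRUE,
                             seed = rfCtrl$seed) {
  stopifnot(nIterations >= 1L)
  panel <- snpInfo(train)$snp_id
  if (k > length(panel))
    stop("k (", k, ") exceeds the panel size (", length(panel), ")")
  train <- imputeMissingFromControls(train, train, deriveSeed(seed, 31L))
  test <- imputeMissingFromControls(test, train, deriveSeed(seed, 32L))
  aucs <- numeric(nIterations)
  selections <- vector("list", nIterations)
  for (it in seq_len(nIterations)) {
    itSeed <- deriveSeed(seed, 2000L + it)
    ids <- withSeed(itSeed, sample(panel, k))
    selections[[it]] <- ids
    model <- buildPredictionModel(train, modelSpec(ids, includeClinical),
                                  rfCtrl, seed = deriveSeed(itSeed, 2L))
    aucs[it] <- aucScore(predictScores(model, test), outcome(test))@auc
  }
  structure(list(results = data.frame(iteration = seq_len(nIterations),
                                      auc = aucs),
                 mean_auc = mean(aucs), selections = selections,
                 control_type = "random_snp"),
            class = "ControlResult")
}

#' @export
print.ControlResult <- function(x, ...) {
  cat(sprintf("%s control: %d iterations, mean AUC = %.3f (range %.3f-%.3f)\n",
              x$control_type, nrow(x$results), x$mean_auc,
              min(x$results$auc), max(x$results$auc)))
  invisible(x)
}
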