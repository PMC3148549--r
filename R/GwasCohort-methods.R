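#' Accessors for GwasCohort and friends
#'
#' \code{genotypes} returns the SNPs x samples integer count matrix
#' (NA = missing); \code{snpInfo} the per-SNP metadata \code{DataFrame};
#' \code{outcome} the binary phenotype vector named by sample;
#' \code{covariates} the four-column clinical table (or NULL before
#' \code{\link{attachCovariates}}); \code{sampleIds}, \code{nSnps} and
#' \code{nSamples} the obvious dimensions.
#'
#' @param x A \linkS4class{GwasCohort}.
#' @param value Replacement outcome vector (0/1/NA, one per sample).
#' @return See individual descriptions above.
#' @name GwasCohort-accessors
#' @aliases genotypes snpInfo outcome outcome<- covariates sampleIds nSnps
#'   nSamples
NULL

#' @rdname GwasCohort-accessors
#' @export
setMethod("genotypes", "GwasCohort", function(x) assay(x, "genotype"))

#' @rdname GwasCohort-accessors
#' @export
setMethod("snpInfo", "GwasCohort", function(x) rowData(x))

#' @rdname GwasCohort-accessors
#' @export
setMethod("outcome", "GwasCohort", function(x) {
  cd <- colData(x)
  if (!"outcome" %in% colnames(cd)) return(NULL)
  stats::setNames(cd$outcome, rownames(cd))
})

#' @rdname GwasCohort-accessors
#' @export
setMethod("outcome<-", "GwasCohort", function(x, value) {
  if (length(value) != ncol(x))
    stop("replacement outcome has length ", length(value),
         ", expected ", ncol(x))
  colData(x)$outcome <- as.integer(value)
  validObject(x)
  x
})

#' @rdname GwasCohort-accessors
#' @export
setMethod("covariates", "GwasCohort", function(x) {
  cd <- colData(x)
  need <- c("age", "sex", "fev1_pct_pred", "treatment")
  if (!all(need %in% colnames(cd))) return(NULL)
  cd[, need]
})

#' @rdname GwasCohort-accessors
#' @export
setMethod("sampleIds", "GwasCohort", function(x) colnames(x))

#' @rdname GwasCohort-accessors
#' @export
setMethod("nSnps", "GwasCohort", function(x) nrow(x))

#' @rdname GwasCohort-accessors
#' @export
setMethod("nSamples", "GwasCohort", function(x) ncol(x))

setMethod("show", "GwasCohort", function(object) {
  y <- outcome(object)
  cat("GwasCohort:", nrow(object), "SNPs x", ncol(object), "samples\n")
  if (!is.null(y) && any(!is.na(y)))
    cat(sprintf("  outcome: %d cases / %d controls (%d NA)\n",
                sum(y == 1, na.rm = TRUE), sum(y == 0, na.rm = TRUE),
                sum(is.na(y))))
  cat("  covariates:",
      if (is.null(covariates(object))) "not attached" else "attached", "\n")
  miss <- mean(is.na(assay(object, "genotype")))
  cat(sprintf("  missing genotype calls: %.2f%%\n", 100 * miss))
  chroms <- unique(as.character(rowData(object)$chromosome))
  cat("  chromosomes:", paste(chroms, collapse = " "), "\n")
  invisible(object)
})

#' Accessors for CohortSplit
#'
#' @param x A \linkS4class{CohortSplit}.
#' @return \code{stage1}/\code{stage2} return the training and replication
#'   \linkS4class{GwasCohort}; \code{manifest} the configuration/seed list.
#' @name CohortSplit-accessors
#' @aliases stage1 stage2 manifest
NULL

#' @rdname CohortSplit-accessors
#' @export
setMethod("stage1", "CohortSplit", function(x) x@stage1)

#' @rdname CohortSplit-accessors
#' @export
setMethod("stage2", "CohortSplit", function(x) x@stage2)

#' @rdname CohortSplit-accessors
#' @export
setMethod("manifest", "CohortSplit", function(x) x@manifest)

setMethod("show", "CohortSplit", function(object) {
  cat("CohortSplit\n stage1 (training): ")
  show(object@stage1)
  cat(" stage2 (replication): ")
  show(object@stage2)
  invisible(object)
})

setMethod("show", "AUCResult", function(object) {
  cat(sprintf("AUC = %.4f (SE %.4f), p vs 0.5 = %.3g  [%d cases / %d controls]\n",
              object@auc, object@se, object@pValue,
              object@nCases, object@nControls))
  invisible(object)
})

#' Extract the fields of an AUCResult
#'
#' @param result An \linkS4class{AUCResult}.
#' @return A named list with elements \code{auc}, \code{se}, \code{pValue},
#'   \code{nCases}, \code{nControls}.
#' @export
aucFields <- function(result) {
  stopifnot(is(result, "AUCResult"))
  list(auc = result@auc, se = result@se, pValue = result@pValue,
       nCases = result@nCases, nControls = result@nControls)
}
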