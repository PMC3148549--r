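#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   assayNames rowData rowData<- colData colData<-
#' @importFrom randomForest randomForest importance
NULL

#' GwasCohort: genotypes, covariates and outcome for one cohort
#'
#' A \linkS4class{SummarizedExperiment} with one assay, \code{"genotype"}:
#' an integer SNPs x samples matrix of minor-allele counts in \{0, 1, 2\},
#' with \code{NA} marking missing calls. \code{rowData} carries the SNP
#' metadata (\code{snp_id}, \code{chromosome}, \code{position},
#' \code{allele_a}, \code{allele_b}, where \code{allele_b} is the counted
#' minor allele, or \code{"0"} when a SNP is monomorphic and the second
#' allele is unobservable). \code{colData} carries the binary outcome
#' (1 = severe exacerbation) and, when attached, the four clinical
#' covariates: \code{age} (years), \code{sex} (1 = male, 2 = female),
#' \code{fev1_pct_pred} (pre-bronchodilator FEV1 percent predicted) and
#' \code{treatment} (group code 1, 2 or 3).
#'
#' SNPs are stored in chromosomal order: chromosomes in blocks
#' (1..22 then X), positions non-decreasing within a block. The chunked
#' screening scan relies on this ordering.
#'
#' @aliases GwasCohort-class
#' @exportClass GwasCohort
setClass("GwasCohort", contains = "SummarizedExperiment")

.validGwasCohort <- function(object) {
  msg <- character(0)
  if (!"genotype" %in% assayNames(object))
    return("assay 'genotype' is required")
  g <- assay(object, "genotype")
  bad <- !is.na(g) & !(g %in% c(0L, 1L, 2L))
  if (any(bad))
    msg <- c(msg, "genotype values must be in {0, 1, 2} or NA")
  rd <- rowData(object)
  need <- c("snp_id", "chromosome", "position", "allele_a", "allele_b")
  missing_cols <- setdiff(need, colnames(rd))
  if (length(missing_cols))
    return(paste("rowData lacks column(s):",
                 paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(rd$snp_id))
    msg <- c(msg, "snp_id values must be unique")
  if (any(rd$position < 0))
    msg <- c(msg, "positions must be non-negative")
  co <- chromOrder(rd$chromosome)
  if (anyNA(co)) {
    msg <- c(msg, "chromosome labels must be 1-22 or X")
  } else if (nrow(rd) > 1L) {
    key <- co * 1e10 + rd$position
    if (is.unsorted(key))
      msg <- c(msg, "SNPs must be in chromosomal order (chromosome blocks, non-decreasing position)")
  }
  cd <- colData(object)
  if ("outcome" %in% colnames(cd)) {
    y <- cd$outcome
    if (any(!is.na(y) & !(y %in% c(0L, 1L))))
      msg <- c(msg, "outcome must be 0, 1 or NA")
  }
  if (all(c("age", "sex", "fev1_pct_pred", "treatment") %in% colnames(cd))) {
    if (any(!cd$sex %in% c(1L, 2L)))
      msg <- c(msg, "sex must be coded 1 (male) or 2 (female)")
    if (any(!cd$treatment %in% c(1L, 2L, 3L)))
      msg <- c(msg, "treatment must be coded 1, 2 or 3")
    if (any(cd$age <= 0) || any(cd$fev1_pct_pred <= 0))
      msg <- c(msg, "age and fev1_pct_pred must be positive")
  }
  if (length(msg)) msg else TRUE
}
setValidity("GwasCohort", .validGwasCohort)

#' Construct a GwasCohort
#'
#' @param genotypes Integer SNPs x samples matrix of minor-allele counts
#'   (0/1/2, NA = missing). Column names are the sample identifiers.
#' @param snpInfo \code{DataFrame} or \code{data.frame} with columns
#'   \code{snp_id}, \code{chromosome}, \code{position}, \code{allele_a},
#'   \code{allele_b}, one row per genotype row, in chromosomal order.
#' @param outcome Optional binary vector (1 = case) per sample; NA allowed.
#' @param covariates Optional data.frame/DataFrame with columns \code{age},
#'   \code{sex}, \code{fev1_pct_pred}, \code{treatment}, rownames = sample
#'   ids (or in sample order).
#' @return A \linkS4class{GwasCohort}.
#' @examples
#' g <- matrix(c(0L, 1L, 2L, 0L), nrow = 2,
#'             dimnames = list(NULL, c("s1", "s2")))
#' info <- data.frame(snp_id = c("rs1", "rs2"), chromosome = c("1", "1"),
#'                    position = c(100L, 200L), allele_a = c("A", "C"),
#'                    allele_b = c("G", "T"))
#' GwasCohort(g, info, outcome = c(1L, 0L))
#' @export
GwasCohort <- function(genotypes, snpInfo, outcome = NULL, covariates = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  snpInfo <- as(snpInfo, "DataFrame")
  rownames(genotypes) <- snpInfo$snp_id
  cd <- DataFrame(row.names = colnames(genotypes))
  if (!is.null(outcome)) {
    if (length(outcome) != ncol(genotypes))
      stop("outcome length (", length(outcome),
           ") does not match sample count (", ncol(genotypes), ")")
    cd$outcome <- as.integer(outcome)
  }
  obj <- new("GwasCohort",
             SummarizedExperiment(assays = list(genotype = genotypes),
                                  rowData = snpInfo, colData = cd))
  if (!is.null(covariates)) obj <- attachCovariates(obj, covariates)
  obj
}

#' CohortSplit: paired training and replication cohorts
#'
#' Bundles a Stage 1 (training) and Stage 2 (independent replication)
#' \linkS4class{GwasCohort} drawn from the same generative law over an
#' identical SNP panel, together with the manifest (simulation configuration
#' and master seed) that produced them.
#'
#' @slot stage1 Training \linkS4class{GwasCohort}.
#' @slot stage2 Replication \linkS4class{GwasCohort}.
#' @slot manifest Named list recording configuration and seed.
#' @aliases CohortSplit-class
#' @exportClass CohortSplit
setClass("CohortSplit",
         representation(stage1 = "GwasCohort", stage2 = "GwasCohort",
                        manifest = "list"))

setValidity("CohortSplit", function(object) {
  msg <- character(0)
  if (length(intersect(colnames(object@stage1), colnames(object@stage2))))
    msg <- c(msg, "stage1 and stage2 sample ids must be disjoint")
  if (!identical(rowData(object@stage1)$snp_id, rowData(object@stage2)$snp_id))
    msg <- c(msg, "stage1 and stage2 must share an identical SNP panel")
  if (length(msg)) msg else TRUE
})

#' AUCResult: area under the ROC curve with significance against chance
#'
#' @slot auc AUC point estimate in [0, 1] (rank-statistic definition,
#'   ties at half credit).
#' @slot se Hanley-McNeil standard error of the estimate.
#' @slot pValue Two-sided p-value for AUC different from 0.5 (normal
#'   approximation to the Mann-Whitney statistic under the null, with tie
#'   correction).
#' @slot nCases,nControls Class sizes the estimate is based on.
#' @aliases AUCResult-class
#' @exportClass AUCResult
setClass("AUCResult",
         representation(auc = "numeric", se = "numeric", pValue = "numeric",
                        nCases = "integer", nControls = "integer"))

setValidity("AUCResult", function(object) {
  if (object@auc < 0 || object@auc > 1) return("auc must be in [0, 1]")
  if (object@pValue <= 0 || object@pValue > 1) return("pValue must be in (0, 1]")
  TRUE
})
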