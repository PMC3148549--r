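#' Random-forest hyperparameters
#'
#' Defaults follow the study protocol: 1,500 trees ("a relatively large
#' number to ensure stable prediction results") and the randomForest default
#' mtry (floor(sqrt(p)) for classification). The importance measure is the
#' mean decrease in Gini impurity by default (what the toolchain reports
#' without extra flags); out-of-bag permutation importance is available as
#' an alternative.
#'
#' @param ntree Number of trees (default 1500).
#' @param mtry Candidate predictors per split; NULL = floor(sqrt(p)).
#' @param importanceMeasure "gini" (mean decrease in node impurity) or
#'   "permutation" (mean decrease in out-of-bag accuracy).
#' @param seed Integer seed; every forest fit derives a deterministic stream
#'   from it.
#' @return A validated list of class \code{"RFControl"}.
#' @export
rfControl <- function(ntree = 1500L, mtry = NULL,
                      importanceMeasure = c("gini", "permutation"),
                      seed = 1L) {
  importanceMeasure <- match.arg(importanceMeasure)
  stopifnot(ntree >= 1L, is.null(mtry) || mtry >= 1L)
  structure(list(ntree = as.integer(ntree),
                 mtry = if (is.null(mtry)) NULL else as.integer(mtry),
                 importanceMeasure = importanceMeasure,
                 seed = as.integer(seed)),
            class = "RFControl")
}

#' Two-stage screening parameters
#'
#' Stage 1 scans the genome in consecutive chunks of \code{chunkSize} SNPs
#' in chromosomal order; stage 2 refits one forest on the global
#' \code{stage2Pool} top-ranked SNPs to re-rank them. \code{selectionSizes}
#' is the ladder of model sizes evaluated downstream.
#'
#' @param chunkSize SNPs per stage-1 chunk (default 4000).
#' @param stage2Pool Size of the stage-2 re-ranking pool (default 4000;
#'   clipped to the panel with a warning when larger).
#' @param selectionSizes Top-k ladder (default c(10, 40, 160, 320)).
#' @return A validated list of class \code{"ScreenControl"}.
#' @export
screenControl <- function(chunkSize = 4000L, stage2Pool = 4000L,
                          selectionSizes = c(10L, 40L, 160L, 320L)) {
  stopifnot(chunkSize >= 1L, stage2Pool >= 1L, all(selectionSizes >= 1L),
            all(selectionSizes <= stage2Pool))
  structure(list(chunkSize = as.integer(chunkSize),
                 stage2Pool = as.integer(stage2Pool),
                 selectionSizes = as.integer(selectionSizes)),
            class = "ScreenControl")
}

#' Fit a bagged classification forest
#'
#' Thin deterministic wrapper around \code{randomForest}: Gini split
#' criterion, \code{mtry} random candidate features per split, per-sample
#' vote fractions and per-feature importance exposed by the usual
#' \code{predict}/\code{\link{computeImportance}} machinery. Missing feature
#' values are a hard error (trees here do not handle them): impute first
#' with \code{\link{imputeMissingFromControls}}.
#'
#' @param features Samples x features numeric matrix or data.frame.
#' @param labels Binary 0/1 vector (or 2-level factor), one per sample.
#' @param control An \code{\link{rfControl}}.
#' @param seed Seed for this fit (default \code{control$seed}).
#' @return A \code{randomForest} object.
#' @export
fitForest <- function(features, labels, control = rfControl(),
                      seed = control$seed) {
  if (anyNA(features))
    stop("features contain missing values; impute first (see imputeMissingFromControls)")
  y <- factor(as.integer(as.character(factor(labels))), levels = c(0L, 1L))
  if (anyNA(y)) stop("labels must be binary 0/1")
  if (length(unique(y)) < 2L)
    stop("degenerate labels: both classes must be present")
  p <- ncol(features)
  mtry <- control$mtry %||% max(1L, floor(sqrt(p)))
  withSeed(seed,
           randomForest(x = features, y = y, ntree = control$ntree,
                        mtry = min(mtry, p),
                        importance = control$importanceMeasure == "permutation"))
}

#' Per-feature importance scores of a fitted forest
#'
#' Gini importance is the total decrease in node impurity attributed to
#' splits on the feature, averaged over trees; permutation importance is the
#' mean decrease in out-of-bag accuracy when the feature is permuted
#' (requires the forest to have been fitted under
#' \code{importanceMeasure = "permutation"}).
#'
#' @param forest A forest from \code{\link{fitForest}}.
#' @param measure "gini" or "permutation".
#' @return Named numeric vector, one score per feature.
#' @export
computeImportance <- function(forest, measure = c("gini", "permutation")) {
  measure <- match.arg(measure)
  imp <- importance(forest,
                    type = if (measure == "gini") 2L else 1L,
                    scale = FALSE)
  stats::setNames(as.numeric(imp[, 1L]), rownames(imp))
}

#' Stage-1 chunked genome-wide importance scan
#'
#' Partitions the SNP panel (already in chromosomal order) into consecutive
#' chunks of \code{chunkSize} SNPs, fits one forest per chunk with the
#' SNPs of that chunk as the only predictors (clinical covariates do not
#' enter screening), and records every SNP's importance score. Global
#' stage-1 ranks compare raw scores across chunks. Chunk seeds are derived
#' from the master seed and the chunk index, so results do not depend on how
#' the scan is split across calls.
#'
#' @param cohort A \linkS4class{GwasCohort} with outcome and no missing
#'   genotypes (impute upstream).
#' @param rfCtrl An \code{\link{rfControl}}.
#' @param screenCtrl A \code{\link{screenControl}}.
#' @param verbose Log one line per chunk.
#' @return A data.frame of importance records: snp_id, chromosome,
#'   position, stage1_score, stage1_rank (ties broken in chromosomal
#'   order).
#' @export
chunkedImportanceScan <- function(cohort, rfCtrl = rfControl(),
                                  screenCtrl = screenControl(),
                                  verbose = FALSE) {
  X <- encodeAdditive(cohort)
  if (anyNA(X))
    stop("missing genotypes in screening data; impute first (see imputeMissingFromControls)")
  y <- outcome(cohort)
  if (is.null(y) || anyNA(y)) stop("cohort must carry a complete binary outcome")
  p <- ncol(X)
  chunkOf <- ceiling(seq_len(p) / screenCtrl$chunkSize)
  score <- numeric(p)
  for (ci in unique(chunkOf)) {
    idx <- which(chunkOf == ci)
    if (verbose)
      message("stage-1 chunk ", ci, "/", max(chunkOf), ": ", length(idx), " SNPs")
    forest <- fitForest(X[, idx, drop = FALSE], y, rfCtrl,
                        seed = deriveSeed(rfCtrl$seed, ci))
    score[idx] <- computeImportance(forest, rfCtrl$importanceMeasure)
  }
  info <- snpInfo(cohort)
  rec <- data.frame(snp_id = info$snp_id,
                    chromosome = as.character(info$chromosome),
                    position = info$position,
                    stage1_score = score,
                    stringsAsFactors = FALSE)
  ## stable order -> score ties resolve in chromosomal order
  rnk <- integer(p)
  rnk[order(-rec$stage1_score)] <- seq_len(p)
  rec$stage1_rank <- rnk
  rec
}

## seed-stream index reserved for the stage-2 refit
.STAGE2_STREAM <- 999983L

#' Stage-2 re-ranking of the top screening pool
#'
#' Takes the stage-1 top \code{stage2Pool} SNPs, fits one forest on them
#' jointly, and re-ranks exactly those SNPs by the joint-fit importance.
#' Ties break by higher stage-1 score, then chromosomal position.
#'
#' @param records Stage-1 records from \code{\link{chunkedImportanceScan}}.
#' @param cohort The same training cohort.
#' @inheritParams chunkedImportanceScan
#' @return The records with stage2_score / stage2_rank columns (NA outside
#'   the pool).
#' @export
rerankTop <- function(records, cohort, rfCtrl = rfControl(),
                      screenCtrl = screenControl()) {
  stopifnot(all(c("snp_id", "stage1_score", "stage1_rank") %in% colnames(records)))
  pool <- screenCtrl$stage2Pool
  if (pool > nrow(records)) {
    warning("stage2Pool (", pool, ") exceeds panel size (", nrow(records),
            "); clipping to the full panel")
    pool <- nrow(records)
  }
  inPool <- records$stage1_rank <= pool
  poolIds <- records$snp_id[inPool]
  X <- encodeAdditive(cohort)
  if (anyNA(X))
    stop("missing genotypes in screening data; impute first (see imputeMissingFromControls)")
  y <- outcome(cohort)
  forest <- fitForest(X[, poolIds, drop = FALSE], y, rfCtrl,
                      seed = deriveSeed(rfCtrl$seed, .STAGE2_STREAM))
  s2 <- computeImportance(forest, rfCtrl$importanceMeasure)
  records$stage2_score <- NA_real_
  records$stage2_score[inPool] <- as.numeric(s2[poolIds])
  records$stage2_rank <- NA_integer_
  sub <- records[inPool, ]
  ord <- order(-sub$stage2_score, -sub$stage1_score,
               chromOrder(sub$chromosome), sub$position)
  rnk <- integer(nrow(sub))
  rnk[ord] <- seq_len(nrow(sub))
  records$stage2_rank[inPool] <- rnk
  records
}

#' Select the top-k SNPs by stage-2 rank
#'
#' @param records Records from \code{\link{rerankTop}}.
#' @param k Number of SNPs (1 <= k <= stage-2 pool size).
#' @return Character vector of k SNP ids, best first.
#' @export
selectTop <- function(records, k) {
  if (k <= 0L) stop("k must be positive")
  inPool <- !is.na(records$stage2_rank)
  if (k > sum(inPool))
    stop("k (", k, ") exceeds the stage-2 pool size (", sum(inPool), ")")
  sub <- records[inPool, ]
  sub$snp_id[order(sub$stage2_rank)][seq_len(k)]
}

#' Export / read the importance table
#'
#' TSV sorted by (chromosome, position) with the columns needed to redraw
#' the importance-score Manhattan plot and to rebuild the ranking:
#' chromosome, position, snp_id, stage1_score, stage1_rank, stage2_score,
#' stage2_rank.
#'
#' @param records Importance records (stage 1, optionally stage 2).
#' @param path Output TSV path.
#' @return \code{exportImportanceTable}: invisibly, the path.
#' @export
exportImportanceTable <- function(records, path) {
  if (!nrow(records)) stop("no importance records to export")
  if (!"stage2_score" %in% colnames(records)) {
    records$stage2_score <- NA_real_
    records$stage2_rank <- NA_integer_
  }
  out <- records[order(chromOrder(records$chromosome), records$position),
                 c("chromosome", "position", "snp_id",
                   "stage1_score", "stage1_rank", "stage2_score", "stage2_rank")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname exportImportanceTable
#' @return \code{readImportanceTable}: the records data.frame.
#' @export
readImportanceTable <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c(chromosome = "character"),
                    stringsAsFactors = FALSE)
}
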