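## PLINK 1.x text dialect (.ped/.map), whitespace-separated.
## .map: chromosome, snp id, genetic distance (ignored, written as 0),
## base-pair position. .ped: FID IID PAT MAT SEX PHENO then two allele
## columns per SNP; "0" marks a missing allele; phenotype 1 = control,
## 2 = case, 0/-9 = missing.

.VALID_ALLELES <- c("A", "C", "G", "T", "0")

#' Read a PLINK text .ped/.map pair into a GwasCohort
#'
#' Genotypes are encoded additively as counts of the minor allele: for each
#' SNP the counted allele (\code{allele_b}) is the less frequent allele among
#' non-missing calls, ties broken lexicographically. Allele pairs containing
#' \code{"0"} become missing (\code{NA}). When only one allele is observed
#' at a SNP, the second allele is unknowable from the file and is recorded
#' as \code{"0"}, giving an all-zero column. The .ped phenotype column
#' (1 = control, 2 = case) becomes the 0/1 \code{outcome}.
#'
#' @param pedPath,mapPath Paths to the .ped and .map files.
#' @return A \linkS4class{GwasCohort} with outcome attached (NA where the
#'   phenotype column is 0 or -9) and no covariates.
#' @seealso \code{\link{writePedMap}}, \code{\link{readCovariateTable}}
#' @export
readPedMap <- function(pedPath, mapPath) {
  mapLines <- readLines(mapPath)
  mapLines <- mapLines[nzchar(trimws(mapLines))]
  mapFields <- lapply(mapLines, function(l) strsplit(trimws(l), "[ \t]+")[[1]])
  if (length(mapFields) && any(lengths(mapFields) < 4L))
    stop("map format error: line ",
         which(lengths(mapFields) < 4L)[1L], " has fewer than 4 columns")
  nSnp <- length(mapFields)
  chrom <- vapply(mapFields, `[`, "", 1L)
  snpId <- vapply(mapFields, `[`, "", 2L)
  pos <- as.integer(vapply(mapFields, `[`, "", 4L))
  if (anyDuplicated(snpId))
    stop("duplicate SNP id in map: ", snpId[duplicated(snpId)][1L])

  pedLines <- readLines(pedPath)
  pedLines <- pedLines[nzchar(trimws(pedLines))]
  n <- length(pedLines)
  expCols <- 6L + 2L * nSnp
  sampleId <- character(n)
  pheno <- integer(n)
  a1 <- matrix("0", nrow = nSnp, ncol = n)
  a2 <- matrix("0", nrow = nSnp, ncol = n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(pedLines[i]), "[ \t]+")[[1]]
    if (length(f) != expCols)
      stop("ped format error: line ", i, " has ", length(f),
           " columns, expected ", expCols)
    sampleId[i] <- f[2L]
    pheno[i] <- suppressWarnings(as.integer(f[6L]))
    if (nSnp) {
      al <- f[-(1:6)]
      bad <- !(al %in% .VALID_ALLELES)
      if (any(bad))
        stop("ped format error: line ", i, ": invalid allele character '",
             al[bad][1L], "'")
      a1[, i] <- al[seq(1L, 2L * nSnp, by = 2L)]
      a2[, i] <- al[seq(2L, 2L * nSnp, by = 2L)]
    }
  }
  if (anyDuplicated(sampleId))
    stop("duplicate sample id in ped: ", sampleId[duplicated(sampleId)][1L])
  y <- ifelse(pheno == 2L, 1L, ifelse(pheno == 1L, 0L, NA_integer_))

  counts <- matrix(NA_integer_, nrow = nSnp, ncol = n,
                   dimnames = list(snpId, sampleId))
  alleleA <- character(nSnp)
  alleleB <- character(nSnp)
  for (j in seq_len(nSnp)) {
    x1 <- a1[j, ]; x2 <- a2[j, ]
    obs <- x1 != "0" & x2 != "0"
    tab <- table(factor(c(x1[obs], x2[obs]), levels = setdiff(.VALID_ALLELES, "0")))
    present <- names(tab)[tab > 0L]
    if (length(present) > 2L)
      stop("SNP ", snpId[j], " has more than two alleles: ",
           paste(present, collapse = ", "))
    if (length(present) == 0L) {
      alleleA[j] <- "0"; alleleB[j] <- "0"
    } else if (length(present) == 1L) {
      alleleA[j] <- present; alleleB[j] <- "0"
      counts[j, obs] <- 0L
    } else {
      ## minor = less frequent; tie -> lexicographically smaller
      cnt <- tab[present]
      minor <- if (cnt[1L] == cnt[2L]) min(present) else present[which.min(cnt)]
      major <- setdiff(present, minor)
      alleleA[j] <- major; alleleB[j] <- minor
      counts[j, obs] <- (x1[obs] == minor) + (x2[obs] == minor)
    }
  }
  info <- DataFrame(snp_id = snpId, chromosome = chrom, position = pos,
                    allele_a = alleleA, allele_b = alleleB)
  GwasCohort(counts, info, outcome = y)
}

#' Write a GwasCohort to a PLINK text .ped/.map pair
#'
#' Byte-deterministic given the cohort: counts map back to allele pairs
#' (0 -> a/a, 1 -> a/b, 2 -> b/b), missing calls to \code{"0 0"}; the
#' outcome is written in phenotype column 6 as 1/2 (control/case), \code{-9}
#' when missing. Family/parent/sex columns are written as placeholders
#' (FID = IID, 0 elsewhere).
#'
#' @param cohort A \linkS4class{GwasCohort}.
#' @param pedPath,mapPath Output paths.
#' @return Invisibly, \code{c(pedPath, mapPath)}.
#' @export
writePedMap <- function(cohort, pedPath, mapPath) {
  info <- snpInfo(cohort)
  g <- genotypes(cohort)
  bad <- info$allele_b == "0" & apply(g, 1L, function(r) any(!is.na(r) & r > 0L))
  if (any(bad))
    stop("SNP ", info$snp_id[bad][1L],
         " has counted-allele '0' but non-zero counts; cannot be written")
  mapOut <- sprintf("%s\t%s\t0\t%d", info$chromosome, info$snp_id, info$position)
  writeLines(mapOut, mapPath)

  y <- outcome(cohort)
  ph <- if (is.null(y)) rep(-9L, ncol(g)) else ifelse(is.na(y), -9L, y + 1L)
  ids <- colnames(g)
  pedOut <- vapply(seq_len(ncol(g)), function(i) {
    gi <- g[, i]
    pair <- character(2L * length(gi))
    if (length(gi)) {
      aa <- info$allele_a; ab <- info$allele_b
      pair[c(TRUE, FALSE)] <- ifelse(is.na(gi), "0", ifelse(gi >= 1L, ab, aa))
      pair[c(FALSE, TRUE)] <- ifelse(is.na(gi), "0", ifelse(gi == 2L, ab, aa))
    }
    paste(c(ids[i], ids[i], "0", "0", "0", ph[i], pair), collapse = " ")
  }, "")
  writeLines(pedOut, pedPath)
  invisible(c(pedPath, mapPath))
}

#' Read a clinical covariate table
#'
#' Expects a header file (comma- or tab-separated, detected from the header
#' line) with a \code{sample_id} column and the four covariates:
#' \code{age} (years), \code{sex} (1 = male, 2 = female),
#' \code{fev1_pct_pred}, \code{treatment} (1/2/3). Missing cells and
#' out-of-range codes are validation errors naming the offending row;
#' covariates are never imputed.
#'
#' @param path Path to the covariate file.
#' @return A \code{DataFrame} with rownames = sample ids.
#' @export
readCovariateTable <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("sample_id", "age", "sex", "fev1_pct_pred", "treatment")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("covariate file lacks column(s): ", paste(miss, collapse = ", "))
  for (cc in need) {
    if (anyNA(tab[[cc]]))
      stop("missing covariate value in column '", cc, "', row ",
           which(is.na(tab[[cc]]))[1L])
  }
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample_id: ", tab$sample_id[duplicated(tab$sample_id)][1L])
  chk <- function(ok, what) {
    if (any(!ok)) stop("invalid ", what, " in row ", which(!ok)[1L])
  }
  chk(tab$sex %in% c(1L, 2L), "sex code (must be 1 or 2)")
  chk(tab$treatment %in% c(1L, 2L, 3L), "treatment code (must be 1, 2 or 3)")
  chk(tab$age > 0, "age (must be > 0)")
  chk(tab$fev1_pct_pred > 0, "fev1_pct_pred (must be > 0)")
  DataFrame(age = as.numeric(tab$age), sex = as.integer(tab$sex),
            fev1_pct_pred = as.numeric(tab$fev1_pct_pred),
            treatment = as.integer(tab$treatment),
            row.names = tab$sample_id)
}

#' Attach clinical covariates to a GwasCohort
#'
#' Joins by sample id; every cohort sample must be present in the covariate
#' table, and covariate rows with no matching genotype sample are an error
#' (orphans are listed).
#'
#' @param cohort A \linkS4class{GwasCohort}.
#' @param covariateTable As returned by \code{\link{readCovariateTable}}, or
#'   any data.frame/DataFrame with the four covariate columns and sample-id
#'   rownames.
#' @return The cohort with covariates in \code{colData}.
#' @export
attachCovariates <- function(cohort, covariateTable) {
  ct <- as(covariateTable, "DataFrame")
  need <- c("age", "sex", "fev1_pct_pred", "treatment")
  miss <- setdiff(need, colnames(ct))
  if (length(miss))
    stop("covariate table lacks column(s): ", paste(miss, collapse = ", "))
  ids <- colnames(cohort)
  if (is.null(rownames(ct))) {
    if (nrow(ct) != length(ids))
      stop("covariate table without sample ids must have one row per sample")
    rownames(ct) <- ids
  }
  absent <- setdiff(ids, rownames(ct))
  if (length(absent))
    stop("no covariates for sample(s): ", paste(absent, collapse = ", "))
  orphans <- setdiff(rownames(ct), ids)
  if (length(orphans))
    stop("covariate rows with no genotyped sample: ",
         paste(orphans, collapse = ", "))
  ct <- ct[ids, , drop = FALSE]
  for (cc in need) colData(cohort)[[cc]] <- ct[[cc]]
  validObject(cohort)
  cohort
}

#' Additive feature encoding of a genotype matrix
#'
#' Returns the samples x SNPs numeric matrix of minor-allele counts used as
#' random-forest features. Missing calls propagate as \code{NA}; downstream
#' model fitting requires them imputed first
#' (\code{\link{imputeMissingFromControls}}).
#'
#' @param x A \linkS4class{GwasCohort}.
#' @return Numeric samples x SNPs matrix, columns named by snp_id.
#' @rdname encodeAdditive
#' @export
setMethod("encodeAdditive", "GwasCohort", function(x) {
  m <- t(genotypes(x))
  storage.mode(m) <- "double"
  m
})
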