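#' Configuration for the synthetic two-stage GWAS cohort generator
#'
#' The generator emulates a two-stage case-control cohort of childhood
#' asthmatics: a training stage (default n = 417, ~30% cases) and an
#' independent replication stage (default n = 164) drawn from the same
#' generative law over a shared SNP panel. Genotypes are independent SNPs in
#' Hardy-Weinberg equilibrium at a MAF drawn uniformly per SNP; disease risk
#' follows a logistic model whose log-odds are additive in minor-allele
#' counts at the planted causal SNPs, plus optional pairwise epistatic
#' (product) terms and linear clinical-covariate terms; the intercept is
#' calibrated numerically so the expected case fraction matches
#' \code{targetPrevalence}.
#'
#' @param nSnps Number of SNPs on the panel.
#' @param nTrain,nTest Stage 1 / Stage 2 sample sizes (defaults 417 / 164).
#' @param mafRange Interval in (0, 0.5] the per-SNP MAF is drawn from.
#' @param nCausal Number of planted additive causal SNPs.
#' @param additiveLogOdds Per-minor-allele log-odds of the causal SNPs;
#'   recycled to length \code{nCausal}.
#' @param causalIndices Panel indices of the causal SNPs; default spreads
#'   them evenly across the panel.
#' @param epistaticPairs Optional 3-column matrix (i, j, log-odds) of
#'   pairwise interaction terms added as \code{logOdds * g_i * g_j}.
#' @param covariateEffects Named log-odds per unit of the raw coded
#'   covariates (age years, sex code 1/2, FEV1 percent, treatment code
#'   1/2/3). Defaults are small non-zero values matching the directions seen
#'   in the cohort table (cases younger, more often male, lower lung
#'   function, more often untreated), so clinical traits alone carry weak
#'   signal.
#' @param covariateMoments Named list of generator moments: \code{ageMean},
#'   \code{ageSd} (normal truncated above 5 years), \code{fev1Mean},
#'   \code{fev1Sd} (truncated above 40), \code{maleFraction}.
#' @param targetPrevalence Expected case fraction (default 0.30).
#' @param missingRate Per-cell probability a genotype call is missing.
#' @param seed Master seed; every stochastic step derives its own stream
#'   from it.
#' @return A validated list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(nSnps,
                             nTrain = 417L, nTest = 164L,
                             mafRange = c(0.05, 0.5),
                             nCausal = 0L,
                             additiveLogOdds = numeric(0),
                             causalIndices = NULL,
                             epistaticPairs = NULL,
                             covariateEffects = c(age = -0.04, sex = -0.25,
                                                  fev1_pct_pred = -0.012,
                                                  treatment = 0.25),
                             covariateMoments = list(ageMean = 8.7, ageSd = 2.1,
                                                     fev1Mean = 93.3,
                                                     fev1Sd = 14.0,
                                                     maleFraction = 0.63),
                             targetPrevalence = 0.30,
                             missingRate = 0,
                             seed = 1L) {
  if (nSnps < 1L) stop("empty SNP panel: nSnps must be >= 1")
  stopifnot(nTrain >= 1L, nTest >= 0L,
            length(mafRange) == 2L, mafRange[1L] > 0, mafRange[2L] <= 0.5,
            mafRange[1L] <= mafRange[2L],
            targetPrevalence > 0, targetPrevalence < 1,
            missingRate >= 0, missingRate < 1)
  nCausal <- as.integer(nCausal)
  if (nCausal > 0L) {
    if (is.null(causalIndices))
      causalIndices <- unique(round(seq(1L, nSnps, length.out = nCausal)))
    causalIndices <- as.integer(causalIndices)
    if (length(causalIndices) != nCausal)
      stop("causalIndices length must equal nCausal")
    if (any(causalIndices < 1L | causalIndices > nSnps))
      stop("causalIndices out of range [1, nSnps]")
    additiveLogOdds <- rep_len(additiveLogOdds, nCausal)
  } else {
    causalIndices <- integer(0)
    additiveLogOdds <- numeric(0)
  }
  if (!is.null(epistaticPairs)) {
    epistaticPairs <- matrix(as.numeric(epistaticPairs), ncol = 3L)
    if (any(epistaticPairs[, 1:2] < 1 | epistaticPairs[, 1:2] > nSnps))
      stop("epistaticPairs indices out of range")
  }
  structure(list(nSnps = as.integer(nSnps), nTrain = as.integer(nTrain),
                 nTest = as.integer(nTest), mafRange = mafRange,
                 nCausal = nCausal, additiveLogOdds = additiveLogOdds,
                 causalIndices = causalIndices,
                 epistaticPairs = epistaticPairs,
                 covariateEffects = covariateEffects,
                 covariateMoments = covariateMoments,
                 targetPrevalence = targetPrevalence,
                 missingRate = missingRate, seed = as.integer(seed)),
            class = "SimulationConfig")
}

## SNP panel shared between stages: ids, 22 chromosome blocks with
## increasing positions, alleles, and the per-SNP MAF.
makeSnpPanel <- function(config, seed) {
  withSeed(seed, {
    p <- config$nSnps
    maf <- stats::runif(p, config$mafRange[1L], config$mafRange[2L])
    chrom <- as.character(sort(rep_len(seq_len(22L), p)))
    pos <- integer(p)
    for (cc in unique(chrom)) {
      idx <- which(chrom == cc)
      pos[idx] <- cumsum(sample(1000:50000, length(idx), replace = TRUE))
    }
    bases <- c("A", "C", "G", "T")
    alleleA <- sample(bases, p, replace = TRUE)
    alleleB <- vapply(alleleA, function(a) sample(setdiff(bases, a), 1L), "")
    info <- DataFrame(snp_id = sprintf("snp%06d", seq_len(p)),
                      chromosome = chrom, position = pos,
                      allele_a = alleleA, allele_b = unname(alleleB))
    list(info = info, maf = maf)
  })
}

#' Simulate a Hardy-Weinberg genotype matrix
#'
#' Each SNP draws a MAF uniformly from \code{mafRange} (unless a shared
#' \code{panel} is supplied) and genotype counts as Binomial(2, MAF), i.e.
#' HWE frequencies ((1-q)^2, 2q(1-q), q^2). SNPs are laid out on 22
#' chromosomes in blocks with increasing positions.
#'
#' @param config A \code{\link{simulationConfig}}.
#' @param n Number of samples (default \code{config$nTrain}).
#' @param seed Seed (default derived from the config seed).
#' @param panel Optional panel from an earlier call (internal use: keeps the
#'   two stages on identical SNPs); when supplied its MAFs are reused.
#' @param idPrefix Sample-id prefix.
#' @return A \linkS4class{GwasCohort} (no outcome, no covariates). The
#'   per-SNP MAFs are attached as \code{metadata(x)$maf}.
#' @export
simulateGenotypes <- function(config, n = config$nTrain,
                              seed = deriveSeed(config$seed, 1L),
                              panel = NULL, idPrefix = "s") {
  if (is.null(panel)) panel <- makeSnpPanel(config, deriveSeed(config$seed, 0L))
  g <- withSeed(seed, {
    m <- matrix(NA_integer_, nrow = config$nSnps, ncol = n)
    for (j in seq_len(config$nSnps))
      m[j, ] <- stats::rbinom(n, 2L, panel$maf[j])
    m
  })
  colnames(g) <- sprintf("%s%05d", idPrefix, seq_len(n))
  canon <- .canonicalizeOrientation(g, panel$info)
  out <- GwasCohort(canon$g, canon$info)
  S4Vectors::metadata(out)$maf <- panel$maf
  out
}

#' Simulate clinical covariates
#'
#' Age ~ Normal(ageMean, ageSd) truncated above 5 years; FEV1 percent
#' predicted ~ Normal(fev1Mean, fev1Sd) truncated above 40; sex Bernoulli
#' (male fraction) coded 1/2; treatment uniform over \{1, 2, 3\}.
#'
#' @inheritParams simulateGenotypes
#' @param n Number of samples.
#' @param sampleIds Optional sample ids for the rownames.
#' @return A \code{DataFrame} with columns age, sex, fev1_pct_pred,
#'   treatment.
#' @export
simulateCovariates <- function(config, n,
                               seed = deriveSeed(config$seed, 2L),
                               sampleIds = NULL) {
  mom <- config$covariateMoments
  rtrunc <- function(n, mean, sd, lower) {
    x <- stats::rnorm(n, mean, sd)
    while (any(bad <- x <= lower))
      x[bad] <- stats::rnorm(sum(bad), mean, sd)
    x
  }
  withSeed(seed, {
    DataFrame(age = rtrunc(n, mom$ageMean, mom$ageSd, 5),
              sex = ifelse(stats::runif(n) < mom$maleFraction, 1L, 2L),
              fev1_pct_pred = rtrunc(n, mom$fev1Mean, mom$fev1Sd, 40),
              treatment = sample(1:3, n, replace = TRUE),
              row.names = sampleIds)
  })
}

## Canonical allele orientation: the counted allele (allele_b) is the
## empirically minor one (ties -> lexicographically smaller), matching the
## convention readPedMap derives from a .ped file, so write/read round-trips
## are exact. Monomorphic SNPs get allele_b = "0" (second allele
## unobservable in the text format).
.canonicalizeOrientation <- function(g, info) {
  nn <- rowSums(!is.na(g))
  freqB <- rowSums(g, na.rm = TRUE) / pmax(2 * nn, 1L)
  flip <- nn > 0 & (freqB > 0.5 |
                      (freqB == 0.5 & info$allele_b > info$allele_a))
  if (any(flip)) {
    g[flip, ] <- 2L - g[flip, , drop = FALSE]
    tmp <- info$allele_a[flip]
    info$allele_a[flip] <- info$allele_b[flip]
    info$allele_b[flip] <- tmp
    freqB[flip] <- 1 - freqB[flip]
  }
  mono <- nn > 0 & freqB == 0
  info$allele_b[mono] <- "0"
  list(g = g, info = info)
}

.recanonicalize <- function(cohort) {
  canon <- .canonicalizeOrientation(genotypes(cohort),
                                    as.data.frame(snpInfo(cohort)))
  assay(cohort, "genotype") <- canon$g
  rowData(cohort)$allele_a <- canon$info$allele_a
  rowData(cohort)$allele_b <- canon$info$allele_b
  cohort
}

## Linear predictor of the disease model, without intercept.
.linearPredictor <- function(features, covariates, config) {
  lp <- numeric(nrow(features))
  if (config$nCausal > 0L)
    lp <- lp + as.vector(features[, config$causalIndices, drop = FALSE] %*%
                           config$additiveLogOdds)
  if (!is.null(config$epistaticPairs)) {
    ep <- config$epistaticPairs
    for (r in seq_len(nrow(ep)))
      lp <- lp + ep[r, 3L] * features[, ep[r, 1L]] * features[, ep[r, 2L]]
  }
  eff <- config$covariateEffects
  if (!is.null(covariates) && length(eff)) {
    for (nm in names(eff))
      lp <- lp + eff[[nm]] * as.numeric(covariates[[nm]])
  }
  lp
}

## Bisection for the intercept b0 with mean(plogis(b0 + lp)) = target.
## The bracket is generous (+/- 750 log-odds) so any realistic effect
## configuration calibrates; linear predictors far beyond it (per-allele
## log-odds in the hundreds) are reported as unattainable.
.calibrateIntercept <- function(lp, target, tol = 0.005) {
  f <- function(b0) mean(stats::plogis(b0 + lp)) - target
  lo <- -750; hi <- 750
  if (f(lo) > 0 || f(hi) < 0)
    stop("prevalence calibration failure: target ", target,
         " unattainable for the given effects")
  mid <- (lo + hi) / 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < tol / 10) break
    if (fm > 0) hi <- mid else lo <- mid
  }
  if (abs(f(mid)) > tol)
    stop("prevalence calibration failure: residual ", abs(f(mid)))
  mid
}

#' Simulate the binary outcome under the logistic disease model
#'
#' P(case) = logistic(b0 + sum of additive SNP terms + interaction terms +
#' covariate terms); the intercept b0 is calibrated by bisection on the
#' supplied linear predictors so the expected case fraction equals
#' \code{config$targetPrevalence} (within 0.005), unless a pre-calibrated
#' \code{intercept} is given (used to keep both cohort stages on one model).
#'
#' @param genotypeFeatures Samples x SNPs additive feature matrix (from
#'   \code{\link{encodeAdditive}}); must contain no missing values.
#' @param covariateTable Covariates for the same samples, or NULL.
#' @param config A \code{\link{simulationConfig}}.
#' @param seed Seed for the Bernoulli draws.
#' @param intercept Optional fixed intercept (skips calibration).
#' @return Integer 0/1 vector with attribute \code{"intercept"}.
#' @export
simulatePhenotype <- function(genotypeFeatures, covariateTable, config,
                              seed = deriveSeed(config$seed, 3L),
                              intercept = NULL) {
  if (anyNA(genotypeFeatures))
    stop("genotypeFeatures must not contain missing values; simulate the phenotype before injecting missingness")
  lp <- .linearPredictor(genotypeFeatures, covariateTable, config)
  b0 <- intercept %||% .calibrateIntercept(lp, config$targetPrevalence)
  y <- withSeed(seed, stats::rbinom(length(lp), 1L, stats::plogis(b0 + lp)))
  names(y) <- rownames(genotypeFeatures)
  attr(y, "intercept") <- b0
  y
}

#' Set genotype calls missing completely at random
#'
#' Each cell is independently set to \code{NA} with probability \code{rate};
#' deterministic given the seed.
#'
#' @param cohort A \linkS4class{GwasCohort}.
#' @param rate Missingness probability in [0, 1).
#' @param seed Integer seed.
#' @return The cohort with missing calls injected.
#' @export
injectMissingness <- function(cohort, rate, seed) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(cohort)
  g <- genotypes(cohort)
  mask <- withSeed(seed, stats::runif(length(g)) < rate)
  g[mask] <- NA_integer_
  assay(cohort, "genotype") <- g
  cohort
}

#' Simulate a complete two-stage cohort
#'
#' Draws one shared SNP panel, then genotypes, covariates and outcomes for
#' the training (Stage 1) and replication (Stage 2) samples from the same
#' generative law; the disease-model intercept is calibrated once on the
#' pooled linear predictors. Missingness (if configured) is injected after
#' the phenotype draw. Fully deterministic given \code{config$seed}.
#'
#' @param config A \code{\link{simulationConfig}}.
#' @return A \linkS4class{CohortSplit}.
#' @export
simulateCohort <- function(config) {
  panel <- makeSnpPanel(config, deriveSeed(config$seed, 0L))
  g1 <- simulateGenotypes(config, config$nTrain, deriveSeed(config$seed, 1L),
                          panel = panel, idPrefix = "tr")
  g2 <- simulateGenotypes(config, config$nTest, deriveSeed(config$seed, 11L),
                          panel = panel, idPrefix = "te")
  c1 <- simulateCovariates(config, config$nTrain, deriveSeed(config$seed, 2L),
                           sampleIds = colnames(g1))
  c2 <- simulateCovariates(config, config$nTest, deriveSeed(config$seed, 12L),
                           sampleIds = colnames(g2))
  f1 <- encodeAdditive(g1)
  f2 <- encodeAdditive(g2)
  lp <- .linearPredictor(rbind(f1, f2), rbind(c1, c2), config)
  b0 <- .calibrateIntercept(lp, config$targetPrevalence)
  y1 <- simulatePhenotype(f1, c1, config, deriveSeed(config$seed, 3L), b0)
  y2 <- simulatePhenotype(f2, c2, config, deriveSeed(config$seed, 13L), b0)
  s1 <- attachCovariates(g1, c1)
  s2 <- attachCovariates(g2, c2)
  outcome(s1) <- y1
  outcome(s2) <- y2
  if (config$missingRate > 0) {
    s1 <- injectMissingness(s1, config$missingRate, deriveSeed(config$seed, 4L))
    s2 <- injectMissingness(s2, config$missingRate, deriveSeed(config$seed, 14L))
    ## dropped calls can move the empirical allele frequency onto/over the
    ## 0.5 boundary, so re-orient against the non-missing calls
    s1 <- .recanonicalize(s1)
    s2 <- .recanonicalize(s2)
  }
  mf <- unclass(config)
  mf$epistaticPairs <- if (is.null(mf$epistaticPairs)) NULL else
    as.data.frame(mf$epistaticPairs)
  mf$intercept <- b0
  new("CohortSplit", stage1 = s1, stage2 = s2, manifest = mf)
}

#' Write a two-stage cohort to disk
#'
#' Emits \code{stage1.ped/.map}, \code{stage2.ped/.map}, per-stage covariate
#' CSVs and a JSON manifest recording the simulation configuration and seed.
#' The two .map files are byte-identical by construction (shared panel).
#'
#' @param split A \linkS4class{CohortSplit}.
#' @param dir Output directory (created if absent).
#' @param overwrite Refuse to write into an existing non-empty directory
#'   unless TRUE.
#' @return Invisibly, the directory path.
#' @export
writeCohort <- function(split, dir, overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !overwrite)
    stop("directory ", dir, " is non-empty; use overwrite = TRUE")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeCov <- function(cohort, path) {
    cv <- as.data.frame(covariates(cohort))
    utils::write.csv(cbind(sample_id = sampleIds(cohort), cv), path,
                     row.names = FALSE, quote = FALSE)
  }
  for (st in c("stage1", "stage2")) {
    cohort <- if (st == "stage1") stage1(split) else stage2(split)
    writePedMap(cohort, file.path(dir, paste0(st, ".ped")),
                file.path(dir, paste0(st, ".map")))
    if (!is.null(covariates(cohort)))
      writeCov(cohort, file.path(dir, paste0(st, "_covariates.csv")))
  }
  jsonlite::write_json(manifest(split), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read back a cohort directory written by writeCohort
#'
#' @param dir Directory containing stage1/stage2 files.
#' @return A \linkS4class{CohortSplit} (manifest as stored in the JSON).
#' @export
readCohort <- function(dir) {
  rd <- function(st) {
    cohort <- readPedMap(file.path(dir, paste0(st, ".ped")),
                         file.path(dir, paste0(st, ".map")))
    covPath <- file.path(dir, paste0(st, "_covariates.csv"))
    if (file.exists(covPath))
      cohort <- attachCovariates(cohort, readCovariateTable(covPath))
    cohort
  }
  mfPath <- file.path(dir, "manifest.json")
  mf <- if (file.exists(mfPath)) jsonlite::read_json(mfPath, simplifyVector = TRUE) else list()
  new("CohortSplit", stage1 = rd("stage1"), stage2 = rd("stage2"),
      manifest = as.list(mf))
}
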