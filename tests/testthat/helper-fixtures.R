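## Shared fixture builders. Everything is generated in code at test time.

## Write a small hand-specified .ped/.map pair; `calls` is a list of
## character vectors (one per sample) of 2*nSnp allele fields.
writePedFixture <- function(calls, pheno, snpIds, chroms, positions,
                            dir = withr::local_tempdir(.local_envir = parent.frame())) {
  ped <- file.path(dir, "fix.ped")
  map <- file.path(dir, "fix.map")
  writeLines(sprintf("%s\t%s\t0\t%d", chroms, snpIds, positions), map)
  lines <- vapply(seq_along(calls), function(i) {
    paste(c(paste0("fam", i), paste0("s", i), 0, 0, 0, pheno[i], calls[[i]]),
          collapse = " ")
  }, "")
  writeLines(lines, ped)
  list(ped = ped, map = map)
}

## Small simulated two-stage cohort for pipeline tests.
smallSplit <- function(seed = 1, nSnps = 100, nTrain = 120, nTest = 60,
                       nCausal = 0, additiveLogOdds = numeric(0),
                       missingRate = 0, mafRange = c(0.1, 0.4), ...) {
  cfg <- simulationConfig(nSnps = nSnps, nTrain = nTrain, nTest = nTest,
                          nCausal = nCausal,
                          additiveLogOdds = additiveLogOdds,
                          mafRange = mafRange, missingRate = missingRate,
                          seed = seed, ...)
  simulateCohort(cfg)
}

## Random score/label fixture for ROC/AUC property tests.
randomScoreFixture <- function(n, tieProb = 0.3) {
  scores <- if (stats::runif(1) < tieProb)
    sample(seq(0, 1, by = 0.1), n, replace = TRUE)
  else stats::runif(n)
  labels <- integer(n)
  while (length(unique(labels)) < 2L)
    labels <- stats::rbinom(n, 1L, 0.4)
  list(scores = scores, labels = labels)
}

## Brute-force AUC: average over all case-control pairs with half credit
## for ties. Independent of the rank-statistic implementation.
bruteForceAuc <- function(scores, labels) {
  cs <- scores[labels == 1]
  ct <- scores[labels == 0]
  tot <- 0
  for (a in cs) for (b in ct)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}

## Brute-force ROC oracle: explicit confusion counts at every distinct
## threshold (call positive when score >= threshold).
bruteForceRoc <- function(scores, labels) {
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  data.frame(threshold = thr,
             fpr = vapply(thr, function(t) mean(scores[labels == 0] >= t), 0),
             tpr = vapply(thr, function(t) mean(scores[labels == 1] >= t), 0))
}
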