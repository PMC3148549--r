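rfcSmall <- rfControl(ntree = 200L, seed = 19L)

test_that("control-frequency imputation reproduces control genotype law", {
  ## degenerate controls: all homozygous reference -> every imputed cell 0
  info <- S4Vectors::DataFrame(snp_id = "rs1", chromosome = "1",
                               position = 10L, allele_a = "A", allele_b = "G")
  ctrlG <- matrix(0L, 1, 50, dimnames = list("rs1", paste0("c", 1:50)))
  controls <- GwasCohort(ctrlG, info, outcome = rep(0L, 50))
  tgtG <- matrix(NA_integer_, 1, 20, dimnames = list("rs1", paste0("t", 1:20)))
  target <- GwasCohort(tgtG, info)
  imp <- imputeMissingFromControls(target, controls, seed = 1)
  expect_true(all(genotypes(imp) == 0L))

  ## multinomial law: control frequencies (0.25, 0.5, 0.25), 1e4 draws
  ctrlG2 <- matrix(rep(c(0L, 1L, 1L, 2L), 25), 1, 100,
                   dimnames = list("rs1", paste0("c", 1:100)))
  controls2 <- GwasCohort(ctrlG2, info, outcome = rep(0L, 100))
  tgtBig <- GwasCohort(matrix(NA_integer_, 1, 10000,
                              dimnames = list("rs1", paste0("t", 1:10000))),
                       info)
  drawn <- genotypes(imputeMissingFromControls(tgtBig, controls2, seed = 2))
  freq <- tabulate(drawn + 1L, 3L) / 10000
  se <- sqrt(c(0.25, 0.5, 0.25) * c(0.75, 0.5, 0.75) / 10000)
  expect_true(all(abs(freq - c(0.25, 0.5, 0.25)) < 3 * se))

  ## determinism and the identity on complete data
  drawn2 <- genotypes(imputeMissingFromControls(tgtBig, controls2, seed = 2))
  expect_identical(drawn, drawn2)
  expect_identical(genotypes(imputeMissingFromControls(controls2, controls2, 9)),
                   ctrlG2)
})

test_that("imputation never alters observed calls and falls back when controls are empty", {
  split <- smallSplit(seed = 61, nSnps = 80, nTrain = 150, nTest = 40,
                      missingRate = 0.1)
  tr <- stage1(split)
  imp <- imputeMissingFromControls(tr, tr, seed = 5)
  obs <- !is.na(genotypes(tr))
  expect_identical(genotypes(imp)[obs], genotypes(tr)[obs])
  expect_false(anyNA(genotypes(imp)))

  ## a SNP missing in every control falls back to pooled frequencies
  info <- S4Vectors::DataFrame(snp_id = "rs1", chromosome = "1",
                               position = 10L, allele_a = "A", allele_b = "G")
  g <- matrix(c(NA, NA, 1L, 1L), 1, 4,
              dimnames = list("rs1", paste0("s", 1:4)))
  train <- GwasCohort(g, info, outcome = c(0L, 0L, 1L, 1L))
  expect_warning(out <- imputeMissingFromControls(train, train, seed = 3),
                 "pooled")
  expect_true(all(genotypes(out) == 1L))  # pooled calls are all heterozygous
})

test_that("model specs control the feature space exactly", {
  split <- smallSplit(seed = 62, nSnps = 50, nTrain = 100, nTest = 30,
                      nCausal = 3, additiveLogOdds = 1.5)
  tr <- stage1(split)
  ## clinical-only model: exactly the 4 clinical attributes
  mClin <- buildPredictionModel(tr, modelSpec(character(0), TRUE), rfcSmall)
  expect_length(mClin$featureNames, 4L)
  ## k SNPs + clinical -> k + 4 features
  ids <- as.character(snpInfo(tr)$snp_id[1:7])
  mBoth <- buildPredictionModel(tr, modelSpec(ids, TRUE), rfcSmall)
  expect_length(mBoth$featureNames, 11L)
  ## SNPs-only variant
  mSnp <- buildPredictionModel(tr, modelSpec(ids, FALSE), rfcSmall)
  expect_length(mSnp$featureNames, 7L)

  expect_error(buildPredictionModel(tr, modelSpec("nope", TRUE), rfcSmall),
               "not on the genotype panel")
  expect_error(modelSpec(character(0), FALSE), "at least one predictor")

  ## determinism: same seed -> identical predictions
  m2 <- buildPredictionModel(tr, modelSpec(ids, TRUE), rfcSmall)
  expect_identical(predictScores(mBoth, tr), predictScores(m2, tr))
})

test_that("vote fractions are tree-vote multiples and track class separation", {
  split <- smallSplit(seed = 63, nSnps = 40, nTrain = 150, nTest = 60,
                      nCausal = 4, additiveLogOdds = 2.0,
                      mafRange = c(0.2, 0.4))
  tr <- stage1(split); te <- stage2(split)
  ids <- as.character(snpInfo(tr)$snp_id[simulationConfig(
    nSnps = 40, nCausal = 4, additiveLogOdds = 2, seed = 63)$causalIndices])
  model <- buildPredictionModel(tr, modelSpec(ids, TRUE), rfcSmall)
  sc <- predictScores(model, te)
  expect_true(all(sc >= 0 & sc <= 1))
  ## score granularity is 1/ntree
  expect_true(all(abs(sc * rfcSmall$ntree - round(sc * rfcSmall$ntree)) < 1e-8))
  ## separable synthetic data: cases score higher on average
  yTe <- outcome(te)
  expect_gt(mean(sc[yTe == 1]), mean(sc[yTe == 0]))
})

test_that("internal cross-validation holds out a stratified tenth", {
  split <- smallSplit(seed = 64, nSnps = 30, nTrain = 200, nTest = 30,
                      nCausal = 3, additiveLogOdds = 1.8,
                      mafRange = c(0.2, 0.4))
  tr <- stage1(split)
  ids <- as.character(snpInfo(tr)$snp_id[c(1, 15, 29)])
  cv1 <- internalCrossValidation(tr, modelSpec(ids, TRUE), rfcSmall, seed = 1)
  cv2 <- internalCrossValidation(tr, modelSpec(ids, TRUE), rfcSmall, seed = 1)
  expect_equal(cv1@auc, cv2@auc)
  ## the 10% fold of a 200-sample cohort holds 20 samples, both classes
  expect_equal(cv1@nCases + cv1@nControls, 20L)
  expect_gt(cv1@nCases, 0L)
  ## repeated splits average
  cvR <- internalCrossValidation(tr, modelSpec(ids, TRUE), rfcSmall,
                                 seed = 1, repeats = 3L)
  expect_length(cvR$results, 3L)
  expect_equal(cvR$mean_auc, mean(vapply(cvR$results, function(a) a@auc, 0)))
})

test_that("independent replication scores the held-out stage correctly", {
  split <- smallSplit(seed = 65, nSnps = 60, nTrain = 200, nTest = 80,
                      nCausal = 5, additiveLogOdds = 1.8,
                      mafRange = c(0.2, 0.4), missingRate = 0.02)
  tr <- stage1(split); te <- stage2(split)
  cfg <- simulationConfig(nSnps = 60, nCausal = 5, additiveLogOdds = 1.8,
                          seed = 65)
  ids <- as.character(snpInfo(tr)$snp_id[cfg$causalIndices])
  res <- independentReplication(tr, te, modelSpec(ids, TRUE), rfcSmall,
                                seed = 7)
  expect_s4_class(res, "AUCResult")
  expect_gt(res@auc, 0.5)
  expect_identical(res@nCases + res@nControls, 80L)
  expect_length(attr(res, "scores"), 80L)

  ## self-replication equals training resubstitution with the same fit seed
  trImp <- imputeMissingFromControls(tr, tr, snpforest:::deriveSeed(7, 31L))
  selfRes <- independentReplication(trImp, trImp, modelSpec(ids, TRUE),
                                    rfcSmall, seed = 7)
  model <- buildPredictionModel(trImp, modelSpec(ids, TRUE), rfcSmall,
                                seed = snpforest:::deriveSeed(7, 33L))
  direct <- aucScore(predictScores(model, trImp), outcome(trImp))
  expect_equal(selfRes@auc, direct@auc)

  ## single-class replication outcome is rejected
  teBad <- te
  outcome(teBad) <- rep(1L, nSamples(te))
  expect_error(independentReplication(tr, teBad, modelSpec(ids, TRUE), rfcSmall),
               "both classes")
})

test_that("the SNP ladder emits one row per size plus the clinical-only row", {
  split <- smallSplit(seed = 66, nSnps = 60, nTrain = 150, nTest = 60,
                      nCausal = 5, additiveLogOdds = 1.5,
                      mafRange = c(0.2, 0.4))
  tr <- stage1(split); te <- stage2(split)
  scc <- screenControl(chunkSize = 60L, stage2Pool = 40L,
                       selectionSizes = c(5L, 15L))
  rfc <- rfControl(ntree = 150L, seed = 9L)
  rec <- rerankTop(chunkedImportanceScan(tr, rfc, scc), tr, rfc, scc)
  lad <- runSnpLadder(tr, te, rec, scc, rfc)
  expect_identical(lad$n_snps, c(0L, 5L, 15L))
  expect_identical(lad$n_features, c(4L, 9L, 19L))
  expect_true(all(lad$train_auc >= 0 & lad$train_auc <= 1))
  expect_true(all(lad$replication_auc >= 0 & lad$replication_auc <= 1))

  ## SNPs-only ladder drops the k = 0 row and the clinical block
  ladSnp <- runSnpLadder(tr, te, rec, scc, rfc, includeClinical = FALSE)
  expect_identical(ladSnp$n_snps, c(5L, 15L))
  expect_identical(ladSnp$n_features, c(5L, 15L))

  ## sizes beyond the pool clip with a warning
  sccBig <- screenControl(chunkSize = 60L, stage2Pool = 40L,
                          selectionSizes = c(5L, 40L))
  expect_warning(runSnpLadder(tr, te, rec,
                              screenControl(chunkSize = 60L, stage2Pool = 40L,
                                            selectionSizes = c(5L, 39L, 40L)),
                              rfc), NA)
  sccOver <- scc; sccOver$selectionSizes <- c(5L, 41L)
  expect_warning(runSnpLadder(tr, te, rec, sccOver, rfc), "clipping")
})
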