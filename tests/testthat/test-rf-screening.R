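rfcFast <- rfControl(ntree = 100L, seed = 11L)

test_that("forest fits are deterministic and vote fractions behave", {
  set.seed(501)
  n <- 80
  x <- data.frame(f1 = c(rnorm(n / 2, 2), rnorm(n / 2, -2)))
  y <- rep(c(1L, 0L), each = n / 2)
  f1 <- fitForest(x, y, rfcFast)
  f2 <- fitForest(x, y, rfcFast)
  v1 <- predict(f1, x, type = "prob")[, "1"]
  expect_identical(v1, predict(f2, x, type = "prob")[, "1"])
  ## perfectly separable single feature: every case scores >= 0.5
  expect_true(all(v1[y == 1L] >= 0.5))

  ## permuted labels: out-of-bag accuracy near the majority-class rate
  yScr <- withr::with_seed(77, sample(rep(c(1L, 0L), c(24, 56))))
  fNull <- fitForest(data.frame(f1 = rnorm(n), f2 = rnorm(n)), yScr, rfcFast)
  oobAcc <- mean(predict(fNull) == yScr)
  expect_lt(abs(oobAcc - 0.7), 0.15)

  expect_error(fitForest(x, rep(1L, n), rfcFast), "degenerate")
  xNA <- x; xNA$f1[3] <- NA
  expect_error(fitForest(xNA, y, rfcFast), "impute")
})

test_that("importance scores have the right shape and find a strong SNP", {
  split <- smallSplit(seed = 52, nSnps = 200, nTrain = 500, nTest = 10,
                      nCausal = 1, additiveLogOdds = 2.0,
                      causalIndices = 100L, mafRange = c(0.25, 0.35),
                      covariateEffects = numeric(0))
  X <- encodeAdditive(stage1(split))
  y <- outcome(stage1(split))
  for (seed in c(1, 2, 3)) {
    forest <- fitForest(X, y, rfControl(ntree = 300L, seed = seed))
    imp <- computeImportance(forest)
    expect_length(imp, 200L)
    expect_identical(names(imp), colnames(X))
    ## the planted log-odds-2 SNP dominates 199 noise SNPs
    expect_identical(which.max(imp), c(snp000100 = 100L))
  }
  ## permutation importance is exposed as the alternative measure
  fp <- fitForest(X[, 90:110], y,
                  rfControl(ntree = 200L, importanceMeasure = "permutation",
                            seed = 4))
  impP <- computeImportance(fp, "permutation")
  expect_identical(which.max(impP), c(snp000100 = 11L))
})

test_that("chunked scan partitions exactly and matches single fits", {
  split <- smallSplit(seed = 53, nSnps = 81, nTrain = 100, nTest = 10)
  tr <- stage1(split)
  scc <- screenControl(chunkSize = 40L, stage2Pool = 60L,
                       selectionSizes = c(5L, 10L))
  rec <- chunkedImportanceScan(tr, rfcFast, scc)
  expect_identical(nrow(rec), 81L)
  expect_identical(sort(rec$stage1_rank), 1:81)
  expect_identical(rec$snp_id, as.character(snpInfo(tr)$snp_id))

  ## chunk boundaries: 40 + 40 + 1, each chunk equal to a direct fit with
  ## the chunk-derived seed
  X <- encodeAdditive(tr); y <- outcome(tr)
  for (ci in 1:3) {
    idx <- seq((ci - 1) * 40 + 1, min(ci * 40, 81))
    direct <- computeImportance(
      fitForest(X[, idx, drop = FALSE], y, rfcFast,
                seed = snpforest:::deriveSeed(rfcFast$seed, ci)))
    expect_equal(unname(rec$stage1_score[idx]), unname(direct))
  }

  ## single-chunk scan equals one direct fit
  scc1 <- screenControl(chunkSize = 100L, stage2Pool = 50L,
                        selectionSizes = 5L)
  rec1 <- chunkedImportanceScan(tr, rfcFast, scc1)
  direct1 <- computeImportance(fitForest(X, y, rfcFast,
                                         seed = snpforest:::deriveSeed(rfcFast$seed, 1L)))
  expect_equal(rec1$stage1_score, unname(direct1))

  ## missing genotypes are rejected with a pointer to imputation
  trNA <- injectMissingness(tr, 0.05, 1)
  expect_error(chunkedImportanceScan(trNA, rfcFast, scc), "impute")
})

test_that("stage-2 re-ranking permutes the stage-1 pool and orders effects", {
  split <- smallSplit(seed = 54, nSnps = 120, nTrain = 400, nTest = 10,
                      nCausal = 2, additiveLogOdds = c(2.0, 0.5),
                      causalIndices = c(30L, 90L), mafRange = c(0.25, 0.35),
                      covariateEffects = numeric(0))
  tr <- stage1(split)
  scc <- screenControl(chunkSize = 60L, stage2Pool = 50L,
                       selectionSizes = c(5L, 20L))
  rec <- chunkedImportanceScan(tr, rfControl(ntree = 300L, seed = 3L), scc)
  rec2 <- rerankTop(rec, tr, rfControl(ntree = 300L, seed = 3L), scc)

  inPool <- !is.na(rec2$stage2_rank)
  expect_identical(sum(inPool), 50L)
  ## stage-2 scores exist exactly for the stage-1 top pool
  expect_setequal(rec2$snp_id[inPool], rec$snp_id[rec$stage1_rank <= 50])
  expect_identical(sort(rec2$stage2_rank[inPool]), 1:50)
  ## the stronger planted SNP outranks the weaker one
  r30 <- rec2$stage2_rank[rec2$snp_id == "snp000030"]
  r90 <- rec2$stage2_rank[rec2$snp_id == "snp000090"]
  expect_lt(r30, r90)

  ## clipping: pool larger than panel covers the whole panel with a warning
  sccBig <- screenControl(chunkSize = 60L, stage2Pool = 4000L,
                          selectionSizes = 5L)
  expect_warning(recAll <- rerankTop(rec, tr, rfcFast, sccBig), "clipping")
  expect_false(anyNA(recAll$stage2_rank))

  ## selectTop: k = 1 is the rank-1 SNP; k = pool returns the whole pool;
  ## the k list is a prefix of the k+1 list
  expect_identical(selectTop(rec2, 1),
                   rec2$snp_id[which(rec2$stage2_rank == 1L)])
  expect_setequal(selectTop(rec2, 50), rec2$snp_id[inPool])
  for (k in c(1, 7, 20)) {
    expect_identical(selectTop(rec2, k), selectTop(rec2, k + 1)[seq_len(k)])
  }
  expect_error(selectTop(rec2, 0), "positive")
  expect_error(selectTop(rec2, 51), "exceeds")
})

test_that("importance tables export sorted and round-trip", {
  split <- smallSplit(seed = 55, nSnps = 60, nTrain = 80, nTest = 10)
  tr <- stage1(split)
  scc <- screenControl(chunkSize = 30L, stage2Pool = 40L, selectionSizes = 5L)
  rec <- rerankTop(chunkedImportanceScan(tr, rfcFast, scc), tr, rfcFast, scc)
  path <- file.path(withr::local_tempdir(), "imp.tsv")
  exportImportanceTable(rec, path)
  tab <- readImportanceTable(path)
  expect_identical(nrow(tab), 60L)
  key <- snpforest:::chromOrder(tab$chromosome) * 1e9 + tab$position
  expect_false(is.unsorted(key))
  ## re-parse reproduces the records (export is already chrom-sorted here)
  expect_equal(tab$stage1_score, rec$stage1_score)
  expect_identical(tab$stage1_rank, rec$stage1_rank)
  expect_equal(tab$stage2_score, rec$stage2_score)
  expect_error(exportImportanceTable(rec[0, ], path), "no importance")
})

test_that("under a null phenotype, top-k membership is close to uniform", {
  ## zero planted effects: each SNP should enter the stage-2 top k with
  ## probability ~ k/p across seeds
  p <- 40L; k <- 8L; nSeeds <- 12L
  hits <- integer(p)
  for (s in seq_len(nSeeds)) {
    split <- smallSplit(seed = 600 + s, nSnps = p, nTrain = 120, nTest = 10,
                        covariateEffects = numeric(0))
    tr <- stage1(split)
    scc <- screenControl(chunkSize = p, stage2Pool = p, selectionSizes = k)
    rec <- rerankTop(chunkedImportanceScan(tr, rfControl(ntree = 100L, seed = s), scc),
                     tr, rfControl(ntree = 100L, seed = s), scc)
    hits[match(selectTop(rec, k), rec$snp_id)] <-
      hits[match(selectTop(rec, k), rec$snp_id)] + 1L
  }
  ## coarse-binned chi-square against uniform expectation k*nSeeds/p
  bins <- split(hits, rep(1:8, each = p / 8))
  obs <- vapply(bins, sum, 0)
  expd <- rep(k * nSeeds / 8, 8)
  stat <- sum((obs - expd)^2 / expd)
  expect_gt(stats::pchisq(stat, df = 7, lower.tail = FALSE), 0.001)
})
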