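# Fold construction, sampling strategies, per-fold training.

test_that("21 cases split into seven folds of exactly three", {
  ids <- sprintf("pt_%02d", 1:21)
  folds <- makeFolds(ids, K = 7, seed = 3)
  sizes <- table(foldOf(folds))
  expect_identical(as.integer(sizes), rep(3L, 7))
  # partition: union of folds is the id set, pairwise disjoint by naming
  expect_setequal(names(foldOf(folds)), ids)
  # deterministic under the seed
  expect_identical(foldOf(makeFolds(ids, K = 7, seed = 3)), foldOf(folds))
  expect_false(identical(foldOf(makeFolds(ids, K = 7, seed = 4)),
                         foldOf(folds)))
  expect_error(makeFolds(ids[1:5], K = 7), "at least")
  # uneven division keeps sizes within one of each other
  sizes10 <- table(foldOf(makeFolds(ids[1:10], K = 3, seed = 1)))
  expect_lte(max(sizes10) - min(sizes10), 1)
})

test_that("epoch sample plans match the variant strategies", {
  plan <- epochSamplePlan("aug", c("a", "b"), nSlices = 10)
  expect_identical(nrow(plan), 60L)                # 3 levels x 2 x 10
  expect_setequal(unique(plan$level), c(50, 70, 120))
  base <- epochSamplePlan("baseline", c("a", "b"), nSlices = 10)
  expect_identical(nrow(base), 20L)
  expect_true(all(base$level == 70))
  fuse <- epochSamplePlan("fuse", c("a", "b"), nSlices = 10)
  expect_identical(nrow(fuse), 20L)
  expect_true(all(is.na(fuse$level)))              # all levels in one sample
  expect_error(epochSamplePlan("other", "a", 4), "unknown variant")
})

test_that("a short training run logs finite per-epoch losses", {
  manifest <- tinyCohort(4)
  folds <- makeFolds(manifestCaseIds(manifest), K = 2, seed = 5)
  spec <- modelSpec("unetpp", "aug", widths = c(3, 4, 6))
  ck <- trainFold(manifest, folds, heldOutFold = 2, spec,
                  trainConfig(epochs = 2, batchSize = 8, seed = 9))
  expect_identical(nrow(ck$log), 2L)
  expect_true(all(is.finite(ck$log$meanLoss)))
  expect_true(all(ck$log$meanLoss >= 0 & ck$log$meanLoss <= 1))
  expect_error(trainFold(manifest, folds, heldOutFold = 9, spec),
               "invalid held-out fold")

  # checkpoint round trip reproduces the validation loss exactly
  path <- tempfile(fileext = ".rds")
  saveCheckpoint(ck, path)
  heldOut <- names(foldOf(folds))[foldOf(folds) == 2]
  v1 <- validationLoss(ck, manifest, heldOut)
  v2 <- validationLoss(loadCheckpoint(path), manifest, heldOut)
  expect_identical(v1, v2)
})

test_that("repeated optimizer steps overfit a single batch", {
  set.seed(31)
  spec <- modelSpec("unetpp", "baseline", widths = c(3, 4, 6))
  m <- buildModel(spec, seed = 8)
  lab <- matrix(0L, 16, 16)
  lab[5:12, 5:12] <- 1L; lab[7:10, 7:10] <- 2L; lab[1:3, 1:3] <- 3L
  # intensities carry the class signal with mild noise
  x <- array(rep(lab / 3, 3), c(16, 16, 3, 1)) +
    array(rnorm(16 * 16 * 3, sd = 0.05), c(16, 16, 3, 1))
  tgt <- array(oneHot(lab), c(16, 16, 4, 1))
  params <- m$params
  state <- spectralseg:::.adamInit(params)
  losses <- numeric(50)
  for (it in 1:50) {
    s <- spectralseg:::.trainStep(spec, params, state, x, tgt, 1e-2, 1e-5)
    params <- s$params; state <- s$state; losses[it] <- s$loss
  }
  expect_lt(losses[50], losses[1])
  expect_lt(losses[50], 0.8 * losses[1])  # real progress, not noise
})
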