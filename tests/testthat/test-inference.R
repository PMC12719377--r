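# Whole-volume prediction and ensemble averaging.

test_that("predicted volumes share the stack grid and are normalized", {
  cs <- loadCase(tinyCohort(4), "case_002")
  m <- buildModel(modelSpec("unetpp", "aug", widths = c(3, 4, 6)), seed = 2)
  prob <- predictVolume(m, cs$stack)
  expect_identical(dim(prob)[1:3], dim(labelArray(cs$labels)))
  expect_identical(dim(prob)[4], 4L)
  sums <- apply(prob, c(1, 2, 3), sum)
  expect_lt(max(abs(sums - 1)), 1e-9)
})

test_that("aug-variant inference consumes only the 70 keV level", {
  cs <- loadCase(tinyCohort(4), "case_003")
  m <- buildModel(modelSpec("unetpp", "aug", widths = c(3, 4, 6)), seed = 2)
  p1 <- predictVolume(m, cs$stack)
  # perturbing the 50 and 120 keV volumes changes nothing
  vols <- cs$stack@volumes
  vols[["50"]] <- vols[["50"]] + 40
  vols[["120"]] <- vols[["120"]] - 25
  p2 <- predictVolume(m, SpectralStack(vols, voxelSpacing(cs$stack)))
  expect_identical(p1, p2)
  # perturbing 70 keV does
  vols[["70"]] <- vols[["70"]] + 15
  p3 <- predictVolume(m, SpectralStack(vols, voxelSpacing(cs$stack)))
  expect_false(identical(p1, p3))
})

test_that("ensemble averaging is exact, idempotent and order-invariant", {
  set.seed(41)
  mk <- function() {
    p <- array(runif(4 * 4 * 2 * 4), c(4, 4, 2, 4))
    s <- apply(p, c(1, 2, 3), sum)
    for (cls in 1:4) p[, , , cls] <- p[, , , cls] / s
    p
  }
  p <- mk(); q <- mk(); r <- mk()
  expect_equal(ensembleAverage(list(p, p, p, p, p, p, p)), p)
  expect_equal(ensembleAverage(list(p, q)), (p + q) / 2)
  expect_equal(ensembleAverage(list(p, q, r)), ensembleAverage(list(r, p, q)))
  sums <- apply(ensembleAverage(list(p, q, r)), c(1, 2, 3), sum)
  expect_lt(max(abs(sums - 1)), 1e-12)
  expect_error(ensembleAverage(list(p, array(0, c(2, 2, 2, 4)))), "shape")
  expect_error(ensembleAverage(list()), "at least one")
})

test_that("argmax segmentation recovers one-hot classes and breaks ties low", {
  lab <- array(sample(0:3, 4 * 4 * 3, TRUE), c(4, 4, 3))
  oh <- array(0, c(4, 4, 3, 4))
  for (cls in 0:3) oh[, , , cls + 1] <- as.numeric(lab == cls)
  seg <- argmaxSegmentation(oh, spacing = c(2, 2, 2))
  expect_identical(labelArray(seg), lab)
  expect_identical(voxelSpacing(seg), c(2, 2, 2))
  # uniform probabilities resolve to the background class (code 0)
  uniform <- array(0.25, c(2, 2, 1, 4))
  expect_true(all(labelArray(argmaxSegmentation(uniform)) == 0L))
  # argmax invariant under positive per-voxel rescaling
  scaled <- oh * array(runif(prod(dim(oh)[1:3]), 0.5, 2), dim(oh)[1:4])
  expect_identical(classArgmax(scaled), classArgmax(oh))
})

test_that("slice-identical stacks give identical interior slice predictions", {
  plane <- matrix(rnorm(32 * 32, mean = 25, sd = 5), 32)
  vols <- lapply(c("50", "70", "120"), function(l)
    array(plane, c(32, 32, 6)))
  names(vols) <- c("50", "70", "120")
  stk <- SpectralStack(vols, c(3, 3, 3))
  m <- buildModel(modelSpec("unetpp", "baseline", widths = c(3, 4, 6)),
                  seed = 3)
  prob <- predictVolume(m, stk)
  # all slices see an identical pseudo-3D context (edge replication makes
  # the first/last context equal to the neighbors' too)
  for (z in 2:6)
    expect_equal(prob[, , z, ], prob[, , 1, ], tolerance = 1e-12)
})

test_that("the fold ensemble produces a labeled SegmentationResult", {
  manifest <- tinyCohort(4)
  cs <- loadCase(manifest, "case_004")
  models <- lapply(1:2, function(s)
    buildModel(modelSpec("unetpp", "aug", widths = c(3, 4, 6)), seed = s))
  res <- predictEnsemble(models, cs$stack, caseId = "case_004")
  expect_s4_class(res, "SegmentationResult")
  expect_identical(dim(labelArray(res)), dim(labelArray(cs$labels)))
  expect_true(all(labelArray(res) %in% 0:3))
})
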