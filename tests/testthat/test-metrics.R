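# Segmentation metrics and the statistics stack.

test_that("DSC matches set-count cases and is symmetric", {
  a <- array(FALSE, c(4, 4, 1)); a[1:3, 1, 1] <- TRUE   # |A| = 3
  b <- array(FALSE, c(4, 4, 1)); b[2:4, 1, 1] <- TRUE   # |B| = 3, overlap 2
  expect_equal(dsc(a, b), 2 * 2 / 6)
  expect_equal(dsc(a, b), dsc(b, a))
  expect_equal(dsc(a, a), 1)
  disjoint <- array(FALSE, c(4, 4, 1)); disjoint[4, 4, 1] <- TRUE
  expect_equal(dsc(a, disjoint), 0)
  empty <- array(FALSE, c(4, 4, 1))
  expect_equal(dsc(empty, empty), 1)   # both empty: perfect agreement
  expect_error(dsc(a, array(FALSE, c(2, 2, 1))), "shape")
})

test_that("HD95 handles analytic cases and scales with spacing", {
  m1 <- array(FALSE, c(12, 12, 3)); m1[3, 3, 2] <- TRUE
  m2 <- array(FALSE, c(12, 12, 3)); m2[8, 3, 2] <- TRUE  # 5 voxels apart
  expect_equal(hd95(m1, m2, spacing = c(1, 1, 1)), 5)
  expect_equal(hd95(m1, m1, spacing = c(1, 1, 1)), 0)
  # linear in spacing
  set.seed(51)
  a <- randomMask(c(8, 8, 8), 0.2); b <- randomMask(c(8, 8, 8), 0.2)
  expect_equal(hd95(a, b, spacing = c(2, 2, 2)),
               2 * hd95(a, b, spacing = c(1, 1, 1)))
  expect_error(hd95(array(FALSE, dim(a)), a), "empty")
})

test_that("HD95 agrees with the brute-force all-pairs oracle", {
  set.seed(52)
  for (rep in 1:10) {
    dims <- sample(5:16, 3, replace = TRUE)
    a <- randomMask(dims, runif(1, 0.1, 0.5))
    b <- randomMask(dims, runif(1, 0.1, 0.5))
    if (!sum(a) || !sum(b)) next
    sp <- runif(3, 0.5, 3)
    expect_equal(hd95(a, b, sp), bruteHd95(a, b, sp), tolerance = 1e-9)
  }
})

test_that("signed AVD follows the printed definition", {
  expect_equal(signedAvd(100, 100), 0)
  expect_equal(signedAvd(100, 110), -10)   # overestimation is negative
  expect_equal(signedAvd(80, 60), 25)
  expect_error(signedAvd(0, 10), "undefined")
})

test_that("class volumes convert voxel counts to mL and conserve totals", {
  lab <- array(0L, c(10, 10, 10))
  lab[1:10, 1:10, 1] <- 1L                 # 100 voxels of WM
  tlm <- TissueLabelMap(lab, c(1, 1, 1))
  expect_equal(volumeOfClass(tlm, 1), 0.1)  # 100 mm^3 = 0.1 mL
  expect_equal(volumeOfClass(tlm, 3), 0)
  total <- sum(vapply(0:3, function(k) volumeOfClass(tlm, k), 0))
  expect_equal(total, 1)                    # 1000 mm^3 grid = 1 mL
  expect_equal(volumeOfClass(lab, 1, spacing = c(2, 2, 2)), 0.8)
})

test_that("absolute AVD summary averages magnitudes per class", {
  rec <- data.frame(class = c("wm", "wm", "gm"), avdSigned = c(10, -20, 5))
  rec$avdAbs <- abs(rec$avdSigned)
  expect_warning(s <- absoluteAvdSummary(rec), "csf")
  expect_equal(s$perClass$meanAbsAvd[s$perClass$class == "wm"], 15)
  expect_equal(s$perClass$meanAbsAvd[s$perClass$class == "gm"], 5)
  expect_equal(s$grandMean, 10)
  # negating every signed AVD changes nothing
  rec2 <- transform(rec, avdSigned = -avdSigned, avdAbs = abs(avdSigned))
  expect_warning(s2 <- absoluteAvdSummary(rec2), "csf")
  expect_equal(s2$perClass, s$perClass)
})

test_that("Bland-Altman points pair mean volume with signed AVD", {
  rec <- data.frame(vGt = c(100, 80), vModel = c(100, 60),
                    avdSigned = c(0, 25))
  ba <- blandAltmanPoints(rec)
  expect_equal(nrow(ba$points), 2)
  expect_equal(ba$points$meanVolume, c(100, 70))
  expect_equal(ba$points$avdSigned[1], 0)
  expect_equal(ba$meanLine, mean(c(0, 25)))
})

test_that("jackknife CI matches the closed-form standard error of a mean", {
  x <- c(0.8, 0.82, 0.84, 0.86, 0.88)
  ci <- jackknifeCi(x)
  # for the mean statistic the delete-one jackknife SE equals sd(x)/sqrt(n)
  seHand <- sd(x) / sqrt(length(x))
  expect_equal(unname(ci["mean"]), mean(x))
  expect_equal(unname(ci["hi"] - ci["mean"]), qnorm(0.975) * seHand,
               tolerance = 1e-12)
  expect_equal(unname(ci["mean"] - ci["lo"]), qnorm(0.975) * seHand,
               tolerance = 1e-12)
  # identical values: zero-width interval at the value
  ci0 <- jackknifeCi(rep(0.5, 5))
  expect_equal(unname(ci0), c(0.5, 0.5, 0.5))
  expect_error(jackknifeCi(c(1, 2)), "at least 3")
})

test_that("Welch test matches stats::t.test and is antisymmetric", {
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  w <- welchTest(a, b)
  ref <- t.test(a, b, var.equal = FALSE)
  expect_equal(w$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(w$dof, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(w$p, ref$p.value, tolerance = 1e-12)
  # identical samples: t = 0, p = 1
  w0 <- welchTest(a, a)
  expect_equal(w0$t, 0)
  expect_equal(w0$p, 1)
  # swapping arguments flips t, keeps p
  wsw <- welchTest(b, a)
  expect_equal(wsw$t, -w$t)
  expect_equal(wsw$p, w$p)
  expect_error(welchTest(c(1, 1), c(1, 1)), "degenerate")
  expect_error(welchTest(1, b), "at least 2")
})

test_that("Bonferroni correction multiplies by seven and caps at one", {
  expect_equal(bonferroni(0.01), 0.07)
  expect_equal(bonferroni(0.2), 1)
  expect_equal(bonferroni(0), 0)
  p <- runif(20)
  expect_true(all(bonferroni(p) >= p))
  expect_error(bonferroni(1.2), "\\[0, 1\\]")
})

test_that("model comparison reports corrected p per class", {
  set.seed(53)
  mk <- function(shift) data.frame(
    class = rep(c("wm", "gm", "csf"), each = 5),
    dsc = rep(c(0.9, 0.85, 0.8), each = 5) + rnorm(15, shift, 0.01))
  cmp <- compareModels(list(best = mk(0.02), other = mk(0), third = mk(-0.01)),
                       reference = "best")
  expect_identical(nrow(cmp), 6L)  # 2 models x 3 classes
  expect_true(all(cmp$pCorrected >= cmp$p))
  expect_true(all(cmp$pCorrected <= 1))
  expect_equal(cmp$pCorrected, pmin(1, 7 * cmp$p))
})

test_that("caseMetrics assembles records with missing-metric handling", {
  lab <- array(0L, c(12, 12, 6))
  lab[4:9, 4:9, 2:5] <- 1L
  lab[5:8, 5:8, 3:4] <- 2L
  lab[1:2, 1:2, 1:2] <- 3L
  truth <- TissueLabelMap(lab, c(2, 2, 2))
  pred <- lab
  pred[4, 4, 2] <- 0L  # shave one WM voxel
  rec <- caseMetrics(pred, truth, caseId = "t1")
  expect_identical(rec$class, c("wm", "gm", "csf"))
  expect_true(all(rec$dsc <= 1 & rec$dsc > 0.9))
  expect_equal(rec$avdAbs, abs(rec$avdSigned))
  # a class absent from the prediction yields NA HD95, not zero
  pred2 <- lab; pred2[pred2 == 3L] <- 0L
  rec2 <- caseMetrics(pred2, truth, caseId = "t2")
  expect_true(is.na(rec2$hd95[rec2$class == "csf"]))
  expect_equal(rec2$dsc[rec2$class == "csf"], 0)
})
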