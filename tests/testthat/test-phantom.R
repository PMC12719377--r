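# Phantom cohort generator: geometry, spectral rendering, cohort on disk.

test_that("label volumes are deterministic and contain all four classes", {
  lab1 <- generateLabelVolume(tinyGeometry(), tinyGrid(), seed = 7)
  lab2 <- generateLabelVolume(tinyGeometry(), tinyGrid(), seed = 7)
  expect_identical(labelArray(lab1), labelArray(lab2))
  counts <- table(labelArray(lab1))
  expect_setequal(as.integer(names(counts)), 0:3)
  expect_true(all(counts > 0))
  # conservation: class counts sum to the grid size
  expect_equal(sum(counts), prod(tinyGrid()@shape))
  # a different seed moves the cortical fold phase
  lab3 <- generateLabelVolume(tinyGeometry(), tinyGrid(), seed = 8)
  expect_false(identical(labelArray(lab1), labelArray(lab3)))
})

test_that("WM core volume matches the analytic ellipsoid difference", {
  g <- PhantomGeometry(headSemiAxes = c(28, 24, 20), csfShellThickness = 4,
                       cortexThickness = 4, ventricleSemiAxes = c(6, 4, 4),
                       foldAmplitude = 0, foldFrequency = 8, jitter = 0)
  lab <- generateLabelVolume(g, GridSpec(c(64L, 64L, 48L), c(1, 1, 1)),
                             seed = 1)
  wmCount <- sum(labelArray(lab) == tissueClasses()[["wm"]])
  analytic <- 4 / 3 * pi * (20 * 16 * 12 - 6 * 4 * 4)  # core minus ventricle
  expect_lt(abs(wmCount - analytic) / analytic, 0.05)
})

test_that("zero fold amplitude gives a smooth ellipsoidal GM/WM interface", {
  g <- PhantomGeometry(headSemiAxes = c(26, 26, 22), csfShellThickness = 3,
                       cortexThickness = 4, ventricleSemiAxes = c(5, 5, 4),
                       foldAmplitude = 0, foldFrequency = 8, jitter = 0)
  grid <- GridSpec(c(60L, 60L, 50L), c(1, 1, 1))
  lab <- generateLabelVolume(g, grid, seed = 3)
  arr <- labelArray(lab)
  # every boundary GM voxel sits within one voxel of the analytic shell
  gmIdx <- which(arr == tissueClasses()[["gm"]], arr.ind = TRUE)
  ctr <- (dim(arr) + 1) / 2
  x <- sweep(gmIdx, 2, ctr)  # voxel == mm here
  axGmOuter <- g@headSemiAxes - g@csfShellThickness
  axWm <- axGmOuter - g@cortexThickness
  rhoOuter <- sqrt(colSums((t(x) / axGmOuter)^2))
  rhoInner <- sqrt(colSums((t(x) / axWm)^2))
  r <- sqrt(rowSums(x^2))
  # inside the outer shell surface, outside the WM surface, +/- 1 voxel
  tol <- 1 / pmax(r, 1)
  expect_true(all(rhoOuter <= 1 + tol))
  expect_true(all(rhoInner >= 1 - tol))
})

test_that("degenerate geometry raises an explicit error", {
  g <- tinyGeometry()
  # a grid too coarse to resolve the CSF shell anywhere would leave a class
  # empty; easier: shrink the head below one voxel of the grid
  expect_error(generateLabelVolume(PhantomGeometry(headSemiAxes = c(70, 70, 70)),
                                   tinyGrid(), seed = 1),
               "grid too small")
  coarse <- GridSpec(c(16L, 16L, 8L), c(12, 12, 12))
  thin <- PhantomGeometry(headSemiAxes = c(50, 50, 40),
                          csfShellThickness = 0.4, cortexThickness = 0.4,
                          ventricleSemiAxes = c(2, 2, 2), foldAmplitude = 0,
                          foldFrequency = 5, jitter = 0)
  expect_error(generateLabelVolume(thin, coarse, seed = 1), "degenerate")
})

test_that("spectral rendering follows the HU table and noise model", {
  lab <- generateLabelVolume(tinyGeometry(), tinyGrid(), seed = 7)
  sm <- SpectralModel()

  # noiseless limit: every voxel equals its table mean exactly
  noiseless <- SpectralModel(noiseSd = c("50" = 3e-8, "70" = 2e-8,
                                         "120" = 1e-8))
  stk0 <- renderSpectralStack(lab, noiseless, seed = 1)
  arr <- labelArray(lab)
  for (lev in kevLevels()) {
    mu <- noiseless@huTable[, as.character(lev)][match(arr, tissueClasses())]
    expect_lt(max(abs(stackVolume(stk0, lev) - array(mu, dim(arr)))), 1e-6)
  }

  # Monte-Carlo check of the 70 keV noise SD over >= 10^4 WM voxels
  # (the default grid gives a large enough WM core for a tight estimate)
  labBig <- generateLabelVolume(PhantomGeometry(), GridSpec(), seed = 7)
  stkBig <- renderSpectralStack(labBig, sm, seed = 5)
  wmBig <- labelArray(labBig) == tissueClasses()[["wm"]]
  expect_gte(sum(wmBig), 1e4)
  expect_lt(abs(sd(stackVolume(stkBig, 70)[wmBig]) - 4) / 4, 0.1)

  stk <- renderSpectralStack(lab, sm, seed = 5)
  wm <- arr == tissueClasses()[["wm"]]

  # GM-WM contrast strictly decreases with keV
  gm <- arr == tissueClasses()[["gm"]]
  contrast <- vapply(kevLevels(), function(l)
    mean(stackVolume(stk, l)[gm]) - mean(stackVolume(stk, l)[wm]), 0)
  expect_true(all(diff(contrast) < 0))

  # determinism and grid congruence
  stk2 <- renderSpectralStack(lab, sm, seed = 5)
  expect_identical(stackVolume(stk, 50), stackVolume(stk2, 50))
  expect_identical(dim(stackVolume(stk, 120)), dim(arr))
  expect_identical(voxelSpacing(stk), voxelSpacing(lab))
})

test_that("invalid spectral models are rejected", {
  hu <- SpectralModel()@huTable
  hu["gm", "120"] <- hu["gm", "50"] + 20  # contrast no longer decreasing
  expect_error(SpectralModel(huTable = hu), "contrast")
  expect_error(SpectralModel(noiseSd = c("50" = 3, "70" = 4, "120" = 5)),
               "noise")
})

test_that("cohort generation writes n cases with unique ids, reproducibly", {
  dir1 <- file.path(tempdir(), "cohortA")
  dir2 <- file.path(tempdir(), "cohortB")
  m1 <- generateCohort(3, dir1, geometry = tinyGeometry(), grid = tinyGrid(),
                       seed = 42)
  m2 <- generateCohort(3, dir2, geometry = tinyGeometry(), grid = tinyGrid(),
                       seed = 42)
  ids <- manifestCaseIds(m1)
  expect_length(unique(ids), 3)
  for (cs in m1$cases) {
    expect_length(cs$vmi, 3)
    expect_true(all(file.exists(unlist(cs$vmi))))
    expect_true(file.exists(cs$labels))
  }
  # byte-identical label volumes across identically-seeded runs
  for (i in 1:3)
    expect_identical(readBin(m1$cases[[i]]$labels, "raw", 1e6),
                     readBin(m2$cases[[i]]$labels, "raw", 1e6))
  # per-case jitter: different cases get different head geometry
  lab1 <- loadCase(m1, ids[1])$labels
  lab2 <- loadCase(m1, ids[2])$labels
  expect_false(identical(labelArray(lab1), labelArray(lab2)))
  expect_error(generateCohort(0, tempdir()), "nCases")
})

test_that("a manifest survives the JSON round trip", {
  m <- tinyCohort(4)
  reloaded <- readCohortManifest(file.path(m$cases[[1]]$dir, ".."))
  expect_identical(manifestCaseIds(reloaded), manifestCaseIds(m))
  expect_identical(reloaded$seed, m$seed)
  cs <- loadCase(reloaded, manifestCaseIds(reloaded)[2])
  expect_s4_class(cs$stack, "SpectralStack")
  expect_s4_class(cs$labels, "TissueLabelMap")
})
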