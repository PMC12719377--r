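# Backbone construction, parameter accounting, fusion pathways, attention.

test_that("parameter counting is exact on a hand-counted convolution", {
  params <- list(conv_w = array(0, c(3, 3, 3, 8)), conv_b = numeric(8))
  expect_identical(countParameters(params), 3L * 8L * 9L + 8L)  # 224
  # freezing removes exactly that layer's scalars
  expect_identical(countParameters(params, exclude = "conv_b"), 216L)
  # counts do not depend on weight values
  params$conv_w[] <- rnorm(length(params$conv_w))
  expect_identical(countParameters(params), 224L)
})

test_that("default specs carry the published model sizes", {
  unet <- buildModel(modelSpec("unet", "baseline"))
  unetpp <- buildModel(modelSpec("unetpp", "baseline"))
  expect_equal(round(countParameters(unet) / 1e6, 1), 3.5)
  expect_equal(round(countParameters(unetpp) / 1e6, 1), 2.6)
})

test_that("baseline and aug share one architecture and parameter count", {
  for (bb in c("unet", "unetpp")) {
    a <- buildModel(modelSpec(bb, "baseline", widths = c(4, 8, 16)), seed = 1)
    b <- buildModel(modelSpec(bb, "aug", widths = c(4, 8, 16)), seed = 1)
    expect_identical(countParameters(a), countParameters(b))
    expect_identical(names(a$params), names(b$params))
  }
})

test_that("outputs are per-pixel probability distributions of input shape", {
  set.seed(3)
  for (bb in c("unet", "unetpp")) {
    m <- buildModel(modelSpec(bb, "baseline", widths = c(3, 4, 6)), seed = 2)
    for (hw in list(c(16L, 16L), c(24L, 20L), c(21L, 19L))) {
      x <- array(rnorm(prod(hw) * 3), c(hw, 3L))
      p <- modelPredict(m, x)
      expect_identical(dim(p), c(hw, 4L))
      expect_lt(max(abs(apply(p, c(1, 2), sum) - 1)), 1e-9)
      expect_true(all(p >= 0))
    }
  }
})

test_that("invalid specs are rejected", {
  expect_error(modelSpec("unet", "baseline", widths = c(4, 8)), "depth")
  expect_error(modelSpec("resnet"), "arg")
  expect_error(new("ModelSpec", backbone = "unet", variant = "fuse",
                   widths = c(4L, 8L, 16L), inChannels = 3L, nClasses = 4L,
                   pathwayWidth = 8L, gateInterChannels = 0L,
                   baselineLevel = 70), "inChannels")
})

test_that("fuse pathways are symmetric, sized 3x width, and linear at zero", {
  m <- buildModel(modelSpec("unetpp", "fuse", widths = c(4, 8, 16),
                            pathwayWidth = 5L), seed = 4)
  # identical weights across pathways + identical inputs -> identical outputs
  params <- m$params
  params$path2_w <- params$path1_w; params$path2_b <- params$path1_b
  params$path3_w <- params$path1_w; params$path3_b <- params$path1_b
  oneLevel <- array(rnorm(12 * 12 * 3), c(12, 12, 3))
  x <- array(oneLevel, c(12, 12, 9))  # same 3 planes for all levels
  fb <- fuseInputBlock(x, params)
  expect_equal(fb$pathways[[1]], fb$pathways[[2]])
  expect_equal(fb$pathways[[2]], fb$pathways[[3]])
  expect_identical(dim(fb$fused)[3], 15L)  # 3 x pathwayWidth
  # zero input and bias-free convolution -> zero pathway output pre-norm
  params$path1_b[] <- 0
  fb0 <- fuseInputBlock(array(0, c(12, 12, 9)), params, normalize = FALSE)
  expect_equal(max(abs(fb0$pathways[[1]])), 0)
})

test_that("attention coefficients lie in (0, 1) and scale the skip", {
  m <- buildModel(modelSpec("unet", "gated", widths = c(4, 8, 16)), seed = 5)
  skip <- array(rnorm(16 * 16 * 4), c(16, 16, 4))
  gate <- array(rnorm(16 * 16 * 4), c(16, 16, 4))
  res <- attentionGate(skip, gate, m$params)
  expect_true(all(res$alpha > 0 & res$alpha < 1))
  expect_equal(res$output, applyAttention(skip, res$alpha))
  # identity and annihilation limits of the scaling
  expect_equal(applyAttention(skip, array(1, c(16, 16, 1))), skip)
  expect_equal(max(abs(applyAttention(skip, array(0, c(16, 16, 1))))), 0)
})

test_that("the gated variant reduces to fuse when alpha is clamped to 1", {
  gated <- buildModel(modelSpec("unetpp", "gated", widths = c(3, 4, 6)),
                      seed = 6)
  fuse <- buildModel(modelSpec("unetpp", "fuse", widths = c(3, 4, 6)),
                     seed = 6)
  # share every non-gate parameter
  shared <- names(fuse$params)
  fuse$params[shared] <- gated$params[shared]
  x <- array(rnorm(16 * 16 * 9), c(16, 16, 9))
  expect_equal(modelPredict(gated, x, gateOverride = 1),
               modelPredict(fuse, x), tolerance = 1e-12)
})

test_that("backpropagated gradients match finite differences", {
  set.seed(9)
  spec <- modelSpec("unetpp", "baseline", widths = c(3, 4, 6))
  m <- buildModel(spec, seed = 7)
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3, 1))
  tgt <- array(0, c(8, 8, 4, 1))
  tgt[, , , 1] <- oneHot(matrix(sample(0:3, 64, TRUE), 8))
  lossOf <- function(params) {
    tp <- spectralseg:::tapeNew()
    pids <- lapply(params, spectralseg:::tpLeaf, tp = tp)
    pid <- spectralseg:::.netForward(tp, spec, pids,
                                     spectralseg:::tpLeaf(tp, x))
    spectralseg:::tpVal(tp, spectralseg:::tpMaskedDiceLoss(tp, pid, tgt))
  }
  tp <- spectralseg:::tapeNew()
  pids <- lapply(m$params, spectralseg:::tpLeaf, tp = tp)
  pid <- spectralseg:::.netForward(tp, spec, pids, spectralseg:::tpLeaf(tp, x))
  grads <- spectralseg:::tpBackward(
    tp, spectralseg:::tpMaskedDiceLoss(tp, pid, tgt))
  for (nm in c("node1_0_c1_w", "up1_1_w", "node1_2_c2_b", "final_w")) {
    j <- sample(length(m$params[[nm]]), 1)
    eps <- 1e-5
    up <- m$params; up[[nm]][j] <- up[[nm]][j] + eps
    dn <- m$params; dn[[nm]][j] <- dn[[nm]][j] - eps
    numeric <- (lossOf(up) - lossOf(dn)) / (2 * eps)
    analytic <- grads[[pids[[nm]]]][j]
    expect_lt(abs(numeric - analytic) /
                max(abs(numeric), abs(analytic), 1e-6), 1e-4)
  }
})
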