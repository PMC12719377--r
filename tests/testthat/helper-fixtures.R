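# Shared fixtures and independent oracles, built in code at test time.

# small grid/geometry pair that keeps phantom generation fast
tinyGrid <- function() GridSpec(c(32L, 32L, 16L), c(6, 6, 6))

tinyGeometry <- function(jitter = 0.1)
  PhantomGeometry(headSemiAxes = c(66, 80, 42), csfShellThickness = 6,
                  cortexThickness = 10, ventricleSemiAxes = c(16, 22, 11),
                  foldAmplitude = 3, foldFrequency = 7, jitter = jitter)

# cached tiny cohort on disk, shared within a test file
.fixtures <- new.env(parent = emptyenv())

tinyCohort <- function(n = 4L, seed = 11L) {
  key <- sprintf("cohort_%d_%d", n, seed)
  if (is.null(.fixtures[[key]])) {
    dir <- file.path(tempdir(), paste0("spectralseg_", key))
    .fixtures[[key]] <- generateCohort(n, dir, geometry = tinyGeometry(),
                                       grid = tinyGrid(), seed = seed)
  }
  .fixtures[[key]]
}

randomMask <- function(dims, p = 0.3) {
  array(runif(prod(dims)) < p, dims)
}

# brute-force HD95 oracle: full all-pairs distance matrices, pooled directed
# nearest-neighbor sets, quantile with linear interpolation
bruteHd95 <- function(a, b, spacing = c(1, 1, 1), percentile = 0.95) {
  border <- function(m) {
    d <- dim(m)
    keep <- array(FALSE, d)
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      if (!m[i, j, k]) next
      nb <- c(
        if (i > 1) m[i - 1, j, k] else FALSE,
        if (i < d[1]) m[i + 1, j, k] else FALSE,
        if (j > 1) m[i, j - 1, k] else FALSE,
        if (j < d[2]) m[i, j + 1, k] else FALSE,
        if (k > 1) m[i, j, k - 1] else FALSE,
        if (k < d[3]) m[i, j, k + 1] else FALSE)
      if (!all(nb)) keep[i, j, k] <- TRUE
    }
    keep
  }
  A <- sweep(which(border(a), arr.ind = TRUE), 2, spacing, `*`)
  B <- sweep(which(border(b), arr.ind = TRUE), 2, spacing, `*`)
  dmat <- sqrt(pmax(outer(rowSums(A^2), rowSums(B^2), `+`) -
                      2 * A %*% t(B), 0))
  pooled <- c(apply(dmat, 1, min), apply(dmat, 2, min))
  as.numeric(quantile(pooled, percentile, type = 7))
}

# direct-summation Dice-loss oracle: explicit per-class loops
directMaskedDice <- function(pred, target, smooth = 1e-5) {
  C <- dim(pred)[3]
  terms <- numeric(0)
  for (cls in seq_len(C)) {
    if (length(dim(pred)) == 4) {
      p <- pred[, , cls, ]; t <- target[, , cls, ]
    } else {
      p <- pred[, , cls]; t <- target[, , cls]
    }
    if (sum(t) == 0) next
    terms <- c(terms, 1 - (2 * sum(p * t) + smooth) / (sum(p) + sum(t) + smooth))
  }
  mean(terms)
}

# random (prediction, one-hot target) batch with a controllable set of
# absent target classes; predictions are softmax-normalized random fields
randomLossBatch <- function(H = 6L, W = 6L, C = 4L, N = 2L, absent = integer(0)) {
  logits <- array(rnorm(H * W * C * N), c(H, W, C, N))
  e <- exp(logits)
  tot <- array(apply(e, c(1, 2, 4), sum), c(H, W, 1, N))
  pred <- array(0, dim(e))
  for (cls in seq_len(C))
    pred[, , cls, ] <- e[, , cls, , drop = FALSE] / tot
  presentClasses <- setdiff(seq_len(C), absent)
  lab <- array(sample(presentClasses - 1L, H * W * N, TRUE), c(H, W, N))
  target <- array(0, c(H, W, C, N))
  for (cls in seq_len(C)) target[, , cls, ] <- as.numeric(lab == cls - 1L)
  list(pred = pred, target = target)
}
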