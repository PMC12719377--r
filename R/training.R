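# Fold construction, epoch sampling strategies and per-fold training with
# the class-masked Dice loss.

#' Partition case ids into cross-validation folds
#'
#' Randomly assigns the ids to `K` folds whose sizes differ by at most one.
#' The assignment is deterministic given the seed, so one partition can be
#' reused across all model variants.
#'
#' @param caseIds Character vector of unique case ids (length >= K).
#' @param K Number of folds (default 7).
#' @param seed Integer seed.
#' @return A [FoldAssignment].
#' @export
#' @examples
#' makeFolds(sprintf("case_%02d", 1:21), K = 7, seed = 1)
makeFolds <- function(caseIds, K = 7L, seed = 1L) {
  caseIds <- as.character(caseIds)
  if (anyDuplicated(caseIds)) stop("case ids must be unique")
  n <- length(caseIds)
  if (n < K) stop("need at least K = ", K, " cases, got ", n)
  set.seed(seed)
  perm <- sample(caseIds)
  fold <- rep(seq_len(K), length.out = n)   # sizes differ by at most 1
  assignment <- as.integer(fold[match(caseIds, perm)])
  names(assignment) <- caseIds
  new("FoldAssignment", assignment = assignment,
      K = as.integer(K), seed = as.integer(seed))
}

#' Training configuration
#'
#' @param epochs Training epochs (the full study protocol uses 100).
#' @param batchSize Slices per batch.
#' @param optimizer Optimizer name (`"adam"`).
#' @param lr Learning rate.
#' @param k Pseudo-3D plane count per level (odd; default 3).
#' @param baselineLevel VMI level (keV) for the baseline variant.
#' @param window Intensity window in HU, mapped to \[0, 1\].
#' @param smooth Dice-loss smoothing term.
#' @param seed Integer seed controlling initialization and batch order.
#' @return A `TrainConfig` list.
#' @export
trainConfig <- function(epochs = 100L, batchSize = 8L, optimizer = "adam",
                        lr = 1e-3, k = 3L, baselineLevel = 70,
                        window = c(0, 100), smooth = 1e-5, seed = 1L) {
  if (epochs < 1L) stop("epochs must be >= 1")
  if (batchSize < 1L) stop("batchSize must be >= 1")
  if (optimizer != "adam") stop("unsupported optimizer: ", optimizer)
  cfg <- list(epochs = as.integer(epochs), batchSize = as.integer(batchSize),
              optimizer = optimizer, lr = lr, k = as.integer(k),
              baselineLevel = baselineLevel, window = window,
              smooth = smooth, seed = as.integer(seed))
  class(cfg) <- "TrainConfig"
  cfg
}

#' Per-epoch sample plan for a training variant
#'
#' Enumerates the samples one epoch visits. The Aug variant uses every VMI
#' level of every slice as its own training sample (3x the slice count);
#' baseline visits each slice once at the designated level; Fuse and Gated
#' visit each slice once with all three levels packed into one 9-channel
#' sample (`level = NA`).
#'
#' @param variant Model variant.
#' @param caseIds Character vector of training case ids.
#' @param nSlices Axial slice count per case (scalar or per-case vector).
#' @param levels VMI levels available (default 50, 70, 120).
#' @param baselineLevel Level used by the baseline variant.
#' @return `data.frame` with columns `case`, `z`, `level`.
#' @export
#' @examples
#' nrow(epochSamplePlan("aug", c("a", "b"), 10))  # 60
epochSamplePlan <- function(variant, caseIds, nSlices,
                            levels = c(50, 70, 120), baselineLevel = 70) {
  if (!variant %in% c("baseline", "aug", "fuse", "gated"))
    stop("unknown variant: ", variant)
  nSlices <- rep(nSlices, length.out = length(caseIds))
  perCase <- lapply(seq_along(caseIds), function(i) {
    base <- data.frame(case = caseIds[i], z = seq_len(nSlices[i]))
    switch(variant,
      aug = merge(base, data.frame(level = levels)),
      baseline = transform(base, level = baselineLevel),
      transform(base, level = NA_real_))
  })
  plan <- do.call(rbind, perCase)
  rownames(plan) <- NULL
  plan[, c("case", "z", "level")]
}

# --- Adam -------------------------------------------------------------------

.adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

.adamStep <- function(params, grads, state, lr) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    mhat <- state$m[[nm]] / corr1
    vhat <- state$v[[nm]] / corr2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + state$eps)
  }
  list(params = params, state = state)
}

# one optimization step on a batch; returns loss and updated params/state
.trainStep <- function(spec, params, state, x, target, lr, smooth) {
  tp <- tapeNew()
  pids <- lapply(params, tpLeaf, tp = tp)
  pOut <- .netForward(tp, spec, pids, tpLeaf(tp, x))
  lossId <- tpMaskedDiceLoss(tp, pOut, target, smooth)
  grads <- tpBackward(tp, lossId)
  g <- lapply(pids, function(id) grads[[id]])
  upd <- .adamStep(params, g, state, lr)
  list(loss = tpVal(tp, lossId), params = upd$params, state = upd$state)
}

# assemble the (x, y, C, B) input and one-hot target batch for plan rows
.assembleBatch <- function(rows, stacks, labels, variant, k, nClasses,
                           baselineLevel) {
  B <- nrow(rows)
  first <- layoutChannels(stacks[[rows$case[1]]], variant, rows$z[1], k,
                          level = if (is.na(rows$level[1])) baselineLevel
                                  else rows$level[1])
  d <- dim(first)
  x <- array(0, c(d[1], d[2], d[3], B))
  t <- array(0, c(d[1], d[2], nClasses, B))
  for (b in seq_len(B)) {
    lev <- if (is.na(rows$level[b])) baselineLevel else rows$level[b]
    x[, , , b] <- layoutChannels(stacks[[rows$case[b]]], variant, rows$z[b],
                                 k, level = lev)
    t[, , , b] <- oneHot(labels[[rows$case[b]]][, , rows$z[b]], nClasses)
  }
  list(x = x, target = t)
}

#' Train one cross-validation fold
#'
#' Trains the model on all cohort cases except those in `heldOutFold`,
#' using the epoch sample plan of the spec's variant and the class-masked
#' Dice loss, and returns a reloadable checkpoint together with the
#' per-epoch mean loss log. Fully deterministic given the config seed.
#'
#' @param manifest A `CohortManifest` (see [generateCohort()]).
#' @param folds A [FoldAssignment] over (a subset of) the manifest's cases.
#' @param heldOutFold Fold index in 1..K excluded from training.
#' @param spec A [modelSpec()].
#' @param config A [trainConfig()].
#' @return Checkpoint list: `spec`, `params`, `config`, `heldOutFold`,
#'   `log` (data.frame epoch/meanLoss).
#' @export
trainFold <- function(manifest, folds, heldOutFold, spec,
                      config = trainConfig()) {
  stopifnot(is(folds, "FoldAssignment"), is(spec, "ModelSpec"))
  if (!heldOutFold %in% seq_len(folds@K)) stop("invalid held-out fold")
  trainIds <- names(folds@assignment)[folds@assignment != heldOutFold]
  if (!length(trainIds)) stop("empty training partition")

  cases <- lapply(trainIds, function(id) loadCase(manifest, id))
  names(cases) <- trainIds
  stacks <- lapply(cases, function(cs)
    normalizeIntensity(cs$stack, config$window))
  labels <- lapply(cases, function(cs) labelArray(cs$labels))
  nSlices <- vapply(labels, function(l) dim(l)[3], 0L)

  plan <- epochSamplePlan(spec@variant, trainIds, nSlices[trainIds],
                          baselineLevel = config$baselineLevel)
  params <- .initParams(spec, seed = .childSeed(config$seed, 1L))
  state <- .adamInit(params)
  log <- data.frame(epoch = integer(0), meanLoss = numeric(0))

  for (epoch in seq_len(config$epochs)) {
    set.seed(.childSeed(config$seed, 100L + epoch))
    order <- sample(nrow(plan))
    losses <- numeric(0)
    for (start in seq(1L, nrow(plan), by = config$batchSize)) {
      rows <- plan[order[start:min(start + config$batchSize - 1L,
                                   nrow(plan))], , drop = FALSE]
      batch <- .assembleBatch(rows, stacks, labels, spec@variant, config$k,
                              spec@nClasses, config$baselineLevel)
      step <- .trainStep(spec, params, state, batch$x, batch$target,
                         config$lr, config$smooth)
      params <- step$params; state <- step$state
      losses <- c(losses, step$loss)
    }
    log <- rbind(log, data.frame(epoch = epoch, meanLoss = mean(losses)))
  }
  list(spec = spec, params = params, config = config,
       heldOutFold = as.integer(heldOutFold), log = log)
}

#' Save / load a training checkpoint
#'
#' @param checkpoint A checkpoint as returned by [trainFold()].
#' @param path Destination file.
#' @return `loadCheckpoint`: the checkpoint list.
#' @export
saveCheckpoint <- function(checkpoint, path) {
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  if (!file.exists(path)) stop("no checkpoint at ", path)
  readRDS(path)
}

#' Validation loss of a checkpoint on a set of cases
#'
#' Mean class-masked Dice loss over all slices of the given cases,
#' evaluated with the checkpoint's own windowing and slice layout.
#'
#' @param checkpoint Checkpoint from [trainFold()].
#' @param manifest A `CohortManifest`.
#' @param caseIds Cases to evaluate on.
#' @return Mean loss (scalar).
#' @export
validationLoss <- function(checkpoint, manifest, caseIds) {
  spec <- checkpoint$spec; config <- checkpoint$config
  model <- list(spec = spec, params = checkpoint$params)
  class(model) <- "SegmentationModel"
  losses <- unlist(lapply(caseIds, function(id) {
    cs <- loadCase(manifest, id)
    stk <- normalizeIntensity(cs$stack, config$window)
    lab <- labelArray(cs$labels)
    vapply(seq_len(dim(lab)[3]), function(z) {
      x <- layoutChannels(stk, spec@variant, z, config$k,
                          level = config$baselineLevel)
      p <- modelPredict(model, x)
      maskedDiceLoss(p, oneHot(lab[, , z], spec@nClasses), config$smooth)
    }, 0)
  }))
  mean(losses)
}
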