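# Slice-wise whole-volume prediction and fold-ensemble averaging.

#' Predict per-class probabilities for a whole volume
#'
#' Windows the stack, assembles each axial slice's pseudo-3D channel layout
#' for the model's variant (baseline and Aug consume only the designated
#' 70 keV level at test time; Fuse and Gated consume all three levels) and
#' reassembles the per-slice softmax outputs into a per-class probability
#' volume.
#'
#' @param model A `SegmentationModel` or checkpoint from [trainFold()].
#' @param stack A [SpectralStack] in HU.
#' @param k Pseudo-3D plane count (default 3).
#' @param window Intensity window in HU.
#' @param batchSize Slices predicted per forward pass.
#' @return 4D array (x, y, z, class) of probabilities summing to 1 per
#'   voxel.
#' @export
predictVolume <- function(model, stack, k = 3L, window = c(0, 100),
                          batchSize = 8L) {
  if (!inherits(model, "SegmentationModel")) {
    if (is.list(model) && !is.null(model$spec) && !is.null(model$params)) {
      if (!is.null(model$config)) {
        k <- model$config$k
        window <- model$config$window
      }
      model <- structure(list(spec = model$spec, params = model$params),
                         class = "SegmentationModel")
    } else stop("model must be a SegmentationModel or checkpoint")
  }
  stopifnot(is(stack, "SpectralStack"))
  spec <- model$spec
  stk <- normalizeIntensity(stack, window)
  d <- dim(stackVolume(stk, 70))
  prob <- array(0, c(d[1], d[2], d[3], spec@nClasses))
  for (start in seq(1L, d[3], by = batchSize)) {
    zs <- start:min(start + batchSize - 1L, d[3])
    x <- array(0, c(d[1], d[2], spec@inChannels, length(zs)))
    for (i in seq_along(zs))
      x[, , , i] <- layoutChannels(stk, spec@variant, zs[i], k,
                                   level = spec@baselineLevel)
    p <- modelPredict(model, x)
    for (i in seq_along(zs)) prob[, , zs[i], ] <- p[, , , i]
  }
  prob
}

#' Voxel-wise average of probability volumes
#'
#' Arithmetic mean of the ensemble members' per-class probability volumes;
#' normalization is preserved. Idempotent on identical inputs and invariant
#' to the order of the volumes.
#'
#' @param probVolumes List of congruent probability arrays.
#' @return Averaged probability array.
#' @export
ensembleAverage <- function(probVolumes) {
  if (!length(probVolumes)) stop("need at least one probability volume")
  d <- dim(probVolumes[[1]])
  for (p in probVolumes)
    if (!identical(dim(p), d)) stop("probability volumes differ in shape")
  Reduce(`+`, probVolumes) / length(probVolumes)
}

#' Discrete segmentation from a probability volume
#'
#' Per-voxel class of maximal probability; ties break toward the lowest
#' class code.
#'
#' @param prob 4D probability array (x, y, z, class).
#' @param spacing Voxel spacing in mm.
#' @return A [TissueLabelMap].
#' @export
argmaxSegmentation <- function(prob, spacing = c(1, 1, 1)) {
  TissueLabelMap(classArgmax(prob), spacing)
}

#' Fold-ensemble segmentation of one case
#'
#' Runs every fold checkpoint over the stack, averages the probability
#' volumes and takes the voxel-wise argmax, mirroring the cross-validation
#' ensemble used at test time.
#'
#' @param checkpoints List of checkpoints (one per fold) from [trainFold()].
#' @param stack A [SpectralStack] in HU.
#' @param caseId Case identifier recorded in the result.
#' @return A [SegmentationResult].
#' @export
predictEnsemble <- function(checkpoints, stack, caseId = "case") {
  if (!length(checkpoints)) stop("need at least one checkpoint")
  probs <- lapply(checkpoints, predictVolume, stack = stack)
  avg <- ensembleAverage(probs)
  lab <- classArgmax(avg)
  new("SegmentationResult", prob = avg, labels = lab,
      caseId = as.character(caseId),
      checkpoints = sprintf("fold_%d",
                            vapply(checkpoints, function(ck)
                              as.integer(ck$heldOutFold %||% NA_integer_),
                              0L)),
      spacing = voxelSpacing(stack))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
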