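# Evaluation metrics: Dice similarity, 95th-percentile Hausdorff distance,
# volume-difference statistics, jackknife confidence intervals and Welch
# tests with Bonferroni correction.

#' Dice similarity coefficient
#'
#' Spatial overlap `2|A n B| / (|A| + |B|)` between two binary masks,
#' ranging from 0 (disjoint) to 1 (identical); two empty masks count as
#' perfect agreement (1).
#'
#' @param predMask,gtMask Congruent logical/0-1 arrays.
#' @return DSC in \[0, 1\].
#' @export
#' @examples
#' dsc(c(1, 1, 1, 0) > 0, c(0, 1, 1, 1) > 0)  # 2/3
dsc <- function(predMask, gtMask) {
  if (!identical(dim(predMask), dim(gtMask)) ||
      length(predMask) != length(gtMask))
    stop("masks must have identical shapes")
  a <- sum(predMask != 0)
  b <- sum(gtMask != 0)
  if (a + b == 0) return(1)
  2 * sum(predMask != 0 & gtMask != 0) / (a + b)
}

# border voxels: in the mask with at least one face-adjacent (6-connected)
# neighbor outside it; voxels touching the volume edge count as border
.maskBorder <- function(mask) {
  d <- dim(mask)
  interior <- array(TRUE, d)
  shift <- function(m, axis, by) {
    out <- array(FALSE, d)
    idx <- lapply(d, seq_len)
    src <- idx
    idx[[axis]] <- seq_len(d[axis] - abs(by)) + max(by, 0)
    src[[axis]] <- seq_len(d[axis] - abs(by)) + max(-by, 0)
    out[idx[[1]], idx[[2]], idx[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    out
  }
  for (axis in 1:3)
    for (by in c(-1L, 1L))
      interior <- interior & shift(mask, axis, by)
  mask & !interior
}

#' 95th-percentile Hausdorff distance
#'
#' Extracts the border voxels of both masks (mask voxels with a
#' face-adjacent non-mask neighbor), computes both directed
#' nearest-neighbor border-to-border distance sets in physical units, pools
#' the two directed sets and returns their 95th percentile (linear
#' interpolation between order statistics) -- a robust surrogate for the
#' maximum (Hausdorff) distance.
#'
#' @param predMask,gtMask Congruent non-empty logical/0-1 3D arrays.
#' @param spacing Voxel spacing in mm.
#' @param percentile Percentile of the pooled distance set (default 0.95).
#' @return Distance in mm (>= 0).
#' @export
hd95 <- function(predMask, gtMask, spacing = c(1, 1, 1), percentile = 0.95) {
  if (!identical(dim(predMask), dim(gtMask)))
    stop("masks must have identical shapes")
  if (sum(predMask != 0) == 0 || sum(gtMask != 0) == 0)
    stop("hd95 undefined for an empty mask; record the metric as missing")
  pb <- which(.maskBorder(predMask != 0), arr.ind = TRUE)
  gb <- which(.maskBorder(gtMask != 0), arr.ind = TRUE)
  A <- sweep(pb, 2, spacing, `*`)
  B <- sweep(gb, 2, spacing, `*`)
  pooled <- c(.nnDistances(A, B), .nnDistances(B, A))
  as.numeric(quantile(pooled, percentile, type = 7))
}

#' Signed average volume difference (AVD)
#'
#' `(V_GT - V_M) / V_GT * 100` percent for one tissue class: negative when
#' the model overestimates the volume, positive when it underestimates.
#'
#' @param vGt Ground-truth volume (mL), > 0.
#' @param vModel Model-estimated volume (mL).
#' @return Signed AVD in percent.
#' @export
#' @examples
#' signedAvd(100, 110)  # -10
signedAvd <- function(vGt, vModel) {
  if (any(vGt <= 0))
    stop("AVD undefined for zero ground-truth volume; record as missing")
  (vGt - vModel) / vGt * 100
}

#' Volume of a tissue class
#'
#' @param labels A [TissueLabelMap] or integer array of class codes.
#' @param class Class code (see [tissueClasses()]).
#' @param spacing Voxel spacing in mm (taken from a `TissueLabelMap`).
#' @return Volume in mL.
#' @export
volumeOfClass <- function(labels, class, spacing = c(1, 1, 1)) {
  if (is(labels, "TissueLabelMap")) {
    spacing <- labels@spacing
    labels <- labels@labels
  }
  sum(labels == class) * prod(spacing) / 1000
}

#' Per-case, per-class segmentation metrics
#'
#' DSC, HD95, class volumes and signed/absolute AVD for the three
#' intracranial tissue classes (WM, GM, CSF; background is not reported).
#' HD95 and AVD are recorded as `NA` where undefined (empty mask / zero
#' ground-truth volume).
#'
#' @param pred Predicted labels ([TissueLabelMap], [SegmentationResult] or
#'   integer array).
#' @param truth Ground-truth labels (same forms).
#' @param spacing Voxel spacing in mm (defaults to the truth's spacing when
#'   available).
#' @param caseId Case identifier for the records.
#' @return `data.frame`, one row per class: `case`, `class`, `dsc`, `hd95`,
#'   `vGt`, `vModel`, `avdSigned`, `avdAbs`.
#' @export
caseMetrics <- function(pred, truth, spacing = NULL, caseId = "case") {
  if (is(truth, "TissueLabelMap") && is.null(spacing))
    spacing <- truth@spacing
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  predLab <- if (is.array(pred)) pred else labelArray(pred)
  gtLab <- if (is.array(truth)) truth else labelArray(truth)
  if (!identical(dim(predLab), dim(gtLab)))
    stop("prediction and truth grids differ")
  classes <- .CLASS_CODES[c("wm", "gm", "csf")]
  rows <- lapply(names(classes), function(nm) {
    k <- classes[[nm]]
    pm <- predLab == k
    gm <- gtLab == k
    h <- tryCatch(hd95(pm, gm, spacing), error = function(e) NA_real_)
    vG <- sum(gm) * prod(spacing) / 1000
    vM <- sum(pm) * prod(spacing) / 1000
    avd <- tryCatch(signedAvd(vG, vM), error = function(e) NA_real_)
    data.frame(case = caseId, class = nm, dsc = dsc(pm, gm), hd95 = h,
               vGt = vG, vModel = vM, avdSigned = avd, avdAbs = abs(avd))
  })
  do.call(rbind, rows)
}

#' Mean absolute AVD per class
#'
#' Averages the magnitude of the signed AVD within each tissue class, plus
#' the grand mean across classes (the overall volumetric error of a model).
#' Classes without records are omitted with a warning.
#'
#' @param records Metrics records with columns `class` and `avdSigned` (or
#'   `avdAbs`), e.g. from [caseMetrics()].
#' @return List with `perClass` (data.frame `class`, `meanAbsAvd`, `sd`,
#'   `n`) and `grandMean`.
#' @export
absoluteAvdSummary <- function(records) {
  if (is.null(records$avdAbs)) records$avdAbs <- abs(records$avdSigned)
  records <- records[!is.na(records$avdAbs), , drop = FALSE]
  present <- unique(records$class)
  missing <- setdiff(c("wm", "gm", "csf"), present)
  if (length(missing))
    warning("no AVD records for class(es): ", paste(missing, collapse = ", "))
  if (!nrow(records)) stop("no AVD records")
  perClass <- do.call(rbind, lapply(split(records, records$class),
    function(r) data.frame(class = r$class[1],
                           meanAbsAvd = mean(r$avdAbs),
                           sd = if (nrow(r) > 1) sd(r$avdAbs) else NA_real_,
                           n = nrow(r))))
  rownames(perClass) <- NULL
  list(perClass = perClass, grandMean = mean(perClass$meanAbsAvd))
}

#' Bland-Altman agreement points
#'
#' One point per record: x is the mean of ground-truth and model volumes,
#' y the signed AVD (%); the per-model mean line is the arithmetic mean of
#' the y values.
#'
#' @param records Metrics records with `vGt`, `vModel`, `avdSigned`.
#' @return List with `points` (data.frame `meanVolume`, `avdSigned`, plus
#'   `case`/`class` when present) and `meanLine`.
#' @export
blandAltmanPoints <- function(records) {
  pts <- data.frame(meanVolume = (records$vGt + records$vModel) / 2,
                    avdSigned = records$avdSigned)
  for (extra in c("case", "class"))
    if (!is.null(records[[extra]])) pts[[extra]] <- records[[extra]]
  list(points = pts, meanLine = mean(pts$avdSigned, na.rm = TRUE))
}

#' Leave-one-out jackknife confidence interval
#'
#' Delete-one resampling over the test cases: the n leave-one-out replicate
#' means give the jackknife standard error
#' `sqrt((n-1)/n * sum((theta_i - mean(theta))^2))`, and the interval is the
#' overall mean +/- the normal quantile times that standard error.
#'
#' @param values Per-case metric values (n >= 3).
#' @param level Confidence level (default 0.95).
#' @return Named vector `c(lo, mean, hi)`.
#' @export
#' @examples
#' jackknifeCi(c(0.8, 0.82, 0.84, 0.86, 0.88))
jackknifeCi <- function(values, level = 0.95) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3) stop("jackknife CI needs at least 3 cases")
  loo <- vapply(seq_len(n), function(i) mean(values[-i]), 0)
  se <- sqrt((n - 1) / n * sum((loo - mean(loo))^2))
  z <- qnorm(1 - (1 - level) / 2)
  m <- mean(values)
  c(lo = m - z * se, mean = m, hi = m + z * se)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom and a
#' two-sided p-value.
#'
#' @param a,b Numeric samples, each of length >= 2, with nonzero variance
#'   in at least one.
#' @return List with `t`, `dof`, `p`.
#' @export
welchTest <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least 2 observations")
  va <- var(a); vb <- var(b)
  if (va == 0 && vb == 0) stop("degenerate samples: both variances are zero")
  sa <- va / length(a); sb <- vb / length(b)
  t <- (mean(a) - mean(b)) / sqrt(sa + sb)
  dof <- (sa + sb)^2 / (sa^2 / (length(a) - 1) + sb^2 / (length(b) - 1))
  list(t = t, dof = dof, p = 2 * pt(-abs(t), dof))
}

#' Bonferroni correction
#'
#' Multiplies the p-value by the number of comparisons (7 compared models
#' by default) and caps at 1.
#'
#' @param p P-value(s) in \[0, 1\].
#' @param m Number of comparisons (default 7).
#' @return Corrected p-value(s).
#' @export
#' @examples
#' bonferroni(0.01)  # 0.07
bonferroni <- function(p, m = 7) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  pmin(1, m * p)
}

#' Pairwise model comparison by Welch test with Bonferroni correction
#'
#' Compares a reference model's per-case DSC values against every other
#' model, per class, correcting each p-value by the number of compared
#' models.
#'
#' @param dscByModel Named list of data.frames with columns `class` and
#'   `dsc` (e.g. [caseMetrics()] outputs), one per model.
#' @param reference Name of the reference (best-performing) model.
#' @param m Bonferroni multiplier (default 7).
#' @return `data.frame`: `reference`, `model`, `class`, `t`, `dof`, `p`,
#'   `pCorrected`.
#' @export
compareModels <- function(dscByModel, reference, m = 7) {
  if (!reference %in% names(dscByModel))
    stop("unknown reference model: ", reference)
  others <- setdiff(names(dscByModel), reference)
  ref <- dscByModel[[reference]]
  rows <- list()
  for (nm in others)
    for (cl in intersect(unique(ref$class),
                         unique(dscByModel[[nm]]$class))) {
      w <- welchTest(ref$dsc[ref$class == cl],
                     dscByModel[[nm]]$dsc[dscByModel[[nm]]$class == cl])
      rows[[length(rows) + 1L]] <-
        data.frame(reference = reference, model = nm, class = cl,
                   t = w$t, dof = w$dof, p = w$p,
                   pCorrected = bonferroni(w$p, m))
    }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
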