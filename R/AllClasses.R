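# S4 containers for the phantom generator, the spectral volumes and the
# segmentation models.

#' GridSpec: voxel grid of a phantom volume
#'
#' Shape (voxels) and spacing (mm) of an axial volume; slices run along the
#' third axis.
#'
#' @slot shape Integer triple, number of voxels along (x, y, z).
#' @slot spacing Numeric triple, voxel edge lengths in mm.
#' @export
setClass("GridSpec", representation(shape = "integer", spacing = "numeric"))

setValidity("GridSpec", function(object) {
  if (length(object@shape) != 3L || length(object@spacing) != 3L)
    return("shape and spacing must have length 3")
  if (any(object@shape < c(16L, 16L, 8L)))
    return("grid shape must be at least (16, 16, 8)")
  if (any(object@spacing <= 0)) return("spacing must be positive")
  TRUE
})

#' @param shape Integer triple of voxel counts.
#' @param spacing Numeric triple of voxel sizes in mm.
#' @return A `GridSpec` object.
#' @rdname GridSpec-class
#' @export
#' @examples
#' GridSpec(c(64L, 64L, 32L), c(3, 3, 3))
GridSpec <- function(shape = c(64L, 64L, 32L), spacing = c(3, 3, 3)) {
  new("GridSpec", shape = as.integer(shape), spacing = as.numeric(spacing))
}

#' PhantomGeometry: parametric head-phantom anatomy
#'
#' An ellipsoidal head with, outside-in: background, a cerebrospinal-fluid
#' (CSF) shell, a folded gray-matter (GM) ribbon, a white-matter (WM) core,
#' and ventricular CSF inside the core. Tissue interfaces are concentric
#' ellipsoids (semi-axes reduced by the layer thicknesses); the GM/WM
#' interface additionally carries a sinusoidal radial perturbation emulating
#' cortical folding.
#'
#' @slot headSemiAxes Numeric triple, outer head semi-axes in mm.
#' @slot csfShellThickness CSF shell thickness in mm.
#' @slot cortexThickness GM ribbon thickness in mm.
#' @slot ventricleSemiAxes Numeric triple, ventricular ellipsoid semi-axes mm.
#' @slot foldAmplitude Radial amplitude of cortical folding, mm.
#' @slot foldFrequency Folding frequency, cycles per revolution.
#' @slot jitter Per-case uniform jitter fraction applied to lengths.
#' @export
setClass("PhantomGeometry", representation(
  headSemiAxes = "numeric", csfShellThickness = "numeric",
  cortexThickness = "numeric", ventricleSemiAxes = "numeric",
  foldAmplitude = "numeric", foldFrequency = "numeric", jitter = "numeric"))

setValidity("PhantomGeometry", function(object) {
  g <- object
  if (length(g@headSemiAxes) != 3L || length(g@ventricleSemiAxes) != 3L)
    return("semi-axes must be numeric triples")
  if (any(c(g@headSemiAxes, g@csfShellThickness, g@cortexThickness,
            g@ventricleSemiAxes, g@foldFrequency) <= 0))
    return("all lengths and the fold frequency must be positive")
  if (g@foldAmplitude < 0) return("foldAmplitude must be >= 0")
  if (g@csfShellThickness + g@cortexThickness >= min(g@headSemiAxes))
    return("cortexThickness + csfShellThickness must be < min(headSemiAxes)")
  core <- g@headSemiAxes - g@csfShellThickness - g@cortexThickness
  if (any(g@ventricleSemiAxes >= core - g@foldAmplitude))
    return("ventricles must lie strictly inside the WM core")
  if (g@jitter < 0 || g@jitter >= 1) return("jitter must be in [0, 1)")
  TRUE
})

#' @param headSemiAxes,csfShellThickness,cortexThickness,ventricleSemiAxes
#'   Geometry lengths in mm; see slots.
#' @param foldAmplitude,foldFrequency Cortical folding parameters.
#' @param jitter Per-case uniform jitter fraction (default 0.1, ten percent).
#' @return A `PhantomGeometry` object.
#' @rdname PhantomGeometry-class
#' @export
#' @examples
#' PhantomGeometry()
PhantomGeometry <- function(headSemiAxes = c(66, 80, 42),
                            csfShellThickness = 4,
                            cortexThickness = 7,
                            ventricleSemiAxes = c(16, 22, 11),
                            foldAmplitude = 3,
                            foldFrequency = 11,
                            jitter = 0.1) {
  new("PhantomGeometry", headSemiAxes = as.numeric(headSemiAxes),
      csfShellThickness = as.numeric(csfShellThickness),
      cortexThickness = as.numeric(cortexThickness),
      ventricleSemiAxes = as.numeric(ventricleSemiAxes),
      foldAmplitude = as.numeric(foldAmplitude),
      foldFrequency = as.numeric(foldFrequency),
      jitter = as.numeric(jitter))
}

#' SpectralModel: tissue attenuation and noise across VMI levels
#'
#' Mean attenuation (HU) per tissue class at each virtual monoenergetic level
#' and the Gaussian noise standard deviation per level. Valid models have
#' GM-WM contrast strictly decreasing with keV, noise strictly decreasing
#' with keV, and CSF < WM < GM attenuation at every level.
#'
#' @slot huTable Numeric matrix, rows `background, wm, gm, csf`, columns
#'   `"50"`, `"70"`, `"120"`; mean HU per class and level.
#' @slot noiseSd Named numeric vector of per-level noise SD in HU.
#' @export
setClass("SpectralModel", representation(huTable = "matrix",
                                         noiseSd = "numeric"))

setValidity("SpectralModel", function(object) {
  lev <- as.character(.KEV_LEVELS)
  hu <- object@huTable
  if (!all(lev %in% colnames(hu)))
    return("huTable must have columns '50', '70', '120'")
  if (!all(names(.CLASS_CODES) %in% rownames(hu)))
    return("huTable must have rows background, wm, gm, csf")
  if (!all(lev %in% names(object@noiseSd)))
    return("noiseSd must be named by keV level 50, 70, 120")
  contrast <- hu["gm", lev] - hu["wm", lev]
  if (any(diff(contrast) >= 0))
    return("GM-WM contrast must strictly decrease with keV")
  if (any(diff(object@noiseSd[lev]) >= 0))
    return("noise SD must strictly decrease with keV")
  for (l in lev)
    if (!(hu["csf", l] < hu["wm", l] && hu["wm", l] < hu["gm", l]))
      return("CSF < WM < GM attenuation must hold at every level")
  if (any(object@noiseSd < 0)) return("noise SD must be >= 0")
  TRUE
})

#' @param huTable,noiseSd See slots; defaults give brain-window attenuation
#'   with decreasing GM-WM contrast and decreasing noise as keV rises.
#' @return A `SpectralModel` object.
#' @rdname SpectralModel-class
#' @export
#' @examples
#' SpectralModel()
SpectralModel <- function(
    huTable = matrix(c(-1000, 31, 44, 7,
                       -1000, 29, 38, 9,
                       -1000, 28, 34, 10),
                     nrow = 4, dimnames = list(
                       c("background", "wm", "gm", "csf"),
                       c("50", "70", "120"))),
    noiseSd = c("50" = 6, "70" = 4, "120" = 3)) {
  new("SpectralModel", huTable = huTable, noiseSd = noiseSd)
}

#' SpectralStack: co-registered multi-keV volumes
#'
#' Three HU-valued volumes of one case, keyed by virtual monoenergetic level,
#' sharing one grid and voxel spacing.
#'
#' @slot volumes Named list of 3D arrays, names `"50"`, `"70"`, `"120"`.
#' @slot spacing Numeric triple, voxel size in mm.
#' @export
setClass("SpectralStack", representation(volumes = "list",
                                         spacing = "numeric"))

setValidity("SpectralStack", function(object) {
  lev <- as.character(.KEV_LEVELS)
  if (!identical(sort(names(object@volumes)), sort(lev)))
    return("volumes must be named '50', '70', '120'")
  dims <- lapply(object@volumes, dim)
  if (any(vapply(dims, length, 1L) != 3L)) return("volumes must be 3D arrays")
  if (!all(vapply(dims, identical, TRUE, dims[[1]])))
    return("all volumes must share one grid")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be a positive triple")
  TRUE
})

#' @param volumes Named list of congruent 3D arrays (`"50"`, `"70"`, `"120"`).
#' @param spacing Voxel spacing in mm.
#' @return A `SpectralStack`.
#' @rdname SpectralStack-class
#' @export
SpectralStack <- function(volumes, spacing) {
  new("SpectralStack", volumes = volumes[as.character(.KEV_LEVELS)],
      spacing = as.numeric(spacing))
}

#' TissueLabelMap: integer tissue segmentation volume
#'
#' @slot labels 3D integer array with values in `tissueClasses()`.
#' @slot spacing Numeric triple, voxel size in mm.
#' @export
setClass("TissueLabelMap", representation(labels = "array",
                                          spacing = "numeric"))

setValidity("TissueLabelMap", function(object) {
  if (length(dim(object@labels)) != 3L) return("labels must be a 3D array")
  if (!all(object@labels %in% .CLASS_CODES))
    return("labels must take values 0 (background), 1 (WM), 2 (GM), 3 (CSF)")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be a positive triple")
  TRUE
})

#' @param labels 3D array of class codes.
#' @param spacing Voxel spacing in mm.
#' @return A `TissueLabelMap`.
#' @rdname TissueLabelMap-class
#' @export
TissueLabelMap <- function(labels, spacing) {
  storage.mode(labels) <- "integer"
  new("TissueLabelMap", labels = labels, spacing = as.numeric(spacing))
}

#' ModelSpec: segmentation network specification
#'
#' Backbone (`unet` or `unetpp`), spectral-input variant (`baseline`, `aug`,
#' `fuse`, `gated`), encoder channel widths and I/O channel counts. The
#' baseline and Aug variants consume one VMI level (3 pseudo-3D channels);
#' Fuse and Gated consume all three levels (9 channels) through per-level
#' input pathways. Instance normalization throughout; PReLU activations for
#' the U-Net backbone, LeakyReLU for U-Net++.
#'
#' @slot backbone `"unet"` or `"unetpp"`.
#' @slot variant `"baseline"`, `"aug"`, `"fuse"` or `"gated"`.
#' @slot widths Integer vector of encoder channel widths, one per depth.
#' @slot inChannels Input channel count (3 for baseline/aug, 9 fuse/gated).
#' @slot nClasses Number of output classes (4).
#' @slot pathwayWidth Per-pathway output channels of the fuse input block.
#' @slot gateInterChannels Intermediate channels of the attention gate
#'   (0 = half the top width).
#' @slot baselineLevel VMI level (keV) consumed by baseline/aug at test time.
#' @export
setClass("ModelSpec", representation(
  backbone = "character", variant = "character", widths = "integer",
  inChannels = "integer", nClasses = "integer", pathwayWidth = "integer",
  gateInterChannels = "integer", baselineLevel = "numeric"))

setValidity("ModelSpec", function(object) {
  if (!object@backbone %in% c("unet", "unetpp"))
    return("backbone must be 'unet' or 'unetpp'")
  if (!object@variant %in% c("baseline", "aug", "fuse", "gated"))
    return("variant must be baseline, aug, fuse or gated")
  if (length(object@widths) < 3L) return("depth (length of widths) must be >= 3")
  if (any(object@widths <= 0L)) return("widths must be strictly positive")
  expected <- if (object@variant %in% c("baseline", "aug")) 3L else 9L
  if (object@inChannels != expected)
    return(sprintf("inChannels must be %d for variant '%s'", expected,
                   object@variant))
  if (object@nClasses < 2L) return("nClasses must be >= 2")
  if (object@pathwayWidth < 1L) return("pathwayWidth must be >= 1")
  if (object@gateInterChannels < 0L)
    return("gateInterChannels must be >= 0 (0 = auto)")
  TRUE
})

#' Default encoder channel widths
#'
#' The default channel plans: a doubling encoder (16, 32, 64, 128) with a
#' widened bottleneck sized so that the default backbones carry 3.5 M
#' (U-Net) and 2.6 M (U-Net++) trainable parameters.
#'
#' @param backbone `"unet"` or `"unetpp"`.
#' @return Integer vector of per-depth channel widths.
#' @export
#' @examples
#' defaultWidths("unet")
defaultWidths <- function(backbone = c("unet", "unetpp")) {
  backbone <- match.arg(backbone)
  if (backbone == "unet") c(16L, 32L, 64L, 128L, 448L)
  else c(16L, 32L, 64L, 128L, 304L)
}

#' @param backbone,variant,widths,nClasses,pathwayWidth,gateInterChannels,baselineLevel
#'   See slots. `widths = NULL` selects [defaultWidths()] for the backbone.
#' @return A `ModelSpec`.
#' @rdname ModelSpec-class
#' @export
#' @examples
#' modelSpec("unet", "baseline")
modelSpec <- function(backbone = c("unet", "unetpp"),
                      variant = c("baseline", "aug", "fuse", "gated"),
                      widths = NULL, nClasses = 4L, pathwayWidth = 8L,
                      gateInterChannels = 0L, baselineLevel = 70) {
  backbone <- match.arg(backbone)
  variant <- match.arg(variant)
  if (is.null(widths)) widths <- defaultWidths(backbone)
  inChannels <- if (variant %in% c("baseline", "aug")) 3L else 9L
  new("ModelSpec", backbone = backbone, variant = variant,
      widths = as.integer(widths), inChannels = inChannels,
      nClasses = as.integer(nClasses),
      pathwayWidth = as.integer(pathwayWidth),
      gateInterChannels = as.integer(gateInterChannels),
      baselineLevel = as.numeric(baselineLevel))
}

#' SegmentationResult: per-class probabilities and label map for one case
#'
#' @slot prob 4D array (x, y, z, class); non-negative, sums to 1 per voxel.
#' @slot labels 3D integer array of argmax classes.
#' @slot caseId Case identifier.
#' @slot checkpoints Character vector of contributing checkpoint paths/ids.
#' @slot spacing Numeric triple, voxel size in mm.
#' @export
setClass("SegmentationResult", representation(
  prob = "array", labels = "array", caseId = "character",
  checkpoints = "character", spacing = "numeric"))

setValidity("SegmentationResult", function(object) {
  dp <- dim(object@prob)
  if (length(dp) != 4L) return("prob must be a 4D array")
  if (!identical(dp[1:3], dim(object@labels)))
    return("labels grid must match prob grid")
  if (any(object@prob < -1e-9)) return("probabilities must be non-negative")
  s <- apply(object@prob, c(1, 2, 3), sum)
  if (max(abs(s - 1)) > 1e-6) return("probabilities must sum to 1 per voxel")
  if (!all(object@labels %in% .CLASS_CODES)) return("labels out of range")
  TRUE
})

#' FoldAssignment: cross-validation fold membership
#'
#' A random equal partition of case ids into K folds (sizes differ by at
#' most one); the same assignment is reused across all model variants.
#'
#' @slot assignment Named integer vector mapping case id to fold in 1..K.
#' @slot K Number of folds.
#' @slot seed Seed the partition was drawn with.
#' @export
setClass("FoldAssignment", representation(assignment = "integer",
                                          K = "integer", seed = "integer"))

setValidity("FoldAssignment", function(object) {
  a <- object@assignment
  if (is.null(names(a)) || anyDuplicated(names(a)))
    return("assignment must be named by unique case ids")
  if (any(a < 1L | a > object@K)) return("fold indices must lie in 1..K")
  sizes <- tabulate(a, nbins = object@K)
  if (max(sizes) - min(sizes) > 1L)
    return("fold sizes must differ by at most 1")
  TRUE
})

setMethod("show", "GridSpec", function(object) {
  cat("GridSpec:", paste(object@shape, collapse = " x "), "voxels @",
      paste(object@spacing, collapse = " x "), "mm\n")
})

setMethod("show", "PhantomGeometry", function(object) {
  cat("PhantomGeometry\n")
  cat("  head semi-axes :", paste(object@headSemiAxes, collapse = ", "), "mm\n")
  cat("  CSF shell      :", object@csfShellThickness, "mm\n")
  cat("  cortex         :", object@cortexThickness, "mm (fold amp",
      object@foldAmplitude, "mm, freq", object@foldFrequency, "/rev)\n")
  cat("  ventricles     :", paste(object@ventricleSemiAxes, collapse = ", "),
      "mm; jitter +/-", object@jitter * 100, "%\n")
})

setMethod("show", "SpectralModel", function(object) {
  cat("SpectralModel (HU means; noise SD in HU)\n")
  print(object@huTable)
  cat("noise:", paste(sprintf("%s keV = %g", names(object@noiseSd),
                              object@noiseSd), collapse = ", "), "\n")
})

setMethod("show", "SpectralStack", function(object) {
  d <- dim(object@volumes[[1]])
  cat("SpectralStack:", paste(names(object@volumes), collapse = "/"),
      "keV,", paste(d, collapse = " x "), "voxels @",
      paste(signif(object@spacing, 3), collapse = " x "), "mm\n")
})

setMethod("show", "TissueLabelMap", function(object) {
  d <- dim(object@labels)
  counts <- vapply(.CLASS_CODES, function(k) sum(object@labels == k), 0)
  cat("TissueLabelMap:", paste(d, collapse = " x "), "voxels @",
      paste(signif(object@spacing, 3), collapse = " x "), "mm\n")
  cat("  voxels:", paste(sprintf("%s = %d", names(counts), counts),
                         collapse = ", "), "\n")
})

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec: %s (%s), widths [%s], in %d ch, %d classes\n",
              object@backbone, object@variant,
              paste(object@widths, collapse = ", "),
              object@inChannels, object@nClasses))
})

setMethod("show", "SegmentationResult", function(object) {
  cat("SegmentationResult for case", object@caseId, "-",
      paste(dim(object@labels), collapse = " x "), "voxels,",
      length(object@checkpoints), "checkpoint(s)\n")
})

setMethod("show", "FoldAssignment", function(object) {
  cat("FoldAssignment:", length(object@assignment), "cases in", object@K,
      "folds (seed", object@seed, ")\n")
  print(split(names(object@assignment), object@assignment))
})

#' Accessors for spectral stacks and label maps
#'
#' @param x A `SpectralStack`, `TissueLabelMap`, or `SegmentationResult`.
#' @param level keV level (50, 70 or 120) for `stackVolume`.
#' @return `stackVolume`: 3D array; `labelArray`: 3D integer array;
#'   `voxelSpacing`: numeric triple (mm); `probArray`: 4D array.
#' @name accessors
NULL

#' @rdname accessors
#' @export
stackVolume <- function(x, level) {
  stopifnot(is(x, "SpectralStack"))
  v <- x@volumes[[as.character(level)]]
  if (is.null(v)) stop("no volume at level ", level, " keV")
  v
}

#' @rdname accessors
#' @export
labelArray <- function(x) {
  if (is(x, "TissueLabelMap")) return(x@labels)
  if (is(x, "SegmentationResult")) return(x@labels)
  stop("labelArray: unsupported type")
}

#' @rdname accessors
#' @export
voxelSpacing <- function(x) {
  if (is(x, "SpectralStack") || is(x, "TissueLabelMap") ||
      is(x, "SegmentationResult")) return(x@spacing)
  if (is(x, "GridSpec")) return(x@spacing)
  stop("voxelSpacing: unsupported type")
}

#' @rdname accessors
#' @export
probArray <- function(x) {
  stopifnot(is(x, "SegmentationResult"))
  x@prob
}

#' @rdname accessors
#' @export
foldOf <- function(x) {
  stopifnot(is(x, "FoldAssignment"))
  x@assignment
}
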