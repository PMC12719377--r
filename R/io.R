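# Volume I/O, intensity windowing, pseudo-3D slice assembly and one-hot
# label encoding.

#' Read / write a volume in NIfTI format
#'
#' Volumes are stored as 64-bit floats so write-then-read round-trips are
#' exact; voxel spacing travels in the NIfTI header.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `readVolume`: list with `volume` (array) and `spacing` (numeric
#'   triple, mm).
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("no such volume file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("malformed NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  v <- as.array(img)
  attributes(v) <- list(dim = dim(v))
  list(volume = v, spacing = RNifti::pixdim(img)[seq_len(3)])
}

#' @param volume Numeric array (3D, or 4D for probability volumes).
#' @param spacing Numeric voxel spacing in mm (length 3).
#' @rdname readVolume
#' @return `writeVolume`: the path, invisibly.
#' @export
writeVolume <- function(volume, spacing, path) {
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- c(spacing, rep(1, length(dim(volume)) - 3L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Window and rescale stack intensities to [0, 1]
#'
#' Clips every voxel to the HU window and maps the window affinely onto
#' \[0, 1\]; the default (0, 100) HU brain window spans the CSF-GM range.
#'
#' @param stack A [SpectralStack].
#' @param window Numeric pair (low, high) in HU, low < high.
#' @return A [SpectralStack] with normalized volumes.
#' @export
normalizeIntensity <- function(stack, window = c(0, 100)) {
  stopifnot(is(stack, "SpectralStack"))
  if (length(window) != 2 || !(window[1] < window[2]))
    stop("window must be a (low, high) pair with low < high")
  vols <- lapply(stack@volumes, function(v) {
    (pmin(pmax(v, window[1]), window[2]) - window[1]) / diff(window)
  })
  SpectralStack(vols, stack@spacing)
}

#' Extract a pseudo-3D slice neighborhood
#'
#' Returns the k consecutive axial planes centered on slice `z` (in order
#' inferior to superior). Out-of-range neighbors are replaced by the nearest
#' valid slice (edge replication), so the first and last slices still see a
#' full k-channel context.
#'
#' @param volume 3D array.
#' @param z Axial slice index (1-based).
#' @param k Odd number of planes (k = 1 returns the plane itself).
#' @return Array of shape (x, y, k).
#' @export
extractPseudoSlice <- function(volume, z, k = 3L) {
  d <- dim(volume)
  if (length(d) != 3L) stop("volume must be 3D")
  if (k %% 2L != 1L || k < 1L) stop("k must be odd and >= 1")
  if (z < 1L || z > d[3]) stop("slice index out of range")
  half <- (k - 1L) %/% 2L
  idx <- pmin(pmax(z + seq(-half, half), 1L), d[3])
  volume[, , idx, drop = FALSE]
}

#' Assemble the multi-channel input sample for one axial slice
#'
#' Builds the channel stack a model variant consumes at slice `z`:
#' baseline and Aug variants use k pseudo-3D planes from a single VMI level
#' (3 channels for k = 3); Fuse and Gated use all three levels, ordered
#' level-major (the 50-keV triplet, then 70, then 120; 9 channels). Within a
#' level, planes run inferior to superior.
#'
#' @param stack A [SpectralStack] (typically normalized).
#' @param variant One of `"baseline"`, `"aug"`, `"fuse"`, `"gated"`.
#' @param z Axial slice index.
#' @param k Pseudo-3D plane count (odd; default 3).
#' @param level VMI level used by baseline (default 70) or designated by the
#'   Aug sampler for this sample.
#' @return Array (x, y, channels) with attributes `centerIndex` and
#'   `levels` (the keV level of each channel).
#' @export
layoutChannels <- function(stack, variant, z, k = 3L, level = 70) {
  stopifnot(is(stack, "SpectralStack"))
  if (!variant %in% c("baseline", "aug", "fuse", "gated"))
    stop("unknown variant: ", variant)
  levels <- if (variant %in% c("fuse", "gated")) .KEV_LEVELS else level
  planes <- lapply(levels, function(l)
    extractPseudoSlice(stackVolume(stack, l), z, k))
  out <- array(unlist(planes, use.names = FALSE),
               c(dim(planes[[1]])[1:2], k * length(levels)))
  attr(out, "centerIndex") <- z
  attr(out, "levels") <- rep(levels, each = k)
  out
}

#' One-hot encode a label plane
#'
#' @param labels 2D integer plane with values in `0 .. C-1`.
#' @param C Number of classes (default 4).
#' @return Array (x, y, C) of exact indicator planes (summing to 1 at every
#'   pixel).
#' @export
oneHot <- function(labels, C = 4L) {
  bad <- setdiff(unique(as.vector(labels)), 0:(C - 1L))
  if (length(bad))
    stop("labels out of range 0..", C - 1L, ": ",
         paste(sort(bad), collapse = ", "))
  d <- dim(labels)
  out <- array(0, c(d[1], d[2], C))
  for (c in 0:(C - 1L)) out[, , c + 1L] <- as.numeric(labels == c)
  out
}

#' Argmax class of a one-hot or probability plane/volume
#'
#' Ties break toward the lowest class code.
#'
#' @param p Array whose last dimension indexes the C classes.
#' @return Integer array of class codes `0 .. C-1` (last dimension dropped).
#' @export
classArgmax <- function(p) {
  d <- dim(p)
  C <- d[length(d)]
  m <- matrix(p, ncol = C)
  lab <- max.col(m, ties.method = "first") - 1L
  array(as.integer(lab), d[-length(d)])
}
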