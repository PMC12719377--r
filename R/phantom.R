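# Synthetic multi-keV head-phantom cohort: nested ellipsoidal tissue
# geometry rendered into noisy virtual monoenergetic volumes.

#' Generate a phantom tissue label volume
#'
#' Builds the nested head anatomy on the requested grid: outside-in the
#' classes are background, CSF shell, folded GM ribbon and WM core, with a
#' ventricular CSF ellipsoid inside the core. Tissue interfaces are
#' concentric ellipsoids whose semi-axes are the head semi-axes minus the
#' cumulative layer thicknesses; the GM/WM interface radius is additionally
#' perturbed by `foldAmplitude * cos(foldFrequency * phi + phase) * sin(theta)`
#' in spherical angles, giving the thin, convoluted cortical ribbon that
#' makes overlap metrics sensitive to boundary errors. The fold phase is
#' drawn from `seed`, so the output is fully reproducible.
#'
#' @param geometry A [PhantomGeometry()].
#' @param grid A [GridSpec()].
#' @param seed Integer seed (drives the cortical fold phase).
#' @return A [TissueLabelMap] containing all four classes.
#' @export
#' @examples
#' lab <- generateLabelVolume(PhantomGeometry(), GridSpec(), seed = 7)
#' table(labelArray(lab))
generateLabelVolume <- function(geometry, grid, seed = 1L) {
  stopifnot(is(geometry, "PhantomGeometry"), is(grid, "GridSpec"))
  validObject(geometry); validObject(grid)
  g <- geometry
  shape <- grid@shape; sp <- grid@spacing
  half <- (shape + 1) / 2
  xs <- (seq_len(shape[1]) - half[1]) * sp[1]
  ys <- (seq_len(shape[2]) - half[2]) * sp[2]
  zs <- (seq_len(shape[3]) - half[3]) * sp[3]
  if (any(g@headSemiAxes > c(max(abs(xs)), max(abs(ys)), max(abs(zs)))))
    stop("grid too small to contain the head ellipsoid")

  X <- array(xs, shape)
  Y <- array(rep(ys, each = shape[1]), shape)
  Z <- array(rep(zs, each = shape[1] * shape[2]), shape)
  r <- sqrt(X^2 + Y^2 + Z^2)

  # normalized ellipsoid radii: rho <= 1 means inside the surface
  rhoOf <- function(ax) sqrt((X / ax[1])^2 + (Y / ax[2])^2 + (Z / ax[3])^2)
  rhoHead <- rhoOf(g@headSemiAxes)
  rhoGm <- rhoOf(g@headSemiAxes - g@csfShellThickness)
  axWm <- g@headSemiAxes - g@csfShellThickness - g@cortexThickness
  rhoWm <- rhoOf(axWm)
  rhoVent <- rhoOf(g@ventricleSemiAxes)

  set.seed(seed)
  phase <- runif(1, 0, 2 * pi)

  # GM/WM interface: analytic radius R(u) = r / rhoWm, perturbed radially
  phi <- atan2(Y, X)
  theta <- acos(ifelse(r > 0, pmin(pmax(Z / pmax(r, 1e-12), -1), 1), 1))
  delta <- g@foldAmplitude * cos(g@foldFrequency * phi + phase) * sin(theta)
  Rwm <- r / pmax(rhoWm, 1e-12)  # analytic interface radius along voxel ray

  lab <- array(.CLASS_CODES[["background"]], shape)
  lab[rhoHead <= 1] <- .CLASS_CODES[["csf"]]
  lab[rhoGm <= 1] <- .CLASS_CODES[["gm"]]
  inWm <- rhoGm <= 1 & r <= Rwm + delta
  lab[inWm] <- .CLASS_CODES[["wm"]]
  lab[inWm & rhoVent <= 1] <- .CLASS_CODES[["csf"]]

  counts <- vapply(.CLASS_CODES, function(k) sum(lab == k), 0)
  if (any(counts == 0))
    stop("degenerate geometry: class(es) with zero voxels: ",
         paste(names(counts)[counts == 0], collapse = ", "))
  TissueLabelMap(lab, sp)
}

#' Render a label volume into a noisy multi-keV spectral stack
#'
#' Each virtual monoenergetic volume is the per-class mean attenuation from
#' the spectral model's HU table plus independent zero-mean Gaussian noise
#' with the per-level standard deviation. Noise fields are independent
#' across levels and fully determined by `seed`.
#'
#' @param labels A [TissueLabelMap].
#' @param spectral A [SpectralModel()].
#' @param seed Integer seed for the noise fields.
#' @return A [SpectralStack] sharing the label grid and spacing.
#' @export
#' @examples
#' lab <- generateLabelVolume(PhantomGeometry(), GridSpec(), seed = 7)
#' stk <- renderSpectralStack(lab, SpectralModel(), seed = 7)
renderSpectralStack <- function(labels, spectral, seed = 1L) {
  stopifnot(is(labels, "TissueLabelMap"), is(spectral, "SpectralModel"))
  validObject(spectral)
  lev <- as.character(.KEV_LEVELS)
  if (!all(lev %in% colnames(spectral@huTable)) ||
      !all(lev %in% names(spectral@noiseSd)))
    stop("spectral model is missing a keV level among 50, 70, 120")
  lab <- labels@labels
  shape <- dim(lab)
  set.seed(seed)
  vols <- lapply(lev, function(l) {
    mu <- spectral@huTable[, l][match(lab, .CLASS_CODES)]
    v <- mu + rnorm(length(lab), sd = spectral@noiseSd[[l]])
    array(v, shape)
  })
  names(vols) <- lev
  SpectralStack(vols, labels@spacing)
}

.jitterGeometry <- function(geometry, seed) {
  g <- geometry
  set.seed(seed)
  jit <- function(x) x * (1 + runif(length(x), -g@jitter, g@jitter))
  new("PhantomGeometry",
      headSemiAxes = jit(g@headSemiAxes),
      csfShellThickness = jit(g@csfShellThickness),
      cortexThickness = jit(g@cortexThickness),
      ventricleSemiAxes = jit(g@ventricleSemiAxes),
      foldAmplitude = jit(g@foldAmplitude),
      foldFrequency = g@foldFrequency,
      jitter = g@jitter)
}

#' Generate a cohort of phantom cases on disk
#'
#' Writes `nCases` case directories, each holding the three VMI volumes
#' (`vmi_050/070/120.nii.gz`) and the tissue label volume
#' (`labels.nii.gz`), all NIfTI with the voxel spacing in the header. The
#' geometry of every case is independently jittered (uniform, +/- the
#' geometry's jitter fraction) from a per-case seed derived from the global
#' seed, creating the inter-case variability that cross-validation and the
#' jackknife act on.
#'
#' @param nCases Number of cases (>= 1).
#' @param outDir Output directory (created if missing).
#' @param geometry,spectral,grid Cohort-level generation settings.
#' @param seed Global integer seed.
#' @return A `CohortManifest` (list, also written as `manifest.json`):
#'   generator version, global seed, and one record per case with its id,
#'   file paths and seed.
#' @export
generateCohort <- function(nCases, outDir, geometry = PhantomGeometry(),
                           spectral = SpectralModel(), grid = GridSpec(),
                           seed = 1L) {
  if (nCases < 1) stop("nCases must be >= 1")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  cases <- vector("list", nCases)
  for (i in seq_len(nCases)) {
    id <- sprintf("case_%03d", i)
    caseDir <- file.path(outDir, id)
    dir.create(caseDir, showWarnings = FALSE)
    caseSeed <- .childSeed(seed, i)
    gi <- .jitterGeometry(geometry, caseSeed)
    lab <- generateLabelVolume(gi, grid, seed = .childSeed(caseSeed, 1L))
    stk <- renderSpectralStack(lab, spectral, seed = .childSeed(caseSeed, 2L))
    vmiPaths <- vapply(.KEV_LEVELS, function(l) {
      p <- file.path(caseDir, sprintf("vmi_%03d.nii.gz", l))
      writeVolume(stackVolume(stk, l), voxelSpacing(stk), p)
      p
    }, "")
    names(vmiPaths) <- as.character(.KEV_LEVELS)
    labPath <- file.path(caseDir, "labels.nii.gz")
    writeVolume(labelArray(lab), voxelSpacing(lab), labPath)
    cases[[i]] <- list(id = id, dir = caseDir, vmi = as.list(vmiPaths),
                       labels = labPath, seed = caseSeed)
  }
  manifest <- list(generator = "spectralseg-phantom",
                   version = as.character(utils::packageVersion("spectralseg")),
                   seed = as.integer(seed),
                   grid = list(shape = grid@shape, spacing = grid@spacing),
                   cases = cases)
  class(manifest) <- "CohortManifest"
  jsonlite::write_json(unclass(manifest),
                       file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

#' Read a cohort manifest back from disk
#'
#' @param path Path to `manifest.json` or to the cohort directory.
#' @return A `CohortManifest` list.
#' @export
readCohortManifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.json")
  if (!file.exists(path)) stop("no manifest at ", path)
  m <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  m$cases <- lapply(m$cases, function(cs) {
    cs$vmi <- as.list(unlist(cs$vmi)); cs
  })
  class(m) <- "CohortManifest"
  m
}

#' @export
print.CohortManifest <- function(x, ...) {
  cat("CohortManifest:", length(x$cases), "cases (seed", x$seed, ")\n")
  invisible(x)
}

#' Case ids of a cohort manifest
#' @param manifest A `CohortManifest`.
#' @return Character vector of case ids.
#' @export
manifestCaseIds <- function(manifest) {
  vapply(manifest$cases, `[[`, "", "id")
}

#' Load one case from a cohort
#'
#' @param manifest A `CohortManifest`.
#' @param caseId Case identifier.
#' @return List with `stack` ([SpectralStack]) and `labels`
#'   ([TissueLabelMap]).
#' @export
loadCase <- function(manifest, caseId) {
  ids <- manifestCaseIds(manifest)
  i <- match(caseId, ids)
  if (is.na(i)) stop("unknown case id: ", caseId)
  cs <- manifest$cases[[i]]
  vols <- lapply(cs$vmi, function(p) readVolume(p)$volume)
  names(vols) <- names(cs$vmi)
  labRead <- readVolume(cs$labels)
  lab <- labRead$volume
  storage.mode(lab) <- "integer"
  list(stack = SpectralStack(vols, labRead$spacing),
       labels = TissueLabelMap(lab, labRead$spacing))
}
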