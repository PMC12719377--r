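# U-Net and U-Net++ backbones with spectral-fusion input pathways and an
# additive attention gate on the top skip connection.
#
# Blocks are two 3x3 convolutions, each followed by instance normalization
# and the backbone's activation (PReLU for U-Net, LeakyReLU for U-Net++).
# Downsampling is 2x2 max pooling, upsampling a 2x2 stride-2 transposed
# convolution; the head is a 1x1 convolution with a softmax over the four
# classes. Inputs whose height/width are not divisible by 2^(depth-1) are
# reflect-padded up and the output cropped back.

.heInit <- function(dims) {
  fanIn <- prod(dims[-length(dims)])
  array(rnorm(prod(dims), sd = sqrt(2 / fanIn)), dims)
}

.gateWidth <- function(spec) {
  if (spec@gateInterChannels > 0L) spec@gateInterChannels
  else max(spec@widths[1] %/% 2L, 1L)
}

.initParams <- function(spec, seed = 1L) {
  set.seed(seed)
  P <- list()
  addConv <- function(name, k, cin, cout) {
    P[[paste0(name, "_w")]] <<- .heInit(c(k, k, cin, cout))
    P[[paste0(name, "_b")]] <<- numeric(cout)
  }
  addAct <- function(name) {
    if (spec@backbone == "unet") P[[name]] <<- 0.25  # PReLU slope
  }
  addBlock <- function(prefix, cin, cout) {
    addConv(paste0(prefix, "_c1"), 3L, cin, cout); addAct(paste0(prefix, "_a1"))
    addConv(paste0(prefix, "_c2"), 3L, cout, cout); addAct(paste0(prefix, "_a2"))
  }
  w <- spec@widths
  D <- length(w)
  fused <- spec@variant %in% c("fuse", "gated")
  if (fused) {
    for (l in 1:3) {
      addConv(sprintf("path%d", l), 3L, spec@inChannels %/% 3L,
              spec@pathwayWidth)
      addAct(sprintf("path%d_a", l))
    }
  }
  in0 <- if (fused) 3L * spec@pathwayWidth else spec@inChannels
  if (spec@backbone == "unet") {
    for (i in seq_len(D))
      addBlock(paste0("enc", i), if (i == 1L) in0 else w[i - 1L], w[i])
    for (i in seq.int(D - 1L, 1L)) {
      P[[paste0("up", i, "_w")]] <- .heInit(c(2L, 2L, w[i + 1L], w[i]))
      P[[paste0("up", i, "_b")]] <- numeric(w[i])
      addBlock(paste0("dec", i), 2L * w[i], w[i])
    }
  } else {
    for (i in seq_len(D))
      addBlock(sprintf("node%d_0", i), if (i == 1L) in0 else w[i - 1L], w[i])
    for (j in seq_len(D - 1L))
      for (i in seq_len(D - j)) {
        P[[sprintf("up%d_%d_w", i, j)]] <- .heInit(c(2L, 2L, w[i + 1L], w[i]))
        P[[sprintf("up%d_%d_b", i, j)]] <- numeric(w[i])
        addBlock(sprintf("node%d_%d", i, j), (j + 1L) * w[i], w[i])
      }
  }
  addConv("final", 1L, w[1], spec@nClasses)
  if (spec@variant == "gated") {
    skipCh <- if (spec@backbone == "unet") w[1] else (D - 1L) * w[1]
    Fint <- .gateWidth(spec)
    addConv("gate_theta", 1L, skipCh, Fint)
    addConv("gate_phi", 1L, w[1], Fint)
    addConv("gate_psi", 1L, Fint, 1L)
  }
  P
}

.tpAct <- function(tp, xid, pids, aname, spec) {
  if (spec@backbone == "unet") tpPReLU(tp, xid, pids[[aname]])
  else tpLeakyReLU(tp, xid)
}

.tpConvBlock <- function(tp, xid, pids, prefix, spec) {
  h <- tpConv2d(tp, xid, pids[[paste0(prefix, "_c1_w")]],
                pids[[paste0(prefix, "_c1_b")]], 1L)
  h <- tpInstanceNorm(tp, h)
  h <- .tpAct(tp, h, pids, paste0(prefix, "_a1"), spec)
  h <- tpConv2d(tp, h, pids[[paste0(prefix, "_c2_w")]],
                pids[[paste0(prefix, "_c2_b")]], 1L)
  h <- tpInstanceNorm(tp, h)
  .tpAct(tp, h, pids, paste0(prefix, "_a2"), spec)
}

# per-level input pathways: conv -> activation -> instance norm, then concat
.tpFuseBlock <- function(tp, xid, pids, spec) {
  x <- tpVal(tp, xid)
  perPath <- dim(x)[3] %/% 3L
  outs <- integer(3)
  for (l in 1:3) {
    sl <- tpSliceChannels(tp, xid, (l - 1L) * perPath + seq_len(perPath))
    h <- tpConv2d(tp, sl, pids[[sprintf("path%d_w", l)]],
                  pids[[sprintf("path%d_b", l)]], 1L)
    h <- .tpAct(tp, h, pids, sprintf("path%d_a", l), spec)
    outs[l] <- tpInstanceNorm(tp, h)
  }
  tpConcat(tp, outs)
}

.tpAttentionGate <- function(tp, skipId, gateId, pids, spec,
                             gateOverride = NULL) {
  th <- tpConv2d(tp, skipId, pids$gate_theta_w, pids$gate_theta_b, 0L)
  ph <- tpConv2d(tp, gateId, pids$gate_phi_w, pids$gate_phi_b, 0L)
  ds <- dim(tpVal(tp, th)); dg <- dim(tpVal(tp, ph))
  if (ds[1] != dg[1] || ds[2] != dg[2])
    ph <- tpResizeBilinear(tp, ph, ds[1], ds[2])
  a <- tpSigmoid(tp, tpConv2d(tp, tpReLU(tp, tpAdd(tp, th, ph)),
                              pids$gate_psi_w, pids$gate_psi_b, 0L))
  if (!is.null(gateOverride)) {
    av <- tpVal(tp, a)
    a <- tpLeaf(tp, array(gateOverride, dim(av)))
  }
  list(out = tpScaleByGate(tp, skipId, a), alpha = a)
}

.tpBackbone <- function(tp, spec, pids, xid, gateOverride = NULL) {
  D <- length(spec@widths)
  if (spec@variant %in% c("fuse", "gated"))
    xid <- .tpFuseBlock(tp, xid, pids, spec)
  if (spec@backbone == "unet") {
    enc <- integer(D)
    h <- xid
    for (i in seq_len(D)) {
      if (i > 1L) h <- tpMaxPool(tp, h)
      h <- .tpConvBlock(tp, h, pids, paste0("enc", i), spec)
      enc[i] <- h
    }
    for (i in seq.int(D - 1L, 1L)) {
      up <- tpConvT2d(tp, h, pids[[paste0("up", i, "_w")]],
                      pids[[paste0("up", i, "_b")]])
      skip <- enc[i]
      if (i == 1L && spec@variant == "gated")
        skip <- .tpAttentionGate(tp, skip, up, pids, spec, gateOverride)$out
      h <- .tpConvBlock(tp, tpConcat(tp, c(skip, up)), pids,
                        paste0("dec", i), spec)
    }
  } else {
    X <- vector("list", D)
    prev <- xid
    for (i in seq_len(D)) {
      inp <- if (i == 1L) prev else tpMaxPool(tp, X[[i - 1L]][1L])
      X[[i]] <- .tpConvBlock(tp, inp, pids, sprintf("node%d_0", i), spec)
    }
    for (j in seq_len(D - 1L)) {
      for (i in seq_len(D - j)) {
        up <- tpConvT2d(tp, X[[i + 1L]][j], pids[[sprintf("up%d_%d_w", i, j)]],
                        pids[[sprintf("up%d_%d_b", i, j)]])
        skips <- X[[i]][seq_len(j)]
        if (i == 1L && j == D - 1L && spec@variant == "gated") {
          skipCat <- tpConcat(tp, skips)
          gated <- .tpAttentionGate(tp, skipCat, up, pids, spec,
                                    gateOverride)$out
          inp <- tpConcat(tp, c(gated, up))
        } else {
          inp <- tpConcat(tp, c(skips, up))
        }
        X[[i]] <- c(X[[i]], .tpConvBlock(tp, inp, pids,
                                         sprintf("node%d_%d", i, j), spec))
      }
    }
    h <- X[[1L]][D]
  }
  tpConv2d(tp, h, pids$final_w, pids$final_b, 0L)
}

.netForward <- function(tp, spec, pids, xid, gateOverride = NULL) {
  d0 <- dim(tpVal(tp, xid))
  mult <- 2L^(length(spec@widths) - 1L)
  padH <- (mult - d0[1] %% mult) %% mult
  padW <- (mult - d0[2] %% mult) %% mult
  if (padH >= d0[1] || padW >= d0[2])
    stop("input spatial size too small for network depth")
  xid <- tpPadReflect(tp, xid, padH, padW)
  logits <- .tpBackbone(tp, spec, pids, xid, gateOverride)
  logits <- tpCrop(tp, logits, d0[1], d0[2])
  tpSoftmaxCh(tp, logits)
}

#' Build a segmentation model from a specification
#'
#' Instantiates the backbone/variant of `spec` with randomly initialized
#' weights (He initialization, reproducible via `seed`). The model maps a
#' (x, y, channels\[, batch\]) input to per-class probabilities of the same
#' spatial shape, summing to 1 at every pixel.
#'
#' @param spec A [modelSpec()].
#' @param seed Integer seed for weight initialization.
#' @return A `SegmentationModel` (list with `spec` and `params`).
#' @export
#' @examples
#' m <- buildModel(modelSpec("unet", "baseline", widths = c(4, 8, 16)))
#' countParameters(m)
buildModel <- function(spec, seed = 1L) {
  stopifnot(is(spec, "ModelSpec"))
  validObject(spec)
  model <- list(spec = spec, params = .initParams(spec, seed))
  class(model) <- "SegmentationModel"
  model
}

#' @export
print.SegmentationModel <- function(x, ...) {
  cat(sprintf("SegmentationModel: %s (%s), %s trainable parameters\n",
              x$spec@backbone, x$spec@variant,
              format(countParameters(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters
#'
#' Exact count of trainable scalars (convolution weights and biases and
#' PReLU slopes). Parameters whose names match a prefix in `exclude` are
#' treated as frozen and not counted.
#'
#' @param model A `SegmentationModel`, or a named list of parameter arrays.
#' @param exclude Character vector of parameter-name prefixes to freeze.
#' @return Integer parameter count.
#' @export
countParameters <- function(model, exclude = character()) {
  params <- if (inherits(model, "SegmentationModel")) model$params else model
  if (length(exclude))
    params <- params[!Reduce(`|`, lapply(exclude, startsWith,
                                         x = names(params)))]
  sum(vapply(params, length, 0L))
}

#' Run a model forward on an input batch
#'
#' @param model A `SegmentationModel`.
#' @param x Input array (x, y, channels) or (x, y, channels, batch) matching
#'   the spec's `inChannels`.
#' @param gateOverride Optional constant in \[0, 1\] forced onto the
#'   attention coefficients (diagnostics; `NULL` = learned gate).
#' @return Per-class probability array of the same spatial shape
#'   (x, y, nClasses\[, batch\]).
#' @export
modelPredict <- function(model, x, gateOverride = NULL) {
  d <- dim(x)
  squeeze <- length(d) == 3L
  if (squeeze) dim(x) <- c(d, 1L)
  if (dim(x)[3] != model$spec@inChannels)
    stop("input has ", dim(x)[3], " channels; spec expects ",
         model$spec@inChannels)
  tp <- tapeNew()
  pids <- lapply(model$params, tpLeaf, tp = tp)
  out <- tpVal(tp, .netForward(tp, model$spec, pids, tpLeaf(tp, x),
                               gateOverride))
  if (squeeze) dim(out) <- dim(out)[1:3]
  out
}

#' Spectral-fusion input block
#'
#' Applies one per-level pathway (3x3 convolution, activation, instance
#' normalization) to each of the three VMI channel groups and concatenates
#' the pathway outputs channel-wise, as fed to the backbone's first block in
#' the Fuse and Gated variants.
#'
#' @param x Input array (x, y, 9\[, batch\]): three 3-channel level groups,
#'   level-major.
#' @param params Named list with `path1_w/b`, `path2_w/b`, `path3_w/b` (and
#'   `path1_a` ... for a PReLU backbone); e.g. from `buildModel()$params`.
#' @param activation `"prelu"` or `"lrelu"`.
#' @param normalize Apply the pathway instance normalization (default TRUE;
#'   disable to inspect raw pathway outputs).
#' @return List with `fused` (concatenated output) and `pathways` (list of
#'   the three per-pathway outputs).
#' @export
fuseInputBlock <- function(x, params, activation = c("lrelu", "prelu"),
                           normalize = TRUE) {
  activation <- match.arg(activation)
  d <- dim(x)
  squeeze <- length(d) == 3L
  if (squeeze) dim(x) <- c(d, 1L)
  if (dim(x)[3] %% 3L != 0L) stop("channel count must be divisible by 3")
  perPath <- dim(x)[3] %/% 3L
  tp <- tapeNew()
  paths <- vector("list", 3L)
  for (l in 1:3) {
    w <- params[[sprintf("path%d_w", l)]]
    if (is.null(w)) stop("missing pathway parameters: path", l)
    sl <- x[, , (l - 1L) * perPath + seq_len(perPath), , drop = FALSE]
    h <- tpConv2d(tp, tpLeaf(tp, sl), tpLeaf(tp, w),
                  tpLeaf(tp, params[[sprintf("path%d_b", l)]]), 1L)
    h <- if (activation == "prelu")
      tpPReLU(tp, h, tpLeaf(tp, params[[sprintf("path%d_a", l)]]))
    else tpLeakyReLU(tp, h)
    if (normalize) h <- tpInstanceNorm(tp, h)
    paths[[l]] <- tpVal(tp, h)
  }
  fused <- array(unlist(lapply(paths, as.vector)),
                 c(dim(paths[[1]])[1:2], 3L * dim(paths[[1]])[3],
                   dim(paths[[1]])[4]))
  if (squeeze) {
    dim(fused) <- dim(fused)[1:3]
    paths <- lapply(paths, function(p) { dim(p) <- dim(p)[1:3]; p })
  }
  list(fused = fused, pathways = paths)
}

#' Additive attention gate
#'
#' Oktay-style gate: attention coefficients `alpha` in (0, 1) are a sigmoid
#' over a 1x1-convolved combination of the projected skip features and
#' gating signal (the gating signal is bilinearly resampled to the skip's
#' spatial size when they differ); the output is `alpha * skip`, per
#' position, broadcast across skip channels.
#'
#' @param skip Skip-connection features (x, y, C\[, batch\]).
#' @param gate Gating signal (x, y, Cg\[, batch\]).
#' @param params Named list with `gate_theta_w/b`, `gate_phi_w/b`,
#'   `gate_psi_w/b` 1x1 convolution parameters.
#' @return List with `output` (gated skip features) and `alpha` (the
#'   attention coefficients, single channel).
#' @export
attentionGate <- function(skip, gate, params) {
  ds <- dim(skip)
  squeeze <- length(ds) == 3L
  if (squeeze) { dim(skip) <- c(ds, 1L); dim(gate) <- c(dim(gate), 1L) }
  tp <- tapeNew()
  pids <- lapply(params, tpLeaf, tp = tp)
  spec <- modelSpec("unet", "baseline")  # backbone irrelevant to the gate
  res <- .tpAttentionGate(tp, tpLeaf(tp, skip), tpLeaf(tp, gate), pids, spec)
  out <- tpVal(tp, res$out)
  alpha <- tpVal(tp, res$alpha)
  if (squeeze) { dim(out) <- dim(out)[1:3]; dim(alpha) <- dim(alpha)[1:3] }
  list(output = out, alpha = alpha)
}

#' Scale skip features by attention coefficients
#'
#' @param skip Feature array (x, y, C\[, batch\]).
#' @param alpha Single-channel coefficient array broadcast over channels.
#' @return `skip * alpha`, elementwise per position.
#' @export
applyAttention <- function(skip, alpha) {
  ds <- dim(skip)
  squeeze <- length(ds) == 3L
  if (squeeze) { dim(skip) <- c(ds, 1L); dim(alpha) <- c(dim(alpha), 1L) }
  out <- skip * alpha[, , rep(1L, dim(skip)[3]), , drop = FALSE]
  if (squeeze) dim(out) <- dim(out)[1:3]
  out
}
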