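# Minimal reverse-mode tape over 4D image batches (H, W, C, N), backing the
# segmentation backbones. Convolution/pooling kernels live in src/; the
# remaining ops are vectorized R. Each tape node stores a value, its parent
# node ids and a backward closure returning the parents' gradients.

tapeNew <- function() {
  tp <- new.env(parent = emptyenv())
  tp$n <- 0L
  tp$nodes <- vector("list", 512L)
  tp
}

tpPush <- function(tp, val, parents = integer(0), backward = NULL) {
  tp$n <- tp$n + 1L
  if (tp$n > length(tp$nodes))
    tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  tp$nodes[[tp$n]] <- list(val = val, parents = as.integer(parents),
                           backward = backward)
  tp$n
}

tpVal <- function(tp, id) {
  force(id)  # `id` may be an expression that pushes nodes onto the tape
  tp$nodes[[id]]$val
}

tpLeaf <- function(tp, val) tpPush(tp, val)

# reverse accumulation from the scalar node `lossId`; returns a list of
# gradients indexed by node id (NULL where the node does not influence loss)
tpBackward <- function(tp, lossId) {
  grads <- vector("list", tp$n)
  grads[[lossId]] <- 1
  for (i in seq.int(lossId, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    nd <- tp$nodes[[i]]
    if (is.null(nd$backward)) next
    pg <- nd$backward(g)
    for (k in seq_along(nd$parents)) {
      if (is.null(pg[[k]])) next
      p <- nd$parents[k]
      grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
    }
  }
  grads
}

# --- convolution ops --------------------------------------------------------

tpConv2d <- function(tp, xid, wid, bid, pad) {
  x <- tpVal(tp, xid); w <- tpVal(tp, wid); b <- tpVal(tp, bid)
  y <- .conv2dForward(x, w, b, as.integer(pad))
  tpPush(tp, y, c(xid, wid, bid), function(dy) {
    g <- .conv2dBackward(x, w, dy, as.integer(pad))
    list(g$dx, g$dw, g$db)
  })
}

tpConvT2d <- function(tp, xid, wid, bid) {
  x <- tpVal(tp, xid); w <- tpVal(tp, wid); b <- tpVal(tp, bid)
  y <- .convT2dForward(x, w, b)
  tpPush(tp, y, c(xid, wid, bid), function(dy) {
    g <- .convT2dBackward(x, w, dy)
    list(g$dx, g$dw, g$db)
  })
}

tpMaxPool <- function(tp, xid) {
  x <- tpVal(tp, xid)
  f <- .maxPoolForward(x)
  xdim <- dim(x)
  tpPush(tp, f$y, xid, function(dy) {
    list(.maxPoolBackward(dy, f$idx, as.integer(xdim)))
  })
}

# --- normalization and activations -----------------------------------------

tpInstanceNorm <- function(tp, xid, eps = 1e-5) {
  f <- .inormForward(tpVal(tp, xid), eps)
  tpPush(tp, f$y, xid, function(dy) {
    list(.inormBackward(f$y, f$sig, dy))
  })
}

tpPReLU <- function(tp, xid, aid) {
  x <- tpVal(tp, xid); a <- tpVal(tp, aid)  # scalar slope
  fac <- a + (1 - a) * (x > 0)
  tpPush(tp, x * fac, c(xid, aid), function(dy) {
    list(dy * fac, sum(dy * pmin(x, 0)))
  })
}

tpLeakyReLU <- function(tp, xid, slope = 0.01) {
  x <- tpVal(tp, xid)
  tpPush(tp, .lreluForward(x, slope), xid,
         function(dy) list(.lreluBackward(x, dy, slope)))
}

tpReLU <- function(tp, xid) {
  x <- tpVal(tp, xid)
  pos <- x > 0
  tpPush(tp, x * pos, xid, function(dy) list(dy * pos))
}

tpSigmoid <- function(tp, xid) {
  s <- 1 / (1 + exp(-tpVal(tp, xid)))
  tpPush(tp, s, xid, function(dy) list(dy * s * (1 - s)))
}

tpAdd <- function(tp, aid, bid) {
  tpPush(tp, tpVal(tp, aid) + tpVal(tp, bid), c(aid, bid),
         function(dy) list(dy, dy))
}

# concatenate along the channel axis (dim 3)
tpConcat <- function(tp, ids) {
  vals <- lapply(ids, tpVal, tp = tp)
  chans <- vapply(vals, function(v) dim(v)[3], 0)
  d1 <- dim(vals[[1]])
  y <- array(0, c(d1[1], d1[2], sum(chans), d1[4]))
  at <- 0L
  for (v in vals) {
    y[, , at + seq_len(dim(v)[3]), ] <- v
    at <- at + dim(v)[3]
  }
  tpPush(tp, y, ids, function(dy) {
    out <- vector("list", length(chans))
    at <- 0L
    for (k in seq_along(chans)) {
      out[[k]] <- dy[, , at + seq_len(chans[k]), , drop = FALSE]
      at <- at + chans[k]
    }
    out
  })
}

# take a subset of channels (dim 3)
tpSliceChannels <- function(tp, xid, idx) {
  x <- tpVal(tp, xid)
  d <- dim(x)
  y <- x[, , idx, , drop = FALSE]
  tpPush(tp, y, xid, function(dy) {
    dx <- array(0, d)
    dx[, , idx, ] <- dy
    list(dx)
  })
}

# interpolation matrix mapping nIn samples onto nOut (half-pixel centers)
.bilinMat <- function(nIn, nOut) {
  A <- matrix(0, nOut, nIn)
  src <- (seq_len(nOut) - 0.5) * nIn / nOut - 0.5   # 0-based source coord
  i0 <- pmin(pmax(floor(src), 0), nIn - 1)
  i1 <- pmin(i0 + 1, nIn - 1)
  wv <- pmin(pmax(src - i0, 0), 1)
  for (r in seq_len(nOut)) {
    A[r, i0[r] + 1] <- A[r, i0[r] + 1] + (1 - wv[r])
    A[r, i1[r] + 1] <- A[r, i1[r] + 1] + wv[r]
  }
  A
}

tpResizeBilinear <- function(tp, xid, H, W) {
  x <- tpVal(tp, xid)
  d <- dim(x)
  if (d[1] == H && d[2] == W) return(xid)
  AH <- .bilinMat(d[1], H)
  AW <- .bilinMat(d[2], W)
  y <- array(0, c(H, W, d[3], d[4]))
  for (n in seq_len(d[4]))
    for (c in seq_len(d[3]))
      y[, , c, n] <- AH %*% x[, , c, n] %*% t(AW)
  tpPush(tp, y, xid, function(dy) {
    dx <- array(0, d)
    for (n in seq_len(d[4]))
      for (c in seq_len(d[3]))
        dx[, , c, n] <- t(AH) %*% dy[, , c, n] %*% AW
    list(dx)
  })
}

# multiply every channel of `skip` by a single-channel spatial gate `alpha`
tpScaleByGate <- function(tp, skipId, alphaId) {
  s <- tpVal(tp, skipId); a <- tpVal(tp, alphaId)
  C <- dim(s)[3]
  aFull <- a[, , rep(1L, C), , drop = FALSE]
  tpPush(tp, s * aFull, c(skipId, alphaId), function(dy) {
    dAlpha <- apply(dy * s, c(1, 2, 4), sum)
    list(dy * aFull, array(dAlpha, dim(a)))
  })
}

tpSoftmaxCh <- function(tp, xid) {
  x <- tpVal(tp, xid)
  d <- dim(x)
  p <- .softmaxCh(x)
  tpPush(tp, p, xid, function(dy) {
    s <- dy * p
    tot <- s[, , 1, , drop = FALSE]
    for (c in seq_len(d[3])[-1]) tot <- tot + s[, , c, , drop = FALSE]
    list(p * (dy - tot[, , rep(1L, d[3]), , drop = FALSE]))
  })
}

.softmaxCh <- function(x) {
  d <- dim(x)
  mx <- x[, , 1, , drop = FALSE]
  for (c in seq_len(d[3])[-1]) mx <- pmax(mx, x[, , c, , drop = FALSE])
  mxFull <- mx[, , rep(1L, d[3]), , drop = FALSE]
  e <- exp(x - mxFull)
  s <- e[, , 1, , drop = FALSE]
  for (c in seq_len(d[3])[-1]) s <- s + e[, , c, , drop = FALSE]
  e / s[, , rep(1L, d[3]), , drop = FALSE]
}

# --- reflect padding / cropping (for inputs not divisible by 2^depth) ------

tpPadReflect <- function(tp, xid, padH, padW) {
  x <- tpVal(tp, xid)
  if (padH == 0L && padW == 0L) return(xid)
  d <- dim(x)
  idxH <- c(seq_len(d[1]), rev(seq_len(d[1]))[seq_len(padH) + 1L])
  idxW <- c(seq_len(d[2]), rev(seq_len(d[2]))[seq_len(padW) + 1L])
  if (padH == 0L) idxH <- seq_len(d[1])
  if (padW == 0L) idxW <- seq_len(d[2])
  y <- x[idxH, idxW, , , drop = FALSE]
  tpPush(tp, y, xid, function(dy) {
    # fold duplicated rows back first, then duplicated columns
    dRows <- array(0, c(d[1], dim(dy)[2], d[3], d[4]))
    for (i in seq_along(idxH))
      dRows[idxH[i], , , ] <- dRows[idxH[i], , , ] + dy[i, , , ]
    dx <- array(0, d)
    for (j in seq_along(idxW))
      dx[, idxW[j], , ] <- dx[, idxW[j], , ] + dRows[, j, , ]
    list(dx)
  })
}

tpCrop <- function(tp, xid, H, W) {
  x <- tpVal(tp, xid)
  d <- dim(x)
  if (d[1] == H && d[2] == W) return(xid)
  y <- x[seq_len(H), seq_len(W), , , drop = FALSE]
  tpPush(tp, y, xid, function(dy) {
    dx <- array(0, d)
    dx[seq_len(H), seq_len(W), , ] <- dy
    list(dx)
  })
}

# --- class-masked Dice loss -------------------------------------------------

# batch-level class presence, dice over present classes only
.maskedDice <- function(pred, target, smooth) {
  d <- dim(pred)
  C <- d[3]
  sp <- st <- sPt <- numeric(C)
  for (c in seq_len(C)) {
    pc <- pred[, , c, , drop = FALSE]
    tc <- target[, , c, , drop = FALSE]
    sp[c] <- sum(pc); st[c] <- sum(tc); sPt[c] <- sum(pc * tc)
  }
  present <- st > 0
  if (!any(present)) stop("masked Dice loss undefined: no class present")
  A <- 2 * sPt + smooth
  B <- sp + st + smooth
  dice <- 1 - A / B
  list(loss = mean(dice[present]), present = present, A = A, B = B)
}

#' Class-masked multi-class Dice loss
#'
#' Soft Dice loss computed class-wise over the whole batch, averaging only
#' over classes present in the target (a class is present when it has at
#' least one positive target pixel anywhere in the batch). Absent classes
#' contribute nothing to the value or to the gradient, so early batches that
#' happen to lack a tissue class cannot push its predictions toward zero.
#' Per present class c the loss term is
#' `1 - (2 * sum(p_c t_c) + s) / (sum(p_c) + sum(t_c) + s)`.
#'
#' @param pred Per-class probability array (x, y, C) or (x, y, C, N); must
#'   sum to 1 over classes at every pixel.
#' @param target One-hot target of the same shape.
#' @param smooth Symmetric smoothing term `s` (default 1e-5).
#' @return Scalar loss in \[0, 1\] (up to smoothing).
#' @export
#' @examples
#' t <- oneHot(matrix(c(0, 1, 1, 2), 2), C = 4)
#' maskedDiceLoss(t, t) < 1e-4
maskedDiceLoss <- function(pred, target, smooth = 1e-5) {
  pred <- .asBatch4d(pred); target <- .asBatch4d(target)
  stopifnot(identical(dim(pred), dim(target)))
  .maskedDice(pred, target, smooth)$loss
}

#' @rdname maskedDiceLoss
#' @return `maskedDiceGrad`: gradient of the loss with respect to `pred`,
#'   same shape as `pred`; exactly zero for absent classes.
#' @export
maskedDiceGrad <- function(pred, target, smooth = 1e-5) {
  p4 <- .asBatch4d(pred); t4 <- .asBatch4d(target)
  stopifnot(identical(dim(p4), dim(t4)))
  md <- .maskedDice(p4, t4, smooth)
  C <- dim(p4)[3]
  nPresent <- sum(md$present)
  g <- array(0, dim(p4))
  for (c in seq_len(C)) {
    if (!md$present[c]) next
    tc <- t4[, , c, , drop = FALSE]
    g[, , c, ] <- (md$A[c] / md$B[c]^2 - 2 * tc / md$B[c]) / nPresent
  }
  array(g, dim(pred))
}

.asBatch4d <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("expected a (x, y, C[, N]) array")
  x
}

tpMaskedDiceLoss <- function(tp, pid, target, smooth = 1e-5) {
  p <- tpVal(tp, pid)
  loss <- maskedDiceLoss(p, target, smooth)
  tpPush(tp, loss, pid, function(dy) {
    list(dy * maskedDiceGrad(p, target, smooth))
  })
}
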