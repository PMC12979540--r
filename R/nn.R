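## A small reference executor for LayerGraph networks: forward pass,
## reverse-mode gradients and an AdamW step.  Feature maps are R arrays
## with dim c(H, W, C, B); flattened activations are matrices (features x B).
## Convolutions use an im2col lowering so the heavy lifting is BLAS matrix
## multiplication; everything is exact, dependency-free and sized for the
## desk-scale models this package trains (tens of channels, <= 64x64 input).

.pad_hw <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, dim = c(d[1] + 2L * p, d[2] + 2L * p, d[3], d[4]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  out
}

## lower padded input (Hp,Wp,C,B) to patches (k*k*C, Ho*Wo*B)
.im2col <- function(xp, k, s, ho, wo) {
  d <- dim(xp); C <- d[3]; B <- d[4]
  cols <- array(0, dim = c(k * k * C, ho * wo * B))
  hi <- (seq_len(ho) - 1L) * s
  wi <- (seq_len(wo) - 1L) * s
  r <- 0L
  for (kj in seq_len(k)) for (ki in seq_len(k)) {
    ## rows ordered ki fastest then kj, per channel blocks afterwards
    slab <- xp[hi + ki, wi + kj, , , drop = FALSE]     # ho x wo x C x B
    slab <- aperm(slab, c(3L, 1L, 2L, 4L))             # C x ho x wo x B
    cols[r + ((seq_len(C) - 1L) * k * k) + 1L, ] <- matrix(slab, nrow = C)
    r <- r + 1L
  }
  cols
}

.col2im <- function(dcols, k, s, ho, wo, hp, wp, C, B) {
  dxp <- array(0, dim = c(hp, wp, C, B))
  hi <- (seq_len(ho) - 1L) * s
  wi <- (seq_len(wo) - 1L) * s
  r <- 0L
  for (kj in seq_len(k)) for (ki in seq_len(k)) {
    blk <- matrix(dcols[r + ((seq_len(C) - 1L) * k * k) + 1L, ], nrow = C)
    blk <- aperm(array(blk, dim = c(C, ho, wo, B)), c(2L, 3L, 1L, 4L))
    dxp[hi + ki, wi + kj, , ] <- dxp[hi + ki, wi + kj, , , drop = FALSE] + blk
    r <- r + 1L
  }
  dxp
}

.conv_forward <- function(x, W, b, k, s, p, groups) {
  d <- dim(x); B <- d[4]; C <- d[3]
  ho <- .conv_out_side(d[1], k, s, p); wo <- ho
  xp <- .pad_hw(x, p)
  cing <- C %/% groups; cout <- dim(W)[4]
  if (groups == 1L) {
    cols <- .im2col(xp, k, s, ho, wo)
    Wm <- matrix(W, k * k * cing, cout)
    out <- crossprod(Wm, cols)                         # cout x (ho wo B)
  } else {                                             # depthwise: groups == C
    cols <- .im2col(xp, k, s, ho, wo)                  # (k k C) x (ho wo B)
    out <- matrix(0, cout, ho * wo * B)
    Wm <- matrix(W, k * k, cout)                       # cing == 1
    for (c0 in seq_len(C))
      out[c0, ] <- crossprod(Wm[, c0, drop = FALSE],
                             cols[(c0 - 1L) * k * k + seq_len(k * k), , drop = FALSE])
  }
  if (!is.null(b)) out <- out + b
  y <- aperm(array(out, dim = c(cout, ho, wo, B)), c(2L, 3L, 1L, 4L))
  list(y = y, cache = list(cols = cols, dimx = d, ho = ho, wo = wo,
                           hp = dim(xp)[1], wp = dim(xp)[2]))
}

.conv_backward <- function(dy, W, k, s, p, groups, cache, need_dx = TRUE) {
  d <- cache$dimx; B <- d[4]; C <- d[3]
  ho <- cache$ho; wo <- cache$wo
  cout <- dim(W)[4]; cing <- C %/% groups
  dm <- matrix(aperm(dy, c(3L, 1L, 2L, 4L)), cout, ho * wo * B)
  db <- rowSums(dm)
  if (groups == 1L) {
    Wm <- matrix(W, k * k * cing, cout)
    dW <- array(tcrossprod(cache$cols, dm), dim = dim(W))
    dx <- NULL
    if (need_dx) {
      dcols <- Wm %*% dm
      dxp <- .col2im(dcols, k, s, ho, wo, cache$hp, cache$wp, C, B)
      dx <- if (p > 0L) dxp[p + seq_len(d[1]), p + seq_len(d[2]), , , drop = FALSE] else dxp
    }
  } else {
    Wm <- matrix(W, k * k, cout)
    dWm <- matrix(0, k * k, cout)
    dcols <- matrix(0, k * k * C, ho * wo * B)
    for (c0 in seq_len(C)) {
      rows <- (c0 - 1L) * k * k + seq_len(k * k)
      dWm[, c0] <- cache$cols[rows, , drop = FALSE] %*% dm[c0, ]
      dcols[rows, ] <- Wm[, c0] %o% dm[c0, ]
    }
    dW <- array(dWm, dim = dim(W))
    dx <- NULL
    if (need_dx) {
      dxp <- .col2im(dcols, k, s, ho, wo, cache$hp, cache$wp, C, B)
      dx <- if (p > 0L) dxp[p + seq_len(d[1]), p + seq_len(d[2]), , , drop = FALSE] else dxp
    }
  }
  list(dx = dx, dW = dW, db = db)
}

.bn_forward <- function(x, w, training, eps = 1e-5, momentum = 0.1) {
  ismat <- is.matrix(x)
  if (ismat) { C <- nrow(x); xm <- x } else {
    d <- dim(x); C <- d[3]
    xm <- matrix(aperm(x, c(3L, 1L, 2L, 4L)), C)
  }
  n <- ncol(xm)
  if (training) {
    mu <- rowMeans(xm)
    v <- rowMeans((xm - mu)^2)
    w$mean <- (1 - momentum) * w$mean + momentum * mu
    w$var <- (1 - momentum) * w$var + momentum * v * n / max(1, n - 1)
  } else { mu <- w$mean; v <- w$var }
  inv <- 1 / sqrt(v + eps)
  xhat <- (xm - mu) * inv
  ym <- xhat * w$gamma + w$beta
  y <- if (ismat) ym else aperm(array(ym, dim = c(C, dim(x)[1], dim(x)[2], dim(x)[4])),
                                c(2L, 3L, 1L, 4L))
  list(y = y, w = w, cache = list(xhat = xhat, inv = inv, ismat = ismat,
                                  dims = if (ismat) dim(x) else dim(x)))
}

.bn_backward <- function(dy, w, cache) {
  if (cache$ismat) dym <- dy else {
    d <- dim(dy); dym <- matrix(aperm(dy, c(3L, 1L, 2L, 4L)), d[3])
  }
  xhat <- cache$xhat; n <- ncol(dym)
  dgamma <- rowSums(dym * xhat)
  dbeta <- rowSums(dym)
  dxhat <- dym * w$gamma
  dxm <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * cache$inv
  dx <- if (cache$ismat) dxm else {
    d <- cache$dims
    aperm(array(dxm, dim = c(d[3], d[1], d[2], d[4])), c(2L, 3L, 1L, 4L))
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

.maxpool_forward <- function(x, k, s, p) {
  d <- dim(x)
  ho <- .conv_out_side(d[1], k, s, p); wo <- ho
  xp <- .pad_hw(x, p)
  CB <- d[3] * d[4]
  xp2 <- array(xp, dim = c(dim(xp)[1], dim(xp)[2], CB, 1L))
  cols <- .im2col(xp2, k, s, ho, wo)          # (k k CB) x (ho wo)
  cols <- array(cols, dim = c(k * k, CB, ho * wo))
  am <- apply(cols, c(2L, 3L), which.max)
  mx <- apply(cols, c(2L, 3L), max)
  y <- array(0, dim = c(ho, wo, d[3], d[4]))
  y[] <- aperm(array(mx, dim = c(CB, ho, wo)), c(2L, 3L, 1L))
  list(y = y, cache = list(am = am, dimx = d, ho = ho, wo = wo,
                           hp = dim(xp)[1], wp = dim(xp)[2]))
}

.maxpool_backward <- function(dy, k, s, p, cache) {
  d <- cache$dimx; ho <- cache$ho; wo <- cache$wo
  CB <- d[3] * d[4]
  dxp <- array(0, dim = c(cache$hp, cache$wp, CB))
  dym <- matrix(aperm(dy, c(3L, 4L, 1L, 2L)), CB)   # CB x (ho wo)
  am <- cache$am                                     # CB x (ho wo)
  for (o in seq_len(ho * wo)) {
    oi <- (o - 1L) %% ho + 1L; oj <- (o - 1L) %/% ho + 1L
    ks <- am[, o]
    ki <- (ks - 1L) %% k + 1L; kj <- (ks - 1L) %/% k + 1L
    hi <- (oi - 1L) * s + ki; wi <- (oj - 1L) * s + kj
    idx <- cbind(hi, wi, seq_len(CB))
    dxp[idx] <- dxp[idx] + dym[, o]
  }
  dxp <- array(dxp, dim = c(cache$hp, cache$wp, d[3], d[4]))
  if (p > 0L) dxp[p + seq_len(d[1]), p + seq_len(d[2]), , , drop = FALSE] else dxp
}

.adapt_bounds <- function(h, p) {
  lo <- floor((seq_len(p) - 1L) * h / p) + 1L
  hi <- ceiling(seq_len(p) * h / p)
  cbind(lo, hi)
}

.avgpool_forward <- function(x, p_out) {
  d <- dim(x)
  bh <- .adapt_bounds(d[1], p_out); bw <- .adapt_bounds(d[2], p_out)
  y <- array(0, dim = c(p_out, p_out, d[3], d[4]))
  for (i in seq_len(p_out)) for (j in seq_len(p_out)) {
    y[i, j, , ] <- apply(x[bh[i, 1]:bh[i, 2], bw[j, 1]:bw[j, 2], , , drop = FALSE],
                         c(3L, 4L), mean)
  }
  list(y = y, cache = list(dimx = d, bh = bh, bw = bw))
}

.avgpool_backward <- function(dy, cache) {
  d <- cache$dimx; bh <- cache$bh; bw <- cache$bw
  dx <- array(0, dim = d)
  p_out <- nrow(bh)
  for (i in seq_len(p_out)) for (j in seq_len(p_out)) {
    nh <- bh[i, 2] - bh[i, 1] + 1L; nw <- bw[j, 2] - bw[j, 1] + 1L
    g <- dy[i, j, , ] / (nh * nw)
    add <- aperm(array(g, dim = c(d[3], d[4], nh, nw)), c(3L, 4L, 1L, 2L))
    dx[bh[i, 1]:bh[i, 2], bw[j, 1]:bw[j, 2], , ] <-
      dx[bh[i, 1]:bh[i, 2], bw[j, 1]:bw[j, 2], , , drop = FALSE] + add
  }
  dx
}

#' Forward pass through a LayerGraph network
#'
#' Runs a batch of images through the network.  Used by training,
#' evaluation and the structural equivalence tests.
#'
#' @param g a \code{LayerGraph}.
#' @param weights weight list (see \code{\link{initWeights}}).
#' @param x input array \code{(H, W, 3, batch)} with values in [0, 1].
#' @param training logical; batchnorm uses batch statistics and updates
#'   running statistics when TRUE.
#' @param keep_cache retain intermediate values for a subsequent backward
#'   pass (internal).
#' @return list with \code{logits} (classes x batch matrix), updated
#'   \code{weights} (running stats), and \code{acts}/\code{caches} when
#'   \code{keep_cache}.
#' @export
forwardPass <- function(g, weights, x, training = FALSE, keep_cache = FALSE) {
  ly <- g@layers
  pred <- .split_preds(ly$predecessors)
  acts <- list(); caches <- list()
  for (i in seq_len(nrow(ly))) {
    id <- ly$id[i]; k <- ly$kind[i]
    inx <- lapply(pred[[i]], function(p) acts[[p]])
    a <- if (length(inx)) inx[[1L]] else NULL
    res <- switch(k,
      input = list(y = x),
      conv = .conv_forward(a, weights[[id]]$W, weights[[id]]$b,
                           ly$kernel[i], ly$stride[i], ly$padding[i],
                           ly$groups[i]),
      batchnorm = {
        r <- .bn_forward(a, weights[[id]], training)
        weights[[id]] <- r$w
        r
      },
      relu = list(y = pmax(a, 0), cache = a),
      sigmoid = list(y = 1 / (1 + exp(-a)), cache = NULL),
      maxpool = .maxpool_forward(a, ly$kernel[i], ly$stride[i], ly$padding[i]),
      adaptivepool = .avgpool_forward(a, ly$kernel[i]),
      globalavgpool = .avgpool_forward(a, 1L),
      flatten = {
        d <- dim(a)
        list(y = matrix(a, d[1] * d[2] * d[3], d[4]), cache = d)
      },
      dense = {
        xm <- if (is.matrix(a)) a else matrix(a, ly$in_channels[i], dim(a)[4])
        y <- crossprod(weights[[id]]$W, xm)
        if (!is.null(weights[[id]]$b)) y <- y + weights[[id]]$b
        list(y = y, cache = xm)
      },
      add = list(y = Reduce(`+`, inx)),
      multiply = {
        ## feature map x channel gate (matrix C x B from the SE branch)
        mats <- vapply(inx, is.matrix, TRUE)
        if (any(mats) && !all(mats)) {
          fm <- inx[[which(!mats)[1L]]]; gt <- inx[[which(mats)[1L]]]
          d <- dim(fm)
          gate <- aperm(array(gt, dim = c(d[3], d[4], d[1], d[2])), c(3L, 4L, 1L, 2L))
          list(y = fm * gate, cache = list(fm = fm, gt = gt, mats = mats))
        } else list(y = Reduce(`*`, inx), cache = list(inx = inx, mats = mats))
      },
      concat = {
        if (is.matrix(inx[[1L]])) list(y = do.call(rbind, inx),
                                       cache = vapply(inx, nrow, 1L))
        else {
          ds <- vapply(inx, function(z) dim(z)[3], 1L)
          d1 <- dim(inx[[1L]])
          y <- array(0, dim = c(d1[1], d1[2], sum(ds), d1[4]))
          at <- 0L
          for (z in inx) { y[, , at + seq_len(dim(z)[3]), ] <- z; at <- at + dim(z)[3] }
          list(y = y, cache = ds)
        }
      },
      output = list(y = a),
      stop(sprintf("unhandled kind '%s'", k)))
    acts[[id]] <- res$y
    if (keep_cache) caches[[id]] <- res$cache
    if (!keep_cache && k != "input") {
      ## free feature maps no longer needed? kept simple: retain all
    }
  }
  out <- list(logits = acts[[g@exit]], weights = weights)
  if (keep_cache) { out$acts <- acts; out$caches <- caches }
  out
}

#' Softmax cross-entropy loss and gradient
#'
#' @param logits classes x batch matrix.
#' @param labels integer class indices (1-based), length batch.
#' @return list(loss, dlogits, probs).
#' @export
softmaxCrossEntropy <- function(logits, labels) {
  B <- ncol(logits)
  z <- logits - apply(logits, 2L, max)[col(logits)]
  ez <- exp(z)
  p <- ez / colSums(ez)[col(ez)]
  idx <- cbind(labels, seq_len(B))
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dp <- p
  dp[idx] <- dp[idx] - 1
  list(loss = loss, dlogits = dp / B, probs = p)
}

#' Backward pass: gradients of the loss w.r.t. all weights
#'
#' @param g a \code{LayerGraph}.
#' @param weights weight list.
#' @param fw result of \code{forwardPass(..., keep_cache = TRUE)}.
#' @param dlogits gradient at the output (classes x batch).
#' @return named list of per-layer gradients mirroring the weight list.
#' @export
backwardPass <- function(g, weights, fw, dlogits) {
  ly <- g@layers
  pred <- .split_preds(ly$predecessors)
  grads <- list()
  dacts <- list()
  dacts[[g@exit]] <- dlogits
  addg <- function(id, v) {
    dacts[[id]] <<- if (is.null(dacts[[id]])) v else dacts[[id]] + v
  }
  for (i in rev(seq_len(nrow(ly)))) {
    id <- ly$id[i]; k <- ly$kind[i]
    dy <- dacts[[id]]
    if (is.null(dy) || k == "input") next
    ps <- pred[[i]]
    ch <- fw$caches[[id]]
    need_dx <- !(ly$kind[match(ps[1L], ly$id)] == "input")
    switch(k,
      conv = {
        r <- .conv_backward(dy, weights[[id]]$W, ly$kernel[i], ly$stride[i],
                            ly$padding[i], ly$groups[i], ch, need_dx)
        grads[[id]] <- list(W = r$dW,
                            b = if (!is.null(weights[[id]]$b)) r$db else NULL)
        if (need_dx) addg(ps[1L], r$dx)
      },
      batchnorm = {
        r <- .bn_backward(dy, weights[[id]], ch)
        grads[[id]] <- list(gamma = r$dgamma, beta = r$dbeta)
        addg(ps[1L], r$dx)
      },
      relu = addg(ps[1L], dy * (ch > 0)),
      sigmoid = {
        s <- fw$acts[[id]]
        addg(ps[1L], dy * s * (1 - s))
      },
      maxpool = addg(ps[1L], .maxpool_backward(dy, ly$kernel[i], ly$stride[i],
                                               ly$padding[i], ch)),
      adaptivepool = addg(ps[1L], .avgpool_backward(dy, ch)),
      globalavgpool = addg(ps[1L], .avgpool_backward(dy, ch)),
      flatten = addg(ps[1L], array(dy, dim = ch)),
      dense = {
        grads[[id]] <- list(W = tcrossprod(ch, dy),
                            b = if (!is.null(weights[[id]]$b)) rowSums(dy) else NULL)
        wx <- weights[[id]]$W %*% dy
        prev <- fw$acts[[ps[1L]]]
        addg(ps[1L], if (is.matrix(prev)) wx else array(wx, dim = dim(prev)))
      },
      add = for (p0 in ps) addg(p0, dy),
      multiply = {
        if (any(ch$mats) && !all(ch$mats)) {
          d <- dim(ch$fm)
          gate <- aperm(array(ch$gt, dim = c(d[3], d[4], d[1], d[2])),
                        c(3L, 4L, 1L, 2L))
          addg(ps[which(!ch$mats)[1L]], dy * gate)
          dg <- apply(dy * ch$fm, c(3L, 4L), sum)
          addg(ps[which(ch$mats)[1L]], dg)
        } else {
          for (j in seq_along(ps)) {
            oth <- Reduce(`*`, ch$inx[-j], 1)
            addg(ps[j], dy * oth)
          }
        }
      },
      concat = {
        if (is.matrix(dy)) {
          at <- 0L
          for (j in seq_along(ps)) {
            addg(ps[j], dy[at + seq_len(ch[j]), , drop = FALSE]); at <- at + ch[j]
          }
        } else {
          at <- 0L
          for (j in seq_along(ps)) {
            addg(ps[j], dy[, , at + seq_len(ch[j]), , drop = FALSE]); at <- at + ch[j]
          }
        }
      },
      output = addg(ps[1L], dy))
  }
  grads
}

#' One AdamW update
#'
#' Decoupled weight decay: \code{p <- p - lr * (mhat/(sqrt(vhat)+eps) +
#' wd * p)}.  Weight decay is applied to convolution and dense weight
#' matrices only (not biases or batchnorm parameters), the usual
#' convention.
#'
#' @param weights weight list.
#' @param grads gradient list from \code{\link{backwardPass}}.
#' @param state optimizer state (NULL on first call).
#' @param lr learning rate.
#' @param wd weight decay.
#' @param beta1,beta2,eps Adam constants.
#' @return list(weights, state).
#' @export
adamwStep <- function(weights, grads, state = NULL, lr = 1e-4, wd = 5e-2,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.null(state)) state <- list(t = 0L, m = list(), v = list())
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (id in names(grads)) {
    for (nm in names(grads[[id]])) {
      gr <- grads[[id]][[nm]]
      if (is.null(gr)) next
      key <- paste0(id, ".", nm)
      m <- state$m[[key]]; v <- state$v[[key]]
      if (is.null(m)) { m <- gr * 0; v <- gr * 0 }
      m <- beta1 * m + (1 - beta1) * gr
      v <- beta2 * v + (1 - beta2) * gr^2
      state$m[[key]] <- m; state$v[[key]] <- v
      upd <- (m / bc1) / (sqrt(v / bc2) + eps)
      decay <- if (nm == "W") wd * weights[[id]][[nm]] else 0
      weights[[id]][[nm]] <- weights[[id]][[nm]] - lr * (upd + decay)
    }
  }
  list(weights = weights, state = state)
}
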