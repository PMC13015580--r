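# Minimal reverse-mode automatic differentiation on dense matrices.
#
# The model code builds a tape of eagerly-evaluated ops; adBackward() walks it
# in reverse accumulating vector-Jacobian products. Only the ops the two
# architectures need are implemented. Node handles are integer indices into
# the tape. Gradient correctness is pinned by finite-difference checks in the
# test suite.

adTape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$vals <- vector("list", 256L)
  tp$parents <- vector("list", 256L)
  tp$vjps <- vector("list", 256L)
  tp$n <- 0L
  tp
}

adPush <- function(tp, value, parents = NULL, vjp = NULL) {
  n <- tp$n + 1L
  if (n > length(tp$vals)) {
    length(tp$vals) <- 2L * n
    length(tp$parents) <- 2L * n
    length(tp$vjps) <- 2L * n
  }
  tp$vals[[n]] <- value
  tp$parents[[n]] <- parents
  tp$vjps[[n]] <- vjp
  tp$n <- n
  n
}

adConst <- function(tp, x) adPush(tp, x)
adVal <- function(tp, i) tp$vals[[i]]

adBackward <- function(tp, root) {
  grads <- vector("list", tp$n)
  rv <- tp$vals[[root]]
  grads[[root]] <- array(1, dim = if (is.matrix(rv)) dim(rv) else c(1L, 1L))
  for (i in root:1L) {
    g <- grads[[i]]
    if (is.null(g)) next
    ps <- tp$parents[[i]]
    if (is.null(ps)) next
    pg <- tp$vjps[[i]](g)
    for (k in seq_along(ps)) {
      gk <- pg[[k]]
      if (is.null(gk)) next
      p <- ps[k]
      grads[[p]] <- if (is.null(grads[[p]])) gk else grads[[p]] + gk
    }
  }
  grads
}

# ---- ops -------------------------------------------------------------------

adMatmul <- function(tp, a, b) {
  force(a); force(b)
  A <- tp$vals[[a]]; B <- tp$vals[[b]]
  adPush(tp, A %*% B, c(a, b), function(g) {
    list(tcrossprod(g, B), crossprod(A, g))
  })
}

adAdd <- function(tp, a, b) {
  force(a); force(b)
  adPush(tp, tp$vals[[a]] + tp$vals[[b]], c(a, b), function(g) list(g, g))
}

# add a length-k bias vector to every row of an n x k matrix
adAddBias <- function(tp, a, bias) {
  force(a); force(bias)
  A <- tp$vals[[a]]; bv <- as.numeric(tp$vals[[bias]])
  adPush(tp, A + rep(bv, each = nrow(A)), c(a, bias), function(g) {
    list(g, matrix(colSums(g), nrow = 1L))
  })
}

adMul <- function(tp, a, b) {
  force(a); force(b)
  A <- tp$vals[[a]]; B <- tp$vals[[b]]
  adPush(tp, A * B, c(a, b), function(g) list(g * B, g * A))
}

adScale <- function(tp, a, s) {
  force(a)
  adPush(tp, tp$vals[[a]] * s, a, function(g) list(g * s))
}

adRelu <- function(tp, a) {
  force(a)
  A <- tp$vals[[a]]
  mask <- A > 0
  adPush(tp, A * mask, a, function(g) list(g * mask))
}

adLeakyRelu <- function(tp, a, alpha = 0.2) {
  force(a)
  A <- tp$vals[[a]]
  slope <- ifelse(A > 0, 1, alpha)
  adPush(tp, A * slope, a, function(g) list(g * slope))
}

# segment sum via a fixed-degree index matrix: inIdx[s, d] is the d-th row of
# A belonging to segment s (0 = none). Nodes in these graphs have bounded
# degree, so a handful of vectorized gathers replaces rowsum().
segsumIdx <- function(A, inIdx) {
  val <- matrix(0, nrow(inIdx), ncol(A))
  for (d in seq_len(ncol(inIdx))) {
    nz <- inIdx[, d] != 0L
    val[nz, ] <- val[nz, ] + A[inIdx[nz, d], , drop = FALSE]
  }
  val
}

# rows of A selected by idx; idx == 0L yields a zero row (used for padding).
# `scatterIdx` is an optional fixed-degree index matrix (nrow(A) x maxdeg)
# listing, per row of A, which output rows select it (for the backward
# scatter-add).
adGather <- function(tp, a, idx, scatterIdx = NULL) {
  force(a)
  A <- tp$vals[[a]]
  if (any(idx == 0L)) {
    val <- matrix(0, length(idx), ncol(A))
    nz <- idx != 0L
    val[nz, ] <- A[idx[nz], , drop = FALSE]
  } else {
    val <- A[idx, , drop = FALSE]
  }
  adPush(tp, val, a, function(g) {
    if (!is.null(scatterIdx)) return(list(segsumIdx(g, scatterIdx)))
    out <- matrix(0, nrow(A), ncol(A))
    nz <- which(idx != 0L)
    rs <- rowsum(g[nz, , drop = FALSE], idx[nz])
    out[as.integer(rownames(rs)), ] <- rs
    list(out)
  })
}

# sum rows of A within segments 1..nseg; `inIdx` is an optional fixed-degree
# index matrix (nseg x maxdeg) of row ids per segment
adSegSum <- function(tp, a, seg, nseg, inIdx = NULL) {
  force(a)
  A <- tp$vals[[a]]
  if (!is.null(inIdx)) {
    val <- segsumIdx(A, inIdx)
  } else {
    val <- matrix(0, nseg, ncol(A))
    rs <- rowsum(A, seg)
    val[as.integer(rownames(rs)), ] <- rs
  }
  adPush(tp, val, a, function(g) list(g[seg, , drop = FALSE]))
}

# scale row i of A by w[i] (w constant)
adRowScale <- function(tp, a, w) {
  force(a)
  A <- tp$vals[[a]]
  adPush(tp, A * w, a, function(g) list(g * w))
}

adSegMean <- function(tp, a, seg, nseg) {
  cnt <- tabulate(seg, nbins = nseg)
  s <- adSegSum(tp, a, seg, nseg)
  adRowScale(tp, s, 1 / pmax(cnt, 1L))
}

# columnwise softmax within segments (attention normalization over incoming
# edges of each destination node)
adSegSoftmax <- function(tp, a, seg, nseg, inIdx = NULL) {
  force(a)
  A <- tp$vals[[a]]
  A <- A - max(A)  # global shift for stability; exact softmax unchanged
  ex <- exp(A)
  if (!is.null(inIdx)) {
    den <- segsumIdx(ex, inIdx)
    den[den == 0] <- 1
  } else {
    den <- matrix(1, nseg, ncol(A))
    rs <- rowsum(ex, seg)
    den[as.integer(rownames(rs)), ] <- rs
  }
  S <- ex / den[seg, , drop = FALSE]
  adPush(tp, S, a, function(g) {
    sg <- S * g
    if (!is.null(inIdx)) {
      tot <- segsumIdx(sg, inIdx)
    } else {
      tot <- matrix(0, nseg, ncol(S))
      rs2 <- rowsum(sg, seg)
      tot[as.integer(rownames(rs2)), ] <- rs2
    }
    list(sg - S * tot[seg, , drop = FALSE])
  })
}

# per-group per-column max with argmax routing (masked max-pooling);
# groups with no rows yield 0
adSegMax <- function(tp, a, seg, nseg) {
  force(a)
  A <- tp$vals[[a]]
  k <- ncol(A)
  val <- matrix(0, nseg, k)
  argrow <- matrix(0L, nseg, k)
  ix <- split(seq_len(nrow(A)), factor(seg, levels = seq_len(nseg)))
  for (gidx in seq_len(nseg)) {
    rows <- ix[[gidx]]
    if (length(rows) == 0L) next
    sub <- A[rows, , drop = FALSE]
    j <- max.col(t(sub), ties.method = "first")
    val[gidx, ] <- sub[cbind(j, seq_len(k))]
    argrow[gidx, ] <- rows[j]
  }
  adPush(tp, val, a, function(g) {
    out <- matrix(0, nrow(A), k)
    for (gidx in seq_len(nseg)) {
      rows <- argrow[gidx, ]
      if (rows[1L] == 0L) next
      out[cbind(rows, seq_len(k))] <- out[cbind(rows, seq_len(k))] + g[gidx, ]
    }
    list(out)
  })
}

# per-head dot product: X is n x (H*F), a is a 1 x (H*F) parameter; result
# n x H with out[, h] = rowSums(X[, block_h] * a[block_h])
adHeadDot <- function(tp, x, a, H) {
  force(x); force(a)
  X <- tp$vals[[x]]; av <- as.numeric(tp$vals[[a]])
  F <- ncol(X) %/% H
  Xa <- X * rep(av, each = nrow(X))
  val <- matrix(0, nrow(X), H)
  for (h in seq_len(H)) {
    val[, h] <- rowSums(Xa[, ((h - 1L) * F + 1L):(h * F), drop = FALSE])
  }
  adPush(tp, val, c(x, a), function(g) {
    gX <- matrix(0, nrow(X), ncol(X))
    ga <- numeric(ncol(X))
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * F + 1L):(h * F)
      gX[, cols] <- g[, h] * rep(av[cols], each = nrow(X))
      ga[cols] <- colSums(X[, cols, drop = FALSE] * g[, h])
    }
    list(gX, matrix(ga, nrow = 1L))
  })
}

# multiply each head block of M (n x H*F) by the head coefficient a (n x H)
adHeadMul <- function(tp, m, a, H) {
  force(m); force(a)
  M <- tp$vals[[m]]; A <- tp$vals[[a]]
  F <- ncol(M) %/% H
  expand <- A[, rep(seq_len(H), each = F), drop = FALSE]
  adPush(tp, M * expand, c(m, a), function(g) {
    gA <- matrix(0, nrow(A), H)
    gm <- g * expand
    gma <- g * M
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * F + 1L):(h * F)
      gA[, h] <- rowSums(gma[, cols, drop = FALSE])
    }
    list(gm, gA)
  })
}

adColBind <- function(tp, ...) {
  ids <- c(...)
  vals <- lapply(ids, function(i) tp$vals[[i]])
  widths <- vapply(vals, ncol, 1L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  adPush(tp, do.call(cbind, vals), ids, function(g) {
    lapply(seq_along(ids), function(k) g[, starts[k]:ends[k], drop = FALSE])
  })
}

adDropout <- function(tp, a, p, training) {
  force(a)
  if (!training || p <= 0) return(a)
  A <- tp$vals[[a]]
  mask <- (matrix(stats::runif(length(A)), nrow(A)) >= p) / (1 - p)
  adPush(tp, A * mask, a, function(g) list(g * mask))
}

# batch normalization over rows; bnState is an environment holding running
# mean/var (updated as a side effect in training mode)
adBatchNorm <- function(tp, a, gamma, beta, bnState, key, training,
                        momentum = 0.1, eps = 1e-5) {
  force(a); force(gamma); force(beta)
  A <- tp$vals[[a]]
  gv <- as.numeric(tp$vals[[gamma]]); bv <- as.numeric(tp$vals[[beta]])
  if (training) {
    n <- nrow(A)
    mu <- colMeans(A)
    xc <- A - rep(mu, each = n)
    v <- colSums(xc^2) / n
    if (is.null(bnState[[key]])) {
      bnState[[key]] <- list(mean = mu, var = v * n / max(n - 1L, 1L))
    } else {
      st <- bnState[[key]]
      bnState[[key]] <- list(
        mean = (1 - momentum) * st$mean + momentum * mu,
        var = (1 - momentum) * st$var + momentum * v * n / max(n - 1L, 1L))
    }
    inv <- 1 / sqrt(v + eps)
    xhat <- xc * rep(inv, each = n)
    val <- xhat * rep(gv, each = n) + rep(bv, each = n)
    adPush(tp, val, c(a, gamma, beta), function(g) {
      dgamma <- colSums(g * xhat)
      dbeta <- colSums(g)
      gg <- g * rep(gv, each = n)
      t1 <- gg - rep(colMeans(gg), each = n)
      t2 <- xhat * rep(colMeans(gg * xhat), each = n)
      dx <- (t1 - t2) * rep(inv, each = n)
      list(dx, matrix(dgamma, nrow = 1L), matrix(dbeta, nrow = 1L))
    })
  } else {
    st <- bnState[[key]]
    if (is.null(st)) st <- list(mean = numeric(ncol(A)), var = rep(1, ncol(A)))
    n <- nrow(A)
    inv <- 1 / sqrt(st$var + eps)
    scale <- gv * inv
    xhat <- (A - rep(st$mean, each = n)) * rep(inv, each = n)
    val <- (A - rep(st$mean, each = n)) * rep(scale, each = n) +
      rep(bv, each = n)
    adPush(tp, val, c(a, gamma, beta), function(g) {
      list(g * rep(scale, each = nrow(g)),
           matrix(colSums(g * xhat), nrow = 1L),
           matrix(colSums(g), nrow = 1L))
    })
  }
}

# numerically stable mean binary cross-entropy on logits z (n x 1)
adBCEWithLogits <- function(tp, z, y) {
  force(z)
  Z <- as.numeric(tp$vals[[z]])
  n <- length(Z)
  # log(1 + exp(z)) - y * z, computed stably
  sp <- ifelse(Z > 0, Z + log1p(exp(-Z)), log1p(exp(Z)))
  val <- matrix(mean(sp - y * Z), 1L, 1L)
  p <- 1 / (1 + exp(-Z))
  adPush(tp, val, z, function(g) {
    list(matrix((p - y) / n * as.numeric(g), ncol = 1L))
  })
}
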