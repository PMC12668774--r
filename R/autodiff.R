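# Minimal reverse-mode automatic differentiation used by the enhancement
# network.  Feature maps are (h, w, C) arrays, rank-one vector stacks are
# (n, C) matrices.  Each op appends a node to a tape; ad_backward() walks the
# tape in reverse, calling each node's backfn with the accumulated output
# gradient and scattering the returned parent gradients.
#
# This is deliberately small: only the ops the generator/discriminator need,
# with gradients hand-derived per op and verified by finite differences in
# the test suite.

ad_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 256L)
  e$k <- 0L
  e
}

ad_node <- function(tape, value, parents = list(), backfn = NULL) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$parents <- parents
  n$backfn <- backfn
  tape$k <- tape$k + 1L
  if (tape$k > length(tape$nodes)) tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[tape$k]] <- n
  n
}

ad_const <- function(tape, value) ad_node(tape, value)
ad_param <- function(tape, value) ad_node(tape, value)

ad_backward <- function(tape, loss) {
  loss$grad <- 1
  for (i in seq(tape$k, 1L)) {
    n <- tape$nodes[[i]]
    if (is.null(n$grad) || is.null(n$backfn)) next
    gs <- n$backfn(n$grad)
    for (j in seq_along(n$parents)) {
      g <- gs[[j]]
      if (is.null(g)) next
      p <- n$parents[[j]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(NULL)
}

ad_add <- function(tape, x, y) {
  ad_node(tape, x$value + y$value, list(x, y), function(g) list(g, g))
}

ad_scale <- function(tape, x, k) {
  ad_node(tape, x$value * k, list(x), function(g) list(g * k))
}

ad_relu <- function(tape, x) {
  mask <- x$value > 0
  ad_node(tape, x$value * mask, list(x), function(g) list(g * mask))
}

ad_lrelu <- function(tape, x, alpha = 0.2) {
  mask <- x$value > 0
  fac <- ifelse(mask, 1, alpha)
  ad_node(tape, x$value * fac, list(x), function(g) list(g * fac))
}

ad_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$value))
  ad_node(tape, s, list(x), function(g) list(g * s * (1 - s)))
}

# softplus clamped above at `cap`: keeps outputs nonnegative without hard
# saturation at 1 (cap defaults to 1.2 in the generator).
ad_softplus_clamp <- function(tape, x, cap = 1.2) {
  sp <- ifelse(x$value > 30, x$value, log1p(exp(pmin(x$value, 30))))
  out <- pmin(sp, cap)
  sig <- 1 / (1 + exp(-x$value))
  mask <- sp < cap
  ad_node(tape, out, list(x), function(g) list(g * sig * mask))
}

# --- convolutions ----------------------------------------------------------

# 3x3 zero-padded im2col as a single cached gather: x (h, w, Cin) ->
# (h*w, 9*Cin); column blocks are ordered by (dj, di) offset, each Cin wide.
# Index maps are memoized per (h, w, cin) since tile shapes repeat thousands
# of times during training.
.im2col_cache <- new.env(parent = emptyenv())

im2col_idx <- function(h, w, cin) {
  key <- paste(h, w, cin, sep = "_")
  got <- .im2col_cache[[key]]
  if (!is.null(got)) return(got)
  hp <- h + 2L; wp <- w + 2L
  # flat index into the padded (hp, wp, cin) array for each X2 entry
  idx <- integer(h * w * 9L * cin)
  pos <- 1L
  for (dj in 0:2) for (di in 0:2) for (cc in seq_len(cin)) {
    rows <- di + seq_len(h)
    cols <- dj + seq_len(w)
    block <- outer(rows, (cols - 1L) * hp, "+") + (cc - 1L) * hp * wp
    idx[pos:(pos + h * w - 1L)] <- as.integer(block)
    pos <- pos + h * w
  }
  out <- list(idx = idx, hp = hp, wp = wp)
  .im2col_cache[[key]] <- out
  out
}

im2col3 <- function(x) {
  d <- dim(x)
  h <- d[1]; w <- d[2]; cin <- d[3]
  ci <- im2col_idx(h, w, cin)
  xp <- numeric(ci$hp * ci$wp * cin)
  dim(xp) <- c(ci$hp, ci$wp, cin)
  xp[1L + seq_len(h), 1L + seq_len(w), ] <- x
  X2 <- xp[ci$idx]
  dim(X2) <- c(h * w, 9L * cin)
  X2
}

col2im3 <- function(dX2, h, w, cin) {
  ci <- im2col_idx(h, w, cin)
  gxp <- numeric(ci$hp * ci$wp * cin)
  nblk <- h * w * cin
  for (t in 1:9) {
    sel <- ci$idx[((t - 1L) * nblk + 1L):(t * nblk)]
    gxp[sel] <- gxp[sel] + dX2[, ((t - 1L) * cin + 1L):(t * cin)]
  }
  dim(gxp) <- c(ci$hp, ci$wp, cin)
  gxp[1L + seq_len(h), 1L + seq_len(w), , drop = FALSE]
}

# 3x3 convolution, stride 1, zero padding 1.  W: (9*Cin, Cout) matrix whose
# row blocks follow im2col3's (dj, di) ordering; b: length Cout.
ad_conv2d <- function(tape, x, W, b) {
  d <- dim(x$value)
  h <- d[1]; w <- d[2]; cin <- d[3]
  cout <- ncol(W$value)
  X2 <- im2col3(x$value)
  Y <- X2 %*% W$value
  Y <- Y + rep(b$value, each = h * w)
  dim(Y) <- c(h, w, cout)
  ad_node(tape, Y, list(x, W, b), function(g) {
    gm <- g
    dim(gm) <- c(h * w, cout)
    list(col2im3(gm %*% t(W$value), h, w, cin),
         crossprod(X2, gm),
         colSums(gm))
  })
}

# 1x1 convolution (per-pixel channel mixing).  W: (Cin, Cout); b: Cout.
ad_conv1x1 <- function(tape, x, W, b) {
  d <- dim(x$value)
  h <- d[1]; w <- d[2]; cin <- d[3]
  cout <- ncol(W$value)
  X <- x$value
  dim(X) <- c(h * w, cin)
  Y <- X %*% W$value + rep(b$value, each = h * w)
  dim(Y) <- c(h, w, cout)
  ad_node(tape, Y, list(x, W, b), function(g) {
    gm <- g
    dim(gm) <- c(h * w, cout)
    gx <- gm %*% t(W$value)
    dim(gx) <- c(h, w, cin)
    list(gx, crossprod(X, gm), colSums(gm))
  })
}

# n x 1 convolution collapsing the first spatial axis: x (n, n, Cin) ->
# vector stack (n, Cout).  W: (n*Cin, Cout) with row index ordered (i, cin);
# out[j, cout] = sum_{i, cin} W[(i,cin), cout] * x[i, j, cin] + b[cout].
ad_conv_nx1 <- function(tape, x, W, b) {
  d <- dim(x$value)
  n <- d[1]; cin <- d[3]
  stopifnot(d[2] == n)
  if (nrow(W$value) != n * cin) stop("spatial size mismatch in n x 1 convolution")
  xm <- aperm(x$value, c(1, 3, 2))
  dim(xm) <- c(n * cin, n)
  out <- crossprod(xm, W$value) + rep(b$value, each = n)
  ad_node(tape, out, list(x, W, b), function(g) {
    dxm <- W$value %*% t(g)
    dim(dxm) <- c(n, cin, n)
    list(aperm(dxm, c(1, 3, 2)),
         xm %*% g,
         colSums(g))
  })
}

# 1-D convolution, kernel 3, zero padding 1, over vector stacks (n, Cin).
# W: (3*Cin, Cout) with row blocks ordered by kernel tap.
ad_conv1d <- function(tape, v, W, b) {
  d <- dim(v$value)
  n <- d[1]; cin <- d[2]
  cout <- ncol(W$value)
  vp <- rbind(matrix(0, 1L, cin), v$value, matrix(0, 1L, cin))
  V2 <- cbind(vp[seq_len(n), , drop = FALSE],
              vp[1L + seq_len(n), , drop = FALSE],
              vp[2L + seq_len(n), , drop = FALSE])
  out <- V2 %*% W$value + rep(b$value, each = n)
  ad_node(tape, out, list(v, W, b), function(g) {
    dV2 <- g %*% t(W$value)
    gvp <- matrix(0, n + 2L, cin)
    for (t in 0:2) {
      gvp[t + seq_len(n), ] <- gvp[t + seq_len(n), ] + dV2[, t * cin + seq_len(cin)]
    }
    list(gvp[1L + seq_len(n), , drop = FALSE],
         crossprod(V2, g),
         colSums(g))
  })
}

# --- shape / pooling ops ---------------------------------------------------

ad_gap <- function(tape, x) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  m <- x$value
  dim(m) <- c(hw, d[3])
  ad_node(tape, colMeans(m), list(x), function(g) {
    gx <- rep(g / hw, each = hw)
    dim(gx) <- d
    list(gx)
  })
}

ad_dense <- function(tape, v, W, b) {
  out <- drop(v$value %*% W$value) + b$value
  ad_node(tape, out, list(v, W, b), function(g) {
    list(drop(W$value %*% g), outer(v$value, g), g)
  })
}

# multiply channel c of x by scalar s[c]
ad_scale_channels <- function(tape, x, s) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  sfull <- rep(s$value, each = hw)
  dim(sfull) <- d
  ad_node(tape, x$value * sfull, list(x, s), function(g) {
    gs <- g * x$value
    dim(gs) <- c(hw, d[3])
    list(g * sfull, colSums(gs))
  })
}

# weighted outer products: v (n, C), wts (C) -> (n, n, C) with channel c equal
# to wts[c] * v[,c] %o% v[,c]; each channel map is exactly symmetric.
ad_outer_bundle <- function(tape, v, wts) {
  n <- nrow(v$value); C <- ncol(v$value)
  out <- array(0, c(n, n, C))
  for (c in seq_len(C)) out[, , c] <- wts$value[c] * tcrossprod(v$value[, c])
  ad_node(tape, out, list(v, wts), function(g) {
    dv <- matrix(0, n, C)
    dw <- numeric(C)
    for (c in seq_len(C)) {
      D <- g[, , c]
      vc <- v$value[, c]
      dv[, c] <- wts$value[c] * ((D + t(D)) %*% vc)
      dw[c] <- sum(D * tcrossprod(vc))
    }
    list(dv, dw)
  })
}

ad_softplus_vec <- function(tape, x) {
  sp <- ifelse(x$value > 30, x$value, log1p(exp(pmin(x$value, 30))))
  sig <- 1 / (1 + exp(-x$value))
  ad_node(tape, sp, list(x), function(g) list(g * sig))
}

ad_crop <- function(tape, x, rows, cols) {
  d <- dim(x$value)
  ad_node(tape, x$value[rows, cols, , drop = FALSE], list(x), function(g) {
    gx <- array(0, d)
    gx[rows, cols, ] <- g
    list(gx)
  })
}

ad_concat_channels <- function(tape, a, b) {
  da <- dim(a$value); db <- dim(b$value)
  stopifnot(all(da[1:2] == db[1:2]))
  out <- array(c(a$value, b$value), c(da[1], da[2], da[3] + db[3]))
  ad_node(tape, out, list(a, b), function(g) {
    list(g[, , seq_len(da[3]), drop = FALSE],
         g[, , da[3] + seq_len(db[3]), drop = FALSE])
  })
}

ad_sym3 <- function(tape, x) {
  out <- (x$value + aperm(x$value, c(2, 1, 3))) / 2
  ad_node(tape, out, list(x), function(g) {
    list((g + aperm(g, c(2, 1, 3))) / 2)
  })
}

# keep every other pixel (equivalent to following a stride-1 conv with a
# stride-2 conv of the same weights)
ad_stride2 <- function(tape, x) {
  d <- dim(x$value)
  ri <- seq(1L, d[1], by = 2L); ci <- seq(1L, d[2], by = 2L)
  ad_node(tape, x$value[ri, ci, , drop = FALSE], list(x), function(g) {
    gx <- array(0, d)
    gx[ri, ci, ] <- g
    list(gx)
  })
}

ad_mean_all <- function(tape, x) {
  n <- length(x$value)
  ad_node(tape, mean(x$value), list(x), function(g) {
    gx <- x$value; gx[] <- g / n
    list(gx)
  })
}

# mean |x - target| with a constant target
ad_l1_loss <- function(tape, x, target) {
  diff <- x$value - target
  n <- length(diff)
  ad_node(tape, mean(abs(diff)), list(x), function(g) {
    gx <- sign(diff) * (g / n)
    list(gx)
  })
}

# mean (x - target)^2 with a constant target (least-squares GAN objective)
ad_mse_loss <- function(tape, x, target) {
  diff <- x$value - target
  n <- length(diff)
  ad_node(tape, mean(diff^2), list(x), function(g) {
    list(2 * diff * (g / n))
  })
}
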