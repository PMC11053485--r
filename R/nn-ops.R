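# Low-level differentiable tensor operations.
#
# Feature maps are plain R arrays with dimension order (batch, height,
# width, channel); flattening the first three dims with `dim<-` therefore
# yields a (B*H*W) x C matrix view without copying, which is what the
# pointwise (1x1) convolutions and the normalization layers operate on.
#
# Every op_* function returns list(y = output, bw = function(dy) ...),
# where bw returns list(dx = ..., <param grads>). Composite blocks wire
# the closures together and accumulate parameter gradients by name.
# Analytic backward passes are verified against central finite
# differences in the test suite.

as_mat <- function(x) {
  d <- dim(x)
  dim(x) <- c(prod(d[-length(d)]), d[length(d)])
  x
}

as_map <- function(x, d) {
  dim(x) <- d
  x
}

# channel-wise broadcast for (B,H,W,C) arrays or (M,C) matrices
# (rep.int with a count vector is the fast path of rep(v, each = m))
bcast <- function(v, m) rep.int(v, rep.int(m, length(v)))

## ---- dense / 1x1 convolution ------------------------------------------

op_linear <- function(x, W, b = NULL) {
  y <- x %*% W
  if (!is.null(b)) y <- y + bcast(b, nrow(x))
  list(y = y, bw = function(dy) {
    list(dx = tcrossprod(dy, W),
         dW = crossprod(x, dy),
         db = if (is.null(b)) NULL else colSums(dy))
  })
}

## ---- depthwise 3x3 convolution (same padding) -------------------------

# pure-R reference for the depthwise 3x3 correlation (same padding);
# the compiled path below is tested against it
dwconv3_raw <- function(x, w) {
  d <- dim(x); B <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  m <- B * H * W
  pad <- array(0, c(B, H + 2L, W + 2L, C))
  pad[, 2:(H + 1L), 2:(W + 1L), ] <- x
  y <- array(0, d)
  for (j in 1:3) for (i in 1:3) {
    sl <- pad[, i:(i + H - 1L), j:(j + W - 1L), , drop = FALSE]
    y <- y + sl * bcast(w[i, j, ], m)
  }
  list(y = y)
}

# compiled hot path; dwconv3_raw above is the pure-R reference the test
# suite checks it against
op_dwconv3 <- function(x, w, b) {
  d <- dim(x)
  y <- dwconv3_fwd_cpp(x, as.integer(d), w, b)
  dim(y) <- d
  list(y = y, bw = function(dy) {
    g <- dwconv3_bwd_cpp(x, as.integer(d), w, dy)
    dim(g$dx) <- d
    g
  })
}

## ---- strided fxf convolution via space-to-depth -----------------------

space_to_depth <- function(x, f) {
  d <- dim(x); B <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  H2 <- H %/% f; W2 <- W %/% f
  cols <- vector("list", f * f)
  k <- 1L
  for (j in 1:f) for (i in 1:f) {
    sl <- x[, seq.int(i, H, f), seq.int(j, W, f), , drop = FALSE]
    cols[[k]] <- as_mat(sl)
    k <- k + 1L
  }
  list(m = do.call(cbind, cols), B = B, H2 = H2, W2 = W2, C = C, f = f,
       H = H, W = W)
}

depth_to_space_grad <- function(dm, info) {
  dx <- array(0, c(info$B, info$H, info$W, info$C))
  n2 <- info$B * info$H2 * info$W2
  k <- 1L
  for (j in 1:info$f) for (i in 1:info$f) {
    blk <- dm[, ((k - 1L) * info$C + 1L):(k * info$C), drop = FALSE]
    dx[, seq.int(i, info$H, info$f), seq.int(j, info$W, info$f), ] <-
      as_map(blk, c(info$B, info$H2, info$W2, info$C))
    k <- k + 1L
  }
  dx
}

# non-overlapping fxf conv with stride f (used for patch embedding and
# stage downsampling); W has dim (f*f*Cin, Cout)
op_convdown <- function(x, W, b, f) {
  info <- space_to_depth(x, f)
  lin <- op_linear(info$m, W, b)
  y <- as_map(lin$y, c(info$B, info$H2, info$W2, ncol(W)))
  list(y = y, bw = function(dy) {
    g <- lin$bw(as_mat(dy))
    list(dx = depth_to_space_grad(g$dx, info), dW = g$dW, db = g$db)
  })
}

## ---- activations -------------------------------------------------------

# GELU in its sigmoid approximation x * sigmoid(1.702 x) (indistinguishable
# from the exact form at network precision, and much cheaper than pnorm)
op_gelu <- function(x) {
  s <- sigmoid(1.702 * x)
  list(y = x * s, bw = function(dy) {
    list(dx = dy * (s + 1.702 * x * s * (1 - s)))
  })
}

op_relu <- function(x) {
  mask <- x > 0
  list(y = x * mask, bw = function(dy) list(dx = dy * mask))
}

## ---- batch normalization ----------------------------------------------

# x is an (M, C) matrix view; running stats are updated in `state_env`
# under names `rm_name` / `rv_name` when training.
op_batchnorm <- function(x, gamma, beta, state_env, rm_name, rv_name,
                         train, momentum = 0.1, eps = 1e-5) {
  M <- nrow(x)
  if (train) {
    mu <- colMeans(x)
    xc <- x - bcast(mu, M)
    v <- colMeans(xc * xc)
    state_env[[rm_name]] <- (1 - momentum) * state_env[[rm_name]] + momentum * mu
    state_env[[rv_name]] <- (1 - momentum) * state_env[[rv_name]] +
      momentum * v * M / max(M - 1, 1)
  } else {
    mu <- state_env[[rm_name]]
    xc <- x - bcast(mu, M)
    v <- state_env[[rv_name]]
  }
  ivar <- 1 / sqrt(v + eps)
  xhat <- xc * bcast(ivar, M)
  y <- xhat * bcast(gamma, M) + bcast(beta, M)
  list(y = y, bw = function(dy) {
    dxhat <- dy * bcast(gamma, M)
    dgamma <- colSums(dy * xhat)
    dbeta <- colSums(dy)
    if (train) {
      dx <- bcast(ivar / M, M) *
        (M * dxhat - bcast(colSums(dxhat), M) - xhat * bcast(colSums(dxhat * xhat), M))
    } else {
      dx <- dxhat * bcast(ivar, M)
    }
    list(dx = dx, dgamma = dgamma, dbeta = dbeta)
  })
}

## ---- layer normalization (over channels, per row) ---------------------

op_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  C <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  ivar <- 1 / sqrt(v + eps)
  xhat <- xc * ivar
  M <- nrow(x)
  y <- xhat * bcast(gamma, M) + bcast(beta, M)
  list(y = y, bw = function(dy) {
    dxhat <- dy * bcast(gamma, M)
    dx <- (ivar / C) * (C * dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
    list(dx = dx, dgamma = colSums(dy * xhat), dbeta = colSums(dy))
  })
}

## ---- global response normalization ------------------------------------

#' Global response normalization
#'
#' Divisive normalization across channels: each channel's response is
#' scaled by its global (per-image) L2 norm relative to the mean norm
#' over channels, with a learnable affine and an identity residual:
#' `y_c = gamma_c * x_c * N_c + beta_c + x_c`,
#' `N_c = ||x_c||_2 / mean_c'(||x_c'||_2)`.
#' With zero-initialized `gamma`/`beta` the layer starts as the identity.
#'
#' @param x feature map array (B, H, W, C).
#' @param gamma,beta numeric vectors of length C.
#' @param eps guard added inside the norm square root.
#' @return list(y, bw) where `bw(dy)` returns gradients.
#' @keywords internal
op_grn <- function(x, gamma, beta, eps = 1e-6) {
  d <- dim(x); B <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  n <- H * W
  xm <- as_mat(x)                                   # (B*n, C), rows b fastest
  grp <- rep.int(seq_len(B), n)                     # spatial-group of each row
  rr <- rep.int(seq_len(B), n)                      # row-replication index
  g <- sqrt(rowsum(xm * xm, grp, reorder = FALSE) + eps)  # (B, C) norms
  m <- rowMeans(g)                                  # per-image mean over channels
  Nv <- g / m                                       # N_{bc}, (B, C)
  gN <- Nv * bcast(gamma, B)                        # gamma_c * N_{bc}
  y <- xm * (1 + gN[rr, ]) + bcast(beta, B * n)
  list(y = as_map(y, d), bw = function(dy) {
    dym <- as_mat(dy)
    A <- rowsum(dym * xm, grp, reorder = FALSE) * bcast(gamma, B)  # (B, C)
    Ag <- rowSums(A * g)
    coef <- (A / m - Ag / (C * m * m)) / g
    dxm <- dym * (1 + gN[rr, ]) + xm * coef[rr, ]
    dgamma <- colSums(rowsum(dym * xm, grp, reorder = FALSE) * Nv)
    dbeta <- colSums(dym)
    list(dx = as_map(dxm, d), dgamma = dgamma, dbeta = dbeta)
  })
}

## ---- SimAM parameter-free attention ------------------------------------

#' SimAM attention weighting
#'
#' Parameter-free 3-D attention: every position in every channel is
#' weighted by a sigmoid of its closed-form energy
#' `E = (x - mu)^2 / (4 * (sigma2_hat + lambda)) + 0.5`, where `mu` and
#' `sigma2_hat` (the n-1 corrected variance) are taken over the spatial
#' positions of the channel. A spatially constant channel gets the
#' uniform weight `sigmoid(0.5)`; so does every channel as
#' `lambda -> Inf`.
#'
#' @param x feature map array (B, H, W, C) with H*W > 1.
#' @param lambda positive energy regularizer.
#' @return list(y, bw).
#' @keywords internal
op_simam <- function(x, lambda) {
  d <- dim(x); B <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  n <- H * W
  if (n < 2) stop_invalid("SimAM requires spatial size > 1 (variance undefined)")
  if (!is.numeric(lambda) || lambda <= 0) stop_config("`simam_lambda` must be > 0")
  xm <- as_mat(x)                                   # (B*n, C), rows b fastest
  grp <- rep.int(seq_len(B), n)
  rr <- rep.int(seq_len(B), n)
  mu <- rowsum(xm, grp, reorder = FALSE) / n        # (B, C) spatial means
  dc <- xm - mu[rr, ]
  D <- 4 * (rowsum(dc * dc, grp, reorder = FALSE) / (n - 1) + lambda)  # (B, C)
  Dx <- D[rr, ]
  E <- dc * dc / Dx + 0.5
  wgt <- sigmoid(E)
  list(y = as_map(xm * wgt, d), weights = as_map(wgt, d),
       bw = function(dy) {
    dym <- as_mat(dy)
    cvec <- dym * xm * wgt * (1 - wgt)              # dL/dE
    cd <- rowsum(cvec * dc, grp, reorder = FALSE)
    cd2 <- rowsum(cvec * dc * dc, grp, reorder = FALSE)
    dxm <- dym * wgt +
      (2 / Dx) * (cvec * dc - cd[rr, ] / n) -
      dc * (8 * cd2 / ((n - 1) * D * D))[rr, ]
    list(dx = as_map(dxm, d))
  })
}

## ---- stochastic depth --------------------------------------------------

op_droppath <- function(x, rate, train) {
  if (!train || rate <= 0) return(list(y = x, bw = function(dy) list(dx = dy)))
  d <- dim(x); B <- d[1]
  keep <- stats::runif(B) >= rate
  scale <- keep / (1 - rate)
  y <- x * rep(scale, times = prod(d[-1]))
  list(y = y, bw = function(dy) list(dx = dy * rep(scale, times = prod(d[-1]))))
}

## ---- pooling / resampling ---------------------------------------------

op_avgpool <- function(x, f) {
  if (f == 1) return(list(y = x, bw = function(dy) list(dx = dy)))
  d <- dim(x); B <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  H2 <- H %/% f; W2 <- W %/% f
  y <- array(0, c(B, H2, W2, C))
  for (i in 1:f) for (j in 1:f) {
    y <- y + x[, seq.int(i, H, f), seq.int(j, W, f), , drop = FALSE]
  }
  y <- y / (f * f)
  list(y = y, bw = function(dy) {
    dx <- array(0, d)
    dyf <- dy / (f * f)
    for (i in 1:f) for (j in 1:f) {
      dx[, seq.int(i, H, f), seq.int(j, W, f), ] <- dyf
    }
    list(dx = dx)
  })
}

op_upsample_nearest <- function(x, f) {
  if (f == 1) return(list(y = x, bw = function(dy) list(dx = dy)))
  d <- dim(x)
  hi <- rep(seq_len(d[2]), each = f)
  wi <- rep(seq_len(d[3]), each = f)
  y <- x[, hi, wi, , drop = FALSE]
  list(y = y, bw = function(dy) {
    list(dx = op_avgpool(dy, f)$y * (f * f))
  })
}

op_global_mean_tokens <- function(x) {
  # x: (B, T, C) -> (B, C) mean over tokens
  d <- dim(x); B <- d[1]; Tn <- d[2]; C <- d[3]
  y <- apply(x, c(1, 3), mean)
  dim(y) <- c(B, C)
  list(y = y, bw = function(dy) {
    # dx[b, t, c] = dy[b, c] / T; element order is (b, t, c), b fastest
    dx <- array(apply(dy, 2, rep, times = Tn), c(B, Tn, C))
    list(dx = dx / Tn)
  })
}
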