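# Minimal neural-network kernel: layers hold weights and gradient accumulators in
# environments; forward functions return a cache, backward functions take (layer,
# upstream grad, cache), accumulate parameter grads and return the input grad.
# Layers are therefore safe to share (e.g. one projection applied to both
# modalities): each call carries its own cache.

#' Derive a reproducible sub-seed from a base seed and a counter
#'
#' Used so that per-sample generation streams are independent of generation
#' order. Result is kept inside the 32-bit integer range R requires.
#'
#' @param seed base integer seed
#' @param counter non-negative integer stream index
#' @return an integer seed
#' @export
derive_seed <- function(seed, counter) {
  s <- (as.double(seed) %% 2147483647)
  x <- (s * 48271 + as.double(counter) * 2654435761) %% 2147483647
  as.integer(x)
}

# truncated-normal init (sd 0.02, clipped at 2 sd) used throughout the network
tnorm <- function(n, sd = 0.02) {
  x <- stats::rnorm(n, 0, sd)
  pmin(pmax(x, -2 * sd), 2 * sd)
}

new_linear <- function(din, dout, bias = TRUE, init = c("tnorm", "zeros", "identity")) {
  init <- match.arg(init)
  L <- new.env(parent = emptyenv())
  L$W <- switch(init,
    # fan-scaled truncated normal (Glorot variance, clipped at 2 sd)
    tnorm    = matrix(tnorm(din * dout, sd = sqrt(2 / (din + dout))), din, dout),
    zeros    = matrix(0, din, dout),
    identity = diag(1, din, dout))
  L$b <- if (bias) numeric(dout) else NULL
  L$dW <- matrix(0, din, dout)
  L$db <- if (bias) numeric(dout) else NULL
  L$pnames <- if (bias) c("W", "b") else "W"
  class(L) <- "dn_layer"
  L
}

lin_fw <- function(L, x) {
  y <- x %*% L$W
  if (!is.null(L$b)) y <- y + rep(L$b, each = nrow(y))
  list(y = y, cache = x)
}

lin_bw <- function(L, dy, cache) {
  L$dW <- L$dW + crossprod(cache, dy)
  if (!is.null(L$b)) L$db <- L$db + colSums(dy)
  dy %*% t(L$W)
}

gelu_fw <- function(x) {
  pn <- stats::pnorm(x)
  list(y = x * pn, cache = list(x = x, pn = pn))
}

gelu_bw <- function(dy, cache) {
  x <- cache$x
  dy * (cache$pn + x * 0.3989422804014327 * exp(-0.5 * x * x))
}

relu_fw <- function(x) list(y = pmax(x, 0), cache = x)
relu_bw <- function(dy, cache) dy * (cache > 0)

sigmoid_fw <- function(x) {
  y <- 1 / (1 + exp(-x))
  list(y = y, cache = y)
}
sigmoid_bw <- function(dy, cache) dy * cache * (1 - cache)

new_layernorm <- function(dim, eps = 1e-5) {
  L <- new.env(parent = emptyenv())
  L$g <- rep(1, dim); L$b <- numeric(dim)
  L$dg <- numeric(dim); L$db <- numeric(dim)
  L$eps <- eps
  L$pnames <- c("g", "b")
  class(L) <- "dn_layer"
  L
}

ln_fw <- function(L, x) {
  n <- nrow(x)
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + L$eps)
  xhat <- xc * inv
  y <- xhat * rep(L$g, each = n) + rep(L$b, each = n)
  list(y = y, cache = list(xhat = xhat, inv = inv))
}

ln_bw <- function(L, dy, cache) {
  xhat <- cache$xhat
  L$dg <- L$dg + colSums(dy * xhat)
  L$db <- L$db + colSums(dy)
  dxh <- dy * rep(L$g, each = nrow(dy))
  (dxh - rowMeans(dxh) - xhat * rowMeans(dxh * xhat)) * cache$inv
}

# ---- scaled dot-product attention over G independent groups ------------------
# Q: (Tq, G, dh), K/V: (Tk, G, dh) arrays (token index first so a time slice is a
# G x dh matrix). Two execution strategies: per-group matmul when there are few
# groups, vectorized token-pair loops when there are many small groups (windows).

slab <- function(A, i) {
  m <- A[i, , , drop = FALSE]
  dim(m) <- dim(A)[2:3]
  m
}

# (G, Tq, Tk) array slice at fixed k-index, kept as a G x Tq matrix
slice3 <- function(A, j) {
  m <- A[, , j, drop = FALSE]
  dim(m) <- dim(A)[1:2]
  m
}

attn_fw <- function(Q, K, V) {
  Tq <- dim(Q)[1]; Tk <- dim(K)[1]; G <- dim(Q)[2]; dh <- dim(Q)[3]
  scale <- 1 / sqrt(dh)
  if (G <= 64) {
    # few big groups: per-group BLAS matmuls
    P <- array(0, c(G, Tq, Tk))
    O <- array(0, c(Tq, G, dh))
    for (g in seq_len(G)) {
      Qg <- matrix(Q[, g, ], Tq, dh); Kg <- matrix(K[, g, ], Tk, dh)
      S <- (Qg %*% t(Kg)) * scale
      S <- S - apply(S, 1, max)
      E <- exp(S)
      Pg <- E / rowSums(E)
      P[g, , ] <- Pg
      O[, g, ] <- Pg %*% matrix(V[, g, ], Tk, dh)
    }
    cache <- list(Q = Q, K = K, V = V, P = P, grouped = FALSE)
  } else {
    # many small groups (windows): vectorize over groups, loop only over the
    # key index. Rows are ordered query-token fastest, then group.
    n <- Tq * G
    Qm <- Q; dim(Qm) <- c(n, dh)
    Km <- K; dim(Km) <- c(Tk * G, dh)
    Vm <- V; dim(Vm) <- c(Tk * G, dh)
    gidx <- rep(seq_len(G), each = Tq)
    base <- Tk * (gidx - 1L) # key-row offset per query row
    S <- matrix(0, n, Tk)
    for (j in seq_len(Tk)) S[, j] <- rowSums(Qm * Km[base + j, , drop = FALSE]) * scale
    M <- S[cbind(seq_len(n), max.col(S, ties.method = "first"))]
    E <- exp(S - M)
    Pm <- E / rowSums(E)
    Om <- matrix(0, n, dh)
    for (j in seq_len(Tk)) Om <- Om + Pm[, j] * Vm[base + j, , drop = FALSE]
    O <- Om; dim(O) <- c(Tq, G, dh)
    # P exposed in the (G, Tq, Tk) convention
    P <- aperm(array(Pm, c(Tq, G, Tk)), c(2, 1, 3))
    cache <- list(Q = Q, K = K, V = V, Pm = Pm, base = base, gidx = gidx,
                  grouped = TRUE)
  }
  list(O = O, P = P, cache = cache)
}

# dP_extra: optional gradient injected directly on the attention weights
# (used by the explanation-attention alignment loss), in (G, Tq, Tk) layout.
attn_bw <- function(dO, cache, dP_extra = NULL) {
  Q <- cache$Q; K <- cache$K; V <- cache$V
  Tq <- dim(Q)[1]; Tk <- dim(K)[1]; G <- dim(Q)[2]; dh <- dim(Q)[3]
  scale <- 1 / sqrt(dh)
  if (!cache$grouped) {
    P <- cache$P
    dP <- array(0, c(G, Tq, Tk))
    dV <- array(0, c(Tk, G, dh))
    dQ <- array(0, c(Tq, G, dh))
    dK <- array(0, c(Tk, G, dh))
    for (g in seq_len(G)) {
      dOg <- matrix(dO[, g, ], Tq, dh)
      Vg <- matrix(V[, g, ], Tk, dh)
      Pg <- matrix(P[g, , ], Tq, Tk)
      dPg <- dOg %*% t(Vg)
      if (!is.null(dP_extra)) dPg <- dPg + matrix(dP_extra[g, , ], Tq, Tk)
      dV[, g, ] <- t(Pg) %*% dOg
      dSg <- Pg * (dPg - rowSums(dPg * Pg))
      dQ[, g, ] <- (dSg %*% matrix(K[, g, ], Tk, dh)) * scale
      dK[, g, ] <- (t(dSg) %*% matrix(Q[, g, ], Tq, dh)) * scale
    }
    return(list(dQ = dQ, dK = dK, dV = dV))
  }
  n <- Tq * G
  Qm <- Q; dim(Qm) <- c(n, dh)
  Km <- K; dim(Km) <- c(Tk * G, dh)
  Vm <- V; dim(Vm) <- c(Tk * G, dh)
  Pm <- cache$Pm; base <- cache$base; gidx <- cache$gidx
  dOm <- dO; dim(dOm) <- c(n, dh)
  dP <- matrix(0, n, Tk)
  for (j in seq_len(Tk)) dP[, j] <- rowSums(dOm * Vm[base + j, , drop = FALSE])
  if (!is.null(dP_extra)) {
    dPe <- aperm(dP_extra, c(2, 1, 3)) # -> (Tq, G, Tk)
    dim(dPe) <- c(n, Tk)
    dP <- dP + dPe
  }
  dS <- Pm * (dP - rowSums(dP * Pm))
  dQm <- matrix(0, n, dh)
  dVm <- matrix(0, Tk * G, dh)
  dKm <- matrix(0, Tk * G, dh)
  jrows <- Tk * (seq_len(G) - 1L)
  gsum <- function(X) { # sum over the query index within each (contiguous) group
    dim(X) <- c(Tq, G, dh)
    colSums(X)
  }
  for (j in seq_len(Tk)) {
    dQm <- dQm + dS[, j] * Km[base + j, , drop = FALSE]
    dVm[jrows + j, ] <- gsum(Pm[, j] * dOm)
    dKm[jrows + j, ] <- gsum(dS[, j] * Qm)
  }
  dQ <- dQm * scale; dim(dQ) <- c(Tq, G, dh)
  dK <- dKm * scale; dim(dK) <- c(Tk, G, dh)
  dV <- dVm; dim(dV) <- c(Tk, G, dh)
  list(dQ = dQ, dK = dK, dV = dV)
}

# reshape a (rows = group-major tokens) matrix with head-major columns into the
# (T, G*heads, dh) layout attn_fw expects, and back
split_heads <- function(xm, T, G, heads) {
  dh <- ncol(xm) / heads
  if (heads == 1L) {
    A <- xm
    dim(A) <- c(T, G, dh)
    return(A)
  }
  A <- array(xm, c(T, G, dh, heads))
  A <- aperm(A, c(1, 2, 4, 3))
  dim(A) <- c(T, G * heads, dh)
  A
}

merge_heads <- function(A, T, G, heads) {
  dh <- dim(A)[3]
  if (heads == 1L) {
    dim(A) <- c(T * G, dh)
    return(A)
  }
  dim(A) <- c(T, G, heads, dh)
  A <- aperm(A, c(1, 2, 4, 3))
  dim(A) <- c(T * G, dh * heads)
  A
}

# ---- multi-head self-attention over grouped tokens ---------------------------
# perm orders the (B*N) token rows as (token-within-group fastest, then group,
# then batch sample); groups are attention neighbourhoods (windows or whole
# sequences).

new_mhsa <- function(dim, heads) {
  stopifnot(dim %% heads == 0)
  L <- new.env(parent = emptyenv())
  L$heads <- heads
  L$q <- new_linear(dim, dim); L$k <- new_linear(dim, dim)
  L$v <- new_linear(dim, dim); L$o <- new_linear(dim, dim)
  class(L) <- "dn_module"
  L
}

mhsa_fw <- function(L, x, perm, T) {
  n <- nrow(x); G <- n / T
  dim_ <- ncol(x); dh <- dim_ %/% L$heads
  qf <- lin_fw(L$q, x); kf <- lin_fw(L$k, x); vf <- lin_fw(L$v, x)
  qp <- qf$y[perm, , drop = FALSE]
  kp <- kf$y[perm, , drop = FALSE]
  vp <- vf$y[perm, , drop = FALSE]
  om <- matrix(0, n, dim_)
  at_caches <- vector("list", L$heads)
  for (h in seq_len(L$heads)) {
    cols <- (h - 1L) * dh + seq_len(dh)
    Q <- qp[, cols, drop = FALSE]; dim(Q) <- c(T, G, dh)
    K <- kp[, cols, drop = FALSE]; dim(K) <- c(T, G, dh)
    V <- vp[, cols, drop = FALSE]; dim(V) <- c(T, G, dh)
    at <- attn_fw(Q, K, V)
    O <- at$O; dim(O) <- c(n, dh)
    om[, cols] <- O
    at_caches[[h]] <- at$cache
  }
  out <- matrix(0, n, dim_)
  out[perm, ] <- om
  of <- lin_fw(L$o, out)
  list(y = of$y, cache = list(qc = qf$cache, kc = kf$cache, vc = vf$cache,
                              oc = of$cache, at = at_caches, perm = perm,
                              T = T, G = G, n = n, dim = dim_, dh = dh))
}

mhsa_bw <- function(L, dy, cache) {
  dout <- lin_bw(L$o, dy, cache$oc)
  dom <- dout[cache$perm, , drop = FALSE]
  n <- cache$n; dh <- cache$dh
  dqp <- matrix(0, n, cache$dim)
  dkp <- matrix(0, n, cache$dim)
  dvp <- matrix(0, n, cache$dim)
  for (h in seq_len(L$heads)) {
    cols <- (h - 1L) * dh + seq_len(dh)
    dO <- dom[, cols, drop = FALSE]; dim(dO) <- c(cache$T, cache$G, dh)
    da <- attn_bw(dO, cache$at[[h]])
    dim(da$dQ) <- c(n, dh); dim(da$dK) <- c(n, dh); dim(da$dV) <- c(n, dh)
    dqp[, cols] <- da$dQ; dkp[, cols] <- da$dK; dvp[, cols] <- da$dV
  }
  unperm <- function(mm) {
    out <- matrix(0, n, cache$dim)
    out[cache$perm, ] <- mm
    out
  }
  lin_bw(L$q, unperm(dqp), cache$qc) +
    lin_bw(L$k, unperm(dkp), cache$kc) +
    lin_bw(L$v, unperm(dvp), cache$vc)
}

# ---- 2-D convolution (single sample, zero padding) ---------------------------
# x: (H, W, C) array. Weights stored as a (k*k*Cin) x Cout matrix.

new_conv2d <- function(k, cin, cout, stride = 1, pad = NULL) {
  L <- new.env(parent = emptyenv())
  if (is.null(pad)) pad <- rep((k - 1) %/% 2, 4) # top, bottom, left, right
  if (length(pad) == 1) pad <- rep(pad, 4)
  L$k <- k; L$cin <- cin; L$cout <- cout; L$stride <- stride; L$pad <- pad
  fan <- k * k * cin
  L$W <- matrix(tnorm(fan * cout, sd = sqrt(2 / (fan + cout))), fan, cout)
  L$b <- numeric(cout)
  L$dW <- matrix(0, nrow(L$W), cout); L$db <- numeric(cout)
  L$pnames <- c("W", "b")
  L$idx_cache <- list()
  class(L) <- "dn_layer"
  L
}

conv_geometry <- function(L, H, W) {
  Hp <- H + L$pad[1] + L$pad[2]; Wp <- W + L$pad[3] + L$pad[4]
  Ho <- (Hp - L$k) %/% L$stride + 1
  Wo <- (Wp - L$k) %/% L$stride + 1
  key <- paste(H, W, sep = "x")
  if (is.null(L$idx_cache[[key]])) {
    oi <- rep(seq(1, by = L$stride, length.out = Ho), times = Wo)
    oj <- rep(seq(1, by = L$stride, length.out = Wo), each = Ho)
    di <- rep(seq_len(L$k), times = L$k * L$cin)
    dj <- rep(rep(seq_len(L$k), each = L$k), times = L$cin)
    dc <- rep(seq_len(L$cin), each = L$k * L$k)
    # linear index into padded (Hp, Wp, C) array
    idx <- outer(oi - 1, di - 1, "+") + Hp * (outer(oj - 1, dj - 1, "+") +
           Wp * matrix(dc - 1, Ho * Wo, L$k * L$k * L$cin, byrow = TRUE)) + 1L
    L$idx_cache[[key]] <- list(idx = idx, Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo)
  }
  L$idx_cache[[key]]
}

conv2d_fw <- function(L, x) {
  d <- dim(x); H <- d[1]; W <- d[2]
  g <- conv_geometry(L, H, W)
  xp <- array(0, c(g$Hp, g$Wp, L$cin))
  xp[L$pad[1] + seq_len(H), L$pad[3] + seq_len(W), ] <- x
  cols <- matrix(xp[g$idx], nrow(g$idx), ncol(g$idx))
  y <- sweep(cols %*% L$W, 2, L$b, "+")
  out <- array(y, c(g$Ho, g$Wo, L$cout))
  list(y = out, cache = list(cols = cols, g = g, H = H, W = W))
}

conv2d_bw <- function(L, dy, cache) {
  g <- cache$g
  dym <- matrix(dy, g$Ho * g$Wo, L$cout)
  L$dW <- L$dW + crossprod(cache$cols, dym)
  L$db <- L$db + colSums(dym)
  dcols <- dym %*% t(L$W)
  # scatter-add one kernel offset at a time: within a column of the im2col
  # matrix all target pixels are distinct, so vectorized indexed addition is safe
  dxp <- numeric(g$Hp * g$Wp * L$cin)
  for (cc in seq_len(ncol(dcols))) {
    ii <- g$idx[, cc]
    dxp[ii] <- dxp[ii] + dcols[, cc]
  }
  dxp <- array(dxp, c(g$Hp, g$Wp, L$cin))
  dxp[L$pad[1] + seq_len(cache$H), L$pad[3] + seq_len(cache$W), , drop = FALSE]
}

# ---- stride-2 transposed convolution via zero insertion ----------------------
# Output is exactly 2x the input grid for any kernel size k >= 2.

new_deconv2d <- function(k, cin, cout) {
  # zero-stuffed size is 2n-1; total pad of k per axis gives output exactly 2n
  pl <- k %/% 2; pr <- k - pl
  L <- new_conv2d(k, cin, cout, stride = 1, pad = c(pl, pr, pl, pr))
  L$is_deconv <- TRUE
  L
}

zero_stuff <- function(x) {
  d <- dim(x)
  out <- array(0, c(2 * d[1] - 1, 2 * d[2] - 1, d[3]))
  out[seq(1, 2 * d[1] - 1, by = 2), seq(1, 2 * d[2] - 1, by = 2), ] <- x
  out
}

deconv2d_fw <- function(L, x) {
  xs <- zero_stuff(x)
  cf <- conv2d_fw(L, xs)
  list(y = cf$y, cache = list(cf = cf$cache, din = dim(x)))
}

deconv2d_bw <- function(L, dy, cache) {
  dxs <- conv2d_bw(L, dy, cache$cf)
  d <- cache$din
  dxs[seq(1, 2 * d[1] - 1, by = 2), seq(1, 2 * d[2] - 1, by = 2), , drop = FALSE]
}

# ---- parameter bookkeeping and AdamW -----------------------------------------

collect_layers <- function(x) {
  if (inherits(x, "dn_layer")) return(list(x))
  if (inherits(x, "dn_module") || is.environment(x)) {
    kids <- mget(ls(x), envir = x)
    return(do.call(c, lapply(Filter(function(k) is.environment(k) || is.list(k), kids),
                             collect_layers)))
  }
  if (is.list(x)) return(do.call(c, lapply(x, collect_layers)))
  list()
}

zero_grads <- function(layers) {
  for (L in layers) for (nm in L$pnames) L[[paste0("d", nm)]] <- L[[paste0("d", nm)]] * 0
  invisible(NULL)
}

n_params <- function(layers) sum(vapply(layers, function(L)
  sum(vapply(L$pnames, function(nm) length(L[[nm]]), 0)), 0))

#' AdamW update step over a list of layers
#'
#' Decoupled weight decay: parameters are shrunk by `lr * wd` independently of
#' the adaptive gradient step. Bias and normalization parameters (length-1
#' dimensional vectors named `b`, `g`) are not decayed.
#' @keywords internal
adamw_step <- function(layers, lr, t, wd = 0.05, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  for (L in layers) for (nm in L$pnames) {
    gnm <- paste0("d", nm)
    g <- L[[gnm]]
    mnm <- paste0("m_", nm); vnm <- paste0("v_", nm)
    if (is.null(L[[mnm]])) { L[[mnm]] <- g * 0; L[[vnm]] <- g * 0 }
    L[[mnm]] <- beta1 * L[[mnm]] + (1 - beta1) * g
    L[[vnm]] <- beta2 * L[[vnm]] + (1 - beta2) * g * g
    mh <- L[[mnm]] / (1 - beta1^t)
    vh <- L[[vnm]] / (1 - beta2^t)
    upd <- mh / (sqrt(vh) + eps)
    if (nm == "W") upd <- upd + wd * L[[nm]]
    L[[nm]] <- L[[nm]] - lr * upd
  }
  invisible(NULL)
}

# serialize / restore all weights of a layer list (checkpointing); with
# optimizer = TRUE the AdamW moment estimates are captured too, so training
# can resume bit-exactly
dump_weights <- function(layers, optimizer = FALSE) {
  lapply(layers, function(L) {
    nms <- L$pnames
    if (optimizer) {
      aux <- grep("^[mv]_", ls(L), value = TRUE)
      nms <- c(nms, aux)
    }
    mget(nms, envir = L)
  })
}

load_weights <- function(layers, state) {
  stopifnot(length(layers) == length(state))
  for (i in seq_along(layers))
    for (nm in names(state[[i]])) layers[[i]][[nm]] <- state[[i]][[nm]]
  invisible(NULL)
}
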