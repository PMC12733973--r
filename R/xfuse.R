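# Bidirectional cross-modal attention: functional single-layer API (used by
# tests and as the reference form of the model's fusion layers) and the
# attention marginal consumed by the explainability module.

#' One bidirectional cross-modal attention layer (functional form)
#'
#' Visual tokens attend over acoustic tokens and vice versa with shared
#' projection matrices:
#' `alpha_va = softmax(V Wq (A Wk)^T / sqrt(d))`, `V' = alpha_va (A Wv) + V`,
#' and symmetrically for the acoustic stream, followed by layer normalization
#' (unit gain) unless disabled.
#'
#' @param V,A token matrices (Nv x d and Na x d)
#' @param Wq,Wk,Wv optional d x d projection matrices (identity if NULL)
#' @param layer_norm apply layer normalization to the updated tokens
#' @return list with `Vp`, `Ap` (updated tokens), `V_pre`, `A_pre`
#'   (pre-normalization), and attention weight matrices `alpha_va` (Nv x Na),
#'   `alpha_av` (Na x Nv); every attention row sums to 1
#' @export
cross_attend <- function(V, A, Wq = NULL, Wk = NULL, Wv = NULL,
                         layer_norm = TRUE) {
  if (ncol(V) != ncol(A)) stop("invalid input: token width mismatch")
  d <- ncol(V)
  id <- diag(d)
  if (is.null(Wq)) Wq <- id
  if (is.null(Wk)) Wk <- id
  if (is.null(Wv)) Wv <- id
  smax <- function(S) {
    E <- exp(S - apply(S, 1, max))
    E / rowSums(E)
  }
  alpha_va <- smax((V %*% Wq) %*% t(A %*% Wk) / sqrt(d))
  alpha_av <- smax((A %*% Wq) %*% t(V %*% Wk) / sqrt(d))
  V_pre <- alpha_va %*% (A %*% Wv) + V
  A_pre <- alpha_av %*% (V %*% Wv) + A
  lnorm <- function(x) {
    mu <- rowMeans(x)
    s <- sqrt(rowMeans((x - mu)^2) + 1e-5)
    (x - mu) / s
  }
  list(Vp = if (layer_norm) lnorm(V_pre) else V_pre,
       Ap = if (layer_norm) lnorm(A_pre) else A_pre,
       V_pre = V_pre, A_pre = A_pre,
       alpha_va = alpha_va, alpha_av = alpha_av)
}

#' Pool fused token streams to an embedding pair
#'
#' Mean over token positions, per stream; deterministic and permutation
#' invariant in the token order.
#'
#' @param out result of [cross_attend()] (or any list with `Vp`, `Ap`)
#' @return list with vectors `zv`, `za`
#' @export
fused_embedding <- function(out) {
  list(zv = colMeans(out$Vp), za = colMeans(out$Ap))
}

# integer block-replication upsample and its adjoint
block_up <- function(mat, fh, fw) {
  mat[rep(seq_len(nrow(mat)), each = fh), rep(seq_len(ncol(mat)), each = fw),
      drop = FALSE]
}

block_up_adj <- function(up, fh, fw) {
  h <- nrow(up) %/% fh; w <- ncol(up) %/% fw
  a <- array(up, c(fh, h, fw, w))
  out <- apply(a, c(2, 4), sum)
  matrix(out, h, w)
}

#' Marginal spatial distribution of cross-modal attention
#'
#' Sums acoustic-to-visual attention over the acoustic query positions,
#' reshapes the mass per visual key onto the visual grid, normalizes it to sum
#' one and upsamples to the explanation resolution (renormalized).
#'
#' @param alpha_av Na x Nv attention matrix (rows sum to 1), or the `P_av`
#'   array of [model_forward()] together with `sample`
#' @param grid visual grid c(h, w); defaults to the square root layout
#' @param size output resolution (square)
#' @param sample batch index when `alpha_av` is a 3-D attention array
#' @return `size` x `size` non-negative matrix summing to 1
#' @export
attention_marginal <- function(alpha_av, grid = NULL, size = 64, sample = 1) {
  if (length(dim(alpha_av)) == 3) {
    A <- alpha_av[sample, , ]
    if (is.null(dim(A))) A <- matrix(A, dim(alpha_av)[2], dim(alpha_av)[3])
  } else A <- alpha_av
  nv <- ncol(A)
  if (is.null(grid)) {
    side <- round(sqrt(nv))
    stopifnot(side * side == nv)
    grid <- c(side, side)
  }
  mass <- colSums(A)
  mc <- matrix(mass, grid[1], grid[2])
  mc <- mc / sum(mc)
  up <- block_up(mc, size %/% grid[1], size %/% grid[2])
  up / sum(up)
}
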