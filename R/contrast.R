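# Cross-species contrastive learning: projection to a unit-norm joint
# embedding, dynamic positive / hard-negative pairing through the batch
# similarity matrix, InfoNCE loss, margin loss and the total objective.
# Loss functions return both the scalar value and its analytic gradient with
# respect to the (unit-norm) embeddings so the training loop can inject it
# into the model backward pass.

#' Contrastive learning configuration
#'
#' @param temperature softmax temperature tau of the InfoNCE loss
#' @param margin margin delta of the triplet constraint
#' @param lambda1,lambda2 weights of the contrastive and margin terms in the
#'   total loss
#' @param hard_k number of hardest negatives kept per anchor (Inf keeps all)
#' @return a `contrast_config` list
#' @export
contrast_config <- function(temperature = 0.07, margin = 0.2,
                            lambda1 = 0.5, lambda2 = 0.1, hard_k = Inf) {
  stopifnot(temperature > 0, margin > 0, lambda1 >= 0, lambda2 >= 0)
  structure(list(temperature = temperature, margin = margin,
                 lambda1 = lambda1, lambda2 = lambda2, hard_k = hard_k),
            class = "contrast_config")
}

#' Project pooled modality features to the joint embedding
#'
#' Applies the model's shared two-layer projection head (GELU between the
#' layers, L2 normalization after) to each modality and returns the joint
#' embedding `zm = normalize((zv + za) / 2)`.
#'
#' @param m an `avmodel`
#' @param zv_raw,za_raw pooled visual / acoustic feature matrices (N x width)
#' @return list with unit-norm `zv`, `za`, `zm`
#' @export
project_joint <- function(m, zv_raw, za_raw) {
  if (ncol(zv_raw) != nrow(m$proj1$W) || ncol(za_raw) != nrow(m$proj1$W))
    stop("invalid input: feature width does not match projection head")
  head1 <- function(x) {
    h <- lin_fw(m$proj1, x)$y
    h <- gelu_fw(h)$y
    l2norm_fw(lin_fw(m$proj2, h)$y)$y
  }
  zv <- head1(zv_raw); za <- head1(za_raw)
  zm <- l2norm_fw((zv + za) / 2)$y
  list(zv = zv, za = za, zm = zm)
}

#' Build positive and hard-negative index sets per anchor
#'
#' Positives are same-label samples (excluding the anchor itself). Negatives
#' are different-label samples ranked by descending embedding similarity
#' (cosine, via the batch similarity matrix `S = Z Z^T`); the `hard_k` most
#' similar are kept. When the anchor's designated confusable class (the
#' species bank's `similar_to` partner) is present in the batch, at least one
#' of its samples is guaranteed to appear among the negatives.
#'
#' @param Z N x d matrix of unit-norm embeddings
#' @param labels integer class labels (length N)
#' @param hard_k negatives kept per anchor (Inf = all)
#' @param similar_map optional named integer vector: class -> confusable class
#' @return list per anchor: `pos` and `neg` index vectors; attribute `S` holds
#'   the similarity matrix
#' @export
build_pairs <- function(Z, labels, hard_k = Inf, similar_map = NULL) {
  N <- nrow(Z)
  stopifnot(length(labels) == N)
  if (length(unique(labels)) < 2) stop("no negatives: batch has a single class")
  S <- Z %*% t(Z)
  pairs <- vector("list", N)
  for (i in seq_len(N)) {
    pos <- which(labels == labels[i])
    pos <- pos[pos != i]
    neg <- which(labels != labels[i])
    neg <- neg[order(S[i, neg], decreasing = TRUE)]
    if (is.finite(hard_k) && length(neg) > hard_k) {
      kept <- neg[seq_len(hard_k)]
      sim_cls <- if (!is.null(similar_map)) similar_map[as.character(labels[i])] else NA
      if (!is.na(sim_cls) && !any(labels[kept] == sim_cls) && any(labels[neg] == sim_cls)) {
        kept[hard_k] <- neg[which(labels[neg] == sim_cls)[1]]
      }
      neg <- kept
    }
    pairs[[i]] <- list(pos = pos, neg = neg)
  }
  attr(pairs, "S") <- S
  pairs
}

#' InfoNCE contrastive loss
#'
#' Default form: for each anchor i and each of its positives p, the loss is
#' `-log( exp(s_ip/tau) / (exp(s_ip/tau) + sum_j exp(s_ij/tau)) )` with the
#' sum over the anchor's negatives and s the cosine similarity (dot product of
#' unit-norm embeddings); the result is averaged over anchors (and positives
#' within an anchor). `verbatim = TRUE` instead evaluates the printed variant
#' `+log( exp(s_ip/tau) / sum_j exp(s_ij/tau) )` without the positive in the
#' denominator, retained for comparison; its optimum contradicts the intended
#' pull-together/push-apart behaviour, so it is not the default.
#'
#' Anchors without positives are excluded from the average with a warning.
#'
#' @param Z N x d unit-norm embedding matrix
#' @param pairs result of [build_pairs()]
#' @param tau temperature
#' @param verbatim evaluate the printed variant instead of the standard form
#' @return list with `value` and `grad` (N x d, gradient w.r.t. Z; NULL for
#'   the verbatim mode which is evaluation-only)
#' @export
loss_infonce <- function(Z, pairs, tau = 0.07, verbatim = FALSE) {
  stopifnot(tau > 0)
  N <- nrow(Z)
  S <- Z %*% t(Z)
  G <- matrix(0, N, N) # dL/dS accumulation
  total <- 0; n_terms <- 0
  skipped <- 0
  for (i in seq_len(N)) {
    pos <- pairs[[i]]$pos; neg <- pairs[[i]]$neg
    if (length(pos) == 0) { skipped <- skipped + 1; next }
    for (p in pos) {
      if (verbatim) {
        lse <- log(sum(exp(S[i, neg] / tau)))
        total <- total + (S[i, p] / tau - lse)
        n_terms <- n_terms + 1
        next
      }
      idx <- c(p, neg)
      lo <- S[i, idx] / tau
      mx <- max(lo)
      w <- exp(lo - mx)
      w <- w / sum(w)
      total <- total - (lo[1] - mx - log(sum(exp(lo - mx))))
      n_terms <- n_terms + 1
      # d(-log softmax_p)/dS[i, idx] = (w - onehot_p)/tau
      G[i, idx] <- G[i, idx] + (w - c(1, numeric(length(neg)))) / tau
    }
  }
  if (skipped > 0) warning(skipped, " anchor(s) without positives excluded")
  if (n_terms == 0) stop("no anchor-positive pairs in batch")
  value <- total / n_terms
  if (verbatim) return(list(value = value, grad = NULL))
  G <- G / n_terms
  # S = Z Z^T with S symmetric in indices but G not: dL/dZ = G Z + G^T Z
  list(value = value, grad = (G + t(G)) %*% Z)
}

#' Margin (triplet) loss
#'
#' Default form: `max(0, delta + ||z_i - z_p||^2 - ||z_i - z_n||^2)` averaged
#' over all (anchor, positive, negative) triplets from the built pairs,
#' consistent with the convergence requirement that positives end up closer
#' than negatives. `verbatim = TRUE` evaluates the printed variant
#' `max(0, delta - ||z_i - z_p||^2 + ||z_i - z_n||^2)` (signs reversed),
#' retained for comparison only.
#'
#' @inheritParams loss_infonce
#' @param delta margin
#' @return list with `value` and `grad` (NULL in verbatim mode)
#' @export
loss_margin <- function(Z, pairs, delta = 0.2, verbatim = FALSE) {
  N <- nrow(Z)
  dZ <- Z * 0
  total <- 0; n_terms <- 0
  for (i in seq_len(N)) {
    pos <- pairs[[i]]$pos; neg <- pairs[[i]]$neg
    if (length(pos) == 0 || length(neg) == 0) next
    for (p in pos) for (q in neg) {
      dp <- sum((Z[i, ] - Z[p, ])^2)
      dn <- sum((Z[i, ] - Z[q, ])^2)
      h <- if (verbatim) delta - dp + dn else delta + dp - dn
      n_terms <- n_terms + 1
      if (h > 0) {
        total <- total + h
        if (!verbatim) {
          dZ[i, ] <- dZ[i, ] + 2 * (Z[q, ] - Z[p, ]) # d(dp - dn)/dz_i
          dZ[p, ] <- dZ[p, ] - 2 * (Z[i, ] - Z[p, ])
          dZ[q, ] <- dZ[q, ] + 2 * (Z[i, ] - Z[q, ])
        }
      }
    }
  }
  if (n_terms == 0) stop("no triplets available")
  value <- total / n_terms
  if (verbatim) return(list(value = value, grad = NULL))
  list(value = value, grad = dZ / n_terms)
}

#' Total training objective
#'
#' `L_total = L_cls + lambda1 * L_cs + lambda2 * L_margin`.
#'
#' @param l_cls classification (cross-entropy) loss
#' @param l_cs contrastive loss
#' @param l_margin margin loss
#' @param config a [contrast_config()]
#' @return scalar
#' @export
loss_total <- function(l_cls, l_cs, l_margin, config = contrast_config()) {
  if (!all(is.finite(c(l_cls, l_cs, l_margin))))
    stop("training abort: non-finite loss component")
  l_cls + config$lambda1 * l_cs + config$lambda2 * l_margin
}

# softmax cross-entropy over logit rows; returns loss and dlogits
cross_entropy <- function(logits, labels01) {
  N <- nrow(logits)
  mx <- apply(logits, 1, max)
  e <- exp(logits - mx)
  p <- e / rowSums(e)
  idx <- cbind(seq_len(N), labels01 + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-300)))
  d <- p
  d[idx] <- d[idx] - 1
  list(value = loss, grad = d / N, prob = p)
}
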