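# Full audio-visual recognition model: hierarchical windowed-attention visual
# branch with a convolutional decoder, patch-Transformer acoustic branch with
# temporal positional encoding, shared projection, bidirectional cross-modal
# attention fusion, classification / contrastive / interpreter heads.
#
# The forward pass stores every intermediate needed by the hand-written
# backward pass in a cache list; the backward pass accepts gradient injections
# at the nodes where the different losses attach (logits, joint embedding,
# visual feature map, final-layer attention weights) and propagates them in a
# single sweep, accumulating parameter gradients inside the layer objects.

#' Model configuration
#'
#' `tiny` divides all widths of the reference scale by 8 and uses 128 x 128
#' inputs; `paper` uses the full widths (96/192/384/768 stage channels,
#' d = 512, embedding 256) at 256 x 256. Both reduce to an 8 x 8 visual and
#' 8 x 4 acoustic token grid.
#'
#' @param scale "tiny" or "paper"
#' @param n_classes number of species classes
#' @param mel_bins,mel_frames acoustic input geometry
#' @param image_size optional override of the input resolution (must be a
#'   multiple of 8 times the patch size); smaller values shrink the token
#'   grids of every stage proportionally
#' @return an `encoder_config` list
#' @export
encoder_config <- function(scale = c("tiny", "paper"), n_classes = 3,
                           mel_bins = 64, mel_frames = 96, image_size = NULL) {
  scale <- match.arg(scale)
  div <- if (scale == "tiny") 8L else 1L
  cfg <- list(
    scale = scale,
    n_classes = as.integer(n_classes),
    image_size = if (!is.null(image_size)) as.integer(image_size)
                 else if (scale == "tiny") 128L else 256L,
    patch = if (scale == "tiny") 4L else 8L,
    window = 4L,
    stage_channels = c(96L, 192L, 384L, 768L) %/% div,
    stage_heads = c(3L, 6L, 12L, 24L),
    d = 512L %/% div,
    embed_dim = 256L %/% div,
    fusion_channels = c(128L, 256L, 512L, 512L) %/% div,
    n_fusion_layers = 4L,
    mel_bins = as.integer(mel_bins),
    mel_frames = as.integer(mel_frames),
    acoustic_grid = c(8L, 4L),
    stem_channels = 4L,
    interp_reduce = 128L %/% div
  )
  stopifnot(all(cfg$stage_channels %% cfg$stage_heads == 0),
            cfg$image_size %% (cfg$patch * 8L) == 0)
  class(cfg) <- "encoder_config"
  cfg
}

# window-partition permutation for an h x w token grid (column-major token
# index i + h*(j-1)), window size ws, cyclic shift s
win_perm <- function(h, w, ws, s = 0) {
  i <- rep(seq_len(h), w); j <- rep(seq_len(w), each = h)
  si <- ((i - 1 + s) %% h) + 1
  sj <- ((j - 1 + s) %% w) + 1
  win <- ceiling(si / ws) + (h %/% ws) * (ceiling(sj / ws) - 1)
  pos <- ((si - 1) %% ws + 1) + ws * ((sj - 1) %% ws)
  order(win, pos)
}

batch_perm <- function(perm, N, B) rep(perm, B) + rep((seq_len(B) - 1L) * N, each = N)

merge_idx <- function(h, w) {
  h2 <- h %/% 2; w2 <- w %/% 2
  i2 <- rep(seq_len(h2), w2); j2 <- rep(seq_len(w2), each = h2)
  list(i1 = (2 * i2 - 1) + h * (2 * j2 - 2),
       i2 = (2 * i2)     + h * (2 * j2 - 2),
       i3 = (2 * i2 - 1) + h * (2 * j2 - 1),
       i4 = (2 * i2)     + h * (2 * j2 - 1))
}

batch_idx <- function(idx, N, B) rep(idx, B) + rep((seq_len(B) - 1L) * N, each = length(idx))

new_block <- function(dim, heads) {
  list(att = new_mhsa(dim, heads),
       ln1 = new_layernorm(dim),
       fc1 = new_linear(dim, 4 * dim),
       fc2 = new_linear(4 * dim, dim),
       ln2 = new_layernorm(dim))
}

block_fw <- function(bl, x, perm, T) {
  a <- mhsa_fw(bl$att, x, perm, T)
  l1 <- ln_fw(bl$ln1, x + a$y)
  f1 <- lin_fw(bl$fc1, l1$y)
  g1 <- gelu_fw(f1$y)
  f2 <- lin_fw(bl$fc2, g1$y)
  l2 <- ln_fw(bl$ln2, l1$y + f2$y)
  list(y = l2$y, cache = list(a = a$cache, l1 = l1$cache, f1 = f1$cache,
                              g1 = g1$cache, f2 = f2$cache, l2 = l2$cache))
}

block_bw <- function(bl, dy, c) {
  d2 <- ln_bw(bl$ln2, dy, c$l2)
  df2 <- lin_bw(bl$fc2, d2, c$f2)
  dg1 <- gelu_bw(df2, c$g1)
  df1 <- lin_bw(bl$fc1, dg1, c$f1)
  dl1 <- d2 + df1
  d1 <- ln_bw(bl$ln1, dl1, c$l1)
  da <- mhsa_bw(bl$att, d1, c$a)
  d1 + da
}

# temporal sinusoidal positional encoding for the acoustic token grid
#(freq-major ordering: token = f + n_freq*(t-1))
acoustic_pe <- function(n_freq, n_time, dim) {
  pe <- matrix(0, n_freq * n_time, dim)
  tpos <- rep(seq_len(n_time) - 1, each = n_freq)
  for (k in seq_len(dim)) {
    rate <- 10000^(-((k - 1) %/% 2) * 2 / dim)
    pe[, k] <- if (k %% 2 == 1) sin(tpos * rate) else cos(tpos * rate)
  }
  pe
}

patch_extract_idx <- function(H, W, C, ph, pw) {
  # non-overlapping ph x pw patches, token order column-major over the
  # (H/ph) x (W/pw) grid; each row of the index matrix is one token
  nh <- H %/% ph; nw <- W %/% pw
  tok_i <- rep(seq_len(nh), nw); tok_j <- rep(seq_len(nw), each = nh)
  di <- rep(seq_len(ph), pw * C)
  dj <- rep(rep(seq_len(pw), each = ph), C)
  dc <- rep(seq_len(C), each = ph * pw)
  base_i <- outer((tok_i - 1) * ph, di - 1, "+")       # (ntok, phpwC)
  base_j <- outer((tok_j - 1) * pw, dj - 1, "+")
  base_c <- matrix(dc - 1, nh * nw, ph * pw * C, byrow = TRUE)
  base_i + H * base_j + H * W * base_c + 1L
}

#' Build an audio-visual recognition model
#'
#' @param config an [encoder_config()]
#' @param seed integer seed for weight initialization
#' @param fusion if FALSE the bidirectional cross-attention layers are skipped
#'   and the projected encoder outputs are pooled directly (the
#'   "early fusion" ablation)
#' @return an object of class `avmodel`
#' @export
build_model <- function(config, seed = 1, fusion = TRUE) {
  stopifnot(inherits(config, "encoder_config"))
  with_seed(seed, {
    cs <- config$stage_channels
    g0 <- config$image_size %/% config$patch # first-stage grid side
    grids <- g0 %/% c(1L, 2L, 4L, 8L)
    m <- list(config = config, fusion = fusion, grids = grids)
    # visual branch
    m$v_patch <- new_conv2d(config$patch, 3, cs[1], stride = config$patch, pad = 0)
    m$v_stages <- lapply(1:4, function(s) {
      ws <- min(config$window, grids[s])
      list(blocks = list(new_block(cs[s], config$stage_heads[s]),
                         new_block(cs[s], config$stage_heads[s])),
           ws = ws,
           perm0 = win_perm(grids[s], grids[s], ws, 0),
           perm1 = win_perm(grids[s], grids[s], ws, ws %/% 2))
    })
    m$v_merge <- lapply(1:3, function(s) new_linear(4 * cs[s], cs[s + 1]))
    m$v_merge_idx <- lapply(1:3, function(s) merge_idx(grids[s], grids[s]))
    m$v_decoder <- new_deconv2d(3, cs[4], cs[4])
    m$Nv <- (2L * grids[4])^2 # visual tokens after the stride-2 decoder
    # acoustic branch
    m$a_stem <- new_conv2d(3, 1, config$stem_channels)
    gf <- config$acoustic_grid[1]; gt <- config$acoustic_grid[2]
    ph <- config$mel_bins %/% gf; pw <- config$mel_frames %/% gt
    m$a_patch_idx <- patch_extract_idx(config$mel_bins, config$mel_frames,
                                       config$stem_channels, ph, pw)
    m$a_embed <- new_linear(ph * pw * config$stem_channels, cs[1])
    m$a_pe <- acoustic_pe(gf, gt, cs[1])
    m$a_layers <- lapply(1:4, function(l) list(
      trans = if (l > 1 && cs[l] != cs[l - 1]) new_linear(cs[l - 1], cs[l]) else NULL,
      block = new_block(cs[l], config$stage_heads[l])))
    m$a_ntok <- gf * gt
    # shared projection to the unified width d
    m$wp <- new_linear(cs[4], config$d)
    # bidirectional cross-modal fusion
    fc <- config$fusion_channels
    m$f_layers <- lapply(seq_len(config$n_fusion_layers), function(l) {
      din <- if (l == 1) config$d else fc[l - 1]
      list(trans = new_linear(din, fc[l]),
           wq = new_linear(fc[l], fc[l], bias = FALSE),
           wk = new_linear(fc[l], fc[l], bias = FALSE),
           wv = new_linear(fc[l], fc[l], bias = FALSE),
           lnv = new_layernorm(fc[l]),
           lna = new_layernorm(fc[l]))
    })
    df <- if (fusion) fc[config$n_fusion_layers] else config$d
    m$pool_dim <- df
    # heads
    m$clf_f <- new_linear(2 * df, config$n_classes)
    m$clf_v <- new_linear(df, config$n_classes)
    m$clf_a <- new_linear(df, config$n_classes)
    m$proj1 <- new_linear(df, df)
    m$proj2 <- new_linear(df, config$embed_dim)
    # interpreter heads (trained auxiliaries) and the fusion gate
    ir <- config$interp_reduce
    m$interp_v <- list(red = new_conv2d(1, config$d, ir, pad = 0),
                       d1 = new_deconv2d(4, ir, ir %/% 2),
                       d2 = new_deconv2d(4, ir %/% 2, ir %/% 4),
                       d3 = new_deconv2d(4, ir %/% 4, 1))
    m$interp_a <- list(red = new_conv2d(1, config$d, ir, pad = 0),
                       d1 = new_deconv2d(4, ir, ir %/% 2),
                       d2 = new_deconv2d(4, ir %/% 2, ir %/% 4),
                       d3 = new_deconv2d(4, ir %/% 4, 1))
    m$gate1 <- new_conv2d(1, 2, 16, pad = 0)
    m$gate2 <- new_conv2d(1, 16, 1, pad = 0)
    class(m) <- "avmodel"
    m
  })
}

model_layers <- function(model) collect_layers(unclass(model))

# rows of a batched token matrix belonging to sample b
tok_rows <- function(b, N) (b - 1L) * N + seq_len(N)

#' @keywords internal
visual_fw <- function(m, images) {
  B <- length(images)
  cfg <- m$config
  pc <- vector("list", B)
  toks <- vector("list", B)
  for (b in seq_len(B)) {
    f <- conv2d_fw(m$v_patch, images[[b]])
    pc[[b]] <- f$cache
    toks[[b]] <- matrix(f$y, prod(dim(f$y)[1:2]), dim(f$y)[3])
  }
  x <- do.call(rbind, toks)
  N <- m$grids[1]^2
  stage_caches <- vector("list", 4)
  merge_caches <- vector("list", 3)
  for (s in 1:4) {
    N <- m$grids[s]^2
    st <- m$v_stages[[s]]
    T <- st$ws^2
    p0 <- batch_perm(st$perm0, N, B)
    p1 <- batch_perm(st$perm1, N, B)
    b1 <- block_fw(st$blocks[[1]], x, p0, T)
    b2 <- block_fw(st$blocks[[2]], b1$y, p1, T)
    stage_caches[[s]] <- list(b1 = b1$cache, b2 = b2$cache, p0 = p0, p1 = p1, T = T, N = N)
    x <- b2$y
    if (s < 4) {
      mi <- m$v_merge_idx[[s]]
      I <- lapply(mi, batch_idx, N = N, B = B)
      x4 <- cbind(x[I$i1, , drop = FALSE], x[I$i2, , drop = FALSE],
                  x[I$i3, , drop = FALSE], x[I$i4, , drop = FALSE])
      mf <- lin_fw(m$v_merge[[s]], x4)
      merge_caches[[s]] <- list(c = mf$cache, I = I, N = N, C = ncol(x))
      x <- mf$y
    }
  }
  # decoder: 4x4 -> 8x8 per sample
  Nd <- m$grids[4]^2
  dec_caches <- vector("list", B)
  gcaches <- vector("list", B)
  outs <- vector("list", B)
  C4 <- cfg$stage_channels[4]
  for (b in seq_len(B)) {
    xa <- array(x[tok_rows(b, Nd), , drop = FALSE], c(m$grids[4], m$grids[4], C4))
    df <- deconv2d_fw(m$v_decoder, xa)
    gf <- gelu_fw(df$y)
    dec_caches[[b]] <- df$cache
    gcaches[[b]] <- gf$cache
    outs[[b]] <- matrix(gf$y, m$Nv, C4)
  }
  y <- do.call(rbind, outs)
  list(y = y, cache = list(pc = pc, stages = stage_caches, merges = merge_caches,
                           dec = dec_caches, gelu = gcaches, B = B))
}

#' @keywords internal
visual_bw <- function(m, dy, c) {
  B <- c$B
  C4 <- m$config$stage_channels[4]
  dx <- matrix(0, B * m$grids[4]^2, C4)
  side <- 2L * m$grids[4]
  for (b in seq_len(B)) {
    dg <- gelu_bw(array(dy[tok_rows(b, m$Nv), , drop = FALSE], c(side, side, C4)),
                  c$gelu[[b]])
    dxa <- deconv2d_bw(m$v_decoder, dg, c$dec[[b]])
    dx[tok_rows(b, m$grids[4]^2), ] <- matrix(dxa, m$grids[4]^2, C4)
  }
  for (s in 4:1) {
    if (s < 4) {
      mc <- c$merges[[s]]
      dx4 <- lin_bw(m$v_merge[[s]], dx, mc$c)
      C <- mc$C
      dprev <- matrix(0, B * mc$N, C)
      dprev[mc$I$i1, ] <- dx4[, 1:C]
      dprev[mc$I$i2, ] <- dx4[, C + 1:C]
      dprev[mc$I$i3, ] <- dx4[, 2 * C + 1:C]
      dprev[mc$I$i4, ] <- dx4[, 3 * C + 1:C]
      dx <- dprev
    }
    sc <- c$stages[[s]]
    st <- m$v_stages[[s]]
    dx <- block_bw(st$blocks[[2]], dx, sc$b2)
    dx <- block_bw(st$blocks[[1]], dx, sc$b1)
  }
  N1 <- m$grids[1]^2
  for (b in seq_len(B)) {
    dtok <- dx[tok_rows(b, N1), , drop = FALSE]
    conv2d_bw(m$v_patch, array(dtok, c(m$grids[1], m$grids[1], ncol(dtok))), c$pc[[b]])
  }
  invisible(NULL)
}

#' @keywords internal
acoustic_fw <- function(m, mels) {
  B <- length(mels)
  sc <- vector("list", B)
  gc <- vector("list", B)
  toks <- vector("list", B)
  for (b in seq_len(B)) {
    f <- conv2d_fw(m$a_stem, array(mels[[b]], c(dim(mels[[b]]), 1)))
    g <- gelu_fw(f$y)
    sc[[b]] <- f$cache
    gc[[b]] <- g$cache
    toks[[b]] <- matrix(g$y[m$a_patch_idx], nrow(m$a_patch_idx), ncol(m$a_patch_idx))
  }
  x0 <- do.call(rbind, toks)
  ef <- lin_fw(m$a_embed, x0)
  N <- m$a_ntok
  x <- ef$y + m$a_pe[rep(seq_len(N), B), , drop = FALSE]
  perm <- batch_perm(seq_len(N), N, B)
  layer_caches <- vector("list", 4)
  for (l in 1:4) {
    la <- m$a_layers[[l]]
    tc <- NULL
    if (!is.null(la$trans)) {
      tf <- lin_fw(la$trans, x)
      tc <- tf$cache
      x <- tf$y
    }
    bf <- block_fw(la$block, x, perm, N)
    layer_caches[[l]] <- list(t = tc, b = bf$cache)
    x <- bf$y
  }
  list(y = x, cache = list(stem = sc, gelu = gc, embed = ef$cache,
                           layers = layer_caches, perm = perm, B = B))
}

#' @keywords internal
acoustic_bw <- function(m, dy, c, want_dmel = FALSE) {
  B <- c$B
  dx <- dy
  for (l in 4:1) {
    lc <- c$layers[[l]]
    la <- m$a_layers[[l]]
    dx <- block_bw(la$block, dx, lc$b)
    if (!is.null(la$trans)) dx <- lin_bw(la$trans, dx, lc$t)
  }
  dx0 <- lin_bw(m$a_embed, dx, c$embed)
  dmels <- if (want_dmel) vector("list", B) else NULL
  N <- m$a_ntok
  cfg <- m$config
  for (b in seq_len(B)) {
    dtok <- dx0[tok_rows(b, N), , drop = FALSE]
    dstem_out <- array(0, c(cfg$mel_bins, cfg$mel_frames, cfg$stem_channels))
    dstem_out[as.vector(m$a_patch_idx)] <- as.vector(dtok)
    dg <- gelu_bw(dstem_out, c$gelu[[b]])
    dmel <- conv2d_bw(m$a_stem, dg, c$stem[[b]])
    if (want_dmel) dmels[[b]] <- dmel[, , 1]
  }
  dmels
}

l2norm_fw <- function(x) {
  n <- sqrt(rowSums(x * x))
  if (any(n < 1e-12)) stop("degenerate embedding: zero norm before normalization")
  list(y = x / n, cache = list(y = x / n, n = n))
}

l2norm_bw <- function(dy, c) {
  (dy - c$y * rowSums(dy * c$y)) / c$n
}

#' Full model forward pass
#'
#' @param m an `avmodel`
#' @param images list of H x W x 3 arrays (batch)
#' @param mels list of F x T mel-spectrogram matrices
#' @param mode classification head: "fused", "visual" or "acoustic"
#' @return list with `logits`, unit-norm `zm`/`zv`/`za` embeddings, pooled
#'   features, projected token maps `Fv`/`Fa`, per-layer attention weights and
#'   the cache needed by [model_backward()]
#' @export
model_forward <- function(m, images, mels, mode = "fused") {
  B <- length(images)
  vf <- visual_fw(m, images)
  af <- acoustic_fw(m, mels)
  pvf <- lin_fw(m$wp, vf$y) # shared projection, two caches
  paf <- lin_fw(m$wp, af$y)
  V <- pvf$y; A <- paf$y
  Fv <- V; Fa <- A
  Nv <- m$Nv; Na <- m$a_ntok
  fcaches <- NULL
  P_va <- P_av <- NULL
  if (m$fusion) {
    fcaches <- vector("list", length(m$f_layers))
    for (l in seq_along(m$f_layers)) {
      fl <- m$f_layers[[l]]
      tv <- lin_fw(fl$trans, V); ta <- lin_fw(fl$trans, A)
      Vt <- tv$y; At <- ta$y
      qv <- lin_fw(fl$wq, Vt); kv <- lin_fw(fl$wk, Vt); vv <- lin_fw(fl$wv, Vt)
      qa <- lin_fw(fl$wq, At); ka <- lin_fw(fl$wk, At); va <- lin_fw(fl$wv, At)
      cl <- ncol(Vt)
      arr <- function(x, T) split_heads(x, T, B, 1L)
      at_va <- attn_fw(arr(qv$y, Nv), arr(ka$y, Na), arr(va$y, Na))
      at_av <- attn_fw(arr(qa$y, Na), arr(kv$y, Nv), arr(vv$y, Nv))
      Ova <- merge_heads(at_va$O, Nv, B, 1L)
      Oav <- merge_heads(at_av$O, Na, B, 1L)
      lv <- ln_fw(fl$lnv, Vt + Ova)
      la <- ln_fw(fl$lna, At + Oav)
      fcaches[[l]] <- list(tv = tv$cache, ta = ta$cache, qv = qv$cache,
                           kv = kv$cache, vv = vv$cache, qa = qa$cache,
                           ka = ka$cache, va = va$cache, at_va = at_va$cache,
                           at_av = at_av$cache, lv = lv$cache, la = la$cache)
      V <- lv$y; A <- la$y
      if (l == length(m$f_layers)) { P_va <- at_va$P; P_av <- at_av$P }
    }
  }
  # mean-pool tokens per sample
  pool <- function(X, N) {
    t(vapply(seq_len(B), function(b) colMeans(X[tok_rows(b, N), , drop = FALSE]),
             numeric(ncol(X))))
  }
  zv_pool <- pool(V, Nv)
  za_pool <- pool(A, Na)
  # classification head
  logits <- switch(mode,
    fused = lin_fw(m$clf_f, cbind(zv_pool, za_pool)),
    visual = lin_fw(m$clf_v, zv_pool),
    acoustic = lin_fw(m$clf_a, za_pool))
  # contrastive projection head (shared across modalities)
  p1v <- lin_fw(m$proj1, zv_pool); g1v <- gelu_fw(p1v$y)
  p2v <- lin_fw(m$proj2, g1v$y);  nv <- l2norm_fw(p2v$y)
  p1a <- lin_fw(m$proj1, za_pool); g1a <- gelu_fw(p1a$y)
  p2a <- lin_fw(m$proj2, g1a$y);  na <- l2norm_fw(p2a$y)
  zmid <- (nv$y + na$y) / 2
  nm <- l2norm_fw(zmid)
  list(logits = logits$y, zm = nm$y, zv = nv$y, za = na$y,
       zv_pool = zv_pool, za_pool = za_pool,
       Fv = Fv, Fa = Fa, Vtok = V, Atok = A, P_va = P_va, P_av = P_av,
       B = B, Nv = Nv, Na = Na, mode = mode,
       cache = list(vf = vf$cache, af = af$cache, pv = pvf$cache, pa = paf$cache,
                    f = fcaches, clf = logits$cache,
                    p1v = p1v$cache, g1v = g1v$cache, p2v = p2v$cache, nv = nv$cache,
                    p1a = p1a$cache, g1a = g1a$cache, p2a = p2a$cache, na = na$cache,
                    nm = nm$cache))
}

#' Full model backward pass
#'
#' Propagates loss gradients injected at the output nodes back through the
#' network, accumulating parameter gradients. Gradient injections: `dlogits`
#' (classification loss), `dzm` (contrastive losses, on the unit-norm joint
#' embedding), `dFv` (gating regularizer on the projected visual map), and
#' `dP_av` (explanation-attention alignment, on the final fusion layer's
#' acoustic-to-visual attention weights).
#'
#' @param m an `avmodel`
#' @param out result of [model_forward()]
#' @param dlogits,dzm,dFv,dP_av optional gradient injections
#' @param want_dmel if TRUE, per-sample gradients w.r.t. the mel-spectrogram
#'   inputs are returned (integrated gradients needs them)
#' @param want_dfeat if TRUE, the gradients at the projected visual/acoustic
#'   token maps are returned (class-activation mapping needs them)
#' @return list with `dmels`, `dFv`, `dFa` (NULL unless requested)
#' @export
model_backward <- function(m, out, dlogits = NULL, dzm = NULL, dFv = NULL,
                           dP_av = NULL, want_dmel = FALSE, want_dfeat = FALSE) {
  B <- out$B; Nv <- out$Nv; Na <- out$Na
  c <- out$cache
  df <- m$pool_dim
  dzv_pool <- matrix(0, B, df)
  dza_pool <- matrix(0, B, df)
  if (!is.null(dlogits)) {
    if (out$mode == "fused") {
      dcat <- lin_bw(m$clf_f, dlogits, c$clf)
      dzv_pool <- dzv_pool + dcat[, 1:df, drop = FALSE]
      dza_pool <- dza_pool + dcat[, df + 1:df, drop = FALSE]
    } else if (out$mode == "visual") {
      dzv_pool <- dzv_pool + lin_bw(m$clf_v, dlogits, c$clf)
    } else {
      dza_pool <- dza_pool + lin_bw(m$clf_a, dlogits, c$clf)
    }
  }
  if (!is.null(dzm)) {
    dmid <- l2norm_bw(dzm, c$nm)
    dnv <- dmid / 2; dna <- dmid / 2
    d2v <- l2norm_bw(dnv, c$nv)
    d2a <- l2norm_bw(dna, c$na)
    dg1v <- lin_bw(m$proj2, d2v, c$p2v)
    dg1a <- lin_bw(m$proj2, d2a, c$p2a)
    dzv_pool <- dzv_pool + lin_bw(m$proj1, gelu_bw(dg1v, c$g1v), c$p1v)
    dza_pool <- dza_pool + lin_bw(m$proj1, gelu_bw(dg1a, c$g1a), c$p1a)
  }
  # un-pool: each token receives grad / N
  dV <- matrix(0, B * Nv, df)
  dA <- matrix(0, B * Na, df)
  for (b in seq_len(B)) {
    dV[tok_rows(b, Nv), ] <- matrix(dzv_pool[b, ] / Nv, Nv, df, byrow = TRUE)
    dA[tok_rows(b, Na), ] <- matrix(dza_pool[b, ] / Na, Na, df, byrow = TRUE)
  }
  if (m$fusion) {
    for (l in rev(seq_along(m$f_layers))) {
      fl <- m$f_layers[[l]]
      fc <- c$f[[l]]
      dlv <- ln_bw(fl$lnv, dV, fc$lv)
      dla <- ln_bw(fl$lna, dA, fc$la)
      dVt <- dlv; dAt <- dla
      arr <- function(x, T) split_heads(x, T, B, 1L)
      bwa_va <- attn_bw(arr(dlv, Nv), fc$at_va)
      bwa_av <- attn_bw(arr(dla, Na), fc$at_av,
                        dP_extra = if (l == length(m$f_layers)) dP_av else NULL)
      mh <- function(A, T) merge_heads(A, T, B, 1L)
      dVt <- dVt + lin_bw(fl$wq, mh(bwa_va$dQ, Nv), fc$qv) +
                   lin_bw(fl$wk, mh(bwa_av$dK, Nv), fc$kv) +
                   lin_bw(fl$wv, mh(bwa_av$dV, Nv), fc$vv)
      dAt <- dAt + lin_bw(fl$wq, mh(bwa_av$dQ, Na), fc$qa) +
                   lin_bw(fl$wk, mh(bwa_va$dK, Na), fc$ka) +
                   lin_bw(fl$wv, mh(bwa_va$dV, Na), fc$va)
      dV <- lin_bw(fl$trans, dVt, fc$tv)
      dA <- lin_bw(fl$trans, dAt, fc$ta)
    }
  }
  dFv_out <- if (want_dfeat) dV else NULL # grad at the projected maps,
  dFa_out <- if (want_dfeat) dA else NULL # before external injections
  if (!is.null(dFv)) dV <- dV + dFv
  dy_v <- lin_bw(m$wp, dV, c$pv)
  dy_a <- lin_bw(m$wp, dA, c$pa)
  visual_bw(m, dy_v, c$vf)
  dmels <- acoustic_bw(m, dy_a, c$af, want_dmel = want_dmel)
  list(dmels = dmels, dFv = dFv_out, dFa = dFa_out)
}

#' Save / load model checkpoints
#'
#' A checkpoint is a single RDS file containing the configuration, the fusion
#' flag, all weights and (by default) the AdamW moment estimates, so that
#' training resumed from a checkpoint reproduces the next optimization step;
#' [load_checkpoint()] rebuilds the model and restores the state.
#'
#' @param m an `avmodel`
#' @param path file path
#' @param optimizer_state include AdamW moments for exact resumption
#' @return `path` / the restored model
#' @export
save_checkpoint <- function(m, path, optimizer_state = TRUE) {
  saveRDS(list(config = m$config, fusion = m$fusion,
               weights = dump_weights(model_layers(m), optimizer = optimizer_state)),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  m <- build_model(ck$config, seed = 0, fusion = ck$fusion)
  load_weights(model_layers(m), ck$weights)
  m
}
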