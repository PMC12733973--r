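# Dual-modality explainability: gradient-based saliency (Grad-CAM,
# Grad-CAM++, integrated gradients), trained interpreter upsampling heads,
# learned gated fusion of the two saliency maps, and the explanation losses
# (total variation, explanation-attention KL alignment, class gating).

#' Explainability configuration
#'
#' @param ig_steps integration steps for integrated gradients (>= 8)
#' @param ig_baseline "zeros" or "mean" (mean-spectrogram baseline)
#' @param mu1,mu2,mu3 weights of the TV, alignment and gating terms
#' @param tv "anisotropic" (l1 of forward differences, default) or
#'   "isotropic" (l2 gradient magnitude)
#' @return an `xai_config` list
#' @export
xai_config <- function(ig_steps = 32, ig_baseline = c("zeros", "mean"),
                       mu1 = 0.1, mu2 = 0.1, mu3 = 0.01,
                       tv = c("anisotropic", "isotropic")) {
  if (ig_steps < 8) stop("invalid config: ig_steps must be >= 8")
  if (any(c(mu1, mu2, mu3) < 0)) stop("invalid config: negative mu weight")
  structure(list(ig_steps = as.integer(ig_steps),
                 ig_baseline = match.arg(ig_baseline),
                 mu1 = mu1, mu2 = mu2, mu3 = mu3, tv = match.arg(tv)),
            class = "xai_config")
}

#' Min-max normalization of a saliency map to \[0,1\]
#' @param x numeric matrix
#' @return normalized matrix (all-zero if constant)
#' @export
normalize01 <- function(x) {
  r <- range(x)
  if (r[2] - r[1] < 1e-12) return(x * 0)
  (x - r[1]) / (r[2] - r[1])
}

#' Bilinear resize of a matrix
#' @param mat input matrix
#' @param H,W output dimensions
#' @return resized matrix
#' @export
resize_bilinear <- function(mat, H, W) {
  xs <- seq(1, nrow(mat), length.out = H)
  ys <- seq(1, ncol(mat), length.out = W)
  xi <- matrix(rep(xs, W), H, W)
  yi <- matrix(rep(ys, each = H), H, W)
  bilinear_at(mat, xi, yi)
}

new_heatmap <- function(grid, modality, class_id = NA_integer_) {
  structure(grid, class = "heatmap", modality = modality, class_id = class_id)
}

#' Grad-CAM class activation map
#'
#' Channel weights are the spatially averaged gradients
#' `alpha_k = (1/Z) sum_ij d y_c / d A_ijk`; the map is
#' `ReLU(sum_k alpha_k A_k)`, min-max normalized and upsampled.
#'
#' @param features h x w x C activation array A
#' @param grads array of the same shape: gradient of the class logit w.r.t. A
#' @param size output resolution
#' @param class_id class the gradients were taken for (metadata)
#' @return a `heatmap` (size x size, values in \[0,1\])
#' @export
gradcam <- function(features, grads, size = 64, class_id = NA_integer_) {
  stopifnot(all(dim(features) == dim(grads)))
  alpha <- apply(grads, 3, mean)
  if (all(alpha == 0)) warning("all-zero gradients: empty class activation map")
  cam <- matrix(0, dim(features)[1], dim(features)[2])
  for (k in seq_along(alpha)) cam <- cam + alpha[k] * features[, , k]
  cam <- pmax(cam, 0)
  new_heatmap(normalize01(resize_bilinear(cam, size, size)), "visual", class_id)
}

# spatially summed Grad-CAM channel weights (exposed for oracle tests)
gradcam_weights <- function(grads) apply(grads, 3, mean)

#' Grad-CAM++ class activation map
#'
#' Default form is the standard Grad-CAM++ closed form under the
#' exponential-logit surrogate: with g the logit gradient, per-pixel weights
#' `alpha = g^2 / (2 g^2 + sum_ij(A) * g^3)` (stabilized denominator; weight 0
#' where the denominator vanishes) and channel weights
#' `w_k = sum_ij alpha * ReLU(g)`. `verbatim = TRUE` instead uses the printed
#' second/third-derivative ratio with spatially summed numerator and
#' denominator and no ReLU-gradient factor.
#'
#' @inheritParams gradcam
#' @param verbatim use the printed ratio form
#' @return a `heatmap`
#' @export
gradcam_pp <- function(features, grads, size = 64, class_id = NA_integer_,
                       verbatim = FALSE) {
  stopifnot(all(dim(features) == dim(grads)))
  C <- dim(features)[3]
  sumA <- apply(features, 3, sum)
  cam <- matrix(0, dim(features)[1], dim(features)[2])
  for (k in seq_len(C)) {
    g <- grads[, , k]
    g2 <- g * g; g3 <- g2 * g
    if (verbatim) {
      den <- 2 * sum(g2) + sumA[k] * sum(g3)
      wk <- if (abs(den) < 1e-8) 0 else sum(g2) / den
    } else {
      den <- 2 * g2 + sumA[k] * g3
      alpha <- ifelse(abs(den) < 1e-8, 0, g2 / (den + 1e-8))
      wk <- sum(alpha * pmax(g, 0))
    }
    cam <- cam + wk * features[, , k]
  }
  cam <- pmax(cam, 0)
  new_heatmap(normalize01(resize_bilinear(cam, size, size)), "visual", class_id)
}

#' Second and third derivatives under the exponential-logit surrogate
#'
#' For `y = exp(s)` with `ds/dA = g` (and s locally linear in A),
#' `d2y/dA2 = g^2 exp(s)` and `d3y/dA3 = g^3 exp(s)`. Exposed so the
#' derivative-ratio form of Grad-CAM++ can be verified symbolically.
#'
#' @param g gradient of the pre-exponential logit s w.r.t. the activations
#' @param s scalar logit value
#' @return list with `d2` and `d3` arrays
#' @export
exp_surrogate_derivs <- function(g, s) {
  list(d2 = g^2 * exp(s), d3 = g^3 * exp(s))
}

#' Integrated gradients (generic)
#'
#' Midpoint Riemann approximation of the path integral from `baseline` to `S`
#' of the model gradient, multiplied elementwise by `(S - baseline)`. The
#' completeness residual `|sum(attributions) - (f(S) - f(baseline))|` is
#' reported.
#'
#' @param f function taking an input like `S` and returning
#'   `list(value, grad)` for the target class logit
#' @param S input (matrix)
#' @param baseline same shape as `S`
#' @param steps number of integration points
#' @param size output heatmap resolution
#' @return list with `heatmap` (abs attributions, normalized, resized),
#'   `attributions` (raw, shape of S), `residual`, `delta` (f(S)-f(baseline))
#' @export
integrated_gradients <- function(f, S, baseline = NULL, steps = 32, size = 64) {
  if (is.null(baseline)) baseline <- S * 0
  if (!all(dim(S) == dim(baseline))) stop("invalid input: baseline shape mismatch")
  diff <- S - baseline
  acc <- S * 0
  for (k in seq_len(steps)) {
    a <- (k - 0.5) / steps
    acc <- acc + f(baseline + a * diff)$grad
  }
  attributions <- diff * acc / steps
  delta <- f(S)$value - f(baseline)$value
  residual <- abs(sum(attributions) - delta)
  hm <- new_heatmap(normalize01(resize_bilinear(abs(attributions), size, size)),
                    "acoustic")
  list(heatmap = hm, attributions = attributions, residual = residual,
       delta = delta)
}

#' Integrated gradients of a model class logit w.r.t. the mel-spectrogram
#'
#' Path points are evaluated in one batched forward/backward pass (the image
#' is held fixed).
#'
#' @param m an `avmodel`
#' @param image H x W x 3 array
#' @param mel F x T mel-spectrogram
#' @param class_id 0-based class
#' @param steps integration points
#' @param baseline "zeros" or "mean"
#' @param mode classification head used for the logit
#' @return as [integrated_gradients()]
#' @export
model_ig <- function(m, image, mel, class_id, steps = 32,
                     baseline = c("zeros", "mean"), mode = "fused") {
  baseline <- match.arg(baseline)
  S0 <- if (baseline == "zeros") mel * 0 else mel * 0 + mean(mel)
  diff <- mel - S0
  alphas <- (seq_len(steps) - 0.5) / steps
  mels <- lapply(alphas, function(a) S0 + a * diff)
  images <- rep(list(image), steps)
  out <- model_forward(m, images, mels, mode = mode)
  onehot <- matrix(0, steps, ncol(out$logits))
  onehot[, class_id + 1] <- 1
  bk <- model_backward(m, out, dlogits = onehot, want_dmel = TRUE)
  acc <- Reduce(`+`, bk$dmels)
  attributions <- diff * acc / steps
  out_ends <- model_forward(m, list(image, image), list(mel, S0), mode = mode)
  delta <- out_ends$logits[1, class_id + 1] - out_ends$logits[2, class_id + 1]
  residual <- abs(sum(attributions) - delta)
  hm <- new_heatmap(normalize01(resize_bilinear(abs(attributions), 64, 64)),
                    "acoustic", class_id)
  list(heatmap = hm, attributions = attributions, residual = residual,
       delta = delta)
}

#' Grad-CAM / Grad-CAM++ saliency from a model
#'
#' Runs one forward pass, backpropagates the chosen class logit to the
#' projected token map of the requested modality and applies the CAM
#' weighting.
#'
#' @param m an `avmodel`
#' @param image,mel one input pair
#' @param class_id 0-based class
#' @param method "gradcam" or "gradcam++"
#' @param modality "visual" or "acoustic"
#' @param mode classification head
#' @return a `heatmap`
#' @export
model_saliency <- function(m, image, mel, class_id,
                           method = c("gradcam++", "gradcam"),
                           modality = c("visual", "acoustic"), mode = "fused") {
  method <- match.arg(method)
  modality <- match.arg(modality)
  out <- model_forward(m, list(image), list(mel), mode = mode)
  onehot <- matrix(0, 1, ncol(out$logits))
  onehot[1, class_id + 1] <- 1
  bk <- model_backward(m, out, dlogits = onehot, want_dfeat = TRUE)
  if (modality == "visual") {
    side <- 2L * m$grids[4]
    A <- array(out$Fv, c(side, side, ncol(out$Fv)))
    dA <- array(bk$dFv, c(side, side, ncol(out$Fv)))
  } else {
    gf <- m$config$acoustic_grid[1]; gt <- m$config$acoustic_grid[2]
    A <- array(out$Fa, c(gf, gt, ncol(out$Fa)))
    dA <- array(bk$dFa, c(gf, gt, ncol(out$Fa)))
  }
  hm <- if (method == "gradcam") gradcam(A, dA, class_id = class_id)
        else gradcam_pp(A, dA, class_id = class_id)
  attr(hm, "modality") <- modality
  hm
}

# ---- interpreter upsampling heads -------------------------------------------

interp_net <- function(m, modality) if (modality == "visual") m$interp_v else m$interp_a

#' Interpreter head: feature map to 64 x 64 saliency
#'
#' 1x1 channel reduction followed by three stride-2 transposed convolutions
#' (GELU between), then integer block upsampling to 64 x 64 where the token
#' grid is not square (the 8 x 4 acoustic grid reaches 64 x 32 after three
#' doublings and is width-doubled at the end).
#'
#' @param m an `avmodel`
#' @param featmap h x w x d feature array (projected token map)
#' @param modality "visual" or "acoustic"
#' @return list with `map` (64 x 64) and `cache` for training
#' @export
interp_head <- function(m, featmap, modality = c("visual", "acoustic")) {
  modality <- match.arg(modality)
  net <- interp_net(m, modality)
  if (dim(featmap)[3] != net$red$cin) stop("invalid input: wrong channel width")
  r <- conv2d_fw(net$red, featmap)
  a0 <- gelu_fw(r$y)
  d1 <- deconv2d_fw(net$d1, a0$y); a1 <- gelu_fw(d1$y)
  d2 <- deconv2d_fw(net$d2, a1$y); a2 <- gelu_fw(d2$y)
  d3 <- deconv2d_fw(net$d3, a2$y)
  mp <- d3$y[, , 1]
  fh <- 64L %/% nrow(mp); fw <- 64L %/% ncol(mp)
  map <- if (fh > 1 || fw > 1) block_up(mp, fh, fw) else mp
  list(map = map,
       cache = list(r = r$cache, a0 = a0$cache, d1 = d1$cache, a1 = a1$cache,
                    d2 = d2$cache, a2 = a2$cache, d3 = d3$cache,
                    fh = fh, fw = fw, hw = dim(mp)))
}

# L2 regression of the interpreter head onto a detached saliency target;
# accumulates head parameter gradients, returns the scalar loss
interp_head_train <- function(m, featmap, target, modality) {
  fw <- interp_head(m, featmap, modality)
  diffm <- fw$map - target
  loss <- mean(diffm^2)
  dmap <- 2 * diffm / length(diffm)
  c <- fw$cache
  dmp <- if (c$fh > 1 || c$fw > 1) block_up_adj(dmap, c$fh, c$fw) else dmap
  net <- interp_net(m, modality)
  dd3 <- array(dmp, c(c$hw, 1))
  d2g <- deconv2d_bw(net$d3, dd3, c$d3)
  d2g <- gelu_bw(d2g, c$a2)
  d1g <- deconv2d_bw(net$d2, d2g, c$d2)
  d1g <- gelu_bw(d1g, c$a1)
  d0g <- deconv2d_bw(net$d1, d1g, c$d1)
  d0g <- gelu_bw(d0g, c$a0)
  conv2d_bw(net$red, d0g, c$r) # input grad discarded: features are detached
  loss
}

# ---- gated fusion ------------------------------------------------------------

#' Learned gated fusion of the two saliency maps
#'
#' `G = sigmoid(conv1x1(GELU(conv1x1([Hv, Ha]))))` per pixel (2 -> 16 -> 1),
#' `Hc = G * Hv + (1 - G) * Ha`. Since `G` lies in \[0,1\], `Hc` is pointwise
#' bounded between `min(Hv, Ha)` and `max(Hv, Ha)`. Inputs outside \[0,1\] are
#' min-max normalized with a warning.
#'
#' @param m an `avmodel`
#' @param Hv,Ha 64 x 64 saliency maps in \[0,1\]
#' @return list with `Hc`, `G` and a `cache` for gate training
#' @export
gated_fuse <- function(m, Hv, Ha) {
  fix <- function(H, nm) {
    if (min(H) < 0 || max(H) > 1) {
      warning(nm, " not normalized to [0,1]; applying min-max normalization")
      normalize01(H)
    } else H
  }
  Hv <- fix(Hv, "Hv"); Ha <- fix(Ha, "Ha")
  U <- array(c(Hv, Ha), c(dim(Hv), 2))
  c1 <- conv2d_fw(m$gate1, U)
  a1 <- gelu_fw(c1$y)
  c2 <- conv2d_fw(m$gate2, a1$y)
  sg <- sigmoid_fw(c2$y[, , 1])
  G <- sg$y
  Hc <- G * Hv + (1 - G) * Ha
  list(Hc = Hc, G = G,
       cache = list(c1 = c1$cache, a1 = a1$cache, c2 = c2$cache, sg = sg$cache,
                    Hv = Hv, Ha = Ha))
}

# backward for the gate network: dHc (and optional direct dG) -> parameter
# gradients; the saliency inputs are detached
gate_bw <- function(m, dHc, cache, dG_extra = NULL) {
  dG <- dHc * (cache$Hv - cache$Ha)
  if (!is.null(dG_extra)) dG <- dG + dG_extra
  ds <- sigmoid_bw(dG, cache$sg)
  dc2 <- array(ds, c(dim(ds), 1))
  da1 <- conv2d_bw(m$gate2, dc2, cache$c2)
  dc1 <- gelu_bw(da1, cache$a1)
  conv2d_bw(m$gate1, dc1, cache$c1)
  invisible(NULL)
}

#' Fixed-weight saliency fusion (non-learned baseline)
#'
#' `beta * Hv + (1 - beta) * Ha` with `beta` in \[0,1\].
#'
#' @param Hv,Ha saliency maps
#' @param beta modality weight
#' @return fused map
#' @export
fixed_beta_fuse <- function(Hv, Ha, beta) {
  if (beta < 0 || beta > 1) stop("invalid config: beta outside [0,1]")
  beta * Hv + (1 - beta) * Ha
}

# ---- explanation losses ------------------------------------------------------

#' Total variation of a saliency map
#'
#' Anisotropic (default): sum of absolute forward differences along both
#' axes. Isotropic: sum of the l2 gradient magnitude. Returns the value and
#' the gradient w.r.t. the map.
#'
#' @param H saliency matrix
#' @param type "anisotropic" or "isotropic"
#' @return list with `value` and `grad`
#' @export
tv_loss <- function(H, type = c("anisotropic", "isotropic")) {
  type <- match.arg(type)
  h <- nrow(H); w <- ncol(H)
  dx <- H[-1, , drop = FALSE] - H[-h, , drop = FALSE]
  dy <- H[, -1, drop = FALSE] - H[, -w, drop = FALSE]
  g <- H * 0
  if (type == "anisotropic") {
    value <- sum(abs(dx)) + sum(abs(dy))
    sx <- sign(dx); sy <- sign(dy)
    g[-1, ] <- g[-1, ] + sx; g[-h, ] <- g[-h, ] - sx
    g[, -1] <- g[, -1] + sy; g[, -w] <- g[, -w] - sy
  } else {
    dxc <- dx[, -w, drop = FALSE]; dyc <- dy[-h, , drop = FALSE]
    mag <- sqrt(dxc^2 + dyc^2 + 1e-12)
    value <- sum(mag)
    gx <- dxc / mag; gy <- dyc / mag
    g[-1, -w] <- g[-1, -w] + gx; g[-h, -w] <- g[-h, -w] - gx
    g[-h, -1] <- g[-h, -1] + gy; g[-h, -w] <- g[-h, -w] - gy
  }
  list(value = value, grad = g)
}

#' KL alignment between a heatmap and the attention marginal
#'
#' Both maps are softmax-normalized over flattened pixels; returns
#' `KL(H_tilde || M_tilde)` (non-negative, zero iff the normalized maps are
#' equal) and gradients w.r.t. both raw maps.
#'
#' @param H,M same-shape matrices
#' @return list with `value`, `dH`, `dM`
#' @export
kl_heatmap <- function(H, M) {
  sm <- function(x) {
    e <- exp(x - max(x))
    e / sum(e)
  }
  p <- sm(H); q <- sm(M)
  value <- sum(p * (log(p) - log(q)))
  gh <- log(p) - log(q)
  dH <- p * (gh - sum(gh * p))
  dM <- q - p
  list(value = value, dH = matrix(dH, nrow(H)), dM = matrix(dM, nrow(H)))
}

#' Combined explanation loss
#'
#' `L_xai = mu1 * TV(Hc) + mu2 * KL(softmax(Hc) || softmax(Mc)) + mu3 *
#' ||F - Pi_c * F||^2`. Gradients are returned for the fused map, the
#' attention marginal and the feature map.
#'
#' @param Hc fused 64 x 64 explanation map
#' @param Mc attention marginal (same shape)
#' @param features feature array F (h x w x C)
#' @param mask binary class mask Pi_c (h x w), broadcast over channels
#' @param config an [xai_config()]
#' @return list with `value`, `components`, `dHc`, `dMc`, `dF`
#' @export
loss_xai <- function(Hc, Mc, features, mask, config = xai_config()) {
  tv <- tv_loss(Hc, config$tv)
  kl <- kl_heatmap(Hc, Mc)
  keep <- array(rep(mask, dim(features)[3]), dim(features))
  resid <- features - keep * features
  rgate <- sum(resid^2)
  value <- config$mu1 * tv$value + config$mu2 * kl$value + config$mu3 * rgate
  list(value = value,
       components = c(tv = tv$value, align = kl$value, gate = rgate),
       dHc = config$mu1 * tv$grad + config$mu2 * kl$dH,
       dMc = config$mu2 * kl$dM,
       dF = config$mu3 * 2 * resid)
}

# ---- end-to-end explanation --------------------------------------------------

#' Explain one aligned pair
#'
#' Algorithm: one forward pass; Grad-CAM++ on the projected visual map and
#' integrated gradients on the mel-spectrogram for the chosen class;
#' interpreter-head maps for both modalities; learned gated fusion; attention
#' marginal of the final fusion layer.
#'
#' @param m an `avmodel`
#' @param pair aligned pair (needs `image`, `melspec`)
#' @param class_id 0-based class; the predicted class if NULL
#' @param config an [xai_config()]
#' @return list with `Hv`, `Ha`, `Hv_up`, `Ha_up`, `Hc`, `G`, `Mc`,
#'   `class_id`, `prob`
#' @export
explain_pair <- function(m, pair, class_id = NULL, config = xai_config()) {
  out <- model_forward(m, list(pair$image), list(pair$melspec))
  prob <- exp(out$logits[1, ] - max(out$logits[1, ]))
  prob <- prob / sum(prob)
  if (is.null(class_id)) class_id <- which.max(prob) - 1L
  onehot <- matrix(0, 1, ncol(out$logits))
  onehot[1, class_id + 1] <- 1
  bk <- model_backward(m, out, dlogits = onehot, want_dfeat = TRUE)
  side <- 2L * m$grids[4]
  d <- ncol(out$Fv)
  Av <- array(out$Fv, c(side, side, d))
  dAv <- array(bk$dFv, c(side, side, d))
  Hv <- gradcam_pp(Av, dAv, class_id = class_id)
  ig <- model_ig(m, pair$image, pair$melspec, class_id,
                 steps = config$ig_steps, baseline = config$ig_baseline)
  Ha <- ig$heatmap
  gf <- m$config$acoustic_grid[1]; gt <- m$config$acoustic_grid[2]
  Aa <- array(out$Fa, c(gf, gt, d))
  Hv_up <- interp_head(m, Av, "visual")$map
  Ha_up <- interp_head(m, Aa, "acoustic")$map
  fuse <- gated_fuse(m, unclass(Hv), unclass(Ha))
  Mc <- if (!is.null(out$P_av)) attention_marginal(out$P_av, grid = c(side, side))
        else NULL
  list(Hv = Hv, Ha = Ha, Hv_up = Hv_up, Ha_up = Ha_up,
       Hc = new_heatmap(fuse$Hc, "fused", class_id), G = fuse$G, Mc = Mc,
       class_id = class_id, prob = prob, ig_residual = ig$residual)
}

#' Write a saliency overlay PNG
#'
#' Alpha-blends the heatmap (red channel) over a grayscale rendering of the
#' image or spectrogram.
#'
#' @param base H x W x 3 image in \[0,1\] or a F x T spectrogram matrix
#' @param H saliency map (resized to the base resolution)
#' @param path output PNG path
#' @return `path`, invisibly
#' @export
write_overlay <- function(base, H, path) {
  if (length(dim(base)) == 2) {
    g <- normalize01(base)
    base <- array(rep(g, 3), c(dim(g), 3))
  }
  hh <- resize_bilinear(unclass(H), dim(base)[1], dim(base)[2])
  out <- base * 0.55
  out[, , 1] <- pmin(1, out[, , 1] + 0.45 * hh)
  png::writePNG(out, path)
  invisible(path)
}
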