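# Explainability module: CAM closed forms, integrated-gradients axioms,
# interpreter heads, gated fusion bounds and the explanation losses.

test_that("Grad-CAM weights follow the linear-model closed form", {
  set.seed(1)
  A <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  wk <- c(0.5, -1, 2)
  # y = sum_k wk * mean(A_k): gradient w.r.t. A_ijk is wk / Z
  grads <- array(rep(wk / 16, each = 16), c(4, 4, 3))
  alpha <- duetnet:::gradcam_weights(grads)
  expect_equal(alpha, wk / 16, tolerance = 1e-12)
  hm <- gradcam(A, grads, size = 8)
  expect_true(all(hm >= 0 & hm <= 1))

  # negative-only weighted sums are annihilated by the ReLU
  An <- array(abs(rnorm(4 * 4 * 2)), c(4, 4, 2))
  gn <- array(-abs(rnorm(4 * 4 * 2)), c(4, 4, 2))
  expect_warning(hz <- gradcam(An * 0, gn * 0, size = 8), "all-zero")
  hneg <- gradcam(An, gn, size = 8)
  expect_true(all(hneg == 0))
})

test_that("Grad-CAM++ degenerates to Grad-CAM on a single positive pixel and
           its derivative ratio matches the exp-logit surrogate", {
  A <- array(0, c(2, 2, 1)); A[1, 1, 1] <- 1.5
  g <- array(0, c(2, 2, 1)); g[1, 1, 1] <- 0.7
  h1 <- gradcam(A, g, size = 4)
  h2 <- gradcam_pp(A, g, size = 4)
  expect_equal(unclass(h1), unclass(h2), tolerance = 1e-9)

  # analytic second/third derivatives of y = exp(s), s linear with slope g
  set.seed(2)
  gs <- array(rnorm(8), c(2, 2, 2))
  s <- 0.3
  d <- exp_surrogate_derivs(gs, s)
  expect_equal(d$d2, gs^2 * exp(s), tolerance = 1e-5)
  expect_equal(d$d3, gs^3 * exp(s), tolerance = 1e-5)
  # printed ratio form: exp(s) cancels between numerator and denominator
  A2 <- array(abs(rnorm(8)), c(2, 2, 2))
  for (k in 1:2) {
    num <- sum(d$d2[, , k])
    den <- 2 * sum(d$d2[, , k]) + sum(A2[, , k]) * sum(d$d3[, , k])
    plain <- sum(gs[, , k]^2) / (2 * sum(gs[, , k]^2) +
                                 sum(A2[, , k]) * sum(gs[, , k]^3))
    expect_equal(num / den, plain, tolerance = 1e-9)
  }

  # maps are non-negative for arbitrary inputs
  set.seed(3)
  Ar <- array(rnorm(32), c(4, 4, 2)); gr <- array(rnorm(32), c(4, 4, 2))
  expect_gte(min(gradcam_pp(Ar, gr, size = 8)), 0)
  expect_gte(min(gradcam_pp(Ar, gr, size = 8, verbatim = TRUE)), 0)
})

test_that("integrated gradients: zero path, linear exactness, completeness", {
  set.seed(4)
  S <- matrix(abs(rnorm(20)), 4, 5)
  w <- matrix(rnorm(20), 4, 5)
  lin <- function(X) list(value = sum(w * X), grad = w)
  z <- integrated_gradients(lin, S, S, steps = 16)
  expect_true(all(z$attributions == 0))

  # linear model: attributions equal w * (S - S') for any step count
  for (steps in c(8, 64)) {
    r <- integrated_gradients(lin, S, S * 0, steps = steps)
    expect_equal(r$attributions, w * S, tolerance = 1e-10)
    expect_lt(r$residual, 1e-9)
  }
  expect_error(integrated_gradients(lin, S, matrix(0, 2, 2)), "shape")

  # nonlinear model: completeness residual shrinks as steps double
  f <- function(X) list(value = sum(sin(X)) + sum(X^3) / 10,
                        grad = cos(X) + 3 * X^2 / 10)
  res <- vapply(c(8, 32, 128), function(s)
    integrated_gradients(f, S, S * 0, steps = s)$residual, 0)
  expect_lt(res[3], res[1] + 1e-12)
  expect_lt(res[3] / abs(integrated_gradients(f, S, S * 0, steps = 128)$delta), 0.01)
})

test_that("model-level IG satisfies completeness on the acoustic pathway", {
  m <- micro_model()
  inp <- micro_inputs(1, seed = 41)
  r <- model_ig(m, inp$images[[1]], inp$mels[[1]], class_id = 1, steps = 64)
  expect_lt(r$residual, 0.01 * max(abs(r$delta), 1e-6))
  expect_equal(dim(unclass(r$heatmap)), c(64, 64))
  expect_gte(min(unclass(r$heatmap)), 0)
})

test_that("interpreter heads upsample any token grid to 64 x 64", {
  m <- micro_model()
  d <- m$config$d
  side <- 2L * m$grids[4]
  set.seed(5)
  fv <- array(rnorm(side * side * d), c(side, side, d))
  hv <- interp_head(m, fv, "visual")
  expect_equal(dim(hv$map), c(64, 64))
  fa <- array(rnorm(8 * 4 * d), c(8, 4, d))
  ha <- interp_head(m, fa, "acoustic")
  expect_equal(dim(ha$map), c(64, 64))
  expect_error(interp_head(m, array(0, c(8, 4, d + 1)), "acoustic"), "channel")

  # zero weights give a zero map (fresh model: the fixture is shared)
  mz <- build_model(encoder_config("tiny", n_classes = 3, image_size = 32),
                    seed = 8)
  for (nm in c("red", "d1", "d2", "d3")) {
    mz$interp_v[[nm]]$W[] <- 0; mz$interp_v[[nm]]$b[] <- 0
  }
  expect_true(all(interp_head(mz, fv, "visual")$map == 0))

  # training the head moves gradient into the 1x1 reduction layer
  m2 <- build_model(encoder_config("tiny", n_classes = 3, image_size = 32),
                    seed = 9)
  layers <- duetnet:::collect_layers(m2$interp_v)
  duetnet:::zero_grads(layers)
  target <- matrix(runif(64 * 64), 64, 64)
  loss <- duetnet:::interp_head_train(m2, fv, target, "visual")
  expect_gt(loss, 0)
  expect_gt(sum(m2$interp_v$red$dW^2), 0)
})

test_that("gated fusion stays within the pointwise envelope of its inputs", {
  m <- micro_model()
  set.seed(6)
  Hv <- matrix(runif(64 * 64), 64, 64)
  Ha <- matrix(runif(64 * 64), 64, 64)
  gf <- gated_fuse(m, Hv, Ha)
  expect_true(all(gf$G >= 0 & gf$G <= 1))
  expect_true(all(gf$Hc >= pmin(Hv, Ha) - 1e-12))
  expect_true(all(gf$Hc <= pmax(Hv, Ha) + 1e-12))

  # identical inputs pass through unchanged regardless of the gate
  same <- gated_fuse(m, Hv, Hv)
  expect_equal(same$Hc, Hv, tolerance = 1e-12)

  # a strongly positive gate bias forces G ~ 1 and Hc ~ Hv
  m$gate2$b[] <- 50
  forced <- gated_fuse(m, Hv, Ha)
  expect_equal(forced$Hc, Hv, tolerance = 1e-6)
  m$gate2$b[] <- 0

  expect_warning(gated_fuse(m, Hv * 3, Ha), "normalized")

  # integral form of the envelope: for any non-negative weighting w
  w <- matrix(runif(64 * 64), 64, 64)
  lo <- min(sum(w * Hv), sum(w * Ha)); hi <- max(sum(w * Hv), sum(w * Ha))
  expect_gte(sum(w * gf$Hc), lo - 1e-9)
  expect_lte(sum(w * gf$Hc), hi + 1e-9)
})

test_that("fixed-beta fusion is the stated convex combination", {
  Hv <- matrix(0.2, 4, 4); Ha <- matrix(0.6, 4, 4)
  expect_equal(fixed_beta_fuse(Hv, Ha, 1), Hv)
  expect_equal(fixed_beta_fuse(Hv, Ha, 0.5), matrix(0.4, 4, 4))
  expect_error(fixed_beta_fuse(Hv, Ha, 1.2), "beta")

  # reduces to the learned gate when G is constant at beta
  m <- micro_model()
  set.seed(7)
  A <- matrix(runif(16), 4, 4); B <- matrix(runif(16), 4, 4)
  G <- matrix(0.3, 4, 4)
  expect_equal(G * A + (1 - G) * B, fixed_beta_fuse(A, B, 0.3), tolerance = 1e-12)
})

test_that("explanation losses: KL alignment, TV smoothness, class gating", {
  set.seed(8)
  H <- matrix(runif(64 * 64), 64, 64)
  M <- matrix(runif(64 * 64), 64, 64)
  kl <- kl_heatmap(H, M)
  expect_gte(kl$value, 0)
  expect_lt(kl_heatmap(H, H)$value, 1e-10)
  expect_lt(kl_heatmap(H, H + 2.5)$value, 1e-10) # softmax shift invariance

  # gradients match finite differences (small maps: better FD conditioning)
  Hs <- matrix(runif(64), 8, 8); Ms <- matrix(runif(64), 8, 8)
  kls <- kl_heatmap(Hs, Ms)
  idx <- sample(64, 6)
  numH <- fd_grad(function(v) { Hp <- Hs; Hp[idx] <- v; kl_heatmap(Hp, Ms)$value },
                  Hs[idx], eps = 1e-5)
  numM <- fd_grad(function(v) { Mp <- Ms; Mp[idx] <- v; kl_heatmap(Hs, Mp)$value },
                  Ms[idx], eps = 1e-5)
  expect_equal(kls$dH[idx], numH, tolerance = 1e-4)
  expect_equal(kls$dM[idx], numM, tolerance = 1e-4)

  expect_equal(tv_loss(matrix(3, 16, 16))$value, 0)
  tv <- tv_loss(H)
  expect_gt(tv$value, 0)
  tvis <- tv_loss(Hs, "isotropic")
  numT <- fd_grad(function(v) { Hp <- Hs; Hp[idx] <- v; tv_loss(Hp, "isotropic")$value },
                  Hs[idx], eps = 1e-7)
  expect_equal(tvis$grad[idx], numT, tolerance = 1e-3)

  F <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  Pi1 <- matrix(1, 4, 4)
  cfgx <- xai_config(mu1 = 0.1, mu2 = 0.1, mu3 = 0.01)
  lx1 <- loss_xai(H, M, F, Pi1, cfgx)
  expect_equal(unname(lx1$components["gate"]), 0)
  lxH <- loss_xai(H, H, F, Pi1, cfgx)
  expect_lt(unname(lxH$components["align"]), 1e-10)
  Pi0 <- matrix(0, 4, 4)
  lx0 <- loss_xai(H, M, F, Pi0, cfgx)
  expect_equal(unname(lx0$components["gate"]), sum(F^2), tolerance = 1e-12)
  expect_error(xai_config(mu1 = -1), "negative")
  expect_error(xai_config(ig_steps = 4), "ig_steps")
})

test_that("after training, fused saliency concentrates on the organism", {
  tf <- trained_fit64()
  m <- tf$fit$model
  ratios <- vapply(tf$val[1:6], function(p) {
    ex <- suppressWarnings(explain_pair(m, p, config = xai_config(ig_steps = 8)))
    mk <- resize_bilinear(p$mask, 64, 64) > 0.5
    mean(ex$Hc[mk]) / mean(ex$Hc[!mk])
  }, 0)
  # on average the fused heatmap places more mass on the rendered insect
  # than on the background
  expect_gt(mean(ratios), 1)
})

test_that("end-to-end explanation of a pair returns coherent artifacts", {
  m <- micro_model()
  ds <- tiny_ds()
  p <- ds$pairs[[1]]
  # adapt the pair to the micro geometry
  p$image <- p$image[seq(1, 64, 2), seq(1, 64, 2), , drop = FALSE]
  ex <- explain_pair(m, p, config = xai_config(ig_steps = 8))
  expect_equal(dim(unclass(ex$Hv)), c(64, 64))
  expect_equal(dim(unclass(ex$Ha)), c(64, 64))
  expect_equal(dim(ex$Hc), c(64, 64))
  expect_equal(dim(ex$G), c(64, 64))
  expect_true(all(ex$G >= 0 & ex$G <= 1))
  expect_equal(sum(ex$Mc), 1, tolerance = 1e-9)
  expect_equal(sum(ex$prob), 1, tolerance = 1e-9)
  td <- withr::local_tempdir()
  write_overlay(p$image, ex$Hv, file.path(td, "ov.png"))
  write_overlay(p$melspec, ex$Ha, file.path(td, "oa.png"))
  expect_true(all(file.exists(file.path(td, c("ov.png", "oa.png")))))
})
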