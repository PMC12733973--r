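# Schedule, metrics, SNR harness, folds and the training loop's contracts.

# independent confusion-matrix oracle (naive loops)
oracle_metrics <- function(scores, labels) {
  N <- nrow(scores); C <- ncol(scores)
  pred <- integer(N)
  for (i in seq_len(N)) pred[i] <- which(scores[i, ] == max(scores[i, ]))[1] - 1L
  acc <- sum(pred == labels) / N
  prec <- rec <- numeric(C)
  tps <- fps <- fns <- integer(C)
  for (c0 in 0:(C - 1)) {
    tp <- fp <- fn <- 0
    for (i in seq_len(N)) {
      if (pred[i] == c0 && labels[i] == c0) tp <- tp + 1
      if (pred[i] == c0 && labels[i] != c0) fp <- fp + 1
      if (pred[i] != c0 && labels[i] == c0) fn <- fn + 1
    }
    tps[c0 + 1] <- tp; fps[c0 + 1] <- fp; fns[c0 + 1] <- fn
    prec[c0 + 1] <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec[c0 + 1] <- if (tp + fn == 0) 0 else tp / (tp + fn)
  }
  list(acc = acc, macro_p = mean(prec), macro_r = mean(rec),
       micro_p = if (sum(tps + fps) == 0) 0 else sum(tps) / sum(tps + fps))
}

test_that("cosine schedule hits its endpoints and midpoint exactly", {
  expect_equal(cosine_lr(0, 100, 1e-6, 1e-3), 1e-3)
  expect_equal(cosine_lr(100, 100, 1e-6, 1e-3), 1e-6)
  expect_equal(cosine_lr(50, 100, 1e-6, 1e-3), (1e-6 + 1e-3) / 2)
  expect_warning(v <- cosine_lr(101, 100, 1e-6, 1e-3), "clamping")
  expect_equal(v, 1e-6)
})

test_that("metrics: perfect predictions, hand-computed counts, top-k limits", {
  scores <- diag(3)[c(1, 2, 3, 1), ]
  perfect <- compute_metrics(scores, c(0, 1, 2, 0), k = 1)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$map50, 1)
  expect_equal(perfect$topk, 1)

  # class 0 with TP=3, FP=1, FN=1: precision = recall = F1 = 0.75
  labels <- c(0, 0, 0, 0, 1, 1)
  preds <- c(0, 0, 0, 1, 0, 1)
  sc <- matrix(0, 6, 2); sc[cbind(1:6, preds + 1)] <- 1
  suppressWarnings(r <- compute_metrics(sc, labels, k = 1))
  row0 <- r$per_class[1, ]
  expect_equal(c(row0$TP, row0$FP, row0$FN), c(3, 1, 1))
  expect_equal(row0$precision, 0.75)
  expect_equal(row0$recall, 0.75)
  expect_equal(2 * 0.75 * 0.75 / 1.5, 0.75)

  # k equal to the class count makes top-k trivially one
  set.seed(1)
  sr <- matrix(rnorm(40), 10, 4)
  lr <- sample(0:3, 10, replace = TRUE)
  suppressWarnings(expect_equal(compute_metrics(sr, lr, k = 4)$topk, 1))
  expect_error(compute_metrics(matrix(0, 0, 2), integer(0)), "empty")
})

test_that("metrics agree with the brute-force oracle on 100 random cases", {
  set.seed(2)
  for (case in 1:100) {
    N <- sample(5:30, 1); C <- sample(2:5, 1)
    scores <- matrix(rnorm(N * C), N, C)
    labels <- sample(0:(C - 1), N, replace = TRUE)
    suppressWarnings(r <- compute_metrics(scores, labels))
    o <- oracle_metrics(scores, labels)
    expect_identical(r$accuracy, o$acc)
    expect_identical(r$precision, o$macro_p)
    expect_identical(r$recall, o$macro_r)
    expect_identical(r$micro$precision, o$micro_p)
  }
})

test_that("average precision equals a step-integrated oracle", {
  set.seed(3)
  for (case in 1:20) {
    n <- sample(6:20, 1)
    score <- rnorm(n)
    pos <- as.logical(rbinom(n, 1, 0.4))
    if (!any(pos)) pos[1] <- TRUE
    # naive oracle: interpolated precision at each positive, summed over
    # recall increments
    ord <- order(score, decreasing = TRUE)
    tp <- cumsum(pos[ord]); prec <- tp / seq_len(n); rec <- tp / sum(pos)
    ap <- 0
    prev <- 0
    for (i in seq_len(n)) if (pos[ord][i]) {
      ap <- ap + (rec[i] - prev) * max(prec[i:n])
      prev <- rec[i]
    }
    expect_equal(duetnet:::average_precision(score, pos), ap, tolerance = 1e-12)
  }
})

test_that("SNR mixing hits its target within 0.01 dB and degenerates cleanly", {
  set.seed(4)
  clean <- sin(2 * pi * 200 * seq_len(8000) / 8000)
  noise <- rnorm(8000)
  for (target in c(20, 10, 0)) {
    r <- mix_at_snr(clean, noise, target)
    expect_lt(abs(r$achieved_snr_db - target), 0.01)
  }
  r0 <- mix_at_snr(clean, noise, 0)
  expect_lt(abs(mean((r0$scale * noise)^2) / mean(clean^2) - 1), 1e-4)
  # unit-power signal at 10 dB: noise power 0.1
  u <- clean / sqrt(mean(clean^2))
  r10 <- mix_at_snr(u, noise, 10)
  expect_lt(abs(mean((r10$scale * noise)^2) - 0.1), 1e-4)
  expect_identical(mix_at_snr(clean, noise, Inf)$wave, clean)
  expect_error(mix_at_snr(numeric(10), rnorm(10), 10), "zero-power")
})

test_that("noise profiles are unit power with the stated spectral shape", {
  sr <- 16000; n <- sr
  for (kind in c("gaussian", "wind", "rustle", "insect")) {
    w <- make_noise(kind, n, sr, rng_state = 5)
    expect_equal(mean(w^2), 1, tolerance = 1e-9)
  }
  band_energy <- function(w, lo, hi, sr) {
    p <- Mod(stats::fft(w))^2
    f <- (seq_along(p) - 1) * sr / length(p)
    sum(p[f >= lo & f <= hi]) / sum(p[f <= sr / 2])
  }
  wind <- make_noise("wind", n, sr, rng_state = 6)
  expect_gt(band_energy(wind, 0, 400, sr), 0.9)
  rustle <- make_noise("rustle", n, sr, rng_state = 6)
  expect_gt(band_energy(rustle, 1800, 6500, sr), 0.8)
})

test_that("stratified folds partition each sample into validation once", {
  ds <- tiny_ds()
  runner <- function(train, val, fold) {
    list(n_train = length(train), n_val = length(val),
         balanced = length(unique(vapply(val, `[[`, 0, "label"))))
  }
  cv <- kfold_cv(ds$pairs, k = 4, runner, seed = 2)
  expect_equal(sort(unique(cv$assignment)), 1:4)
  expect_equal(as.integer(table(cv$assignment)), rep(6L, 4))
  expect_true(all(vapply(cv$folds, `[[`, 0, "n_val") == 6))
  # deterministic under the seed
  cv2 <- kfold_cv(ds$pairs, k = 4, runner, seed = 2)
  expect_identical(cv$assignment, cv2$assignment)
  # a class with fewer members than k triggers the unstratified fallback
  small <- ds$pairs[c(1:4, 9:12, 17:18)] # classes of size 4, 4, 2 with k = 5
  expect_warning(kfold_cv(small, k = 5, runner, seed = 1), "unstratified")

  # pooled micro accuracy equals the mean of per-fold accuracy when folds
  # are equal-sized (algebraic identity, checked on synthetic predictions)
  set.seed(6)
  labels <- rep(0:2, each = 8)
  preds <- labels; flip <- sample(24, 6); preds[flip] <- (preds[flip] + 1) %% 3
  folds <- split(seq_len(24), rep(1:4, 6))
  per_fold <- vapply(folds, function(ix) mean(preds[ix] == labels[ix]), 0)
  expect_equal(mean(per_fold), mean(preds == labels), tolerance = 1e-12)
})

test_that("split_dataset stratifies by class at the requested fractions", {
  ds <- tiny_ds()
  sp <- split_dataset(ds$pairs, c(0.5, 0.25, 0.25), seed = 3)
  expect_length(sp$train, 12)
  expect_length(sp$val, 6)
  expect_length(sp$test, 6)
  expect_equal(as.integer(table(vapply(sp$train, `[[`, 0, "label"))), rep(4L, 3))
  all_idx <- c(vapply(sp$train, `[[`, 0, "t_visual"),
               vapply(sp$val, `[[`, 0, "t_visual"),
               vapply(sp$test, `[[`, 0, "t_visual"))
  expect_equal(sort(all_idx), sort(vapply(ds$pairs, `[[`, 0, "t_visual")))
})

test_that("training logs losses, respects ablation identities and checkpoints", {
  ds <- tiny_ds()
  sp <- split_dataset(ds$pairs, c(0.75, 0.25, 0), seed = 1)
  ec <- encoder_config("tiny", n_classes = 3, image_size = 64)
  fit <- suppressWarnings(
    train_model(sp$train, sp$val, config = ec,
                tc = train_config(epochs = 2, seed = 9, xai_every = 2),
                bank = ds$bank, sample_rate = 16000, verbose = FALSE))
  expect_s3_class(fit, "avfit")
  expect_true(all(c("l_cls", "l_cs", "l_margin", "l_xai", "l_total") %in%
                  colnames(fit$log)))
  expect_true(all(is.finite(fit$log$l_total)))
  expect_gt(max(fit$log$l_xai), 0) # explanation loss was active
  expect_equal(nrow(fit$history), 2)

  # lambda = mu = 0 reduces the objective to plain cross-entropy
  fit0 <- suppressWarnings(
    train_model(sp$train, sp$val, config = ec,
                tc = train_config(epochs = 1, seed = 9),
                cc = contrast_config(lambda1 = 0, lambda2 = 0),
                use_contrast = FALSE, use_xai = FALSE, sample_rate = 16000))
  expect_true(all(fit0$log$l_cs == 0))
  expect_true(all(fit0$log$l_margin == 0))
  expect_true(all(fit0$log$l_xai == 0))
  expect_equal(fit0$log$l_total, fit0$log$l_cls, tolerance = 1e-12)

  # checkpoint round trip reproduces the forward pass exactly
  td <- withr::local_tempdir()
  save_checkpoint(fit$model, file.path(td, "ck.rds"))
  m2 <- load_checkpoint(file.path(td, "ck.rds"))
  o1 <- model_forward(fit$model, lapply(sp$val[1:2], `[[`, "image"),
                      lapply(sp$val[1:2], `[[`, "melspec"))
  o2 <- model_forward(m2, lapply(sp$val[1:2], `[[`, "image"),
                      lapply(sp$val[1:2], `[[`, "melspec"))
  expect_identical(o1$logits, o2$logits)

  # resuming from the checkpointed weights reproduces the next-step loss
  step1 <- function(m) {
    layers <- duetnet:::model_layers(m)
    duetnet:::zero_grads(layers)
    out <- model_forward(m, lapply(sp$train[1:4], `[[`, "image"),
                         lapply(sp$train[1:4], `[[`, "melspec"))
    ce <- duetnet:::cross_entropy(out$logits,
                                  vapply(sp$train[1:4], `[[`, 0, "label"))
    model_backward(m, out, dlogits = ce$grad)
    duetnet:::adamw_step(layers, 1e-4, 1)
    out2 <- model_forward(m, lapply(sp$train[1:4], `[[`, "image"),
                          lapply(sp$train[1:4], `[[`, "melspec"))
    duetnet:::cross_entropy(out2$logits,
                            vapply(sp$train[1:4], `[[`, 0, "label"))$value
  }
  expect_equal(step1(fit$model), step1(m2), tolerance = 1e-6)
})
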