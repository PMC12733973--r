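# Training loop (AdamW + cosine annealing + early stopping), evaluation
# metrics, stratified k-fold protocol and the SNR-controlled robustness
# harness.

#' Cosine annealing learning rate
#'
#' `eta_t = eta_min + (eta_max - eta_min) * (1 + cos(pi t / T)) / 2`.
#' Steps beyond `T` clamp to `eta_min` with a warning.
#'
#' @param t current step (0-based)
#' @param T total steps
#' @param eta_min,eta_max schedule bounds
#' @return learning rate at step t
#' @export
cosine_lr <- function(t, T, eta_min, eta_max) {
  if (t > T) {
    warning("step beyond schedule end; clamping to eta_min")
    return(eta_min)
  }
  eta_min + 0.5 * (eta_max - eta_min) * (1 + cos(t * pi / T))
}

#' Classification metrics from ranked class scores
#'
#' Micro-aggregated and macro-averaged precision/recall/F1 from one-vs-rest
#' confusion counts, mean average precision (area under the interpolated
#' one-vs-rest precision-recall curve, averaged over classes; reported as
#' `map50`) and top-k accuracy.
#'
#' @param scores N x C matrix of class scores (higher = more confident)
#' @param labels 0-based true labels, length N
#' @param k top-k cutoff
#' @return a `metrics_report` list: accuracy, precision, recall, f1 (macro),
#'   map50, topk, `micro` (micro-averaged), `per_class` data frame with
#'   TP/FP/FN/TN
#' @export
compute_metrics <- function(scores, labels, k = 5) {
  if (length(labels) == 0 || is.null(dim(scores)) || nrow(scores) == 0)
    stop("invalid input: empty predictions")
  if (!all(is.finite(scores))) stop("invalid input: non-finite scores")
  N <- nrow(scores); C <- ncol(scores)
  k <- min(k, C)
  pred <- max.col(scores, ties.method = "first") - 1L
  acc <- mean(pred == labels)
  per <- data.frame(class = 0:(C - 1), TP = 0L, FP = 0L, FN = 0L, TN = 0L,
                    precision = 0, recall = 0, ap = 0)
  warned <- FALSE
  for (c0 in 0:(C - 1)) {
    tp <- sum(pred == c0 & labels == c0)
    fp <- sum(pred == c0 & labels != c0)
    fn <- sum(pred != c0 & labels == c0)
    tn <- N - tp - fp - fn
    prec <- if (tp + fp == 0) { warned <- TRUE; 0 } else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    per[c0 + 1, 2:7] <- c(tp, fp, fn, tn, prec, rec)
    per$ap[c0 + 1] <- average_precision(scores[, c0 + 1], labels == c0)
  }
  if (warned) warning("precision undefined (TP+FP=0) for some class; set to 0")
  macro_p <- mean(per$precision); macro_r <- mean(per$recall)
  macro_f1 <- if (macro_p + macro_r == 0) 0 else 2 * macro_p * macro_r / (macro_p + macro_r)
  mtp <- sum(per$TP); mfp <- sum(per$FP); mfn <- sum(per$FN)
  micro_p <- if (mtp + mfp == 0) 0 else mtp / (mtp + mfp)
  micro_r <- if (mtp + mfn == 0) 0 else mtp / (mtp + mfn)
  micro_f1 <- if (micro_p + micro_r == 0) 0 else 2 * micro_p * micro_r / (micro_p + micro_r)
  ord <- apply(scores, 1, order, decreasing = TRUE)
  topk <- mean(vapply(seq_len(N), function(i) (labels[i] + 1L) %in% ord[seq_len(k), i], TRUE))
  structure(list(accuracy = acc, precision = macro_p, recall = macro_r,
                 f1 = macro_f1, map50 = mean(per$ap), topk = topk, k = k,
                 micro = list(precision = micro_p, recall = micro_r, f1 = micro_f1),
                 per_class = per, n = N),
            class = "metrics_report")
}

# area under the interpolated precision-recall curve (one-vs-rest)
average_precision <- function(score, is_pos) {
  npos <- sum(is_pos)
  if (npos == 0) return(0)
  ord <- order(score, decreasing = TRUE)
  tp <- cumsum(is_pos[ord])
  prec <- tp / seq_along(tp)
  rec <- tp / npos
  # interpolated precision: running max from the right
  ip <- rev(cummax(rev(prec)))
  ap <- 0; prev_r <- 0
  for (i in seq_along(rec)) {
    if (is_pos[ord][i]) {
      ap <- ap + (rec[i] - prev_r) * ip[i]
      prev_r <- rec[i]
    }
  }
  ap
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.3f  precision %.3f  recall %.3f  F1 %.3f  mAP@50 %.3f  top-%d %.3f (n=%d)\n",
              x$accuracy, x$precision, x$recall, x$f1, x$map50, x$k, x$topk, x$n))
  invisible(x)
}

#' Mix a waveform with noise at a controlled SNR
#'
#' The noise is scaled so that `10 log10(P_signal / P_noise)` equals the
#' target exactly (by construction). `target_snr_db = Inf` returns the clean
#' signal.
#'
#' @param clean clean waveform (non-zero power)
#' @param noise noise waveform of the same length
#' @param target_snr_db target signal-to-noise ratio in dB
#' @return list with `wave`, `achieved_snr_db`, `scale`
#' @export
mix_at_snr <- function(clean, noise, target_snr_db) {
  if (is.infinite(target_snr_db) && target_snr_db > 0)
    return(list(wave = clean, achieved_snr_db = Inf, scale = 0))
  if (length(clean) != length(noise)) stop("invalid input: length mismatch")
  ps <- mean(clean^2)
  if (ps <= 0) stop("invalid input: zero-power clean signal")
  pn <- mean(noise^2)
  if (pn <= 0) stop("invalid input: zero-power noise")
  scale <- sqrt(ps / (pn * 10^(target_snr_db / 10)))
  out <- clean + scale * noise
  achieved <- 10 * log10(ps / (scale^2 * pn))
  list(wave = out, achieved_snr_db = achieved, scale = scale)
}

#' Generate an ecological noise profile
#'
#' `gaussian` is white noise; `wind` is low-pass filtered noise (< 300 Hz);
#' `rustle` is band-pass noise (2-6 kHz, leaf movement); `insect` is a
#' harmonic stack at a random fundamental with vibrato (off-frame insect
#' call). All profiles are normalized to unit RMS.
#'
#' @param kind noise type
#' @param n length in samples
#' @param sample_rate sampling rate (Hz)
#' @param rng_state integer seed
#' @return numeric waveform with RMS 1
#' @export
make_noise <- function(kind = c("gaussian", "wind", "rustle", "insect"),
                       n, sample_rate = 44100, rng_state = 1) {
  kind <- match.arg(kind)
  w <- with_seed(rng_state, {
    base <- stats::rnorm(n)
    nyq <- sample_rate / 2
    switch(kind,
      gaussian = base,
      wind = {
        bf <- signal::butter(4, min(300 / nyq, 0.99), type = "low")
        as.numeric(signal::filter(bf, base))
      },
      rustle = {
        hi <- min(6000 / nyq, 0.99); lo <- min(2000 / nyq, 0.9 * hi)
        bf <- signal::butter(4, c(lo, hi), type = "pass")
        as.numeric(signal::filter(bf, base))
      },
      insect = {
        t <- seq_len(n) / sample_rate
        f0 <- stats::runif(1, 300, 800)
        vib <- 1 + 0.02 * sin(2 * pi * 5 * t)
        s <- numeric(n)
        for (h in 1:4) s <- s + exp(-0.5 * (h - 1)) * sin(2 * pi * f0 * h * vib * t +
                                                          stats::runif(1, 0, 2 * pi))
        s + 0.05 * base
      })
  })
  w / sqrt(mean(w^2))
}

#' Training configuration
#'
#' @param batch minibatch size
#' @param lr,lr_min cosine schedule bounds (initial / final learning rate)
#' @param weight_decay,beta1,beta2 AdamW settings
#' @param epochs maximum epochs
#' @param patience early-stopping patience (epochs without validation
#'   accuracy improvement)
#' @param seed seed for shuffling and initialization
#' @param xai_every compute the explanation loss every this many steps
#'   (stochastic single-sample regularization)
#' @return a `train_config` list
#' @export
train_config <- function(batch = 8, lr = 1e-4, lr_min = 1e-6,
                         weight_decay = 0.05, beta1 = 0.9, beta2 = 0.999,
                         epochs = 30, patience = 10, seed = 1, xai_every = 8) {
  stopifnot(batch >= 2, lr_min <= lr, epochs >= 1)
  structure(list(batch = as.integer(batch), lr = lr, lr_min = lr_min,
                 weight_decay = weight_decay, beta1 = beta1, beta2 = beta2,
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 seed = as.integer(seed), xai_every = as.integer(xai_every)),
            class = "train_config")
}

# class scores (logits) for a list of pairs, forward-only
predict_scores <- function(m, pairs, mode = "fused", batch = 8) {
  n <- length(pairs)
  out <- matrix(0, n, m$config$n_classes)
  i <- 1
  while (i <= n) {
    j <- min(i + batch - 1, n)
    idx <- i:j
    o <- model_forward(m, lapply(pairs[idx], `[[`, "image"),
                       lapply(pairs[idx], `[[`, "melspec"), mode = mode)
    out[idx, ] <- o$logits
    i <- j + 1
  }
  out
}

#' Evaluate a model on aligned pairs
#'
#' Optionally corrupts the acoustic modality at a controlled SNR before
#' evaluation (the robustness protocol); mel-spectrograms are recomputed from
#' the corrupted waveforms.
#'
#' @param m an `avmodel`
#' @param pairs list of aligned pairs
#' @param mode classification head
#' @param snr_db optional SNR in dB (Inf or NULL = clean)
#' @param noise_kind noise profile for corruption
#' @param sample_rate pairs' audio sampling rate
#' @param seed seed for noise generation
#' @param k top-k cutoff
#' @return a `metrics_report`
#' @export
evaluate_model <- function(m, pairs, mode = "fused", snr_db = NULL,
                           noise_kind = "gaussian", sample_rate = 44100,
                           seed = 1, k = 5) {
  if (!is.null(snr_db) && is.finite(snr_db)) {
    pairs <- lapply(seq_along(pairs), function(i) {
      p <- pairs[[i]]
      nz <- make_noise(noise_kind, length(p$wave), sample_rate,
                       rng_state = derive_seed(seed, i))
      p$wave <- mix_at_snr(p$wave, nz, snr_db)$wave
      p$melspec <- melspectrogram(p$wave, sample_rate,
                                  n_mels = nrow(p$melspec),
                                  n_frames = ncol(p$melspec))
      p
    })
  }
  scores <- predict_scores(m, pairs, mode = mode)
  labels <- vapply(pairs, `[[`, 0, "label")
  compute_metrics(scores, labels, k = k)
}

# binary class mask on the visual token grid (block-mean threshold)
mask_to_grid <- function(mask, side) {
  f <- nrow(mask) %/% side
  m <- block_up_adj(mask, f, f) / f^2
  (m > 0.5) * 1
}

#' Train the audio-visual model
#'
#' Joint optimization of the classification cross-entropy, the contrastive
#' objective (InfoNCE + margin over mined hard negatives, weighted by
#' lambda1/lambda2) and the explanation loss (TV + attention alignment +
#' class gating, weighted by mu1..3), with AdamW and cosine learning-rate
#' annealing, early stopping on validation accuracy, and per-step CSV-ready
#' logs. Weakly aligned pairs are excluded.
#'
#' @param train_pairs,val_pairs lists of aligned pairs
#' @param config an [encoder_config()]
#' @param tc,cc,xc training / contrastive / explainability configurations
#' @param bank optional species bank (guarantees confusable-class negatives)
#' @param fusion build with bidirectional cross-attention (FALSE = early
#'   fusion ablation)
#' @param use_contrast,use_xai enable the contrastive / explanation losses
#' @param mode classification head to train
#' @param augment apply stochastic paired augmentation per sample (photometric
#'   jitter plus acoustic noise and time shift; geometry-preserving so the
#'   foreground mask stays valid for the gating loss)
#' @param snr_augment range c(lo, hi) in dB: a fraction of training clips is
#'   additionally corrupted with background noise at a random SNR from this
#'   range, mimicking the acoustic variability of field sites; NULL disables
#' @param sample_rate audio sampling rate of the pairs (augmentation needs it)
#' @param init_model optional model to continue training from
#' @param verbose print per-epoch progress
#' @return an `avfit`: list with `model`, `log` (per step), `history` (per
#'   epoch), `best_epoch`, configurations
#' @export
train_model <- function(train_pairs, val_pairs = NULL,
                        config = encoder_config("tiny", n_classes = 3),
                        tc = train_config(), cc = contrast_config(),
                        xc = xai_config(ig_steps = 8), bank = NULL,
                        fusion = TRUE, use_contrast = TRUE, use_xai = TRUE,
                        mode = "fused", augment = TRUE, snr_augment = c(0, 20),
                        sample_rate = 44100, init_model = NULL, verbose = FALSE) {
  train_pairs <- Filter(function(p) isTRUE(p$aligned), train_pairs)
  labels_all <- vapply(train_pairs, `[[`, 0, "label")
  if (length(unique(labels_all)) < 2) stop("need >= 2 classes to train")
  set.seed(tc$seed)
  m <- if (is.null(init_model)) build_model(config, seed = tc$seed, fusion = fusion)
       else init_model
  layers <- model_layers(m)
  n <- length(train_pairs)
  steps_per_epoch <- max(1L, n %/% tc$batch)
  T_total <- tc$epochs * steps_per_epoch
  similar_map <- NULL
  if (!is.null(bank)) {
    sm <- vapply(bank, function(s) if (is.null(s$similar_to)) NA_integer_
                 else as.integer(s$similar_to), 0L)
    names(sm) <- vapply(bank, function(s) as.character(s$class_id), "")
    similar_map <- sm
  }
  log_rows <- list()
  history <- list()
  best_acc <- -Inf; best_epoch <- 0L; best_w <- NULL; stall <- 0L
  step <- 0L; t_adam <- 0L
  side <- 2L * m$grids[4]
  for (epoch in seq_len(tc$epochs)) {
    ord <- sample(n)
    for (s in seq_len(steps_per_epoch)) {
      idx <- ord[((s - 1) * tc$batch + 1):min(s * tc$batch, n)]
      batch <- train_pairs[idx]
      labels <- vapply(batch, `[[`, 0, "label")
      step <- step + 1L
      if (augment) {
        batch <- lapply(seq_along(batch), function(b) {
          rs <- derive_seed(tc$seed, step * 1000L + b)
          p <- batch[[b]]
          if (with_seed(rs, stats::runif(1)) >= 0.5) {
            asp <- with_seed(rs + 1L, augment_spec(
              brightness = stats::runif(1, -20, 20),
              contrast = stats::runif(1, 0.8, 1.2),
              noise_scale = stats::runif(1, 0, 0.1),
              time_shift = stats::runif(1, -0.1, 0.1)))
            p <- paired_augment(p, asp, rng_state = rs + 2L,
                                sample_rate = sample_rate)
          }
          if (!is.null(snr_augment) && with_seed(rs + 3L, stats::runif(1)) < 0.35) {
            snr <- with_seed(rs + 4L, stats::runif(1, snr_augment[1], snr_augment[2]))
            nz <- make_noise("gaussian", length(p$wave), sample_rate,
                             rng_state = rs + 5L)
            p$wave <- mix_at_snr(p$wave, nz, snr)$wave
            p$melspec <- melspectrogram(p$wave, sample_rate,
                                        n_mels = nrow(p$melspec),
                                        n_frames = ncol(p$melspec))
          }
          p
        })
      }
      do_xai <- use_xai && (xc$mu1 > 0 || xc$mu2 > 0 || xc$mu3 > 0) &&
        step %% tc$xai_every == 0L && fusion
      # detached saliency maps for the explanation loss (separate pass; its
      # parameter-gradient side effects are cleared before the main pass)
      xsal <- NULL
      if (do_xai) {
        p1 <- batch[[1]]
        Hv <- model_saliency(m, p1$image, p1$melspec, labels[1],
                             method = "gradcam++", mode = mode)
        ig <- model_ig(m, p1$image, p1$melspec, labels[1], steps = xc$ig_steps,
                       baseline = xc$ig_baseline, mode = mode)
        xsal <- list(Hv = unclass(Hv), Ha = unclass(ig$heatmap))
      }
      zero_grads(layers)
      out <- model_forward(m, lapply(batch, `[[`, "image"),
                           lapply(batch, `[[`, "melspec"), mode = mode)
      ce <- cross_entropy(out$logits, labels)
      l_cs <- 0; l_margin <- 0; dzm <- NULL
      if (use_contrast && (cc$lambda1 > 0 || cc$lambda2 > 0) &&
          length(unique(labels)) >= 2) {
        pr <- build_pairs(out$zm, labels, hard_k = cc$hard_k,
                          similar_map = similar_map)
        li <- loss_infonce(out$zm, pr, tau = cc$temperature)
        lm <- loss_margin(out$zm, pr, delta = cc$margin)
        l_cs <- li$value; l_margin <- lm$value
        dzm <- cc$lambda1 * li$grad + cc$lambda2 * lm$grad
      }
      l_x <- 0; dFv_inj <- NULL; dP_inj <- NULL
      if (do_xai && !is.null(out$P_av)) {
        gfu <- gated_fuse(m, xsal$Hv, xsal$Ha)
        Mc_grid <- matrix(colSums(out$P_av[1, , ]), side, side)
        Mc_up <- block_up(Mc_grid, 64L %/% side, 64L %/% side)
        Pi_c <- mask_to_grid(batch[[1]]$mask, side)
        Fv1 <- array(out$Fv[tok_rows(1L, out$Nv), , drop = FALSE],
                     c(side, side, ncol(out$Fv)))
        lx <- loss_xai(gfu$Hc, Mc_up, Fv1, Pi_c, xc)
        l_x <- lx$value
        gate_bw(m, lx$dHc, gfu$cache)
        # interpreter heads regress onto the detached saliency maps
        interp_head_train(m, Fv1, xsal$Hv, "visual")
        gf <- m$config$acoustic_grid[1]; gt <- m$config$acoustic_grid[2]
        Fa1 <- array(out$Fa[tok_rows(1L, out$Na), , drop = FALSE],
                     c(gf, gt, ncol(out$Fa)))
        interp_head_train(m, Fa1, xsal$Ha, "acoustic")
        # dMc -> attention injection (chain through the block upsample);
        # dF -> visual feature injection, sample 1 only
        dmc_grid <- block_up_adj(lx$dMc, 64L %/% side, 64L %/% side)
        dP_inj <- array(0, dim(out$P_av))
        dP_inj[1, , ] <- matrix(as.vector(dmc_grid), out$Na, out$Nv, byrow = TRUE)
        dFv_inj <- matrix(0, nrow(out$Fv), ncol(out$Fv))
        dFv_inj[tok_rows(1L, out$Nv), ] <- matrix(lx$dF, out$Nv, ncol(out$Fv))
      }
      model_backward(m, out, dlogits = ce$grad, dzm = dzm, dFv = dFv_inj,
                     dP_av = dP_inj)
      l_total <- loss_total(ce$value, l_cs, l_margin, cc) + l_x
      lr_t <- cosine_lr(step - 1L, T_total, tc$lr_min, tc$lr)
      t_adam <- t_adam + 1L
      adamw_step(layers, lr_t, t_adam, wd = tc$weight_decay,
                 beta1 = tc$beta1, beta2 = tc$beta2)
      log_rows[[step]] <- data.frame(step = step, epoch = epoch, lr = lr_t,
                                     l_cls = ce$value, l_cs = l_cs,
                                     l_margin = l_margin, l_xai = l_x,
                                     l_total = l_total)
      if (!is.finite(l_total)) stop("training abort: non-finite loss at step ", step)
    }
    val_acc <- NA_real_
    if (!is.null(val_pairs)) {
      vm <- evaluate_model(m, val_pairs, mode = mode)
      val_acc <- vm$accuracy
      history[[epoch]] <- data.frame(epoch = epoch, val_accuracy = vm$accuracy,
                                     val_f1 = vm$f1, val_map50 = vm$map50)
      if (vm$accuracy > best_acc + 1e-12) {
        best_acc <- vm$accuracy; best_epoch <- epoch
        best_w <- dump_weights(layers); stall <- 0L
      } else stall <- stall + 1L
      if (stall >= tc$patience) {
        if (verbose) message("early stop at epoch ", epoch)
        break
      }
    }
    if (verbose)
      message(sprintf("epoch %d  loss %.4f  val_acc %s", epoch,
                      log_rows[[step]]$l_total,
                      ifelse(is.na(val_acc), "-", sprintf("%.3f", val_acc))))
  }
  if (!is.null(best_w)) load_weights(layers, best_w)
  structure(list(model = m, log = do.call(rbind, log_rows),
                 history = if (length(history)) do.call(rbind, history) else NULL,
                 best_epoch = best_epoch, best_val_accuracy = best_acc,
                 tc = tc, cc = cc, xc = xc, mode = mode),
            class = "avfit")
}

#' Stratified train/validation/test split
#'
#' @param pairs list of aligned pairs
#' @param fractions length-3 fractions summing to 1
#' @param seed shuffle seed
#' @return list with `train`, `val`, `test`
#' @export
split_dataset <- function(pairs, fractions = c(0.7, 0.15, 0.15), seed = 1) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  labels <- vapply(pairs, `[[`, 0, "label")
  tr <- va <- te <- integer(0)
  with_seed(seed, {
    for (c0 in unique(labels)) {
      idx <- sample(which(labels == c0))
      n <- length(idx)
      n_tr <- round(fractions[1] * n)
      n_va <- round(fractions[2] * n)
      tr <- c(tr, idx[seq_len(n_tr)])
      va <- c(va, idx[n_tr + seq_len(min(n_va, n - n_tr))])
      te <- c(te, idx[setdiff(seq_len(n), seq_len(n_tr + n_va))])
    }
  })
  list(train = pairs[tr], val = pairs[va], test = pairs[te])
}

#' Stratified k-fold cross-validation
#'
#' Partitions the pairs into k non-overlapping stratified folds (classes with
#' fewer than k members trigger a warning and an unstratified fallback); each
#' fold is validated exactly once by `runner(train_pairs, val_pairs, fold)`.
#'
#' @param pairs list of aligned pairs
#' @param k number of folds (>= 2)
#' @param runner function returning a `metrics_report` (or any named numeric
#'   list) per fold
#' @param seed fold assignment seed
#' @return list with `folds` (per-fold reports), `mean` and `sd` of the
#'   shared numeric metrics, and the fold `assignment`
#' @export
kfold_cv <- function(pairs, k, runner, seed = 1) {
  n <- length(pairs)
  stopifnot(k >= 2, n >= k)
  labels <- vapply(pairs, `[[`, 0, "label")
  assignment <- integer(n)
  with_seed(seed, {
    if (min(table(labels)) < k) {
      warning("class with fewer than k members; falling back to unstratified folds")
      assignment <- sample(rep(seq_len(k), length.out = n))
    } else {
      for (c0 in unique(labels)) {
        idx <- sample(which(labels == c0))
        assignment[idx] <- rep(seq_len(k), length.out = length(idx))
      }
    }
  })
  folds <- lapply(seq_len(k), function(f)
    runner(pairs[assignment != f], pairs[assignment == f], f))
  nums <- lapply(folds, function(r)
    unlist(r[vapply(r, function(v) is.numeric(v) && length(v) == 1, TRUE)]))
  keys <- Reduce(intersect, lapply(nums, names))
  mat <- do.call(rbind, lapply(nums, `[`, keys))
  list(folds = folds, mean = colMeans(mat), sd = apply(mat, 2, stats::sd),
       assignment = assignment)
}
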