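# Shared fixtures, built once per session and cached.

.fixtures <- new.env()

# small paired dataset: 3 classes x 8, reduced resolution and sampling rate
tiny_ds <- function() {
  if (is.null(.fixtures$ds)) {
    .fixtures$ds <- build_dataset(synth_config(
      n_classes = 3, samples_per_class = 8, image_size = 64,
      sample_rate = 16000, seed = 42))
  }
  .fixtures$ds
}

# smallest legal model geometry (32 x 32 input), used for gradient oracles
micro_model <- function(fusion = TRUE) {
  key <- paste0("micro_", fusion)
  if (is.null(.fixtures[[key]])) {
    cfg <- encoder_config("tiny", n_classes = 3, image_size = 32)
    .fixtures[[key]] <- build_model(cfg, seed = 5, fusion = fusion)
  }
  .fixtures[[key]]
}

micro_inputs <- function(n = 2, seed = 31) {
  set.seed(seed)
  list(images = lapply(seq_len(n), function(i) array(runif(32 * 32 * 3), c(32, 32, 3))),
       mels = lapply(seq_len(n), function(i) matrix(abs(rnorm(64 * 96)), 64, 96)))
}

# a trained model on the reduced benchmark, shared by saliency tests
trained_fit64 <- function() {
  if (is.null(.fixtures$fit64)) {
    ds <- build_dataset(synth_config(n_classes = 3, samples_per_class = 12,
                                     image_size = 64, sample_rate = 16000,
                                     seed = 7))
    sp <- split_dataset(ds$pairs, c(0.75, 0.25, 0), seed = 1)
    fit <- suppressWarnings(train_model(
      sp$train, sp$val,
      config = encoder_config("tiny", n_classes = 3, image_size = 64),
      tc = train_config(epochs = 15, seed = 1, patience = 5),
      bank = ds$bank, sample_rate = 16000))
    .fixtures$fit64 <- list(fit = fit, val = sp$val)
  }
  .fixtures$fit64
}

# central finite difference of a scalar function at selected indices
fd_grad <- function(f, x, idx = seq_along(x), eps = 1e-5) {
  vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, 0)
}

# unit vectors with all pairwise cosine similarities equal (regular simplex)
simplex_unit <- function(n) {
  X <- diag(n) - 1 / n
  X / sqrt(rowSums(X^2))
}
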