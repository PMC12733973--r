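# Augmentation operators for the two modalities, plus the paired-consistency
# wrapper that keeps visual and acoustic augmentation temporally coherent.

#' Augmentation parameter specification
#'
#' @param crop_ratio zoom factor alpha in (0, 1]; 1 keeps the full frame
#' @param dx,dy crop window offset in pixels
#' @param brightness additive brightness shift, 8-bit intensity units
#' @param contrast multiplicative contrast factor
#' @param noise_scale additive waveform noise gain (lambda)
#' @param noise_sd standard deviation of the waveform noise
#' @param time_shift acoustic time shift in seconds
#' @param kernel_f,kernel_t 1-D non-negative smoothing kernels (normalized to
#'   sum 1) applied along the spectrogram frequency / time axes
#' @return an `augment_spec` list
#' @export
augment_spec <- function(crop_ratio = 1, dx = 0, dy = 0, brightness = 0,
                         contrast = 1, noise_scale = 0, noise_sd = 1,
                         time_shift = 0, kernel_f = 1, kernel_t = 1) {
  if (crop_ratio <= 0 || crop_ratio > 1) stop("invalid spec: crop_ratio must be in (0,1]")
  if (any(kernel_f < 0) || any(kernel_t < 0)) stop("invalid spec: kernels must be non-negative")
  structure(list(crop_ratio = crop_ratio, dx = dx, dy = dy,
                 brightness = brightness, contrast = contrast,
                 noise_scale = noise_scale, noise_sd = noise_sd,
                 time_shift = time_shift,
                 kernel_f = kernel_f / sum(kernel_f),
                 kernel_t = kernel_t / sum(kernel_t)),
            class = "augment_spec")
}

bilinear_at <- function(channel, xi, yi) {
  # sample channel (rows = x) at fractional positions, clamped to the frame;
  # output takes the shape of the coordinate grids
  H <- nrow(channel); W <- ncol(channel)
  xi <- pmin(pmax(xi, 1), H); yi <- pmin(pmax(yi, 1), W)
  x0 <- pmin(floor(xi), max(H - 1, 1)); y0 <- pmin(floor(yi), max(W - 1, 1))
  fx <- xi - x0; fy <- yi - y0
  i00 <- as.vector(x0 + H * (y0 - 1)) # linear index of lower-left neighbour
  iH <- if (H > 1) 1L else 0L
  iW <- if (W > 1) H else 0L
  v <- as.vector((1 - fx) * (1 - fy)) * channel[i00] +
       as.vector(fx * (1 - fy)) * channel[i00 + iH] +
       as.vector((1 - fx) * fy) * channel[i00 + iW] +
       as.vector(fx * fy) * channel[i00 + iH + iW]
  matrix(v, nrow(xi), ncol(xi))
}

#' Random crop with rescale
#'
#' Samples the input at `I(alpha * x + dx, alpha * y + dy)` with bilinear
#' interpolation, so the output has the input's size and shows a zoomed
#' translated window. Out-of-bounds coordinates are clamped (no error).
#'
#' @param image H x W x 3 array
#' @param alpha crop ratio in (0, 1]
#' @param dx,dy window offset in pixels
#' @return augmented image, same shape
#' @export
random_crop <- function(image, alpha, dx = 0, dy = 0) {
  if (alpha <= 0 || alpha > 1) stop("invalid spec: alpha must be in (0,1]")
  d <- dim(image)
  xs <- alpha * (seq_len(d[1]) - 1) + dx + 1
  ys <- alpha * (seq_len(d[2]) - 1) + dy + 1
  xi <- matrix(rep(xs, d[2]), d[1], d[2])
  yi <- matrix(rep(ys, each = d[1]), d[1], d[2])
  out <- image
  for (c in seq_len(d[3])) out[, , c] <- bilinear_at(image[, , c], xi, yi)
  out
}

#' Photometric jitter (brightness / contrast)
#'
#' `p' = clip(c * p + b, 0, 255)` per pixel, in the 8-bit convention. Inputs in
#' \[0,1\] are scaled up and back transparently.
#'
#' @param image H x W x 3 array, in \[0,1\] or \[0,255\]
#' @param contrast multiplicative factor c
#' @param brightness additive bias b, 8-bit units
#' @return jittered image on the input's scale
#' @export
jitter_photometric <- function(image, contrast = 1, brightness = 0) {
  unit_scale <- max(image) <= 1
  p <- if (unit_scale) image * 255 else image
  out <- pmin(pmax(contrast * p + brightness, 0), 255)
  if (unit_scale) out / 255 else out
}

#' Background replacement under a foreground mask
#'
#' `I_bg = M * I + (1 - M) * B` elementwise.
#'
#' @param image,background H x W x 3 arrays of the same shape
#' @param mask H x W binary matrix (1 = foreground)
#' @return composited image
#' @export
replace_background <- function(image, mask, background) {
  if (!all(dim(image) == dim(background))) stop("invalid input: shape mismatch")
  if (!all(mask %in% c(0, 1))) stop("invalid input: mask must be binary")
  out <- image
  for (c in seq_len(dim(image)[3]))
    out[, , c] <- mask * image[, , c] + (1 - mask) * background[, , c]
  out
}

#' Temporal shift of a waveform
#'
#' `s_shift(t) = s(t + dt)`; vacated samples are zero-padded and the length is
#' preserved. Requires `|dt|` below the clip length.
#'
#' @param wave numeric waveform
#' @param dt shift in seconds (positive advances the signal)
#' @param sample_rate sampling rate in Hz
#' @return shifted waveform, same length
#' @export
shift_time <- function(wave, dt, sample_rate) {
  n <- length(wave)
  k <- round(dt * sample_rate)
  if (abs(k) >= n) stop("invalid spec: |time_shift| >= clip length")
  if (k == 0) return(wave)
  out <- numeric(n)
  if (k > 0) out[seq_len(n - k)] <- wave[(k + 1):n]
  else out[(-k + 1):n] <- wave[seq_len(n + k)]
  out
}

#' Additive Gaussian noise
#'
#' `s_noise = s + lambda * n`, `n ~ N(0, sd^2)`; reproducible under a fixed
#' RNG state.
#'
#' @param wave numeric waveform
#' @param lambda noise gain (>= 0)
#' @param sd noise standard deviation
#' @param rng_state integer seed
#' @return noisy waveform
#' @export
add_noise <- function(wave, lambda, sd = 1, rng_state = 1) {
  if (lambda < 0) stop("invalid spec: lambda must be >= 0")
  if (lambda == 0) return(wave)
  wave + lambda * with_seed(rng_state, stats::rnorm(length(wave), 0, sd))
}

conv1d_reflect <- function(x, k) {
  # 'same' 1-D convolution with reflective padding, along vector x
  m <- length(k)
  if (m == 1) return(x * k)
  hl <- (m - 1) %/% 2; hr <- m - 1 - hl
  n <- length(x)
  if (m > n) stop("invalid spec: kernel longer than axis")
  pre <- if (hl > 0) x[(hl + 1):2] else numeric(0)
  post <- if (hr > 0) x[(n - 1):(n - hr)] else numeric(0)
  xp <- c(pre, x, post)
  out <- numeric(n)
  for (i in seq_len(m)) out <- out + k[i] * xp[i:(i + n - 1)]
  out
}

#' Separable spectrogram smoothing
#'
#' Convolves the mel-spectrogram with normalized 1-D kernels along the
#' frequency axis then the time axis, with reflective padding; the shape is
#' preserved.
#'
#' @param melspec F x T matrix
#' @param kernel_f,kernel_t non-negative 1-D kernels (normalized internally)
#' @return smoothed spectrogram, same shape
#' @export
smooth_spectrogram <- function(melspec, kernel_f, kernel_t) {
  if (any(kernel_f < 0) || any(kernel_t < 0)) stop("invalid spec: negative kernel")
  kf <- kernel_f / sum(kernel_f); kt <- kernel_t / sum(kernel_t)
  if (length(kf) > nrow(melspec) || length(kt) > ncol(melspec))
    stop("invalid spec: kernel longer than axis")
  out <- apply(melspec, 2, conv1d_reflect, k = kf)
  t(apply(out, 1, conv1d_reflect, k = kt))
}

#' Apply a coherent augmentation to an aligned pair
#'
#' Visual ops (crop, photometric jitter) and acoustic ops (time shift, noise,
#' spectrogram smoothing) are applied with one shared RNG state. A non-zero
#' time shift updates the pair's acoustic timestamp by the same amount so that
#' cross-modal consistency can be asserted afterwards. The label is unchanged.
#'
#' @param pair an aligned pair from [build_dataset()]
#' @param spec an [augment_spec()]
#' @param rng_state integer seed shared by all stochastic sub-ops
#' @param sample_rate audio sampling rate of the pair's waveform
#' @param mel_args list of arguments for re-computing the mel-spectrogram
#' @return the augmented pair
#' @export
paired_augment <- function(pair, spec, rng_state = 1, sample_rate = 44100,
                           mel_args = list()) {
  stopifnot(inherits(spec, "augment_spec"))
  out <- pair
  out$image <- random_crop(pair$image, spec$crop_ratio, spec$dx, spec$dy)
  out$image <- jitter_photometric(out$image, spec$contrast, spec$brightness)
  w <- pair$wave
  if (spec$time_shift != 0) {
    w <- shift_time(w, spec$time_shift, sample_rate)
    out$t_acoustic <- pair$t_acoustic + spec$time_shift
  }
  w <- add_noise(w, spec$noise_scale, spec$noise_sd, rng_state = rng_state)
  out$wave <- w
  if (spec$time_shift != 0 || spec$noise_scale != 0) {
    ma <- utils::modifyList(list(sample_rate = sample_rate,
                                 n_mels = nrow(pair$melspec),
                                 n_frames = ncol(pair$melspec)), mel_args)
    out$melspec <- do.call(melspectrogram, c(list(w), ma))
  }
  if (length(spec$kernel_f) > 1 || length(spec$kernel_t) > 1)
    out$melspec <- smooth_spectrogram(out$melspec, spec$kernel_f, spec$kernel_t)
  out
}

#' Sample a random augmentation spec from configured ranges
#'
#' Ranges follow the package defaults (crop ratio 0.7-1, brightness +-20,
#' contrast 0.8-1.2, noise gain 0-0.1, time shift +-0.1 s); a YAML registry
#' file with entries `op: c(lo, hi)` can override them.
#'
#' @param rng_state integer seed
#' @param ranges optional named list of c(lo, hi) ranges
#' @param yaml_path optional YAML file of ranges
#' @return an [augment_spec()]
#' @export
sample_augment_spec <- function(rng_state = 1, ranges = list(), yaml_path = NULL) {
  def <- list(crop_ratio = c(0.7, 1), brightness = c(-20, 20),
              contrast = c(0.8, 1.2), noise_scale = c(0, 0.1),
              time_shift = c(-0.1, 0.1))
  if (!is.null(yaml_path)) ranges <- utils::modifyList(yaml::read_yaml(yaml_path), ranges)
  r <- utils::modifyList(def, ranges)
  with_seed(rng_state, {
    a <- stats::runif(1, r$crop_ratio[1], r$crop_ratio[2])
    augment_spec(crop_ratio = a,
                 dx = stats::runif(1, 0, 4), dy = stats::runif(1, 0, 4),
                 brightness = stats::runif(1, r$brightness[1], r$brightness[2]),
                 contrast = stats::runif(1, r$contrast[1], r$contrast[2]),
                 noise_scale = stats::runif(1, r$noise_scale[1], r$noise_scale[2]),
                 time_shift = stats::runif(1, r$time_shift[1], r$time_shift[2]))
  })
}
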