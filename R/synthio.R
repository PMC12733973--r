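# Synthetic paired image/audio generator. Each species class has a distinct
# visual morphology (ellipse body, pronotum band, spot pattern) and a distinct
# acoustic signature (wingbeat fundamental + harmonic stack). Even-indexed
# classes are paired with a deliberately confusable partner class to exercise
# hard-negative mining downstream.

# evaluate expr under a temporary RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a bank of synthetic species specifications
#'
#' Every even-indexed class (0-based) is paired with the next class as a
#' designated "similar" partner: the partner shares its body morphology and
#' differs in exactly one visual attribute (pronotum colour) and by at most
#' 15% in wingbeat fundamental, so the pair forms a genuinely hard negative.
#'
#' @param n_classes number of classes (>= 2)
#' @param seed integer seed; the bank is deterministic given the seed
#' @param sample_rate audio sampling rate the clips will use (harmonics are
#'   kept below Nyquist)
#' @return a list of species specs, each a list with `class_id`, `spot_count`,
#'   `spot_layout` (n x 2 fractional coordinates), `body_hue`, `pronotum_hue`,
#'   `wingbeat_hz`, `harmonic_weights`, `similar_to`
#' @export
make_species_bank <- function(n_classes, seed = 1, sample_rate = 44100) {
  if (!is.numeric(n_classes) || n_classes < 2)
    stop("invalid config: n_classes must be >= 2")
  n_classes <- as.integer(n_classes)
  with_seed(seed, {
    bank <- vector("list", n_classes)
    for (i in seq_len(n_classes)) {
      id <- i - 1L
      if (id %% 2L == 0L || is.null(bank[[i - 1]])) {
        nspot <- sample(0:6, 1)
        spec <- list(
          class_id = id,
          spot_count = nspot,
          spot_layout = if (nspot > 0)
            cbind(runif(nspot, 0.15, 0.85), runif(nspot, 0.2, 0.8))
          else matrix(0, 0, 2),
          body_hue = runif(3, 0.2, 1),
          pronotum_hue = runif(3, 0, 1),
          wingbeat_hz = runif(1, 120, 600),
          harmonic_weights = {
            nh <- sample(3:5, 1)
            w <- exp(-0.7 * (seq_len(nh) - 1)) * runif(nh, 0.7, 1)
            w / max(w)
          },
          similar_to = if (id %% 2L == 0L && id + 1L < n_classes) id + 1L else NULL
        )
      } else {
        # partner of the previous (even) class: one visual attribute changed,
        # wingbeat within 15%
        base <- bank[[i - 1]]
        spec <- base
        spec$class_id <- id
        spec$pronotum_hue <- runif(3, 0, 1)
        spec$wingbeat_hz <- base$wingbeat_hz * runif(1, 0.88, 1.14)
        spec$similar_to <- id - 1L
      }
      nyq <- sample_rate / 2
      stopifnot(spec$wingbeat_hz > 0, spec$wingbeat_hz < nyq)
      bank[[i]] <- spec
    }
    bank
  })
}

#' Procedural background scene
#'
#' Low-frequency coloured gradients with soft blobs, loosely imitating foliage
#' or soil; used as the compositing background for rendered insects and as the
#' replacement pool for background-swap augmentation.
#'
#' @param image_size pixels per side
#' @param seed integer seed
#' @return `image_size` x `image_size` x 3 array in \[0,1\]
#' @export
make_background <- function(image_size, seed = 1) {
  with_seed(seed, {
    n <- image_size
    u <- matrix(rep(seq(0, 1, length.out = n), n), n, n)
    v <- t(u)
    base <- runif(3, 0.1, 0.6)
    dir <- runif(2, -1, 1)
    img <- array(0, c(n, n, 3))
    grad <- dir[1] * u + dir[2] * v
    for (c in 1:3) img[, , c] <- base[c] + 0.25 * grad
    for (b in seq_len(6)) {
      cx <- runif(1); cy <- runif(1); r <- runif(1, 0.05, 0.25)
      blob <- exp(-((u - cx)^2 + (v - cy)^2) / (2 * r^2))
      hue <- runif(3, -0.2, 0.2)
      for (c in 1:3) img[, , c] <- img[, , c] + hue[c] * blob
    }
    pmin(pmax(img, 0), 1)
  })
}

#' Render a synthetic insect image
#'
#' Draws an ellipse body in the species' body hue with a pronotum band at the
#' anterior end and `spot_count` dark spots at the spec's fractional layout
#' positions, composited onto the supplied background. The returned binary
#' foreground mask is reused by background-replacement augmentation and as the
#' class gating mask of the explanation loss.
#'
#' @param spec a species spec from [make_species_bank()]
#' @param background H x W x 3 array in \[0,1\]
#' @param rng_state integer seed controlling pose jitter
#' @return list with `image` (H x W x 3 in \[0,1\]) and `mask` (H x W in {0,1})
#' @export
render_image <- function(spec, background, rng_state = 1) {
  d <- dim(background)
  if (length(d) != 3 || d[3] != 3) stop("invalid input: background must be HxWx3")
  if (nrow(spec$spot_layout) > 0 &&
      (any(spec$spot_layout < 0) || any(spec$spot_layout > 1)))
    stop("invalid spec: spot coordinates outside [0,1]")
  n <- d[1]
  with_seed(rng_state, {
    u <- matrix(rep(seq(0, 1, length.out = n), d[2]), n, d[2])
    v <- matrix(rep(seq(0, 1, length.out = d[2]), each = n), n, d[2])
    cx <- 0.5 + runif(1, -0.06, 0.06)
    cy <- 0.5 + runif(1, -0.06, 0.06)
    th <- runif(1, 0, pi)
    a <- 0.30; b <- 0.19 # semi-axes in fractional units
    xr <- (u - cx) * cos(th) + (v - cy) * sin(th)
    yr <- -(u - cx) * sin(th) + (v - cy) * cos(th)
    ell <- (xr / a)^2 + (yr / b)^2
    mask <- ell <= 1
    img <- background
    shade <- 1 - 0.35 * pmin(ell, 1) # radial shading for body texture
    for (c in 1:3) {
      ch <- img[, , c]
      ch[mask] <- (spec$body_hue[c] * shade)[mask]
      img[, , c] <- ch
    }
    # pronotum: anterior band of the ellipse along the major axis
    pron <- mask & (xr > 0.55 * a)
    for (c in 1:3) {
      ch <- img[, , c]
      ch[pron] <- spec$pronotum_hue[c]
      img[, , c] <- ch
    }
    # spots in body-frame coordinates
    if (spec$spot_count > 0) {
      for (s in seq_len(spec$spot_count)) {
        sx <- (spec$spot_layout[s, 1] * 2 - 1) * a * 0.8
        sy <- (spec$spot_layout[s, 2] * 2 - 1) * b * 0.8
        spot <- ((xr - sx)^2 + (yr - sy)^2 <= (0.03)^2) & mask
        for (c in 1:3) {
          ch <- img[, , c]
          ch[spot] <- 0.05
          img[, , c] <- ch
        }
      }
    }
    list(image = pmin(pmax(img, 0), 1), mask = mask * 1)
  })
}

#' Synthesize a wingbeat audio clip
#'
#' Sum of sinusoids at multiples of the wingbeat fundamental weighted by the
#' spec's harmonic weights, with slow amplitude modulation and a small Gaussian
#' noise floor; peak-normalized to at most 1. Harmonics at or above Nyquist
#' are dropped with a warning.
#'
#' @param spec a species spec
#' @param clip_seconds clip duration (s)
#' @param sample_rate sampling rate (Hz)
#' @param rng_state integer seed (phases, AM rate, noise)
#' @param noise_floor standard deviation of the additive noise floor
#' @return numeric waveform of length `clip_seconds * sample_rate`
#' @export
synth_clip <- function(spec, clip_seconds = 1, sample_rate = 44100,
                       rng_state = 1, noise_floor = 0.01) {
  n <- round(clip_seconds * sample_rate)
  if (n < 1) stop("invalid config: clip too short")
  with_seed(rng_state, {
    t <- seq_len(n) / sample_rate
    sig <- numeric(n)
    w <- spec$harmonic_weights
    for (k in seq_along(w)) {
      fk <- spec$wingbeat_hz * k
      if (fk >= sample_rate / 2) {
        warning(sprintf("harmonic %d at %.0f Hz above Nyquist; dropped", k, fk))
        next
      }
      if (w[k] > 0) sig <- sig + w[k] * sin(2 * pi * fk * t + runif(1, 0, 2 * pi))
    }
    if (any(sig != 0)) {
      am <- 1 + 0.3 * sin(2 * pi * runif(1, 2, 8) * t + runif(1, 0, 2 * pi))
      sig <- sig * am
    }
    out <- sig + noise_floor * stats::rnorm(n)
    pk <- max(abs(out))
    if (pk > 1) out <- out / pk
    out
  })
}

#' Configuration for a synthetic paired dataset
#'
#' @param n_classes number of species classes
#' @param samples_per_class pairs generated per class
#' @param image_size image pixels per side
#' @param sample_rate audio sampling rate (Hz)
#' @param clip_seconds audio clip length (s)
#' @param mel_bins mel filterbank size
#' @param mel_frames spectrogram frames (clips are padded/truncated)
#' @param timestamp_jitter_sd s.d. (seconds) of the visual-acoustic timestamp offset
#' @param background_pool_size number of procedural backgrounds cycled through
#' @param weak_fraction fraction of pairs flagged weakly aligned (overlapping
#'   call from a second species mixed in at equal power)
#' @param background_snr_db range c(lo, hi) of the per-clip background-noise
#'   SNR in dB, drawn uniformly per sample; emulates the acoustic conditions
#'   of field recordings (quiet sites near the high end, windy or busy sites
#'   near the low end). NULL disables background noise.
#' @param seed master seed; fixes the entire generation stream
#' @return a `synth_config` list
#' @export
synth_config <- function(n_classes = 3, samples_per_class = 20, image_size = 128,
                         sample_rate = 44100, clip_seconds = 1, mel_bins = 64,
                         mel_frames = 96, timestamp_jitter_sd = 0.02,
                         background_pool_size = 8, weak_fraction = 0.05,
                         background_snr_db = c(8, 18), seed = 1) {
  cfg <- list(n_classes = as.integer(n_classes),
              samples_per_class = as.integer(samples_per_class),
              image_size = as.integer(image_size), sample_rate = sample_rate,
              clip_seconds = clip_seconds, mel_bins = as.integer(mel_bins),
              mel_frames = as.integer(mel_frames),
              timestamp_jitter_sd = timestamp_jitter_sd,
              background_pool_size = as.integer(background_pool_size),
              weak_fraction = weak_fraction,
              background_snr_db = background_snr_db, seed = as.integer(seed))
  if (cfg$n_classes < 2 || cfg$samples_per_class < 1 || cfg$image_size < 16 ||
      cfg$mel_bins < 8 || cfg$timestamp_jitter_sd < 0)
    stop("invalid config")
  class(cfg) <- "synth_config"
  cfg
}

#' Build a synthetic paired image/audio dataset
#'
#' Generates `n_classes * samples_per_class` aligned pairs. Per-sample RNG
#' substreams are derived from the master seed by counter, so generation is
#' reproducible and order-independent. About `weak_fraction` of pairs are
#' flagged weakly aligned: a clip from a different species is mixed in at equal
#' power (overlapping-call simulation) and the pair is excluded from supervised
#' multimodal training by downstream code.
#'
#' @param config a [synth_config()]
#' @param out_dir optional directory; if given, images (PNG), audio (WAV),
#'   labels (JSON), environment metadata (CSV) and a manifest (YAML) are written
#' @return list with `pairs` (list of aligned pairs: `image`, `mask`, `melspec`,
#'   `wave`, `label`, `t_visual`, `t_acoustic`, `aligned`), `bank`, `config`
#' @export
build_dataset <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  bank <- make_species_bank(config$n_classes, seed = config$seed,
                            sample_rate = config$sample_rate)
  bgs <- lapply(seq_len(config$background_pool_size), function(i)
    make_background(config$image_size, seed = derive_seed(config$seed, 9000 + i)))
  n_total <- config$n_classes * config$samples_per_class
  step <- config$clip_seconds + 0.5
  pairs <- vector("list", n_total)
  idx <- 0L
  n_weak <- floor(config$weak_fraction * n_total)
  weak_every <- if (n_weak > 0) max(2L, floor(n_total / n_weak)) else NA_integer_
  for (ci in seq_len(config$n_classes)) {
    for (si in seq_len(config$samples_per_class)) {
      idx <- idx + 1L
      sd_i <- derive_seed(config$seed, idx)
      spec <- bank[[ci]]
      bg <- bgs[[(idx - 1L) %% length(bgs) + 1L]]
      ri <- render_image(spec, bg, rng_state = sd_i)
      wave <- synth_clip(spec, config$clip_seconds, config$sample_rate,
                         rng_state = derive_seed(config$seed, idx + 50000L))
      if (!is.null(config$background_snr_db)) {
        # ambient background at a field-realistic per-clip SNR
        bsd <- derive_seed(config$seed, idx + 60000L)
        snr <- with_seed(bsd, stats::runif(1, config$background_snr_db[1],
                                           config$background_snr_db[2]))
        bgn <- with_seed(bsd + 1L, stats::rnorm(length(wave)))
        wave <- mix_at_snr(wave, bgn, snr)$wave
        pk <- max(abs(wave)); if (pk > 1) wave <- wave / pk
      }
      aligned <- TRUE
      if (!is.na(weak_every) && idx %% weak_every == 0L) {
        other <- bank[[(ci %% config$n_classes) + 1L]]
        ow <- synth_clip(other, config$clip_seconds, config$sample_rate,
                         rng_state = derive_seed(config$seed, idx + 70000L))
        ow <- ow * sqrt(mean(wave^2) / max(mean(ow^2), 1e-12)) # equal power
        wave <- (wave + ow)
        pk <- max(abs(wave)); if (pk > 1) wave <- wave / pk
        aligned <- FALSE
      }
      tv <- (idx - 1L) * step
      ta <- tv + with_seed(derive_seed(config$seed, idx + 90000L),
                           stats::rnorm(1, 0, config$timestamp_jitter_sd))
      mel <- melspectrogram(wave, config$sample_rate, n_mels = config$mel_bins,
                            n_frames = config$mel_frames)
      pairs[[idx]] <- list(image = ri$image, mask = ri$mask, melspec = mel,
                           wave = wave, label = spec$class_id,
                           t_visual = tv, t_acoustic = ta, aligned = aligned)
    }
  }
  ds <- list(pairs = pairs, bank = bank, config = config)
  if (!is.null(out_dir)) write_dataset(ds, out_dir)
  ds
}

#' Write a synthetic dataset to disk
#'
#' Emits one PNG and one WAV per pair, a labels JSON (file stem to class id,
#' alignment flag and timestamps), an environment CSV (timestamp, temperature,
#' humidity, light) and a manifest YAML with the configuration and label
#' histogram.
#'
#' @param ds result of [build_dataset()]
#' @param out_dir output directory (created if needed)
#' @return `out_dir`, invisibly
#' @export
write_dataset <- function(ds, out_dir) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("I/O error: cannot create ", out_dir)
  labels <- list()
  stems <- character(length(ds$pairs))
  for (i in seq_along(ds$pairs)) {
    p <- ds$pairs[[i]]
    stem <- sprintf("pair_%04d", i)
    stems[i] <- stem
    png::writePNG(p$image, file.path(out_dir, paste0(stem, ".png")))
    write_wav(p$wave, file.path(out_dir, paste0(stem, ".wav")),
              ds$config$sample_rate)
    labels[[stem]] <- list(class_id = p$label, aligned = p$aligned,
                           t_visual = p$t_visual, t_acoustic = p$t_acoustic)
  }
  jsonlite::write_json(labels, file.path(out_dir, "labels.json"),
                       auto_unbox = TRUE, digits = NA)
  tv <- vapply(ds$pairs, `[[`, 0, "t_visual")
  env <- data.frame(
    timestamp = tv,
    temperature = with_seed(derive_seed(ds$config$seed, 123321L),
                            22 + 5 * sin(tv / 600) + stats::rnorm(length(tv), 0, 0.3)),
    humidity = with_seed(derive_seed(ds$config$seed, 123322L),
                         60 + 10 * cos(tv / 900) + stats::rnorm(length(tv), 0, 1)),
    light = with_seed(derive_seed(ds$config$seed, 123323L),
                      pmax(0, 800 + 300 * sin(tv / 450) + stats::rnorm(length(tv), 0, 20))))
  utils::write.csv(env, file.path(out_dir, "environment.csv"), row.names = FALSE)
  hist <- table(vapply(ds$pairs, `[[`, 0, "label"))
  manifest <- list(
    config = unclass(ds$config),
    n_pairs = length(ds$pairs),
    label_histogram = as.list(stats::setNames(as.integer(hist), names(hist))),
    files = stems)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' Read timestamp streams back from a written dataset
#'
#' @param dir directory previously produced by [write_dataset()]
#' @return list with sorted `t_visual` and `t_acoustic` vectors
#' @export
read_timestamps <- function(dir) {
  labels <- jsonlite::read_json(file.path(dir, "labels.json"))
  list(t_visual = sort(vapply(labels, function(x) x$t_visual, 0)),
       t_acoustic = sort(vapply(labels, function(x) x$t_acoustic, 0)))
}
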