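# Synthetic paired-data generator: class structure, similarity structure,
# acoustic signatures, dataset assembly and its determinism.

test_that("species bank pairs confusable classes and is deterministic", {
  expect_error(make_species_bank(1), "n_classes")
  b2 <- make_species_bank(2, seed = 7)
  expect_length(b2, 2)
  expect_identical(b2[[1]]$similar_to, 1L)

  b15 <- make_species_bank(15, seed = 1)
  starts <- Filter(function(s) s$class_id %% 2 == 0 && !is.null(s$similar_to), b15)
  expect_length(starts, 7) # 7 similar pairs + 1 singleton
  expect_null(b15[[15]]$similar_to)

  expect_identical(make_species_bank(15, seed = 3), make_species_bank(15, seed = 3))
  expect_false(identical(make_species_bank(15, seed = 3), make_species_bank(15, seed = 4)))
})

test_that("confusable partners differ in one visual attribute and <= 15% wingbeat", {
  b <- make_species_bank(10, seed = 11)
  for (i in seq(1, 9, by = 2)) {
    a <- b[[i]]; p <- b[[i + 1]]
    expect_identical(a$spot_count, p$spot_count)
    expect_identical(a$spot_layout, p$spot_layout)
    expect_identical(a$body_hue, p$body_hue)
    expect_false(identical(a$pronotum_hue, p$pronotum_hue))
    expect_lte(abs(p$wingbeat_hz / a$wingbeat_hz - 1), 0.15)
  }
})

test_that("render_image composites a masked body onto the background", {
  b <- make_species_bank(3, seed = 2)
  bg <- make_background(64, seed = 1)
  ri <- render_image(b[[1]], bg, rng_state = 9)
  expect_equal(dim(ri$image), c(64, 64, 3))
  expect_true(all(ri$image >= 0 & ri$image <= 1))
  expect_true(all(ri$mask %in% c(0, 1)))
  expect_gt(sum(ri$mask), 0)

  # zero-spot spec: mask is exactly the ellipse; spots only darken inside it
  spec0 <- b[[1]]; spec0$spot_count <- 0L; spec0$spot_layout <- matrix(0, 0, 2)
  r0 <- render_image(spec0, bg, rng_state = 9)
  expect_identical(r0$mask, ri$mask)

  # white body on black background: foreground brighter than background
  spec_w <- spec0
  spec_w$body_hue <- c(1, 1, 1); spec_w$pronotum_hue <- c(1, 1, 1)
  rw <- render_image(spec_w, array(0, c(64, 64, 3)), rng_state = 5)
  inside <- mean(rw$image[rw$mask == 1])
  outside <- mean(rw$image[rw$mask == 0])
  expect_gt(inside, outside)

  # determinism and spot-coordinate validation
  expect_identical(render_image(b[[2]], bg, rng_state = 4),
                   render_image(b[[2]], bg, rng_state = 4))
  bad <- b[[1]]; bad$spot_count <- 1L; bad$spot_layout <- matrix(c(1.4, 0.5), 1)
  expect_error(render_image(bad, bg), "spot coordinates")
})

test_that("synth_clip places its spectral peak at the wingbeat fundamental", {
  spec <- make_species_bank(2, seed = 1)[[1]]
  spec$wingbeat_hz <- 200; spec$harmonic_weights <- 1
  w <- synth_clip(spec, 1, 8000, rng_state = 3)
  expect_lte(max(abs(w)), 1)
  p <- Mod(stats::fft(w))^2
  half <- p[seq_len(length(w) / 2)]
  peak_hz <- (which.max(half) - 1) * 8000 / length(w)
  expect_lte(abs(peak_hz - 200), 8000 / length(w)) # within one FFT bin

  # zero harmonic weights: pure noise floor at the configured RMS
  spec$harmonic_weights <- c(0, 0)
  w0 <- synth_clip(spec, 1, 8000, rng_state = 3, noise_floor = 0.01)
  expect_lt(abs(sqrt(mean(w0^2)) / 0.01 - 1), 0.05)

  # determinism
  spec$harmonic_weights <- c(1, 0.5)
  expect_identical(synth_clip(spec, 1, 8000, rng_state = 6),
                   synth_clip(spec, 1, 8000, rng_state = 6))

  # harmonics above Nyquist are dropped with a warning
  spec$wingbeat_hz <- 3000; spec$harmonic_weights <- c(1, 1)
  expect_warning(synth_clip(spec, 0.5, 8000, rng_state = 1), "Nyquist")
})

test_that("build_dataset produces counted, jittered, reproducible pairs", {
  ds <- tiny_ds()
  expect_length(ds$pairs, 24)
  expect_equal(as.integer(table(vapply(ds$pairs, `[[`, 0, "label"))), rep(8L, 3))
  expect_true(all(vapply(ds$pairs, function(p) min(p$melspec) >= 0, TRUE)))
  expect_true(all(vapply(ds$pairs, function(p)
    min(p$image) >= 0 && max(p$image) <= 1, TRUE)))
  # ~5% weakly aligned (floor(0.05 * 24) = 1)
  expect_equal(sum(!vapply(ds$pairs, `[[`, TRUE, "aligned")), 1)

  # zero jitter: timestamps coincide
  ds0 <- build_dataset(synth_config(n_classes = 2, samples_per_class = 3,
                                    image_size = 32, sample_rate = 8000,
                                    timestamp_jitter_sd = 0, seed = 5))
  expect_equal(vapply(ds0$pairs, `[[`, 0, "t_visual"),
               vapply(ds0$pairs, `[[`, 0, "t_acoustic"))

  # full determinism under the seed
  ds1 <- build_dataset(synth_config(n_classes = 2, samples_per_class = 3,
                                    image_size = 32, sample_rate = 8000, seed = 9))
  ds2 <- build_dataset(synth_config(n_classes = 2, samples_per_class = 3,
                                    image_size = 32, sample_rate = 8000, seed = 9))
  expect_identical(ds1$pairs, ds2$pairs)
})

test_that("written dataset round-trips through the manifest formats", {
  ds <- build_dataset(synth_config(n_classes = 2, samples_per_class = 3,
                                   image_size = 32, sample_rate = 8000, seed = 9))
  td <- withr::local_tempdir()
  write_dataset(ds, td)
  expect_length(list.files(td, pattern = "\\.png$"), 6)
  expect_length(list.files(td, pattern = "\\.wav$"), 6)
  expect_true(all(file.exists(file.path(td, c("labels.json", "environment.csv",
                                              "manifest.yaml")))))
  man <- yaml::read_yaml(file.path(td, "manifest.yaml"))
  expect_equal(man$n_pairs, 6)
  expect_equal(unlist(man$label_histogram), c(`0` = 3L, `1` = 3L))
  wv <- read_wav(file.path(td, "pair_0001.wav"))
  expect_equal(wv$sample_rate, 8000)
  expect_lt(max(abs(wv$wave - ds$pairs[[1]]$wave)), 1 / 32000) # 16-bit quantization
  ts <- read_timestamps(td)
  expect_length(ts$t_visual, 6)
  expect_false(is.unsorted(ts$t_visual))
})

test_that("generator encodes class signal: nearest-centroid beats chance", {
  ds <- build_dataset(synth_config(n_classes = 3, samples_per_class = 20,
                                   image_size = 64, sample_rate = 16000, seed = 13))
  lab <- vapply(ds$pairs, `[[`, 0, "label")
  # joint raw-input descriptor: image channel means + mel row means
  X <- t(vapply(ds$pairs, function(p)
    c(apply(p$image, 3, mean), rowMeans(p$melspec)), numeric(3 + 64)))
  correct <- 0
  for (i in seq_len(nrow(X))) {
    cents <- vapply(0:2, function(c0)
      colMeans(X[lab == c0 & seq_len(nrow(X)) != i, , drop = FALSE]), numeric(ncol(X)))
    d <- colSums((cents - X[i, ])^2)
    correct <- correct + (which.min(d) - 1 == lab[i])
  }
  expect_gt(correct / nrow(X), 1 / 3)
})

test_that("similar classes are closer in image space than dissimilar ones", {
  ds <- build_dataset(synth_config(n_classes = 4, samples_per_class = 6,
                                   image_size = 64, sample_rate = 16000, seed = 21))
  lab <- vapply(ds$pairs, `[[`, 0, "label")
  feat <- t(vapply(ds$pairs, function(p) as.vector(apply(p$image, 3, mean)), numeric(3)))
  cent <- vapply(0:3, function(c0) colMeans(feat[lab == c0, , drop = FALSE]), numeric(3))
  dmat <- as.matrix(stats::dist(t(cent)))
  similar <- mean(c(dmat[1, 2], dmat[3, 4]))          # designated pairs (0,1), (2,3)
  dissimilar <- mean(dmat[cbind(c(1, 1, 2, 2), c(3, 4, 3, 4))])
  expect_lt(similar, dissimilar)
})

test_that("full-scale generation of 300 pairs stays under a minute", {
  t0 <- Sys.time()
  ds <- build_dataset(synth_config(n_classes = 5, samples_per_class = 60,
                                   image_size = 128, sample_rate = 44100,
                                   clip_seconds = 1, seed = 3))
  elapsed <- as.numeric(Sys.time() - t0, units = "secs")
  expect_length(ds$pairs, 300)
  expect_lt(elapsed, 60)
})

test_that("mel-spectrogram front end is shaped and non-negative", {
  w <- sin(2 * pi * 440 * seq_len(8000) / 8000)
  mel <- melspectrogram(w, 8000, n_mels = 32, n_frames = 50)
  expect_equal(dim(mel), c(32, 50))
  expect_gte(min(mel), 0)
  # energy concentrates near the 440 Hz band rather than the top bins
  expect_gt(sum(mel[1:16, ]), sum(mel[17:32, ]))
})
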