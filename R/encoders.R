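# Public single-sample encoder API. The visual branch is a hierarchical
# windowed-attention encoder (window plus cyclically shifted window blocks per
# stage, patch merging between stages) with a stride-2 transposed-convolution
# decoder; the acoustic branch is a patch Transformer over the mel-spectrogram
# with a small convolutional stem and sinusoidal temporal positional encoding.
# Both project into a shared width d through one shared matrix.

featuremap <- function(arr, modality) structure(arr, class = "featuremap",
                                                modality = modality)

#' Encode an image to a spatial feature map
#'
#' @param m an `avmodel`
#' @param image H x W x 3 array matching the configured input size
#' @param project apply the shared projection to width d (default)
#' @return a `featuremap`: side x side x channels array (8 x 8 x d at the
#'   reference geometry), deterministic for fixed weights
#' @export
encode_visual <- function(m, image, project = TRUE) {
  d <- dim(image)
  if (length(d) != 3 || d[1] != m$config$image_size || d[2] != m$config$image_size)
    stop("invalid input: image must be ", m$config$image_size, "x",
         m$config$image_size, "x3")
  vf <- visual_fw(m, list(image))
  y <- vf$y
  if (project) y <- lin_fw(m$wp, y)$y
  side <- 2L * m$grids[4]
  featuremap(array(y, c(side, side, ncol(y))), "visual")
}

#' Encode a mel-spectrogram to a time-frequency feature map
#'
#' @param m an `avmodel`
#' @param melspec F x T matrix matching the configured geometry
#' @param project apply the shared projection to width d (default)
#' @return a `featuremap`: 8 x 4 x channels array
#' @export
encode_acoustic <- function(m, melspec, project = TRUE) {
  if (nrow(melspec) != m$config$mel_bins || ncol(melspec) != m$config$mel_frames)
    stop("invalid input: melspec must be ", m$config$mel_bins, "x",
         m$config$mel_frames)
  af <- acoustic_fw(m, list(melspec))
  y <- af$y
  if (project) y <- lin_fw(m$wp, y)$y
  g <- m$config$acoustic_grid
  featuremap(array(y, c(g[1], g[2], ncol(y))), "acoustic")
}

#' Apply the shared cross-modal projection
#'
#' One projection matrix `Wp` maps both modality feature maps, position-wise,
#' to the unified width d.
#'
#' @param m an `avmodel`
#' @param feature h x w x C array with C matching the projection input width
#' @return projected `featuremap` (h x w x d)
#' @export
project_shared <- function(m, feature) {
  d <- dim(feature)
  if (d[3] != nrow(m$wp$W))
    stop("invalid input: channel width ", d[3], " does not match projection")
  y <- lin_fw(m$wp, matrix(feature, d[1] * d[2], d[3]))$y
  featuremap(array(y, c(d[1], d[2], ncol(y))),
             attr(feature, "modality") %||% "unknown")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
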