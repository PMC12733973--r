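# Timestamp alignment between the visual and acoustic streams, and the
# cross-modal feature consistency check.

check_streams <- function(t_visual, t_acoustic) {
  if (length(t_visual) == 0 || length(t_acoustic) == 0)
    stop("invalid input: empty timestamp stream")
  if (is.unsorted(t_visual, strictly = TRUE) || is.unsorted(t_acoustic, strictly = TRUE))
    stop("invalid input: timestamp streams must be strictly increasing")
  invisible(TRUE)
}

#' Nearest-neighbour timestamp alignment
#'
#' Maps every visual timestamp to the acoustic timestamp minimizing the
#' absolute time difference; ties are broken toward the earlier acoustic
#' timestamp. The reported `mean_abs_error` is the mean absolute residual of
#' the chosen mapping.
#'
#' @param t_visual,t_acoustic strictly increasing timestamp vectors (seconds)
#' @return an `alignment_result`: list with `mapping` (1-based indices into
#'   `t_acoustic`), `abs_error` per frame, `mean_abs_error`, and `method`
#' @export
align_nearest <- function(t_visual, t_acoustic) {
  check_streams(t_visual, t_acoustic)
  mapping <- vapply(t_visual, function(tv) {
    d <- abs(tv - t_acoustic)
    which(d == min(d))[1] # earliest index on ties
  }, 0L)
  err <- abs(t_visual - t_acoustic[mapping])
  structure(list(mapping = mapping, abs_error = err,
                 mean_abs_error = mean(err), method = "nearest"),
            class = "alignment_result")
}

#' Dynamic-time-warping timestamp alignment
#'
#' Monotone non-decreasing mapping of visual onto acoustic timestamps
#' minimizing the summed absolute time difference, computed by dynamic
#' programming. Step pattern: each visual frame is matched to one acoustic
#' index which may repeat (many frames per clip) but never decreases.
#'
#' @inheritParams align_nearest
#' @return an `alignment_result` (see [align_nearest()]); `mapping` is monotone
#' @export
align_dtw <- function(t_visual, t_acoustic) {
  check_streams(t_visual, t_acoustic)
  nv <- length(t_visual); na <- length(t_acoustic)
  cost <- outer(t_visual, t_acoustic, function(a, b) abs(a - b))
  # D[i, j]: minimal cost of aligning frames 1..i with mapping(i) == j
  D <- matrix(Inf, nv, na)
  D[1, ] <- cost[1, ]
  B <- matrix(0L, nv, na)
  for (i in 2:max(nv, 2)) {
    if (i > nv) break
    # mapping(i) = j requires mapping(i-1) <= j: running minimum over prior row
    runmin <- D[i - 1, 1]; argmin <- 1L
    for (j in seq_len(na)) {
      if (D[i - 1, j] < runmin) { runmin <- D[i - 1, j]; argmin <- j }
      D[i, j] <- runmin + cost[i, j]
      B[i, j] <- argmin
    }
  }
  mapping <- integer(nv)
  j <- which.min(D[nv, ])
  mapping[nv] <- j
  if (nv > 1) for (i in nv:2) {
    j <- B[i, j]
    mapping[i - 1] <- j
  }
  err <- abs(t_visual - t_acoustic[mapping])
  structure(list(mapping = mapping, abs_error = err,
                 mean_abs_error = mean(err), method = "dtw"),
            class = "alignment_result")
}

#' Cross-modal feature consistency check
#'
#' Computes the Euclidean distance between a visual and an acoustic feature
#' vector and compares it against the allowable deviation threshold epsilon.
#'
#' @param fv,fa equal-length feature vectors
#' @param epsilon positive threshold (use `Inf` to always pass)
#' @return list with `distance` and logical `pass`
#' @export
check_consistency <- function(fv, fa, epsilon) {
  if (length(fv) != length(fa)) stop("invalid input: feature dimension mismatch")
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0)
    stop("invalid config: epsilon must be > 0")
  d <- sqrt(sum((fv - fa)^2))
  list(distance = d, pass = d <= epsilon)
}

#' Calibrate the consistency threshold from intra-pair distances
#'
#' Default threshold is the 95th percentile of observed intra-pair
#' visual-acoustic feature distances on a held-out calibration split.
#'
#' @param distances numeric vector of intra-pair feature distances
#' @param q quantile used as threshold
#' @return epsilon
#' @export
calibrate_epsilon <- function(distances, q = 0.95) {
  stopifnot(length(distances) > 0)
  as.numeric(stats::quantile(distances, q, names = FALSE))
}

#' Alignment report as a data frame (writable as CSV)
#'
#' @param res an `alignment_result`
#' @param t_visual,t_acoustic the streams that produced it
#' @param path optional CSV output path
#' @return data.frame with index, tv, ta, abs_error
#' @export
alignment_report <- function(res, t_visual, t_acoustic, path = NULL) {
  df <- data.frame(index = seq_along(res$mapping), tv = t_visual,
                   ta = t_acoustic[res$mapping], abs_error = res$abs_error)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
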