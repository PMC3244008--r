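# Per-frame feature families: DC component, variance, spectral energy,
# frequency-domain entropy, and inter-channel correlation coefficients.

.check_frame <- function(frame) {
  if (!inherits(frame, "accel_frame")) stop("expected an `accel_frame`", call. = FALSE)
  if (ncol(frame$window) < 1L) stop("frame is empty", call. = FALSE)
  invisible(frame)
}

.channel_names <- function(frame) {
  rownames(frame$window) %||% paste0("ch", seq_len(nrow(frame$window)))
}

#' DC component of each channel
#'
#' The per-channel mean over the window. Dominated by the projection of
#' gravity on the sensor axis, so it encodes body orientation and is the
#' workhorse feature for discriminating static postures.
#'
#' @param frame An `accel_frame` from [make_frames()].
#' @return Named numeric vector, one value per channel.
#' @export
dc_component <- function(frame) {
  .check_frame(frame)
  out <- rowMeans(frame$window)
  names(out) <- .channel_names(frame)
  out
}

#' Variance of each detrended channel
#'
#' Mean of the squared detrended samples (population variance) per channel.
#'
#' @inheritParams dc_component
#' @return Named numeric vector.
#' @export
variance_feature <- function(frame) {
  .check_frame(frame)
  w <- frame$window
  out <- rowMeans((w - rowMeans(w))^2)
  names(out) <- .channel_names(frame)
  out
}

#' Spectral energy of each channel
#'
#' Sum of squared magnitudes of the discrete Fourier coefficients of the
#' detrended channel, excluding the zero-frequency bin, divided by the
#' window length. By Parseval's identity this equals the sum of squared
#' detrended samples, i.e. the energy of the AC part of the signal, and it
#' scales quadratically with signal amplitude.
#'
#' @inheritParams dc_component
#' @return Named numeric vector of non-negative energies.
#' @export
energy_feature <- function(frame) {
  .check_frame(frame)
  w <- frame$window
  W <- ncol(w)
  out <- apply(w, 1L, function(x) {
    spec <- Mod(stats::fft(x - mean(x)))^2
    sum(spec[-1L]) / W
  })
  names(out) <- .channel_names(frame)
  out
}

#' Frequency-domain entropy of each channel
#'
#' For every channel the magnitudes of the short-time Fourier coefficients
#' of the detrended window (positive-frequency bins, one segment spanning
#' the whole window) are treated as a sample; an Epanechnikov kernel density
#' is fitted to that sample and its differential entropy
#' \eqn{-\int f \log f} is evaluated by trapezoidal integration on the KDE
#' grid. Impact-rich gaits such as walking spread spectral magnitude over
#' many bins and score a much higher entropy than smooth periodic motions
#' such as cycling, whose spectrum is concentrated in a single tone.
#'
#' @inheritParams dc_component
#' @param bandwidth Kernel bandwidth; `NULL` (default) applies Silverman's
#'   rule-of-thumb ([stats::bw.nrd0()]) to the magnitude sample.
#' @param grid_points Number of equally spaced density evaluation points;
#'   the grid spans `[min - 3h, max + 3h]`.
#' @return Named numeric vector of entropies (nats). An all-zero
#'   (degenerate) channel yields 0 with a warning.
#' @export
entropy_feature <- function(frame, bandwidth = NULL, grid_points = 512) {
  .check_frame(frame)
  if (!is.null(bandwidth)) {
    .assert_scalar_number(bandwidth, "bandwidth")
    if (bandwidth <= 0) stop("`bandwidth` must be positive", call. = FALSE)
  }
  w <- frame$window
  W <- ncol(w)
  half <- seq_len(floor(W / 2)) + 1L   # positive-frequency bins, DC excluded
  out <- apply(w, 1L, function(x) {
    x <- x - mean(x)
    mags <- Mod(stats::fft(x))[half]
    if (all(mags < 1e-12) || stats::sd(mags) < 1e-12) {
      warning("degenerate channel in entropy_feature(); returning 0", call. = FALSE)
      return(0)
    }
    h <- bandwidth %||% stats::bw.nrd0(mags)
    if (!is.finite(h) || h <= 0) {
      warning("degenerate bandwidth in entropy_feature(); returning 0", call. = FALSE)
      return(0)
    }
    dens <- stats::density(mags, bw = h, kernel = "epanechnikov",
                           n = grid_points, cut = 3)
    f <- pmax(dens$y, 0)
    -trapz(dens$x, f * log(pmax(f, 1e-12)))
  })
  names(out) <- .channel_names(frame)
  out
}

#' Correlation coefficients between channel pairs
#'
#' For every unordered pair of channels (including self-pairs) the dot
#' product of the two detrended channel vectors normalised by the product of
#' their Euclidean norms, i.e. the Pearson correlation of the pair.
#' Detrending removes the gravity offset, which would otherwise dominate the
#' inner product. Pairs are enumerated in lexicographic order `(i, j)` with
#' `i <= j`, giving `c(c+1)/2` coefficients for `c` channels (55 for 10);
#' self-pairs are identically 1 for any non-constant channel.
#'
#' @inheritParams dc_component
#' @return Named numeric vector with entries in `[-1, 1]`. A pair involving
#'   a constant (zero-norm) channel is set to 0 with a warning.
#' @export
correlation_block <- function(frame) {
  .check_frame(frame)
  w <- frame$window
  chn <- .channel_names(frame)
  d <- w - rowMeans(w)
  norms <- sqrt(rowSums(d^2))
  c_ <- nrow(w)
  out <- numeric(c_ * (c_ + 1) / 2)
  nms <- character(length(out))
  idx <- 0L
  warned <- FALSE
  for (i in seq_len(c_)) {
    for (j in i:c_) {
      idx <- idx + 1L
      nms[idx] <- paste0("corr_", chn[i], "_", chn[j])
      if (norms[i] < 1e-12 || norms[j] < 1e-12) {
        out[idx] <- 0
        warned <- TRUE
      } else {
        out[idx] <- sum(d[i, ] * d[j, ]) / (norms[i] * norms[j])
      }
    }
  }
  if (warned) warning("zero-norm detrended channel; correlation set to 0", call. = FALSE)
  names(out) <- nms
  pmin(pmax(out, -1), 1)
}

#' Assemble the full feature vector of a frame
#'
#' Concatenates the DC components, energies, entropies and correlation
#' coefficients in that fixed order. For `c` channels the vector has
#' `3c + c(c+1)/2` components: 85 for the default 10-channel setup
#' (30 per-channel features plus 55 correlations).
#'
#' @inheritParams entropy_feature
#' @return Named numeric vector.
#' @export
assemble_features <- function(frame, bandwidth = NULL, grid_points = 512) {
  .check_frame(frame)
  chn <- .channel_names(frame)
  dc <- dc_component(frame)
  en <- energy_feature(frame)
  ent <- entropy_feature(frame, bandwidth = bandwidth, grid_points = grid_points)
  names(dc) <- paste0("dc_", chn)
  names(en) <- paste0("energy_", chn)
  names(ent) <- paste0("entropy_", chn)
  c(dc, en, ent, correlation_block(frame))
}

#' Extract a per-frame feature table from a recording
#'
#' Windows the recording with [make_frames()] and applies
#' [assemble_features()] to every window.
#'
#' @inheritParams make_frames
#' @inheritParams entropy_feature
#' @param label Optional activity label attached to every frame.
#' @return A tibble with one row per frame: `frame_start` (0-based sample
#'   offset), the feature columns, and `label` if supplied.
#' @export
#' @examples
#' rec <- raw_recording(matrix(rnorm(2048 * 2), ncol = 2))
#' extract_features(rec, width = 512)
extract_features <- function(recording, width = 512, overlap = 0.5,
                             label = NULL, bandwidth = NULL, grid_points = 512) {
  frames <- make_frames(recording, width = width, overlap = overlap)
  if (length(frames) == 0L) {
    return(tibble::tibble(frame_start = integer()))
  }
  rows <- purrr::map(frames, assemble_features,
                     bandwidth = bandwidth, grid_points = grid_points)
  out <- tibble::as_tibble(do.call(rbind, rows))
  out <- dplyr::bind_cols(
    tibble::tibble(frame_start = vapply(frames, `[[`, integer(1), "start_index")),
    out
  )
  if (!is.null(label)) out$label <- as.character(label)
  out
}
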