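#' Wrap a multi-channel acceleration time series
#'
#' A recording is a tibble with one numeric column per accelerometer channel
#' and one row per sample, carrying the sampling rate as an attribute. The
#' default rate of 76.25 Hz matches the body-worn sensor network the package
#' emulates (five bi-axial accelerometers, ten data channels).
#'
#' @param data A data frame or matrix, samples in rows, channels in columns.
#' @param rate Sampling frequency in Hz. Must be positive.
#' @param channel_names Optional channel identifiers; defaults to existing
#'   column names or `ch1 ... chC`.
#' @return A `raw_recording` tibble.
#' @export
#' @examples
#' rec <- raw_recording(matrix(rnorm(1024 * 2), ncol = 2), rate = 76.25)
#' sampling_rate(rec)
raw_recording <- function(data, rate = 76.25, channel_names = NULL) {
  .assert_scalar_number(rate, "rate")
  if (rate <= 0) stop("`rate` must be positive", call. = FALSE)
  data <- as.data.frame(data)
  if (ncol(data) < 1L) stop("a recording needs at least one channel", call. = FALSE)
  if (!all(vapply(data, is.numeric, logical(1)))) {
    stop("all channels must be numeric", call. = FALSE)
  }
  channel_names <- channel_names %||% colnames(data) %||% paste0("ch", seq_len(ncol(data)))
  if (is.null(colnames(data)) || any(colnames(data) == "") ||
      any(grepl("^V[0-9]+$", colnames(data)))) {
    colnames(data) <- paste0("ch", seq_len(ncol(data)))
  } else {
    colnames(data) <- channel_names
  }
  out <- tibble::as_tibble(data)
  attr(out, "rate") <- rate
  class(out) <- c("raw_recording", class(out))
  out
}

#' @rdname raw_recording
#' @param recording A `raw_recording`.
#' @export
sampling_rate <- function(recording) {
  attr(recording, "rate") %||% 76.25
}

#' Duration of one analysis window
#'
#' At the default settings (512 samples at 76.25 Hz) each window spans
#' 6.7 seconds of signal, and with 50% overlap a new window becomes
#' available every 3.35 s.
#'
#' @param width Window width in samples.
#' @param rate Sampling frequency in Hz.
#' @return Duration in seconds.
#' @export
frame_duration <- function(width = 512, rate = 76.25) {
  .assert_scalar_number(width, "width")
  .assert_scalar_number(rate, "rate")
  width / rate
}

#' Cut a recording into overlapping analysis windows
#'
#' Windows start at multiples of the stride `width * (1 - overlap)`;
#' trailing samples that do not fill a complete window are dropped (no
#' padding). For a recording of length `L` this yields
#' `floor((L - width) / stride) + 1` frames.
#'
#' @param recording A [raw_recording()] (or any data frame of samples by
#'   channels).
#' @param width Window width in samples (default 512).
#' @param overlap Fractional overlap between consecutive windows in
#'   `[0, 1)`; default 0.5.
#' @return A list of `accel_frame` objects, ordered by start index. Each
#'   frame holds a channels-by-width matrix, the 0-based sample offset
#'   `start_index`, and the sampling rate.
#' @export
#' @examples
#' rec <- raw_recording(matrix(rnorm(1024), ncol = 1))
#' length(make_frames(rec, width = 512, overlap = 0.5)) # 3 frames
make_frames <- function(recording, width = 512, overlap = 0.5) {
  .assert_scalar_number(width, "width")
  .assert_scalar_number(overlap, "overlap")
  width <- as.integer(width)
  if (width < 2L) stop("`width` must be a positive integer >= 2", call. = FALSE)
  if (overlap < 0 || overlap >= 1) stop("`overlap` must lie in [0, 1)", call. = FALSE)
  rate <- sampling_rate(recording)
  x <- t(as.matrix(as.data.frame(recording)))   # channels x time
  n <- ncol(x)
  stride <- as.integer(round(width * (1 - overlap)))
  stride <- max(stride, 1L)
  if (n < width) return(list())
  starts <- seq.int(0L, n - width, by = stride)
  lapply(starts, function(s) {
    structure(
      list(
        window = x[, (s + 1L):(s + width), drop = FALSE],
        start_index = s,
        rate = rate
      ),
      class = "accel_frame"
    )
  })
}

#' @export
print.accel_frame <- function(x, ...) {
  cat(sprintf(
    "<accel_frame> %d channel(s) x %d samples @ %.2f Hz (start %d, %.2f s)\n",
    nrow(x$window), ncol(x$window), x$rate, x$start_index,
    frame_duration(ncol(x$window), x$rate)
  ))
  invisible(x)
}
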