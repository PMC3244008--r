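# Synthetic accelerometer signals and virtual experiments: per-activity
# signal generators, feature libraries, Markov-driven composite sequences
# and garbage-frame injection.

#' Describe a synthetic activity signal
#'
#' An activity is modelled per channel as a constant gravity projection
#' (the DC profile) plus a sum of sinusoids (fundamental gait frequency and
#' harmonics), optional impulsive high-frequency bursts at Poisson times
#' (foot impacts of walking/running-like gaits, which spread spectral
#' energy and raise the frequency-domain entropy), and white Gaussian
#' noise. Static postures use the DC profile and noise only.
#'
#' @param label Activity name.
#' @param dc_profile Per-channel constant offset (gravity projection,
#'   m/s^2).
#' @param periodic A list of components, each `list(freq, amp, phase)` with
#'   `freq` in Hz (must stay below the Nyquist frequency).
#' @param impact `NULL`, or `list(rate, amp, decay, freq)`: Poisson burst
#'   rate (1/s), burst amplitude, exponential decay constant (1/s) and
#'   carrier frequency in Hz (default 0.35 of the sampling rate).
#' @param noise_sd Standard deviation of the additive white noise.
#' @param channel_gain Per-channel amplitude gain for the periodic and
#'   burst parts (default 1 for all channels).
#' @param phase_lag Phase offset between consecutive channels (radians);
#'   creates the stable inter-channel correlation patterns of coordinated
#'   limb motion.
#' @param drift Amplitude of slow baseline wander (two sub-0.1 Hz
#'   random-phase sinusoids per channel and recording), emulating postural
#'   sway and sensor-attachment shifts; the dominant source of
#'   frame-to-frame DC variability.
#' @param jitter Relative per-recording jitter applied once to the
#'   amplitudes and frequencies of the periodic components (mannerism-like
#'   execution variability between recordings).
#' @return An `activity_spec`.
#' @export
activity_spec <- function(label, dc_profile, periodic = list(), impact = NULL,
                          noise_sd = 0.05, channel_gain = NULL, phase_lag = pi / 5,
                          drift = 0.25, jitter = 0.15) {
  dc_profile <- as.numeric(dc_profile)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  for (p in periodic) {
    if (p$amp < 0) stop("periodic amplitudes must be non-negative", call. = FALSE)
  }
  structure(
    list(label = as.character(label), dc_profile = dc_profile,
         periodic = periodic, impact = impact, noise_sd = noise_sd,
         channel_gain = channel_gain %||% rep(1, length(dc_profile)),
         phase_lag = phase_lag, drift = drift, jitter = jitter),
    class = "activity_spec"
  )
}

#' Default ten-channel activity vocabulary
#'
#' Signal specifications for the seven-activity vocabulary (three postures,
#' four gaits) over ten channels, emulating five bi-axial body-worn
#' accelerometers. Postures differ in their gravity (DC) profiles; gaits
#' share an upright DC profile and differ in fundamental frequency,
#' amplitude and impact content: walking, climbing and running carry
#' impulsive foot-impact bursts, cycling is a smooth low-noise pedalling
#' tone — so walking frames score a much higher spectral entropy than
#' cycling frames.
#'
#' @param channels Number of channels (default 10).
#' @return Named list of [activity_spec()]s in the label order of
#'   [seven_activity_omm()].
#' @export
default_activity_specs <- function(channels = 10) {
  ch <- seq_len(channels)
  upright <- 9.81 * cos(ch * pi / 4) * 0.5          # standing-like projection
  specs <- list(
    activity_spec("lying", dc_profile = 9.81 * sin(ch * pi / 3) * 0.6,
                  noise_sd = 0.15, drift = 0.25),
    activity_spec("cycling", dc_profile = upright + 0.5 * sin(ch),
                  periodic = list(list(freq = 1.0, amp = 2.0, phase = 0)),
                  noise_sd = 0.1, phase_lag = pi / 3, drift = 0.3),
    activity_spec("climbing", dc_profile = upright + 0.25,
                  periodic = list(list(freq = 1.7, amp = 1.6, phase = 0),
                                  list(freq = 3.4, amp = 0.8, phase = 1)),
                  impact = list(rate = 1.7, amp = 2.5, decay = 30),
                  noise_sd = 0.35, phase_lag = pi / 6, drift = 0.4),
    activity_spec("walking", dc_profile = upright,
                  periodic = list(list(freq = 2.0, amp = 1.5, phase = 0),
                                  list(freq = 4.0, amp = 0.8, phase = 0.7)),
                  impact = list(rate = 2.0, amp = 3.0, decay = 30),
                  noise_sd = 0.35, phase_lag = pi / 5, drift = 0.4),
    activity_spec("running", dc_profile = upright - 0.2,
                  periodic = list(list(freq = 2.8, amp = 2.6, phase = 0),
                                  list(freq = 5.6, amp = 1.1, phase = 0.4)),
                  impact = list(rate = 2.8, amp = 4.5, decay = 25),
                  noise_sd = 0.45, phase_lag = pi / 4, drift = 0.45),
    activity_spec("sitting", dc_profile = upright + 0.55 * sin(ch * 1.1 + 0.4),
                  noise_sd = 0.15, drift = 0.25),
    activity_spec("standing", dc_profile = upright, noise_sd = 0.15,
                  drift = 0.25)
  )
  stats::setNames(specs, vapply(specs, `[[`, character(1), "label"))
}

#' Garbage (out-of-vocabulary) activity specifications
#'
#' A distinct spec family standing in for activities outside the trained
#' vocabulary: shifted gravity profiles unlike any of the seven primitives,
#' odd fundamental frequencies and heavy noise. Used to inject spurious
#' frames that the rejection stage must learn to flag.
#'
#' @inheritParams default_activity_specs
#' @return Named list of [activity_spec()]s.
#' @export
garbage_activity_specs <- function(channels = 10) {
  ch <- seq_len(channels)
  specs <- list(
    activity_spec("garbage_scrub", dc_profile = 9.81 * sin(ch * 2.1) * 1.4 + 4,
                  periodic = list(list(freq = 0.6, amp = 4.5, phase = 0.3),
                                  list(freq = 7.3, amp = 2.0, phase = 1.1)),
                  noise_sd = 1.5, phase_lag = 1.9),
    activity_spec("garbage_shake", dc_profile = -9.81 * cos(ch * 1.3) - 5,
                  periodic = list(list(freq = 5.1, amp = 6.0, phase = 0)),
                  impact = list(rate = 4, amp = 8, decay = 15),
                  noise_sd = 2.0, phase_lag = 0.7),
    activity_spec("garbage_drift", dc_profile = 9.81 * cos(ch * 0.4) * 1.8 - 6,
                  periodic = list(list(freq = 0.25, amp = 5.0, phase = 2)),
                  noise_sd = 1.0, phase_lag = 2.6)
  )
  stats::setNames(specs, vapply(specs, `[[`, character(1), "label"))
}

#' Synthesise a raw multi-channel recording for one activity
#'
#' @param spec An [activity_spec()].
#' @param duration Recording length in seconds (must cover at least one
#'   analysis window).
#' @param rate Sampling frequency in Hz.
#' @param seed Optional seed; the same seed reproduces the recording
#'   exactly.
#' @return A [raw_recording()] of `round(duration * rate)` samples.
#' @export
synth_recording <- function(spec, duration, rate = 76.25, seed = NULL) {
  stopifnot(inherits(spec, "activity_spec"))
  for (p in spec$periodic) {
    if (p$freq >= rate / 2) {
      stop(sprintf("periodic component at %.2f Hz is at or above Nyquist (%.2f Hz)",
                   p$freq, rate / 2), call. = FALSE)
    }
  }
  n <- round(duration * rate)
  if (n < 1L) stop("`duration` too short", call. = FALSE)
  tt <- (seq_len(n) - 1L) / rate
  C <- length(spec$dc_profile)
  with_seed_if(seed, {
    periodic <- lapply(spec$periodic, function(p) {
      p$amp <- p$amp * stats::runif(1, 1 - spec$jitter, 1 + spec$jitter)
      p$freq <- min(p$freq * stats::runif(1, 1 - spec$jitter / 2, 1 + spec$jitter / 2),
                    0.999 * rate / 2)
      p
    })
    base_burst <- numeric(n)
    if (!is.null(spec$impact)) {
      imp <- spec$impact
      f_b <- imp$freq %||% (0.35 * rate)
      n_bursts <- stats::rpois(1, imp$rate * duration)
      t0s <- sort(stats::runif(n_bursts, 0, duration))
      for (t0 in t0s) {
        after <- tt >= t0
        tau <- tt[after] - t0
        base_burst[after] <- base_burst[after] +
          imp$amp * exp(-imp$decay * tau) * cos(2 * pi * f_b * tau)
      }
    }
    x <- matrix(0, n, C)
    for (c_ in seq_len(C)) {
      sig <- rep(spec$dc_profile[c_], n)
      for (p in periodic) {
        sig <- sig + spec$channel_gain[c_] * p$amp *
          sin(2 * pi * p$freq * tt + p$phase + (c_ - 1) * spec$phase_lag)
      }
      if (spec$drift > 0) {
        f_d <- stats::runif(2, 0.02, 0.08)
        ph_d <- stats::runif(2, 0, 2 * pi)
        sig <- sig + spec$drift * (sin(2 * pi * f_d[1] * tt + ph_d[1]) +
                                     sin(2 * pi * f_d[2] * tt + ph_d[2]))
      }
      sig <- sig + spec$channel_gain[c_] * base_burst +
        stats::rnorm(n, 0, spec$noise_sd)
      x[, c_] <- sig
    }
    colnames(x) <- paste0("ch", seq_len(C))
    raw_recording(x, rate = rate)
  })
}

#' Build a labelled feature library
#'
#' Generates several recordings per activity spec (so that per-recording
#' mannerism jitter is *sampled* rather than fixed — a library built from a
#' single bout per activity would carry one arbitrary jitter draw as a
#' systematic bias), windows them, extracts the full feature vector of
#' every window and labels it with the generating activity. This is the
#' pool of "motor word" examples from which virtual experiments sample.
#'
#' @param specs A list of [activity_spec()]s.
#' @param frames_per_class Number of frames per activity (the pool size N).
#' @param rate,width,overlap Windowing parameters (see [make_frames()]).
#' @param frames_per_recording At most this many frames are taken from one
#'   simulated bout; `frames_per_class` is spread over
#'   `ceiling(frames_per_class / frames_per_recording)` bouts.
#' @param seed Integer seed; per-activity, per-bout streams are derived
#'   from it.
#' @return A tibble with `label`, `frame_start` and feature columns.
#' @export
build_frame_library <- function(specs, frames_per_class = 30, rate = 76.25,
                                width = 512, overlap = 0.5,
                                frames_per_recording = 4, seed = 1) {
  stopifnot(frames_per_class >= 1, frames_per_recording >= 1)
  stride <- round(width * (1 - overlap))
  n_rec <- ceiling(frames_per_class / frames_per_recording)
  per_rec <- rep(frames_per_class %/% n_rec, n_rec)
  extra <- frames_per_class - sum(per_rec)
  if (extra > 0) per_rec[seq_len(extra)] <- per_rec[seq_len(extra)] + 1L
  out <- purrr::imap(specs, function(spec, nm) {
    i <- match(nm, names(specs))
    bouts <- lapply(seq_len(n_rec), function(r) {
      n_samples <- width + (per_rec[r] - 1) * stride
      duration <- (n_samples + 1) / rate
      rec <- synth_recording(spec, duration, rate = rate,
                             seed = seed * 1000L + i * 53L + r)
      feats <- extract_features(rec, width = width, overlap = overlap)
      feats[seq_len(per_rec[r]), , drop = FALSE]
    })
    feats <- dplyr::bind_rows(bouts)
    feats$label <- spec$label
    feats
  })
  dplyr::bind_rows(out) |> dplyr::relocate("label")
}

#' Compose a virtual experiment from an OMM and a frame library
#'
#' Simulates one composite activity ("motor sentence"): a state sequence is
#' drawn from the observable Markov model, and each state is given a
#' feature vector sampled with replacement from that activity's pool in the
#' library.
#'
#' @param model An [omm()] whose labels are all present in the library.
#' @param library A frame library from [build_frame_library()].
#' @param n_frames Sequence length T (default 300).
#' @param seed Optional seed.
#' @return A `virtual_experiment` tibble with columns `label`, `spurious`
#'   (all `FALSE`) and the feature columns.
#' @export
make_virtual_experiment <- function(model, library, n_frames = 300, seed = NULL) {
  model <- validate_omm(model)
  lib_labels <- as.character(library$label)
  missing <- setdiff(model$labels, unique(lib_labels))
  if (length(missing) > 0L) {
    stop(sprintf("library has no frames for state(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  feat_cols <- setdiff(names(library), .meta_cols)
  with_seed_if(seed, {
    states <- generate_states(model, n_frames)
    rows <- vapply(states, function(s) {
      pool <- which(lib_labels == s)
      pool[sample.int(length(pool), 1L)]
    }, integer(1))
    out <- dplyr::bind_cols(
      tibble::tibble(label = states, spurious = FALSE),
      library[rows, feat_cols, drop = FALSE]
    )
    class(out) <- c("virtual_experiment", class(out))
    out
  })
}

#' Intersperse garbage frames into a virtual experiment
#'
#' Inserts `floor(ratio * T)` spurious frames (sampled with replacement
#' from a garbage pool) at uniformly random positions among the `T` genuine
#' frames, preserving their order. A ratio of 1/3 reproduces the "one
#' spurious frame every three data frames" stress condition. Inserted
#' frames carry label `"SPURIOUS"` and `spurious = TRUE`.
#'
#' @param experiment A `virtual_experiment`.
#' @param garbage A feature table of garbage frames (same feature columns).
#' @param ratio Spurious-per-genuine insertion rate in `[0, 1/3]`.
#' @param seed Optional seed.
#' @return A `virtual_experiment` of length `T + floor(ratio * T)`.
#' @export
inject_garbage <- function(experiment, garbage, ratio = 1 / 3, seed = NULL) {
  .assert_scalar_number(ratio, "ratio")
  if (ratio < 0) stop("`ratio` must be non-negative", call. = FALSE)
  if (ratio > 1 / 3 + 1e-12) stop("`ratio` must not exceed 1/3", call. = FALSE)
  n_gen <- nrow(experiment)
  n_spur <- floor(ratio * n_gen)
  if (n_spur == 0L) return(experiment)
  feat_cols <- setdiff(names(experiment), .meta_cols)
  if (!all(feat_cols %in% names(garbage))) {
    stop("garbage pool lacks required feature columns", call. = FALSE)
  }
  with_seed_if(seed, {
    total <- n_gen + n_spur
    spur_pos <- sort(sample.int(total, n_spur))
    picks <- sample.int(nrow(garbage), n_spur, replace = TRUE)
    gi <- si <- 1L
    genuine <- as.data.frame(experiment)
    garb <- as.data.frame(garbage[, feat_cols, drop = FALSE])
    is_spur <- logical(total)
    is_spur[spur_pos] <- TRUE
    lab <- character(total)
    feats <- matrix(NA_real_, total, length(feat_cols),
                    dimnames = list(NULL, feat_cols))
    for (t in seq_len(total)) {
      if (is_spur[t]) {
        lab[t] <- "SPURIOUS"
        feats[t, ] <- as.numeric(garb[picks[si], ])
        si <- si + 1L
      } else {
        lab[t] <- genuine$label[gi]
        feats[t, ] <- as.numeric(genuine[gi, feat_cols])
        gi <- gi + 1L
      }
    }
    out <- dplyr::bind_cols(tibble::tibble(label = lab, spurious = is_spur),
                            tibble::as_tibble(feats))
    class(out) <- c("virtual_experiment", class(out))
    out
  })
}
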