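#' Zero-phase band-pass filter
#'
#' Fourth-order Butterworth band-pass (a second-order analog prototype,
#' whose order doubles under the band-pass transform) applied forward and
#' backward with [signal::filtfilt()], so the net response is zero-phase
#' with the squared magnitude of the underlying filter. The default
#' 0.01–0.2 Hz band keeps slow hemodynamics while rejecting cardiac
#' (~1.2 Hz) and respiratory (~0.25 Hz) oscillations; Mayer waves
#' (~0.1 Hz) lie inside the band and are not removed.
#'
#' For a raw recording the filter is applied to the intensity fluctuation
#' around the per-channel mean and the mean is added back, so that
#' intensities stay positive for the subsequent log transform; to first
#' order in the fluctuation this equals filtering the optical density.
#'
#' @param x numeric vector/matrix (time in rows), [raw_recording()],
#'   [od_series()] or [hemo_series()].
#' @param low_hz,high_hz band edges in Hz; `0 < low < high < fs/2`.
#' @param fs sampling rate in Hz (taken from the object when `x` is a
#'   pipeline container).
#' @param ... passed between methods.
#' @return filtered object of the same shape/class.
#' @export
bandpass <- function(x, low_hz = 0.01, high_hz = 0.2, fs = NULL, ...) {
  UseMethod("bandpass")
}

check_band <- function(low_hz, high_hz, fs) {
  if (is.null(fs) || !is.finite(fs) || fs <= 0)
    stop("a positive sampling rate is required")
  if (!(low_hz > 0 && high_hz > low_hz && high_hz < fs / 2))
    stop(sprintf("invalid band: need 0 < %g < %g < fs/2 = %g",
                 low_hz, high_hz, fs / 2))
}

bp_core <- function(mat, low_hz, high_hz, fs) {
  mat <- as.matrix(mat)
  # warm-up: filtfilt pads with ~3x the filter length at each end
  if (nrow(mat) < 30)
    stop("series too short for the band-pass filter (need >= 30 samples)")
  bf <- signal::butter(2, c(low_hz, high_hz) / (fs / 2), type = "pass")
  out <- mat
  for (j in seq_len(ncol(mat)))
    out[, j] <- signal::filtfilt(bf, mat[, j])
  out
}

#' @rdname bandpass
#' @export
bandpass.default <- function(x, low_hz = 0.01, high_hz = 0.2, fs = NULL, ...) {
  check_band(low_hz, high_hz, fs)
  if (is.null(dim(x))) drop(bp_core(matrix(x, ncol = 1), low_hz, high_hz, fs))
  else bp_core(x, low_hz, high_hz, fs)
}

#' @rdname bandpass
#' @export
bandpass.raw_recording <- function(x, low_hz = 0.01, high_hz = 0.2,
                                   fs = NULL, ...) {
  fs <- x$fs
  check_band(low_hz, high_hz, fs)
  out <- x
  for (w in seq_len(dim(x$intensity)[3])) {
    sl <- x$intensity[, , w]
    mu <- colMeans(sl)
    flt <- bp_core(sweep(sl, 2, mu), low_hz, high_hz, fs)
    out$intensity[, , w] <- sweep(flt, 2, mu, `+`)
  }
  if (any(out$intensity <= 0))
    stop("band-pass produced non-positive intensities; ",
         "fluctuations too large relative to the mean")
  out
}

#' @rdname bandpass
#' @export
bandpass.od_series <- function(x, low_hz = 0.01, high_hz = 0.2,
                               fs = NULL, ...) {
  fs <- x$fs
  check_band(low_hz, high_hz, fs)
  out <- x
  for (w in seq_len(dim(x$od)[3]))
    out$od[, , w] <- bp_core(x$od[, , w], low_hz, high_hz, fs)
  out
}

#' @rdname bandpass
#' @export
bandpass.hemo_series <- function(x, low_hz = 0.01, high_hz = 0.2,
                                 fs = NULL, ...) {
  fs <- x$fs
  check_band(low_hz, high_hz, fs)
  out <- x
  out$hbo <- bp_core(x$hbo, low_hz, high_hz, fs)
  out$hbr <- bp_core(x$hbr, low_hz, high_hz, fs)
  out
}

#' Baseline-correct hemodynamic responses per film clip
#'
#' For each event, subtracts from the clip segment the per-channel mean
#' over the `window_s` seconds immediately preceding clip onset. Returns
#' the corrected per-clip segments (epochs), each covering
#' `[onset, offset)`.
#'
#' @param hemo a [hemo_series()].
#' @param events event table (`clip_id`, `onset_s`, `offset_s`,
#'   `condition`, optionally `target_emotion`); defaults to the table
#'   carried by `hemo`.
#' @param window_s baseline window length in seconds before onset.
#' @return object of class `hemo_epochs`: a list of per-clip entries with
#'   fields `clip_id`, `condition`, `target_emotion`, `onset_s`,
#'   `offset_s`, `fs`, `hbo`, `hbr`.
#' @export
baseline_correct <- function(hemo, events = hemo$events, window_s = 10) {
  stopifnot(inherits(hemo, "hemo_series"))
  if (is.null(events)) stop("an event table is required")
  validate_events(events)
  fs <- hemo$fs
  n_t <- nrow(hemo$hbo)
  epochs <- lapply(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    i_on <- round(ev$onset_s * fs) + 1
    i_off <- round(ev$offset_s * fs)       # segment = [onset, offset)
    i_b0 <- round((ev$onset_s - window_s) * fs) + 1
    if (i_b0 < 1)
      stop(sprintf("clip %s: insufficient pre-stimulus data for a %g-s baseline",
                   ev$clip_id, window_s))
    if (i_off > n_t)
      stop(sprintf("clip %s extends beyond the recording", ev$clip_id))
    base_idx <- i_b0:(i_on - 1)
    seg_idx <- i_on:i_off
    mu_o <- colMeans(hemo$hbo[base_idx, , drop = FALSE])
    mu_r <- colMeans(hemo$hbr[base_idx, , drop = FALSE])
    list(clip_id = ev$clip_id, condition = ev$condition,
         target_emotion = if ("target_emotion" %in% names(ev))
           ev$target_emotion else NA_character_,
         onset_s = ev$onset_s, offset_s = ev$offset_s, fs = fs,
         hbo = sweep(hemo$hbo[seg_idx, , drop = FALSE], 2, mu_o),
         hbr = sweep(hemo$hbr[seg_idx, , drop = FALSE], 2, mu_r))
  })
  structure(epochs, class = "hemo_epochs")
}

#' Cut the last 30 s of each clip into three 10-s sample windows
#'
#' Emotional responses build over a clip, so the final 30 s of each film
#' clip are extracted and tiled into three non-overlapping 10-s windows
#' (half-open: `[offset-30, offset-20)`, `[offset-20, offset-10)`,
#' `[offset-10, offset)`), indexed 1..3 from earliest to latest. At 50 Hz
#' each window holds exactly 500 time points. Clips shorter than 30 s are
#' an error: no partial windows are produced.
#'
#' @param x a `hemo_epochs` object from [baseline_correct()], or a
#'   [hemo_series()] together with `events` (no baseline correction is
#'   applied in that case).
#' @param events event table, required when `x` is a [hemo_series()].
#' @param window_s window length (s).
#' @param n_windows number of trailing windows per clip.
#' @return object of class `sample_windows`: list of window entries with
#'   fields `clip_id`, `condition`, `target_emotion`, `sample_index`,
#'   `fs`, `hbo`, `hbr` (each `window_s * fs` rows).
#' @export
extract_samples <- function(x, events = NULL, window_s = 10, n_windows = 3) {
  if (inherits(x, "hemo_series")) {
    if (is.null(events)) events <- x$events
    if (is.null(events)) stop("an event table is required")
    epochs <- lapply(seq_len(nrow(events)), function(i) {
      ev <- events[i, ]
      i_on <- round(ev$onset_s * x$fs) + 1
      i_off <- round(ev$offset_s * x$fs)
      if (i_off > nrow(x$hbo))
        stop(sprintf("clip %s extends beyond the recording", ev$clip_id))
      list(clip_id = ev$clip_id, condition = ev$condition,
           target_emotion = if ("target_emotion" %in% names(ev))
             ev$target_emotion else NA_character_,
           onset_s = ev$onset_s, offset_s = ev$offset_s, fs = x$fs,
           hbo = x$hbo[i_on:i_off, , drop = FALSE],
           hbr = x$hbr[i_on:i_off, , drop = FALSE])
    })
  } else if (inherits(x, "hemo_epochs")) {
    epochs <- unclass(x)
  } else stop("x must be a hemo_series or hemo_epochs object")

  total_s <- window_s * n_windows
  windows <- list()
  for (ep in epochs) {
    dur <- ep$offset_s - ep$onset_s
    if (dur < total_s)
      stop(sprintf("clip %s lasts %.1f s; need at least %g s for %d windows of %g s",
                   ep$clip_id, dur, total_s, n_windows, window_s))
    n_seg <- nrow(ep$hbo)
    n_w <- round(window_s * ep$fs)
    for (k in seq_len(n_windows)) {
      # window k covers [offset - total_s + (k-1)*window_s, ... + window_s)
      i1 <- n_seg - round((total_s - (k - 1) * window_s) * ep$fs) + 1
      idx <- i1:(i1 + n_w - 1)
      windows[[length(windows) + 1]] <- list(
        clip_id = ep$clip_id, condition = ep$condition,
        target_emotion = ep$target_emotion, sample_index = k, fs = ep$fs,
        hbo = ep$hbo[idx, , drop = FALSE],
        hbr = ep$hbr[idx, , drop = FALSE])
    }
  }
  structure(windows, class = "sample_windows")
}

#' Reduce sample windows to 24-dimensional spatial feature vectors
#'
#' Each 10-s window is summarised by its per-channel time mean, one
#' feature vector per chromophore, giving the spatial response pattern
#' over the montage (24 dimensions for the default montage).
#'
#' @param windows a `sample_windows` object from [extract_samples()].
#' @param participant_id identifier stored with each sample.
#' @return a `data.frame` of class `feature_samples` with columns
#'   `participant`, `clip_id`, `condition`, `target_emotion`,
#'   `sample_index`, `chromophore`, then one column per channel
#'   (`ch01`...).
#' @export
build_features <- function(windows, participant_id = NA) {
  stopifnot(inherits(windows, "sample_windows"))
  if (!length(windows)) stop("no sample windows provided")
  rows <- lapply(windows, function(w) {
    if (anyNA(w$hbo) || anyNA(w$hbr))
      stop(sprintf("clip %s window %d has missing channel data",
                   w$clip_id, w$sample_index))
    do.call(rbind, lapply(c("hbo", "hbr"), function(chrom) {
      v <- colMeans(w[[chrom]])
      out <- data.frame(participant = participant_id, clip_id = w$clip_id,
                        condition = w$condition,
                        target_emotion = w$target_emotion,
                        sample_index = w$sample_index,
                        chromophore = if (chrom == "hbo") "HbO" else "HbR",
                        stringsAsFactors = FALSE)
      out[channel_labels(length(v))] <- as.list(v)
      out
    }))
  })
  feats <- do.call(rbind, rows)
  rownames(feats) <- NULL
  class(feats) <- c("feature_samples", "data.frame")
  feats
}

#' Extract the numeric channel matrix from feature samples
#' @param features a `feature_samples` data.frame.
#' @return numeric matrix, one row per sample, one column per channel.
#' @export
feature_matrix <- function(features) {
  chs <- grep("^ch[0-9]+$", names(features), value = TRUE)
  as.matrix(features[, chs, drop = FALSE])
}
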