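#' Write / read a raw recording as long-format CSV
#'
#' Intensity is serialised with columns `time_s`, `channel`,
#' `wavelength_nm`, `value`; events, if present, go to a companion CSV
#' (see [write_events()]). On reading, the file is validated: complete
#' channel x wavelength grid, monotone time, strictly positive
#' intensities.
#'
#' @param raw a [raw_recording()].
#' @param path output CSV path for the intensity table.
#' @param events_path optional path for the event table.
#' @return `path`, invisibly.
#' @export
write_recording <- function(raw, path, events_path = NULL) {
  stopifnot(inherits(raw, "raw_recording"))
  d <- dim(raw$intensity)
  tt <- (seq_len(d[1]) - 1) / raw$fs
  long <- data.frame(
    time_s = rep(tt, times = d[2] * d[3]),
    channel = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    wavelength_nm = rep(raw$wavelengths, each = d[1] * d[2]),
    value = as.vector(raw$intensity))
  write.csv(long, path, row.names = FALSE)
  if (!is.null(events_path) && !is.null(raw$events))
    write_events(raw$events, events_path)
  invisible(path)
}

#' @rdname write_recording
#' @param events_path path to the companion events CSV (optional).
#' @param montage montage for the resulting recording.
#' @param participant_id identifier attached to the recording.
#' @return for `read_recording`, a validated [raw_recording()].
#' @export
read_recording <- function(path, events_path = NULL,
                           montage = default_montage(),
                           participant_id = NA) {
  if (!file.exists(path)) stop("recording file not found: ", path)
  long <- read.csv(path)
  req <- c("time_s", "channel", "wavelength_nm", "value")
  missing_cols <- setdiff(req, names(long))
  if (length(missing_cols))
    stop("recording CSV missing columns: ",
         paste(missing_cols, collapse = ", "))
  wls <- sort(unique(long$wavelength_nm))
  chs <- sort(unique(long$channel))
  tt <- sort(unique(long$time_s))
  if (nrow(long) != length(wls) * length(chs) * length(tt))
    stop("incomplete channel x wavelength x time grid")
  cnt <- table(long$channel, long$wavelength_nm)
  if (any(cnt != length(tt))) {
    bad <- which(cnt != length(tt), arr.ind = TRUE)[1, ]
    stop(sprintf("missing samples for channel %s at wavelength %s nm",
                 rownames(cnt)[bad[1]], colnames(cnt)[bad[2]]))
  }
  dt <- diff(tt)
  if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-6)
    stop("time axis must be strictly increasing and uniformly sampled")
  fs <- round(1 / dt[1], 6)
  long <- long[order(long$wavelength_nm, long$channel, long$time_s), ]
  if (any(long$value <= 0))
    stop("recording contains non-positive intensities")
  intensity <- array(long$value,
                     dim = c(length(tt), length(chs), length(wls)))
  events <- if (!is.null(events_path)) read_events(events_path) else NULL
  raw_recording(intensity, fs, wls, montage = montage, events = events,
                participant_id = participant_id)
}

#' Write / read an event table CSV
#' @param events event table (`clip_id`, `onset_s`, `offset_s`,
#'   `condition`, optional extras).
#' @param path CSV path.
#' @return the path (write) or validated event `data.frame` (read).
#' @export
write_events <- function(events, path) {
  validate_events(events)
  write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("event file not found: ", path)
  ev <- read.csv(path, stringsAsFactors = FALSE)
  validate_events(ev)
  ev
}

#' Write / read a hemodynamic series as long-format CSV
#'
#' Columns: `time_s`, `channel`, `chromophore` (`HbO`/`HbR`), `value`.
#' @param hemo a [hemo_series()].
#' @param path CSV path.
#' @return the path (write) or a [hemo_series()] (read).
#' @export
write_hemo <- function(hemo, path) {
  stopifnot(inherits(hemo, "hemo_series"))
  n_t <- nrow(hemo$hbo); n_ch <- ncol(hemo$hbo)
  tt <- (seq_len(n_t) - 1) / hemo$fs
  long <- data.frame(
    time_s = rep(tt, times = 2 * n_ch),
    channel = rep(rep(seq_len(n_ch), each = n_t), times = 2),
    chromophore = rep(c("HbO", "HbR"), each = n_t * n_ch),
    value = c(as.vector(hemo$hbo), as.vector(hemo$hbr)))
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hemo
#' @export
read_hemo <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  long <- read.csv(path)
  tt <- sort(unique(long$time_s))
  chs <- sort(unique(long$channel))
  fs <- round(1 / diff(tt)[1], 6)
  long <- long[order(long$chromophore, long$channel, long$time_s), ]
  n_t <- length(tt); n_ch <- length(chs)
  hbo <- matrix(long$value[long$chromophore == "HbO"], n_t, n_ch)
  hbr <- matrix(long$value[long$chromophore == "HbR"], n_t, n_ch)
  hemo_series(hbo, hbr, fs)
}

#' Write / read a rating matrix as long-format CSV
#'
#' Columns: `participant`, `clip_id`, `condition`, `target_emotion`,
#' `item`, `value`.
#' @param ratings a [rating_matrix()].
#' @param path CSV path.
#' @return the path (write) or a [rating_matrix()] (read).
#' @export
write_ratings <- function(ratings, path) {
  stopifnot(inherits(ratings, "rating_matrix"))
  d <- dim(ratings$ratings)
  ci <- ratings$clip_info
  long <- data.frame(
    participant = rep(seq_len(d[1]), times = d[2] * d[3]),
    clip_id = rep(rep(ci$clip_id, each = d[1]), times = d[3]),
    condition = rep(rep(ci$condition, each = d[1]), times = d[3]),
    target_emotion = rep(rep(ci$target_emotion, each = d[1]), times = d[3]),
    item = rep(ratings$items, each = d[1] * d[2]),
    value = as.vector(ratings$ratings))
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ratings
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) stop("ratings file not found: ", path)
  long <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("participant", "clip_id", "item", "value")
  missing_cols <- setdiff(req, names(long))
  if (length(missing_cols))
    stop("ratings CSV missing columns: ",
         paste(missing_cols, collapse = ", "))
  parts <- sort(unique(long$participant))
  clips <- unique(long$clip_id)
  items <- unique(long$item)
  # preserve canonical item order when recognisable
  canon <- emotion_items()
  if (setequal(items, canon)) items <- canon
  arr <- array(NA_real_, dim = c(length(parts), length(clips), length(items)))
  long$p_i <- match(long$participant, parts)
  long$c_i <- match(long$clip_id, clips)
  long$i_i <- match(long$item, items)
  arr[cbind(long$p_i, long$c_i, long$i_i)] <- long$value
  if (anyNA(arr)) stop("ratings CSV has missing participant/clip/item cells")
  first <- long[!duplicated(long$clip_id), ]
  ci <- data.frame(clip_id = first$clip_id,
                   condition = if ("condition" %in% names(long))
                     first$condition else "positive",
                   target_emotion = if ("target_emotion" %in% names(long))
                     first$target_emotion else NA_character_,
                   stringsAsFactors = FALSE)
  rating_matrix(arr, items, ci)
}
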