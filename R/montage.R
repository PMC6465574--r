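#' Default 24-channel frontal montage
#'
#' A generic frontal optode grid standing in for a 20-probe (6 sources, 14
#' detectors) continuous-wave system with 24 measurement channels and a
#' source-detector separation of 30 mm, centred near FPz. Channels are laid
#' out on a 3-row by 8-column grid; the `x` coordinate (in units of half the
#' inter-optode spacing) and the derived `region` (left / medial / right)
#' are used by the simulator to place spatial activation patterns and by
#' plotting helpers. The grid is a caricature of the physical probe
#' geometry, not a registration of any specific device.
#'
#' @param n_channels number of channels (only 24 is supported by the
#'   default grid).
#' @param separation_mm source-detector separation in mm.
#' @return a `data.frame` of class `nirs_montage` with columns
#'   `channel`, `source_id`, `detector_id`, `separation_mm`, `x`, `y`,
#'   `region`.
#' @export
default_montage <- function(n_channels = 24, separation_mm = 30) {
  if (n_channels != 24)
    stop("the default grid defines exactly 24 channels")
  if (separation_mm <= 0) stop("separation_mm must be positive")
  col <- rep(1:8, times = 3)
  row <- rep(1:3, each = 8)
  x <- col - 4.5
  region <- ifelse(col <= 3, "left", ifelse(col <= 5, "medial", "right"))
  m <- data.frame(
    channel = 1:24,
    source_id = rep(1:6, each = 4),
    detector_id = ((0:23) %% 12) + 1,
    separation_mm = separation_mm,
    x = x,
    y = row - 2,
    region = region,
    stringsAsFactors = FALSE
  )
  class(m) <- c("nirs_montage", "data.frame")
  m
}

validate_montage <- function(montage) {
  stopifnot(is.data.frame(montage))
  req <- c("channel", "separation_mm")
  if (!all(req %in% names(montage)))
    stop("montage must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(montage$channel))
    stop("montage channels must be unique")
  if (any(montage$separation_mm <= 0))
    stop("montage separations must be strictly positive")
  invisible(montage)
}

#' Channel labels used across the package
#' @param n number of channels
#' @return character vector `"ch01"..."chNN"`
#' @keywords internal
channel_labels <- function(n = 24) sprintf("ch%02d", seq_len(n))
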