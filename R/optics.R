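#' Extinction coefficient / DPF table
#'
#' Wavelength-keyed table of specific extinction coefficients for oxy- and
#' deoxy-hemoglobin plus the differential path-length factor (DPF) that
#' converts the geometric source-detector distance into an effective photon
#' path length. Units: `eps_*` in mm^-1 per uM, `dpf` dimensionless, so
#' that with separations in mm the recovered concentration changes are in
#' uM (documented convention, not enforced).
#'
#' @param wavelength_nm numeric vector of wavelengths.
#' @param eps_hbo,eps_hbr extinction coefficients, mm^-1 uM^-1; all > 0.
#' @param dpf differential path-length factors; all > 0.
#' @return data.frame of class `extinction_table`.
#' @export
extinction_table <- function(wavelength_nm, eps_hbo, eps_hbr, dpf) {
  n <- length(wavelength_nm)
  stopifnot(length(eps_hbo) == n, length(eps_hbr) == n, length(dpf) == n)
  if (any(!is.finite(c(eps_hbo, eps_hbr, dpf))) ||
      any(c(eps_hbo, eps_hbr) < 0) || any(dpf <= 0))
    stop("extinction coefficients must be finite and >= 0, DPF > 0")
  if (anyDuplicated(wavelength_nm)) stop("duplicate wavelengths")
  E <- cbind(eps_hbo, eps_hbr)
  if (n >= 2 && qr(E)$rank < 2)
    stop("extinction matrix [eps_hbo, eps_hbr] is rank deficient: ",
         "the two chromophores cannot be separated")
  tab <- data.frame(wavelength_nm = wavelength_nm, eps_hbo = eps_hbo,
                    eps_hbr = eps_hbr, dpf = dpf)
  tab <- tab[order(tab$wavelength_nm), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("extinction_table", "data.frame")
  tab
}

#' Read an extinction table from a CSV config file
#'
#' The file must have columns `wavelength_nm`, `eps_hbo`, `eps_hbr`, `dpf`.
#'
#' @param path path to the CSV file.
#' @return an [extinction_table()].
#' @export
read_extinction <- function(path) {
  if (!file.exists(path)) stop("extinction config not found: ", path)
  tab <- read.csv(path)
  req <- c("wavelength_nm", "eps_hbo", "eps_hbr", "dpf")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols))
    stop("extinction config missing columns: ",
         paste(missing_cols, collapse = ", "))
  extinction_table(tab$wavelength_nm, tab$eps_hbo, tab$eps_hbr, tab$dpf)
}

#' Default extinction table at 785 / 808 / 850 nm
#'
#' Specific extinction coefficients interpolated from published compiled
#' hemoglobin spectra (converted to mm^-1 uM^-1) and typical adult-forehead
#' DPF values of about 6, mildly decreasing with wavelength. The exact
#' values used by any given instrument are device calibration constants;
#' absolute concentration scales therefore carry the table's arbitrariness,
#' while classification and correlation results are scale-invariant. The
#' same table must be used for forward simulation and inversion for
#' round trips to be exact.
#'
#' @return an [extinction_table()] with rows at 785, 808 and 850 nm.
#' @export
default_extinction <- function() {
  path <- system.file("extdata", "extinction_defaults.csv",
                      package = "nirsemotion", mustWork = TRUE)
  read_extinction(path)
}

#' Construct a raw fNIRS recording
#'
#' @param intensity numeric array `[time, channel, wavelength]` of raw
#'   light intensities (arbitrary units, strictly positive).
#' @param fs sampling rate in Hz.
#' @param wavelengths numeric vector matching `dim(intensity)[3]`.
#' @param montage a montage `data.frame`; see [default_montage()].
#' @param events event table with columns `clip_id`, `onset_s`, `offset_s`,
#'   `condition` (and optionally `target_emotion`).
#' @param participant_id optional identifier.
#' @return object of class `raw_recording`.
#' @export
raw_recording <- function(intensity, fs, wavelengths,
                          montage = default_montage(),
                          events = NULL, participant_id = NA) {
  stopifnot(is.array(intensity), length(dim(intensity)) == 3)
  if (dim(intensity)[3] != length(wavelengths))
    stop("third dimension of intensity must match wavelengths")
  if (dim(intensity)[2] != nrow(montage))
    stop("second dimension of intensity must match montage channels")
  validate_montage(montage)
  if (fs <= 0) stop("fs must be positive")
  if (!is.null(events)) validate_events(events, fs, dim(intensity)[1])
  dimnames(intensity) <- list(NULL, channel_labels(dim(intensity)[2]),
                              paste0("wl", wavelengths))
  structure(list(intensity = intensity, fs = fs, wavelengths = wavelengths,
                 montage = montage, events = events,
                 participant_id = participant_id),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("raw fNIRS recording: %d samples x %d channels x %d wavelengths (%s nm) at %g Hz\n",
              d[1], d[2], d[3], paste(x$wavelengths, collapse = "/"), x$fs))
  if (!is.null(x$events))
    cat(sprintf("  %d events (%s)\n", nrow(x$events),
                paste(names(table(x$events$condition)), collapse = ", ")))
  invisible(x)
}

validate_events <- function(events, fs = NULL, n_samples = NULL) {
  req <- c("clip_id", "onset_s", "offset_s", "condition")
  missing_cols <- setdiff(req, names(events))
  if (length(missing_cols))
    stop("event table missing columns: ", paste(missing_cols, collapse = ", "))
  if (any(events$offset_s <= events$onset_s))
    stop("event offsets must exceed onsets")
  ord <- order(events$onset_s)
  ev <- events[ord, , drop = FALSE]
  if (nrow(ev) > 1 && any(ev$onset_s[-1] < ev$offset_s[-nrow(ev)]))
    stop("events overlap")
  if (!is.null(fs) && !is.null(n_samples) &&
      any(events$offset_s > n_samples / fs))
    stop("events extend beyond the end of the recording")
  invisible(events)
}

#' Optical density change series
#' @param od array `[time, channel, wavelength]` of delta-OD values.
#' @param fs sampling rate (Hz).
#' @param wavelengths wavelengths (nm).
#' @param events optional event table carried along the pipeline.
#' @return object of class `od_series`.
#' @export
od_series <- function(od, fs, wavelengths, events = NULL) {
  stopifnot(is.array(od), length(dim(od)) == 3,
            dim(od)[3] == length(wavelengths))
  if (!all(is.finite(od))) stop("optical density values must be finite")
  structure(list(od = od, fs = fs, wavelengths = wavelengths,
                 events = events), class = "od_series")
}

#' Hemoglobin concentration-change series
#' @param hbo,hbr matrices `[time, channel]` of concentration changes (uM).
#' @param fs sampling rate (Hz).
#' @param events optional event table carried along the pipeline.
#' @return object of class `hemo_series`.
#' @export
hemo_series <- function(hbo, hbr, fs, events = NULL) {
  hbo <- as.matrix(hbo); hbr <- as.matrix(hbr)
  stopifnot(all(dim(hbo) == dim(hbr)))
  if (!all(is.finite(hbo)) || !all(is.finite(hbr)))
    stop("hemoglobin series must be finite")
  colnames(hbo) <- colnames(hbr) <- channel_labels(ncol(hbo))
  structure(list(hbo = hbo, hbr = hbr, fs = fs, events = events),
            class = "hemo_series")
}

#' @export
print.hemo_series <- function(x, ...) {
  cat(sprintf("hemodynamic series: %d samples x %d channels at %g Hz (HbO + HbR)\n",
              nrow(x$hbo), ncol(x$hbo), x$fs))
  invisible(x)
}

#' Convert raw light intensity to optical density changes
#'
#' Delta-OD is the log attenuation relative to a reference intensity:
#' `dOD(lambda, c, t) = ln(I_ref(lambda, c) / I(lambda, c, t))`. The
#' reference is, by default, the per-channel per-wavelength mean over the
#' whole recording; a pre-stimulus reference (mean over the window before
#' the first event onset) is also available. The choice only shifts each
#' dOD trace by a constant and is removed later by baseline correction.
#'
#' @param raw a [raw_recording()].
#' @param reference_policy `"mean"` (default) or `"prestim"`.
#' @return an [od_series()].
#' @export
compute_delta_od <- function(raw, reference_policy = c("mean", "prestim")) {
  stopifnot(inherits(raw, "raw_recording"))
  reference_policy <- match.arg(reference_policy)
  ii <- raw$intensity
  if (any(ii <= 0)) {
    bad <- which(ii <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "non-positive intensity at time index %d, channel %d, wavelength %s nm",
      bad[1], bad[2], raw$wavelengths[bad[3]]))
  }
  if (reference_policy == "prestim") {
    if (is.null(raw$events) || nrow(raw$events) == 0)
      stop("prestim reference requires an event table")
    n_ref <- floor(min(raw$events$onset_s) * raw$fs)
    if (n_ref < 1) stop("no pre-stimulus samples before the first onset")
    ref <- apply(ii[seq_len(n_ref), , , drop = FALSE], c(2, 3), mean)
  } else {
    ref <- apply(ii, c(2, 3), mean)
  }
  od <- array(0, dim = dim(ii))
  for (w in seq_len(dim(ii)[3]))
    od[, , w] <- log(matrix(ref[, w], nrow = dim(ii)[1],
                            ncol = dim(ii)[2], byrow = TRUE) / ii[, , w])
  od_series(od, raw$fs, raw$wavelengths, events = raw$events)
}

#' Forward modified Beer-Lambert law
#'
#' Predicts the optical density change at each wavelength from hemoglobin
#' concentration changes:
#' `dOD(lambda) = (eps_HbO(lambda) dC_HbO + eps_HbR(lambda) dC_HbR) * r * DPF(lambda)`
#' with `r` the source-detector separation (per channel, mm) and DPF the
#' differential path-length factor.
#'
#' @param hemo a [hemo_series()].
#' @param ext an [extinction_table()].
#' @param montage montage giving per-channel separations.
#' @return an [od_series()] with one layer per wavelength in `ext`.
#' @export
forward_mbll <- function(hemo, ext = default_extinction(),
                         montage = default_montage()) {
  stopifnot(inherits(hemo, "hemo_series"), inherits(ext, "extinction_table"))
  validate_montage(montage)
  n_ch <- ncol(hemo$hbo)
  if (nrow(montage) != n_ch)
    stop("montage has ", nrow(montage), " channels but series has ", n_ch)
  r <- montage$separation_mm
  n_wl <- nrow(ext)
  od <- array(0, dim = c(nrow(hemo$hbo), n_ch, n_wl))
  for (w in seq_len(n_wl)) {
    lw <- ext$dpf[w] * r  # per-channel path scaling, length n_ch
    od[, , w] <- sweep(ext$eps_hbo[w] * hemo$hbo + ext$eps_hbr[w] * hemo$hbr,
                       2, lw, `*`)
  }
  od_series(od, hemo$fs, ext$wavelength_nm, events = hemo$events)
}

#' Invert the modified Beer-Lambert law
#'
#' Recovers per-channel, per-timepoint HbO/HbR concentration changes from
#' optical density at three (or more) wavelengths. The system
#' `dOD(lambda)/(r * DPF(lambda)) = eps_HbO(lambda) dC_HbO + eps_HbR(lambda) dC_HbR`
#' is overdetermined (3 equations, 2 unknowns); the solution is the
#' least-squares (Moore-Penrose) solution via the normal equations, the only
#' coherent reading of a pseudo-inverse of the non-square extinction matrix.
#'
#' @param od an [od_series()] with at least 3 wavelength layers matching
#'   `ext$wavelength_nm`.
#' @param ext an [extinction_table()].
#' @param montage montage giving per-channel separations.
#' @return a [hemo_series()] in uM (given the documented unit conventions).
#' @export
invert_mbll <- function(od, ext = default_extinction(),
                        montage = default_montage()) {
  stopifnot(inherits(od, "od_series"), inherits(ext, "extinction_table"))
  validate_montage(montage)
  n_wl <- dim(od$od)[3]
  if (n_wl < 3) stop("need at least 3 wavelengths, got ", n_wl)
  if (n_wl != nrow(ext) || !all(od$wavelengths == ext$wavelength_nm))
    stop("od wavelengths do not match the extinction table")
  n_ch <- dim(od$od)[2]
  if (nrow(montage) != n_ch)
    stop("montage has ", nrow(montage), " channels but series has ", n_ch)
  E <- cbind(ext$eps_hbo, ext$eps_hbr)
  if (qr(E)$rank < 2) stop("extinction matrix is rank deficient")
  # pseudo-inverse (2 x n_wl); same for all channels/timepoints
  Pinv <- solve(crossprod(E), t(E))
  n_t <- dim(od$od)[1]
  hbo <- matrix(0, n_t, n_ch)
  hbr <- matrix(0, n_t, n_ch)
  r <- montage$separation_mm
  for (ch in seq_len(n_ch)) {
    y <- od$od[, ch, ] / matrix(r[ch] * ext$dpf, n_t, n_wl, byrow = TRUE)
    sol <- y %*% t(Pinv)
    hbo[, ch] <- sol[, 1]
    hbr[, ch] <- sol[, 2]
  }
  hemo_series(hbo, hbr, od$fs, events = od$events)
}
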