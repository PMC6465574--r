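#' Default target correlation structure of the 14 rating items
#'
#' The published pairwise Pearson correlations between the 14 rating
#' items (10 positive emotions, arousal, valence, familiarity, liking),
#' used as the simulator's default target for the latent rating
#' structure. Values are projected to the nearest positive-definite
#' correlation matrix before use.
#'
#' @return 14 x 14 symmetric matrix with unit diagonal.
#' @export
rating_target_correlations <- function() {
  path <- system.file("extdata", "rating_item_correlations.csv",
                      package = "nirsemotion", mustWork = TRUE)
  tab <- read.csv(path, check.names = FALSE)
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab$item
  m
}

#' Study design for the synthetic-data generator
#'
#' Encodes the conditions of the emulated study: 13 participants watch 37
#' film clips (30 positive = 10 emotions x 3 clips, 6 negative, 1
#' neutral) whose durations span 30-129 s with mean ~70 s, separated by
#' rests of at least 45 s, while a 24-channel frontal montage records
#' tri-wavelength intensity at 50 Hz. Emotion-cluster-specific spatial
#' activation patterns (caricatures: encouragement = medial HbO
#' increase, playfulness = global HbR decrease, harmony = left-lateral,
#' negative = right-lateral) are scaled by `effect_amplitude_um` and
#' superimposed on physiological noise: cardiac (~1.2 Hz), respiratory
#' (~0.25 Hz) and Mayer-wave (~0.1 Hz) oscillations, 1/f-like drift,
#' band-limited hemodynamic background and white measurement noise.
#' Clip durations are clip properties drawn once from `seed`; per-
#' participant presentation order is randomized by [gen_recording()].
#'
#' @param n_participants number of participants.
#' @param clips_per_emotion positive clips per target emotion.
#' @param n_negative,n_neutral control clip counts.
#' @param fs sampling rate (Hz).
#' @param montage channel montage, see [default_montage()].
#' @param ext extinction/DPF table shared by simulation and inversion.
#' @param effect_amplitude_um peak cluster-pattern amplitude (uM HbO).
#' @param seed seed for the clip-schedule draw.
#' @param ... overrides for the remaining design fields (`noise`,
#'   `rating`, `rest_s`, `rest_jitter_s`, `lead_in_s`, `ramp_s`,
#'   `participant_scale_sd`, `clip_gain_sd`, `baseline_intensity`).
#' @return object of class `sim_design`.
#' @export
sim_design <- function(n_participants = 13, clips_per_emotion = 3,
                       n_negative = 6, n_neutral = 1, fs = 50,
                       montage = default_montage(),
                       ext = default_extinction(),
                       effect_amplitude_um = 0.4,
                       seed = 1001, ...) {
  emotions <- emotion_items("positive")
  n_pos <- length(emotions) * clips_per_emotion
  clip_info <- data.frame(
    clip_id = seq_len(n_pos + n_negative + n_neutral),
    condition = c(rep("positive", n_pos), rep("negative", n_negative),
                  rep("neutral", n_neutral)),
    target_emotion = c(rep(emotions, each = clips_per_emotion),
                       rep(NA_character_, n_negative + n_neutral)),
    arousal_level = c(rep(NA_character_, n_pos),
                      rep(c("high", "low"), length.out = n_negative),
                      rep(NA_character_, n_neutral)),
    stringsAsFactors = FALSE)
  cl_def <- default_clusters()
  clip_info$cluster <- NA_character_
  for (cl in names(cl_def))
    clip_info$cluster[clip_info$target_emotion %in% cl_def[[cl]]] <- cl
  clip_info$cluster[clip_info$condition == "negative"] <- "negative"
  # durations 30-129 s, mean ~70: scaled Beta(2, 2.95) has mean 0.404
  clip_info$duration_s <- with_seed(seed, round(
    30 + 99 * rbeta(nrow(clip_info), 2, 2.95), 1))

  design <- list(
    n_participants = n_participants,
    fs = fs, montage = montage, ext = ext,
    clip_info = clip_info,
    clusters = cl_def,
    effect_amplitude_um = effect_amplitude_um,
    effect_patterns = default_effect_patterns(montage),
    noise = list(cardiac_hz = 1.2, cardiac_um = 0.75,
                 resp_hz = 0.25, resp_um = 0.4,
                 mayer_hz = 0.1, mayer_um = 0.3,
                 freq_jitter = 0.03, drift_um = 1.0,
                 background_um = 0.3, white_um = 0.15,
                 hbr_scale = 0.35, measurement = 5e-4),
    rating = list(target_corr = pd_project(rating_target_correlations()),
                  target_shift = 2.2, sibling_shift = 1.4,
                  negative_shift = 1.5,
                  participant_noise_sd = 0.6, rater_bias_sd = 0.15),
    rest_s = 45, rest_jitter_s = 15, lead_in_s = 60, ramp_s = 5,
    tail_s = 30,
    participant_scale_sd = 0.2, clip_gain_sd = 0.25,
    baseline_intensity = 1.0,
    seed = seed)
  extra <- list(...)
  for (nm in names(extra)) {
    if (nm %in% c("noise", "rating"))
      design[[nm]] <- modifyList(design[[nm]], extra[[nm]])
    else design[[nm]] <- extra[[nm]]
  }
  class(design) <- "sim_design"
  design
}

#' @export
print.sim_design <- function(x, ...) {
  cat(sprintf(
    "simulation design: %d participants, %d clips (%d positive / %d negative / %d neutral), %d channels at %g Hz\n",
    x$n_participants, nrow(x$clip_info),
    sum(x$clip_info$condition == "positive"),
    sum(x$clip_info$condition == "negative"),
    sum(x$clip_info$condition == "neutral"),
    nrow(x$montage), x$fs))
  invisible(x)
}

pd_project <- function(m) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) > 1e-8) return(m)
  out <- tryCatch(
    as.matrix(Matrix::nearPD(m, corr = TRUE)$mat),
    error = function(e) stop("target correlation matrix cannot be ",
                             "projected to positive definite: ",
                             conditionMessage(e)))
  dimnames(out) <- dimnames(m)
  out
}

#' Default cluster spatial activation patterns
#'
#' Relative (unitless) per-channel HbO/HbR weights for each emotion
#' cluster and the negative condition, built from the montage's
#' left/medial/right regions. These are plausibility caricatures for
#' simulation, not measured quantities; the neutral condition has no
#' pattern. Multiplied by the design's `effect_amplitude_um`.
#'
#' @param montage montage providing the `region` column.
#' @return named list of lists with `hbo` and `hbr` 24-vectors.
#' @export
default_effect_patterns <- function(montage = default_montage()) {
  reg <- montage$region
  w <- function(where, peak, base = 0) ifelse(reg %in% where, peak, base)
  list(
    encouragement = list(hbo = w("medial", 1.0, 0.15),
                         hbr = -w("medial", 0.30, 0.05)),
    playfulness   = list(hbo = rep(0.25, nrow(montage)),
                         hbr = rep(-0.80, nrow(montage))),
    harmony       = list(hbo = w("left", 0.90, 0.10),
                         hbr = -w("left", 0.30, 0.05)),
    negative      = list(hbo = w("right", 0.90, 0.10),
                         hbr = -w("right", 0.25, 0.05)),
    neutral       = list(hbo = rep(0, nrow(montage)),
                         hbr = rep(0, nrow(montage))))
}

#' Simulate the Likert rating matrix
#'
#' Each clip draws a latent 14-dimensional item profile from a Gaussian
#' with the design's target inter-item correlation; a deterministic
#' elevation is then added to the clip's target emotion, a smaller one to
#' the target's cluster siblings (a clip eliciting awe also elicits some
#' gratitude and inspiration), and valence is depressed for negative
#' clips, so that manipulation checks and cluster-based stimulus
#' selection have the configured effect size. Participants rate each clip as the latent
#' profile plus a rater bias and independent noise, discretised to 1-7
#' by equal-probability thresholds on the latent scale.
#'
#' @param design a [sim_design()].
#' @param seed RNG seed; the same (design, seed) pair is bit-identical.
#' @return list with `ratings` (a [rating_matrix()]) and `truth`
#'   (pre-shift latent clip profiles, shifted profiles, parameters).
#' @export
gen_ratings <- function(design, seed = 1) {
  stopifnot(inherits(design, "sim_design"))
  items <- emotion_items()
  ci <- design$clip_info
  rp <- design$rating
  n_c <- nrow(ci); n_i <- length(items); n_p <- design$n_participants
  with_seed(seed, {
    L <- matrix(rnorm(n_c * n_i), n_c, n_i) %*% chol(rp$target_corr)
    colnames(L) <- items
    Ls <- L
    for (i in seq_len(n_c)) {
      if (ci$condition[i] == "positive") {
        Ls[i, ci$target_emotion[i]] <- Ls[i, ci$target_emotion[i]] +
          rp$target_shift
        sibs <- setdiff(design$clusters[[ci$cluster[i]]],
                        ci$target_emotion[i])
        Ls[i, sibs] <- Ls[i, sibs] + rp$sibling_shift
        Ls[i, "valence"] <- Ls[i, "valence"] + 0.5 * rp$target_shift
      } else if (ci$condition[i] == "negative") {
        pos <- emotion_items("positive")
        Ls[i, pos] <- Ls[i, pos] - rp$negative_shift
        Ls[i, "valence"] <- Ls[i, "valence"] - 1.5 * rp$negative_shift
        Ls[i, "arousal"] <- Ls[i, "arousal"] +
          if (ci$arousal_level[i] == "high") 1 else -1
      }
    }
    sd_tot <- sqrt(1 + rp$participant_noise_sd^2 + rp$rater_bias_sd^2)
    cuts <- qnorm(seq_len(6) / 7, mean = 0, sd = sd_tot)
    arr <- array(0L, dim = c(n_p, n_c, n_i))
    for (p in seq_len(n_p)) {
      bias <- rnorm(1, 0, rp$rater_bias_sd)
      latent <- Ls + bias +
        matrix(rnorm(n_c * n_i, 0, rp$participant_noise_sd), n_c, n_i)
      arr[p, , ] <- matrix(findInterval(latent, cuts) + 1L, n_c, n_i)
    }
  })
  list(ratings = rating_matrix(arr, items, ci),
       truth = list(latent = L, latent_shifted = Ls, params = rp,
                    seed = seed))
}

band_limited_noise <- function(n, fs, low, high) {
  x <- bp_core(matrix(rnorm(n), ncol = 1), low, high, fs)
  drop(x) / max(sd(x), .Machine$double.eps)
}

#' Simulate one participant's raw fNIRS recording
#'
#' Builds the participant's stimulus schedule (neutral clip first, then
#' the negative clips, then the positive clips, order randomized within
#' the last two blocks; rests of `rest_s` plus uniform jitter), composes
#' the true HbO/HbR concentration changes per channel (cluster spatial
#' pattern times a ramped boxcar during each clip, scaled by a
#' per-participant factor and per-clip gain, plus all noise components),
#' converts them to optical density by the forward modified Beer-Lambert
#' law with the design's shared extinction table, and emits raw light
#' intensity `I = I0 * exp(-dOD)` with multiplicative measurement noise.
#'
#' @param design a [sim_design()].
#' @param participant participant index (1-based).
#' @param seed RNG seed; (design, participant, seed) is bit-identical.
#' @return list with `recording` (a [raw_recording()]) and `truth`
#'   (schedule with applied gains, per-participant scale, the pattern
#'   set, and the noise-free signal description).
#' @export
gen_recording <- function(design, participant = 1, seed = 1) {
  stopifnot(inherits(design, "sim_design"))
  fs <- design$fs
  n_ch <- nrow(design$montage)
  # distinct stream per participant; kept below 2^31 for set.seed()
  with_seed((seed %% 2000000) * 1000 + participant, {
    ci <- design$clip_info
    idx_neu <- which(ci$condition == "neutral")
    idx_neg <- sample(which(ci$condition == "negative"))
    idx_pos <- sample(which(ci$condition == "positive"))
    order_idx <- c(idx_neu, idx_neg, idx_pos)
    t_cursor <- design$lead_in_s
    onset <- offset <- numeric(length(order_idx))
    for (k in seq_along(order_idx)) {
      onset[k] <- t_cursor
      offset[k] <- t_cursor + ci$duration_s[order_idx[k]]
      t_cursor <- offset[k] + design$rest_s +
        runif(1, 0, design$rest_jitter_s)
    }
    events <- data.frame(clip_id = ci$clip_id[order_idx],
                         onset_s = round(onset, 2),
                         offset_s = round(offset, 2),
                         condition = ci$condition[order_idx],
                         target_emotion = ci$target_emotion[order_idx],
                         cluster = ci$cluster[order_idx],
                         stringsAsFactors = FALSE)
    total_s <- max(events$offset_s) + design$tail_s
    n_t <- ceiling(total_s * fs)
    tt <- (seq_len(n_t) - 1) / fs

    p_scale <- exp(rnorm(1, 0, design$participant_scale_sd))
    clip_gain <- pmax(0, rnorm(nrow(events), 1, design$clip_gain_sd))

    hbo <- matrix(0, n_t, n_ch)
    hbr <- matrix(0, n_t, n_ch)
    for (k in seq_len(nrow(events))) {
      cl <- events$cluster[k]
      if (is.na(cl)) cl <- "neutral"
      pat <- design$effect_patterns[[cl]]
      box <- ramped_boxcar(tt, events$onset_s[k], events$offset_s[k],
                           design$ramp_s)
      amp <- design$effect_amplitude_um * p_scale * clip_gain[k]
      act <- which(box > 0)
      if (length(act)) {
        hbo[act, ] <- hbo[act, ] + (box[act] * amp) %o% pat$hbo
        hbr[act, ] <- hbr[act, ] + (box[act] * amp) %o% pat$hbr
      }
    }
    truth_signal <- list(events = events, clip_gain = clip_gain,
                         participant_scale = p_scale,
                         patterns = design$effect_patterns)

    nz <- design$noise
    for (ch in seq_len(n_ch)) {
      osc <- physiological_oscillations(tt, nz)
      drift <- cumsum(rnorm(n_t))
      drift <- drift / max(sd(drift), .Machine$double.eps) * nz$drift_um
      bg <- band_limited_noise(n_t, fs, 0.01, 0.2) * nz$background_um
      white <- rnorm(n_t, 0, nz$white_um)
      hbo[, ch] <- hbo[, ch] + osc + drift + bg + white
      osc_r <- physiological_oscillations(tt, nz)
      drift_r <- cumsum(rnorm(n_t))
      drift_r <- drift_r / max(sd(drift_r), .Machine$double.eps) * nz$drift_um
      bg_r <- band_limited_noise(n_t, fs, 0.01, 0.2) * nz$background_um
      hbr[, ch] <- hbr[, ch] + nz$hbr_scale *
        (osc_r + drift_r + bg_r) + rnorm(n_t, 0, nz$white_um * nz$hbr_scale)
    }

    hemo <- hemo_series(hbo, hbr, fs, events = events)
    od <- forward_mbll(hemo, design$ext, design$montage)
    intensity <- array(0, dim = dim(od$od))
    for (w in seq_len(dim(od$od)[3]))
      intensity[, , w] <- design$baseline_intensity * exp(-od$od[, , w]) *
        (1 + matrix(rnorm(n_t * n_ch, 0, nz$measurement), n_t, n_ch))
    if (any(intensity <= 0))
      stop("simulated intensity non-positive; reduce noise amplitudes")
    rec <- raw_recording(intensity, fs, design$ext$wavelength_nm,
                         montage = design$montage, events = events,
                         participant_id = participant)
  })
  list(recording = rec, truth = truth_signal)
}

ramped_boxcar <- function(tt, onset, offset, ramp_s) {
  box <- numeric(length(tt))
  inside <- tt >= onset & tt < offset
  box[inside] <- 1
  if (ramp_s > 0) {
    up <- inside & tt < onset + ramp_s
    box[up] <- 0.5 * (1 - cos(pi * (tt[up] - onset) / ramp_s))
    dn <- inside & tt >= offset - ramp_s
    box[dn] <- pmin(box[dn],
                    0.5 * (1 - cos(pi * (offset - tt[dn]) / ramp_s)))
  }
  box
}

physiological_oscillations <- function(tt, nz) {
  comp <- function(f0, amp) {
    f <- f0 * (1 + rnorm(1, 0, nz$freq_jitter))
    amp * sin(2 * pi * f * tt + runif(1, 0, 2 * pi))
  }
  comp(nz$cardiac_hz, nz$cardiac_um) + comp(nz$resp_hz, nz$resp_um) +
    comp(nz$mayer_hz, nz$mayer_um)
}

#' Simulate a cohort with no class effect
#'
#' Identical to [gen_recording()] for every participant but with all
#' effect amplitudes set to zero, so class labels are independent of the
#' features: the fixture for chance-level estimation.
#'
#' @param design a [sim_design()].
#' @param seed base RNG seed; participant `p` uses the same stream as
#'   `gen_recording(design0, p, seed)` with zeroed amplitudes.
#' @param process optional function applied to each participant's
#'   `gen_recording()` output before collection (e.g. a preprocessing
#'   reduction to feature samples, to bound memory); default identity.
#' @return list of length `design$n_participants` with the (possibly
#'   processed) per-participant results.
#' @export
gen_null_cohort <- function(design, seed = 1, process = identity) {
  stopifnot(inherits(design, "sim_design"))
  d0 <- design
  d0$effect_amplitude_um <- 0
  lapply(seq_len(design$n_participants), function(p)
    process(gen_recording(d0, participant = p, seed = seed)))
}
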