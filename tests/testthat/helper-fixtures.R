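# Shared fixtures, built in code at test time.

# two-channel montage for hand-sized optics examples
mini_montage <- function(n = 2, sep = 30) {
  data.frame(channel = seq_len(n), separation_mm = sep)
}

# identity-style extinction table for hand arithmetic:
# rows (1,0), (0,1), (1,1), r = 1, DPF = 1
unit_ext <- function() {
  extinction_table(wavelength_nm = c(1, 2, 3),
                   eps_hbo = c(1, 0, 1), eps_hbr = c(0, 1, 1),
                   dpf = c(1, 1, 1))
}

# raw recording with constant intensity, for delta-OD examples
const_recording <- function(n_t = 100, n_ch = 2, value = 2, fs = 50) {
  raw_recording(array(value, dim = c(n_t, n_ch, 3)), fs = fs,
                wavelengths = c(785, 808, 850),
                montage = mini_montage(n_ch))
}

# reduced simulation design for fast unit tests (13 clips, 2 participants)
small_design <- function(n_participants = 2, ...) {
  sim_design(n_participants = n_participants, clips_per_emotion = 1,
             n_negative = 2, n_neutral = 1, seed = 2002, ...)
}

# a quiet, low-noise design for signal-recovery checks
quiet_noise <- function(scale = 0.02) {
  list(cardiac_um = 0.75 * scale, resp_um = 0.4 * scale,
       mayer_um = 0.3 * scale, drift_um = 1.0 * scale,
       background_um = 0.3 * scale, white_um = 0.15 * scale,
       measurement = 1e-6)
}

# feature_samples data frame from per-clip channel means:
# clips x (3 windows) rows, gaussian around per-class mean vectors
gauss_features <- function(mu_by_clip, sd = 1, n_windows = 3, n_ch = 24,
                           participant = 1, chromophore = "HbO") {
  rows <- lapply(seq_along(mu_by_clip), function(ci) {
    do.call(rbind, lapply(seq_len(n_windows), function(k) {
      v <- rnorm(n_ch, mean = mu_by_clip[[ci]], sd = sd)
      out <- data.frame(participant = participant, clip_id = ci,
                        condition = "positive", target_emotion = NA,
                        sample_index = k, chromophore = chromophore)
      out[nirsemotion:::channel_labels(n_ch)] <- as.list(v)
      out
    }))
  })
  feats <- do.call(rbind, rows)
  class(feats) <- c("feature_samples", "data.frame")
  feats
}

# balanced two-class decoding problem: clips 1..6 vs 7..12, class-mean
# separation `delta` on the first 12 channels
gauss_problem <- function(delta, sd = 1, seed = 1, n_ch = 24) {
  mu_a <- c(rep(delta / 2, n_ch / 2), rep(0, n_ch / 2))
  mu_b <- c(rep(-delta / 2, n_ch / 2), rep(0, n_ch / 2))
  mus <- c(rep(list(mu_a), 6), rep(list(mu_b), 6))
  feats <- nirsemotion:::with_seed(seed, gauss_features(mus, sd = sd, n_ch = n_ch))
  assemble_problem(feats, 1:6, 7:12, seed = seed)
}

# brute-force Benjamini-Hochberg step-up, independent of p.adjust
bh_stepup_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- 1
  for (i in n:1) {
    running <- min(running, p[o[i]] * n / i)
    adj[o[i]] <- running
  }
  adj
}
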