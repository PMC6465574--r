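fs <- 50

test_that("band-pass removes DC and has the required frequency response", {
  # the 0.01-Hz high-pass edge transient decays with a ~16-s time
  # constant, so steady-state behaviour needs a long series
  n <- 900 * fs
  tt <- (0:(n - 1)) / fs
  mid <- (n %/% 3):(2 * n %/% 3)   # steady-state portion, away from edges

  const <- bandpass(rep(3, n), fs = fs)
  expect_lt(max(abs(const[mid])), 1e-6 * 3)

  gain_at <- function(f) {
    y <- bandpass(sin(2 * pi * f * tt), fs = fs)
    max(abs(y[mid]))
  }
  expect_gt(gain_at(0.1), 0.9)    # passband (Mayer-wave band retained)
  expect_lt(gain_at(0.1), 1.1)
  expect_lt(gain_at(1.2), 0.05)   # cardiac band rejected
  expect_lt(gain_at(0.001), 0.1)  # drift rejected

  expect_error(bandpass(rep(1, 10), fs = fs), "too short")
  expect_error(bandpass(rnorm(100), low_hz = 0.2, high_hz = 0.01, fs = fs),
               "invalid band")
  expect_error(bandpass(rnorm(100), low_hz = 0.01, high_hz = 30, fs = fs),
               "invalid band")
})

test_that("baseline correction subtracts the 10-s pre-onset mean", {
  n_ch <- 3
  n <- 60 * fs
  mont_sig <- matrix(rnorm(n * n_ch), n, n_ch)
  ev <- data.frame(clip_id = 7, onset_s = 20, offset_s = 55,
                   condition = "positive")
  h <- hemo_series(mont_sig, mont_sig * 0.5, fs = fs)

  # hand-built ramp: baseline mean of a linear ramp equals its midpoint
  ramp <- seq(0, 1, length.out = 10 * fs)
  h$hbo[(10 * fs + 1):(20 * fs), 1] <- ramp
  base_oracle <- mean(ramp)
  ep <- baseline_correct(h, ev)
  seg <- h$hbo[(20 * fs + 1):(55 * fs), 1]
  expect_equal(ep[[1]]$hbo[, 1], seg - base_oracle, tolerance = 1e-12)

  # clip identical to its baseline mean -> corrected segment == 0
  h2 <- hemo_series(matrix(2.5, n, n_ch), matrix(-1, n, n_ch), fs = fs)
  ep2 <- baseline_correct(h2, ev)
  expect_true(all(ep2[[1]]$hbo == 0) && all(ep2[[1]]$hbr == 0))

  # adding a channel-wise constant leaves the output unchanged
  h3 <- h
  h3$hbo <- h$hbo + 100
  ep3 <- baseline_correct(h3, ev)
  expect_equal(ep3[[1]]$hbo, ep[[1]]$hbo, tolerance = 1e-9)

  ev_bad <- data.frame(clip_id = 9, onset_s = 5, offset_s = 40,
                       condition = "positive")
  expect_error(baseline_correct(h, ev_bad), "clip 9")
})

test_that("the last 30 s tile into three non-overlapping 10-s windows", {
  n_ch <- 2
  ev <- data.frame(clip_id = 1, onset_s = 20, offset_s = 90,
                   condition = "positive")   # 70-s clip
  n <- 100 * fs
  h <- hemo_series(matrix(seq_len(n), n, n_ch), matrix(0, n, n_ch), fs = fs)
  w <- extract_samples(h, ev)
  expect_length(w, 3)
  expect_true(all(vapply(w, function(x) nrow(x$hbo), numeric(1)) == 500))
  expect_equal(vapply(w, `[[`, numeric(1), "sample_index"), 1:3)

  # tiling: the three windows jointly cover exactly the last 30 s
  joined <- do.call(rbind, lapply(w, `[[`, "hbo"))[, 1]
  expect_equal(joined, seq(90 * fs - 30 * fs + 1, 90 * fs))

  # six clips -> 18 windows
  ev6 <- data.frame(clip_id = 1:6, onset_s = seq(20, 520, by = 100),
                    offset_s = seq(90, 590, by = 100),
                    condition = "positive")
  n2 <- 600 * fs
  h2 <- hemo_series(matrix(0, n2, n_ch), matrix(0, n2, n_ch), fs = fs)
  expect_length(extract_samples(h2, ev6), 18)

  ev_short <- data.frame(clip_id = 3, onset_s = 20, offset_s = 49.9,
                         condition = "positive")
  expect_error(extract_samples(h, ev_short), "clip 3")
})

test_that("features are per-channel window means over 24 dimensions", {
  n <- 200 * fs
  hbo <- matrix(rnorm(n * 24), n, 24)
  hbo[, 5] <- 4.2                     # constant channel -> feature = 4.2
  h <- hemo_series(hbo, -0.5 * hbo, fs = fs)
  ev <- data.frame(clip_id = 1, onset_s = 30, offset_s = 100,
                   condition = "positive")
  w <- extract_samples(h, ev)
  f <- build_features(w, participant_id = 3)
  expect_s3_class(f, "feature_samples")
  expect_equal(nrow(f), 6)            # 3 windows x 2 chromophores
  expect_equal(ncol(feature_matrix(f)), 24)
  expect_true(all(abs(f$ch05[f$chromophore == "HbO"] - 4.2) < 1e-12))

  # window mean equals the arithmetic oracle on a hand-built window
  idx <- (70 * fs + 1):(80 * fs)      # first 10-s window of the last 30 s
  oracle <- mean(hbo[idx, 1])
  expect_equal(f$ch01[f$chromophore == "HbO" & f$sample_index == 1][1],
               oracle, tolerance = 1e-12)

  # invariant to time reversal within windows
  w_rev <- w
  for (k in seq_along(w_rev)) {
    w_rev[[k]]$hbo <- w_rev[[k]]$hbo[nrow(w_rev[[k]]$hbo):1, ]
    w_rev[[k]]$hbr <- w_rev[[k]]$hbr[nrow(w_rev[[k]]$hbr):1, ]
  }
  expect_equal(feature_matrix(build_features(w_rev)),
               feature_matrix(build_features(w)), tolerance = 1e-12)
})

test_that("constant activation survives the full chain within 15%", {
  # inject a known sustained activation in one channel, run the complete
  # intensity -> filter -> OD -> MBLL -> baseline -> feature chain, and
  # compare against the filter-response oracle applied to the same boxcar
  delta <- 0.5
  ext <- default_extinction()
  mont <- default_montage()
  dur <- 70; onset <- 60
  n <- (onset + dur + 40) * fs
  tt <- (0:(n - 1)) / fs
  box <- nirsemotion:::ramped_boxcar(tt, onset, onset + dur, 5)
  hbo <- matrix(0, n, 24); hbo[, 3] <- delta * box
  hemo <- hemo_series(hbo, -0.3 * hbo, fs = fs)
  od <- forward_mbll(hemo, ext, mont)
  intensity <- array(0, dim = dim(od$od))
  for (w in 1:3) intensity[, , w] <- exp(-od$od[, , w])
  ev <- data.frame(clip_id = 1, onset_s = onset, offset_s = onset + dur,
                   condition = "positive")
  raw <- raw_recording(intensity, fs, ext$wavelength_nm, mont, events = ev)
  f <- preprocess_recording(raw, ext)
  got <- mean(feature_matrix(f)[f$chromophore == "HbO", 3])

  # oracle: band-pass + baseline + window-mean applied to the boxcar itself
  fb <- bandpass(delta * box, fs = fs)
  base <- mean(fb[((onset - 10) * fs + 1):(onset * fs)])
  oracle <- mean(fb[((onset + dur - 30) * fs + 1):((onset + dur) * fs)]) - base
  expect_lt(abs(got - oracle) / abs(oracle), 0.15)
  # and the attenuated oracle still reflects most of the injected step
  expect_gt(oracle / delta, 0.3)
})
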