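# single-participant design used for the recording-level loops:
# 10 positive (one per emotion) + 6 negative + 1 neutral clips
loop_design <- function(...) {
  sim_design(n_participants = 1, clips_per_emotion = 1, n_negative = 6,
             n_neutral = 1, seed = 3003, ...)
}

decode_one <- function(design, seed, chromophore = "HbO") {
  g <- gen_recording(design, participant = 1, seed = seed)
  f <- preprocess_recording(g$recording, ext = design$ext)
  pos <- design$clip_info$clip_id[design$clip_info$condition == "positive"]
  neg <- design$clip_info$clip_id[design$clip_info$condition == "negative"]
  prob <- assemble_problem(f, sort(pos)[1:6], neg,
                           chromophore = chromophore, seed = seed)
  list(problem = prob, accuracy = crossval_accuracy(prob)$accuracy)
}

test_that("simulated ratings are valid Likert draws with the target structure", {
  d <- small_design()
  gr <- gen_ratings(d, seed = 5)
  vals <- gr$ratings$ratings
  expect_true(all(vals == round(vals)))
  expect_true(all(vals >= 1 & vals <= 7))
  gr2 <- gen_ratings(d, seed = 5)
  expect_identical(gr$ratings$ratings, gr2$ratings$ratings)
  expect_false(identical(gr$ratings$ratings,
                         gen_ratings(d, seed = 6)$ratings$ratings))

  # latent correlation recovery at n = 3000 positive clips
  d_big <- sim_design(n_participants = 1, clips_per_emotion = 300,
                      seed = 1001)
  gr_big <- gen_ratings(d_big, seed = 11)
  got <- cor(gr_big$truth$latent)
  target <- d_big$rating$target_corr
  expect_lt(max(abs(got - target)), 0.05)
})

test_that("recordings are reproducible and respect the schedule contract", {
  d <- small_design()
  g1 <- gen_recording(d, participant = 1, seed = 8)
  g2 <- gen_recording(d, participant = 1, seed = 8)
  expect_identical(g1$recording$intensity, g2$recording$intensity)
  expect_identical(g1$truth$events, g2$truth$events)
  g3 <- gen_recording(d, participant = 2, seed = 8)
  expect_false(identical(g1$recording$intensity, g3$recording$intensity))

  ev <- g1$recording$events
  expect_true(all(ev$onset_s >= 10))
  durs <- ev$offset_s - ev$onset_s
  expect_true(all(durs >= 30 & durs <= 129))
  # neutral first, then negatives, then positives
  expect_equal(ev$condition[1], "neutral")
  expect_true(all(ev$condition[2:3] == "negative"))
  gaps <- ev$onset_s[-1] - ev$offset_s[-nrow(ev)]
  expect_true(all(gaps >= d$rest_s - 1e-9))
  # the design's stated mean duration is ~70 s over the full 37-clip set
  d_full <- sim_design()
  expect_equal(mean(d_full$clip_info$duration_s), 70, tolerance = 0.1 * 70)
  expect_true(all(d_full$clip_info$duration_s >= 30 &
                    d_full$clip_info$duration_s <= 129))
})

test_that("noise-free forward simulation is exactly invertible", {
  zero_noise <- list(cardiac_um = 0, resp_um = 0, mayer_um = 0,
                     drift_um = 0, background_um = 0, white_um = 0,
                     measurement = 0)
  d <- loop_design(noise = zero_noise, effect_amplitude_um = 0.5)
  g <- gen_recording(d, participant = 1, seed = 4)
  hemo <- invert_mbll(compute_delta_od(g$recording), d$ext, d$montage)
  # the intensity reference only shifts each channel by a constant
  ev <- g$recording$events
  tt <- (seq_len(nrow(hemo$hbo)) - 1) / d$fs
  k <- which(ev$condition == "positive")[1]
  pat <- d$effect_patterns[[ev$cluster[k]]]$hbo
  amp <- d$effect_amplitude_um * g$truth$participant_scale *
    g$truth$clip_gain[k]
  box <- nirsemotion:::ramped_boxcar(tt, ev$onset_s[k], ev$offset_s[k], 5)
  truth_ch <- amp * pat[3] * box
  rec_ch <- hemo$hbo[, 3]
  # the mean intensity reference shifts the recovered trace by a constant;
  # compare within the clip's window (rests isolate it from other clips)
  win <- tt >= ev$onset_s[k] - 10 & tt < ev$offset_s[k] + 10
  expect_lt(max(abs((rec_ch[win] - mean(rec_ch[win])) -
                      (truth_ch[win] - mean(truth_ch[win])))), 1e-8)
})

test_that("the pipeline recovers injected spatial patterns at high SNR", {
  d <- loop_design(noise = quiet_noise(0.02), effect_amplitude_um = 0.5)
  g <- gen_recording(d, participant = 1, seed = 21)
  f <- preprocess_recording(g$recording, ext = d$ext)
  x <- feature_matrix(f)
  for (cl in c("encouragement", "playfulness", "harmony", "negative")) {
    clips <- d$clip_info$clip_id[!is.na(d$clip_info$cluster) &
                                   d$clip_info$cluster == cl]
    rows <- f$chromophore == "HbO" & f$clip_id %in% clips
    recovered <- colMeans(x[rows, , drop = FALSE])
    injected <- d$effect_patterns[[cl]]$hbo
    if (sd(injected) > 0)
      expect_gt(cor(recovered, injected), 0.9)
  }
})

test_that("null cohorts have label-independent features decoding at chance", {
  d0 <- loop_design(effect_amplitude_um = 0)
  accs <- numeric(16)
  rbar <- matrix(0, 16, 24)
  for (s in 1:16) {
    out <- decode_one(d0, seed = 500 + s)
    accs[s] <- out$accuracy
    y <- as.numeric(out$problem$y == levels(out$problem$y)[1])
    rbar[s, ] <- apply(out$problem$x, 2, function(v) cor(v, y))
  }
  expect_equal(mean(accs), 50, tolerance = 6)
  expect_lt(abs(mean(rbar)), 0.025)    # point-biserial centred on zero

  # gen_null_cohort: reproducible, zero-effect equivalent of the design
  d_small <- small_design()
  coh <- gen_null_cohort(d_small, seed = 9)
  expect_length(coh, 2)
  d_zero <- small_design(effect_amplitude_um = 0)
  ref <- gen_recording(d_zero, participant = 1, seed = 9)
  expect_identical(coh[[1]]$recording$intensity, ref$recording$intensity)
  n_samp <- vapply(coh, function(x) nrow(x$recording$events), numeric(1))
  expect_true(all(n_samp == nrow(d_small$clip_info)))
})

test_that("decoding power at 3x background noise exceeds 70%", {
  d3 <- loop_design(effect_amplitude_um = 3 * 0.3)
  accs <- vapply(1:12, function(s) decode_one(d3, seed = 900 + s)$accuracy,
                 numeric(1))
  expect_gt(mean(accs), 70)
})
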