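test_that("matched filter scores a verbatim kernel at 1.0 at the true time", {
  fs <- 400
  k <- synthesize_call("fin", fs, jitter = 0)
  x <- numeric(fs * 30)
  x[(fs * 10 + 1):(fs * 10 + length(k$samples))] <- k$samples
  ev <- detect_matched_filter(waveform(x, fs), k, highpass = 0)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$begin_time, 10)
  expect_equal(ev$score, 1, tolerance = 1e-6)
  expect_true(all(abs(ev$score) <= 1))
  expect_error(detect_matched_filter(waveform(x, 500), k), "rates differ")
  expect_error(detect_matched_filter(k, waveform(x, fs)), "longer")
})

test_that("matched filter rejects the time-reversed sweep", {
  fs <- 400
  k <- synthesize_call("fin", fs, jitter = 0)
  noise <- generate_ambient_noise(120, fs, shelf_spectrum(75), seed = 14)
  rev_k <- waveform(rev(k$samples), fs)
  attr(rev_k, "low_freq") <- attr(k, "low_freq")
  attr(rev_k, "high_freq") <- attr(k, "high_freq")
  attr(rev_k, "species") <- "fin"
  mix <- inject_calls(noise, tibble::tibble(
    time = c(30, 60, 90), wave = list(rev_k, rev_k, rev_k), species = "fin"),
    snr_db = 10)
  ev <- detect_matched_filter(mix$wave, k)
  expect_equal(nrow(ev), 0)
})

test_that("template cross-correlation finds an exact template copy", {
  fs <- 500
  cw <- synthesize_call("sei", fs, seed = 9, jitter = 0)
  ts <- make_template_set(list(cw))
  # insert the call into very faint noise
  bg <- generate_ambient_noise(60, fs, shelf_spectrum(10), seed = 15)
  x <- bg$samples
  i0 <- fs * 30
  x[(i0 + 1):(i0 + length(cw$samples))] <- x[(i0 + 1):(i0 + length(cw$samples))] +
    cw$samples * 1e4
  s <- compute_spectrogram(waveform(x, fs), 256, 0.5)
  ev <- detect_template_xcorr(s, ts)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$begin_time, 30, tolerance = 0.6)
  expect_gt(ev$score, 0.9)
  expect_lte(ev$score, 1)
})

test_that("upcall contour detector accepts upsweeps and rejects downsweeps", {
  fs <- 2000
  noise <- generate_ambient_noise(60, fs, shelf_spectrum(70), seed = 31)
  up <- synthesize_call("right", fs, seed = 5, jitter = 0)
  mix <- inject_calls(noise, tibble::tibble(time = 30, wave = list(up),
                                            species = "right"), snr_db = 10)
  ev <- detect_upcall(compute_spectrogram(mix$wave, 512, 0.75))
  expect_equal(nrow(ev), 1)
  expect_lte(ev$begin_time, 30.1)
  expect_gte(ev$end_time, 30.5)
  expect_gt(ev$score, 0.6)

  dn <- waveform(rev(up$samples), fs)
  attr(dn, "low_freq") <- attr(up, "low_freq")
  attr(dn, "high_freq") <- attr(up, "high_freq")
  mix2 <- inject_calls(noise, tibble::tibble(time = 30, wave = list(dn),
                                             species = "right"), snr_db = 10)
  expect_equal(nrow(detect_upcall(compute_spectrogram(mix2$wave, 512, 0.75))), 0)

  silent <- waveform(numeric(fs * 10), fs)
  expect_equal(nrow(detect_upcall(compute_spectrogram(silent, 512, 0.75))), 0)
  expect_error(detect_upcall(compute_spectrogram(mix$wave, 512, 0.75),
                             low = 1500, high = 1600), "band")
})

test_that("humpback unit detector requires tonality, not just energy", {
  fs <- 2000
  noise <- generate_ambient_noise(60, fs, shelf_spectrum(70), seed = 16)
  hb <- synthesize_call("humpback", fs, seed = 7)
  mix <- inject_calls(noise, tibble::tibble(time = 20, wave = list(hb),
                                            species = "humpback"), snr_db = 10)
  units <- detect_humpback_units(compute_spectrogram(mix$wave, 512, 0.5))
  expect_gte(nrow(units), 2)
  expect_true(all(units$score >= 0 & units$score <= 1))

  vessel <- generate_ambient_noise(600, fs, shelf_spectrum(70),
    vessel_events = tibble::tibble(time = 300, level_db = 20, width = 5),
    seed = 17)
  fa <- detect_humpback_units(compute_spectrogram(vessel, 512, 0.5))
  expect_equal(nrow(fa), 0)

  silent <- waveform(numeric(fs * 10), fs)
  expect_equal(nrow(detect_humpback_units(compute_spectrogram(silent, 512, 0.5))), 0)
})

test_that("co-occurrence screening removes only concurrent upcalls", {
  up <- tibble::tibble(begin_time = c(10, 20, 30, 40, 50),
                       end_time = c(11, 21, 31, 41, 51),
                       low_freq = 100, high_freq = 200, score = 0.9,
                       species = "right", site_id = "a")
  expect_identical(screen_cooccurrence(up, up[0, ]), up)
  hb <- tibble::tibble(begin_time = c(19.5, 39), end_time = c(21.5, 42),
                       low_freq = 200, high_freq = 400, score = 0.8,
                       species = "humpback", site_id = "a")
  kept <- screen_cooccurrence(up, hb)
  expect_equal(nrow(kept), 3)
  expect_equal(kept$begin_time, c(10, 30, 50))
})

test_that("review subsampling schedule is deterministic", {
  expect_equal(subsample_review_schedule(4), c(0L, 4L, 8L, 12L, 16L, 20L))
  expect_equal(subsample_review_schedule(1), 0:23)
  expect_error(subsample_review_schedule(0), "k")
})

test_that("detection is deterministic and stays on the sample time base", {
  fs <- 400
  scene <- make_scene("fin", fs, 120, 8, 10, seed = 18, jitter = 0.3)
  k <- synthesize_call("fin", fs, jitter = 0)
  e1 <- detect_matched_filter(scene$wave, k)
  e2 <- detect_matched_filter(scene$wave, k)
  expect_identical(e1, e2)
  # begin times are exact multiples of the sample period
  expect_true(all(abs(e1$begin_time * fs - round(e1$begin_time * fs)) < 1e-9))
})

test_that("detection probability is non-decreasing in SNR", {
  fs <- 400
  k <- synthesize_call("fin", fs, jitter = 0)
  recall <- vapply(c(-5, 0, 5, 10, 15), function(snr) {
    scene <- make_scene("fin", fs, 300, 20, snr, seed = 20 + snr, jitter = 0.3)
    m <- match_detections(detect_matched_filter(scene$wave, k),
                          scene$annotations)
    mean(m$matched)
  }, numeric(1))
  expect_true(all(diff(recall) >= -0.05))
  expect_lt(recall[1], 0.5)
  expect_gt(recall[5], 0.95)
})
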