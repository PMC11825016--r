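test_that("decimation preserves in-band content and removes above-Nyquist content", {
  w <- make_tone(20, 2, 5000)
  d <- decimate(w, 400)
  expect_equal(d$sample_rate, 400)
  db_change <- 20 * log10(sqrt(mean(d$samples^2)) / sqrt(mean(w$samples^2)))
  expect_lt(abs(db_change), 1)

  # 190 Hz is above the 100 Hz Nyquist of a 200 Hz stream
  w2 <- make_tone(190, 2, 5000)
  d2 <- decimate(w2, 200)
  atten <- 20 * log10(sqrt(mean(d2$samples^2)) / sqrt(mean(w2$samples^2)))
  expect_lt(atten, -20)

  expect_identical(decimate(w, 5000), w)
  expect_error(decimate(w, 10000), "upsample")
})

test_that("band filtering isolates the requested band", {
  fs <- 2000
  w <- waveform(make_tone(50, 2, fs)$samples + make_tone(300, 2, fs)$samples, fs)
  inb <- band_rms(w, 250, 350)
  expect_equal(inb, 1, tolerance = 0.01)
  expect_lt(band_rms(w, 400, 500), 0.01)
  expect_error(band_filter(w, 100, 1500), "Nyquist")
})

test_that("count calibration maps full scale through the sensitivity", {
  # a full-scale count with -168 dB re 1 V/uPa sensitivity and 1 V full
  # scale corresponds to 10^(168/20) uPa
  w <- calibrate_counts(c(0, 2^11), sample_rate = 5000, bit_depth = 12,
                        sensitivity_db = -168)
  expect_equal(w$samples[2], 10^(168 / 20), tolerance = 1e-12)
  expect_equal(w$samples[1], 0)
})

test_that("WAV files round-trip within quantisation error", {
  w <- generate_ambient_noise(2, 2000, shelf_spectrum(60), seed = 4)
  path <- withr::local_tempfile(fileext = ".wav")
  sc <- write_wav(w, path)
  r <- read_wav(path, scale = sc)
  expect_equal(r$sample_rate, 2000)
  expect_equal(length(r$samples), length(w$samples))
  expect_lt(max(abs(r$samples - w$samples)), sc / 32767)
})

test_that("spectrogram localises tones and satisfies Parseval", {
  fs <- 1000
  w <- make_tone(100, 4, fs)
  s <- compute_spectrogram(w, 256, overlap = 0)
  expect_equal(s$freq[which.max(rowMeans(s$power))], 100, tolerance = s$freq_step)

  # rectangular window, zero overlap: total power equals waveform power
  n <- generate_ambient_noise(4, fs, shelf_spectrum(50, corner_hz = 499), seed = 9)
  sr <- compute_spectrogram(n, 256, overlap = 0, window = "rectangular")
  used <- 256 * ncol(sr$power)
  expect_equal(mean(colSums(sr$power)), mean(n$samples[1:used]^2),
               tolerance = 0.01)

  # archival-recorder settings: 5 kHz with a 512-point FFT
  w5 <- make_tone(100, 1, 5000)
  s5 <- compute_spectrogram(w5, 512)
  expect_equal(s5$freq_step, 5000 / 512)

  # white noise: approximately flat mean power across interior bins
  flat <- compute_spectrogram(n, 256, overlap = 0)
  m <- rowMeans(flat$power)[5:120]
  expect_lt(sd(m) / mean(m), 0.5)

  expect_error(compute_spectrogram(waveform(numeric(0), fs), 256), "empty")
  expect_error(compute_spectrogram(w5, 1e6), "length")
})

test_that("synthesized calls honour their stated bands and durations", {
  # right whale upsweep: at least 90% of energy inside 71-224 Hz
  for (sd in 1:5) {
    cw <- synthesize_call("right", 2000, seed = sd)
    frac <- band_rms(cw, 71, 224)^2 / mean(cw$samples^2)
    expect_gt(frac, 0.9)
    expect_gte(duration(cw), 0.3)
    expect_lte(duration(cw), 1.5)
  }
  # sei downsweep near 1.4 s
  for (sd in 1:5) expect_equal(duration(synthesize_call("sei", 500, seed = sd)),
                               1.4, tolerance = 0.2)
  # zero amplitude: silent, correct length
  z <- synthesize_call("fin", 400, seed = 1, amplitude = 0)
  expect_true(all(z$samples == 0))
  expect_gt(length(z$samples), 0)
  # band above Nyquist rejected
  expect_error(synthesize_call("right", 200, seed = 1), "Nyquist")
})

test_that("sweep directions match the species signal descriptions", {
  peak_track <- function(cw, fft = 128) {
    s <- compute_spectrogram(cw, fft, 0.75)
    s$freq[apply(s$power, 2, which.max)]
  }
  fs <- 500
  up <- peak_track(synthesize_call("right", 2000, seed = 3), 256)
  expect_gt(cor(seq_along(up), up), 0.8)
  dn <- peak_track(synthesize_call("sei", fs, seed = 3))
  expect_lt(cor(seq_along(dn), dn), -0.8)
  # fin note: zero-crossing rate (2x instantaneous frequency) falls from
  # about 25 Hz to about 17 Hz across the note
  fw <- synthesize_call("fin", 400, seed = 3)
  zc_rate <- function(x, fs) sum(abs(diff(sign(x))) > 0) / 2 / (length(x) / fs)
  n <- length(fw$samples); q <- round(n / 4)
  f_start <- zc_rate(fw$samples[1:q], 400)
  f_end <- zc_rate(fw$samples[(n - q + 1):n], 400)
  expect_gt(f_start, 21); expect_lt(f_end, 21)
  expect_true(f_start <= 26 && f_end >= 16)
  # blue A-B: first half approximately constant, later descending
  bl <- synthesize_call("blue", 200, seed = 3)
  tr <- peak_track(bl, 256)
  a <- tr[2:round(length(tr) * 0.3)]
  expect_lt(max(a) - min(a), 1.5)
  b <- tr[tr > 0]
  expect_lt(b[length(b) - 1], max(a) - 1)
})
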