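test_that("generators are pure functions of their seed", {
  a <- generate_ambient_noise(5, 1000, seed = 7)
  b <- generate_ambient_noise(5, 1000, seed = 7)
  expect_identical(a$samples, b$samples)
  expect_false(identical(a$samples,
                         generate_ambient_noise(5, 1000, seed = 8)$samples))

  c1 <- synthesize_call("sei", 500, seed = 3)
  c2 <- synthesize_call("sei", 500, seed = 3)
  expect_identical(c1$samples, c2$samples)

  d1 <- simulate_presence_dataset(presence_sim_params(), 3, 200, seed = 5)
  d2 <- simulate_presence_dataset(presence_sim_params(), 3, 200, seed = 5)
  expect_identical(d1$state, d2$state)

  # generators do not disturb the global RNG stream
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(generate_ambient_noise(1, 500, seed = 1))
  expect_identical(runif(1), before)
})

test_that("vessel events raise the containing interval's Leq", {
  fs <- 1000
  band <- tibble::tibble(label = "full", low = 10, high = 499)
  quiet <- generate_ambient_noise(120, fs, shelf_spectrum(70), seed = 6)
  busy <- generate_ambient_noise(120, fs, shelf_spectrum(70),
    vessel_events = tibble::tibble(time = 90, level_db = 20, width = 5),
    seed = 6)
  lq <- leq(quiet, band, interval = 60)$leq
  lb <- leq(busy, band, interval = 60)$leq
  expect_equal(lb[1], lq[1], tolerance = 0.5) # event-free interval untouched
  expect_gt(lb[2], lq[2] + 3)
})

test_that("injected calls achieve the requested band SNR", {
  fs <- 500
  noise <- generate_ambient_noise(120, fs, shelf_spectrum(75), seed = 11)
  calls <- tibble::tibble(
    time = seq(5, 100, length.out = 10),
    wave = lapply(1:10, function(i) synthesize_call("sei", fs, seed = i)),
    species = "sei")

  mix0 <- inject_calls(noise, calls[1, ], snr_db = 0)
  a <- mix0$annotations
  seg <- function(w) waveform(w$samples[(round(a$begin_time * fs) + 1):
                                          (round(a$end_time * fs))], fs)
  prof <- species_profile("sei")
  call_only <- waveform(mix0$wave$samples - noise$samples, fs)
  r_call <- band_rms(seg(call_only), prof$analysis_low, prof$analysis_high)
  r_noise <- band_rms(seg(noise), prof$analysis_low, prof$analysis_high)
  expect_equal(20 * log10(r_call / r_noise), 0, tolerance = 0.5)

  mix10 <- inject_calls(noise, calls, snr_db = 10)
  expect_equal(nrow(mix10$annotations), 10)
  expect_equal(mix10$annotations$begin_time, calls$time)
  # re-measured SNR of every call within 1 dB of the request
  co <- waveform(mix10$wave$samples - noise$samples, fs)
  snrs <- vapply(seq_len(10), function(i) {
    i0 <- round(mix10$annotations$begin_time[i] * fs) + 1
    i1 <- round(mix10$annotations$end_time[i] * fs)
    rc <- band_rms(waveform(co$samples[i0:i1], fs), prof$analysis_low, prof$analysis_high)
    rn <- band_rms(waveform(noise$samples[i0:i1], fs), prof$analysis_low, prof$analysis_high)
    20 * log10(rc / rn)
  }, numeric(1))
  expect_true(all(abs(snrs - 10) < 1))

  expect_error(inject_calls(noise, dplyr::mutate(calls, time = 119),
                            snr_db = 0), "beyond")
})

test_that("presence simulator matches its latent model", {
  # flat null: empirical rate ~ 0.5
  p0 <- presence_sim_params(baseline = 0, seasonal_amplitude = 0,
                            year_effects = 0, site_sd = 0, ar1_rho = 0,
                            latent_sd = 0)
  d <- simulate_presence_dataset(p0, sites = 10, days = 1000, seed = 2)
  rate <- mean(d$state == "detected")
  expect_lt(abs(rate - 0.5), 3 * sqrt(0.25 / 10000))

  # AR1 latent autocorrelation recovered
  p8 <- presence_sim_params(ar1_rho = 0.8, seasonal_amplitude = 0,
                            year_effects = 0, site_sd = 0)
  d8 <- simulate_presence_dataset(p8, sites = 1, days = 5000, seed = 3)
  lat <- attr(d8, "latent")[, 1]
  expect_equal(cor(lat[-1], lat[-length(lat)]), 0.8, tolerance = 0.05)

  expect_error(presence_sim_params(ar1_rho = 1), "ar1_rho")
})

test_that("deployment gaps subtract days and propagate as missing", {
  sched <- tibble::tibble(start = as.Date("2018-01-01"),
                          end = as.Date("2018-12-31"))
  expect_identical(simulate_deployment_gaps(sched, NULL), sched)

  gap <- tibble::tibble(start = as.Date("2018-06-01"),
                        end = as.Date("2018-06-30"))
  masked <- simulate_deployment_gaps(sched, gap)
  expect_equal(length(schedule_days <- unlist(Map(seq,
    masked$start, masked$end, by = "1 day"))), 365 - 30)

  # gap days are missing in the presence table and excluded downstream
  masked$site_id <- "a"
  pt <- daily_presence(tibble::tibble(site_id = character(),
                                      date = as.Date(character()),
                                      species = character()),
                       masked, species = "fin",
                       span = c(sched$start, sched$end))
  expect_equal(sum(pt$state == "missing"), 30)
  sm <- summarize_presence(pt, by = "none")
  expect_equal(sm$total_days, 335)
})
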