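#' Default shelf ambient-noise spectrum
#'
#' A vessel-traffic-dominated continental-shelf spectral shape: flat
#' power spectral density up to a corner frequency, then a power-law decay
#' of about -10 dB per decade. Structural stand-in for measured shelf
#' spectra, not a fit to any site.
#'
#' @param level_db PSD at and below the corner, dB re 1 uPa^2/Hz.
#' @param corner_hz Corner frequency (Hz).
#' @param slope_db_per_decade Decay above the corner (negative).
#' @return A function `f(freq_hz) -> PSD dB re 1 uPa^2/Hz`, vectorised.
#' @export
shelf_spectrum <- function(level_db = 75, corner_hz = 50,
                           slope_db_per_decade = -10) {
  force(level_db); force(corner_hz); force(slope_db_per_decade)
  function(f) {
    ifelse(f <= corner_hz, level_db,
           level_db + slope_db_per_decade * log10(f / corner_hz))
  }
}

#' Generate spectrally shaped ambient noise
#'
#' Gaussian noise shaped in the frequency domain to a target one-sided
#' power spectral density, with optional transient broadband level boosts
#' representing vessel passages (smooth Gaussian temporal envelopes).
#' Fully deterministic given the seed.
#'
#' @param duration Seconds (> 0).
#' @param sample_rate Hz.
#' @param spectrum Function mapping frequency (Hz) to PSD
#'   (dB re 1 uPa^2/Hz), defined over `[0, sample_rate/2]`;
#'   see [shelf_spectrum()].
#' @param vessel_events Optional tibble with columns `time` (s, event
#'   centre), `level_db` (peak broadband boost, dB), `width` (s, envelope
#'   standard deviation).
#' @param seed Integer seed.
#' @param start_time Optional `POSIXct` start.
#' @return A calibrated [waveform()] (uPa).
#' @export
#' @examples
#' w <- generate_ambient_noise(60, 2000, shelf_spectrum(70), seed = 1)
generate_ambient_noise <- function(duration, sample_rate,
                                   spectrum = shelf_spectrum(),
                                   vessel_events = NULL, seed = 1,
                                   start_time = NULL) {
  if (duration <= 0) abort("`duration` must be positive")
  n <- round(duration * sample_rate)
  f <- fft_freqs(n, sample_rate)
  psd <- spectrum(f)
  if (any(!is.finite(psd))) abort("spectrum undefined over [0, Nyquist]")
  gain <- sqrt(10^(psd / 10) * sample_rate / 2)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  z <- rnorm(n)
  x <- Re(fft(fft(z) * gain, inverse = TRUE)) / n
  if (!is.null(vessel_events) && nrow(vessel_events) > 0) {
    t <- (seq_len(n) - 1) / sample_rate
    boost_db <- numeric(n)
    for (i in seq_len(nrow(vessel_events))) {
      ev <- vessel_events[i, ]
      boost_db <- boost_db +
        ev$level_db * exp(-(t - ev$time)^2 / (2 * ev$width^2))
    }
    x <- x * 10^(boost_db / 20)
  }
  waveform(x, sample_rate, start_time)
}

# save/restore the global RNG state so generators are pure in `seed`
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Synthesize one species call
#'
#' Calls are analytic chirps/tones with a raised-cosine onset and offset
#' (10% of duration each) to limit spectral splatter:
#'
#' * `right` — upsweep chirp within 71–224 Hz, 0.3–1.5 s;
#' * `sei` — downsweep 82 to 34 Hz, about 1.4 s;
#' * `fin` — short downswept note within 17–25 Hz;
#' * `blue` — constant tone (part A) followed by a descending tone
#'   (part B) within 15–19 Hz;
#' * `humpback` — a sequence of tonal/FM units between 150 and 600 Hz
#'   separated by short gaps.
#'
#' Per-call duration and sweep endpoints are drawn within the profile's
#' stated ranges; `jitter = 0` gives the deterministic canonical call
#' (useful as a matched-filter kernel or correlation template).
#'
#' @param species One of `"right"`, `"humpback"`, `"fin"`, `"sei"`, `"blue"`.
#' @param sample_rate Hz; must exceed twice the signal band top.
#' @param seed Integer seed for the per-call randomisation.
#' @param amplitude RMS pressure scale (uPa); 0 yields silence.
#' @param jitter Fraction (0–1) controlling how far endpoints/durations may
#'   deviate from the canonical call.
#' @return A [waveform()] with attributes `species`, `low_freq`,
#'   `high_freq` (the emitted band).
#' @export
synthesize_call <- function(species, sample_rate, seed = 1, amplitude = 1,
                            jitter = 1) {
  prof <- species_profile(species)
  if (sample_rate < 2 * prof$band_high && species != "humpback")
    abort("signal band exceeds Nyquist at this sample rate")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  j <- function(lo, hi, mid = (lo + hi) / 2) mid + (runif(1, lo, hi) - mid) * jitter
  out <- switch(species,
    right = {
      dur <- j(0.6, 1.3)
      f0 <- j(90, 110); f1 <- f0 + j(70, 100)
      list(x = chirp(f0, min(f1, 220), dur, sample_rate), lo = f0, hi = min(f1, 220))
    },
    sei = {
      dur <- j(1.25, 1.55, 1.4)
      f0 <- j(76, 82); f1 <- j(34, 40)
      list(x = chirp(f0, f1, dur, sample_rate), lo = f1, hi = f0)
    },
    fin = {
      # near-full-band sweep: the note's time-bandwidth product is what
      # gives the matched filter its sweep-direction selectivity
      dur <- j(0.9, 1.1, 1.0)
      f0 <- j(24.2, 25, 25); f1 <- j(17, 17.8, 17)
      list(x = chirp(f0, f1, dur, sample_rate), lo = f1, hi = f0)
    },
    blue = {
      a_dur <- j(7, 9, 8); b_dur <- j(9, 11, 10); gap <- j(0.8, 1.2, 1)
      fa <- j(17.8, 18.4, 18.1)
      a <- chirp(fa, fa, a_dur, sample_rate)
      b <- chirp(j(17.5, 18, 17.8), j(15.2, 15.8, 15.5), b_dur, sample_rate)
      list(x = c(a, numeric(round(gap * sample_rate)), b), lo = 15, hi = 18.6)
    },
    humpback = {
      n_units <- max(2, round(j(3, 6)))
      units <- map(seq_len(n_units), function(i) {
        dur <- runif(1, 0.4, 1.2)
        f0 <- runif(1, 150, 500)
        f1 <- f0 * runif(1, 0.8, 1.3)
        u <- chirp(f0, min(f1, 600), dur, sample_rate)
        c(u, numeric(round(runif(1, 0.2, 0.6) * sample_rate)))
      })
      list(x = unlist(units), lo = 150, hi = 600)
    },
    abort(paste0("unknown species: ", species))
  )
  x <- out$x
  rms <- sqrt(mean(x^2))
  if (rms > 0) x <- x * amplitude / rms else x <- x * 0
  w <- waveform(x, sample_rate)
  attr(w, "species") <- species
  attr(w, "low_freq") <- out$lo
  attr(w, "high_freq") <- out$hi
  w
}

# linear chirp with 10% raised-cosine taper at each end
chirp <- function(f0, f1, dur, fs) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  phase <- 2 * pi * (f0 * t + (f1 - f0) / (2 * dur) * t^2)
  sin(phase) * raised_cosine_taper(length(t), 0.1)
}

#' Inject calls into a noise waveform at controlled band SNR
#'
#' Each call is scaled so that its RMS pressure in the species analysis
#' band, relative to the background's band RMS over the same time window,
#' equals the requested SNR in dB. Returns the mixed waveform together
#' with a ground-truth annotation table carrying exact time-frequency
#' boxes.
#'
#' @param noise Background [waveform()].
#' @param calls Tibble with columns `time` (s, call start), `wave` (list of
#'   call [waveform()]s at the same rate), `species`, and optionally
#'   `snr_db` per call.
#' @param snr_db Default band SNR (dB) for calls without their own.
#' @param site_id,date Carried into the annotation table.
#' @return List with elements `wave` (the mix) and `annotations` (tibble
#'   with `begin_time`, `end_time`, `low_freq`, `high_freq`, `species`,
#'   `snr_db`, `site_id`, `date`).
#' @export
inject_calls <- function(noise, calls, snr_db = 10, site_id = "site",
                         date = as.Date("2018-01-01")) {
  stopifnot(inherits(noise, "waveform"))
  fs <- noise$sample_rate
  x <- noise$samples
  if (nrow(calls) == 0) {
    return(list(wave = noise, annotations = tibble(
      begin_time = numeric(), end_time = numeric(), low_freq = numeric(),
      high_freq = numeric(), species = character(), snr_db = numeric(),
      site_id = character(), date = as.Date(character()))))
  }
  if (!"snr_db" %in% names(calls)) calls$snr_db <- snr_db
  ann <- vector("list", nrow(calls))
  for (i in seq_len(nrow(calls))) {
    cw <- calls$wave[[i]]
    if (!isTRUE(all.equal(cw$sample_rate, fs))) abort("call/noise rate mismatch")
    prof <- species_profile(calls$species[i])
    i0 <- round(calls$time[i] * fs) + 1
    i1 <- i0 + length(cw$samples) - 1
    if (i1 > length(x)) abort("call extends beyond the noise duration")
    lo <- prof$analysis_low; hi <- min(prof$analysis_high, fs / 2)
    noise_rms <- band_rms(waveform(noise$samples[i0:i1], fs), lo, hi)
    call_rms <- band_rms(cw, lo, hi)
    g <- noise_rms * 10^(calls$snr_db[i] / 20) / call_rms
    x[i0:i1] <- x[i0:i1] + g * cw$samples
    ann[[i]] <- tibble(
      begin_time = calls$time[i],
      end_time = calls$time[i] + duration(cw),
      low_freq = attr(cw, "low_freq") %||% prof$band_low,
      high_freq = attr(cw, "high_freq") %||% prof$band_high,
      species = calls$species[i], snr_db = calls$snr_db[i],
      site_id = site_id, date = date
    )
  }
  list(wave = waveform(x, fs, noise$start_time), annotations = list_rbind(ann))
}
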