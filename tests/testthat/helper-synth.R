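# shared fixtures built in code

make_tone <- function(freq, dur, fs, rms = 1) {
  waveform(rms * sqrt(2) * sin(2 * pi * freq * seq(0, dur - 1 / fs, by = 1 / fs)), fs)
}

# a short noise + injected-calls scene for one species
make_scene <- function(species, fs, dur, n_calls, snr_db, seed,
                       noise_level = 75, jitter = 1) {
  noise <- generate_ambient_noise(dur, fs, shelf_spectrum(noise_level),
                                  seed = seed)
  calls <- tibble::tibble(
    time = seq(5, dur - 10, length.out = n_calls),
    wave = lapply(seq_len(n_calls), function(i)
      synthesize_call(species, fs, seed = seed * 100 + i, jitter = jitter)),
    species = species
  )
  inject_calls(noise, calls, snr_db = snr_db)
}

# hourly humpback calling grid over `days` days: each calling day has one
# contiguous song bout of 6-14 h at a random start hour
make_bout_grid <- function(days, p_calling = 0.7, seed = 1) {
  set.seed(seed)
  lapply(seq_len(days), function(d) {
    if (runif(1) > p_calling) return(rep(FALSE, 24))
    len <- sample(6:14, 1)
    start <- sample(0:(24 - len), 1)
    hrs <- rep(FALSE, 24)
    hrs[(start + 1):(start + len)] <- TRUE
    hrs
  })
}
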