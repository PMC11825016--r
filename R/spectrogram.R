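#' Compute a power spectrogram
#'
#' Short-time Fourier transform with the stated window, FFT size and
#' fractional overlap. Power is scaled so that the sum of one-sided bin
#' powers in a frame equals the (window-corrected) mean-square pressure of
#' that frame; summing bins over a band therefore yields band power in
#' uPa^2, the quantity [leq()] integrates.
#'
#' @param w A [waveform()].
#' @param fft_size Frame length in samples (also the FFT length).
#' @param overlap Fractional overlap in `[0, 1)`.
#' @param window `"hann"` or `"rectangular"`.
#' @return A `spectrogram` object: list with `power` (freq x time matrix),
#'   `freq`, `time` (frame start, s), `freq_step`, `time_step`,
#'   `sample_rate`, `window`, `fft_size`, `overlap`.
#' @export
#' @examples
#' w <- waveform(sin(2 * pi * 100 * seq(0, 2, by = 1 / 1000)), 1000)
#' s <- compute_spectrogram(w, 256)
#' s$freq[which.max(rowMeans(s$power))]
compute_spectrogram <- function(w, fft_size, overlap = 0.5, window = "hann") {
  stopifnot(inherits(w, "waveform"))
  n <- length(w$samples)
  if (n == 0) abort("empty waveform")
  if (fft_size > n) abort("fft_size exceeds waveform length")
  if (overlap < 0 || overlap >= 1) abort("overlap must be in [0, 1)")
  win <- switch(window,
    hann = 0.5 * (1 - cos(2 * pi * seq_len(fft_size) / fft_size)),
    rectangular = rep(1, fft_size),
    abort("window must be 'hann' or 'rectangular'")
  )
  hop <- max(1L, round(fft_size * (1 - overlap)))
  starts <- seq(1L, n - fft_size + 1L, by = hop)
  nbin <- fft_size %/% 2 + 1L
  # frame matrix: columns are windowed frames
  idx <- outer(0:(fft_size - 1L), starts, "+")
  frames <- matrix(w$samples[idx], nrow = fft_size) * win
  X <- mvfft(frames)
  p <- abs(X[1:nbin, , drop = FALSE])^2 / (fft_size * sum(win^2))
  # one-sided: double interior bins (not DC, not Nyquist when present)
  dbl <- 2:(nbin - if (fft_size %% 2 == 0) 1L else 0L)
  p[dbl, ] <- 2 * p[dbl, ]
  structure(list(
    power = p,
    freq = (0:(nbin - 1L)) * w$sample_rate / fft_size,
    time = (starts - 1L) / w$sample_rate,
    freq_step = w$sample_rate / fft_size,
    time_step = hop / w$sample_rate,
    sample_rate = w$sample_rate,
    window = window, fft_size = fft_size, overlap = overlap
  ), class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d freq bins x %d frames (df = %.3g Hz, dt = %.3g s, %s window)\n",
              nrow(x$power), ncol(x$power), x$freq_step, x$time_step, x$window))
  invisible(x)
}

#' Tidy a spectrogram into a long tibble
#' @param x A `spectrogram`.
#' @param ... Unused.
#' @return Tibble with `time`, `freq`, `power`, `db` columns.
#' @export
tidy.spectrogram <- function(x, ...) {
  tibble(
    time = rep(x$time, each = nrow(x$power)),
    freq = rep(x$freq, times = ncol(x$power)),
    power = as.vector(x$power)
  ) |>
    mutate(db = 10 * log10(pmax(.data$power, 1e-30)))
}

#' Plot a spectrogram
#' @param object A `spectrogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spectrogram <- function(object, ...) {
  tidy(object) |>
    ggplot(aes(.data$time, .data$freq, fill = .data$db)) +
    geom_tile() +
    scale_fill_viridis_c(name = "dB") +
    labs(x = "Time (s)", y = "Frequency (Hz)") +
    theme_minimal()
}

# rows of the power matrix whose bin centres lie in [low, high)
band_bins <- function(s, low, high) which(s$freq >= low & s$freq < high)
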