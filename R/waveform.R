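#' Calibrated pressure waveform
#'
#' Container for a single-channel acoustic recording. Samples are stored as
#' calibrated pressure in micro-Pascals (uPa) so that level metrics
#' (e.g. [leq()]) are directly referenced to 1 uPa. Raw ADC counts from an
#' archival recorder can be converted with [calibrate_counts()].
#'
#' @param samples Numeric vector of pressure samples (uPa).
#' @param sample_rate Sampling rate in Hz.
#' @param start_time Optional `POSIXct` (UTC) timestamp of the first sample.
#'
#' @return An object of class `waveform`: a list with elements `samples`,
#'   `sample_rate`, `start_time`.
#' @export
#' @examples
#' w <- waveform(sin(2 * pi * 100 * seq(0, 1, by = 1 / 2000)), 2000)
#' duration(w)
waveform <- function(samples, sample_rate, start_time = NULL) {
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0)
    abort("`sample_rate` must be a single positive number.")
  if (!is.numeric(samples)) abort("`samples` must be numeric.")
  structure(
    list(samples = as.numeric(samples), sample_rate = sample_rate,
         start_time = start_time),
    class = "waveform"
  )
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %g Hz (%.2f s)%s\n",
              length(x$samples), x$sample_rate, duration(x),
              if (!is.null(x$start_time)) paste0(" starting ", format(x$start_time)) else ""))
  invisible(x)
}

#' Duration of a waveform in seconds
#' @param w A [waveform()].
#' @return Length in seconds.
#' @export
duration <- function(w) length(w$samples) / w$sample_rate

#' Convert raw ADC counts to calibrated pressure
#'
#' Maps integer counts to volts through the converter full-scale voltage and
#' bit depth, then volts to uPa through the hydrophone sensitivity
#' (dB re 1 V/uPa). A flat frequency response is assumed.
#'
#' @param counts Integer ADC samples.
#' @param sample_rate Hz.
#' @param bit_depth ADC resolution in bits.
#' @param sensitivity_db Hydrophone sensitivity, dB re 1 V/uPa (negative).
#' @param full_scale_volts Peak voltage corresponding to full-scale counts.
#' @param start_time Optional `POSIXct` start.
#' @return A [waveform()] in uPa.
#' @export
calibrate_counts <- function(counts, sample_rate, bit_depth,
                             sensitivity_db, full_scale_volts = 1,
                             start_time = NULL) {
  volts <- counts / (2^(bit_depth - 1)) * full_scale_volts
  upa <- volts / 10^(sensitivity_db / 20)
  waveform(upa, sample_rate, start_time)
}

# two-sided FFT bin frequencies for an n-point transform at rate fs
fft_freqs <- function(n, fs) {
  k <- 0:(n - 1)
  f <- k * fs / n
  f[f > fs / 2] <- f[f > fs / 2] - fs
  abs(f)
}

# Zero-phase brick-wall band-pass via the FFT: keeps bins whose (absolute)
# frequency lies in [low, high]. Used for SNR measurement and detector
# pre-filtering where an exactly known passband matters.
band_filter_samples <- function(x, fs, low, high) {
  n <- length(x)
  if (n == 0) return(x)
  f <- fft_freqs(n, fs)
  X <- fft(x)
  X[f < low | f > high] <- 0i
  Re(fft(X, inverse = TRUE)) / n
}

#' Band-pass filter a waveform
#'
#' Zero-phase FFT brick-wall filter; content outside `[low, high]` Hz is
#' removed exactly.
#'
#' @param w A [waveform()].
#' @param low,high Band edges in Hz; `high` must not exceed Nyquist.
#' @return A filtered [waveform()].
#' @export
band_filter <- function(w, low, high) {
  stopifnot(inherits(w, "waveform"))
  if (low < 0 || high <= low) abort("need 0 <= low < high")
  if (high > w$sample_rate / 2) abort("band exceeds Nyquist frequency")
  waveform(band_filter_samples(w$samples, w$sample_rate, low, high),
           w$sample_rate, w$start_time)
}

#' Band-limited RMS pressure
#'
#' @param w A [waveform()].
#' @param low,high Band edges in Hz.
#' @return RMS pressure (uPa) of the band-filtered waveform.
#' @export
band_rms <- function(w, low, high) {
  y <- band_filter_samples(w$samples, w$sample_rate, low, high)
  sqrt(mean(y^2))
}

# Sinc (FFT-domain) resampling: truncates the spectrum at the new Nyquist,
# so content below it is preserved exactly and content above is removed
# entirely (the anti-alias filter is implicit and ideal).
resample_fft <- function(x, fs, target_rate) {
  n <- length(x)
  m <- round(n * target_rate / fs)
  if (m == n) return(x)
  X <- fft(x)
  Y <- complex(real = numeric(m), imaginary = numeric(m))
  half <- ceiling(m / 2) # positive-frequency bins 0..half-1
  Y[1:half] <- X[1:half]
  if (m %% 2 == 0) Y[half + 1] <- Re(X[half + 1]) # new Nyquist bin kept real
  if (half > 1) {
    kneg <- 1:(half - 1)
    Y[m + 1 - kneg] <- X[n + 1 - kneg]
  }
  Re(fft(Y, inverse = TRUE)) / n
}

#' Decimate a waveform to a lower sample rate
#'
#' Anti-aliased rate reduction by Fourier resampling: spectral content below
#' the new Nyquist frequency is preserved within a fraction of a dB; content
#' above it is removed. Non-integer rate ratios (e.g. 5000 Hz to 400 Hz) are
#' supported.
#'
#' @param w A [waveform()].
#' @param target_rate New rate in Hz; must not exceed the current rate.
#' @return A [waveform()] at `target_rate`.
#' @export
#' @examples
#' w <- waveform(sin(2 * pi * 20 * seq(0, 2, by = 1 / 5000)), 5000)
#' decimate(w, 400)
decimate <- function(w, target_rate) {
  stopifnot(inherits(w, "waveform"))
  if (target_rate > w$sample_rate) abort("cannot upsample: target rate above source rate")
  if (target_rate == w$sample_rate) return(w)
  waveform(resample_fft(w$samples, w$sample_rate, target_rate),
           target_rate, w$start_time)
}

# raised-cosine on/off taper over the first/last `frac` of the signal
raised_cosine_taper <- function(n, frac = 0.1) {
  m <- max(1L, round(n * frac))
  env <- rep(1, n)
  ramp <- 0.5 * (1 - cos(pi * seq_len(m) / m))
  env[1:m] <- ramp
  env[(n - m + 1):n] <- rev(ramp)
  env
}
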