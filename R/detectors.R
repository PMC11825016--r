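#' @name detectors
#' @title Species signal detectors
#' @description
#' Automated operators for the five target signal types. All detectors
#' emit tidy event tables (`begin_time`, `end_time`, `low_freq`,
#' `high_freq`, `score`, `species`, `site_id`) with correlation-type
#' scores in `[-1, 1]`, so thresholds transfer across recordings.
#' Overlapping hits within a merge window are collapsed to one event per
#' call, keeping the maximum score.
NULL

empty_events <- function() {
  tibble(begin_time = numeric(), end_time = numeric(),
         low_freq = numeric(), high_freq = numeric(),
         score = numeric(), species = character(), site_id = character())
}

# collapse events whose time spans fall within `gap` seconds of each other,
# keeping the highest-scoring representative
merge_events <- function(events, gap = 0.5) {
  if (nrow(events) < 2) return(events)
  ev <- arrange(events, .data$begin_time)
  grp <- cumsum(c(1, ev$begin_time[-1] > ev$end_time[-nrow(ev)] + gap))
  ev |>
    mutate(.grp = grp) |>
    group_by(.data$.grp) |>
    dplyr::slice_max(.data$score, n = 1, with_ties = FALSE) |>
    ungroup() |>
    select(-".grp")
}

#' Matched-filter detection on a waveform
#'
#' Normalised sliding cross-correlation of the waveform with a reference
#' call (kernel): at each lag, the Pearson-style score is the inner
#' product of the kernel with the signal segment divided by both norms,
#' hence in `[-1, 1]`. Local maxima above `threshold` are emitted with a
#' minimum inter-event spacing. Intended for the stereotyped low-frequency
#' notes (fin 20-Hz notes at 400 Hz; blue A-B phrases at 200 Hz), on
#' decimated audio.
#'
#' @param w A [waveform()].
#' @param kernel Reference call [waveform()] at the same rate (e.g. the
#'   canonical `synthesize_call(species, rate, jitter = 0)`).
#' @param threshold Score threshold in `[-1, 1]`.
#' @param species,site_id Labels for the output events.
#' @param min_spacing Minimum peak separation, s (default: half the kernel
#'   duration).
#' @param highpass Remove content below this frequency (Hz) before
#'   correlating; suppresses low-frequency ambient energy outside the
#'   signal band.
#' @return A detection-event tibble.
#' @export
detect_matched_filter <- function(w, kernel, threshold = 0.45,
                                  species = attr(kernel, "species") %||% "fin",
                                  site_id = "site",
                                  min_spacing = NULL, highpass = 5) {
  stopifnot(inherits(w, "waveform"), inherits(kernel, "waveform"))
  if (!isTRUE(all.equal(w$sample_rate, kernel$sample_rate)))
    abort("waveform and kernel sample rates differ")
  L <- length(kernel$samples)
  n <- length(w$samples)
  if (L >= n) abort("kernel longer than waveform")
  fs <- w$sample_rate
  x <- if (highpass > 0) band_filter_samples(w$samples, fs, highpass, fs / 2)
       else w$samples
  k <- kernel$samples - mean(kernel$samples)
  # FFT cross-correlation for the numerator
  kpad <- c(k, numeric(n - L))
  num <- Re(fft(fft(x) * Conj(fft(kpad)), inverse = TRUE)) / n
  num <- num[1:(n - L + 1)]
  # running energy for the denominator
  cs <- cumsum(c(0, x^2))
  seg_energy <- cs[(L + 1):(n + 1)] - cs[1:(n - L + 1)]
  # segments with essentially no energy cannot carry a meaningful
  # correlation (numeric noise would otherwise dominate)
  ke <- sum(k^2)
  score <- ifelse(seg_energy > 1e-12 * ke,
                  num / (sqrt(seg_energy) * sqrt(ke)), 0)
  min_spacing <- min_spacing %||% (L / fs / 2)
  peaks <- score_peaks(score, threshold, round(min_spacing * fs))
  if (!length(peaks)) return(empty_events())
  lo <- attr(kernel, "low_freq") %||% 0
  hi <- attr(kernel, "high_freq") %||% (fs / 2)
  merge_events(tibble(
    begin_time = (peaks - 1) / fs,
    end_time = (peaks - 1 + L) / fs,
    low_freq = lo, high_freq = hi,
    score = score[peaks], species = species, site_id = site_id
  ))
}

# indices of cluster-maximum threshold exceedances, clusters separated by
# at least `min_gap` samples
score_peaks <- function(score, threshold, min_gap) {
  above <- which(score > threshold)
  if (!length(above)) return(integer())
  grp <- cumsum(c(1, diff(above) > min_gap))
  unname(vapply(split(above, grp),
                function(ix) ix[which.max(score[ix])], numeric(1)))
}

#' Build a spectrogram template set from example calls
#'
#' Each example call is rendered on the detection spectrogram grid and
#' stored as a dB-scale patch (clamped 40 dB below its peak) together with
#' its band. The resulting set drives [detect_template_xcorr()].
#'
#' @param calls List of call [waveform()]s (e.g. representative downsweep
#'   examples).
#' @param fft_size,overlap,window Spectrogram settings; must match the
#'   spectrogram the templates are applied to.
#' @param threshold Default correlation threshold carried with the set.
#' @return A `template_set` object.
#' @export
make_template_set <- function(calls, fft_size = 256, overlap = 0.5,
                              window = "hann", threshold = 0.45) {
  if (!length(calls)) abort("need at least one template call")
  templates <- map(calls, function(cw) {
    pad <- numeric(fft_size) # breathing room so the call is fully framed
    w <- waveform(c(pad, cw$samples, pad), cw$sample_rate)
    s <- compute_spectrogram(w, fft_size, overlap, window)
    lo <- attr(cw, "low_freq") %||% 0
    hi <- attr(cw, "high_freq") %||% (cw$sample_rate / 2)
    rows <- which(s$freq >= lo - s$freq_step & s$freq <= hi + s$freq_step)
    patch <- 10 * log10(pmax(s$power[rows, , drop = FALSE], 1e-30))
    patch <- pmax(patch, max(patch) - 40)
    list(patch = patch, low = lo, high = hi,
         duration = duration(cw), species = attr(cw, "species") %||% "sei")
  })
  structure(list(templates = templates, fft_size = fft_size,
                 overlap = overlap, window = window, threshold = threshold),
            class = "template_set")
}

#' Spectrogram template cross-correlation detection
#'
#' Slides each template patch along the time axis of the spectrogram (in
#' dB) at its own frequency rows and computes the normalised 2-D
#' correlation (Pearson over patch pixels, in `[-1, 1]`). The per-frame
#' score is the maximum over templates; threshold exceedances are emitted
#' as events carrying the winning template's band, with overlapping hits
#' merged.
#'
#' @param s A [compute_spectrogram()] result (same settings as the
#'   template set).
#' @param template_set A [make_template_set()] object.
#' @param threshold Correlation threshold; default from the set.
#' @param species,site_id Output labels.
#' @return A detection-event tibble.
#' @export
detect_template_xcorr <- function(s, template_set,
                                  threshold = template_set$threshold,
                                  species = "sei", site_id = "site") {
  stopifnot(inherits(s, "spectrogram"), inherits(template_set, "template_set"))
  if (!isTRUE(all.equal(s$fft_size, template_set$fft_size)))
    abort("spectrogram and template set use different FFT sizes")
  S <- 10 * log10(pmax(s$power, 1e-30))
  ntime <- ncol(S)
  per_template <- map(template_set$templates, function(tp) {
    rows <- which(s$freq >= tp$low - s$freq_step & s$freq <= tp$high + s$freq_step)
    rows <- rows[seq_len(min(length(rows), nrow(tp$patch)))]
    P <- tp$patch[seq_along(rows), , drop = FALSE]
    nf <- ncol(P)
    if (nf > ntime) abort("template longer than spectrogram")
    nlag <- ntime - nf + 1
    Sb <- S[rows, , drop = FALSE]
    np <- length(P)
    sumP <- sum(P); ssP <- sum(P^2)
    sdP <- sqrt(ssP - sumP^2 / np)
    col1 <- colSums(Sb); col2 <- colSums(Sb^2)
    # windowed sums over nf consecutive frames
    w1 <- window_sum(col1, nf); w2 <- window_sum(col2, nf)
    # numerator: sum over template frames of row-dot-products at each lag
    A <- crossprod(P, Sb) # nf x ntime
    num <- numeric(nlag)
    for (j in seq_len(nf)) num <- num + A[j, j:(j + nlag - 1)]
    sdS <- sqrt(pmax(w2 - w1^2 / np, 1e-12))
    r <- (num - w1 * sumP / np) / (sdS * sdP)
    list(r = r, lo = tp$low, hi = tp$high, nf = nf, dur = tp$duration)
  })
  nlag_min <- min(map_dbl(per_template, ~ length(.x$r)))
  scores <- do.call(rbind, map(per_template, ~ .x$r[seq_len(nlag_min)]))
  best <- apply(scores, 2, which.max)
  score <- apply(scores, 2, max)
  peaks <- score_peaks(score, threshold,
                       max(1L, round(0.5 / s$time_step)))
  if (!length(peaks)) return(empty_events())
  ev <- map(peaks, function(p) {
    tp <- per_template[[best[p]]]
    tibble(begin_time = s$time[p], end_time = s$time[p] + tp$dur,
           low_freq = tp$lo, high_freq = tp$hi,
           score = score[p], species = species, site_id = site_id)
  }) |> list_rbind()
  merge_events(ev)
}

window_sum <- function(x, k) {
  cs <- cumsum(c(0, x))
  cs[(k + 1):length(cs)] - cs[1:(length(cs) - k)]
}

#' Upsweep contour detection (right whale upcalls)
#'
#' Extracts a ridge contour from the spectrogram: within the search band,
#' each frame contributes its peak frequency when the peak exceeds an
#' adaptive per-bin noise floor (the median dB over time) by
#' `excess_db`. Runs of consecutive voiced frames form candidate contours;
#' a contour is accepted as an upcall when its duration lies in
#' `[min_dur, max_dur]`, its bandwidth is at least `min_bandwidth`, and
#' its frequency rises (positive net sweep and positive time-frequency
#' correlation). The event score is the contour's time-frequency Pearson
#' correlation, so downsweeps score negative and are rejected.
#'
#' @param s A [compute_spectrogram()] result covering the band.
#' @param low,high Search band, Hz (71–224 by default).
#' @param min_dur,max_dur Accepted contour duration, s.
#' @param min_bandwidth Minimum swept bandwidth, Hz.
#' @param excess_db Required dB excess over the adaptive floor.
#' @param species,site_id Output labels.
#' @return A detection-event tibble.
#' @export
detect_upcall <- function(s, low = 71, high = 224, min_dur = 0.3,
                          max_dur = 1.5, min_bandwidth = 30,
                          excess_db = 10, species = "right",
                          site_id = "site") {
  stopifnot(inherits(s, "spectrogram"))
  rows <- band_bins(s, low, high)
  if (!length(rows)) abort("search band outside the spectrogram range")
  Sb <- 10 * log10(pmax(s$power[rows, , drop = FALSE], 1e-30))
  floor_db <- apply(Sb, 1, median)
  ex <- Sb - floor_db
  peak_val <- apply(ex, 2, max)
  peak_row <- apply(ex, 2, which.max)
  voiced <- peak_val > excess_db
  contour_events(voiced, s$freq[rows][peak_row], s, min_dur, max_dur,
                 min_bandwidth, species, site_id, slope = "up")
}

# shared contour grouping/filtering for sweep detectors
contour_events <- function(voiced, freq_track, s, min_dur, max_dur,
                           min_bandwidth, species, site_id,
                           slope = c("up", "down")) {
  slope <- match.arg(slope)
  if (!any(voiced)) return(empty_events())
  idx <- which(voiced)
  grp <- cumsum(c(1, diff(idx) > 1))
  ev <- map(split(idx, grp), function(ix) {
    if (length(ix) < 4) return(NULL)
    f <- freq_track[ix]
    t <- s$time[ix]
    dur <- (max(ix) - min(ix) + 1) * s$time_step
    bw <- max(f) - min(f)
    net <- f[length(f)] - f[1]
    r <- suppressWarnings(cor(t, f))
    if (is.na(r)) return(NULL)
    steps <- sign(diff(f))
    mono <- if (slope == "up") mean(steps >= 0) else mean(steps <= 0)
    ok <- dur >= min_dur && dur <= max_dur && bw >= min_bandwidth &&
      mono >= 0.75 &&
      if (slope == "up") (net > 0 && r > 0.6) else (net < 0 && r < -0.6)
    if (!ok) return(NULL)
    tibble(begin_time = s$time[min(ix)],
           end_time = s$time[max(ix)] + s$time_step,
           low_freq = min(f), high_freq = max(f),
           score = r, species = species, site_id = site_id)
  })
  ev <- list_rbind(purrr::compact(ev))
  if (is.null(ev) || nrow(ev) == 0) return(empty_events())
  merge_events(ev)
}

#' Band-energy unit detection (humpback song/social-call units)
#'
#' Adaptive band-energy detector with a tonality gate: frames whose in-band
#' energy exceeds the adaptive noise floor by `excess_db` and whose
#' spectral concentration (1 minus spectral flatness of the in-band power)
#' exceeds `tonality_min` are clustered into units; units of plausible
#' duration become events. Broadband level steps (e.g. a close vessel
#' passage) raise energy but not tonality and are rejected.
#'
#' @param s A [compute_spectrogram()] result covering the band.
#' @param low,high Search band, Hz.
#' @param excess_db Required dB excess of in-band energy over its median.
#' @param tonality_min Minimum spectral concentration in `[0, 1]`.
#' @param min_dur,max_dur Accepted unit duration, s.
#' @param species,site_id Output labels.
#' @return A detection-event tibble; `score` is the unit's mean spectral
#'   concentration (in `[0, 1]`).
#' @export
detect_humpback_units <- function(s, low = 100, high = 600, excess_db = 6,
                                  tonality_min = 0.6, min_dur = 0.2,
                                  max_dur = 3, species = "humpback",
                                  site_id = "site") {
  stopifnot(inherits(s, "spectrogram"))
  rows <- band_bins(s, low, high)
  if (!length(rows)) abort("search band outside the spectrogram range")
  P <- s$power[rows, , drop = FALSE]
  energy_db <- 10 * log10(pmax(colSums(P), 1e-30))
  floor_db <- median(energy_db)
  # spectral concentration: 1 - geometric/arithmetic mean ratio
  flat <- exp(colMeans(log(pmax(P, 1e-30)))) / pmax(colMeans(P), 1e-30)
  conc <- 1 - flat
  qual <- energy_db > floor_db + excess_db & conc > tonality_min
  if (!any(qual)) return(empty_events())
  idx <- which(qual)
  grp <- cumsum(c(1, diff(idx) > 1))
  ev <- map(split(idx, grp), function(ix) {
    dur <- (max(ix) - min(ix) + 1) * s$time_step
    if (dur < min_dur || dur > max_dur) return(NULL)
    prow <- apply(P[, ix, drop = FALSE], 2, which.max)
    f <- s$freq[rows][prow]
    tibble(begin_time = s$time[min(ix)],
           end_time = s$time[max(ix)] + s$time_step,
           low_freq = min(f), high_freq = max(f),
           score = mean(conc[ix]), species = species, site_id = site_id)
  })
  ev <- list_rbind(purrr::compact(ev))
  if (is.null(ev) || nrow(ev) == 0) return(empty_events())
  merge_events(ev, gap = 0.1)
}

#' Screen upcall detections for concurrent humpback signals
#'
#' Upcall detectors can false-trigger on humpback units with similar
#' shapes, so upcall events whose time span overlaps (within `window`
#' seconds) any humpback event are removed from the right whale presence
#' analysis.
#'
#' @param upcalls,humpback Detection-event tibbles on the same time base.
#' @param window Guard interval, s.
#' @return The surviving upcall events.
#' @export
screen_cooccurrence <- function(upcalls, humpback, window = 0) {
  if (nrow(humpback) == 0 || nrow(upcalls) == 0) return(upcalls)
  keep <- map_lgl(seq_len(nrow(upcalls)), function(i) {
    u <- upcalls[i, ]
    !any(u$begin_time <= humpback$end_time + window &
         u$end_time >= humpback$begin_time - window)
  })
  upcalls[keep, ]
}

#' Deterministic 1-in-k-hour review schedule
#'
#' Hour indices reviewed under a 1-in-`k`-hours subsampling scheme (the
#' manual-review workload reduction): hours `0, k, 2k, ...` of each day.
#' Daily presence is then computed from the scheduled hours only.
#'
#' @param k Review 1 of every `k` hours (>= 1).
#' @return Integer vector of hour indices in `0:23`.
#' @export
#' @examples
#' subsample_review_schedule(4)
subsample_review_schedule <- function(k) {
  if (k < 1) abort("`k` must be >= 1")
  seq(0L, 23L, by = as.integer(k))
}
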