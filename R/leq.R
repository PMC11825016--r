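#' Band-limited equivalent continuous sound level (Leq)
#'
#' Measures the time-averaged band sound pressure level of a calibrated
#' waveform: 1-s Hann frames with zero overlap and 1-Hz resolution, band
#' power summed over bins whose centres lie in `[low, high)`, averaged over
#' each measurement interval (default 10 min), and expressed as
#' `10*log10(mean band power / 1 uPa^2)`. A trailing partial interval is
#' discarded.
#'
#' @param w A calibrated [waveform()] (uPa).
#' @param bands Tibble with `label`, `low`, `high` columns (Hz); defaults to
#'   the species analysis bands of [default_bands()]. Bands are truncated at
#'   the Nyquist frequency; a band lying entirely above Nyquist is an error.
#' @param interval Averaging interval in seconds (multiple of 1 s).
#' @param site_id Site label carried into the output.
#' @return A tibble (noise series) with columns `site_id`, `label`,
#'   `interval_start` (s from waveform start), `interval_s`, `leq`
#'   (dB re 1 uPa).
#' @export
#' @examples
#' fs <- 2000
#' w <- waveform(1000 * sqrt(2) * sin(2 * pi * 100 * seq(0, 60, by = 1 / fs)), fs)
#' leq(w, tibble::tibble(label = "b", low = 70.8, high = 224), interval = 60)
leq <- function(w, bands = default_bands(), interval = 600, site_id = "site") {
  stopifnot(inherits(w, "waveform"))
  if (interval %% 1 != 0 || interval < 1) abort("`interval` must be a whole number of seconds")
  fs <- w$sample_rate
  if (fs %% 1 != 0) abort("sample rate must be an integer for 1-s framing")
  nyq <- fs / 2
  if (any(bands$low >= nyq)) abort("band lies entirely above the Nyquist frequency")
  s <- compute_spectrogram(w, fft_size = as.integer(fs), overlap = 0, window = "hann")
  nsec <- ncol(s$power)
  nint <- nsec %/% interval
  if (nint == 0) abort("waveform shorter than one measurement interval")
  grp <- rep(seq_len(nint), each = interval)
  purrr::pmap(list(bands$label, bands$low, pmin(bands$high, nyq)),
    function(label, low, high) {
      bins <- band_bins(s, low, high)
      sec_power <- colSums(s$power[bins, seq_len(nint * interval), drop = FALSE])
      int_power <- tapply(sec_power, grp, mean)
      tibble(site_id = site_id, label = label,
             interval_start = (seq_len(nint) - 1) * interval,
             interval_s = interval,
             leq = 10 * log10(as.numeric(int_power)))
    }) |>
    list_rbind()
}

#' Percentiles of a noise series
#'
#' Empirical percentiles of band Leq per site and band, describing low
#' (5th), median (50th) and high (95th) noise conditions.
#'
#' @param series A noise-series tibble from [leq()] (columns `site_id`,
#'   `label`, `leq`).
#' @param percentiles Numeric percentiles in (0, 100).
#' @return Tibble with `site_id`, `label`, `percentile`, `level` columns.
#' @export
noise_percentiles <- function(series, percentiles = c(5, 50, 95)) {
  if (nrow(series) == 0) abort("empty noise series")
  series |>
    group_by(.data$site_id, .data$label) |>
    dplyr::reframe(percentile = percentiles,
                   level = as.numeric(quantile(.data$leq, percentiles / 100)))
}

#' Grouped summaries of a noise series
#'
#' Median and quartiles of band Leq grouped by any of season, survey year
#' and site. Dates are derived from `start_time` plus the interval offset;
#' season and survey-year labels follow [season_of()] and
#' [survey_year_of()].
#'
#' @param series Noise series with an added `date` column, or with
#'   `interval_start` and a `start_time` attribute supplied via `origin`.
#' @param by Character vector of grouping keys among
#'   `"season"`, `"survey_year"`, `"site"`.
#' @param origin Optional `Date`/`POSIXct` origin used to derive `date`
#'   from `interval_start` when `series` has no `date` column.
#' @return Tibble of group medians and quartiles (`n`, `q25`, `median`,
#'   `q75`); groups with no data are absent.
#' @export
summarize_noise <- function(series, by = "site", origin = NULL) {
  ok <- c("season", "survey_year", "site")
  if (!all(by %in% ok)) abort("`by` keys must be among season, survey_year, site")
  df <- series
  if (!"date" %in% names(df)) {
    if (is.null(origin)) abort("supply `origin` or a `date` column to group by time")
    df <- mutate(df, date = as.Date(.env$origin) + floor(.data$interval_start / 86400))
  }
  if ("season" %in% by) df <- mutate(df, season = season_of(.data$date))
  if ("survey_year" %in% by)
    df <- mutate(df, survey_year = survey_year_of(.data$date))
  keys <- c(if ("site" %in% by) "site_id", "label",
            intersect(c("season", "survey_year"), by))
  df |>
    group_by(across(dplyr::all_of(keys))) |>
    summarise(n = dplyr::n(),
              q25 = as.numeric(quantile(.data$leq, 0.25)),
              median = median(.data$leq),
              q75 = as.numeric(quantile(.data$leq, 0.75)),
              .groups = "drop")
}

#' Plot a noise series
#' @param series Noise series tibble from [leq()].
#' @return A ggplot of Leq against interval start, faceted by band.
#' @export
plot_noise_series <- function(series) {
  ggplot(series, aes(.data$interval_start, .data$leq, colour = .data$site_id)) +
    geom_line() +
    facet_wrap(~label, scales = "free_y") +
    labs(x = "Interval start (s)", y = expression(L[eq] ~ "(dB re 1" ~ mu * "Pa)"),
         colour = "Site") +
    theme_minimal()
}
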