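#' Default species acoustic profiles
#'
#' One row per target species with the published signal description used
#' throughout the pipeline: the signal band, the 1/3-octave analysis band
#' bracketing it (used for SNR, ambient-noise Leq and detection-range
#' calculations), the RMS source level at 1 m with its spread, the nominal
#' source depth, and the typical call duration range.
#'
#' * right whale — frequency-modulated upcall, 71–224 Hz, 0.3–1.5 s,
#'   SL 172 ± 6.6 dB, source depth 2 m;
#' * humpback whale — song/social-call units, analysis band 17.8–708 Hz,
#'   SL 169 ± 3 dB, source depth 50 m;
#' * fin whale — 20-Hz note, 17–25 Hz, SL 189 ± 4 dB, source depth 20 m;
#' * sei whale — downsweep, 34–82 Hz, about 1.4 s, SL 173.5 ± 3.2 dB,
#'   source depth 20 m;
#' * blue whale — A–B song phrase, 15–19 Hz, SL 189 ± 3 dB, source depth
#'   30 m.
#'
#' @return A tibble with columns `species`, `signal_name`, `band_low`,
#'   `band_high`, `analysis_low`, `analysis_high` (Hz), `source_level`,
#'   `source_level_sd` (dB re 1 uPa at 1 m RMS), `source_depth` (m),
#'   `dur_min`, `dur_max` (s).
#' @export
#' @examples
#' species_profiles()
species_profiles <- function() {
  tibble(
    species       = c("right", "humpback", "fin", "sei", "blue"),
    signal_name   = c("upcall", "song", "20-Hz note", "downsweep", "A-B phrase"),
    band_low      = c(71,   29,   17,   34,   15),
    band_high     = c(224,  2480, 25,   82,   19),
    analysis_low  = c(70.8, 17.8, 17.8, 28.2, 14.1),
    analysis_high = c(224,  708,  28.2, 89.2, 22.4),
    source_level  = c(172,  169,  189,  173.5, 189),
    source_level_sd = c(6.6, 3,   4,    3.2,  3),
    source_depth  = c(2,    50,   20,   20,   30),
    dur_min       = c(0.3,  0.4,  0.9,  1.2,  14),
    dur_max       = c(1.5,  2.0,  1.1,  1.6,  22)
  )
}

#' Look up one species profile
#' @param species One of `"right"`, `"humpback"`, `"fin"`, `"sei"`, `"blue"`.
#' @return A one-row tibble from [species_profiles()].
#' @export
species_profile <- function(species) {
  p <- dplyr::filter(species_profiles(), .data$species == .env$species)
  if (nrow(p) != 1) abort(paste0("unknown species: ", species))
  p
}

#' Default analysis band set
#'
#' The five species 1/3-octave analysis bands plus the full measurement
#' band (8.9–2239.6 Hz, spanning the 1/3-octave centre frequencies of the
#' recorded bandwidth). Bands wider than the Nyquist frequency of a given
#' recording are truncated by [leq()].
#'
#' @return A tibble with columns `label`, `low`, `high` (Hz).
#' @export
default_bands <- function() {
  p <- species_profiles()
  dplyr::bind_rows(
    tibble(label = p$species, low = p$analysis_low, high = p$analysis_high),
    tibble(label = "full", low = 8.9, high = 2239.6)
  )
}

#' Site specification
#'
#' Describes one bottom-moored recorder deployment: position, water depth,
#' recorder profile (a 5 kHz / 12-bit and an 8 kHz / 24-bit profile mirror
#' the two archival recorder types used on continental-shelf surveys), and
#' the date intervals during which the unit recorded.
#'
#' @param site_id Short site label, e.g. `"1M"`, `"8A"`.
#' @param latitude,longitude Degrees.
#' @param depth Water depth in m (> 0).
#' @param sample_rate Hz (5000 or 8000 for the default profiles).
#' @param bit_depth ADC bits.
#' @param sensitivity_db Hydrophone sensitivity, dB re 1 V/uPa.
#' @param recording_intervals Tibble with `start`, `end` (`Date`), the
#'   non-overlapping deployment intervals.
#' @return A one-row tibble (`site_spec`).
#' @export
site_spec <- function(site_id, latitude = 40, longitude = -72, depth = 50,
                      sample_rate = 5000, bit_depth = 12,
                      sensitivity_db = -168,
                      recording_intervals = NULL) {
  if (depth <= 0) abort("`depth` must be positive")
  if (!is.null(recording_intervals)) {
    ri <- dplyr::arrange(recording_intervals, .data$start)
    if (any(ri$end < ri$start)) abort("recording interval with end < start")
    if (nrow(ri) > 1 && any(ri$start[-1] <= ri$end[-nrow(ri)]))
      abort("recording intervals overlap")
  }
  tibble(site_id = site_id, latitude = latitude, longitude = longitude,
         depth = depth, sample_rate = sample_rate, bit_depth = bit_depth,
         sensitivity_db = sensitivity_db,
         recording_intervals = list(recording_intervals))
}
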