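#' Hybrid spherical/intermediate transmission loss
#'
#' One-way transmission loss with spherical spreading (`20 log10 R`) out to
#' the transition depth `H` and intermediate spreading (`17 log10`) beyond:
#' `TL = 20 log10(H) + 17 log10(R / H)` for `R > H`. Continuous at
#' `R = H`.
#'
#' @param R Range from source to receiver, m (> 0); vectorised.
#' @param H Transition depth, m (> 0). By convention the approximate water
#'   depth; a source-depth reading is selectable in
#'   [bearing_averaged_range()].
#' @return TL in dB.
#' @export
#' @examples
#' transmission_loss(c(50, 5000), H = 50)
transmission_loss <- function(R, H) {
  if (any(R <= 0) || any(H <= 0)) abort("R and H must be positive")
  ifelse(R <= H, 20 * log10(R), 20 * log10(H) + 17 * log10(R / H))
}

#' Received level from the passive sonar equation
#'
#' `RL = SL - TL`.
#'
#' @param SL Source level, dB re 1 uPa at 1 m.
#' @param TL Transmission loss, dB.
#' @return Received level, dB re 1 uPa.
#' @export
received_level <- function(SL, TL) {
  if (any(!is.finite(SL)) || any(!is.finite(TL))) abort("non-finite input")
  SL - TL
}

#' Solve the zero-SNR detection range along one bearing
#'
#' Marches outward in `range_step` increments, evaluating the received
#' level against the ambient noise level in the species band, and returns
#' the largest range at which `RL >= NL` (detection range at SNR = 0).
#' `H` may be a constant depth or a bathymetry profile (a function of
#' range, m) along the bearing. With constant depth the march matches the
#' closed form `R* = H * 10^((SL - NL - 20 log10 H) / 17)` within one step.
#'
#' @param SL Source level, dB re 1 uPa at 1 m.
#' @param NL Band ambient noise level, dB re 1 uPa.
#' @param H Constant depth (m) or `function(range_m) -> depth_m`.
#' @param range_step March increment, m.
#' @param max_range Censoring range, m.
#' @return List with `range` (m) and `censored` (logical: `RL >= NL` still
#'   at `max_range`).
#' @export
#' @examples
#' solve_detection_range(SL = 172, NL = 106, H = 50)
solve_detection_range <- function(SL, NL, H, range_step = 10,
                                  max_range = 5e5) {
  if (NL >= SL) abort("noise level at or above source level: range below 1 m")
  depth_at <- if (is.function(H)) H else function(r) H
  r <- seq(range_step, max_range, by = range_step)
  d <- vapply(r, depth_at, numeric(1))
  if (any(d <= 0)) abort("non-positive depth in profile")
  rl <- received_level(SL, transmission_loss(r, d))
  ok <- rl >= NL
  if (all(ok)) return(list(range = max_range, censored = TRUE))
  if (!any(ok)) return(list(range = range_step, censored = FALSE))
  list(range = r[max(which(ok))], censored = FALSE)
}

# closed-form detection range for constant depth (used as oracle and for
# fast vectorised evaluation)
detection_range_closed_form <- function(SL, NL, H) {
  r_sph <- 10^((SL - NL) / 20)
  ifelse(r_sph <= H, r_sph, H * 10^((SL - NL - 20 * log10(H)) / 17))
}

#' Bearing-averaged detection range for one site and species
#'
#' Solves the SNR = 0 range along eight fixed bearings (0, 45, ...,
#' 315 degrees) for each requested noise percentile, then averages across
#' bearings. Censored bearings (range exceeding `max_range`) are excluded
#' from the mean and flagged; if all eight are censored the mean is `NA`
#' (blank, by the reporting convention for ranges beyond 500 km).
#'
#' @param site A [site_spec()] row (provides the default constant depth).
#' @param profile A [species_profile()] row (source level; source depth
#'   used when `h_mode = "source_depth"`).
#' @param noise Tibble from [noise_percentiles()] filtered to the species
#'   band: columns `percentile`, `level`.
#' @param bathymetry Optional named list mapping bearing (as character
#'   degrees) to `function(range_m) -> depth_m`; default constant site
#'   depth on all bearings.
#' @param h_mode `"water_depth"` (transition at the approximate water
#'   depth; default) or `"source_depth"` (transition at the species source
#'   depth).
#' @param range_step,max_range Solver controls, m.
#' @return Tibble with one row per percentile: `site_id`, `species`,
#'   `percentile`, `mean_range_m`, `se_range_m`, `n_bearings`,
#'   `n_censored`, plus a `ranges` list-column of per-bearing results.
#' @export
bearing_averaged_range <- function(site, profile, noise,
                                   bathymetry = NULL,
                                   h_mode = c("water_depth", "source_depth"),
                                   range_step = 10, max_range = 5e5) {
  h_mode <- match.arg(h_mode)
  bearings <- seq(0, 315, by = 45)
  base_h <- if (h_mode == "water_depth") site$depth else profile$source_depth
  purrr::map(seq_len(nrow(noise)), function(i) {
    per <- noise$percentile[i]; nl <- noise$level[i]
    res <- map(bearings, function(b) {
      H <- if (!is.null(bathymetry) && !is.null(bathymetry[[as.character(b)]]))
        bathymetry[[as.character(b)]] else base_h
      solve_detection_range(profile$source_level, nl, H,
                            range_step = range_step, max_range = max_range)
    })
    rng <- map_dbl(res, "range")
    cen <- map_lgl(res, "censored")
    kept <- rng[!cen]
    tibble(site_id = site$site_id, species = profile$species,
           percentile = per,
           mean_range_m = if (length(kept)) mean(kept) else NA_real_,
           se_range_m = if (length(kept) > 1) sd(kept) / sqrt(length(kept)) else
             if (length(kept) == 1) 0 else NA_real_,
           n_bearings = length(bearings), n_censored = sum(cen),
           ranges = list(tibble(bearing = bearings, range_m = rng,
                                censored = cen)))
  }) |>
    list_rbind()
}

#' Circular detection area from a detection range
#'
#' @param range_m Detection range in metres (`NA` propagates).
#' @return Area in km^2 (`pi * R^2`).
#' @export
#' @examples
#' detection_area(7000)
detection_area <- function(range_m) {
  if (any(range_m < 0, na.rm = TRUE)) abort("range must be >= 0")
  pi * (range_m / 1000)^2
}
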