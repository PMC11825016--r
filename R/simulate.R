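#' Parameters for the daily-presence simulator
#'
#' The simulator draws a Bernoulli daily detection series from a latent
#' logit process with the same structure the seasonal presence model
#' assumes: a cyclic seasonal term over calendar month, survey-year
#' offsets, a per-site random intercept, and AR1-correlated daily latent
#' noise.
#'
#' @param baseline Grand intercept (logit units).
#' @param seasonal_amplitude Amplitude of the cyclic seasonal term (logit).
#' @param seasonal_phase Month (1–12) of seasonal peak.
#' @param year_effects Numeric vector of per-survey-year offsets (logit);
#'   recycled over years.
#' @param site_sd Standard deviation of site random intercepts (logit).
#' @param ar1_rho Lag-1 correlation of the latent daily noise, |rho| < 1.
#' @param latent_sd Marginal SD of the latent daily noise (logit); the
#'   day-to-day calling variability beyond the structured terms.
#' @return A list of class `presence_sim_params`.
#' @export
presence_sim_params <- function(baseline = -1, seasonal_amplitude = 1.5,
                                seasonal_phase = 3,
                                year_effects = c(0, 0, -1),
                                site_sd = 0.5, ar1_rho = 0.3,
                                latent_sd = 1) {
  if (abs(ar1_rho) >= 1) abort("|ar1_rho| must be < 1")
  if (site_sd < 0 || latent_sd < 0) abort("sds must be non-negative")
  structure(list(baseline = baseline, seasonal_amplitude = seasonal_amplitude,
                 seasonal_phase = seasonal_phase, year_effects = year_effects,
                 site_sd = site_sd, ar1_rho = ar1_rho, latent_sd = latent_sd),
            class = "presence_sim_params")
}

# cyclic seasonal term evaluated at integer months
seasonal_term <- function(month, amplitude, phase) {
  amplitude * cos(2 * pi * (month - phase) / 12)
}

#' Simulate a daily presence dataset
#'
#' Draws one Bernoulli observation per site and day from the latent model
#' described in [presence_sim_params()]. Days run from `start_date`;
#' survey-year membership follows [survey_year_of()]'s 16 October
#' boundaries.
#'
#' @param params A [presence_sim_params()].
#' @param sites Number of sites (or a character vector of site ids).
#' @param days Number of consecutive days.
#' @param seed Integer seed; fully determines the draw.
#' @param start_date First day (`Date`).
#' @param species Species label carried in the table.
#' @return A daily presence tibble with columns `site_id`, `date`,
#'   `species`, `state` (`"detected"`/`"not_detected"`), plus hidden
#'   attributes `latent` (matrix of latent logits, day x site) and
#'   `truth` (the generating parameters).
#' @export
#' @examples
#' d <- simulate_presence_dataset(presence_sim_params(), sites = 3,
#'                                days = 100, seed = 1)
#' table(d$state)
simulate_presence_dataset <- function(params, sites, days, seed = 1,
                                      start_date = as.Date("2017-10-16"),
                                      species = "right") {
  stopifnot(inherits(params, "presence_sim_params"))
  if (days < 1) abort("`days` must be >= 1")
  site_ids <- if (is.character(sites)) sites else
    sprintf("S%02d", seq_len(sites))
  nsite <- length(site_ids)
  dates <- start_date + 0:(days - 1)
  month <- lubridate::month(dates)
  yr_idx <- survey_year_index(dates, origin = start_date)
  yr_eff <- params$year_effects[((yr_idx - 1) %% length(params$year_effects)) + 1]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  site_int <- rnorm(nsite, 0, params$site_sd)
  rho <- params$ar1_rho
  latent <- matrix(0, nrow = days, ncol = nsite)
  for (s in seq_len(nsite)) {
    e <- numeric(days)
    e[1] <- rnorm(1, 0, params$latent_sd)
    if (days > 1) {
      innov <- rnorm(days - 1, 0, params$latent_sd * sqrt(1 - rho^2))
      for (t in 2:days) e[t] <- rho * e[t - 1] + innov[t - 1]
    }
    latent[, s] <- params$baseline +
      seasonal_term(month, params$seasonal_amplitude, params$seasonal_phase) +
      yr_eff + site_int[s] + e
  }
  y <- matrix(rbinom(days * nsite, 1, plogis(as.vector(latent))),
              nrow = days)
  out <- tibble(
    site_id = rep(site_ids, each = days),
    date = rep(dates, times = nsite),
    species = species,
    state = ifelse(as.vector(y) == 1, "detected", "not_detected")
  )
  attr(out, "latent") <- latent
  attr(out, "truth") <- params
  out
}

# survey-year index (1-based) for dates, with years starting on the
# month/day of `origin` (16 October by default usage)
survey_year_index <- function(dates, origin) {
  yrs <- lubridate::year(dates)
  anchor <- lubridate::make_date(yrs, lubridate::month(origin),
                                 lubridate::mday(origin))
  start_year <- ifelse(dates >= anchor, yrs, yrs - 1)
  start_year - min(start_year) + 1L
}

#' Apply data-loss gaps to a recording schedule
#'
#' Removes gap periods (e.g. trawled, lost or malfunctioning units) from a
#' set of recording intervals. Days inside a gap carry no recording and
#' must appear as `missing` (never as non-detection) in downstream presence
#' tables.
#'
#' @param schedule Tibble with `start`, `end` (`Date`) recording intervals.
#' @param gaps Tibble with `start`, `end` (`Date`) gap intervals, or `NULL`
#'   for no loss.
#' @return A tibble of `start`, `end` intervals with the gaps removed.
#' @export
#' @examples
#' sched <- tibble::tibble(start = as.Date("2018-01-01"),
#'                         end = as.Date("2018-12-31"))
#' simulate_deployment_gaps(sched,
#'   tibble::tibble(start = as.Date("2018-06-01"), end = as.Date("2018-06-30")))
simulate_deployment_gaps <- function(schedule, gaps = NULL) {
  if (is.null(gaps) || nrow(gaps) == 0) return(schedule)
  out <- schedule
  for (i in seq_len(nrow(gaps))) {
    g0 <- gaps$start[i]; g1 <- gaps$end[i]
    pieces <- vector("list", nrow(out))
    for (k in seq_len(nrow(out))) {
      s <- out$start[k]; e <- out$end[k]
      if (g1 < s || g0 > e) { # disjoint
        pieces[[k]] <- tibble(start = s, end = e)
      } else {
        keep <- list()
        if (g0 > s) keep <- c(keep, list(tibble(start = s, end = g0 - 1)))
        if (g1 < e) keep <- c(keep, list(tibble(start = g1 + 1, end = e)))
        pieces[[k]] <- if (length(keep)) list_rbind(keep) else
          tibble(start = as.Date(character()), end = as.Date(character()))
      }
    }
    out <- list_rbind(pieces)
  }
  arrange(out, .data$start)
}

# expand recording intervals to the set of recorded dates
schedule_days <- function(schedule) {
  if (is.null(schedule) || nrow(schedule) == 0) return(as.Date(character()))
  unique(as.Date(unlist(
    map2(schedule$start, schedule$end, function(s, e) seq(s, e, by = "day"))
  ), origin = "1970-01-01"))
}
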