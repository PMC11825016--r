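#' Season label of a date
#'
#' Month-based seasons: Fall = September–November, Winter =
#' December–February, Spring = March–May, Summer = June–August. Winter
#' spans the year boundary, so December of year y is labelled together
#' with January–February of y+1 (e.g. `"Winter 2017-2018"`).
#'
#' @param date A `Date` vector.
#' @return Character season labels including the year(s).
#' @export
#' @examples
#' season_of(as.Date(c("2018-03-15", "2017-12-25", "2018-11-30")))
season_of <- function(date) {
  m <- lubridate::month(date)
  y <- lubridate::year(date)
  dplyr::case_when(
    m %in% 9:11 ~ paste("Fall", y),
    m == 12 ~ paste0("Winter ", y, "-", y + 1),
    m %in% 1:2 ~ paste0("Winter ", y - 1, "-", y),
    m %in% 3:5 ~ paste("Spring", y),
    TRUE ~ paste("Summer", y)
  )
}

#' Survey-year label of a date
#'
#' Survey years run from 16 October to 15 October: Year 1 starts on
#' `origin` (16 October 2017 by default), Year 2 one calendar year later,
#' and so on, with inclusive boundaries.
#'
#' @param date A `Date` vector.
#' @param origin Start of Year 1.
#' @param n_years Number of valid survey years; dates outside the span
#'   raise an error.
#' @return Character labels `"Year 1"`, `"Year 2"`, ...
#' @export
#' @examples
#' survey_year_of(as.Date(c("2017-10-16", "2018-10-15", "2018-10-16")))
survey_year_of <- function(date, origin = as.Date("2017-10-16"), n_years = 3) {
  if (any(date < origin)) abort("date before the survey span")
  idx <- survey_year_index(c(origin, date), origin)[-1]
  if (any(idx > n_years)) abort("date after the survey span")
  paste("Year", idx)
}

#' Build a daily presence table from detection events
#'
#' One row per site, calendar day and species: `detected` if at least one
#' validated event fell on that day, `not_detected` if the site recorded
#' that day without events, `missing` if the site was not recording (data
#' gaps are never counted as non-detection).
#'
#' @param events Tibble of detection events with `site_id`, `date`,
#'   `species` columns (empty tibble allowed).
#' @param schedule Tibble of recording intervals with `site_id`, `start`,
#'   `end` (`Date`).
#' @param species Species labels for the output grid; defaults to those in
#'   `events` (or `"right"` when empty).
#' @param span Optional `Date` length-2 vector bounding the grid; defaults
#'   to the schedule's span.
#' @return A daily presence tibble (`site_id`, `date`, `species`, `state`).
#' @export
daily_presence <- function(events, schedule, species = NULL, span = NULL) {
  if (is.null(species)) {
    species <- if (nrow(events)) sort(unique(events$species)) else "right"
  }
  span <- span %||% c(min(schedule$start), max(schedule$end))
  dates <- seq(span[1], span[2], by = "day")
  sites <- sort(unique(schedule$site_id))
  recorded <- schedule |>
    group_by(.data$site_id) |>
    dplyr::group_map(function(df, key) {
      tibble(site_id = key$site_id, date = schedule_days(df), recorded = TRUE)
    }) |>
    list_rbind()
  grid <- tidyr::expand_grid(site_id = sites, date = dates, species = species)
  ev <- if (nrow(events)) {
    distinct(events, .data$site_id, .data$date, .data$species) |>
      mutate(hit = TRUE)
  } else {
    tibble(site_id = character(), date = as.Date(character()),
           species = character(), hit = logical())
  }
  out <- grid |>
    left_join(recorded, by = c("site_id", "date")) |>
    left_join(ev, by = c("site_id", "date", "species")) |>
    mutate(
      recorded = !is.na(.data$recorded),
      hit = !is.na(.data$hit),
      state = dplyr::case_when(
        !.data$recorded & .data$hit ~ NA_character_,
        !.data$recorded ~ "missing",
        .data$hit ~ "detected",
        TRUE ~ "not_detected"
      )
    )
  if (any(is.na(out$state)))
    abort("detection event on a day with no recording: schedule inconsistency")
  select(out, "site_id", "date", "species", "state")
}

round_half_up <- function(x) floor(x + 0.5)

#' Summarise a daily presence table
#'
#' Counts recorded days and detected days per group and species, and the
#' percentage of recorded days with a detection (integer, half-up
#' rounding). Two modes: pooled across sites (`per_site = FALSE`, the
#' default) counts calendar days on which at least one site recorded
#' (detected if any site detected); per-site mode counts site recording
#' days. Missing days never enter denominators.
#'
#' @param table A daily presence tibble from [daily_presence()] or
#'   [simulate_presence_dataset()].
#' @param by Grouping key: one of `"season"`, `"month"`, `"survey_year"`,
#'   `"none"` (plus site when `per_site = TRUE`).
#' @param per_site Summarise per site rather than pooling across sites.
#' @return Tibble with `species`, the grouping column(s), `total_days`,
#'   `days_detected`, `pct_detected`.
#' @export
summarize_presence <- function(table, by = "season", per_site = FALSE) {
  if (!by %in% c("season", "month", "survey_year", "none"))
    abort("`by` must be one of season, month, survey_year, none")
  df <- filter(table, .data$state != "missing")
  df <- switch(by,
    season = mutate(df, group = season_of(.data$date)),
    month = mutate(df, group = lubridate::month(.data$date)),
    survey_year = mutate(df, group = survey_year_of(.data$date)),
    none = mutate(df, group = "all")
  )
  keys <- c("species", "group", if (per_site) "site_id")
  if (!per_site) {
    # pool: one observation per calendar day; detected if any site detected
    df <- df |>
      group_by(across(dplyr::all_of(c("species", "group", "date")))) |>
      summarise(detected = any(.data$state == "detected"), .groups = "drop")
  } else {
    df <- mutate(df, detected = .data$state == "detected")
  }
  out <- df |>
    group_by(across(dplyr::all_of(keys))) |>
    summarise(total_days = dplyr::n(),
              days_detected = sum(.data$detected),
              .groups = "drop") |>
    mutate(pct_detected = round_half_up(100 * .data$days_detected / .data$total_days))
  if (by != "none") names(out)[names(out) == "group"] <- by
  out
}

#' Pool a per-season detection summary into survey totals
#'
#' Takes a per-season summary table (one row per season with the total
#' calendar days recorded and the days-detected count for each species)
#' and reproduces the survey-wide totals: summed recorded days, summed
#' detected days per species, and the integer percentage of recorded days
#' with a detection. A published summary of this layout ships as
#' `system.file("extdata", "season_detection_summary.tsv",
#' package = "pambaleen")`.
#'
#' @param seasons Tibble with columns `season`, `total_days`, and one
#'   `<species>_detected` column per species.
#' @return Tibble with `species`, `days_detected`, `total_days`,
#'   `pct_detected` (half-up integer percent).
#' @export
#' @examples
#' path <- system.file("extdata", "season_detection_summary.tsv",
#'                     package = "pambaleen")
#' pool_season_summary(readr::read_tsv(path, show_col_types = FALSE))
pool_season_summary <- function(seasons) {
  total <- sum(seasons$total_days)
  det_cols <- grep("_detected$", names(seasons), value = TRUE)
  tibble(
    species = sub("_detected$", "", det_cols),
    days_detected = unname(vapply(det_cols,
                                  function(cl) sum(seasons[[cl]]), numeric(1))),
    total_days = total
  ) |>
    mutate(pct_detected = round_half_up(100 * .data$days_detected / .data$total_days))
}

#' Plot daily presence
#' @param table A daily presence tibble.
#' @return A ggplot tile chart of state by site and date.
#' @export
plot_presence <- function(table) {
  ggplot(table, aes(.data$date, .data$site_id, fill = .data$state)) +
    geom_tile() +
    facet_wrap(~species, ncol = 1) +
    labs(x = NULL, y = "Site", fill = "State") +
    theme_minimal()
}
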