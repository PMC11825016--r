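#' Build a ground-truth review schedule
#'
#' Arithmetic sequence of calendar days to be manually searched for target
#' signals: every `every_n_days`-th day from `start` through `end`,
#' optionally restricted to a set of months (e.g. reviewing every 10th day
#' only during November–May, when a species is commonly detected).
#'
#' @param start,end `Date` bounds (inclusive).
#' @param every_n_days Step in days (>= 1).
#' @param restrict_months Optional integer vector of months (1–12) to keep.
#' @return A `Date` vector of review days.
#' @export
#' @examples
#' build_groundtruth_schedule(as.Date("2017-10-24"), as.Date("2020-10-15"), 20)
build_groundtruth_schedule <- function(start, end, every_n_days,
                                       restrict_months = NULL) {
  if (start > end) abort("start after end")
  if (every_n_days < 1) abort("`every_n_days` must be >= 1")
  days <- seq(start, end, by = every_n_days)
  if (!is.null(restrict_months))
    days <- days[lubridate::month(days) %in% restrict_months]
  days
}

#' Match automated detections to ground-truth annotations
#'
#' An annotation is matched when at least one detection overlaps it in
#' both time and frequency (closed intervals: boundary touching counts).
#' A single detection may match several annotations.
#'
#' @param detections Tibble of detection events with `begin_time`,
#'   `end_time`, `low_freq`, `high_freq`.
#' @param annotations Ground-truth tibble with the same four columns.
#' @return `annotations` with an added logical `matched` column.
#' @export
match_detections <- function(detections, annotations) {
  matched <- map_lgl(seq_len(nrow(annotations)), function(i) {
    a <- annotations[i, ]
    any(detections$begin_time <= a$end_time &
        detections$end_time >= a$begin_time &
        detections$low_freq <= a$high_freq &
        detections$high_freq >= a$low_freq)
  })
  mutate(annotations, matched = matched)
}

#' Daily-scale true positive rate
#'
#' Evaluated days with ground-truth signals are true-positive (TP) days
#' when at least one automated detection matched a ground-truthed signal,
#' and false-negative (FN) days otherwise. `TPR = TP / (TP + FN)`; days
#' without ground-truth signals do not enter the rate.
#'
#' @param day_results Tibble with one row per evaluated day:
#'   `day` (`Date`), `has_groundtruth` (logical), `has_matched_detection`
#'   (logical).
#' @param species Label carried into the result.
#' @return A `validation_result`: list with `species`, `tp_days`,
#'   `fn_days`, `tpr` (reported to 2 decimals), `evaluated_days`.
#'   If no day carries ground truth, `tpr` is `NA` with a warning.
#' @export
#' @examples
#' days <- tibble::tibble(day = as.Date("2018-01-01") + 0:28,
#'                        has_groundtruth = TRUE,
#'                        has_matched_detection = rep(c(TRUE, FALSE), c(20, 9)))
#' daily_tpr(days)$tpr
daily_tpr <- function(day_results, species = "unspecified") {
  gt <- filter(day_results, .data$has_groundtruth)
  tp <- sum(gt$has_matched_detection)
  fn <- sum(!gt$has_matched_detection)
  tpr <- if (tp + fn > 0) round(tp / (tp + fn), 2) else {
    warn("no ground-truth days: TPR undefined")
    NA_real_
  }
  structure(list(species = species, tp_days = tp, fn_days = fn, tpr = tpr,
                 evaluated_days = day_results$day),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("<validation_result> %s: TP days %d, FN days %d, TPR %s (%d days evaluated)\n",
              x$species, x$tp_days, x$fn_days,
              ifelse(is.na(x$tpr), "NA", format(x$tpr)),
              length(x$evaluated_days)))
  invisible(x)
}

#' @export
tidy.validation_result <- function(x, ...) {
  tibble(species = x$species, tp_days = x$tp_days, fn_days = x$fn_days,
         tpr = x$tpr, n_evaluated = length(x$evaluated_days))
}
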