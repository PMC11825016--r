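sel_cols <- c(`Begin Time (s)` = "begin_time", `End Time (s)` = "end_time",
              `Low Freq (Hz)` = "low_freq", `High Freq (Hz)` = "high_freq",
              Species = "species", Date = "date", Site = "site_id")

#' Write events or annotations as a tab-separated selection table
#'
#' The dialect is a plain TSV with the header
#' `Begin Time (s)`, `End Time (s)`, `Low Freq (Hz)`, `High Freq (Hz)`,
#' `Species`, `Date`, `Site` (extra columns such as `score` or `snr_db`
#' are appended as-is).
#'
#' @param events Tibble with `begin_time`, `end_time`, `low_freq`,
#'   `high_freq`, `species`, and optionally `date`, `site_id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection_table <- function(events, path) {
  df <- events
  if (!"date" %in% names(df)) df$date <- NA
  if (!"site_id" %in% names(df)) df$site_id <- NA
  main <- stats::setNames(df[unname(sel_cols)], names(sel_cols))
  extra <- df[setdiff(names(df), unname(sel_cols))]
  readr::write_tsv(dplyr::bind_cols(main, extra), path)
  invisible(path)
}

#' Read a tab-separated selection table
#'
#' Parses the dialect written by [write_selection_table()]. Rows with
#' non-numeric times/frequencies or negative durations are rejected with
#' their line numbers; missing required columns are an error. A
#' header-only file yields an empty table.
#'
#' @param path File path.
#' @return Tibble with `begin_time`, `end_time`, `low_freq`, `high_freq`,
#'   `species`, `date`, `site_id` plus any extra columns.
#' @export
read_selection_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  miss <- setdiff(names(sel_cols), names(raw))
  if (length(miss))
    abort(paste0("missing required column(s): ", paste(miss, collapse = ", ")))
  num_cols <- names(sel_cols)[1:4]
  out <- raw
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[cl]]))
    bad <- which(is.na(v) & !is.na(raw[[cl]]))
    if (length(bad))
      abort(paste0("non-numeric value in '", cl, "' at line ",
                   paste(bad + 1, collapse = ", ")))
    out[[cl]] <- v
  }
  names(out)[match(names(sel_cols), names(out))] <- unname(sel_cols)
  bad_dur <- which(out$end_time < out$begin_time)
  if (length(bad_dur))
    abort(paste0("negative duration at line ", paste(bad_dur + 1, collapse = ", ")))
  out$date <- as.Date(out$date)
  for (cl in c("score", "snr_db"))
    if (cl %in% names(out)) out[[cl]] <- as.numeric(out[[cl]])
  as_tibble(out)
}
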