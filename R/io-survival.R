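#' Read a survival table
#'
#' Expects columns `sample_id`, `time` (days), `event` (1 = death,
#' 0 = censored) and optionally `expression`. Rows with missing time — the
#' samples without clinical time-of-death data — are dropped and counted;
#' the count is attached as attribute `dropped_count` and reported.
#'
#' @param path Path to a TSV/CSV file.
#' @return A tibble with attribute `dropped_count`.
#' @export
read_survival_table <- function(path) {
  tbl <- readr::read_delim(path, delim = sniff_delim(path), show_col_types = FALSE, progress = FALSE)
  validate_survival_table(tbl)
}

validate_survival_table <- function(tbl) {
  tbl <- as_tibble(tbl)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(tbl))) {
    abort(paste0("survival table needs columns ", paste(need, collapse = ", ")),
          class = "channelscreen_format_error")
  }
  dropped <- sum(is.na(tbl$time))
  if (dropped > 0) {
    message(dropped, " sample(s) without survival time excluded")
    tbl <- filter(tbl, !is.na(.data$time))
  }
  if (any(tbl$time < 0)) {
    abort(paste0("negative survival time for sample '",
                 tbl$sample_id[which(tbl$time < 0)[1]], "'"),
          class = "channelscreen_validation_error")
  }
  if (!all(tbl$event %in% c(0, 1))) {
    abort("event indicator must be 0 (censored) or 1 (death)",
          class = "channelscreen_validation_error")
  }
  attr(tbl, "dropped_count") <- dropped
  tbl
}
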