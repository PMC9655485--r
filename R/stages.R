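# Lactation-stage schedule: weekly collections in the first month
# (days 7, 14, 21, 28), then monthly points through month 12, then
# "beyond one year". 17 labels in total.

#' Lactation sampling schedule
#'
#' Defines the 17-stage collection plan: `<7 days`, `7 days`, `14 days`,
#' `21 days`, `28 days`, `2 months` ... `12 months`, `>1 year of feeding`.
#' A day is assigned to the most recent completed scheduled point, with the
#' monthly points placed at calendar-approximated months of
#' `month_length_days` (default 30.44) days and everything beyond
#' `year_cutoff_days` (default 366) mapping to the final label.
#'
#' @param month_length_days length of a calendar month in days.
#' @param year_cutoff_days days after which a sample counts as
#'   `>1 year of feeding`.
#' @return An object of class `stage_schedule` with elements `labels`,
#'   `starts` (first day of each stage), `rep_days` (a representative
#'   collection day per stage, used by the synthetic generator),
#'   `month_length_days` and `year_cutoff_days`.
#' @export
#' @examples
#' stage_label_for(c(1, 7, 30, 400))
stage_schedule <- function(month_length_days = 30.44, year_cutoff_days = 366) {
  stopifnot(month_length_days > 28, year_cutoff_days > 12 * month_length_days - 1)
  labels <- c("<7 days", "7 days", "14 days", "21 days", "28 days",
              paste(2:12, "months"), ">1 year of feeding")
  starts <- c(1, 7, 14, 21, 28, round(month_length_days * (2:12)))
  rep_days <- c(4, 7, 14, 21, 28, round(month_length_days * (2:12)),
                year_cutoff_days + 34)
  structure(list(labels = labels, starts = starts, rep_days = rep_days,
                 month_length_days = month_length_days,
                 year_cutoff_days = year_cutoff_days),
            class = "stage_schedule")
}

#' @export
print.stage_schedule <- function(x, ...) {
  cat("Lactation stage schedule:", length(x$labels), "stages\n")
  print(data.frame(label = x$labels, first_day = x$starts))
  invisible(x)
}

#' @rdname stage_schedule
#' @export
stage_labels <- function(schedule = stage_schedule()) schedule$labels

#' Map days postpartum to a stage label
#'
#' @param days integer vector of days postpartum (>= 1).
#' @param schedule a [stage_schedule()].
#' @return Character vector of stage labels.
#' @export
stage_label_for <- function(days, schedule = stage_schedule()) {
  if (length(days) == 0) return(character(0))
  if (any(!is.finite(days)) || any(days < 1)) {
    stop("days postpartum must be >= 1", call. = FALSE)
  }
  idx <- findInterval(days, schedule$starts)
  idx[days > schedule$year_cutoff_days] <- length(schedule$labels)
  schedule$labels[idx]
}
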