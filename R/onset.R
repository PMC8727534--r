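# Time-to-onset: days from the target drug's start date to adverse event
# onset, with explicit exclusion accounting for missing/partial dates and
# event-before-start records.

#' Compute time to onset for a cohort
#'
#' Onset is the whole-day interval from the earliest primary-suspect start
#' date of the target drug to the event onset date. Both dates must carry
#' day precision; partial dates are excluded, never imputed. A same-day
#' start and event counts as onset 0; a strictly earlier event is the
#' "incorrect input" exclusion.
#'
#' Exclusion reasons, in order of precedence per case: \code{missing_date}
#' (event or start date absent), \code{partial_date} (present but not
#' day-precise), \code{event_before_start}, \code{none} (included).
#'
#' @param reports a deduplicated \code{faers_reports} object restricted to
#'   the drug's cohort (or any report set; reports without a matching
#'   PS-role drug entry are excluded as \code{missing_date}).
#' @param config the drug's \code{cohort_config}.
#' @return object of class \code{onset_records}: data.frame with columns
#'   \code{primaryid}, \code{onset_days} (NA unless included),
#'   \code{included}, \code{exclusion_reason}.
#' @export
compute_onset <- function(reports, config) {
  demo <- reports$demo
  d <- reports$drug
  syn <- normalize_drug_name(config$synonyms)
  is_target <- (normalize_drug_name(d$drugname) %in% syn |
                  (d$prod_ai != "" & normalize_drug_name(d$prod_ai) %in% syn)) &
    d$role_cod == "PS"

  td <- d[is_target, , drop = FALSE]
  has_start_any <- demo$primaryid %in% td$primaryid[td$start_precision != "missing"]
  day_ok <- td$start_precision == "day"
  start_dates <- partial_as_date(data.frame(
    year = td$start_year, month = td$start_month, day = td$start_day,
    precision = td$start_precision))
  # earliest day-precision PS start per report
  first_start <- rep(as.Date(NA), nrow(demo))
  if (any(day_ok)) {
    agg <- tapply(as.numeric(start_dates[day_ok]), td$primaryid[day_ok], min)
    first_start <- as.Date(as.numeric(agg[demo$primaryid]),
                           origin = "1970-01-01")
  }

  ev_date <- partial_as_date(data.frame(
    year = demo$event_year, month = demo$event_month, day = demo$event_day,
    precision = demo$event_precision))
  ev_precision <- demo$event_precision

  reason <- rep("none", nrow(demo))
  reason[!is.na(ev_date) & !is.na(first_start) & ev_date < first_start] <-
    "event_before_start"
  reason[(is.na(ev_date) & ev_precision != "missing") |
           (is.na(first_start) & has_start_any)] <- "partial_date"
  reason[ev_precision == "missing" |
           !(demo$primaryid %in% td$primaryid)] <- "missing_date"
  reason[!has_start_any & demo$primaryid %in% td$primaryid &
           reason != "missing_date"] <- "missing_date"

  included <- reason == "none"
  onset <- rep(NA_integer_, nrow(demo))
  onset[included] <- as.integer(ev_date[included] - first_start[included])
  structure(data.frame(primaryid = demo$primaryid, onset_days = onset,
                       included = included, exclusion_reason = reason,
                       stringsAsFactors = FALSE),
            class = c("onset_records", "data.frame"))
}

#' Summarize onset times
#'
#' Median, IQR (linear-interpolation quartiles) and mean over included
#' records only.
#'
#' @param records an \code{onset_records} data.frame.
#' @return list with \code{n_included}, \code{median_days}, \code{iqr} =
#'   c(q1, q3), \code{mean_days}, \code{exclusions} (counts per reason);
#'   NA summary with a \code{reason} when nothing is included.
#' @export
onset_summary <- function(records) {
  excl <- table(factor(records$exclusion_reason,
                       levels = c("missing_date", "partial_date",
                                  "event_before_start", "none")))
  x <- records$onset_days[records$included]
  if (length(x) == 0) {
    return(list(n_included = 0L, median_days = NA_real_,
                iqr = c(NA_real_, NA_real_), mean_days = NA_real_,
                exclusions = excl, reason = "no included onset records"))
  }
  q <- quartiles(x)
  list(n_included = length(x), median_days = q[2], iqr = c(q[1], q[3]),
       mean_days = mean(x), exclusions = excl, reason = NULL)
}

#' Compare onset times between two groups (Mann-Whitney)
#'
#' Two-sided Wilcoxon rank-sum test: exact when both groups are small and
#' tie-free, otherwise the normal approximation with tie correction.
#'
#' @param records_1,records_2 \code{onset_records} data.frames (or numeric
#'   vectors of onset days).
#' @return list with \code{u} (rank-sum statistic W for group 1),
#'   \code{p_value}, \code{n1}, \code{n2}.
#' @export
compare_onset <- function(records_1, records_2) {
  x <- if (is.data.frame(records_1)) {
    records_1$onset_days[records_1$included]
  } else records_1
  y <- if (is.data.frame(records_2)) {
    records_2$onset_days[records_2$included]
  } else records_2
  if (length(x) == 0 || length(y) == 0) {
    stop("both groups need at least one included onset record", call. = FALSE)
  }
  ht <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                            correct = FALSE))
  list(u = unname(ht$statistic), p_value = unname(ht$p.value),
       n1 = length(x), n2 = length(y))
}

#' Histogram of onset times in surveillance-report bins
#' @param records an \code{onset_records} data.frame.
#' @param breaks upper edges of the day bins (default 30/60/90/120 and
#'   beyond).
#' @param main plot title.
#' @return invisibly, the per-bin counts.
#' @export
plot_onset <- function(records, breaks = c(30, 60, 90, 120), main = "Time to onset") {
  x <- records$onset_days[records$included]
  edges <- c(-0.5, breaks + 0.5, Inf)
  labels <- c(paste0(c(0, utils::head(breaks, -1) + 1), "-", breaks),
              paste0(">", breaks[length(breaks)]))
  cnt <- table(cut(x, edges, labels = labels))
  graphics::barplot(cnt, main = main, xlab = "days", ylab = "cases")
  invisible(cnt)
}

#' Write per-case onset records and a summary to CSV
#' @param records an \code{onset_records} data.frame.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_onset_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
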