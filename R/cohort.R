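# Cohort container and CSV interchange.

#' Construct a cohort
#'
#' A cohort bundles one subject per row: the daily time-use composition,
#' covariates, follow-up and vital status, together with study-level
#' metadata (device placement and whether sleep was measured).
#'
#' @param data Data frame with columns `id`, the part columns `mvpa`,
#'   `lipa`, `sb` (and `sleep` for 24-h studies), `followup` (years),
#'   `event` (0/1), plus any covariate columns.
#' @param study Study label.
#' @param device Accelerometer placement, `"wrist"` or `"hip"`.
#' @param total Minutes/day the compositions are closed to (1440 for a
#'   full day; the waking-day total otherwise).  Defaults to the median
#'   row total.
#' @return An object of class `cohort`.
#' @export
cohort <- function(data, study = "study", device = c("wrist", "hip"),
                   total = NULL) {
  device <- match.arg(device)
  data <- as.data.frame(data)
  measures_sleep <- "sleep" %in% names(data)
  parts <- if (measures_sleep) .parts4 else .parts3
  need <- c("id", parts, "followup", "event")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("cohort data lacks column(s): ", paste(miss, collapse = ", "))
  if (any(!data$event %in% c(0, 1)))
    stop("`event` must be 0/1")
  if (any(!is.finite(data$followup)) || any(data$followup <= 0))
    stop("`followup` must be positive and finite for every subject")
  if (is.null(total)) total <- stats::median(rowSums(data[parts]))
  covariates <- setdiff(names(data), need)
  structure(
    list(data = data, study = study, device = device,
         measures_sleep = measures_sleep, total = total,
         parts = parts, covariates = covariates),
    class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort '%s': n=%d, events=%d, %s device, %s, total %g min>\n",
    x$study, nrow(x$data), sum(x$data$event), x$device,
    if (x$measures_sleep) "24-h day" else "waking day", x$total))
  if (length(x$covariates))
    cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

#' Extract the composition matrix of a cohort
#' @param x A `cohort`.
#' @return Numeric matrix, one composition per row.
#' @export
compositions <- function(x) {
  stopifnot(inherits(x, "cohort"))
  as.matrix(x$data[x$parts])
}

# CSV schema: id, sleep_min (optional), sb_min, lipa_min, mvpa_min,
# followup_years, event, then covariates.
.csv_map <- c(sleep = "sleep_min", mvpa = "mvpa_min", lipa = "lipa_min",
              sb = "sb_min", followup = "followup_years", event = "event",
              id = "id")

#' Read a cohort from CSV
#'
#' Expects columns `id`, `sb_min`, `lipa_min`, `mvpa_min`,
#' `followup_years`, `event` and optionally `sleep_min`; any further
#' columns are taken as covariates.  Absence of `sleep_min` flags a
#' waking-day study.  Rows with negative minutes or missing follow-up are
#' rejected, naming the offending rows.
#'
#' @param path CSV file path.
#' @inheritParams cohort
#' @return A [cohort()].
#' @export
read_cohort <- function(path, study = basename(path),
                        device = c("wrist", "hip"), total = NULL) {
  device <- match.arg(device)
  df <- utils::read.csv(path, check.names = TRUE)
  need <- c("id", "sb_min", "lipa_min", "mvpa_min", "followup_years",
            "event")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("malformed cohort header in ", path, ": missing ",
         paste(miss, collapse = ", "),
         " (expected id, [sleep_min], sb_min, lipa_min, mvpa_min, ",
         "followup_years, event, covariates...)")
  has_sleep <- "sleep_min" %in% names(df)
  mins <- c(if (has_sleep) "sleep_min", "mvpa_min", "lipa_min", "sb_min")
  bad_neg <- which(apply(df[mins] < 0, 1, any))
  bad_fu <- which(!is.finite(df$followup_years) | df$followup_years <= 0)
  if (length(bad_neg))
    stop("negative minutes in row(s): ",
         paste(utils::head(bad_neg, 10), collapse = ", "))
  if (length(bad_fu))
    stop("missing or non-positive follow-up in row(s): ",
         paste(utils::head(bad_fu, 10), collapse = ", "))
  out <- df
  for (p in names(.csv_map)) {
    src <- .csv_map[[p]]
    if (src %in% names(df)) names(out)[names(out) == src] <- p
  }
  cohort(out, study = study, device = device, total = total)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]; a write/read round trip preserves the
#' cohort.
#'
#' @param x A `cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  df <- x$data
  for (p in names(.csv_map)) {
    if (p %in% names(df)) names(df)[names(df) == p] <- .csv_map[[p]]
  }
  first <- c("id", if (x$measures_sleep) "sleep_min", "sb_min",
             "lipa_min", "mvpa_min", "followup_years", "event")
  df <- df[c(first, setdiff(names(df), first))]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
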