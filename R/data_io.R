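#' Daily pollutant concentration series
#'
#' Container for one pollutant's daily concentration record: strictly
#' increasing calendar dates at daily spacing, one concentration per day
#' (ug/m3; mg/m3 for CO) and a per-day missingness flag. All downstream
#' stages (imputation, decomposition, forecasting, evaluation) consume
#' this class.
#'
#' @param dates `Date` vector, strictly increasing, daily spacing.
#' @param values numeric vector of concentrations, same length as `dates`;
#'   `NA` marks missing days.
#' @param pollutant one of `"PM2.5"`, `"PM10"`, `"NO2"`, `"SO2"`, `"CO"`,
#'   `"O3"`.
#' @return An object of class `pollutant_series`.
#' @examples
#' s <- pollutant_series(as.Date("2018-01-01") + 0:4, c(10, NA, 30, 25, 20))
#' s
#' @export
pollutant_series <- function(dates, values, pollutant = "PM2.5") {
  pollutant <- check_pollutant(pollutant)
  dates <- as.Date(dates)
  values <- as.numeric(values)
  if (length(dates) != length(values))
    stop("`dates` and `values` must have the same length", call. = FALSE)
  if (length(dates) == 0)
    stop("empty series", call. = FALSE)
  if (length(dates) > 1) {
    dd <- as.integer(diff(dates))
    if (any(dd != 1L))
      stop("`dates` must be strictly increasing with daily spacing",
           call. = FALSE)
  }
  if (any(values < 0, na.rm = TRUE))
    stop("concentrations must be non-negative", call. = FALSE)
  structure(
    list(dates = dates, values = values, pollutant = pollutant,
         missing_mask = is.na(values)),
    class = "pollutant_series")
}

#' @export
print.pollutant_series <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf("<pollutant_series> %s (%s), %d days: %s .. %s\n",
              x$pollutant, pollutant_unit(x$pollutant), n,
              format(x$dates[1]), format(x$dates[n])))
  cat(sprintf("  missing: %d  mean: %s\n", sum(x$missing_mask),
              format(mean(x$values, na.rm = TRUE), digits = 4)))
  invisible(x)
}

#' @export
length.pollutant_series <- function(x) length(x$values)

#' @export
as.data.frame.pollutant_series <- function(x, ...) {
  data.frame(date = x$dates, value = x$values)
}

#' Read a pollutant series from CSV
#'
#' Expects the standard layout `date,PM2.5,PM10,NO2,SO2,CO,O3` (one row per
#' day, empty cell = missing) but any subset of pollutant columns is
#' accepted; `column_map` renames non-standard headers. Rows are sorted
#' chronologically and unparseable numeric cells become missing.
#'
#' @param path CSV file path.
#' @param pollutant which pollutant column to extract.
#' @param column_map optional named character vector mapping standard names
#'   to the file's column names, e.g. `c("PM2.5" = "pm25")`.
#' @param date_column name of the date column (default `"date"`).
#' @return A [pollutant_series].
#' @export
read_series <- function(path, pollutant = "PM2.5", column_map = NULL,
                        date_column = "date") {
  pollutant <- check_pollutant(pollutant)
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0)
    stop("empty file: ", path, call. = FALSE)
  col <- pollutant
  if (!is.null(column_map) && pollutant %in% names(column_map))
    col <- column_map[[pollutant]]
  if (!col %in% names(df))
    stop(sprintf("column '%s' not present in %s", col, path), call. = FALSE)
  if (!date_column %in% names(df))
    stop(sprintf("date column '%s' not present in %s", date_column, path),
         call. = FALSE)
  dates <- as.Date(df[[date_column]])
  if (anyNA(dates))
    stop("unparseable dates in ", path, call. = FALSE)
  ord <- order(dates)
  vals <- suppressWarnings(as.numeric(df[[col]][ord]))
  pollutant_series(dates[ord], vals, pollutant)
}

#' Write a pollutant series to CSV
#'
#' Writes `date,<pollutant>` with empty cells for missing days; the numeric
#' content round-trips bit-exactly through [read_series()].
#'
#' @param series a [pollutant_series].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "pollutant_series"))
  df <- data.frame(date = format(series$dates),
                   value = format_full(series$values))
  names(df)[2] <- series$pollutant
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# Full-precision decimal rendering so CSV round-trips are bit-exact.
format_full <- function(x) {
  out <- vapply(x, function(v)
    if (is.na(v)) NA_character_ else sprintf("%.17g", v), character(1))
  out
}

#' Impute missing days by the nearby mean
#'
#' Each missing value is replaced by the mean of the nearest observed value
#' before it and the nearest observed value after it; at the series edges,
#' where only one side has an observation, that nearest observed value is
#' used directly. Observed values are never changed.
#'
#' @param series a [pollutant_series], possibly with missing days.
#' @return A [pollutant_series] with no missing values.
#' @examples
#' s <- pollutant_series(as.Date("2018-01-01") + 0:2, c(1, NA, 3))
#' impute_missing(s)$values  # 1 2 3
#' @export
impute_missing <- function(series) {
  stopifnot(inherits(series, "pollutant_series"))
  v <- series$values
  obs <- which(!is.na(v))
  if (length(obs) == 0)
    stop("cannot impute an all-missing series", call. = FALSE)
  for (i in which(is.na(v))) {
    prev <- obs[obs < i]
    nxt <- obs[obs > i]
    prev <- if (length(prev)) v[max(prev)] else NULL
    nxt <- if (length(nxt)) v[min(nxt)] else NULL
    v[i] <- mean(c(prev, nxt))
  }
  pollutant_series(series$dates, v, series$pollutant)
}

#' Split a series into training and testing periods
#'
#' The training part contains all days up to and including `boundary`; the
#' testing part the remainder. Concatenating the two reproduces the input.
#'
#' @param series a [pollutant_series].
#' @param boundary a `Date` (or string) inside the series' date range and
#'   strictly before its last day, so that both parts are non-empty.
#' @return A list with elements `train` and `test`, both [pollutant_series].
#' @export
split_series <- function(series, boundary) {
  stopifnot(inherits(series, "pollutant_series"))
  boundary <- as.Date(boundary)
  n <- length(series$values)
  if (boundary < series$dates[1] || boundary >= series$dates[n])
    stop("`boundary` must fall inside the date range and leave a non-empty ",
         "test period", call. = FALSE)
  idx <- series$dates <= boundary
  list(
    train = pollutant_series(series$dates[idx], series$values[idx],
                             series$pollutant),
    test = pollutant_series(series$dates[!idx], series$values[!idx],
                            series$pollutant))
}

#' Build lag-window supervised pairs
#'
#' Row `i` of `inputs` holds the `window` consecutive values immediately
#' preceding `targets[i]`, the next-day value. The per-pollutant window
#' length plays the role of the model's input variable count.
#'
#' @param x a [pollutant_series] or numeric vector (no missing values).
#' @param window positive integer lag length, `< length(x)`.
#' @return An object of class `supervised_windows`: list with `inputs`
#'   (matrix, `length(x) - window` rows), `targets` and `window`.
#' @examples
#' w <- make_windows(1:6, window = 3)
#' w$inputs[1, ]  # 1 2 3
#' w$targets[1]   # 4
#' @export
make_windows <- function(x, window) {
  v <- if (inherits(x, "pollutant_series")) x$values else as.numeric(x)
  if (anyNA(v))
    stop("series contains missing values; impute first", call. = FALSE)
  window <- as.integer(window)
  if (window < 1)
    stop("`window` must be a positive integer", call. = FALSE)
  n <- length(v)
  if (window >= n)
    stop("`window` must be smaller than the series length", call. = FALSE)
  rows <- n - window
  inputs <- matrix(0, nrow = rows, ncol = window)
  for (j in seq_len(window)) inputs[, j] <- v[j:(j + rows - 1)]
  structure(list(inputs = inputs, targets = v[(window + 1):n],
                 window = window),
            class = "supervised_windows")
}
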