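#' Synthetic pollutant generator configuration
#'
#' Defaults emulate the marginal statistics of two years of daily urban
#' pollutant records in a large northern-Chinese city: right-skewed
#' concentrations with strong day-to-day persistence and an annual cycle
#' (winter-peaking particulates, summer-peaking ozone).
#'
#' @param n_days series length, >= 100 (default 760: a two-year record plus
#'   one month).
#' @param targets data frame with columns `pollutant`, `mean`, `sd` giving
#'   the target marginal moments; defaults to the packaged urban values
#'   (e.g. PM2.5 mean 61.2, sd 57.5 ug/m3).
#' @param ar AR(2) coefficients of the latent persistence process
#'   (default `c(0.55, 0.2)`, lag-1 autocorrelation about 0.7).
#' @param seasonal_weight,ar_weight,noise_weight relative contributions of
#'   the annual sinusoid, the AR process and white noise to the latent
#'   signal (squares need not sum to 1; they are renormalized).
#' @param period seasonal period in days (default 365.25).
#' @param noise_family `"lognormal"` (right-skewed, strictly positive;
#'   default) or `"gaussian"` (additive, truncated at 0).
#' @param start_date first calendar day (default `"2016-09-01"`).
#' @param seed integer seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_days = 760, targets = default_targets(),
                         ar = c(0.55, 0.2), seasonal_weight = 0.45,
                         ar_weight = 0.75, noise_weight = 0.48,
                         period = 365.25,
                         noise_family = c("lognormal", "gaussian"),
                         start_date = "2016-09-01", seed = 1L) {
  noise_family <- match.arg(noise_family)
  n_days <- as.integer(n_days)
  if (n_days < 100) stop("`n_days` must be >= 100", call. = FALSE)
  if (any(targets$sd <= 0)) stop("target sd must be > 0", call. = FALSE)
  if (any(targets$mean <= 0)) stop("target mean must be > 0", call. = FALSE)
  structure(list(n_days = n_days, targets = targets, ar = ar,
                 seasonal_weight = seasonal_weight, ar_weight = ar_weight,
                 noise_weight = noise_weight, period = period,
                 noise_family = noise_family,
                 start_date = as.Date(start_date), seed = as.integer(seed)),
            class = "synth_config")
}

#' Default marginal targets for the six pollutants
#'
#' Mean and standard deviation of daily concentrations typical of a large
#' polluted northern city over two years (ug/m3; CO in mg/m3), plus the
#' seasonal phase: particulates, NO2, SO2 and CO peak in winter, O3 in
#' summer.
#'
#' @return Data frame with columns `pollutant`, `mean`, `sd`,
#'   `winter_peak`.
#' @export
default_targets <- function() {
  data.frame(
    pollutant = POLLUTANTS,
    mean = c(61.2, 89.8, 45.5, 7.2, 1.0, 98.4),
    sd = c(57.5, 72.8, 22.2, 7.2, 0.8, 63.3),
    winter_peak = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
}

# Latent standardized signal: weighted AR(2) + annual sinusoid + white
# noise, scaled to unit variance.
latent_signal <- function(cfg, winter_peak) {
  n <- cfg$n_days
  ar <- if (any(cfg$ar != 0))
    as.numeric(stats::arima.sim(list(ar = cfg$ar), n))
  else numeric(n)
  s_ar <- sd(ar)
  if (s_ar > 0) ar <- ar / s_ar
  doy <- as.integer(format(cfg$start_date + seq_len(n) - 1, "%j"))
  # winter peak: maximum near 1 January; summer peak: shifted half a year
  phase <- if (winter_peak) 0 else pi
  season <- sqrt(2) * cos(2 * pi * doy / cfg$period + phase)
  eps <- if (cfg$noise_weight > 0) rnorm(n) else numeric(n)
  w <- cfg$ar_weight * ar + cfg$seasonal_weight * season +
    cfg$noise_weight * eps
  s_w <- sd(w)
  if (s_w > 0) w <- (w - mean(w)) / s_w
  w
}

#' Generate six synthetic pollutant series
#'
#' Each pollutant's series combines an AR(2) persistence process, an
#' annual sinusoid and white noise into a standardized latent signal,
#' then maps it onto the target marginal moments: the lognormal family
#' exponentiates (`exp(mu + sigma * w)` with `mu`, `sigma` matched to the
#' target mean and coefficient of variation, strictly positive and
#' right-skewed); the gaussian family shifts/scales additively and
#' truncates at 0.
#'
#' @param cfg a [synth_config()].
#' @return Named list of six [pollutant_series].
#' @examples
#' series <- generate_pollutants(synth_config(n_days = 200, seed = 3))
#' series$PM2.5
#' @export
generate_pollutants <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  dates <- cfg$start_date + seq_len(cfg$n_days) - 1
  with_seed(cfg$seed, {
    out <- list()
    for (i in seq_len(nrow(cfg$targets))) {
      tg <- cfg$targets[i, ]
      w <- latent_signal(cfg, isTRUE(tg$winter_peak))
      if (cfg$noise_family == "lognormal") {
        cv <- tg$sd / tg$mean
        sigma <- sqrt(log(1 + cv^2))
        mu <- log(tg$mean) - sigma^2 / 2
        v <- exp(mu + sigma * w)
      } else {
        v <- tg$mean + tg$sd * w
      }
      # affine shift/scale onto the target moments, then clip at 0; the
      # right-skewed shapes leave little mass below zero so the clip
      # perturbs the moments only marginally
      s_v <- sd(v)
      if (s_v > 0) v <- (v - mean(v)) / s_v * tg$sd + tg$mean
      v <- pmax(0, v)
      out[[tg$pollutant]] <- pollutant_series(dates, v, tg$pollutant)
    }
    out
  })
}

#' Mask interior points as missing
#'
#' Exactly `floor(fraction * n)` interior days (never the first or last)
#' are set missing, reproducibly by seed; used to exercise imputation.
#'
#' @param series a [pollutant_series].
#' @param fraction fraction in [0, 0.5).
#' @param seed integer seed.
#' @return A [pollutant_series] with a missing mask.
#' @export
inject_missing <- function(series, fraction, seed = 1L) {
  stopifnot(inherits(series, "pollutant_series"))
  if (fraction < 0 || fraction >= 0.5)
    stop("`fraction` must lie in [0, 0.5)", call. = FALSE)
  n <- length(series$values)
  k <- floor(fraction * n)
  if (k == 0) return(series)
  idx <- with_seed(seed, sample(2:(n - 1), k))
  v <- series$values
  v[idx] <- NA
  pollutant_series(series$dates, v, series$pollutant)
}

#' Write six pollutant series as one standard CSV
#'
#' Header `date,PM2.5,PM10,NO2,SO2,CO,O3`, one row per day, empty cell for
#' missing.
#'
#' @param series_list named list of six [pollutant_series] on a common
#'   date grid.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_pollutant_csv <- function(series_list, path) {
  dates <- series_list[[1]]$dates
  df <- data.frame(date = format(dates))
  for (p in POLLUTANTS) {
    if (!p %in% names(series_list))
      stop("missing series for ", p, call. = FALSE)
    if (!identical(series_list[[p]]$dates, dates))
      stop("series date grids differ", call. = FALSE)
    df[[p]] <- format_full(series_list[[p]]$values)
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
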