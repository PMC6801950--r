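# Small builders shared across tests.

daily_series <- function(values, start = "2018-01-01", pollutant = "PM2.5") {
  pollutant_series(as.Date(start) + seq_along(values) - 1, values, pollutant)
}

# The two-year-plus-one-month date grid used by the study design:
# 2016-09-01 .. 2018-09-30 (760 days), train/test boundary 2018-07-31.
study_series <- function(values, pollutant = "PM2.5") {
  stopifnot(length(values) == 760)
  pollutant_series(as.Date("2016-09-01") + 0:759, values, pollutant)
}

two_tone <- function(n = 512) {
  t <- seq(0, 1, length.out = n)
  list(t = t, fast = sin(2 * pi * 8 * t), slow = sin(2 * pi * t),
       x = sin(2 * pi * 8 * t) + sin(2 * pi * t))
}
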