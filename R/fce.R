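#' Concentration limits per air-quality level
#'
#' The default 6-pollutant by 5-level limits table used to grade daily
#' concentrations (ug/m3; CO in mg/m3), levels I (excellent) to V
#' (hazardous). Rows must be strictly increasing across levels.
#'
#' @param limits optional 6 x 5 numeric matrix (rows = pollutants in the
#'   order PM2.5, PM10, NO2, SO2, CO, O3; columns = levels I..V) to
#'   override the defaults.
#' @return A 6 x 5 matrix with dimnames, class `aq_limits`.
#' @export
aq_limits <- function(limits = NULL) {
  if (is.null(limits)) {
    limits <- matrix(c(
       35,  75, 115, 150,  250,   # PM2.5
       50, 150, 250, 350,  420,   # PM10
       40,  80, 180, 280,  565,   # NO2
       50, 150, 475, 800, 1600,   # SO2
        2,   4,  14,  24,   36,   # CO
      100, 160, 215, 265,  800),  # O3
      nrow = 6, byrow = TRUE)
  }
  limits <- as.matrix(limits)
  if (!all(dim(limits) == c(6, 5)))
    stop("limits must be a 6 x 5 matrix", call. = FALSE)
  if (any(apply(limits, 1, diff) <= 0))
    stop("limits must be strictly increasing across levels", call. = FALSE)
  dimnames(limits) <- list(POLLUTANTS, c("I", "II", "III", "IV", "V"))
  structure(limits, class = c("aq_limits", "matrix"))
}

#' Halved-trapezoidal membership degrees of one concentration
#'
#' Piecewise-linear membership of a concentration `x` in each of the five
#' levels, given that pollutant's increasing limits `u1..u5`: level I
#' saturates at 1 below `u1` and falls linearly to 0 at `u2`; interior
#' levels are triangular between their neighbours; level V rises from 0 at
#' `u4` and saturates at 1 above `u5`. For `x` strictly between `u1` and
#' `u5` the two adjacent nonzero memberships sum to 1.
#'
#' @param x non-negative concentration.
#' @param limits_row increasing numeric vector of 5 level limits.
#' @return Length-5 membership vector in [0, 1].
#' @examples
#' membership_row(55, c(35, 75, 115, 150, 250))  # 0.5 0.5 0 0 0
#' @export
membership_row <- function(x, limits_row) {
  u <- as.numeric(limits_row)
  if (length(u) != 5 || any(diff(u) <= 0))
    stop("`limits_row` must be 5 strictly increasing limits", call. = FALSE)
  if (!is.finite(x) || x < 0)
    stop("concentration must be finite and non-negative", call. = FALSE)
  r <- numeric(5)
  # level I: saturating-left branch
  r[1] <- if (x <= u[1]) 1 else if (x <= u[2]) (u[2] - x) / (u[2] - u[1]) else 0
  # interior triangular levels
  for (j in 2:4) {
    r[j] <- if (x >= u[j - 1] && x <= u[j]) (x - u[j - 1]) / (u[j] - u[j - 1])
            else if (x > u[j] && x <= u[j + 1]) (u[j + 1] - x) / (u[j + 1] - u[j])
            else 0
  }
  # level V: saturating-right branch
  r[5] <- if (x <= u[4]) 0 else if (x <= u[5]) (x - u[4]) / (u[5] - u[4]) else 1
  r
}

#' Multi-scale factor weights
#'
#' Weighs each pollutant by its concentration relative to the mean of its
#' five level limits, normalized to sum to one: a pollutant sitting high
#' against its own scale dominates the evaluation.
#'
#' @param x length-6 vector of concentrations (order PM2.5, PM10, NO2,
#'   SO2, CO, O3), not all zero.
#' @param limits an [aq_limits()] table.
#' @return Length-6 weight vector summing to 1.
#' @export
factor_weights <- function(x, limits = aq_limits()) {
  x <- as.numeric(x)
  if (length(x) != 6 || any(!is.finite(x)) || any(x < 0))
    stop("`x` must be 6 finite non-negative concentrations", call. = FALSE)
  if (all(x == 0))
    stop("all-zero concentration vector has no defined weights",
         call. = FALSE)
  ratio <- x / rowMeans(unclass(limits))
  as.numeric(ratio / sum(ratio))
}

#' Zadeh min-max composition
#'
#' Composite membership of each level: `B_j = max_i min(W_i, R[i, j])`.
#'
#' @param W length-m weight vector.
#' @param R m x 5 membership matrix.
#' @return Length-5 composite vector `B`.
#' @export
fce_compose <- function(W, R) {
  R <- as.matrix(R)
  if (length(W) != nrow(R))
    stop("`W` length must match the rows of `R`", call. = FALSE)
  apply(R, 2, function(col) max(pmin(W, col)))
}

#' Assign the air-quality level by maximum membership
#'
#' Ties resolve toward the better (lower) level.
#'
#' @param B length-5 composite membership vector, not all zero.
#' @return Integer level in 1..5 with names `"I".."V"`.
#' @export
classify_level <- function(B) {
  B <- as.numeric(B)
  if (length(B) != 5) stop("`B` must have 5 entries", call. = FALSE)
  if (all(B == 0))
    stop("all-zero composite vector cannot be classified", call. = FALSE)
  lv <- which.max(B)  # which.max takes the first maximum: best level wins ties
  names(lv) <- c("I", "II", "III", "IV", "V")[lv]
  lv
}

HANDBOOK <- data.frame(
  level = c("I", "II", "III", "IV", "V"),
  category = c("excellent", "good", "moderate", "poor", "hazardous"),
  color = c("green", "blue", "yellow", "red", "purple"),
  condition = c(
    "satisfactory air quality",
    "acceptable air quality",
    "mild pollution is unhealthy to sensitive people",
    "moderate pollution is unhealthy to all people",
    "heavy pollution is hazardous to all people"),
  measure = c(
    "Outdoor activities are suitable for all people.",
    "The very few abnormally sensitive people should reduce outdoor activities.",
    paste("Sensitive people including children, the elderly and patients with",
          "respiratory tract, cardiovascular and cerebrovascular diseases",
          "should reduce outdoor activities. Public transportation is",
          "recommended for travel."),
    paste("Sensitive people should avoid outdoor activities which also need",
          "to be reduced by general people. Prefer public transportation and",
          "reduce construction and traffic dust."),
    paste("Besides above measures, road flushing and cleaning, suspension of",
          "large-scale open-air activities, outdoor personnel wear masks are",
          "all needed.")),
  stringsAsFactors = FALSE)

#' Early-warning handbook entry for a level
#'
#' @param level integer 1..5 or roman string `"I".."V"`.
#' @return One-row data frame: `level`, `category`, `color`, `condition`,
#'   `measure`.
#' @export
handbook <- function(level) {
  if (is.character(level)) level <- match(level, HANDBOOK$level)
  level <- as.integer(level)
  if (is.na(level) || level < 1 || level > 5)
    stop("unknown air-quality level", call. = FALSE)
  HANDBOOK[level, ]
}

#' Fuzzy comprehensive evaluation of one day
#'
#' Chains the full evaluation: per-pollutant membership rows form the 6 x 5
#' fuzzy matrix `R`, multi-scale weights `W` are composed with `R` by the
#' Zadeh min-max operator into the composite vector `B`, the level is the
#' maximum-membership entry of `B`, and the handbook supplies category,
#' color and advice.
#'
#' @param x length-6 concentrations (PM2.5, PM10, NO2, SO2, CO, O3;
#'   ug/m3, CO mg/m3).
#' @param limits an [aq_limits()] table.
#' @return A list of class `evaluation_result`: `R`, `W`, `B`, `level`
#'   (integer with roman name), `category`, `color`, `condition`,
#'   `measure`.
#' @examples
#' evaluate_day(c(55, 100, 60, 100, 3, 130))
#' @export
evaluate_day <- function(x, limits = aq_limits()) {
  x <- as.numeric(x)
  if (length(x) != 6 || any(!is.finite(x)) || any(x < 0))
    stop("`x` must be 6 finite non-negative concentrations", call. = FALSE)
  lm <- unclass(limits)
  R <- t(vapply(seq_len(6), function(i) membership_row(x[i], lm[i, ]),
                numeric(5)))
  dimnames(R) <- dimnames(lm)
  W <- factor_weights(x, limits)
  B <- fce_compose(W, R)
  level <- classify_level(B)
  hb <- handbook(level)
  structure(list(R = R, W = W, B = B, level = level,
                 category = hb$category, color = hb$color,
                 condition = hb$condition, measure = hb$measure),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation_result> level %s (%s, %s)\n",
              names(x$level), x$category, x$color))
  cat("  B:", paste(sprintf("%.4f", x$B), collapse = " "), "\n")
  invisible(x)
}

#' Evaluate a multi-day table of concentrations
#'
#' @param df data frame with columns `date`, `PM2.5`, `PM10`, `NO2`,
#'   `SO2`, `CO`, `O3`.
#' @param limits an [aq_limits()] table.
#' @return Data frame: `date`, `bI..bV`, `level`, `category`, `color`.
#' @export
evaluate_days <- function(df, limits = aq_limits()) {
  miss <- setdiff(POLLUTANTS, names(df))
  if (length(miss))
    stop("missing pollutant columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    ev <- evaluate_day(as.numeric(df[i, POLLUTANTS]), limits)
    data.frame(date = df$date[i], bI = ev$B[1], bII = ev$B[2],
               bIII = ev$B[3], bIV = ev$B[4], bV = ev$B[5],
               level = names(ev$level), category = ev$category,
               color = ev$color, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
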