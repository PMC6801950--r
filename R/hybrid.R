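#' Hybrid forecaster configuration
#'
#' Bundles the knobs of the decomposition-ensemble pipeline: one ICEEMDAN
#' decomposition of the training series, one WOA-tuned ELM per mode (and
#' the residue), forecasts summed across modes.
#'
#' @param window lag length fed to each per-mode model. The per-pollutant
#'   defaults of the system are PM2.5/PM10: 4, NO2: 8, SO2: 3, CO: 8,
#'   O3: 3 (see [default_windows()]).
#' @param L hidden neurons per ELM (default 20).
#' @param sift a [sift_config()] for the decomposition.
#' @param n_agents,woa_max_iter WOA budget per mode model (defaults 10
#'   agents, 200 iterations).
#' @param val_fraction chronological validation tail used as WOA fitness.
#' @param mode_extension how test-period mode values are obtained for the
#'   rolling one-step forecast: `"fixed"` (default) decomposes once and
#'   lets each mode model extend its own mode recursively; `"refit"`
#'   re-decomposes training data plus the observed test history before
#'   each step. Both are causal; `"refit"` is far more expensive and its
#'   re-decomposition suffers end effects exactly at the forecast origin,
#'   which degrades accuracy in practice.
#' @param seed master seed; per-mode model seeds are derived from it.
#' @return A list of class `hybrid_config`.
#' @export
hybrid_config <- function(window = 4, L = 20, sift = sift_config(),
                          n_agents = 10, woa_max_iter = 200,
                          val_fraction = 0.2,
                          mode_extension = c("fixed", "refit"),
                          seed = 1L) {
  mode_extension <- match.arg(mode_extension)
  window <- as.integer(window)
  if (window < 1) stop("`window` must be >= 1", call. = FALSE)
  structure(list(window = window, L = as.integer(L), sift = sift,
                 n_agents = as.integer(n_agents),
                 woa_max_iter = as.integer(woa_max_iter),
                 val_fraction = val_fraction,
                 mode_extension = mode_extension, seed = as.integer(seed)),
            class = "hybrid_config")
}

#' Per-pollutant default lag windows
#'
#' The input-variable counts used by the system for each pollutant.
#'
#' @return Named integer vector.
#' @export
default_windows <- function() {
  c("PM2.5" = 4L, "PM10" = 4L, "NO2" = 8L, "SO2" = 3L, "CO" = 8L, "O3" = 3L)
}

#' Fit the decomposition-ensemble forecaster
#'
#' Decomposes the training series with ICEEMDAN and trains one WOA-tuned
#' ELM per intrinsic mode plus one for the residue. If the series has no
#' interior extrema (zero modes), the pipeline falls back to a single
#' WOA-ELM on the raw series, with a message.
#'
#' @param train a [pollutant_series] (no missing values) or numeric vector.
#' @param cfg a [hybrid_config()].
#' @return An object of class `hybrid_forecaster`.
#' @export
hybrid_fit <- function(train, cfg = hybrid_config()) {
  values <- if (inherits(train, "pollutant_series")) train$values
            else as.numeric(train)
  if (anyNA(values)) stop("training series has missing values", call. = FALSE)
  if (length(values) <= cfg$window + 10)
    stop("training series too short for the configured window",
         call. = FALSE)
  imfs <- iceemdan(values, cfg$sift)
  fallback <- length(imfs$modes) == 0
  if (fallback) {
    message("decomposition produced zero modes; ",
            "falling back to a single WOA-ELM on the raw series")
    components <- list(values)
  } else {
    components <- c(imfs$modes, list(imfs$residue))
  }
  models <- vector("list", length(components))
  for (k in seq_along(components)) {
    w <- make_windows(components[[k]], cfg$window)
    models[[k]] <- train_woa_elm(w, L = cfg$L, n_agents = cfg$n_agents,
                                 max_iter = cfg$woa_max_iter,
                                 val_fraction = cfg$val_fraction,
                                 seed = cfg$seed + 1000L * k)
  }
  structure(list(train_values = values, imfs = imfs, models = models,
                 component_ranges = lapply(components, range),
                 fallback = fallback, n_modes = length(imfs$modes),
                 cfg = cfg),
            class = "hybrid_forecaster")
}

#' @export
print.hybrid_forecaster <- function(x, ...) {
  cat(sprintf("<hybrid_forecaster> %d mode(s) + residue, %d models, window %d\n",
              x$n_modes, length(x$models), x$cfg$window))
  if (x$fallback) cat("  (fallback: single model on raw series)\n")
  invisible(x)
}

# One-step prediction for every component given a matrix of component
# series (columns = components); uses each component's trailing window.
# Recursive multi-step extension clamps every mode forecast to that
# mode's training range, the usual guard against runaway feedback in
# recursive neural forecasting.
step_component_preds <- function(comp_mat, models, window, ranges) {
  n <- nrow(comp_mat)
  vapply(seq_along(models), function(k) {
    p <- predict(models[[k]], comp_mat[(n - window + 1):n, k])
    min(max(p, ranges[[k]][1]), ranges[[k]][2])
  }, numeric(1))
}

#' Rolling one-step-ahead forecast
#'
#' Produces `horizon` forecasts. When `actuals` are supplied the forecast
#' is rolling one-step-ahead: before predicting day `t`, days `1..t-1` of
#' the observed test period join the history. Under
#' `mode_extension = "refit"` the full history is re-decomposed at each
#' step (capped at the fitted mode count so models stay aligned) and each
#' model reads its own mode's trailing window; under `"fixed"` each model
#' extends its own training-time mode recursively. Without `actuals` the
#' forecast is free-running in both modes. The integrated forecast is the
#' elementwise sum of the per-mode forecasts.
#'
#' @param object a fitted `hybrid_forecaster`.
#' @param horizon number of days to forecast, >= 1.
#' @param actuals optional numeric vector (or [pollutant_series]) of
#'   observed test values, length >= `horizon`.
#' @param ... unused.
#' @return A list of class `forecast_result`: `predicted` (length
#'   `horizon`), `mode_predictions` (`horizon x n_models` matrix),
#'   `actuals` (or `NULL`) and the config snapshot.
#' @export
predict.hybrid_forecaster <- function(object, horizon, actuals = NULL, ...) {
  horizon <- as.integer(horizon)
  if (horizon < 1) stop("`horizon` must be >= 1", call. = FALSE)
  if (!is.null(actuals)) {
    if (inherits(actuals, "pollutant_series")) actuals <- actuals$values
    actuals <- as.numeric(actuals)
    if (length(actuals) < horizon)
      stop("`actuals` shorter than `horizon`", call. = FALSE)
  }
  cfg <- object$cfg
  nm <- length(object$models)
  preds <- matrix(0, horizon, nm)
  # component matrix holding training-time modes (and later extensions)
  comp <- if (object$fallback) matrix(object$train_values, ncol = 1)
          else as.matrix(object$imfs)
  refit <- cfg$mode_extension == "refit" && !object$fallback
  history <- object$train_values
  active <- rep(TRUE, nm)
  for (t in seq_len(horizon)) {
    if (refit && t > 1) {
      # causal re-decomposition of train + observed history so far
      sift <- cfg$sift
      sift$max_imfs <- object$n_modes
      im <- iceemdan(history, sift)
      K_t <- length(im$modes)
      m <- matrix(0, length(history), nm)
      if (K_t > 0) m[, seq_len(K_t)] <- matrix(unlist(im$modes), ncol = K_t)
      m[, nm] <- m[, nm] + im$residue  # residue model reads the residue
      comp <- m
      # a shallower re-decomposition leaves middle mode streams empty;
      # their models are silenced for this step
      active <- c(rep(TRUE, K_t), rep(FALSE, nm - 1 - K_t), TRUE)
    }
    preds[t, ] <- step_component_preds(comp, object$models, cfg$window,
                                       object$component_ranges)
    preds[t, !active] <- 0
    integrated_t <- sum(preds[t, ])
    next_obs <- if (!is.null(actuals)) actuals[t] else integrated_t
    history <- c(history, next_obs)
    if (!refit) {
      # each component extends itself recursively (fixed decomposition)
      comp <- rbind(comp, preds[t, ])
    }
  }
  structure(list(predicted = rowSums(preds), mode_predictions = preds,
                 actuals = if (!is.null(actuals)) actuals[seq_len(horizon)],
                 horizon = horizon, cfg = cfg),
            class = "forecast_result")
}

#' @export
print.forecast_result <- function(x, ...) {
  cat(sprintf("<forecast_result> horizon %d, %d mode stream(s)\n",
              x$horizon, ncol(x$mode_predictions)))
  if (!is.null(x$actuals))
    cat(sprintf("  RMSE vs actuals: %.4g\n",
                sqrt(mean((x$predicted - x$actuals)^2))))
  invisible(x)
}

#' Serialize a fitted hybrid forecaster to flat text
#'
#' Plain `dput()` text including nested model objects; read back with
#' [read_hybrid()].
#'
#' @param fitted a `hybrid_forecaster`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hybrid <- function(fitted, path) {
  stopifnot(inherits(fitted, "hybrid_forecaster"))
  dput(fitted, file = path,
       control = c("keepNA", "keepInteger", "niceNames", "showAttributes",
                   "digits17"))
  invisible(path)
}

#' @rdname write_hybrid
#' @export
read_hybrid <- function(path) {
  obj <- dget(path)
  stopifnot(inherits(obj, "hybrid_forecaster"))
  obj
}
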