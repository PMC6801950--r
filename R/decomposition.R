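#' Sifting / decomposition configuration
#'
#' Controls the EMD sifting core and the noise-assisted ICEEMDAN ensemble.
#'
#' @param max_sift_iters maximum sifting iterations per mode (default 100).
#' @param sd_threshold Cauchy-type sifting stop threshold: sifting of a
#'   candidate mode ends once `sum((h_prev - h_new)^2) / sum(h_prev^2)`
#'   drops below this value (default 0.2, the classical convention).
#' @param max_imfs cap on the number of extracted modes (default 30, i.e.
#'   effectively unbounded for daily series; extraction stops naturally
#'   when the residue has fewer than 3 extrema).
#' @param ensemble_size number of white-noise realizations `I` averaged by
#'   ICEEMDAN (default 50).
#' @param noise_scale relative noise amplitude `beta0`: the stage-k noise
#'   standard deviation is `beta0 * sd(current residue)` (default 0.2).
#' @param total_sift_budget total sifting iterations allowed across one
#'   decomposition call (default 1000). Once exhausted, remaining modes are
#'   extracted with single-pass sifting.
#' @param seed integer seed for the noise ensemble.
#' @return A list of class `sift_config`.
#' @export
sift_config <- function(max_sift_iters = 100, sd_threshold = 0.2,
                        max_imfs = 30, ensemble_size = 50,
                        noise_scale = 0.2, total_sift_budget = 1000,
                        seed = 1L) {
  if (max_sift_iters < 1 || sd_threshold <= 0 || max_imfs < 1 ||
      total_sift_budget < 1)
    stop("sifting parameters must be positive", call. = FALSE)
  if (ensemble_size < 1)
    stop("`ensemble_size` must be >= 1", call. = FALSE)
  if (noise_scale < 0)
    stop("`noise_scale` must be >= 0", call. = FALSE)
  structure(list(max_sift_iters = as.integer(max_sift_iters),
                 sd_threshold = sd_threshold,
                 max_imfs = as.integer(max_imfs),
                 ensemble_size = as.integer(ensemble_size),
                 noise_scale = noise_scale,
                 total_sift_budget = as.integer(total_sift_budget),
                 seed = as.integer(seed)),
            class = "sift_config")
}

# Indices of strict local maxima and minima. Flat plateaus contribute the
# midpoint of the flat stretch.
find_extrema <- function(y) {
  n <- length(y)
  if (n < 3) return(list(maxima = integer(0), minima = integer(0)))
  d <- diff(y)
  # collapse zero slopes to the previous non-zero slope so plateaus count once
  s <- sign(d)
  nz <- which(s != 0)
  if (length(nz) < 2) return(list(maxima = integer(0), minima = integer(0)))
  maxima <- integer(0); minima <- integer(0)
  for (k in seq_len(length(nz) - 1)) {
    i <- nz[k]; j <- nz[k + 1]
    if (s[i] > 0 && s[j] < 0)
      maxima <- c(maxima, as.integer(floor((i + 1 + j) / 2)))
    else if (s[i] < 0 && s[j] > 0)
      minima <- c(minima, as.integer(floor((i + 1 + j) / 2)))
  }
  list(maxima = maxima, minima = minima)
}

n_extrema <- function(y) {
  e <- find_extrema(y)
  length(e$maxima) + length(e$minima)
}

# Mirrored boundary extension for one (left) end, following the classical
# envelope boundary rule: reflect up to `nbsym` extrema of each kind about
# the outermost extremum, unless the end sample protrudes beyond the first
# envelope knot, in which case the end sample itself becomes a knot and
# extrema are reflected about it. The right end reuses this on the
# reversed signal.
mirror_left <- function(y, indmax, indmin, nbsym = 2L) {
  add_max <- integer(0); add_min <- integer(0)
  odd <- TRUE  # point-symmetric reflection: continues local trends
  if (indmax[1] < indmin[1]) {
    if (y[1] > y[indmin[1]]) {
      lmax <- head(indmax[-1], nbsym); lmin <- head(indmin, nbsym)
      lsym <- indmax[1]
    } else {
      lmax <- head(indmax, nbsym); lmin <- head(indmin, nbsym - 1L)
      lsym <- 1L; add_min <- 1L; odd <- FALSE
    }
  } else {
    if (y[1] < y[indmax[1]]) {
      lmin <- head(indmin[-1], nbsym); lmax <- head(indmax, nbsym)
      lsym <- indmin[1]
    } else {
      lmin <- head(indmin, nbsym); lmax <- head(indmax, nbsym - 1L)
      lsym <- 1L; add_max <- 1L; odd <- FALSE
    }
  }
  tmax <- 2L * lsym - lmax; tmin <- 2L * lsym - lmin
  bad <- !length(c(tmax, add_max)) || !length(c(tmin, add_min)) ||
    min(c(tmax, add_max)) > 1L || min(c(tmin, add_min)) > 1L
  if (bad && lsym != 1L) {
    # mirrored knots do not reach past the end sample: mirror about it
    if (lsym == indmax[1]) lmax <- head(indmax, nbsym)
    else lmin <- head(indmin, nbsym)
    tmax <- 2L - lmax; tmin <- 2L - lmin
    odd <- FALSE
  }
  vmax <- y[lmax]; vmin <- y[lmin]
  if (odd) {
    # reflect values about each envelope's outermost knot so a rising or
    # falling trend is extrapolated instead of folded back
    vmax <- 2 * y[indmax[1]] - vmax
    vmin <- 2 * y[indmin[1]] - vmin
  }
  list(tmax = c(tmax, add_max), vmax = c(vmax, y[add_max]),
       tmin = c(tmin, add_min), vmin = c(vmin, y[add_min]))
}

mirror_right <- function(y, indmax, indmin, nbsym = 2L) {
  n <- length(y)
  m <- mirror_left(rev(y), rev(n + 1L - indmax), rev(n + 1L - indmin), nbsym)
  list(tmax = rev(n + 1L - m$tmax), vmax = rev(m$vmax),
       tmin = rev(n + 1L - m$tmin), vmin = rev(m$vmin))
}

env_eval <- function(px, py, n) {
  o <- order(px); px <- px[o]; py <- py[o]
  keep <- !duplicated(px)
  px <- px[keep]; py <- py[keep]
  if (length(px) < 2) return(rep(py[1], n))
  splinefun(px, py, method = "fmm")(seq_len(n))
}

# Upper and lower cubic-spline envelopes through maxima/minima with the
# mirrored boundary extension above.
envelopes <- function(y, indmax, indmin) {
  n <- length(y)
  le <- mirror_left(y, indmax, indmin)
  ri <- mirror_right(y, indmax, indmin)
  list(upper = env_eval(c(le$tmax, indmax, ri$tmax),
                        c(le$vmax, y[indmax], ri$vmax), n),
       lower = env_eval(c(le$tmin, indmin, ri$tmin),
                        c(le$vmin, y[indmin], ri$vmin), n))
}

#' Local mean of a signal
#'
#' The mean of the upper (through maxima) and lower (through minima)
#' cubic-spline envelopes -- the quantity subtracted in one sifting pass.
#' A signal without interior extrema is its own local mean.
#'
#' @param y numeric vector.
#' @return Numeric vector, same length as `y`.
#' @export
local_mean <- function(y) {
  y <- as.numeric(y)
  e <- find_extrema(y)
  if (length(e$maxima) < 1 || length(e$minima) < 1) return(y)
  env <- envelopes(y, e$maxima, e$minima)
  (env$upper + env$lower) / 2
}

# One full sifting: extract the first candidate mode from y. Returns the
# mode, the local-mean remainder, and the number of sift iterations used.
sift_first_mode <- function(y, cfg, budget = Inf) {
  h <- y
  iters <- 0L
  repeat {
    e <- find_extrema(h)
    if (length(e$maxima) < 1 || length(e$minima) < 1) break
    env <- envelopes(h, e$maxima, e$minima)
    m <- (env$upper + env$lower) / 2
    h_new <- h - m
    iters <- iters + 1L
    crit <- sum((h - h_new)^2) / max(sum(h^2), .Machine$double.eps)
    h <- h_new
    if (crit < cfg$sd_threshold || iters >= cfg$max_sift_iters ||
        iters >= budget) break
  }
  list(mode = h, iters = iters)
}

make_imf_set <- function(modes, residue, x) {
  structure(list(modes = modes, residue = residue,
                 source_length = length(x),
                 reconstruction_error = if (length(modes))
                   max(abs(x - (Reduce(`+`, modes) + residue)))
                 else max(abs(x - residue))),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d mode(s) + residue, length %d\n",
              length(x$modes), x$source_length))
  cat(sprintf("  max reconstruction error: %.3g\n", x$reconstruction_error))
  invisible(x)
}

#' @export
as.matrix.imf_set <- function(x, ...) {
  K <- length(x$modes)
  m <- matrix(unlist(c(x$modes, list(x$residue))), ncol = K + 1)
  colnames(m) <- c(if (K) paste0("imf", seq_len(K)), "residue")
  m
}

#' Write a decomposition to CSV
#'
#' Columns `imf1..imfK,residue`, one row per time point.
#'
#' @param imfs an `imf_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_imfs <- function(imfs, path) {
  stopifnot(inherits(imfs, "imf_set"))
  write.csv(as.data.frame(as.matrix(imfs)), path, row.names = FALSE)
  invisible(path)
}

#' Empirical mode decomposition
#'
#' Classical EMD: repeatedly sift the residue (cubic-spline envelopes
#' through maxima/minima, subtract the envelope mean, stop on the SD
#' criterion) to peel off intrinsic mode functions ordered from high to
#' low frequency, until the residue has fewer than 3 extrema. The modes
#' plus residue reconstruct the input exactly (telescoping sums).
#'
#' @param x numeric vector, length >= 4, finite values. A constant or
#'   monotone input yields zero modes with `residue = x`.
#' @param cfg a [sift_config()].
#' @return An `imf_set`: list with `modes` (list of numeric vectors),
#'   `residue`, `source_length` and `reconstruction_error`.
#' @examples
#' t <- seq(0, 1, length.out = 256)
#' d <- emd(sin(2 * pi * 8 * t) + sin(2 * pi * t))
#' length(d$modes)
#' @export
emd <- function(x, cfg = sift_config()) {
  x <- as.numeric(x)
  if (length(x) < 4) stop("signal too short (need length >= 4)", call. = FALSE)
  if (!all(is.finite(x))) stop("signal must be finite", call. = FALSE)
  modes <- list()
  residue <- x
  used <- 0L
  x_scale <- sd(x)
  while (length(modes) < cfg$max_imfs && n_extrema(residue) >= 2 &&
         sd(residue) > 1e-12 * x_scale) {
    s <- sift_first_mode(residue, cfg, budget = cfg$total_sift_budget - used)
    used <- used + s$iters
    if (s$iters == 0L) break
    modes[[length(modes) + 1L]] <- s$mode
    residue <- residue - s$mode
    if (used >= cfg$total_sift_budget) break
  }
  make_imf_set(modes, residue, x)
}

#' Improved complete ensemble EMD with adaptive noise (ICEEMDAN)
#'
#' Noise-assisted decomposition that estimates each stage's residue as the
#' ensemble average of local means of noise-perturbed copies of the current
#' residue: stage 1 computes `r1 = <M(x + beta0 * E1(w_i))>` over
#' `ensemble_size` white-noise realizations `w_i` and sets `d1 = x - r1`;
#' stage k perturbs `r_{k-1}` with the k-th EMD mode of each stored noise
#' realization, scaled to `noise_scale * sd(r_{k-1})`, and sets
#' `d_k = r_{k-1} - r_k`. The local-mean operator `M` removes the first
#' sifted mode of its argument. Reconstruction is exact by construction.
#' With `noise_scale = 0` and `ensemble_size = 1` the recursion collapses
#' to plain [emd()].
#'
#' @inheritParams emd
#' @return An `imf_set`.
#' @export
iceemdan <- function(x, cfg = sift_config()) {
  x <- as.numeric(x)
  if (length(x) < 4) stop("signal too short (need length >= 4)", call. = FALSE)
  if (!all(is.finite(x))) stop("signal must be finite", call. = FALSE)
  n <- length(x)
  I <- cfg$ensemble_size
  use_noise <- cfg$noise_scale > 0
  # noise realizations and incremental extraction of their EMD modes
  # each realization gets its own derived seed so that appending samples
  # to the signal leaves the first n noise values of every realization
  # unchanged (stable re-decomposition of a growing series)
  noise_res <- if (use_noise)
    lapply(seq_len(I), function(i) with_seed(cfg$seed + 7919L * i, rnorm(n)))
  else list()
  next_noise_mode <- function() {
    # advances each realization's EMD by one mode; returns list of modes
    out <- vector("list", I)
    for (i in seq_len(I)) {
      res <- noise_res[[i]]
      if (is.null(res) || n_extrema(res) < 2) { out[i] <- list(NULL); next }
      s <- sift_first_mode(res, cfg)
      noise_res[[i]] <<- res - s$mode
      out[[i]] <- s$mode
    }
    out
  }
  M <- function(y, budget) {
    s <- sift_first_mode(y, cfg, budget)
    list(mean = y - s$mode, iters = s$iters)
  }
  modes <- list()
  residue <- x
  # the sift budget bounds each realization's sifting stream, so that one
  # ICEEMDAN call does the same per-stream work as one plain EMD call
  used <- integer(I)
  x_scale <- sd(x)
  while (length(modes) < cfg$max_imfs && n_extrema(residue) >= 2 &&
         sd(residue) > 1e-12 * x_scale &&
         all(used < cfg$total_sift_budget)) {
    beta <- cfg$noise_scale * sd(residue)
    ek <- if (use_noise) next_noise_mode() else NULL
    acc <- numeric(n)
    for (i in seq_len(I)) {
      pert <- residue
      if (use_noise && !is.null(ek[[i]])) {
        s_ek <- sd(ek[[i]])
        if (s_ek > .Machine$double.eps)
          pert <- residue + beta * ek[[i]] / s_ek
      }
      m <- M(pert, budget = cfg$total_sift_budget - used[i])
      used[i] <- used[i] + m$iters
      acc <- acc + m$mean
    }
    r_new <- acc / I
    d <- residue - r_new
    if (max(abs(d)) <= .Machine$double.eps * max(1, max(abs(residue)))) break
    modes[[length(modes) + 1L]] <- d
    residue <- r_new
  }
  make_imf_set(modes, residue, x)
}
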