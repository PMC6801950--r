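#' Whale Optimization Algorithm configuration
#'
#' @param dim problem dimension.
#' @param lower,upper box bounds, scalars or length-`dim` vectors with
#'   `lower < upper` elementwise.
#' @param n_agents number of search agents (whales), >= 2; default 10.
#' @param max_iter iteration budget, >= 1; default 200.
#' @param spiral_constant the logarithmic-spiral shape constant `b`
#'   (default 1, the value of the original algorithm).
#' @param seed integer seed.
#' @return A list of class `woa_config`.
#' @export
woa_config <- function(dim, lower = -1, upper = 1, n_agents = 10,
                       max_iter = 200, spiral_constant = 1, seed = 1L) {
  dim <- as.integer(dim)
  if (dim < 1) stop("`dim` must be >= 1", call. = FALSE)
  lower <- rep_len(as.numeric(lower), dim)
  upper <- rep_len(as.numeric(upper), dim)
  if (any(lower >= upper))
    stop("`lower` must be < `upper` in every dimension", call. = FALSE)
  if (n_agents < 2) stop("`n_agents` must be >= 2", call. = FALSE)
  if (max_iter < 1) stop("`max_iter` must be >= 1", call. = FALSE)
  structure(list(dim = dim, lower = lower, upper = upper,
                 n_agents = as.integer(n_agents),
                 max_iter = as.integer(max_iter),
                 spiral_constant = spiral_constant,
                 seed = as.integer(seed)),
            class = "woa_config")
}

check_shapes <- function(...) {
  lens <- vapply(list(...), length, integer(1))
  if (length(unique(lens)) != 1)
    stop("position/coefficient vectors must share one length", call. = FALSE)
}

#' Shrinking-encircling position update
#'
#' Moves an agent toward the best-so-far position:
#' `x_new = x_best - A * |C * x_best - x|` (elementwise).
#'
#' @param x current position.
#' @param x_best best position so far.
#' @param A,C coefficient vectors (`A = 2*a*r - a`, `C = 2*r`).
#' @return Updated position vector.
#' @export
encircle_update <- function(x, x_best, A, C) {
  check_shapes(x, x_best, A, C)
  x_best - A * abs(C * x_best - x)
}

#' Logarithmic-spiral position update
#'
#' Simulates the helix-shaped bubble-net movement:
#' `x_new = |x_best - x| * exp(b*l) * cos(2*pi*l) + x_best`.
#'
#' @param x current position.
#' @param x_best best position so far.
#' @param l random scalar in `[-1, 1]`.
#' @param b spiral shape constant.
#' @return Updated position vector.
#' @export
spiral_update <- function(x, x_best, l, b = 1) {
  check_shapes(x, x_best)
  if (l < -1 || l > 1) stop("`l` must lie in [-1, 1]", call. = FALSE)
  abs(x_best - x) * exp(b * l) * cos(2 * pi * l) + x_best
}

#' Random-search (exploration) position update
#'
#' As [encircle_update()] but targeting a randomly chosen agent instead of
#' the best one: `x_new = x_rand - A * |C * x_rand - x|`.
#'
#' @param x current position.
#' @param x_rand position of a randomly selected agent.
#' @param A,C coefficient vectors.
#' @return Updated position vector.
#' @export
explore_update <- function(x, x_rand, A, C) {
  check_shapes(x, x_rand, A, C)
  x_rand - A * abs(C * x_rand - x)
}

#' Run the whale optimization algorithm
#'
#' Minimizes `fitness` over the configured box. Each iteration, for each
#' agent: with probability 1/2 the agent either encircles the best position
#' (`|A| < 1`) or explores toward a random agent (`|A| >= 1`); otherwise it
#' takes a spiral step around the best position. `a` decays linearly from
#' 2 to 0 over the iterations; positions are clamped to the box before
#' evaluation. `|A|` is taken as the Euclidean norm of the `A` vector.
#'
#' @param fitness function mapping a length-`dim` numeric vector to a
#'   finite scalar (smaller is better).
#' @param cfg a [woa_config()].
#' @return A list of class `woa_result`: `best_position`, `best_fitness`,
#'   `history` (best fitness after each iteration, length `max_iter`),
#'   `evaluations` (fitness-call count).
#' @examples
#' res <- woa_optimize(function(x) sum(x^2),
#'                     woa_config(dim = 2, lower = -5, upper = 5,
#'                                max_iter = 50, seed = 7))
#' res$best_fitness
#' @export
woa_optimize <- function(fitness, cfg) {
  stopifnot(inherits(cfg, "woa_config"))
  d <- cfg$dim
  nA <- cfg$n_agents
  evals <- 0L
  eval_fit <- function(x) {
    f <- fitness(x)
    evals <<- evals + 1L
    if (!is.finite(f))
      stop(sprintf("non-finite fitness (%s) at position [%s]", format(f),
                   paste(signif(x, 4), collapse = ", ")), call. = FALSE)
    f
  }
  with_seed(cfg$seed, {
    X <- matrix(runif(nA * d, rep(cfg$lower, each = nA),
                      rep(cfg$upper, each = nA)), nrow = nA)
    fit <- apply(X, 1, eval_fit)
    best_i <- which.min(fit)
    x_best <- X[best_i, ]
    f_best <- fit[best_i]
    history <- numeric(cfg$max_iter)
    for (t in seq_len(cfg$max_iter)) {
      a <- 2 - 2 * t / cfg$max_iter
      for (i in seq_len(nA)) {
        r <- runif(d)
        A <- 2 * a * r - a
        C <- 2 * runif(d)
        p <- runif(1)
        l <- runif(1, -1, 1)
        X[i, ] <- if (p < 0.5) {
          if (sqrt(sum(A^2)) < 1) {
            encircle_update(X[i, ], x_best, A, C)
          } else {
            j <- sample.int(nA, 1)
            explore_update(X[i, ], X[j, ], A, C)
          }
        } else {
          spiral_update(X[i, ], x_best, l, cfg$spiral_constant)
        }
      }
      # amend agents that left the search space: clamp to the box
      X <- pmin(pmax(X, matrix(cfg$lower, nA, d, byrow = TRUE)),
                matrix(cfg$upper, nA, d, byrow = TRUE))
      fit <- apply(X, 1, eval_fit)
      if (min(fit) < f_best) {
        best_i <- which.min(fit)
        x_best <- X[best_i, ]
        f_best <- fit[best_i]
      }
      history[t] <- f_best
    }
    structure(list(best_position = x_best, best_fitness = f_best,
                   history = history, evaluations = evals),
              class = "woa_result")
  })
}

#' @export
print.woa_result <- function(x, ...) {
  cat(sprintf("<woa_result> best fitness %.6g after %d evaluations\n",
              x$best_fitness, x$evaluations))
  invisible(x)
}
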