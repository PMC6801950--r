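test_that("the default limits table is the five-level grading standard", {
  lim <- aq_limits()
  expect_equal(dim(lim), c(6, 5))
  expect_equal(unname(lim["PM2.5", ]), c(35, 75, 115, 150, 250))
  expect_equal(unname(lim["SO2", ]), c(50, 150, 475, 800, 1600))
  expect_equal(unname(lim["CO", ]), c(2, 4, 14, 24, 36))
  expect_equal(unname(lim["O3", ]), c(100, 160, 215, 265, 800))
  expect_true(all(apply(lim, 1, diff) > 0))
  expect_error(aq_limits(matrix(1, 6, 5)), "strictly increasing")
})

test_that("halved-trapezoidal memberships match hand evaluation", {
  pm25 <- aq_limits()["PM2.5", ]
  expect_equal(membership_row(55, pm25), c(0.5, 0.5, 0, 0, 0))
  expect_equal(membership_row(75, pm25), c(0, 1, 0, 0, 0))
  expect_equal(membership_row(300, pm25), c(0, 0, 0, 0, 1))
  expect_equal(membership_row(10, pm25), c(1, 0, 0, 0, 0))
  expect_equal(membership_row(95, pm25), c(0, 0.5, 0.5, 0, 0))
  expect_error(membership_row(-1, pm25), "non-negative")
  expect_error(membership_row(50, c(5, 4, 3, 2, 1)), "increasing")
})

test_that("interior concentrations split membership across two levels", {
  lim <- aq_limits()
  for (s in 1:50) {
    i <- withr::with_seed(s, sample(6, 1))
    x <- withr::with_seed(s + 1, runif(1, lim[i, 1] + 1e-9, lim[i, 5] - 1e-9))
    r <- membership_row(x, lim[i, ])
    expect_equal(sum(r), 1, tolerance = 1e-12)
    expect_lte(sum(r > 0), 2)
    nz <- which(r > 0)
    if (length(nz) == 2) expect_equal(diff(nz), 1)  # adjacent levels
  }
})

test_that("memberships shift toward worse levels as concentration rises", {
  # the cumulative membership over levels 1..j is non-increasing in x,
  # i.e. mass only ever moves to worse levels
  lim <- aq_limits()
  for (s in 1:30) {
    i <- withr::with_seed(s, sample(6, 1))
    x <- withr::with_seed(s + 50, runif(1, 0, lim[i, 5] * 1.1))
    bump <- withr::with_seed(s + 99, runif(1, 0.01, 0.5)) * lim[i, 5]
    r1 <- cumsum(membership_row(x, lim[i, ]))
    r2 <- cumsum(membership_row(x + bump, lim[i, ]))
    expect_true(all(r2 <= r1 + 1e-12))
  }
})

test_that("multi-scale weights normalize and favour the loaded pollutant", {
  w_unif <- factor_weights(rowMeans(aq_limits()))
  expect_equal(w_unif, rep(1 / 6, 6), tolerance = 1e-12)
  for (s in 1:10) {
    x <- withr::with_seed(s, runif(6, 1, 200))
    expect_equal(sum(factor_weights(x)), 1, tolerance = 1e-12)
  }
  w <- factor_weights(c(250, 80, 40, 50, 2, 100))
  expect_equal(which.max(w), 1)  # PM2.5 at twice its scale dominates
  expect_error(factor_weights(rep(0, 6)), "all-zero")
})

test_that("Zadeh composition takes min then max", {
  R2 <- rbind(c(1, 0), c(0, 1))
  expect_equal(fce_compose(c(0.5, 0.5), R2), c(0.5, 0.5))
  R <- withr::with_seed(2, matrix(runif(30), 6, 5))
  W <- factor_weights(withr::with_seed(3, runif(6, 1, 100)))
  B <- fce_compose(W, R)
  expect_lte(max(B), max(W))  # composition bound
  expect_equal(fce_compose(c(1, rep(0, 5)), R), R[1, ])
  expect_equal(fce_compose(W, matrix(0, 6, 5)), rep(0, 5))
  expect_error(fce_compose(c(0.5, 0.5), matrix(0, 3, 5)), "match")
})

test_that("classification follows maximum membership with ties to better", {
  expect_identical(names(classify_level(c(0.3759, 0.3409, 0, 0, 0))), "I")
  expect_identical(names(classify_level(c(0.4009, 0.4009, 0, 0, 0))), "I")
  expect_identical(names(classify_level(c(0, 0, 0, 0, 1))), "V")
  expect_identical(names(classify_level(c(0, 0.1, 0.3, 0.3, 0))), "III")
  expect_error(classify_level(rep(0, 5)), "all-zero")
})

test_that("the handbook returns the early-warning rows verbatim", {
  h1 <- handbook(1)
  expect_identical(h1$category, "excellent")
  expect_identical(h1$color, "green")
  expect_identical(h1$condition, "satisfactory air quality")
  expect_identical(handbook("V")$category, "hazardous")
  expect_identical(handbook("V")$color, "purple")
  expect_identical(handbook(3)$color, "yellow")
  expect_match(handbook(2)$measure, "abnormally sensitive")
  expect_error(handbook(6), "unknown")
})

test_that("whole-day evaluation chains the pipeline coherently", {
  lim <- aq_limits()
  # all six pollutants exactly at their level-II limits -> level II
  ev2 <- evaluate_day(lim[, 2])
  expect_true(all(abs(ev2$R[, 2] - 1) < 1e-12))
  expect_identical(names(ev2$level), "II")
  ev1 <- evaluate_day(lim[, 1])
  expect_identical(names(ev1$level), "I")
  # spreadsheet-style hand oracle for a mixed day
  x <- c(55, 100, 60, 100, 3, 130)
  ev <- evaluate_day(x)
  R_hand <- t(sapply(1:6, function(i) membership_row(x[i], lim[i, ])))
  W_hand <- (x / rowMeans(lim)) / sum(x / rowMeans(lim))
  B_hand <- apply(R_hand, 2, function(col) max(pmin(W_hand, col)))
  expect_equal(unname(ev$R), R_hand)
  expect_equal(ev$W, unname(W_hand))
  expect_equal(unname(ev$B), unname(B_hand))
  expect_identical(names(ev$level), names(classify_level(B_hand)))
  # deterministic and pure
  expect_identical(evaluate_day(x)$B, ev$B)
})

test_that("multi-day tables evaluate row-wise with handbook columns", {
  lim <- aq_limits()
  df <- data.frame(date = as.Date("2018-09-01") + 0:1,
                   rbind(lim[, 1], lim[, 3]), check.names = FALSE)
  names(df)[2:7] <- rownames(lim)
  out <- evaluate_days(df)
  expect_identical(out$level, c("I", "III"))
  expect_identical(out$color, c("green", "yellow"))
  expect_error(evaluate_days(df[, -2]), "missing pollutant")
})
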