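test_that("the Gompertz curve has the right asymptote, lag value and peak rate", {
  A <- 5000; mu <- 300; lam <- 35
  expect_equal(gompertz(1e6, A, mu, lam), A)
  expect_equal(gompertz(lam, A, mu, lam), A * exp(-exp(1)))
  # the maximum of dy/dt equals mu_m and is attained where y = A/e
  dy <- function(t) {
    u <- (mu * exp(1) / A) * (lam - t) + 1
    A * exp(-exp(u)) * exp(u) * (mu * exp(1) / A)
  }
  opt <- stats::optimize(dy, c(0, 200), maximum = TRUE, tol = 1e-10)
  expect_equal(opt$objective, mu, tolerance = 1e-9)
  expect_equal(gompertz(opt$maximum, A, mu, lam), A / exp(1), tolerance = 1e-6)
})

test_that("noiseless series refit recovers the generating parameters", {
  d <- data.frame(day = seq(0, 128, by = 4))
  d$ch4 <- gompertz(d$day, A = 1000, mu_m = 50, lambda = 10)
  fit <- fit_gompertz(ch4 ~ day, d)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)), c(1000, 50, 10), tolerance = 1e-6)
  expect_gt(fit$r_squared, 1 - 1e-10)
  expect_lt(max(abs(residuals(fit))), 1e-4)
})

test_that("the fitter refuses degenerate series with clear errors", {
  expect_error(fit_gompertz(ch4 ~ day, data.frame(day = 1:4, ch4 = 1:4)),
               "at least 5 points")
  expect_error(fit_gompertz(ch4 ~ day,
                            data.frame(day = seq(0, 100, 10), ch4 = 0)),
               "no methane production")
})

test_that("fitted Gompertz predictions are nondecreasing in time", {
  set.seed(3)
  for (i in 1:5) {
    A <- stats::runif(1, 200, 8000)
    mu <- stats::runif(1, 2, 1400)
    lam <- stats::runif(1, 0, 60)
    t <- rep(seq(0, 128, 5), 3)
    y <- gompertz(t, A, mu, lam) + stats::rnorm(length(t), 0, 150)
    fit <- fit_gompertz(ch4 ~ day, data.frame(day = t, ch4 = y))
    if (!fit$converged) next
    pred <- predict(fit, seq(0, 128, by = 0.5))
    expect_true(all(diff(pred) >= -1e-9))
  }
})

test_that("the optimizer's minimum matches a brute-force SSR grid search", {
  # an exactly solvable configuration: data generated on the curve itself
  t <- c(0, 20, 40, 60, 128)
  truth <- c(A = 2000, mu = 80, lam = 25)
  y <- gompertz(t, truth[1], truth[2], truth[3])
  fit <- fit_gompertz(ch4 ~ day, data.frame(day = t, ch4 = y))
  ssr_fit <- sum(residuals(fit)^2)
  oracle <- grid_search_gompertz(t, y, truth, span = 0.02, res = 1e-3)
  expect_lte(ssr_fit, oracle[["ssr"]] + 1e-8)
  expect_equal(unname(coef(fit)), unname(truth), tolerance = 1e-5)
})

test_that("the linear model handles exact, noisy and degenerate series", {
  d <- data.frame(day = 0:10, ch4 = 4 * (0:10))
  fit <- fit_linear(ch4 ~ day, d)
  expect_equal(coef(fit)[["slope"]], 4)
  expect_equal(fit$r_squared, 1)
  expect_warning(cfit <- fit_linear(ch4 ~ day,
                                    data.frame(day = 0:5, ch4 = 7)),
                 "constant")
  expect_equal(coef(cfit)[["slope"]], 0)
  expect_equal(cfit$r_squared, 0)
  expect_error(fit_linear(ch4 ~ day, data.frame(day = 0:1, ch4 = 0:1)),
               "at least 3")
})

test_that("a slow disaccharide-like series fits linearly at the expected order", {
  set.seed(11)
  t <- rep(seq(0, 128, 5), 3)
  y <- pmax(0, gompertz(t, 218, 1.9, 53) + stats::rnorm(length(t), 0, 40))
  fit <- fit_linear(ch4 ~ day, data.frame(day = t, ch4 = y))
  slope <- coef(fit)[["slope"]]
  expect_gt(slope, 1.9 / 10)
  expect_lt(slope, 1.9 * 10)
})

test_that("automatic model choice splits sigmoid sugars from slow producers", {
  set.seed(5)
  t <- rep(seq(0, 128, 5), 3)
  sugar <- data.frame(day = t,
                      ch4 = gompertz(t, 6000, 500, 38) +
                        stats::rnorm(length(t), 0, 200))
  slow <- data.frame(day = t,
                     ch4 = pmax(0, 0.5 * t + stats::rnorm(length(t), 0, 30)))
  expect_identical(attr(fit_methane(ch4 ~ day, sugar), "model"), "gompertz")
  expect_identical(attr(fit_methane(ch4 ~ day, slow, r2_min = 0.9), "model"),
                   "linear")
  expect_identical(attr(fit_methane(ch4 ~ day, slow, model = "linear"), "model"),
                   "linear")
})

test_that("group consolidation averages series and propagates spread", {
  s1 <- data.frame(day = seq(0, 100, 10), ch4 = seq(0, 1000, 100))
  cons <- consolidate_group(list(s1, s1))
  expect_equal(cons$ch4, s1$ch4)
  expect_equal(cons$sd, rep(0, nrow(s1)))
  expect_equal(cons$n, rep(2, nrow(s1)))

  # series on a shifted grid are interpolated onto the first grid
  s2 <- data.frame(day = seq(5, 105, 10), ch4 = seq(50, 1050, 100))
  cons2 <- consolidate_group(list(s1, s2))
  expect_equal(cons2$day, seq(10, 100, 10))
  expect_equal(cons2$ch4, seq(100, 1000, 100))

  expect_error(consolidate_group(list()), "non-empty")
})

test_that("six-carbon treatments outpace five-carbon treatments as a group", {
  days <- seq(0, 128, 5)
  p <- reference_parameters()
  mk <- function(tr) {
    r <- p[p$treatment == tr, ]
    data.frame(day = days, ch4 = gompertz(days, r$A, r$mu_m, r$lambda))
  }
  six <- consolidate_group(lapply(c("glucose", "galactose", "mannose"), mk))
  five <- consolidate_group(lapply(c("xylose", "arabinose"), mk))
  expect_gt(coef(rise_rate(six))[["slope"]], coef(rise_rate(five))[["slope"]])
})

test_that("gompertz_fit methods are mutually consistent", {
  d <- data.frame(day = rep(seq(0, 128, 8), 2))
  set.seed(9)
  d$ch4 <- gompertz(d$day, 5000, 400, 30) + stats::rnorm(nrow(d), 0, 100)
  fit <- fit_gompertz(ch4 ~ day, d)
  expect_equal(fitted(fit) + residuals(fit), d$ch4)
  expect_equal(predict(fit), fitted(fit))
  s <- summary(fit)
  expect_identical(dim(s$coefficients), c(3L, 2L))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_identical(dim(sims), c(nrow(d), 3L))
  expect_identical(sims, simulate(fit, nsim = 3, seed = 1))
})
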