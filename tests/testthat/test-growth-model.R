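test_that("predict_weight evaluates the logistic closed form", {
  yp <- yp_params()
  # weight at the inflection age is half the asymptote
  expect_equal(predict_weight(yp, log(yp$B) / yp$K), 160.493 / 2,
               tolerance = 1e-12)
  expect_equal(round(predict_weight(yp, 128.52), 2), 80.25)
  # B = 1 puts the inflection at t = 0
  expect_equal(predict_weight(logistic_params(100, 1, 0.01), 0), 50)
  # frozen closed-form evaluation (independent high-precision oracle)
  expect_equal(predict_weight(qyp_params(), 300), 118.4021193960,
               tolerance = 1e-10)
})

test_that("predict_weight rejects invalid inputs", {
  expect_error(logistic_params(-1, 2, 0.01), "positive")
  expect_error(logistic_params(100, 0, 0.01), "positive")
  expect_error(predict_weight(yp_params(), -5), "non-negative")
  expect_error(predict_weight(list(A = 1), 10), "logistic")
})

test_that("predict_weight is strictly increasing and bounded by A", {
  set.seed(42)
  for (i in 1:25) {
    p <- logistic_params(runif(1, 50, 300), runif(1, 2, 50),
                         runif(1, 0.005, 0.1))
    ages <- sort(runif(50, 0, 2.5 * log(p$B) / p$K))
    w <- predict_weight(p, ages)
    expect_true(all(diff(w) > 0))
    expect_true(all(w > 0 & w < p$A))
  }
})

test_that("growth_rate matches the published maximum daily gain and AK/4", {
  yp <- yp_params()
  r <- growth_rate(yp, log(yp$B) / yp$K)
  expect_equal(round(1000 * r, 2), 882.71)     # g/day at the inflection
  expect_equal(growth_rate(logistic_params(4, 1, 1), 0), 1)  # AK/4
  # frozen central-finite-difference oracle at 100 d for the fat-type curve
  expect_equal(growth_rate(qyp_params(), 100), 0.350524093147,
               tolerance = 1e-6)
})

test_that("analytic growth_rate agrees with finite differences of the curve", {
  set.seed(7)
  for (i in 1:25) {
    A <- runif(1, 50, 300); B <- runif(1, 2, 50); K <- runif(1, 0.005, 0.1)
    t <- runif(1, 0.1, 2.5) * log(B) / K
    expect_equal(growth_rate(logistic_params(A, B, K), t),
                 fd_rate(A, B, K, t), tolerance = 1e-6)
  }
})

test_that("growth landmarks reproduce the published inflection quantities", {
  yl <- growth_landmarks(yp_params())
  expect_equal(round(yl$inflection_weight, 2), 80.25)
  expect_equal(round(yl$inflection_age, 2), 128.52)
  expect_equal(round(yl$max_daily_gain, 2), 882.71)
  ql <- growth_landmarks(qyp_params())
  expect_equal(round(ql$inflection_weight, 2), 68.97)
  expect_equal(round(ql$inflection_age, 2), 187.42)
  expect_equal(round(ql$max_daily_gain, 2), 551.79)
  # fat-type maximum-deceleration age, reported as "around 270 days"
  expect_equal(ql$max_decel_age, 269.727, tolerance = 1e-4)
})

test_that("landmark closed forms hold at unit parameters and as identities", {
  lm1 <- growth_landmarks(logistic_params(2, 1, 1))
  expect_equal(lm1$inflection_age, 0)
  expect_equal(lm1$inflection_weight, 1)
  expect_equal(lm1$max_daily_gain, 500)
  expect_equal(lm1$max_decel_age, log(2 + sqrt(3)))
  set.seed(11)
  for (i in 1:10) {
    p <- logistic_params(runif(1, 50, 300), runif(1, 2, 50),
                         runif(1, 0.005, 0.1))
    lms <- growth_landmarks(p)
    expect_equal(lms$inflection_weight, p$A / 2)
    expect_equal(lms$max_daily_gain, 250 * p$A * p$K)
    expect_equal(lms$max_decel_weight / p$A, (3 + sqrt(3)) / 6)
    expect_gt(lms$max_decel_age, lms$inflection_age)
    expect_gt(lms$max_decel_weight, lms$inflection_weight)
  }
})

test_that("analytic landmarks agree with grid extrema of the derivatives", {
  for (p in list(yp_params(), qyp_params())) {
    lms <- growth_landmarks(p)
    grid <- seq(0, 3 * log(p$B) / p$K, by = 0.01)
    rate <- growth_rate(p, grid)
    expect_lt(abs(grid[which.max(rate)] - lms$inflection_age), 0.011)
    # numerical second derivative of weight, minimized post inflection
    accel <- (rate[-1] - rate[-length(rate)]) / 0.01
    mids <- (grid[-1] + grid[-length(grid)]) / 2
    expect_lt(abs(mids[which.min(accel)] - lms$max_decel_age), 0.011)
  }
})

test_that("fit_logistic recovers exact data and rejects thin data", {
  rec <- exact_records(160.493, 16.901, 0.022)
  fit <- fit_logistic(rec)
  expect_equal(fit$params$A, 160.493, tolerance = 1e-6)
  expect_equal(fit$params$B, 16.901, tolerance = 1e-6)
  expect_equal(fit$params$K, 0.022, tolerance = 1e-6)
  expect_equal(fit$pcc, 1, tolerance = 1e-9)
  expect_error(fit_logistic(rec[1:3, ]), "insufficient")
})

test_that("fit_logistic is unbiased on noisy herds across replicates", {
  spec <- synthetic_herd_spec(n_yp = 60, n_qyp = 60)
  A_hat <- K_hat <- numeric(50)
  for (s in 1:50) {
    h <- simulate_herd(spec, seed = 1000 + s)
    f <- fit_logistic(h[h$breed == "QYP", ])
    A_hat[s] <- f$params$A; K_hat[s] <- f$params$K
  }
  # Monte-Carlo 3-SE bands around the generating truth
  expect_lt(abs(mean(A_hat) - 137.948), 3 * sd(A_hat) / sqrt(50))
  expect_lt(abs(mean(K_hat) - 0.016), 3 * sd(K_hat) / sqrt(50))
})

test_that("ADG conventions: instantaneous peaks at AK/4, cumulative matches closed form", {
  yp <- yp_params()
  expect_equal(adg_table(yp, log(yp$B) / yp$K, "instantaneous"),
               1000 * yp$A * yp$K / 4)
  # closed-form oracle for the cumulative convention at 200 d
  y200 <- 160.493 / (1 + 16.901 * exp(-0.022 * 200))
  y50  <- 160.493 / (1 + 16.901 * exp(-0.022 * 50))
  expect_equal(adg_table(yp, 200, "cumulative"),
               1000 * (y200 - y50) / 150, tolerance = 1e-12)
  expect_error(adg_table(yp, 40, "cumulative"), "start_age")
  # fat-type group-5 mean weight: cumulative ADG has the magnitude of the
  # published per-group ADG values (hundreds of g/day)
  qyp <- qyp_params()
  adg5 <- adg_table(qyp, age_at_weight(qyp, 105.89), "cumulative")
  expect_gt(adg5, 100); expect_lt(adg5, 1000)
})

test_that("age_at_weight inverts predict_weight", {
  p <- qyp_params()
  w <- c(20, 68.974, 120)
  expect_equal(predict_weight(p, age_at_weight(p, w)), w, tolerance = 1e-10)
  expect_error(age_at_weight(p, 200), "asymptote")
})
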