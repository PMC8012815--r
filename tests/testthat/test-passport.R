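test_that("predictive limits match the closed form in standard cases", {
  p <- marker_params("m", mu0 = 0, tau = 1, sigma = 1)
  z <- qnorm(0.995)
  s0 <- new_passport(p)
  expect_equal(unname(predictive_limits(s0)),
               c(-z * sqrt(2), z * sqrt(2)), tolerance = 1e-12)
  expect_equal(predictive_limits(s0)[["upper"]], 3.6427, tolerance = 1e-4)

  s1 <- passport_update(s0, 0)
  expect_equal(unname(predictive_limits(s1)),
               c(-z * sqrt(1.5), z * sqrt(1.5)), tolerance = 1e-12)
  expect_equal(predictive_limits(s1)[["upper"]], 3.1546, tolerance = 1e-4)
})

test_that("a degenerate prior (tau -> 0) pins the limits at mu0 +/- z sigma", {
  p <- marker_params("m", mu0 = 10, tau = 1e-8, sigma = 2)
  z <- qnorm(0.995)
  state <- new_passport(p)
  for (v in c(14, 6, 11)) state <- passport_update(state, v)
  expect_equal(unname(predictive_limits(state)),
               c(10 - z * 2, 10 + z * 2), tolerance = 1e-5)
})

test_that("closed-form limits agree with numerical integration over the prior", {
  cases <- list(
    list(mu0 = 14.6, tau = 0.9, sigma = 0.45, xs = numeric(0)),
    list(mu0 = 14.6, tau = 0.9, sigma = 0.45, xs = 15.2),
    list(mu0 = 90, tau = 12, sigma = 8, xs = c(97, 84)),
    list(mu0 = 0, tau = 1, sigma = 1, xs = c(0.4, -1.1, 2.0))
  )
  for (cs in cases) {
    p <- marker_params("m", cs$mu0, cs$tau, cs$sigma)
    state <- new_passport(p)
    for (x in cs$xs) state <- passport_update(state, x)
    lim <- predictive_limits(state)
    lo <- predictive_quantile_numeric(0.005, cs$mu0, cs$tau, cs$sigma, cs$xs)
    hi <- predictive_quantile_numeric(0.995, cs$mu0, cs$tau, cs$sigma, cs$xs)
    expect_equal(unname(lim), c(lo, hi), tolerance = 1e-6)
  }
})

test_that("single-value flag uses pre-incorporation limits and strict exceedance", {
  p <- marker_params("m", mu0 = 0, tau = 1, sigma = 1)
  s <- passport_update(new_passport(p), 4.0)
  expect_true(s$atpf_single[1])   # |4.0| > 3.6427 population band

  up <- predictive_limits(new_passport(p))[["upper"]]
  s <- passport_update(new_passport(p), up)
  expect_false(s$atpf_single[1])  # exactly on the limit: no flag

  s <- passport_update(new_passport(p), up + 1e-9)
  expect_true(s$atpf_single[1])
})

test_that("repeated values at the prior mean never flag and limits narrow", {
  p <- marker_params("m", mu0 = 14.6, tau = 0.9, sigma = 0.45)
  state <- new_passport(p)
  widths <- numeric(12)
  for (i in 1:12) {
    state <- passport_update(state, 14.6)
    widths[i] <- state$upper[i] - state$lower[i]
  }
  expect_false(any(state$atpf_single))
  expect_true(all(diff(widths) < 0))
  # asymptotic width is the pure within-subject band
  p_inf <- marker_params("m", 14.6, 0.9, 0.45)
  state2 <- new_passport(p_inf)
  for (i in 1:400) state2 <- passport_update(state2, 14.6)
  lim <- predictive_limits(state2)
  expect_equal(lim[["upper"]] - lim[["lower"]], 2 * qnorm(0.995) * 0.45,
               tolerance = 1e-2)
})

test_that("posterior mean shrinks between the prior and the sample mean", {
  set.seed(9)
  p <- marker_params("m", mu0 = 14.6, tau = 0.9, sigma = 0.45)
  for (rep in 1:20) {
    state <- new_passport(p)
    xs <- rnorm(sample(1:8, 1), 15.4, 0.5)
    for (x in xs) state <- passport_update(state, x)
    post_mean <- abpmonitor:::pp_predictive(state)$mean
    lo <- min(p$mu0, mean(xs)); hi <- max(p$mu0, mean(xs))
    expect_true(post_mean >= lo - 1e-12 && post_mean <= hi + 1e-12)
  }
})

test_that("log-transformed markers always have positive limits", {
  p <- marker_params("ret", mu0 = log(1.1), tau = 0.25, sigma = 0.15,
                     transform = "log")
  state <- new_passport(p)
  set.seed(2)
  for (x in exp(rnorm(10, log(1.1), 0.3))) {
    state <- passport_update(state, x)
  }
  expect_true(all(state$lower > 0))
  expect_true(all(state$lower < state$upper))
  expect_error(passport_update(state, -0.5), "> 0")
})

test_that("sequence flag follows the product-of-tails rule", {
  p <- marker_params("m", mu0 = 0, tau = 1, sigma = 1)

  # values pinned at the predictive mean never fire
  res <- values_at_tails(p, rep(0.5, 6))
  expect_false(any(res$state$atpf_sequence))

  # three consecutive 0.05 upper tails: 0.05^3 = 1.25e-4 < 1e-3
  res <- values_at_tails(p, c(0.5, 0.5, 0.05, 0.05, 0.05))
  expect_true(res$state$atpf_sequence[5])

  # two consecutive 0.05 tails alone: 2.5e-3 > 1e-3, no flag
  res <- values_at_tails(p, c(0.05, 0.05))
  expect_false(res$state$atpf_sequence[2])

  # but preceded by median values, the k = 4 window still fires
  # (0.5^2 * 0.05^2 = 6.25e-4 < 1e-3): the rule scans every k in 2..5
  res <- values_at_tails(p, c(0.5, 0.5, 0.5, 0.05, 0.05))
  expect_true(res$state$atpf_sequence[5])
  expect_false(sequence_atpf(res$state, 2))
  expect_true(sequence_atpf(res$state, 4))

  # the rule is one-sided: the same deviations on the lower side fire too
  res <- values_at_tails(p, c(0.5, 0.5, 0.95, 0.95, 0.95))
  expect_true(res$state$atpf_sequence[5])

  expect_error(sequence_atpf(res$state, 6), "2..5")
  expect_error(sequence_atpf(values_at_tails(p, 0.5)$state, 2), "fewer")
})

test_that("distance to limits measures to the nearest limit, inside or out", {
  expect_equal(distance_to_limits(14.0, 12.5, 15.5), 1.5)
  expect_equal(distance_to_limits(15.4, 12.5, 15.5), 0.1)
  expect_equal(distance_to_limits(16.0, 12.5, 15.5), 0.5)
  expect_error(distance_to_limits(1, 2, 2), "lower")
})

test_that("distance summaries report strict-threshold counts and percentages", {
  d <- c(rep(0.05, 4), rep(0.3, 6), rep(2, 110))
  s <- summarize_distances(d, thresholds = c(0.1, 0.5))
  expect_equal(s$near_limit$count, c(4, 10))
  expect_equal(s$near_limit$pct, c(3.3, 8.3))
  s0 <- summarize_distances(rep(5, 40), thresholds = 0.5)
  expect_equal(s0$near_limit$pct, 0)
  expect_error(summarize_distances(numeric(0)), "no distances")
})

test_that("moment-based parameter estimation recovers generating variances", {
  set.seed(31)
  n_ath <- 200; n_obs <- 12
  theta <- rnorm(n_ath, 14.6, 0.9)
  dat <- tibble::tibble(
    athlete_id = rep(sprintf("a%03d", 1:n_ath), each = n_obs),
    hb = rnorm(n_ath * n_obs, rep(theta, each = n_obs), 0.45)
  )
  p <- estimate_marker_params(dat, "hb")
  expect_equal(p$mu0, 14.6, tolerance = 0.05)
  expect_equal(p$tau, 0.9, tolerance = 0.15)
  expect_equal(p$sigma, 0.45, tolerance = 0.05)
})
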