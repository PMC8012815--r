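test_that("normalized power agrees with the brute-force window scan", {
  # constant power: NP equals the power
  expect_equal(normalized_power(rep(250, 1200)), 250)

  # 5 min coasting then 5 min at 300 W, against the exhaustive oracle
  series <- c(rep(0, 300), rep(300, 300))
  expect_equal(normalized_power(series), np_brute_force(series),
               tolerance = 1e-12)
  expect_equal(round(np_brute_force(series), 1), 250.3)

  # random rides
  set.seed(12)
  for (i in 1:5) {
    p <- pmax(0, rnorm(sample(60:3600, 1), 220, 80))
    expect_equal(normalized_power(p), np_brute_force(p),
                 tolerance = 1e-10)
  }
})

test_that("normalized power dominates mean power (Jensen)", {
  set.seed(13)
  for (i in 1:10) {
    p <- pmax(0, rnorm(600, 200, 90))
    expect_gte(normalized_power(p), mean(p) - 1e-9)
  }
  expect_error(normalized_power(rep(200, 29)), "at least 30")
})

test_that("TSS follows the duration-intensity formula", {
  expect_equal(tss(3600, 300, 300), 100)
  expect_equal(tss(7200, 240, 300), 128)   # (7200*240*0.8)/(300*3600)*100
  expect_equal(tss(0, 250, 300), 0)
  expect_error(tss(3600, 250, 0), "ftp")
  # constant-power session closed form: 100 * (t/3600) * (P/FTP)^2
  set.seed(14)
  for (i in 1:20) {
    t <- runif(1, 600, 14400); p <- runif(1, 120, 380)
    ftp <- runif(1, 250, 420)
    expect_equal(tss(t, p, ftp), 100 * (t / 3600) * (p / ftp)^2,
                 tolerance = 1e-12)
  }
})

test_that("FTP is 95% of the 20-minute test power", {
  expect_equal(ftp_from_test(400), 380)
  expect_equal(ftp_from_test(300), 285)
  expect_error(ftp_from_test(0))
})

test_that("window loads use the half-open window excluding the anchor day", {
  mk <- function(dates, tss) {
    start <- if (length(dates) == 0) {
      as.POSIXct(character(0), tz = "UTC")
    } else {
      as.POSIXct(paste(dates, "10:00:00"), tz = "UTC")
    }
    tibble::tibble(athlete_id = rep("a", length(dates)),
                   start = start, tss = tss)
  }
  anchor <- as.Date("2019-06-10")
  expect_equal(window_load(mk(character(0), numeric(0)), anchor,
                           5)$cumulated, 0)
  w <- window_load(mk("2019-06-09", 100), anchor, 5)
  expect_equal(w$cumulated, 100)
  expect_equal(w$mean_daily, 20)
  # the sampling day itself is excluded ...
  expect_equal(window_load(mk("2019-06-10", 100), anchor, 5)$cumulated, 0)
  # ... and the window start day is included
  expect_equal(window_load(mk("2019-06-05", 80), anchor, 5)$cumulated, 80)
  expect_equal(window_load(mk("2019-06-04", 80), anchor, 5)$cumulated, 0)
  expect_warning(window_load(mk("2019-06-09", 10), anchor, 7), "span")
})

test_that("window load is additive over disjoint session sets and order-free", {
  set.seed(15)
  dates <- as.Date("2019-03-01") + sample(0:41, 30, replace = TRUE)
  s <- tibble::tibble(
    athlete_id = "a",
    start = as.POSIXct(paste(dates, "09:00:00"), tz = "UTC"),
    tss = runif(30, 20, 150)
  )
  anchor <- as.Date("2019-04-12")
  whole <- window_load(s, anchor, 42)$cumulated
  half <- sample(c(TRUE, FALSE), 30, replace = TRUE)
  expect_equal(window_load(s[half, ], anchor, 42)$cumulated +
                 window_load(s[!half, ], anchor, 42)$cumulated, whole)
  expect_equal(window_load(s[sample(30), ], anchor, 42)$cumulated, whole)
})

test_that("extreme 12-week periods match the exhaustive scan", {
  set.seed(16)
  dates <- as.Date("2019-01-01") + 0:229
  tss <- round(rgamma(230, 2, 1 / 40), 1) *
    rbinom(230, 1, 0.85)
  daily <- tibble::tibble(date = dates, tss = tss)
  got <- extreme_periods(daily)
  ref <- extreme_brute_force(daily$date, daily$tss)
  expect_equal(got$high$tss, ref$high$tss)
  expect_equal(got$high$start, ref$high$start)
  expect_equal(got$low$tss, ref$low$tss)
  expect_equal(got$low$start, ref$low$start)

  # ties break to the earliest window
  const <- tibble::tibble(date = dates, tss = rep(10, 230))
  got <- extreme_periods(const)
  expect_equal(got$high$start, dates[1])
  expect_equal(got$low$start, dates[1])

  # a single spike day: the earliest window containing it wins
  spike <- tibble::tibble(date = dates, tss = c(rep(0, 120), 500,
                                                rep(0, 109)))
  got <- extreme_periods(spike)
  expect_equal(got$high$start, dates[121 - 83])
  expect_equal(got$high$tss, 500)
  expect_equal(got$low$tss, 0)

  expect_error(extreme_periods(tibble::tibble(date = dates[1:50],
                                              tss = rep(1, 50))), "84")
})

test_that("seasonal load counts calendar-month membership", {
  dates <- seq(as.Date("2019-01-01"), as.Date("2019-12-31"), by = "day")
  daily <- tibble::tibble(date = dates, tss = rep(10, length(dates)))
  s <- seasonal_load(daily)
  expect_equal(s$winter, 900)   # 31 + 31 + 28 days of Dec/Jan/Feb
  expect_equal(s$summer, 920)   # 30 + 31 + 31 days of Jun/Jul/Aug
  july <- tibble::tibble(date = seq(as.Date("2019-07-01"),
                                    as.Date("2019-07-31"), by = "day"),
                         tss = rep(10, 31))
  expect_warning(s2 <- seasonal_load(july), "partial")
  expect_equal(s2$winter, 0)
  expect_equal(seasonal_load(tibble::tibble(date = as.Date(character(0)),
                                            tss = numeric(0))),
               list(winter = 0, summer = 0))
})

test_that("hypoxic dose is altitude-hours and additive over partitions", {
  sojourn <- tibble::tibble(start = as.Date("2019-09-20"),
                            end = as.Date("2019-10-16"),
                            hours_per_day = 24, altitude_m = 2750)
  expect_equal(hypoxic_dose(sojourn), 27 * 24 * 2.75)
  expect_equal(hypoxic_dose(sojourn), 1782)

  tent <- tibble::tibble(start = as.Date("2019-11-01"),
                         end = as.Date("2019-12-06"),
                         hours_per_day = 9, altitude_m = 2500,
                         altitude_end_m = 3500)
  expect_equal(hypoxic_dose(tent), 36 * 9 * 3.0)
  expect_equal(hypoxic_dose(tent), 972)

  # split at the midpoint altitude: 17 + 19 nights
  split <- tibble::tibble(start = as.Date(c("2019-11-01", "2019-11-18")),
                          end = as.Date(c("2019-11-17", "2019-12-06")),
                          hours_per_day = 9, altitude_m = 3000)
  expect_equal(hypoxic_dose(split[1, ]), 459)
  expect_equal(hypoxic_dose(split[2, ]), 513)
  expect_equal(hypoxic_dose(split), 972)

  expect_equal(hypoxic_dose(sojourn[0, ]), 0)
  bad <- sojourn; bad$hours_per_day <- -1
  expect_error(hypoxic_dose(bad), "hours")
})
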