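test_that("the generator is deterministic and writes byte-identical files", {
  cfg <- cohort_config(n_athletes = 4, n_samples = 6)
  b1 <- generate_cohort(cfg, seed = 42)
  b2 <- generate_cohort(cfg, seed = 42)
  expect_identical(b1$blood, b2$blood)
  expect_identical(b1$sessions, b2$sessions)
  expect_identical(b1$rebreathing, b2$rebreathing)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(b1, d1); write_cohort(b2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  b3 <- generate_cohort(cfg, seed = 43)
  expect_false(identical(b1$blood$hb, b3$blood$hb))
})

test_that("the physiological closure holds exactly pre-noise", {
  b <- generate_cohort(cohort_config(), seed = 6)
  m <- b$manifest
  expect_equal(m$pv_true + m$rcv_true, m$bv_true, tolerance = 1e-12)
  expect_equal(m$hb_true * m$bv_true / 100, m$hbmass_true,
               tolerance = 1e-12)
  cfg <- attr(b, "config")
  expect_equal(m$rcv_true, m$hbmass_true / cfg$mchc * 100,
               tolerance = 1e-12)
  # emitted MCHC is internally consistent with hb and hct
  expect_equal(b$blood$mchc, b$blood$hb / b$blood$hct, tolerance = 1e-12)
})

test_that("with every variance source off, hemoglobin is constant per athlete", {
  cfg <- cohort_config(b_pv_atl = 0, pv_seasonal_amp = 0, pv_noise_sd = 0,
                       hb_noise_sd = 0, ret_noise_sd = 0,
                       hypoxia_presets = FALSE, n_athletes = 4)
  b <- generate_cohort(cfg, seed = 2)
  spread <- tapply(b$blood$hb, b$blood$athlete_id,
                   function(x) diff(range(x)))
  expect_true(all(spread < 1e-9))
})

test_that("cohort-level means sit at the configured physiological scale", {
  b <- generate_cohort(cohort_config(), seed = 10)
  m <- b$manifest
  # 2-standard-error plausibility around the configured levels
  expect_lt(abs(mean(m$hbmass_true) - 1030), 2 * 87 / sqrt(10))
  expect_lt(abs(mean(m$pv_true) - 4300), 2.5 * 350 / sqrt(10))
  # athlete-level Hb SD implied by the baselines is ~1 g/dL, so the
  # 10-athlete cohort mean scatters with SE ~0.3
  expect_lt(abs(mean(b$blood$hb) - 14.2), 0.8)
  expect_lt(abs(mean(b$blood$ret_pct) - 1.2), 0.35)
  # sampling intervals emulate the irregular monthly schedule
  gaps <- unlist(tapply(as.Date(b$blood$collection_time),
                        b$blood$athlete_id,
                        function(d) as.numeric(diff(sort(d)))))
  expect_gt(mean(gaps), 24)
  expect_lt(mean(gaps), 40)
  expect_true(all(gaps >= 14))
})

test_that("hypoxia presets reproduce the two canonical exposure doses", {
  b <- generate_cohort(cohort_config(), seed = 3)
  e6 <- b$exposures[b$exposures$athlete_id == "ath06", ]
  e7 <- b$exposures[b$exposures$athlete_id == "ath07", ]
  expect_equal(hypoxic_dose(e6), 1782)
  expect_equal(hypoxic_dose(e7), 972)
  # the Ret% response is visible: exposed athletes' peak Ret% deviation
  # from their own baseline exceeds the cohort's noise scale
  m <- b$manifest
  bump <- tapply(m$ret_true, m$athlete_id, function(x) max(x) - min(x))
  expect_gt(bump[["ath06"]], 0.3)
  expect_gt(bump[["ath07"]], 0.3)
  # hypoxia slowly raises hemoglobin mass
  m7 <- m[m$athlete_id == "ath07", ]
  expect_gt(m7$hbmass_true[12], m7$hbmass_true[1])
})

test_that("the closure-implied slope matches analytic differentiation", {
  b <- generate_cohort(cohort_config(), seed = 5)
  m <- b$manifest
  cfg <- attr(b, "config")
  expect_equal(closure_slope(b),
               mean(-m$hb_true * cfg$b_pv_atl / m$bv_true),
               tolerance = 1e-12)
  expect_lt(closure_slope(b), -0.003)
  expect_gt(closure_slope(b), -0.006)
})

test_that("passport single-flag rate on clean matched cohorts is near 1%", {
  cfg <- cohort_config(n_athletes = 100, hypoxia_presets = FALSE)
  b <- generate_cohort(cfg, seed = 19)
  params <- estimate_marker_params(b$blood, "hb")
  flagged <- 0; total <- 0
  for (d in split(b$blood, b$blood$athlete_id)) {
    prof <- run_passport(params, d$hb, as.Date(d$collection_time))
    flagged <- flagged + sum(prof$atpf_single)
    total <- total + nrow(prof)
  }
  rate <- flagged / total
  expect_gt(rate, 0.001)
  expect_lt(rate, 0.035)
})

test_that("a hemoglobin boost moves the profile toward and past the limits", {
  cfg <- cohort_config(hypoxia_presets = FALSE)
  clean <- generate_cohort(cfg, seed = 9)
  target <- clean$blood[clean$blood$athlete_id == "ath01", ]
  # pick a late sample sitting in the upper half of its band, where a
  # boost must shorten the distance to the (upper) limit
  params0 <- estimate_marker_params(clean$blood, "hb")
  prof0 <- run_passport(params0, target$hb)
  idx <- which(prof0$sample_index >= 5 &
                 prof0$value > (prof0$lower + prof0$upper) / 2)[1]
  day <- as.Date(target$collection_time[idx])

  boosted <- doping_scenario(clean, "hb_boost", 1.5, day, day,
                             athlete_ids = "ath01")
  expect_equal(sum(boosted$blood$perturbed), 1)
  tb <- boosted$blood[boosted$blood$athlete_id == "ath01", ]
  prof_b <- run_passport(params0, tb$hb)
  # the boosted sample moves toward (or past) the upper limit
  expect_true(prof_b$distance[idx] < prof0$distance[idx] ||
                prof_b$atpf_single[idx])

  # zero-magnitude perturbation changes nothing
  same <- doping_scenario(clean, "hb_boost", 0, day, day)
  expect_equal(same$blood$hb, clean$blood$hb)
  expect_false(any(same$blood$perturbed))

  # suppressing Ret% while boosting Hb raises the OFF-score
  supp <- doping_scenario(boosted, "ret_suppression", 0.4, day, day,
                          athlete_ids = "ath01")
  ts <- supp$blood[supp$blood$athlete_id == "ath01", ]
  expect_gt(ts$off_score[idx], target$off_score[idx])

  expect_error(doping_scenario(clean, "hb_boost", 1, "2030-01-01",
                               "2030-02-01"), "outside")
})
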