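#' Configuration of a synthetic monitoring cohort
#'
#' Generative parameters for a one-year elite-cyclist monitoring study:
#' 10 athletes sampled monthly (12 samples, interval 32 +/- 12 days,
#' floor 14), athlete baselines for total hemoglobin mass
#' (Normal(1030, 87^2) g, truncated positive) and plasma volume
#' (Normal(4300, 350^2) mL), a constant cellular MCHC (34 g/dL), an
#' acute-load effect on plasma volume of 2.2 mL per a.u. of 5-day
#' cumulated TSS, a seasonal plasma-volume wave (amplitude 150 mL,
#' mid-summer peak), gamma-distributed daily TSS alternating between
#' high and low 6-week blocks, occasional hypoxic exposure blocks that
#' raise Ret% (lagged) and slowly raise hemoglobin mass, and analyzer
#' noise (Hb 0.1 g/dL, Ret% 0.05).
#'
#' Hemoglobin concentration is never simulated directly: it is derived
#' from hemoglobin mass and the volumes through the physiological
#' closure `Hb = Hbmass / BV(dL)`, `BV = PV + RCV`,
#' `RCV = Hbmass / MCHC x 100`. The negative association between acute
#' load and Hb is therefore an emergent consequence of the
#' plasma-volume effect, with implied slope
#' `-Hb x b_pv_atl / BV(mL)` (about -0.004 g/dL per a.u. at the default
#' scale).
#'
#' @param n_athletes,n_samples Cohort size and samples per athlete.
#' @param interval_mean,interval_sd,interval_min Sampling interval, days.
#' @param study_start First sampling date (Date).
#' @param hbmass_mean,hbmass_sd Baseline hemoglobin mass, g.
#' @param pv_mean,pv_sd Baseline plasma volume, mL.
#' @param mchc Cellular mean hemoglobin concentration, g/dL.
#' @param b_pv_atl Plasma-volume response to acute load, mL per a.u.
#' @param pv_seasonal_amp Seasonal PV amplitude, mL (peak mid-summer).
#' @param pv_noise_sd Day-to-day biological PV noise, mL.
#' @param hb_noise_sd,ret_noise_sd Analyzer noise SDs (g/dL, %).
#' @param ret_mean,ret_between_sd Baseline Ret% level and its
#'   between-athlete SD.
#' @param tss_daily_high,tss_daily_low Mean daily TSS in high/low
#'   blocks, a.u. (for an athlete of average training volume).
#' @param tss_shape Gamma shape of daily TSS.
#' @param rest_prob Probability of a no-training day.
#' @param volume_sd Between-athlete SD of the multiplicative training
#'   volume factor (mean 1), which spreads habitual load and annual
#'   TSS across the cohort.
#' @param block_len_days Length of a high/low training block.
#' @param ftp_mean,ftp_sd Functional threshold power, W.
#' @param body_mass_mean,body_mass_sd Body mass, kg.
#' @param hypoxia_presets Reproduce the two canonical exposure cases
#'   (27 d x 24 h at 2750 m around the 3rd sample of athlete 6 when the
#'   cohort has one; 36 nights x 9 h at 2500->3500 m spanning the 11th
#'   sample of athlete 7).
#' @param ret_response_amp Peak Ret% rise during/after an exposure.
#' @param ret_lag_days,ret_decay_days Onset lag and decay constant of
#'   the Ret% response, days.
#' @param ret_suppress Relative size of the post-exposure Ret% dip.
#' @param hbmass_gain_per_kmh Fractional hemoglobin-mass gain per km·h
#'   of hypoxic dose (delayed by `hbmass_gain_lag_days`).
#' @param hbmass_gain_lag_days Delay of the mass gain, days.
#' @param rebreathing_months Number of trailing sampling occasions with
#'   a CO-rebreathing measurement (device available late in such
#'   studies; default 8 of 12).
#' @param hbco_read_sd SD of one HbCO% analyzer reading, percentage
#'   points (0.14 reproduces a duplicate typical error near 1.8% on
#'   hemoglobin mass).
#' @param f_cell Body/venous hematocrit factor used when emitting
#'   hematocrit; 1 by default (the body/venous distinction is not
#'   simulated, so emitted concentrations close exactly).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_athletes = 10, n_samples = 12,
                          interval_mean = 32, interval_sd = 12,
                          interval_min = 14,
                          study_start = as.Date("2019-01-10"),
                          hbmass_mean = 1030, hbmass_sd = 87,
                          pv_mean = 4300, pv_sd = 350,
                          mchc = 34,
                          b_pv_atl = 2.2,
                          pv_seasonal_amp = 150,
                          pv_noise_sd = 150,
                          hb_noise_sd = 0.1, ret_noise_sd = 0.05,
                          ret_mean = 1.2, ret_between_sd = 0.3,
                          tss_daily_high = 95, tss_daily_low = 72,
                          tss_shape = 16, rest_prob = 0.12,
                          volume_sd = 0.3,
                          block_len_days = 42,
                          ftp_mean = 375, ftp_sd = 25,
                          body_mass_mean = 71.3, body_mass_sd = 4.9,
                          hypoxia_presets = TRUE,
                          ret_response_amp = 0.5,
                          ret_lag_days = 7, ret_decay_days = 30,
                          ret_suppress = 0.15,
                          hbmass_gain_per_kmh = 3e-5,
                          hbmass_gain_lag_days = 14,
                          rebreathing_months = 8,
                          hbco_read_sd = 0.14,
                          f_cell = 1) {
  cfg <- as.list(environment())
  stopifnot(
    n_athletes >= 1, n_samples >= 2,
    hbmass_sd >= 0, pv_sd >= 0, pv_noise_sd >= 0,
    hb_noise_sd >= 0, ret_noise_sd >= 0, hbco_read_sd >= 0,
    interval_min >= 1
  )
  structure(cfg, class = "cohort_config")
}

# Ret% response kernel of one exposure block at day offset(s).
ret_kernel <- function(t, start, end, lag, amp, decay, suppress) {
  t <- as.numeric(t)
  onset <- as.numeric(start) + lag
  off <- as.numeric(end)
  eff <- numeric(length(t))
  ramp <- t >= onset & t <= off
  eff[ramp] <- amp * pmin(1, (t[ramp] - onset) / 14)
  post <- t > off
  u <- (t[post] - off) / decay
  eff[post] <- amp * exp(-u) - suppress * amp * u * exp(-u / 2)
  eff
}

#' Generate a synthetic monitoring study
#'
#' Deterministically (given `config` and `seed`) generates the four
#' linked datasets of a one-year monitoring study — blood samples,
#' CO-rebreathing sessions, training sessions, hypoxic exposures — plus
#' a manifest of the latent truths for recovery tests. At every
#' sampling date the physiological closure holds exactly pre-noise:
#' `PV + RCV = BV` and `Hb x BV(dL) = Hbmass`.
#'
#' @param config A [cohort_config()].
#' @param seed Integer RNG seed.
#' @return A list of tibbles `blood`, `rebreathing`, `sessions`,
#'   `exposures`, `manifest` (per-sample truths), `athletes`
#'   (per-athlete latents), with the config and seed attached as
#'   attributes.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(as.integer(seed))
  cfg <- config
  ids <- sprintf("ath%02d", seq_len(cfg$n_athletes))

  athletes <- tibble::tibble(
    athlete_id = ids,
    hbmass0 = abs(stats::rnorm(cfg$n_athletes, cfg$hbmass_mean,
                               cfg$hbmass_sd)),
    pv0 = stats::rnorm(cfg$n_athletes, cfg$pv_mean, cfg$pv_sd),
    ret0 = pmax(0.5, stats::rnorm(cfg$n_athletes, cfg$ret_mean,
                                  cfg$ret_between_sd)),
    ftp_w = stats::rnorm(cfg$n_athletes, cfg$ftp_mean, cfg$ftp_sd),
    body_mass_kg = stats::rnorm(cfg$n_athletes, cfg$body_mass_mean,
                                cfg$body_mass_sd),
    mcv_fl = stats::rnorm(cfg$n_athletes, 88, 3),
    volume = pmax(0.3, stats::rnorm(cfg$n_athletes, 1, cfg$volume_sd))
  )

  blood <- list(); sessions <- list(); rebreathing <- list()
  exposures <- list(); manifest <- list()

  # habitual acute load implied by each athlete's schedule; the PV
  # response acts on deviations from it so that basePV keeps its meaning
  atl_ref_all <- 5 * (1 - cfg$rest_prob) *
    (cfg$tss_daily_high + cfg$tss_daily_low) / 2 * athletes$volume

  for (a in seq_len(cfg$n_athletes)) {
    ath <- athletes[a, ]
    atl_ref <- atl_ref_all[a]
    gaps <- pmax(cfg$interval_min,
                 round(stats::rnorm(cfg$n_samples - 1, cfg$interval_mean,
                                    cfg$interval_sd)))
    dates <- cfg$study_start + as.integer(sample.int(8, 1) - 1) +
      c(0, cumsum(gaps))

    # -- training calendar: alternating high/low 6-week blocks ----------
    day0 <- min(dates) - 42L
    days <- seq(day0, max(dates) + 6L, by = "day")
    nd <- length(days)
    phase <- sample.int(2L * cfg$block_len_days, 1) - 1L
    high <- ((seq_len(nd) - 1L + phase) %/% cfg$block_len_days) %% 2L == 0L
    mean_tss <- ifelse(high, cfg$tss_daily_high, cfg$tss_daily_low) *
      ath$volume
    rest <- stats::runif(nd) < cfg$rest_prob
    d_tss <- ifelse(rest, 0,
                    stats::rgamma(nd, shape = cfg$tss_shape,
                                  rate = cfg$tss_shape / mean_tss))
    ride <- which(d_tss > 0)
    int_f <- stats::runif(length(ride), 0.65, 0.85)
    np <- int_f * ath$ftp_w
    dur <- d_tss[ride] / (int_f^2 * 100) * 3600
    sessions[[a]] <- tibble::tibble(
      athlete_id = ath$athlete_id,
      start = as.POSIXct(paste(days[ride], "09:00:00"), tz = "UTC"),
      duration_s = dur, np_w = np, ftp_w = ath$ftp_w,
      tss = tss(dur, np, ath$ftp_w)
    )

    cs <- cumsum(c(0, d_tss))
    win_sum <- function(t, span) {
      i_end <- as.integer(t - day0)          # window [t - span, t)
      i_start <- pmax(0L, i_end - span)
      cs[pmin(i_end, nd) + 1L] - cs[i_start + 1L]
    }
    atl <- win_sum(dates, 5L)
    ctl <- win_sum(dates, 42L)

    # -- hypoxic exposures ---------------------------------------------
    expo <- tibble::tibble(athlete_id = character(0),
                           start = as.Date(character(0)),
                           end = as.Date(character(0)),
                           hours_per_day = numeric(0),
                           altitude_m = numeric(0),
                           altitude_end_m = numeric(0))
    if (isTRUE(cfg$hypoxia_presets) && a == 6 && cfg$n_samples >= 3) {
      st <- dates[3] - 37L
      expo <- tibble::add_row(expo, athlete_id = ath$athlete_id,
                              start = st, end = st + 26L,
                              hours_per_day = 24, altitude_m = 2750,
                              altitude_end_m = NA_real_)
    }
    if (isTRUE(cfg$hypoxia_presets) && a == 7 && cfg$n_samples >= 11) {
      st <- dates[11] - 17L
      expo <- tibble::add_row(expo, athlete_id = ath$athlete_id,
                              start = st, end = st + 35L,
                              hours_per_day = 9, altitude_m = 2500,
                              altitude_end_m = 3500)
    }
    exposures[[a]] <- expo

    # cumulative hypoxic dose received by each sampling date (lagged)
    dose_by <- function(t) {
      if (nrow(expo) == 0) return(numeric(length(t)))
      out <- numeric(length(t))
      for (e in seq_len(nrow(expo))) {
        alt <- expo$altitude_m[e]
        if (is.finite(expo$altitude_end_m[e])) {
          alt <- (alt + expo$altitude_end_m[e]) / 2
        }
        d_in <- pmax(0, pmin(as.numeric(t) - as.numeric(expo$start[e]) + 1,
                             as.numeric(expo$end[e] - expo$start[e]) + 1))
        out <- out + d_in * expo$hours_per_day[e] * alt / 1000
      }
      out
    }

    # -- physiological closure at sampling dates -----------------------
    hbm_t <- ath$hbmass0 *
      (1 + cfg$hbmass_gain_per_kmh * dose_by(dates - cfg$hbmass_gain_lag_days))
    doy <- as.integer(format(dates, "%j"))
    season <- cfg$pv_seasonal_amp * cos(2 * pi * (doy - 196) / 365.25)
    pv_t <- ath$pv0 + cfg$b_pv_atl * (atl - atl_ref) + season +
      stats::rnorm(cfg$n_samples, 0, cfg$pv_noise_sd)
    rcv_t <- hbm_t / cfg$mchc * 100
    bv_t <- pv_t + rcv_t
    hb_true <- hbm_t / (bv_t / 100)
    ret_eff <- if (nrow(expo) > 0) {
      Reduce(`+`, lapply(seq_len(nrow(expo)), function(e) {
        ret_kernel(dates, expo$start[e], expo$end[e], cfg$ret_lag_days,
                   cfg$ret_response_amp, cfg$ret_decay_days,
                   cfg$ret_suppress)
      }))
    } else {
      numeric(cfg$n_samples)
    }
    ret_true <- pmax(0.3, ath$ret0 + ret_eff)
    if (any(hb_true <= 5 | hb_true >= 25)) {
      stop("generate_cohort: closure produced non-physiological Hb; check config",
           call. = FALSE)
    }

    hb_obs <- hb_true + stats::rnorm(cfg$n_samples, 0, cfg$hb_noise_sd)
    ret_obs <- pmax(0.1, ret_true + stats::rnorm(cfg$n_samples, 0,
                                                 cfg$ret_noise_sd))
    hct_true <- rcv_t / bv_t / cfg$f_cell
    hct_obs <- hct_true * hb_obs / hb_true  # keeps MCHC consistent
    mch <- hb_obs * 10 / (1000 * hct_obs / ath$mcv_fl)

    blood[[a]] <- tibble::tibble(
      athlete_id = ath$athlete_id,
      collection_time = as.POSIXct(paste(dates, "08:00:00"), tz = "UTC"),
      hb = hb_obs, ret_pct = ret_obs, hct = hct_obs,
      rbc = 1000 * hct_obs / ath$mcv_fl, mcv = ath$mcv_fl, mch = mch,
      mchc = hb_obs / hct_obs,
      off_score = off_score(hb_obs, ret_obs),
      hb_rep1 = hb_obs,
      hb_rep2 = hb_obs + stats::runif(cfg$n_samples, -0.05, 0.05),
      ret_rep1 = ret_obs,
      ret_rep2 = ret_obs + stats::runif(cfg$n_samples, -0.05, 0.05)
    )

    # -- CO-rebreathing sessions (trailing months) ---------------------
    # The rebreathing visit happens 0-5 days after the blood sample
    # (monthly-monitoring logistics); plasma volume is labile on that
    # time scale, so it is re-evaluated at the visit date.
    rb_idx <- seq_len(cfg$n_samples) > cfg$n_samples - cfg$rebreathing_months
    rb_dates <- as.Date(rep(NA, cfg$n_samples))
    pv_rb <- rep(NA_real_, cfg$n_samples)
    atl_rb <- rep(NA_real_, cfg$n_samples)
    if (any(rb_idx)) {
      k <- sum(rb_idx)
      rb_dates[rb_idx] <- dates[rb_idx] +
        (sample.int(6, k, replace = TRUE) - 1L)
      atl_rb[rb_idx] <- win_sum(rb_dates[rb_idx], 5L)
      doy_rb <- as.integer(format(rb_dates[rb_idx], "%j"))
      pv_rb[rb_idx] <- ath$pv0 +
        cfg$b_pv_atl * (atl_rb[rb_idx] - atl_ref) +
        cfg$pv_seasonal_amp * cos(2 * pi * (doy_rb - 196) / 365.25) +
        stats::rnorm(k, 0, cfg$pv_noise_sd)
      rcv_rb <- hbm_t[rb_idx] / cfg$mchc * 100
      bv_rb <- pv_rb[rb_idx] + rcv_rb
      hb_rb <- hbm_t[rb_idx] / (bv_rb / 100) +
        stats::rnorm(k, 0, cfg$hb_noise_sd)
      hct_rb <- (rcv_rb / bv_rb / cfg$f_cell) *
        hb_rb / (hbm_t[rb_idx] / (bv_rb / 100))
      bolus <- 1.5 * ath$body_mass_kg
      unabs <- stats::runif(k, 5, 9)
      p_atm <- stats::rnorm(k, 0.96, 0.01)
      temp <- rep(293.15, k)
      v_l <- co_absorbed_volume(bolus, unabs)
      delta <- delta_hbco_for_hbmass(hbm_t[rb_idx], p_atm, v_l, temp)
      pre <- stats::rnorm(k, 1.0, 0.1)
      noise <- function(n) stats::rnorm(n, 0, cfg$hbco_read_sd)
      rebreathing[[a]] <- tibble::tibble(
        athlete_id = ath$athlete_id, date = rb_dates[rb_idx],
        body_mass_kg = ath$body_mass_kg, co_bolus_ml = bolus,
        co_unabsorbed_ml = unabs,
        hbco_pre_1 = pre + noise(k), hbco_pre_2 = pre + noise(k),
        hbco_pre_3 = pre + noise(k),
        hbco_post_1 = pre + delta + noise(k),
        hbco_post_2 = pre + delta + noise(k),
        hbco_post_3 = pre + delta + noise(k),
        p_atm = p_atm, temp_k = temp,
        hb_gdl = hb_rb, hct = hct_rb
      )
    }

    manifest[[a]] <- tibble::tibble(
      athlete_id = ath$athlete_id, sample_index = seq_len(cfg$n_samples),
      date = dates, atl = atl, ctl = ctl,
      hbmass_true = hbm_t, pv_true = pv_t, rcv_true = rcv_t,
      bv_true = bv_t, hb_true = hb_true, ret_true = ret_true,
      closure_slope = -hb_true * cfg$b_pv_atl / bv_t,
      rb_date = rb_dates, pv_rb_true = pv_rb, atl_rb = atl_rb
    )
  }

  out <- list(
    blood = dplyr::bind_rows(blood),
    rebreathing = dplyr::bind_rows(rebreathing),
    sessions = dplyr::bind_rows(sessions),
    exposures = dplyr::bind_rows(exposures),
    manifest = dplyr::bind_rows(manifest),
    athletes = athletes
  )
  attr(out, "config") <- cfg
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Closure-implied hemoglobin-vs-acute-load slope of a generated cohort
#'
#' Average marginal effect of acute load on hemoglobin concentration
#' implied by the generator's closure,
#' `mean(-Hb_true * b_pv_atl / BV_mL)` over all generated samples —
#' the slope a correctly specified regression should recover.
#'
#' @param bundle A bundle from [generate_cohort()].
#' @return Slope, g/dL per a.u.
#' @export
closure_slope <- function(bundle) {
  mean(bundle$manifest$closure_slope)
}

#' Write a generated cohort to CSV files
#'
#' Emits `blood.csv`, `rebreathing.csv`, `sessions.csv`,
#' `exposures.csv` and `manifest.csv` in the schemas read by the
#' package's readers.
#'
#' @param bundle A bundle from [generate_cohort()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_cohort <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_blood_samples(bundle$blood, file.path(outdir, "blood.csv"))
  sess <- bundle$sessions
  sess$start <- format(sess$start, "%Y-%m-%dT%H:%M:%S")
  readr::write_csv(sess, file.path(outdir, "sessions.csv"))
  readr::write_csv(bundle$rebreathing, file.path(outdir, "rebreathing.csv"))
  readr::write_csv(bundle$exposures, file.path(outdir, "exposures.csv"))
  readr::write_csv(bundle$manifest, file.path(outdir, "manifest.csv"))
  invisible(outdir)
}

#' Apply a blood-manipulation scenario to a generated cohort
#'
#' Additively perturbs observed hemoglobin and/or suppresses Ret% of
#' the blood samples falling in a date window, recomputing the
#' OFF-score; everything else is untouched and perturbed rows carry a
#' `perturbed` provenance flag. Used for sensitivity experiments (e.g.,
#' does a small re-infusion push a profile outside its limits?).
#'
#' @param bundle A bundle from [generate_cohort()].
#' @param scheme `"hb_boost"` or `"ret_suppression"`.
#' @param magnitude Size of the perturbation: g/dL added to Hb, or
#'   percentage points subtracted from Ret%.
#' @param start,end Date window (inclusive) of affected samples.
#' @param athlete_ids Athletes to perturb (default all).
#' @return The perturbed bundle.
#' @export
doping_scenario <- function(bundle, scheme = c("hb_boost",
                                               "ret_suppression"),
                            magnitude, start, end, athlete_ids = NULL) {
  scheme <- match.arg(scheme)
  blood <- bundle$blood
  d <- as.Date(blood$collection_time)
  start <- as.Date(start); end <- as.Date(end)
  if (end < min(d) || start > max(d)) {
    stop("doping_scenario: window lies outside the study dates",
         call. = FALSE)
  }
  sel <- d >= start & d <= end
  if (!is.null(athlete_ids)) sel <- sel & blood$athlete_id %in% athlete_ids
  if (!"perturbed" %in% names(blood)) blood$perturbed <- FALSE
  if (scheme == "hb_boost") {
    blood$hb[sel] <- blood$hb[sel] + magnitude
    for (col in c("hb_rep1", "hb_rep2")) {
      if (col %in% names(blood)) blood[[col]][sel] <-
          blood[[col]][sel] + magnitude
    }
  } else {
    blood$ret_pct[sel] <- pmax(0.05, blood$ret_pct[sel] - magnitude)
    for (col in c("ret_rep1", "ret_rep2")) {
      if (col %in% names(blood)) blood[[col]][sel] <-
          pmax(0.05, blood[[col]][sel] - magnitude)
    }
  }
  blood$off_score[sel] <- off_score(blood$hb[sel], blood$ret_pct[sel])
  blood$perturbed[sel] <- blood$perturbed[sel] | magnitude != 0
  bundle$blood <- blood
  bundle
}
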