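#' Run the full monitoring pipeline
#'
#' End-to-end analysis of a monitoring study: replicate/range quality
#' control, OFF-score computation, adaptive individual passports with
#' atypical-finding flags for Hb, OFF-score and Ret%, CO-rebreathing
#' hemoglobin-mass and volume derivation, acute/chronic load windows,
#' high/low and seasonal load periods, hypoxic dose, mixed-model time
#' and covariate effects, and the plasma-volume vs hemoglobin
#' percent-variation correlation. Re-running on identical inputs gives
#' identical outputs (the pipeline draws no random numbers).
#'
#' @param blood Blood-sample tibble or CSV path (see
#'   [read_blood_samples()]).
#' @param rebreathing Optional rebreathing tibble or CSV path.
#' @param sessions Optional training-session tibble or CSV path.
#' @param exposures Optional hypoxic-exposure tibble or CSV path.
#' @param params Named list of [marker_params()] for `hb`, `off_score`,
#'   `ret_pct`; `"default"` uses [default_marker_params()],
#'   `"estimate"` fits priors to the supplied cohort with
#'   [estimate_marker_params()].
#' @param outdir Optional output directory for the report CSVs and run
#'   log.
#' @param f_cell Body/venous hematocrit factor for volume derivation.
#' @param df_method Denominator-df method for the mixed models.
#' @param baseline Baseline convention for percent-variation series.
#' @return A list with `qc`, `passports`, `flags`, `distance_summary`,
#'   `hbmass`, `loads`, `load_periods`, `time_effects`,
#'   `covariate_effects`, `pv_hb_correlation`, `table1`, `table2`.
#' @export
run_pipeline <- function(blood, rebreathing = NULL, sessions = NULL,
                         exposures = NULL, params = "default",
                         outdir = NULL, f_cell = 0.91,
                         df_method = "residual",
                         baseline = "previous") {
  if (is.character(blood)) blood <- read_blood_samples(blood)
  if (is.character(rebreathing)) rebreathing <- read_rebreathing(rebreathing)
  if (is.character(sessions)) sessions <- read_sessions(sessions)
  if (is.character(exposures)) exposures <- read_exposures(exposures)

  qc <- blood_qc(blood)
  if (nrow(qc$quarantined) > 0) {
    warning(sprintf("run_pipeline: %d sample(s) quarantined by QC",
                    nrow(qc$quarantined)), call. = FALSE)
  }
  clean <- qc$clean
  clean$off_score <- off_score(clean$hb, clean$ret_pct)
  clean <- dplyr::arrange(clean, .data$athlete_id, .data$collection_time)
  clean <- dplyr::mutate(
    dplyr::group_by(clean, .data$athlete_id),
    sample_index = dplyr::row_number(), .before = 2
  )
  clean <- dplyr::ungroup(clean)

  if (identical(params, "default")) {
    params <- default_marker_params()
  } else if (identical(params, "estimate")) {
    params <- list(
      hb = estimate_marker_params(clean, "hb"),
      off_score = estimate_marker_params(clean, "off_score"),
      ret_pct = estimate_marker_params(clean, "ret_pct",
                                       transform = "log")
    )
  }

  passports <- dplyr::bind_rows(lapply(names(params), function(mk) {
    dplyr::bind_rows(lapply(split(clean, clean$athlete_id), function(d) {
      prof <- run_passport(params[[mk]], d[[mk]],
                           as.Date(d$collection_time))
      prof$athlete_id <- d$athlete_id[1]
      prof$marker <- mk
      prof
    }))
  }))
  flags <- dplyr::filter(passports, .data$atpf_single |
                           .data$atpf_sequence)
  distance_summary <- lapply(
    stats::setNames(nm = intersect(c("hb", "off_score"), names(params))),
    function(mk) {
      summarize_distances(passports$distance[passports$marker == mk])
    }
  )

  hbm <- if (!is.null(rebreathing) && nrow(rebreathing) > 0) {
    hbmass_table(rebreathing, f_cell = f_cell)
  } else {
    NULL
  }

  loads <- NULL; load_periods <- NULL
  if (!is.null(sessions) && nrow(sessions) > 0) {
    anchors <- tibble::tibble(athlete_id = clean$athlete_id,
                              sample_index = clean$sample_index,
                              date = as.Date(clean$collection_time))
    loads <- load_at_anchors(sessions, anchors)
    load_periods <- dplyr::bind_rows(lapply(
      split(sessions, sessions$athlete_id), function(s) {
        dts <- daily_tss(s)
        per <- tryCatch(extreme_periods(dts), error = function(e) NULL)
        seas <- suppressWarnings(seasonal_load(dts))
        dose <- if (!is.null(exposures)) {
          hypoxic_dose(exposures[exposures$athlete_id ==
                                   s$athlete_id[1], , drop = FALSE])
        } else {
          0
        }
        tibble::tibble(
          athlete_id = s$athlete_id[1],
          total_tss = sum(s$tss),
          high_tss = if (is.null(per)) NA_real_ else per$high$tss,
          high_start = if (is.null(per)) as.Date(NA) else per$high$start,
          low_tss = if (is.null(per)) NA_real_ else per$low$tss,
          low_start = if (is.null(per)) as.Date(NA) else per$low$start,
          winter_tss = seas$winter, summer_tss = seas$summer,
          hypoxic_dose_kmh = dose
        )
      }
    ))
  }

  markers <- intersect(c("hb", "off_score", "ret_pct"), names(clean))
  time_effects <- dplyr::bind_rows(lapply(markers, function(mk) {
    te <- mixed_time_effect(
      tibble::tibble(athlete_id = clean$athlete_id,
                     occasion = clean$sample_index,
                     value = clean[[mk]]),
      df_method = df_method
    )
    tibble::tibble(marker = mk, f = te$f, df1 = te$df1, df2 = te$df2,
                   p = te$p)
  }))

  covariate_effects <- NULL
  pv_hb_corr <- NULL
  if (!is.null(loads)) {
    joined <- dplyr::left_join(
      clean, loads, by = c("athlete_id", "sample_index")
    )
    specs <- expand.grid(marker = markers, covariate = c("atl", "ctl"),
                         stringsAsFactors = FALSE)
    covariate_effects <- dplyr::bind_rows(lapply(
      seq_len(nrow(specs)), function(i) {
        mk <- specs$marker[i]; cv <- specs$covariate[i]
        eff <- covariate_effect(
          tibble::tibble(athlete_id = joined$athlete_id,
                         value = joined[[mk]], load = joined[[cv]]),
          df_method = df_method
        )
        dplyr::mutate(eff, marker = mk, covariate = cv, .before = 1)
      }
    ))
    if (!is.null(hbm)) {
      # pair each rebreathing-derived PV with the nearest blood sample
      # (within 7 days); the PV~load model uses the acute load at the
      # rebreathing date itself
      rb <- hbm[is.finite(hbm$pv_ml), , drop = FALSE]
      rb_loads <- load_at_anchors(
        sessions, tibble::tibble(athlete_id = rb$athlete_id,
                                 date = rb$date),
        spans = c(atl = 5)
      )
      blood_dates <- dplyr::transmute(
        joined, .data$athlete_id,
        blood_date = as.Date(.data$collection_time), hb = .data$hb
      )
      pv <- dplyr::bind_rows(lapply(seq_len(nrow(rb)), function(i) {
        cand <- blood_dates[blood_dates$athlete_id == rb$athlete_id[i], ]
        if (nrow(cand) == 0) return(NULL)
        gap <- abs(as.numeric(cand$blood_date - rb$date[i]))
        j <- which.min(gap)
        if (gap[j] > 7) return(NULL)
        tibble::tibble(athlete_id = rb$athlete_id[i], date = rb$date[i],
                       hb = cand$hb[j], atl = rb_loads$atl[i],
                       pv_ml = rb$pv_ml[i])
      }))
      enough <- names(which(table(pv$athlete_id) >= 2))
      pv <- pv[pv$athlete_id %in% enough, , drop = FALSE]
      if (nrow(pv) >= 4 && length(enough) >= 2) {
        pv_eff <- covariate_effect(
          tibble::tibble(athlete_id = pv$athlete_id, value = pv$pv_ml,
                         load = pv$atl),
          df_method = df_method
        )
        covariate_effects <- dplyr::bind_rows(
          covariate_effects,
          dplyr::mutate(pv_eff, marker = "pv_ml", covariate = "atl",
                        .before = 1)
        )
        hb_pct <- pct_change_series(
          tibble::tibble(athlete_id = pv$athlete_id, value = pv$hb),
          baseline = baseline
        )
        pv_pct <- pct_change_series(
          tibble::tibble(athlete_id = pv$athlete_id, value = pv$pv_ml),
          baseline = baseline
        )
        if (nrow(hb_pct) >= 3) {
          pv_hb_corr <- pearson_corr(pv_pct$pct, hb_pct$pct)
        }
      }
    }
  }

  table1 <- build_table1(clean, hbm, loads, load_periods)
  table2 <- build_table2(clean, hbm, loads, load_periods, sessions)

  report <- list(
    qc = qc, passports = passports, flags = flags,
    distance_summary = distance_summary, hbmass = hbm, loads = loads,
    load_periods = load_periods, time_effects = time_effects,
    covariate_effects = covariate_effects,
    pv_hb_correlation = pv_hb_corr, table1 = table1, table2 = table2
  )
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

# Table-1-style long summary: per-athlete means +/- SD and cohort row.
build_table1 <- function(clean, hbm, loads, load_periods) {
  long <- tidyr::pivot_longer(
    dplyr::select(clean, "athlete_id",
                  dplyr::any_of(c("hb", "off_score", "ret_pct", "abps"))),
    -"athlete_id", names_to = "variable", values_to = "value"
  )
  if (!is.null(hbm)) {
    long <- dplyr::bind_rows(long, tidyr::pivot_longer(
      dplyr::select(hbm, "athlete_id", hbmass = "hbmass_g", pv = "pv_ml"),
      -"athlete_id", names_to = "variable", values_to = "value"
    ))
  }
  if (!is.null(loads)) {
    long <- dplyr::bind_rows(long, tidyr::pivot_longer(
      dplyr::select(loads, "athlete_id", "atl", "ctl"),
      -"athlete_id", names_to = "variable", values_to = "value"
    ))
  }
  if (!is.null(load_periods)) {
    long <- dplyr::bind_rows(long, tibble::tibble(
      athlete_id = load_periods$athlete_id, variable = "total_tss",
      value = load_periods$total_tss
    ))
  }
  long <- long[is.finite(long$value), , drop = FALSE]
  cohort_table(long)
}

# Table-2-style summary: cohort marker means in summer vs winter and in
# the high- vs low-load 12-week periods, with percent change
# (reference: summer, resp. high load).
build_table2 <- function(clean, hbm, loads, load_periods, sessions) {
  if (is.null(load_periods) || is.null(sessions)) return(NULL)
  d <- dplyr::mutate(clean, date = as.Date(.data$collection_time),
                     month = as.integer(format(.data$date, "%m")))
  vars <- intersect(c("hb", "off_score", "ret_pct", "abps"), names(clean))
  in_period <- function(df, starts, span = 84L) {
    sel <- rep(FALSE, nrow(df))
    for (i in seq_len(nrow(load_periods))) {
      s <- starts[i]
      if (is.na(s)) next
      sel <- sel | (df$athlete_id == load_periods$athlete_id[i] &
                      df$date >= s & df$date < s + span)
    }
    sel
  }
  cohort_mean <- function(df, sel, var) {
    per <- tapply(df[[var]][sel], df$athlete_id[sel], mean, na.rm = TRUE)
    mean(per, na.rm = TRUE)
  }
  rows <- lapply(vars, function(v) {
    su <- cohort_mean(d, d$month %in% c(6, 7, 8), v)
    wi <- cohort_mean(d, d$month %in% c(12, 1, 2), v)
    hi <- cohort_mean(d, in_period(d, load_periods$high_start), v)
    lo <- cohort_mean(d, in_period(d, load_periods$low_start), v)
    tibble::tibble(
      variable = v, summer = su, winter = wi,
      season_change_pct = round(percent_change(su, wi), 1),
      high_load = hi, low_load = lo,
      load_change_pct = round(percent_change(hi, lo), 1)
    )
  })
  su_tss <- mean(load_periods$summer_tss, na.rm = TRUE)
  wi_tss <- mean(load_periods$winter_tss, na.rm = TRUE)
  hi_tss <- mean(load_periods$high_tss, na.rm = TRUE)
  lo_tss <- mean(load_periods$low_tss, na.rm = TRUE)
  rows <- c(rows, list(tibble::tibble(
    variable = "tss", summer = su_tss, winter = wi_tss,
    season_change_pct = round(percent_change(su_tss, wi_tss), 1),
    high_load = hi_tss, low_load = lo_tss,
    load_change_pct = round(percent_change(hi_tss, lo_tss), 1)
  )))
  dplyr::bind_rows(rows)
}

# Write the report bundle as CSV files plus a run log.
write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$passports, file.path(outdir, "passports.csv"))
  for (ath in unique(report$passports$athlete_id)) {
    for (mk in unique(report$passports$marker)) {
      sub <- report$passports[report$passports$athlete_id == ath &
                                report$passports$marker == mk, ]
      readr::write_csv(
        dplyr::select(sub, "sample_index", "date", "value", "lower",
                      "upper", "distance", "atpf_single",
                      "atpf_sequence"),
        file.path(outdir, sprintf("passport_%s_%s.csv", ath, mk))
      )
    }
  }
  readr::write_csv(report$table1, file.path(outdir, "table1.csv"))
  if (!is.null(report$table2)) {
    readr::write_csv(report$table2, file.path(outdir, "table2.csv"))
  }
  if (!is.null(report$hbmass)) {
    readr::write_csv(report$hbmass, file.path(outdir, "hbmass.csv"))
  }
  if (!is.null(report$loads)) {
    readr::write_csv(report$loads, file.path(outdir, "loads.csv"))
  }
  readr::write_csv(report$time_effects,
                   file.path(outdir, "time_effects.csv"))
  if (!is.null(report$covariate_effects)) {
    readr::write_csv(report$covariate_effects,
                     file.path(outdir, "covariate_effects.csv"))
  }
  if (!is.null(report$pv_hb_correlation)) {
    readr::write_csv(
      tibble::tibble(r = report$pv_hb_correlation$r,
                     p = report$pv_hb_correlation$p,
                     n = report$pv_hb_correlation$n),
      file.path(outdir, "pv_hb_correlation.csv")
    )
  }
  log <- c(
    sprintf("run_time: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    sprintf("package_version: %s",
            as.character(utils::packageVersion("abpmonitor"))),
    sprintf("input_hash: %s", rlang::hash(report$passports$value)),
    sprintf("n_samples: %d", nrow(report$qc$clean)),
    sprintf("n_quarantined: %d", nrow(report$qc$quarantined)),
    sprintf("n_atpf: %d", nrow(report$flags))
  )
  writeLines(log, file.path(outdir, "run_log.txt"))
  invisible(outdir)
}
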