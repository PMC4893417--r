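## Per-patient derived metrics from raw perioperative data.  All repeated
## measurements are summarised as areas under the curve by the trapezoidal
## method, accounting for both magnitude and duration of the deviation and
## optionally adjusted for (divided by) the monitoring duration.

## clip a sampled series to a window, interpolating values at the edges
clip_to_window <- function(time_h, value, window) {
  if (is.unsorted(time_h, strictly = TRUE))
    stop2("sample times must be strictly increasing")
  if (!is.null(window)) {
    if (window[2] <= window[1]) stop2("window end must exceed window start")
    lo <- window[1]; hi <- window[2]
    inside <- time_h >= lo & time_h <= hi
    t2 <- time_h[inside]; v2 <- value[inside]
    if (any(time_h < lo) && (!length(t2) || t2[1] > lo)) {
      t2 <- c(lo, t2); v2 <- c(stats::approx(time_h, value, lo)$y, v2)
    }
    if (any(time_h > hi) && (!length(t2) || t2[length(t2)] < hi)) {
      t2 <- c(t2, hi); v2 <- c(v2, stats::approx(time_h, value, hi)$y)
    }
    time_h <- t2; value <- v2
  }
  if (length(time_h) < 2L)
    stop2("need at least 2 samples inside the monitoring window")
  list(time_h = time_h, value = value)
}

#' Trapezoidal area under the curve
#'
#' Integrates a sampled trajectory by the trapezoidal rule over a
#' monitoring window.  Samples outside the window are clipped, with linear
#' interpolation at the window edges.  With `normalize = TRUE` the integral
#' is divided by the window length, yielding the time-averaged value.
#'
#' @param time_h sample times in hours, strictly increasing.
#' @param value sampled values.
#' @param window `c(start_h, end_h)`; `NULL` uses the sampled range.
#' @param normalize divide by the monitoring duration?
#' @return a single number (value x hours, or the mean value if normalized).
#' @examples
#' trapezoid_auc(c(0, 2), c(0, 4))                    # triangle, area 4
#' trapezoid_auc(c(0, 12, 24), c(5, 5, 5), normalize = TRUE)  # constant 5
#' @export
trapezoid_auc <- function(time_h, value, window = NULL, normalize = FALSE) {
  s <- clip_to_window(time_h, value, window)
  auc <- sum(diff(s$time_h) * (utils::head(s$value, -1) + utils::tail(s$value, -1)) / 2)
  if (normalize) auc <- auc / (s$time_h[length(s$time_h)] - s$time_h[1])
  auc
}

#' Threshold-deficit area under the curve
#'
#' Integral of the excursion of a trajectory below (or above) a threshold,
#' with exact linear-interpolation crossing points, e.g. the oliguria
#' burden as the area of urine output below 0.5, 1 or 2 ml/kg/h, or an
#' arterial-pressure deficit below an age-stratum quintile.
#'
#' @inheritParams trapezoid_auc
#' @param threshold threshold value.
#' @param direction `"below"` integrates `max(0, threshold - value)`,
#'   `"above"` integrates `max(0, value - threshold)`.
#' @return deficit area (value x hours), always non-negative.
#' @examples
#' # crosses 0.5 at t = 1: triangle of height 0.5 over 1 h
#' threshold_deficit_auc(c(0, 2), c(1, 0), threshold = 0.5)
#' @export
threshold_deficit_auc <- function(time_h, value, threshold,
                                  direction = c("below", "above"),
                                  window = NULL) {
  direction <- match.arg(direction)
  s <- clip_to_window(time_h, value, window)
  dev <- if (direction == "below") threshold - s$value else s$value - threshold
  t <- s$time_h
  total <- 0
  for (i in seq_len(length(t) - 1L)) {
    d1 <- dev[i]; d2 <- dev[i + 1L]; dt <- t[i + 1L] - t[i]
    if (d1 >= 0 && d2 >= 0) {
      total <- total + dt * (d1 + d2) / 2
    } else if (d1 > 0 && d2 < 0) {
      total <- total + dt * d1^2 / (2 * (d1 - d2))
    } else if (d1 < 0 && d2 > 0) {
      total <- total + dt * d2^2 / (2 * (d2 - d1))
    }
  }
  total
}

#' Age-stratified first-quintile pressure thresholds
#'
#' Pools all post-operative arterial-pressure samples within each age
#' stratum (2 days of age or less; 3 to 28 days; older than 28 days) and
#' returns the 20th percentile per stratum (linear-interpolation
#' percentile).  The downstream pressure-deficit AUC of a patient uses the
#' threshold of that patient's stratum.
#'
#' @param timeseries long data frame (`patient_id`, `variable`, `time_h`,
#'   `value`).
#' @param age_days named or ordered numeric vector of ages, one per
#'   `patient_id` present in the series.
#' @param variable which pressure series to pool (default `"sap"`).
#' @param prob quantile level of the threshold (default 0.20, the first
#'   quintile).
#' @param window monitoring window in hours (default 0-24).
#' @return data frame `stratum`, `threshold`, `n_samples`; an empty stratum
#'   yields an `NA` threshold with a warning.
#' @export
pressure_quintile_thresholds <- function(timeseries, age_days,
                                         variable = "sap", prob = 0.20,
                                         window = c(0, 24)) {
  ser <- timeseries[timeseries$variable == variable &
                      timeseries$time_h >= window[1] &
                      timeseries$time_h <= window[2], , drop = FALSE]
  ids <- unique(timeseries$patient_id)
  if (is.null(names(age_days))) names(age_days) <- ids
  stratum_of <- function(a) ifelse(a <= 2, "<=2d", ifelse(a <= 28, "3-28d", ">28d"))
  strata <- c("<=2d", "3-28d", ">28d")
  ser$stratum <- stratum_of(age_days[as.character(ser$patient_id)])
  out <- data.frame(stratum = strata, threshold = NA_real_, n_samples = 0L)
  for (i in seq_along(strata)) {
    v <- ser$value[ser$stratum == strata[i]]
    out$n_samples[i] <- length(v)
    if (length(v)) out$threshold[i] <- as.numeric(stats::quantile(v, prob, type = 7))
  }
  if (any(is.na(out$threshold)))
    warning("empty age stratum: ", paste(out$stratum[is.na(out$threshold)],
                                         collapse = ", "), call. = FALSE)
  out
}

#' Creatinine variation metrics
#'
#' Summarises the post-operative serum creatinine trajectory relative to
#' its pre-operative baseline: the duration-adjusted AUC of the relative
#' variation `sCr/baseline - 1`, and the (unadjusted) AUC of the excursion
#' above a >50\% increase, i.e. the integral of
#' `max(0, sCr/baseline - 1.5)`, accounting for both the magnitude and the
#' duration of the increase.
#'
#' @inheritParams trapezoid_auc
#' @param scr serum creatinine samples.
#' @param baseline pre-operative serum creatinine (same units), positive.
#' @return list with `rel_auc` (mean relative variation, dimensionless) and
#'   `gt50_auc` (excess x hours above the 1.5 x baseline line).
#' @examples
#' delta_scr_metrics(c(0, 24), c(60, 60), baseline = 30)  # doubled: (1, 12)
#' @export
delta_scr_metrics <- function(time_h, scr, baseline, window = NULL) {
  if (!is.numeric(baseline) || baseline <= 0)
    stop2("'baseline' creatinine must be positive")
  rel <- scr / baseline - 1
  list(rel_auc = trapezoid_auc(time_h, rel, window, normalize = TRUE),
       gt50_auc = threshold_deficit_auc(time_h, scr / baseline, 1.5,
                                        direction = "above", window = window))
}

#' Vasoactive-inotropic score
#'
#' Weighted sum of vasoactive drug infusion rates:
#' dopamine + dobutamine + 100 x epinephrine + 100 x norepinephrine +
#' 10 x milrinone + 10000 x vasopressin.  All rates in ug/kg/min except
#' vasopressin in U/kg/min.
#'
#' @param dopamine,dobutamine,epinephrine,norepinephrine,milrinone,vasopressin
#'   infusion rates (vectors recycle in the usual way).
#' @return numeric score.
#' @examples
#' vis_score(dopamine = 5, milrinone = 0.5)   # 10
#' @export
vis_score <- function(dopamine = 0, dobutamine = 0, epinephrine = 0,
                      norepinephrine = 0, milrinone = 0, vasopressin = 0) {
  rates <- cbind(dopamine, dobutamine, epinephrine, norepinephrine,
                 milrinone, vasopressin)
  if (any(rates < 0)) stop2("infusion rates must be non-negative")
  as.numeric(dopamine + dobutamine + 100 * epinephrine +
               100 * norepinephrine + 10 * milrinone + 10000 * vasopressin)
}

#' Composite pre-operative history score
#'
#' One point for each of eight pre-operative conditions: need for
#' resuscitation; mechanical ventilation; inotropic support; infection;
#' enterocolitis; pulmonary hypertension; exposure to nephrotoxic drugs,
#' diuretics or intravenous contrast; and an identified genetic syndrome.
#'
#' @param flags logical/0-1 vector (one patient) or data frame / matrix with
#'   one column per condition and one row per patient.
#' @return integer score(s), 0 to the number of conditions supplied.
#' @export
composite_preop_score <- function(flags) {
  if (is.data.frame(flags) || is.matrix(flags))
    return(as.integer(rowSums(as.matrix(flags) != 0)))
  as.integer(sum(flags != 0))
}

#' AKIN stage from the creatinine trajectory
#'
#' Stages acute kidney injury by the Acute Kidney Injury Network creatinine
#' criteria within 48 h of surgery: stage 1 for a rise to at least 150\% of
#' baseline or an absolute rise of at least 0.3 mg/dl; stage 2 above 200\%;
#' stage 3 above 300\% or any renal replacement therapy.  Urine-output
#' criteria are not applied; oliguria enters the analysis as its own
#' metric.
#'
#' @inheritParams delta_scr_metrics
#' @param dialysis any renal replacement therapy (logical).
#' @param window staging window in hours (default 0-48).
#' @param abs_rise_mgdl absolute-rise criterion in mg/dl (default 0.3).
#' @param umol_per_mgdl unit conversion when `scr` is in umol/L (default
#'   88.4; set to 1 when working in mg/dl).
#' @return integer stage 0-3.
#' @examples
#' akin_stage(c(0, 24, 48), c(30, 50, 72), baseline = 30)   # 2.4x -> stage 2
#' @export
akin_stage <- function(time_h, scr, baseline, dialysis = FALSE,
                       window = c(0, 48), abs_rise_mgdl = 0.3,
                       umol_per_mgdl = 88.4) {
  if (missing(baseline) || is.null(baseline) || is.na(baseline))
    stop2("baseline creatinine is required for AKIN staging")
  if (baseline <= 0) stop2("'baseline' creatinine must be positive")
  if (isTRUE(dialysis) || (is.numeric(dialysis) && any(dialysis != 0)))
    return(3L)
  keep <- time_h >= window[1] & time_h <= window[2]
  if (!any(keep)) return(0L)
  peak <- max(scr[keep])
  ratio <- peak / baseline
  abs_rise <- (peak - baseline) / umol_per_mgdl
  if (ratio > 3) 3L
  else if (ratio > 2) 2L
  else if (ratio >= 1.5 || abs_rise >= abs_rise_mgdl) 1L
  else 0L
}

#' Fluid balance over the first post-operative day
#'
#' `(intake - output) / weight`, in ml/kg/24h; negative values indicate net
#' fluid loss.
#'
#' @param in_ml fluid intake (ml).
#' @param out_ml fluid output (ml).
#' @param weight_kg body weight (kg), positive.
#' @return numeric balance.
#' @examples
#' fluid_balance(100, 240, 5)   # -28
#' @export
fluid_balance <- function(in_ml, out_ml, weight_kg) {
  if (any(weight_kg <= 0)) stop2("'weight_kg' must be positive")
  (in_ml - out_ml) / weight_kg
}

#' Derive the full per-patient metric table
#'
#' Applies every derived-variable definition to a raw cohort (long-format
#' time series plus static records): the three uNGAL excretion metrics over
#' 12 h, the three oliguria deficit areas over 24 h (<0.5, <1, <2 ml/kg/h),
#' the creatinine variation metrics and the AKIN stage over 48 h, the
#' systolic and mean arterial-pressure deficits below the age-stratum first
#' quintile over 24 h, the lactate AUC, the vasoactive-inotropic score, the
#' fluid balance, and the composite pre-operative score, alongside the
#' static operative and outcome variables.
#'
#' @param timeseries long data frame (`patient_id`, `variable`, `time_h`,
#'   `value`), as produced by [simulate_timeseries()] or read from CSV.
#' @param static per-patient static table (same `patient_id`s).
#' @return data frame of derived variables, one row per patient.
#' @export
derive_metrics <- function(timeseries, static) {
  ids <- static$patient_id
  ## split once by patient for linear-time lookup
  by_pat <- split(timeseries[c("variable", "time_h", "value")],
                  timeseries$patient_id)
  get <- function(id, var) {
    pat <- by_pat[[as.character(id)]]
    s <- pat[pat$variable == var, c("time_h", "value")]
    s[order(s$time_h), ]
  }
  sap_thr <- pressure_quintile_thresholds(timeseries,
                                          stats::setNames(static$age_days, ids),
                                          variable = "sap")
  map_thr <- pressure_quintile_thresholds(timeseries,
                                          stats::setNames(static$age_days, ids),
                                          variable = "map")
  stratum_of <- function(a) ifelse(a <= 2, "<=2d", ifelse(a <= 28, "3-28d", ">28d"))
  out <- lapply(seq_along(ids), function(i) {
    id <- ids[i]
    uo <- get(id, "urine_output")
    scr <- get(id, "scr")
    ung_n <- get(id, "ungal_norm")
    ung_c <- get(id, "ungal_conc")
    lac <- get(id, "lactate")
    sap <- get(id, "sap")
    map <- get(id, "map")
    ds <- delta_scr_metrics(c(0, scr$time_h), c(static$baseline_scr[i], scr$value),
                            baseline = static$baseline_scr[i], window = c(0, 48))
    str <- stratum_of(static$age_days[i])
    ## uNGAL excretion rate (ug/h) = concentration x urine flow (L/h)
    flow <- stats::approx(uo$time_h, uo$value, xout = ung_c$time_h, rule = 2)$y *
      static$weight_kg[i] / 1000
    data.frame(
      patient_id = id,
      ungal = trapezoid_auc(ung_n$time_h, ung_n$value, c(0, 12), normalize = TRUE),
      ungal_conc = trapezoid_auc(ung_c$time_h, ung_c$value, c(0, 12), normalize = TRUE),
      ungal_rate = trapezoid_auc(ung_c$time_h, ung_c$value * flow, c(0, 12),
                                 normalize = TRUE),
      oliguria = threshold_deficit_auc(uo$time_h, uo$value, 0.5, "below", c(0, 24)),
      oliguria_1 = threshold_deficit_auc(uo$time_h, uo$value, 1, "below", c(0, 24)),
      oliguria_2 = threshold_deficit_auc(uo$time_h, uo$value, 2, "below", c(0, 24)),
      mean_urine_output = trapezoid_auc(uo$time_h, uo$value, c(0, 24), normalize = TRUE),
      dscr_rel = ds$rel_auc,
      dscr50 = ds$gt50_auc,
      akin_stage = akin_stage(scr$time_h, scr$value, static$baseline_scr[i],
                              dialysis = static$dialysis[i]),
      sap = threshold_deficit_auc(sap$time_h, sap$value,
                                  sap_thr$threshold[sap_thr$stratum == str],
                                  "below", c(0, 24)),
      map = threshold_deficit_auc(map$time_h, map$value,
                                  map_thr$threshold[map_thr$stratum == str],
                                  "below", c(0, 24)),
      lactate = trapezoid_auc(lac$time_h, lac$value, c(0, 48), normalize = TRUE),
      vis = vis_score(static$dopamine[i], static$dobutamine[i],
                      static$epinephrine[i], static$norepinephrine[i],
                      static$milrinone[i], static$vasopressin[i]),
      fluid_balance = fluid_balance(static$fluid_in_ml[i], static$fluid_out_ml[i],
                                    static$weight_kg[i]),
      preop_score = composite_preop_score(static[i, grep("^preop_", names(static))])
    )
  })
  met <- do.call(rbind, out)
  keep <- c("age_days", "weight_kg", "dur_cpb", "cross_clamp",
            "ultrafiltration", "transfusions", "vent_days", "icu_days",
            "mortality")
  met <- cbind(met, static[match(met$patient_id, static$patient_id), keep])
  names(met)[names(met) == "age_days"] <- "age"
  rownames(met) <- NULL
  met
}
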