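## Raw-level emulation of the perioperative record.  Only the induced
## correlation structure is contractual: each derived metric is anchored to
## a standardized target value drawn from the same measurement model as the
## indicator matrix, and the curve shapes (piecewise trends plus noise) are
## package inventions.

## standardized indicator targets including residual arcs (continuous
## mortality propensity); shares the machinery of simulate_indicators
indicator_targets <- function(latents, config) {
  lo <- config$loadings
  n <- nrow(latents)
  sde2 <- pmax(1 - lo$value^2, 1e-6)
  S_e <- diag(sde2)
  dimnames(S_e) <- list(lo$indicator, lo$indicator)
  rc <- config$residual_correlations
  if (!is.null(rc) && nrow(rc))
    for (i in seq_len(nrow(rc))) {
      a <- rc$a[i]; b <- rc$b[i]
      S_e[a, b] <- S_e[b, a] <- rc$value[i] * sqrt(S_e[a, a] * S_e[b, b])
    }
  Z <- as.matrix(latents[, lo$latent, drop = FALSE]) %*% diag(lo$value) +
    rmvnorm_chol(n, S_e)
  colnames(Z) <- lo$indicator
  Z
}

#' Simulate raw perioperative time series and static records
#'
#' Generates, for each patient, serum creatinine, urine output, systolic and
#' mean arterial pressure, lactate and urine NGAL trajectories on the
#' configured time grids, together with a static record (age, weight,
#' operative characteristics, vasoactive infusion rates, fluid totals,
#' pre-operative history flags, dialysis and outcome fields).  The curves
#' are constructed so that the derived metrics of [derive_metrics()]
#' correlate with the generating latent constructs in the direction and
#' approximate strength of the measurement model: a patient's curve level is
#' anchored to a standardized target drawn as loading x latent + unique
#' noise, mapped to clinical scale, and decorated with within-curve noise.
#'
#' @param latents data frame from [simulate_latents()].
#' @param config the matching [cohort_config()].
#' @return list with `timeseries` (long data frame: `patient_id`,
#'   `variable`, `time_h`, `value`) and `static` (one row per patient).
#' @examples
#' cfg <- cohort_config(n_patients = 20, seed = 3)
#' raw <- simulate_timeseries(simulate_latents(cfg), cfg)
#' head(raw$timeseries)
#' @export
simulate_timeseries <- function(latents, config) {
  stopifnot(inherits(config, "cohort_config"))
  grid <- config$time_grid
  if (any(!lengths(grid)))
    stop2("empty time grid for: ",
          paste(names(grid)[!lengths(grid)], collapse = ", "))
  if (!is.null(config$seed)) set.seed(config$seed + 2L)
  n <- nrow(latents)
  Z <- indicator_targets(latents, config)
  AKI <- latents$AKI; LCOS <- latents$LCOS
  ## shared renal residual component: the creatinine, oliguria and uNGAL
  ## trajectories of one patient all reflect the same injured kidney, so
  ## their patient-level anchors share variance beyond the AKI construct
  ## (the indicator-level model leaves this residual structure unreported).
  ## Mixing weight 0.75 keeps each anchor's loading direction intact while
  ## giving the derived renal metrics the within-factor clustering seen in
  ## real cohorts (the threshold-deficit metrics are zero-inflated, which
  ## attenuates their correlations well below the anchor level).
  renal <- stats::rnorm(n)
  w <- 0.75
  for (v in c("ungal", "dscr50", "oliguria"))
    Z[, v] <- sqrt(1 - w^2) * Z[, v] + w * renal

  rn <- function(sd = 1) stats::rnorm(n, sd = sd)
  ## ---- static record -------------------------------------------------
  age_days <- pmax(1, round(95.8 + 91.1 * Z[, "age"]))
  weight_kg <- round(pmax(1.8, 4.4 + 1.5 * rn()), 1)
  static <- data.frame(
    patient_id = latents$patient_id,
    age_days = age_days,
    weight_kg = weight_kg,
    baseline_scr = round(pmax(15, 30 + 6 * rn()), 1),
    dur_cpb = round(pmax(15, 118.2 + 63.0 * Z[, "dur_cpb"]), 1),
    cross_clamp = round(pmax(5, 62.9 + 33.9 * Z[, "cross_clamp"]), 1),
    ultrafiltration = round(pmax(0.1, 1.4 + 0.6 * Z[, "ultrafiltration"]), 2),
    transfusions = round(pmax(0, 752.8 + 196 * Z[, "transfusions"]), 0),
    dopamine = round(pmax(0, 8 + 4 * (0.6 * LCOS + rn(0.8))), 2),
    dobutamine = 0,
    epinephrine = round(pmax(0, 0.02 + 0.03 * (0.5 * LCOS + rn(0.85))), 3),
    norepinephrine = 0,
    milrinone = round(pmax(0, 0.4 + 0.2 * (0.5 * LCOS + rn(0.85))), 2),
    vasopressin = 0,
    preop_resuscitation = stats::rbinom(n, 1, 0.01),
    preop_mechanical_ventilation = stats::rbinom(n, 1, 0.055),
    preop_inotropic_support = stats::rbinom(n, 1, 0.015),
    preop_infection = stats::rbinom(n, 1, 0.095),
    preop_enterocolitis = stats::rbinom(n, 1, 0.02),
    preop_pulmonary_hypertension = stats::rbinom(n, 1, 0.05),
    preop_nephrotoxic_exposure = stats::rbinom(n, 1, 0.30),
    preop_genetic_syndrome = stats::rbinom(n, 1, 0.04),
    dialysis = as.integer(0.6 * AKI + rn(0.8) > stats::qnorm(0.92)),
    mortality = as.integer(Z[, "mortality"] >
                             stats::qnorm(1 - config$mortality_rate)),
    vent_days = round(pmax(0, 2.5 + 3.0 * Z[, "vent_days"]), 1),
    icu_days = round(pmax(0.5, 5.0 + 3.5 * Z[, "icu_days"]), 1)
  )
  ## fluid balance (ml/kg/24h), mildly positive-balance with AKI
  balance <- -28.06 + 26.8 * (0.35 * AKI + rn(0.94))
  static$fluid_in_ml <- round(150 * weight_kg + 20 * abs(rn()), 0)
  static$fluid_out_ml <- round(static$fluid_in_ml - balance * weight_kg, 0)

  ## ---- time series ---------------------------------------------------
  rows <- vector("list", 7L)
  emit <- function(variable, times, values) {
    data.frame(patient_id = rep(latents$patient_id, each = length(times)),
               variable = variable,
               time_h = rep(times, n),
               value = as.numeric(t(values)))
  }
  ## serum creatinine: baseline * (1 + delta(t)), delta ramps to a peak
  tg <- grid$scr
  dpeak <- 0.264 + 0.471 * Z[, "dscr50"]
  ramp <- pmin(tg / 36, 1)
  scr <- outer(static$baseline_scr * 1, rep(1, length(tg))) *
    (1 + outer(dpeak, ramp)) *
    matrix(exp(stats::rnorm(n * length(tg), sd = 0.02)), n)
  rows[[1L]] <- emit("scr", tg, pmax(scr, 8))
  ## urine output (ml/kg/h): level anchored against the oliguria target
  tg <- grid$urine_output
  uo_lev <- 4.1 - 2.2 * Z[, "oliguria"]
  uo <- outer(uo_lev, rep(1, length(tg))) +
    matrix(stats::rnorm(n * length(tg), sd = 0.9), n)
  rows[[2L]] <- emit("urine_output", tg, pmax(uo, 0))
  ## arterial pressures: age-dependent norm minus an LCOS-driven deficit
  tg <- grid$sap
  sap_base <- 58 + 6 * (age_days > 2) + 8 * (age_days > 28)
  dip <- 1 - 0.08 * exp(-(tg - 4)^2 / 18)      # early post-operative dip
  sap <- (outer(sap_base - 6 * Z[, "sap"], rep(1, length(tg))) +
            matrix(stats::rnorm(n * length(tg), sd = 3.5), n)) *
    outer(rep(1, n), dip)
  rows[[3L]] <- emit("sap", tg, pmax(sap, 20))
  map <- 0.72 * sap + matrix(stats::rnorm(n * length(tg), sd = 2), n)
  rows[[4L]] <- emit("map", grid$map, pmax(map, 15))
  ## lactate: early peak decaying towards 1.2 mmol/L
  tg <- grid$lactate
  lac_pk <- pmax(0.8, 3.8 + 2.0 * Z[, "lactate"])
  lac <- outer(lac_pk - 1.2, exp(-tg / 18)) + 1.2 +
    matrix(stats::rnorm(n * length(tg), sd = 0.25), n)
  rows[[5L]] <- emit("lactate", tg, pmax(lac, 0.3))
  ## urine NGAL, creatinine-normalized (ug/mmol), peaking around 6 h
  tg <- grid$ungal
  shape <- exp(-(tg - 6)^2 / 30)
  ung_lev <- pmax(5, 150 + 120 * Z[, "ungal"])
  ung <- outer(ung_lev, shape) *
    matrix(exp(stats::rnorm(n * length(tg), sd = 0.10)), n)
  rows[[6L]] <- emit("ungal_norm", tg, ung)
  ## absolute concentration (ug/L) = normalized x urine creatinine (mmol/L)
  ucr <- pmax(0.5, 2 + 0.5 * rn())
  rows[[7L]] <- emit("ungal_conc", tg, ung * ucr)

  list(timeseries = do.call(rbind, rows), static = static)
}

#' Write / read long-format time series as CSV
#'
#' @param x list from [simulate_timeseries()] or a long time-series data
#'   frame.
#' @param path file path (time series); `static_path` for the static table.
#' @return `read_timeseries_csv()` returns the same list structure.
#' @export
write_timeseries_csv <- function(x, path, static_path = NULL) {
  ts <- if (is.data.frame(x)) x else x$timeseries
  utils::write.csv(ts, path, row.names = FALSE)
  if (!is.null(static_path) && !is.data.frame(x))
    utils::write.csv(x$static, static_path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timeseries_csv
#' @export
read_timeseries_csv <- function(path, static_path = NULL) {
  out <- list(timeseries = utils::read.csv(path))
  if (!is.null(static_path)) out$static <- utils::read.csv(static_path)
  out
}
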