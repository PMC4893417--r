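#' Reference coefficients of the four-construct AKI model
#'
#' The package ships the standardized solution of a four-construct structural
#' model of cardiac-surgery-associated acute kidney injury (AKI) in infants
#' undergoing cardiopulmonary bypass (CPB).  The constructs are CPB exposure
#' (measured by bypass duration, aortic cross-clamp duration and conventional
#' ultrafiltration), low cardiac output syndrome (LCOS; age, systolic arterial
#' pressure deficit, lactacidemia, day-0 transfusions), AKI (creatinine
#' normalized urine NGAL, a >50\% creatinine increase and oliguria, each as
#' duration-adjusted AUC metrics) and post-operative Outcome (ventilation
#' duration, ICU stay, in-hospital mortality).  Two residual covariance arcs
#' (bypass duration with normalized uNGAL; mortality with the creatinine
#' metric) complete the model.
#'
#' These coefficients serve two purposes: they are the default generative
#' truth of the synthetic cohort generator (see [cohort_config()]), and they
#' are the input for compound-effect decomposition by Wright path tracing
#' (see [total_effect()] and [aki_worked_effects()]).
#'
#' @return `aki_path_coefficients()`: a data frame with one row per model
#'   parameter: `type` (`"directed"` or `"covariance"`), `from`, `to`,
#'   `value` (standardized coefficient) and the reported 95\% bootstrap
#'   confidence limits `ci_lower`, `ci_upper`.
#' @examples
#' aki_path_coefficients()
#' aki_structural_paths()
#' @export
aki_path_coefficients <- function() {
  tab <- rbind(
    data.frame(type = "directed", from = .aki_load$latent, to = .aki_load$indicator,
               value = .aki_load$value, ci_lower = .aki_load$lo, ci_upper = .aki_load$hi),
    data.frame(type = "directed",
               from = c("CPB", "CPB", "LCOS", "AKI"),
               to = c("AKI", "LCOS", "AKI", "Outcome"),
               value = c(0.596, 0.451, 0.347, 0.684),
               ci_lower = c(0.341, 0.319, 0.096, 0.532),
               ci_upper = c(0.747, 0.562, 0.553, 0.878)),
    data.frame(type = "covariance",
               from = c("dur_cpb", "mortality"),
               to = c("ungal", "dscr50"),
               value = c(0.137, 0.197),
               ci_lower = c(0.077, 0.109),
               ci_upper = c(0.404, 0.271))
  )
  rownames(tab) <- NULL
  tab
}

## measurement loadings with reported CIs (internal master table)
.aki_load <- data.frame(
  latent = c(rep("CPB", 3), rep("LCOS", 4), rep("AKI", 3), rep("Outcome", 3)),
  indicator = c("dur_cpb", "cross_clamp", "ultrafiltration",
                "age", "sap", "lactate", "transfusions",
                "ungal", "dscr50", "oliguria",
                "vent_days", "icu_days", "mortality"),
  value = c(0.997, 0.838, 0.708, -0.661, 0.684, 0.749, 0.709,
            0.508, 0.443, 0.494, 0.998, 0.934, 0.652),
  lo = c(0.946, 0.753, 0.592, -0.762, 0.541, 0.674, 0.584,
         0.202, 0.273, 0.250, 0.958, 0.905, 0.375),
  hi = c(1.051, 0.893, 0.791, -0.559, 0.791, 0.822, 0.796,
         0.745, 0.596, 0.864, 1.043, 0.967, 0.784),
  stringsAsFactors = FALSE
)

#' @rdname aki_path_coefficients
#' @return `aki_structural_paths()`: directed paths among the four latent
#'   constructs (`from`, `to`, `value`).
#' @export
aki_structural_paths <- function() {
  data.frame(from = c("CPB", "CPB", "LCOS", "AKI"),
             to = c("AKI", "LCOS", "AKI", "Outcome"),
             value = c(0.596, 0.451, 0.347, 0.684),
             stringsAsFactors = FALSE)
}

#' @rdname aki_path_coefficients
#' @return `aki_loadings()`: measurement loadings (`latent`, `indicator`,
#'   `value`).  The age loading on LCOS is negative: younger infants are the
#'   ones developing low cardiac output.
#' @export
aki_loadings <- function() {
  data.frame(latent = .aki_load$latent, indicator = .aki_load$indicator,
             value = .aki_load$value, stringsAsFactors = FALSE)
}

#' @rdname aki_path_coefficients
#' @return `aki_residual_correlations()`: the two residual covariance arcs,
#'   expressed as residual correlations (`a`, `b`, `value`).  The residual
#'   correlation scale is the only positive-definite reading of these arcs:
#'   the bypass-duration residual variance is 1 - 0.997^2, which bounds any
#'   residual covariance with the uNGAL indicator far below 0.137.
#' @export
aki_residual_correlations <- function() {
  data.frame(a = c("dur_cpb", "mortality"),
             b = c("ungal", "dscr50"),
             value = c(0.137, 0.197),
             stringsAsFactors = FALSE)
}

#' @rdname aki_path_coefficients
#' @return `aki_marginal_scales()`: clinical mean and standard deviation per
#'   indicator, used to map standardized simulated indicators onto clinical
#'   units.  Scales for the AUC-type metrics, which have no conventional
#'   population values, are package defaults chosen to be clinically
#'   plausible for infants under one year of age.
#' @export
aki_marginal_scales <- function() {
  data.frame(
    indicator = c("dur_cpb", "cross_clamp", "ultrafiltration", "age", "sap",
                  "lactate", "transfusions", "ungal", "dscr50", "oliguria",
                  "vent_days", "icu_days", "mortality"),
    mean = c(118.2, 62.9, 1.4, 95.8, 6.0, 3.8, 752.8, 150, 2.0, 0.6,
             2.5, 5.0, 0),
    sd = c(63.0, 33.9, 0.6, 91.1, 5.0, 2.0, 196.0, 120, 4.0, 1.2,
           3.0, 3.5, 1),
    unit = c("min", "min", "ml/kg/min", "days", "mmHg h", "mmol/L",
             "ml", "ug/mmol h", "h", "ml/kg", "days", "days", "0/1"),
    stringsAsFactors = FALSE
  )
}

#' Reference orthogonal four-factor solution
#'
#' The varimax-rotated four-factor loading pattern of the exploratory factor
#' analysis underlying the AKI model (Outcome, CPB, LCOS and AKI factors over
#' the 13 retained indicators; loadings below 0.2 treated as zero).  This
#' pattern is used as an orthogonal generative model for structure-recovery
#' studies of the EFA machinery: the four factors are drawn independently
#' and each indicator is loading-weighted factor score plus unique noise.
#'
#' @return a 13 x 4 numeric matrix of loadings with indicator row names and
#'   factor column names, with the per-factor proportions of explained
#'   variance attached as attribute `"proportion"`.
#' @examples
#' round(aki_efa_loadings(), 2)
#' @export
aki_efa_loadings <- function() {
  vn <- c("age", "dur_cpb", "cross_clamp", "ultrafiltration", "transfusions",
          "lactate", "sap", "oliguria", "dscr50", "ungal",
          "vent_days", "icu_days", "mortality")
  L <- matrix(0, 13, 4, dimnames = list(vn, c("Outcome", "CPB", "LCOS", "AKI")))
  L["age", "LCOS"] <- -0.773
  L["dur_cpb", ] <- c(0.305, 0.907, 0, 0.242)
  L["cross_clamp", "CPB"] <- 0.817
  L["ultrafiltration", "CPB"] <- 0.695
  L["transfusions", ] <- c(0.251, 0.215, 0.627, 0)
  L["lactate", ] <- c(0.280, 0, 0.680, 0)
  L["sap", ] <- c(0, 0.209, 0.610, 0.214)
  L["oliguria", ] <- c(0.188, 0, 0, 0.420)
  L["dscr50", "AKI"] <- 0.538
  L["ungal", ] <- c(0, 0.393, 0, 0.494)
  L["vent_days", ] <- c(0.946, 0, 0.202, 0.227)
  L["icu_days", ] <- c(0.910, 0, 0, 0.227)
  L["mortality", ] <- c(0.613, 0, 0, 0.236)
  attr(L, "proportion") <- c(Outcome = 0.198, CPB = 0.183, LCOS = 0.158,
                             AKI = 0.071)
  L
}

#' Variable families of interchangeable metrics
#'
#' Groups of derived metrics that quantify the same clinical phenomenon and
#' of which only one (the best-loading surrogate) is retained during EFA
#' refinement: the three uNGAL excretion metrics, the three oliguria
#' threshold metrics, the creatinine metrics together with the AKIN stage,
#' and the systolic/mean arterial pressure deficits.
#'
#' @return named list of character vectors of variable names.
#' @export
aki_metric_families <- function() {
  list(
    ungal = c("ungal", "ungal_conc", "ungal_rate"),
    oliguria = c("oliguria", "oliguria_1", "oliguria_2"),
    creatinine = c("dscr50", "dscr_rel", "akin_stage"),
    pressure = c("sap", "map")
  )
}

#' Structural equation model of the AKI study
#'
#' Builds the [sem_spec()] for the four-construct model: the measurement
#' model of [aki_loadings()], the structural paths of
#' [aki_structural_paths()], and optionally the two residual covariance
#' arcs.  All coefficients are left free; latent scaling fixes the exogenous
#' CPB variance at 1.
#'
#' @param covariance_arcs include the two residual covariance arcs
#'   (`dur_cpb ~~ ungal`, `mortality ~~ dscr50`)?  The base model of the
#'   respecification exercise omits them.
#' @return a [sem_spec()] object.
#' @examples
#' spec <- aki_model_spec()
#' spec$df_model   # 13 observed variables, 91 moments
#' @export
aki_model_spec <- function(covariance_arcs = TRUE) {
  lo <- aki_loadings()
  st <- aki_structural_paths()
  paths <- rbind(
    data.frame(from = lo$latent, to = lo$indicator, value = NA_real_),
    data.frame(from = st$from, to = st$to, value = NA_real_)
  )
  covs <- NULL
  if (covariance_arcs) {
    rc <- aki_residual_correlations()
    covs <- data.frame(a = rc$a, b = rc$b, value = NA_real_)
  }
  sem_spec(latents = c("CPB", "LCOS", "AKI", "Outcome"),
           observed = lo$indicator,
           paths = paths, covariances = covs)
}

#' Path diagram of the fitted AKI model
#'
#' The standardized solution as a [path_graph()], with directed edges for
#' loadings and structural paths and covariance edges for the two residual
#' arcs, valued either at the reference coefficients or at a supplied
#' coefficient table of the same layout.
#'
#' @param coefficients a data frame as returned by
#'   [aki_path_coefficients()] (columns `type`, `from`, `to`, `value`).
#' @return a [path_graph()].
#' @export
aki_path_graph <- function(coefficients = aki_path_coefficients()) {
  path_graph(data.frame(from = coefficients$from, to = coefficients$to,
                        type = ifelse(coefficients$type == "covariance",
                                      "covariance", "directed"),
                        value = coefficients$value,
                        stringsAsFactors = FALSE))
}
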