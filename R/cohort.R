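#' Configuration of a synthetic AKI cohort
#'
#' Defines the generative model for synthetic cohorts: directed structural
#' paths among the four latent constructs (CPB, LCOS, AKI, Outcome),
#' measurement loadings of the 13 indicators, residual correlations between
#' indicator pairs, clinical marginal scales, and the in-hospital mortality
#' rate.  Defaults reproduce the reference model (see
#' [aki_path_coefficients()]) with a cohort of 200 infants and a 4\%
#' mortality rate.
#'
#' All coefficients live in standardized space: every latent construct has
#' unit variance (residual variances are derived internally), and every
#' indicator is loading times latent plus unique noise of variance
#' `1 - loading^2` (floored at `1e-6` for loadings very close to one).
#'
#' @param n_patients number of patients (default 200).
#' @param seed integer seed used by the simulators; `NULL` leaves the random
#'   number generator state untouched.
#' @param structural_paths data frame `from`, `to`, `value` of directed
#'   standardized paths among latents; must form a DAG.
#' @param loadings data frame `latent`, `indicator`, `value` of standardized
#'   loadings, all strictly below 1 in magnitude.
#' @param residual_correlations data frame `a`, `b`, `value` of residual
#'   correlations between indicator pairs (each `|value| < 1`).
#' @param marginal_scales data frame `indicator`, `mean`, `sd` mapping
#'   standardized indicators to clinical units.
#' @param mortality_rate expected proportion of in-hospital deaths; the
#'   mortality indicator is dichotomized at the `1 - mortality_rate`
#'   standard-normal quantile of its continuous propensity.
#' @param time_grid named list of sampling times (hours after surgery) per
#'   raw time-series variable; `NULL` uses the package defaults (uNGAL over
#'   12 h, urine output and arterial pressure hourly over 24 h, lactate
#'   6-hourly and creatinine 12-hourly over 48 h).
#' @return an object of class `cohort_config`.
#' @seealso [simulate_latents()], [simulate_indicators()],
#'   [simulate_timeseries()]
#' @examples
#' cfg <- cohort_config(n_patients = 500, seed = 1)
#' lat <- simulate_latents(cfg)
#' ind <- simulate_indicators(lat, cfg)
#' colMeans(ind[, -1])
#' @export
cohort_config <- function(n_patients = 200,
                          seed = NULL,
                          structural_paths = aki_structural_paths(),
                          loadings = aki_loadings(),
                          residual_correlations = aki_residual_correlations(),
                          marginal_scales = aki_marginal_scales(),
                          mortality_rate = 0.04,
                          time_grid = NULL) {
  stopifnot(is.data.frame(structural_paths), is.data.frame(loadings))
  if (any(abs(loadings$value) >= 1))
    stop2("all loadings must be strictly below 1 in magnitude; offending: ",
          paste(loadings$indicator[abs(loadings$value) >= 1], collapse = ", "))
  if (any(abs(structural_paths$value) > 1))
    stop2("structural path magnitudes must not exceed 1")
  if (!is.null(residual_correlations) &&
      any(abs(residual_correlations$value) >= 1))
    stop2("residual correlations must be strictly below 1 in magnitude")
  if (mortality_rate <= 0 || mortality_rate >= 1)
    stop2("'mortality_rate' must be in (0, 1)")
  p <- nrow(loadings)
  if (n_patients < p + 1)
    stop2(sprintf("'n_patients' must be at least %d (one more than the %d indicators)",
                  p + 1, p))
  latents <- unique(c(loadings$latent, structural_paths$from,
                      structural_paths$to))
  ## validates acyclicity as a side effect
  order <- topological_order(latents, structural_paths$from,
                             structural_paths$to)
  ## residual variances of endogenous latents must be positive
  lat_cov <- latent_covariance_from_paths(order, structural_paths)
  cfg <- structure(list(
    n_patients = n_patients, seed = seed,
    structural_paths = structural_paths, loadings = loadings,
    residual_correlations = residual_correlations,
    marginal_scales = marginal_scales, mortality_rate = mortality_rate,
    time_grid = time_grid %||% default_time_grid(),
    latents = order, latent_covariance = lat_cov
  ), class = "cohort_config")
  cfg
}

default_time_grid <- function() {
  list(scr = c(6, 12, 24, 36, 48),
       urine_output = 1:24,
       sap = 1:24,
       map = 1:24,
       lactate = seq(0, 48, by = 6),
       ungal = c(2, 4, 6, 8, 10, 12))
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  %d patients, mortality rate %.1f%%\n",
              x$n_patients, 100 * x$mortality_rate))
  cat(sprintf("  latents: %s\n", paste(x$latents, collapse = ", ")))
  cat(sprintf("  %d indicators, %d structural paths, %d residual arcs\n",
              nrow(x$loadings), nrow(x$structural_paths),
              if (is.null(x$residual_correlations)) 0L
              else nrow(x$residual_correlations)))
  invisible(x)
}

## Closed-form latent covariance implied by the structural DAG with
## unit-variance construction (Wright tracing in matrix form):
## each latent = sum(parent * path) + residual, residual variance chosen so
## that the latent has variance exactly 1.  Errors if that variance would be
## non-positive.
latent_covariance_from_paths <- function(order, paths) {
  k <- length(order)
  V <- matrix(0, k, k, dimnames = list(order, order))
  resvar <- numeric(k)
  names(resvar) <- order
  for (v in order) {
    par <- paths[paths$to == v, , drop = FALSE]
    if (!nrow(par)) {           # exogenous
      V[v, v] <- 1
      resvar[v] <- 1
      next
    }
    b <- par$value
    Vp <- V[par$from, par$from, drop = FALSE]
    sys_var <- as.numeric(t(b) %*% Vp %*% b)
    rv <- 1 - sys_var
    if (rv <= 0)
      stop2(sprintf(
        "implied residual variance of latent '%s' is %.4f (<= 0); reduce its incoming paths",
        v, rv))
    resvar[v] <- rv
    V[v, v] <- 1
    ## covariance with all previously resolved latents
    done <- order[seq_len(match(v, order) - 1L)]
    for (u in done)
      V[u, v] <- V[v, u] <- as.numeric(V[u, par$from, drop = FALSE] %*% b)
  }
  attr(V, "residual_variance") <- resvar
  V
}

#' Model-implied latent covariance of a cohort configuration
#'
#' @param config a [cohort_config()].
#' @return correlation matrix of the latent constructs with the residual
#'   variances used by the generator attached as attribute
#'   `"residual_variance"`.
#' @export
latent_covariance <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  config$latent_covariance
}

#' Simulate latent construct scores
#'
#' Draws per-patient standardized latent scores recursively along the
#' structural DAG: exogenous constructs are standard normal, endogenous
#' constructs are the path-weighted sum of their parents plus a normal
#' residual whose variance makes the construct's population variance exactly
#' one.
#'
#' @param config a [cohort_config()].
#' @return data frame with `patient_id` and one column per latent construct.
#' @examples
#' lat <- simulate_latents(cohort_config(n_patients = 1000, seed = 7))
#' round(cor(lat$CPB, lat$LCOS), 2)   # converges to 0.451
#' @export
simulate_latents <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_patients
  order <- config$latents
  resvar <- attr(config$latent_covariance, "residual_variance")
  paths <- config$structural_paths
  L <- matrix(0, n, length(order), dimnames = list(NULL, order))
  for (v in order) {
    par <- paths[paths$to == v, , drop = FALSE]
    eta <- stats::rnorm(n, sd = sqrt(resvar[v]))
    if (nrow(par))
      eta <- eta + as.numeric(L[, par$from, drop = FALSE] %*% par$value)
    L[, v] <- eta
  }
  out <- data.frame(patient_id = seq_len(n), L)
  attr(out, "config") <- config
  out
}

#' Simulate the indicator matrix
#'
#' Generates the observed indicators from latent scores: each standardized
#' indicator is loading x latent + unique noise with variance
#' `1 - loading^2` (floored at `1e-6`), residual correlation arcs are
#' imposed by drawing the corresponding unique terms jointly, and the
#' mortality indicator is dichotomized at the `1 - mortality_rate` quantile
#' of its continuous propensity (then kept as a numeric 0/1 column, the way
#' it enters all downstream analyses).
#'
#' @param latents data frame from [simulate_latents()].
#' @param config the matching [cohort_config()].
#' @param scale `"standardized"` (default) or `"clinical"`; clinical output
#'   applies `mean + sd * z` per [aki_marginal_scales()].
#' @param mortality `"binary"` (default) dichotomizes the mortality
#'   propensity; `"propensity"` keeps it continuous.  The binary column can
#'   carry at most a point-biserial correlation of about 0.44 with any
#'   normal variable at a 4\% rate, so exact recovery of its generating
#'   loading is only assessable on the propensity scale.
#' @return an `indicator_matrix`: data frame with `patient_id` and one
#'   column per indicator; attributes `scale` and `config`.
#' @examples
#' cfg <- cohort_config(seed = 1)
#' ind <- simulate_indicators(simulate_latents(cfg), cfg)
#' sum(ind$mortality)   # near binomial(200, 0.04)
#' @export
simulate_indicators <- function(latents, config,
                                scale = c("standardized", "clinical"),
                                mortality = c("binary", "propensity")) {
  stopifnot(inherits(config, "cohort_config"))
  scale <- match.arg(scale)
  mortality <- match.arg(mortality)
  lo <- config$loadings
  p <- nrow(lo)
  n <- nrow(latents)
  sde2 <- pmax(1 - lo$value^2, 1e-6)
  ## unique-term covariance with residual correlation arcs
  S_e <- diag(sde2)
  dimnames(S_e) <- list(lo$indicator, lo$indicator)
  rc <- config$residual_correlations
  if (!is.null(rc) && nrow(rc)) {
    for (i in seq_len(nrow(rc))) {
      a <- rc$a[i]; b <- rc$b[i]
      if (!all(c(a, b) %in% lo$indicator))
        stop2("residual correlation names unknown: ", a, ", ", b)
      cv <- rc$value[i] * sqrt(S_e[a, a] * S_e[b, b])
      block <- matrix(c(S_e[a, a], cv, cv, S_e[b, b]), 2)
      if (det(block) <= 0)
        stop2(sprintf("residual correlation %s ~~ %s = %.3f makes the residual block non-positive-definite",
                      a, b, rc$value[i]))
      S_e[a, b] <- S_e[b, a] <- cv
    }
  }
  E <- rmvnorm_chol(n, S_e)
  Z <- as.matrix(latents[, lo$latent, drop = FALSE]) %*% diag(lo$value) + E
  colnames(Z) <- lo$indicator
  if ("mortality" %in% colnames(Z) && mortality == "binary")
    Z[, "mortality"] <-
      as.numeric(Z[, "mortality"] > stats::qnorm(1 - config$mortality_rate))
  if (scale == "clinical") {
    ms <- config$marginal_scales
    for (v in colnames(Z)) {
      if (v == "mortality" && mortality == "binary") next
      i <- match(v, ms$indicator)
      if (!is.na(i)) Z[, v] <- ms$mean[i] + ms$sd[i] * Z[, v]
    }
  }
  out <- data.frame(patient_id = latents$patient_id, Z)
  class(out) <- c("indicator_matrix", "data.frame")
  attr(out, "scale") <- scale
  attr(out, "config") <- config
  out
}

#' Simulate a cohort from the orthogonal four-factor EFA structure
#'
#' Draws an indicator matrix directly from the reference varimax factor
#' solution (see [aki_efa_loadings()]): four independent standard-normal
#' factors, each indicator the loading-weighted factor sum plus unique
#' noise of variance one minus its communality.  This generator is the
#' substrate for structure-recovery studies of the EFA machinery; unlike
#' the structural-model generator ([simulate_indicators()]), its factors
#' are orthogonal by construction, so a varimax solution is a consistent
#' estimator of the generating pattern.
#'
#' @param n number of patients.
#' @param seed integer seed (`NULL` leaves the RNG state untouched).
#' @param loadings p x k loading matrix (defaults to the reference
#'   solution).
#' @param mortality as in [simulate_indicators()]: `"binary"` dichotomizes
#'   the mortality indicator at the `1 - mortality_rate` propensity
#'   quantile.
#' @param mortality_rate expected death rate (default 0.04).
#' @return an `indicator_matrix` data frame.
#' @examples
#' ind <- simulate_efa_cohort(500, seed = 4)
#' kaiser_count(cor(as.matrix(ind[, -1])))   # 4 factors by latent root
#' @export
simulate_efa_cohort <- function(n, seed = NULL, loadings = aki_efa_loadings(),
                                mortality = c("binary", "propensity"),
                                mortality_rate = 0.04) {
  mortality <- match.arg(mortality)
  if (!is.null(seed)) set.seed(seed)
  h2 <- rowSums(loadings^2)
  if (any(h2 >= 1))
    stop2("communalities implied by 'loadings' must be below 1")
  k <- ncol(loadings)
  Fm <- matrix(stats::rnorm(n * k), n, k)
  X <- Fm %*% t(loadings) +
    matrix(stats::rnorm(n * nrow(loadings)), n) %*%
    diag(sqrt(pmax(1 - h2, 1e-6)))
  colnames(X) <- rownames(loadings)
  if ("mortality" %in% colnames(X) && mortality == "binary")
    X[, "mortality"] <-
      as.numeric(X[, "mortality"] > stats::qnorm(1 - mortality_rate))
  out <- data.frame(patient_id = seq_len(n), X)
  class(out) <- c("indicator_matrix", "data.frame")
  attr(out, "scale") <- "standardized"
  out
}

#' Model-implied indicator correlation matrix of a cohort configuration
#'
#' The population correlation matrix of the standardized indicators:
#' loadings times latent covariance times loadings, plus the residual
#' covariance arcs, with unit diagonal.  The sample correlation matrix of a
#' large simulated cohort converges to this matrix.
#'
#' @param config a [cohort_config()].
#' @return p x p correlation matrix.
#' @export
implied_indicator_correlation <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  lo <- config$loadings
  P <- config$latent_covariance
  L <- matrix(0, nrow(lo), ncol(P),
              dimnames = list(lo$indicator, colnames(P)))
  L[cbind(lo$indicator, lo$latent)] <- lo$value
  R <- L %*% P %*% t(L)
  sde2 <- pmax(1 - lo$value^2, 1e-6)
  rc <- config$residual_correlations
  if (!is.null(rc) && nrow(rc))
    for (i in seq_len(nrow(rc))) {
      a <- rc$a[i]; b <- rc$b[i]
      cv <- rc$value[i] *
        sqrt(sde2[match(a, lo$indicator)] * sde2[match(b, lo$indicator)])
      R[a, b] <- R[a, b] + cv
      R[b, a] <- R[a, b]
    }
  diag(R) <- 1
  R
}

#' Write / read an indicator matrix as CSV
#'
#' Plain CSV with a header row of variable names and one row per patient.
#'
#' @param x an `indicator_matrix` (or any data frame with `patient_id`).
#' @param path file path.
#' @return `read_indicator_csv()` returns an `indicator_matrix`.
#' @export
write_indicator_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_indicator_csv
#' @export
read_indicator_csv <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("indicator_matrix", "data.frame")
  out
}
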