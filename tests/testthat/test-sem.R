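test_that("implied covariance follows the RAM algebra", {
  ## no paths: S passes through
  spec0 <- sem_spec(latents = character(0), observed = c("a", "b"),
                    paths = data.frame(from = character(),
                                       to = character(), value = numeric()))
  expect_equal(implied_covariance(spec0, c(1, 1)), diag(2),
               ignore_attr = TRUE)
  ## single factor, loadings (.8, .7), unit latent, residuals 1 - lambda^2
  spec1 <- sem_spec("F1", c("x1", "x2"),
                    data.frame(from = "F1", to = c("x1", "x2"), value = NA))
  Sig <- implied_covariance(spec1, c(0.8, 0.7, 1 - 0.64, 1 - 0.49))
  expect_equal(Sig["x1", "x2"], 0.56)
  expect_equal(diag(Sig), c(x1 = 1, x2 = 1))
})

test_that("fitting the population matrix returns the generating solution", {
  ## the model-implied correlation matrix of the default cohort, fed back
  ## into the engine, must reproduce every generating standardized
  ## coefficient essentially exactly (zero sampling noise)
  cfg <- cohort_config(seed = 91)
  R <- implied_indicator_correlation(cfg)
  fit <- sem_fit(aki_model_spec(), sample_cov = R, n = 10000)
  expect_lt(fit$F_min, 1e-8)
  s <- fit$standardized
  lo <- aki_loadings()
  for (i in seq_len(nrow(lo))) {
    lab <- paste(lo$latent[i], "->", lo$indicator[i])
    expect_equal(s$std[s$label == lab], lo$value[i], tolerance = 1e-3,
                 label = lab)
  }
  st <- aki_structural_paths()
  for (i in seq_len(nrow(st))) {
    lab <- paste(st$from[i], "->", st$to[i])
    expect_equal(s$std[s$label == lab], st$value[i], tolerance = 1e-3,
                 label = lab)
  }
  ## covariance arcs come back on the residual-correlation scale
  expect_equal(s$std[s$label == "dur_cpb ~~ ungal"], 0.137,
               tolerance = 1e-3)
  expect_equal(s$std[s$label == "mortality ~~ dscr50"], 0.197,
               tolerance = 1e-3)
})

test_that("zero-discrepancy recovery returns the generating parameters", {
  spec <- toy_two_latent_spec()
  lambda <- c(0.8, 0.7, 0.6, 0.75, 0.65, 0.55)
  phi <- 0.4
  theta0 <- c(lambda, 1 - lambda^2, phi)
  pm <- spec$parameters[spec$parameters$free, ]
  ## order: 6 loadings, 6 observed variances, 2 latent variances fixed, cov
  Sig0 <- implied_covariance(spec, theta0)
  fit <- sem_fit(spec, sample_cov = Sig0, n = 1000)
  expect_lt(fit$F_min, 1e-8)
  expect_lt(max(abs(fit$theta - theta0)), 1e-4)
  expect_lt(fit$convergence$gradient_norm, 1e-5)
})

test_that("a saturated model fits perfectly with zero degrees of freedom", {
  spec <- sem_spec(latents = character(0), observed = c("a", "b"),
                   paths = data.frame(from = character(), to = character(),
                                      value = numeric()),
                   covariances = data.frame(a = "a", b = "b", value = NA))
  set.seed(92)
  X <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  fit <- sem_fit(spec, as.data.frame(X))
  expect_equal(fit$df, 0)
  expect_lt(abs(fit$chisq), 1e-6)
  expect_equal(fit$fit_indices$rmsea, 0)
  expect_false(fit$fit_indices$rmsea_defined)
})

test_that("fit indices follow their defining formulas", {
  fi <- fit_indices(chisq = 100, df = 50, n = 201, chisq_null = 1000,
                    df_null = 78)
  expect_equal(fi$rmsea, sqrt(50 / 10000))
  expect_equal(fi$nfi, 0.9)
  expect_equal(fi$bic, 100 - 50 * log(201))
  expect_equal(fit_indices(50, 50, 100)$rmsea, 0)
  ## perfect fit: NFI and GFI reach 1
  S <- diag(3)
  fi0 <- fit_indices(0, 2, 100, chisq_null = 500, df_null = 3,
                     S_obs = S, sigma_hat = S)
  expect_equal(fi0$nfi, 1)
  expect_equal(fi0$gfi, 1)
})

test_that("standardized paths recover the generating AKI model", {
  cfg <- cohort_config(n_patients = 5000, seed = 93)
  ind <- simulate_indicators(simulate_latents(cfg), cfg,
                             mortality = "propensity")
  fit <- suppressWarnings(sem_fit(aki_model_spec(), ind))
  s <- fit$standardized
  pick <- function(lab) s$std[s$label == lab]
  expect_equal(pick("CPB -> AKI"), 0.596, tolerance = 0.05)
  expect_equal(pick("CPB -> dur_cpb"), 0.997, tolerance = 0.02)
  expect_equal(pick("LCOS -> age"), -0.661, tolerance = 0.05)
  ## the mortality/creatinine arc is recoverable as residual correlation
  expect_lt(abs(pick("mortality ~~ dscr50") - 0.197), 0.05)
})

test_that("standardized solution is invariant to observed rescaling", {
  cfg <- cohort_config(n_patients = 800, seed = 94)
  ind <- simulate_indicators(simulate_latents(cfg), cfg,
                             mortality = "propensity")
  spec <- aki_model_spec()
  f1 <- sem_fit(spec, ind, use = "covariance")
  ind2 <- ind
  ind2$dur_cpb <- ind2$dur_cpb * 63.0 + 118.2
  ind2$lactate <- ind2$lactate * 2.0
  f2 <- sem_fit(spec, ind2, use = "covariance")
  expect_equal(f1$standardized$std, f2$standardized$std, tolerance = 1e-6)
})

test_that("non-convergence and Heywood conditions are surfaced", {
  ## two indicators for one factor: under-identified, optimizer cannot
  ## settle -- expect an informative failure or a degenerate solution
  spec <- sem_spec("F1", c("x1", "x2", "x3"),
                   data.frame(from = "F1", to = c("x1", "x2", "x3"),
                              value = NA))
  ## Heywood-prone sample: x1 nearly equal to the factor
  set.seed(95)
  f <- rnorm(150)
  X <- data.frame(x1 = 0.99 * f + 0.05 * rnorm(150),
                  x2 = 0.3 * f + rnorm(150),
                  x3 = 0.25 * f + rnorm(150))
  w <- capture_warnings(fit <- sem_fit(spec, X))
  expect_true(any(grepl("Heywood", w)))
  ## bound-at-zero mode keeps all variance estimates non-negative
  fitb <- suppressWarnings(sem_fit(spec, X, bound_variances = TRUE))
  varrows <- fitb$estimates$matrix == "S" &
    fitb$estimates$from == fitb$estimates$to
  expect_true(all(fitb$estimates$est[varrows] >= 0))
})
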