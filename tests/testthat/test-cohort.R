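test_that("latent simulation matches closed-form path-tracing moments", {
  ## independence: all paths zero
  paths0 <- aki_structural_paths()
  paths0$value <- 0
  cfg0 <- cohort_config(n_patients = 1e5, seed = 1, structural_paths = paths0)
  lat0 <- simulate_latents(cfg0)
  r0 <- cor(as.matrix(lat0[, -1]))
  expect_lt(max(abs(r0[upper.tri(r0)])), 0.02)

  ## defaults: corr(CPB, AKI) = 0.596 + 0.451 * 0.347, unit variances
  cfg <- cohort_config(n_patients = 1e5, seed = 2)
  lat <- simulate_latents(cfg)
  expect_lt(abs(cor(lat$CPB, lat$AKI) - (0.596 + 0.451 * 0.347)), 0.01)
  expect_lt(abs(var(lat$AKI) - 1), 0.02)
  expect_lt(abs(var(lat$Outcome) - 1), 0.02)
  ## closed-form latent covariance agrees with the sample
  V <- latent_covariance(cfg)
  expect_lt(max(abs(V - cov(as.matrix(lat[, colnames(V)])))), 0.02)
})

test_that("indicator generation reproduces loadings and residual arcs", {
  cfg <- cohort_config(n_patients = 1e5, seed = 3)
  lat <- simulate_latents(cfg)
  ind <- simulate_indicators(lat, cfg, mortality = "propensity")
  expect_lt(abs(cor(lat$CPB, ind$dur_cpb) - 0.997), 0.005)
  expect_lt(abs(cor(lat$LCOS, ind$age) - (-0.661)), 0.01)
  ## residual correlations: residual = indicator - loading * latent
  e_dur <- ind$dur_cpb - 0.997 * lat$CPB
  e_ung <- ind$ungal - 0.508 * lat$AKI
  expect_lt(abs(cor(e_dur, e_ung) - 0.137), 0.01)
  e_mort <- ind$mortality - 0.652 * lat$Outcome
  e_dscr <- ind$dscr50 - 0.443 * lat$AKI
  expect_lt(abs(cor(e_mort, e_dscr) - 0.197), 0.01)
})

test_that("sample correlations converge to the model-implied matrix", {
  cfg <- cohort_config(n_patients = 1e5, seed = 4)
  ind <- simulate_indicators(simulate_latents(cfg), cfg,
                             mortality = "propensity")
  R_hat <- cor(as.matrix(ind[, -1]))
  R_model <- implied_indicator_correlation(cfg)
  expect_lt(max(abs(R_hat - R_model[colnames(R_hat), colnames(R_hat)])),
            0.02)
})

test_that("mortality is a plausible binomial 0/1 column at the 4% rate", {
  cfg <- cohort_config(n_patients = 200, seed = 5)
  ind <- simulate_indicators(simulate_latents(cfg), cfg)
  expect_true(all(ind$mortality %in% c(0, 1)))
  deaths <- sum(ind$mortality)
  expect_gte(deaths, 1)           # binomial(200, .04): mean 8, sd 2.8
  expect_lte(deaths, 18)
  ## clinical scale maps mean/sd but leaves mortality binary
  clin <- simulate_indicators(simulate_latents(cfg), cfg, scale = "clinical")
  expect_true(all(clin$mortality %in% c(0, 1)))
  expect_equal(mean(clin$dur_cpb), 118.2, tolerance = 15)
})

test_that("simulation is reproducible under a fixed seed and seeds differ", {
  cfg <- cohort_config(n_patients = 100, seed = 11)
  a <- simulate_indicators(simulate_latents(cfg), cfg)
  b <- simulate_indicators(simulate_latents(cfg), cfg)
  expect_identical(a, b)
  cfg2 <- cohort_config(n_patients = 100, seed = 12)
  c <- simulate_indicators(simulate_latents(cfg2), cfg2)
  expect_false(isTRUE(all.equal(a$dur_cpb, c$dur_cpb)))
})

test_that("configuration guards reject impossible generative models", {
  bad_load <- aki_loadings()
  bad_load$value[1] <- 1.01
  expect_error(cohort_config(loadings = bad_load), "below 1")
  cyc <- data.frame(from = c("CPB", "AKI"), to = c("AKI", "CPB"),
                    value = c(0.5, 0.5))
  expect_error(cohort_config(structural_paths = cyc), "cycle")
  ## paths implying negative residual variance name the latent
  hot <- aki_structural_paths()
  hot$value <- c(0.9, 0.9, 0.9, 0.9)
  expect_error(cohort_config(structural_paths = hot), "AKI")
  expect_error(cohort_config(n_patients = 5), "at least")
  ## chained residual correlations that break positive-definiteness
  lo <- data.frame(latent = "F", indicator = c("x1", "x2", "x3"),
                   value = c(0.6, 0.6, 0.6))
  rc <- data.frame(a = c("x1", "x2"), b = c("x2", "x3"),
                   value = c(0.95, 0.95))
  cfg <- cohort_config(n_patients = 50, seed = 1,
                       structural_paths = data.frame(from = character(),
                                                     to = character(),
                                                     value = numeric()),
                       loadings = lo, residual_correlations = rc)
  lat <- simulate_latents(cfg)
  expect_error(simulate_indicators(lat, cfg), "positive-definite")
})

test_that("EFA-structure cohorts carry four factors by the latent root", {
  ind <- simulate_efa_cohort(2000, seed = 21)
  expect_equal(kaiser_count(cor(as.matrix(ind[, -1]))), 4)
  ## simple-structure orthogonal loadings are recovered to +-0.05:
  ## a known 4-factor model with one salient loading per variable is in
  ## varimax position, so rotation indeterminacy reduces to column
  ## permutation and sign
  set.seed(23)
  Ltrue <- matrix(0, 12, 4)
  Ltrue[cbind(1:12, rep(1:4, each = 3))] <- runif(12, 0.5, 0.9)
  rownames(Ltrue) <- paste0("v", 1:12)
  ind3 <- simulate_efa_cohort(5000, seed = 23, loadings = Ltrue,
                              mortality = "propensity")
  sol <- efa(ind3, n_factors = 4)
  rotated <- akisem:::align_loadings(unclass(sol$loadings), Ltrue)
  expect_lt(max(abs(rotated - Ltrue)), 0.05)
  ## the reference pattern itself (with its secondary loadings, slightly
  ## off varimax position) is recovered more loosely
  ind2 <- simulate_efa_cohort(5000, seed = 22, mortality = "propensity")
  sol2 <- efa(ind2, n_factors = 4)
  ref <- aki_efa_loadings()
  rotated2 <- akisem:::align_loadings(unclass(sol2$loadings), ref)
  expect_lt(max(abs(rotated2 - ref)), 0.15)
})
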