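test_that("Bartlett sphericity matches the closed formula", {
  expect_equal(bartlett_sphericity(diag(5), 100)$chisq, 0)
  expect_equal(bartlett_sphericity(diag(29), 200)$df, 406)
  ## random correlation matrix vs independent formula evaluation
  set.seed(61)
  X <- matrix(rnorm(300), 50)
  R <- cor(X)
  b <- bartlett_sphericity(R, 50)
  expect_equal(b$chisq,
               -(50 - 1 - (2 * 6 + 5) / 6) * log(det(R)),
               tolerance = 1e-10)
  expect_error(bartlett_sphericity(matrix(1, 3, 3), 50),
               "positive-definite")
})

test_that("KMO behaves at its analytic anchor points", {
  ## p = 2: the partial correlation equals the marginal, KMO = 0.5 exactly
  R2 <- matrix(c(1, 0.6, 0.6, 1), 2)
  expect_equal(kmo(R2)$overall, 0.5)
  ## strong one-factor data: compact correlations, KMO high
  set.seed(62)
  lambda <- rep(0.85, 8)
  X <- tcrossprod(rnorm(2000), lambda) +
    matrix(rnorm(16000), 2000) %*% diag(sqrt(1 - lambda^2))
  expect_gt(kmo(cor(X))$overall, 0.8)
  ## independent noise with p close to n: diffuse partials, KMO low
  set.seed(63)
  Xn <- matrix(rnorm(40 * 25), 40)
  expect_lt(kmo(cor(Xn))$overall, 0.5)
})

test_that("principal-axis extraction recovers exact factor structures", {
  ## closed-form one-factor construction
  lambda <- c(0.8, 0.7, 0.6)
  R <- tcrossprod(lambda); diag(R) <- 1
  L <- efa_extract(R, 1)$loadings
  expect_lt(max(abs(abs(L[, 1]) - lambda)), 1e-4)
  ## identity matrix: no common variance
  expect_lt(max(abs(efa_extract(diag(4), 1)$loadings)), 1e-8)
  ## communalities respect [0, 1] and equal row sums of squared loadings
  sol <- efa_extract(R, 1)
  expect_equal(sol$communalities, rowSums(sol$loadings^2),
               ignore_attr = TRUE)
})

test_that("extraction agrees with an established implementation", {
  ## oracle loadings computed with statsmodels.multivariate.factor
  ## (principal axis, SMC start; statsmodels 0.14.6) on the shipped
  ## correlation matrices, frozen into fixtures
  for (case in c(101, 202, 303)) {
    R <- as.matrix(read.csv(test_path("fixtures",
                                      sprintf("efa_corr_%d.csv", case)),
                            header = FALSE))
    Lo <- as.matrix(read.csv(test_path("fixtures",
                                       sprintf("efa_loadings_%d.csv", case)),
                             header = FALSE))
    dimnames(R) <- NULL
    L <- efa_extract(R, ncol(Lo))$loadings
    aligned <- akisem:::align_loadings(unclass(L), Lo)
    expect_lt(max(abs(aligned - Lo)), 0.01)
  }
})

test_that("varimax rotation is orthogonal and criterion-optimal", {
  set.seed(64)
  L <- matrix(rnorm(12, 0, 0.5), 6, 2)
  Lr <- efa_varimax(L)
  ## communalities preserved to machine precision
  expect_equal(rowSums(Lr^2), rowSums(L^2), tolerance = 1e-10)
  vcrit <- function(M) sum(apply(M^2, 2, function(z) mean(z^2) - mean(z)^2))
  expect_gte(vcrit(Lr) + 1e-12, vcrit(L))
  ## one-parameter grid-search oracle over the rotation angle (k = 2)
  angles <- seq(0, pi / 2, length.out = 20001)
  best <- max(vapply(angles, function(a) {
    G <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2)
    vcrit(L %*% G)
  }, numeric(1)))
  ## note: stats::varimax Kaiser-normalizes; compare on the raw criterion
  Lr_raw <- unclass(stats::varimax(L, normalize = FALSE)$loadings)
  expect_equal(vcrit(Lr_raw), best, tolerance = 1e-4)
  ## an already optimal matrix is a fixed point (up to permutation/sign)
  Lrr <- efa_varimax(Lr)
  expect_lt(max(abs(abs(Lrr) - abs(Lr))), 1e-4)
  ## sign convention: the largest loading of each factor is positive
  expect_true(all(apply(Lr, 2, function(z) z[which.max(abs(z))] > 0)))
})

test_that("variance proportions sum as published", {
  ve <- variance_explained(aki_efa_loadings())
  expect_equal(sum(attr(aki_efa_loadings(), "proportion")), 0.610)
  expect_lte(ve$total, 1)
  ## single factor with unit loadings explains everything
  expect_equal(variance_explained(matrix(1, 5, 1))$total, 1)
})

test_that("ML extraction is available behind the method flag", {
  set.seed(65)
  lambda <- c(0.8, 0.7, 0.6, 0.5)
  X <- tcrossprod(rnorm(500), lambda) +
    matrix(rnorm(2000), 500) %*% diag(sqrt(1 - lambda^2))
  R <- cor(X)
  ml <- efa_extract(R, 1, method = "ml")
  fa <- stats::factanal(covmat = R, factors = 1, rotation = "none")
  expect_equal(abs(ml$loadings[, 1]), abs(unclass(fa$loadings)[, 1]),
               tolerance = 1e-8, ignore_attr = TRUE)
})
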