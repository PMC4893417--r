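## Shared fixtures and independent oracles for the test suite.

## dense-grid Riemann oracle for the integral of a piecewise-linear
## function sampled at (t, v), independent of the trapezoid implementation
dense_grid_auc <- function(t, v, n_grid = 2e5, transform = identity) {
  g <- seq(min(t), max(t), length.out = n_grid)
  f <- transform(stats::approx(t, v, xout = g)$y)
  sum((f[-1] + f[-n_grid]) / 2) * (g[2] - g[1])
}

## the Table-2-style construct membership used in structure-recovery checks
aki_construct_members <- function() {
  list(CPB = c("dur_cpb", "cross_clamp", "ultrafiltration"),
       LCOS = c("age", "sap", "lactate", "transfusions"),
       AKI = c("ungal", "dscr50", "oliguria"),
       Outcome = c("vent_days", "icu_days", "mortality"))
}

## does a refinement reproduce the four-construct grouping?  Success:
## four factors; for every construct at least two retained members, all on
## one factor; the four construct factors distinct; no retained member on
## a foreign factor.
grouping_matches <- function(refinement,
                             members = aki_construct_members()) {
  if (refinement$n_factors != length(members)) return(FALSE)
  a <- refinement$assignment
  fo <- vapply(members, function(w) {
    x <- a[intersect(w, names(a))]
    if (length(x) >= 2 && length(unique(x)) == 1) unique(x) else NA_integer_
  }, integer(1))
  !anyNA(fo) && length(unique(fo)) == length(members)
}

## a random identified one-factor model: returns a sample correlation
## matrix (n draws) plus the generating loadings
rand_onefactor <- function(seed, p = 5, n = 400) {
  set.seed(seed)
  lambda <- runif(p, 0.4, 0.85) * sample(c(-1, 1), p, replace = TRUE)
  X <- tcrossprod(rnorm(n), lambda) +
    matrix(rnorm(n * p), n) %*% diag(sqrt(1 - lambda^2))
  list(R = cor(X), lambda = lambda, n = n, p = p)
}

## textbook ML discrepancy, written independently of the package engine
fml_direct <- function(Sigma, S) {
  p <- nrow(S)
  as.numeric(determinant(Sigma)$modulus) + sum(diag(S %*% solve(Sigma))) -
    as.numeric(determinant(S)$modulus) - p
}

## two-latent toy model (3 indicators each, free latent correlation):
## sample data plus an independent brute-force ML fit over the explicit
## (lambda_1..6, phi, psi_1..6) parameterisation
toy_two_latent <- function(seed, n = 500) {
  set.seed(seed)
  l1 <- runif(3, 0.5, 0.85)
  l2 <- runif(3, 0.5, 0.85)
  phi <- runif(1, 0.2, 0.6)
  P <- matrix(c(1, phi, phi, 1), 2)
  L <- rbind(cbind(l1, 0), cbind(0, l2))
  eta <- matrix(rnorm(n * 2), n) %*% chol(P)
  X <- eta %*% t(L) + matrix(rnorm(n * 6), n) %*%
    diag(sqrt(1 - c(l1^2, l2^2)))
  colnames(X) <- paste0("x", 1:6)
  list(R = cor(X), n = n)
}

brute_force_two_latent <- function(R) {
  obj <- function(th) {
    L <- rbind(cbind(th[1:3], 0), cbind(0, th[4:6]))
    P <- matrix(c(1, th[7], th[7], 1), 2)
    Sigma <- L %*% P %*% t(L) + diag(th[8:13])
    if (any(th[8:13] <= 1e-6) || abs(th[7]) >= 0.999) return(1e6)
    ch <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(ch)) return(1e6)
    fml_direct(Sigma, R)
  }
  opt <- stats::optim(c(rep(0.6, 6), 0.3, rep(0.5, 6)), obj,
                      method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  ## polish with Nelder-Mead from the BFGS solution
  opt <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  opt
}

## spec object for the same toy model in the package's parameterisation
toy_two_latent_spec <- function() {
  sem_spec(latents = c("G1", "G2"), observed = paste0("x", 1:6),
           paths = data.frame(from = rep(c("G1", "G2"), each = 3),
                              to = paste0("x", 1:6), value = NA))
}
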