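## Maximum-likelihood covariance structure estimation.
##
## F_ML(theta) = ln|Sigma| + tr(S Sigma^-1) - ln|S| - p, minimised by
## quasi-Newton with the analytic gradient.  With B = (I-A)^-1 and
## E = B S B^T the full-variable implied covariance, and
## C = Sigma^-1 (Sigma - S_obs) Sigma^-1 padded to all variables (Cf):
##   dF/dA[r,c] = 2 (E Cf B)[c, r]
##   dF/dS[r,c] = (2 - delta_rc) (B^T Cf B)[r, c]
## which evaluates the whole gradient in a handful of matrix products.

sem_engine <- function(spec) {
  pm <- spec$parameters
  free <- pm[pm$free, , drop = FALSE]
  fixedA <- pm[!pm$free & pm$matrix == "A", , drop = FALSE]
  fixedS <- pm[!pm$free & pm$matrix == "S", , drop = FALSE]
  m <- spec$m; p <- spec$p
  iA <- free$matrix == "A"
  iS <- free$matrix == "S"
  A_rc <- cbind(free$row[iA], free$col[iA])
  S_rc <- cbind(free$row[iS], free$col[iS])
  S_diag <- free$row[iS] == free$col[iS]
  A0 <- matrix(0, m, m); A0[cbind(fixedA$row, fixedA$col)] <- fixedA$value
  S0 <- matrix(0, m, m)
  S0[cbind(fixedS$row, fixedS$col)] <- fixedS$value
  S0[cbind(fixedS$col, fixedS$row)] <- fixedS$value
  build <- function(theta) {
    A <- A0; S <- S0
    A[A_rc] <- theta[iA]
    S[S_rc] <- theta[iS]
    S[S_rc[, c(2, 1), drop = FALSE]] <- theta[iS]
    list(A = A, S = S)
  }
  eval_fg <- function(theta, Sobs, logdet_obs, gradient = TRUE) {
    ms <- build(theta)
    B <- tryCatch(solve(diag(m) - ms$A), error = function(e) NULL)
    if (is.null(B)) return(list(f = 1e10, g = rep(0, length(theta))))
    E <- B %*% ms$S %*% t(B)
    Sig <- E[seq_len(p), seq_len(p), drop = FALSE]
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(ch)) return(list(f = 1e10, g = rep(0, length(theta))))
    iSig <- chol2inv(ch)
    f <- 2 * sum(log(diag(ch))) + sum(iSig * Sobs) - logdet_obs - p
    if (!gradient) return(list(f = as.numeric(f), B = B, E = E, Sig = Sig,
                               iSig = iSig, ms = ms))
    C <- iSig - iSig %*% Sobs %*% iSig
    Cf <- matrix(0, m, m); Cf[seq_len(p), seq_len(p)] <- C
    ECB <- E %*% Cf %*% B
    BCB <- crossprod(B, Cf %*% B)
    g <- numeric(length(theta))
    g[iA] <- 2 * ECB[A_rc[, c(2, 1), drop = FALSE]]
    g[iS] <- ifelse(S_diag, 1, 2) * BCB[S_rc]
    list(f = as.numeric(f), g = g)
  }
  ## per-parameter derivative matrices of the observed-block Sigma
  derivs <- function(B, E, rows, cols, matrices) {
    lapply(seq_along(rows), function(i) {
      r <- rows[i]; c <- cols[i]
      D <- if (matrices[i] == "A") {
        T1 <- outer(B[, r], E[c, ])
        T1 + t(T1)
      } else if (r == c) {
        tcrossprod(B[, r])
      } else {
        T1 <- outer(B[, r], B[, c])
        T1 + t(T1)
      }
      D[seq_len(p), seq_len(p), drop = FALSE]
    })
  }
  list(build = build, eval_fg = eval_fg, derivs = derivs, free = free,
       iA = iA, iS = iS)
}

#' Fit a structural equation model by maximum likelihood
#'
#' Minimises the ML discrepancy between the sample covariance (by default
#' the correlation matrix of the data, so that all results are standardized)
#' and the model-implied covariance, by quasi-Newton iteration with an
#' analytic gradient from documented start values (0.5 for every free
#' coefficient and variance).  Standard errors come from the inverse
#' expected information; the chi-square statistic is `(n - 1) * F_min`.
#'
#' @param spec a [sem_spec()].
#' @param data data frame / matrix of observed variables (a `patient_id`
#'   column is ignored); alternatively supply `sample_cov` and `n`.
#' @param sample_cov sample covariance or correlation matrix.
#' @param n sample size (required with `sample_cov`).
#' @param use `"correlation"` (default) analyses the correlation matrix of
#'   `data`; `"covariance"` the covariance matrix.
#' @param start optional start vector (length `spec$npar`).
#' @param bound_variances constrain variance parameters to be non-negative
#'   (optional treatment of Heywood cases; default `FALSE`, warn only).
#' @param max_iter,tol optimiser controls (`tol` is the relative tolerance
#'   on the discrepancy function).
#' @return a `sem_fit`: estimates with standard errors and z tests,
#'   `standardized` solution, `F_min`, `chisq`, `df`, fit indices
#'   (RMSEA, NFI, GFI, BIC), convergence metadata and Heywood flag.
#' @examples
#' cfg <- cohort_config(n_patients = 500, seed = 5)
#' ind <- simulate_indicators(simulate_latents(cfg), cfg,
#'                            mortality = "propensity")
#' fit <- sem_fit(aki_model_spec(), ind)
#' fit
#' @export
sem_fit <- function(spec, data = NULL, sample_cov = NULL, n = NULL,
                    use = c("correlation", "covariance"), start = NULL,
                    bound_variances = FALSE, max_iter = 1000, tol = 1e-10) {
  use <- match.arg(use)
  if (is.null(sample_cov)) {
    if (is.null(data)) stop2("supply 'data' or 'sample_cov'")
    d <- as.data.frame(data)
    d$patient_id <- NULL
    d <- as.matrix(d[spec$observed])
    n <- nrow(d)
    sample_cov <- if (use == "correlation") stats::cor(d) else stats::cov(d)
  } else {
    if (is.null(n)) stop2("supply 'n' with 'sample_cov'")
    sample_cov <- sample_cov[spec$observed, spec$observed]
  }
  p <- spec$p
  if (n <= spec$npar)
    warning("sample size does not exceed the number of free parameters",
            call. = FALSE)
  ld <- determinant(sample_cov, logarithm = TRUE)
  if (ld$sign <= 0) stop2("sample covariance matrix is not positive-definite")
  logdet_obs <- as.numeric(ld$modulus)
  eng <- sem_engine(spec)
  theta0 <- start %||% spec$parameters$start[spec$parameters$free]
  lower <- if (bound_variances)
    ifelse(eng$iS & eng$free$row == eng$free$col, 0, -Inf) else -Inf
  opt <- stats::nlminb(theta0,
                       function(t) eng$eval_fg(t, sample_cov, logdet_obs)$f,
                       gradient = function(t) eng$eval_fg(t, sample_cov, logdet_obs)$g,
                       lower = lower,
                       control = list(iter.max = max_iter, eval.max = 4 * max_iter,
                                      rel.tol = tol))
  at <- eng$eval_fg(opt$par, sample_cov, logdet_obs)
  gnorm <- sqrt(sum(at$g^2))
  if (opt$objective >= 1e9 ||
      (opt$convergence != 0 && gnorm > 1e-4 && !bound_variances)) {
    cond <- simpleError(sprintf(
      "SEM fit did not converge (%s); best F = %.6g, gradient norm %.3g",
      opt$message, opt$objective, gnorm))
    cond$theta <- opt$par; cond$gradient_norm <- gnorm
    stop(cond)
  }
  theta <- opt$par
  state <- eng$eval_fg(theta, sample_cov, logdet_obs, gradient = FALSE)
  free <- eng$free
  ## Heywood check: negative variance estimates
  var_idx <- which(eng$iS & free$row == free$col)
  heywood <- any(theta[var_idx] < 0)
  if (heywood)
    warning("Heywood case: negative residual variance estimate for ",
            paste(free$label[var_idx][theta[var_idx] < 0], collapse = ", "),
            call. = FALSE)
  ## expected information and standard errors
  D <- eng$derivs(state$B, state$E, free$row, free$col, free$matrix)
  iSig <- state$iSig
  SD <- lapply(D, function(d) iSig %*% d)
  q <- length(D)
  H <- matrix(0, q, q)
  for (i in seq_len(q))
    for (j in i:q)
      H[i, j] <- H[j, i] <- 0.5 * sum(SD[[i]] * t(SD[[j]]))
  acov <- tryCatch(solve(H) / (n - 1), error = function(e) NULL)
  se <- if (is.null(acov)) rep(NA_real_, q) else sqrt(pmax(diag(acov), 0))
  est <- data.frame(label = free$label, from = spec$all_vars[free$col],
                    to = spec$all_vars[free$row], matrix = free$matrix,
                    est = theta, se = se, z = theta / se,
                    p_value = 2 * stats::pnorm(-abs(theta / se)))
  est$from[est$matrix == "S"] <- spec$all_vars[free$row[free$matrix == "S"]]
  est$to[est$matrix == "S"] <- spec$all_vars[free$col[free$matrix == "S"]]
  chisq <- (n - 1) * opt$objective
  df <- spec$df_model
  ## independence (null) model: free variances only
  F_null <- sum(log(diag(sample_cov))) - logdet_obs
  chisq_null <- (n - 1) * F_null
  df_null <- p * (p - 1) / 2
  fi <- fit_indices(chisq, df, n, chisq_null, df_null,
                    S_obs = sample_cov, sigma_hat = state$Sig)
  fit <- structure(list(
    spec = spec, estimates = est, theta = theta, se = se, acov = acov,
    F_min = opt$objective, chisq = chisq, df = df, n = n,
    chisq_null = chisq_null, df_null = df_null,
    fit_indices = fi, S_obs = sample_cov, sigma_hat = state$Sig,
    heywood = heywood,
    convergence = list(iterations = opt$iterations, gradient_norm = gnorm,
                       message = opt$message)),
    class = "sem_fit")
  fit$standardized <- standardized_solution(fit)
  fit
}

#' Covariance-structure fit indices
#'
#' RMSEA `sqrt(max(chisq - df, 0) / (df (n - 1)))`; NFI
#' `(chisq_null - chisq) / chisq_null`; GFI
#' `1 - tr[(Sigma^-1 S - I)^2] / tr[(Sigma^-1 S)^2]`; BIC
#' `chisq - df ln(n)` (the form that yields negative values for
#' well-fitting over-identified models).
#'
#' @param chisq,df model chi-square and degrees of freedom.
#' @param n sample size.
#' @param chisq_null,df_null independence-model chi-square and df.
#' @param S_obs,sigma_hat sample and fitted covariance (for GFI; optional).
#' @return list with `rmsea`, `nfi`, `gfi`, `bic` and `rmsea_defined`.
#' @examples
#' fit_indices(chisq = 100, df = 50, n = 201, chisq_null = 1000,
#'             df_null = 78)$rmsea   # sqrt(50/10000) ~ 0.0707
#' @export
fit_indices <- function(chisq, df, n, chisq_null = NULL, df_null = NULL,
                        S_obs = NULL, sigma_hat = NULL) {
  rmsea_defined <- df > 0
  rmsea <- if (df > 0) sqrt(max(chisq - df, 0) / (df * (n - 1))) else 0
  nfi <- if (!is.null(chisq_null) && chisq_null > 0)
    (chisq_null - chisq) / chisq_null else NA_real_
  gfi <- NA_real_
  if (!is.null(S_obs) && !is.null(sigma_hat)) {
    W <- solve(sigma_hat, S_obs)
    R <- W - diag(nrow(W))
    gfi <- 1 - sum(diag(R %*% R)) / sum(diag(W %*% W))
  }
  list(rmsea = rmsea, rmsea_defined = rmsea_defined, nfi = nfi, gfi = gfi,
       bic = chisq - df * log(n))
}

#' Standardized solution of a fitted model
#'
#' Rescales every coefficient to unit-variance variables: a directed
#' coefficient from j to i becomes `est * sd(j) / sd(i)` with the model-
#' implied standard deviations; a covariance arc between residuals is
#' expressed as the residual correlation
#' `S[a,b] / sqrt(S[a,a] S[b,b])`; variances become proportions of the
#' corresponding variable's implied variance.
#'
#' @param fit a `sem_fit`.
#' @return data frame `label`, `from`, `to`, `matrix`, `est`, `std`.
#' @export
standardized_solution <- function(fit) {
  spec <- fit$spec
  eng <- sem_engine(spec)
  ms <- eng$build(fit$theta)
  B <- solve(diag(spec$m) - ms$A)
  E <- B %*% ms$S %*% t(B)
  sdv <- sqrt(pmax(diag(E), 1e-12))
  free <- eng$free
  std <- numeric(nrow(free))
  for (i in seq_len(nrow(free))) {
    r <- free$row[i]; c <- free$col[i]
    std[i] <- if (free$matrix[i] == "A") {
      fit$theta[i] * sdv[c] / sdv[r]
    } else if (r == c) {
      fit$theta[i] / (sdv[r]^2)
    } else {
      ## residual correlation; near-zero (or Heywood) residual variances
      ## make the ratio degenerate, and a correlation cannot exceed 1 in
      ## magnitude, so the estimate is clamped
      rho <- fit$theta[i] / sqrt(pmax(ms$S[r, r] * ms$S[c, c], 1e-12))
      max(min(rho, 1), -1)
    }
  }
  data.frame(label = free$label, from = spec$all_vars[free$col],
             to = spec$all_vars[free$row], matrix = free$matrix,
             est = fit$theta, std = std)
}

#' @export
print.sem_fit <- function(x, digits = 3, ...) {
  cat(sprintf("SEM fit: chi^2 = %.2f on %d df (n = %d), F_min = %.5f\n",
              x$chisq, x$df, x$n, x$F_min))
  fi <- x$fit_indices
  cat(sprintf("  RMSEA = %.3f, NFI = %.3f, GFI = %.3f, BIC = %.2f\n",
              fi$rmsea, fi$nfi, fi$gfi, fi$bic))
  if (x$heywood) cat("  note: Heywood case (negative residual variance)\n")
  tab <- merge(x$estimates, x$standardized[c("label", "std")], by = "label",
               sort = FALSE)
  print(cbind(tab["label"], round(tab[c("est", "se", "z", "std")], digits)),
        row.names = FALSE)
  invisible(x)
}

#' Export a fitted parameter table as CSV
#'
#' One row per free parameter: estimate, standard error, z, p, and the
#' standardized coefficient.
#'
#' @param fit a `sem_fit`.
#' @param path file path.
#' @export
write_sem_fit_csv <- function(fit, path) {
  tab <- merge(fit$estimates, fit$standardized[c("label", "std")],
               by = "label", sort = FALSE)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Export the fit summary as JSON
#'
#' @param fit a `sem_fit`.
#' @param path file path.
#' @export
write_fit_summary_json <- function(fit, path) {
  jsonlite::write_json(
    list(chisq = fit$chisq, df = fit$df, n = fit$n, F_min = fit$F_min,
         rmsea = fit$fit_indices$rmsea, nfi = fit$fit_indices$nfi,
         gfi = fit$fit_indices$gfi, bic = fit$fit_indices$bic,
         heywood = fit$heywood, convergence = fit$convergence),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
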