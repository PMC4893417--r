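#' Lagrange-multiplier modification indices
#'
#' Score-test statistic for each currently omitted parameter: the expected
#' chi-square drop if the parameter were freed, computed from the gradient
#' and expected information at the restricted optimum,
#' `MI = (n - 1) g_k^2 / (4 (h_kk - h_kf H_ff^-1 h_fk))`, where `g` is the
#' gradient of the ML discrepancy and `h` the half-trace expected-Hessian
#' blocks `(1/2) tr(Sigma^-1 dSigma_i Sigma^-1 dSigma_j)`.
#'
#' @param fit a [sem_fit()].
#' @param candidates data frame `a`, `b`, `matrix` of candidate parameters
#'   (`matrix = "S"` for covariance arcs, `"A"` for directed paths
#'   `a -> b`); `NULL` proposes every omitted residual covariance among the
#'   observed variables.
#' @return data frame `label`, `a`, `b`, `matrix`, `mi`, sorted by
#'   decreasing index.  Freeing a candidate that is already free is an
#'   error.
#' @examples
#' cfg <- cohort_config(n_patients = 300, seed = 2)
#' ind <- simulate_indicators(simulate_latents(cfg), cfg)
#' fit <- sem_fit(aki_model_spec(covariance_arcs = FALSE), ind)
#' head(modification_indices(fit), 3)
#' @export
modification_indices <- function(fit, candidates = NULL) {
  spec <- fit$spec
  auto <- is.null(candidates)
  if (auto) {
    obs <- spec$observed
    cand <- utils::combn(obs, 2)
    candidates <- data.frame(a = cand[1, ], b = cand[2, ], matrix = "S")
  }
  if (is.null(candidates$matrix)) candidates$matrix <- "S"
  pm <- spec$parameters
  idx <- function(v) match(v, spec$all_vars)
  keep <- rep(TRUE, nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    r <- idx(candidates$a[i]); c <- idx(candidates$b[i])
    if (is.na(r) || is.na(c))
      stop2("unknown variable in candidates: ", candidates$a[i], " / ",
            candidates$b[i])
    hit <- if (candidates$matrix[i] == "S")
      which(pm$matrix == "S" & ((pm$row == r & pm$col == c) |
                                  (pm$row == c & pm$col == r)))
    else which(pm$matrix == "A" & pm$row == c & pm$col == r)
    if (length(hit)) {
      if (any(pm$free[hit]) && !auto)
        stop2("candidate already free: ", candidates$a[i],
              if (candidates$matrix[i] == "S") " ~~ " else " -> ",
              candidates$b[i])
      keep[i] <- FALSE            # already in the model: not a candidate
    }
  }
  candidates <- candidates[keep, , drop = FALSE]
  eng <- sem_engine(spec)
  state <- eng$eval_fg(fit$theta, fit$S_obs,
                       as.numeric(determinant(fit$S_obs)$modulus),
                       gradient = FALSE)
  B <- state$B; E <- state$E; iSig <- state$iSig
  C <- iSig %*% (state$Sig - fit$S_obs) %*% iSig
  p <- spec$p; m <- spec$m
  Cf <- matrix(0, m, m); Cf[seq_len(p), seq_len(p)] <- C
  free <- eng$free
  ## derivative matrices: free parameters then candidates
  crow <- ifelse(candidates$matrix == "A", idx(candidates$b), idx(candidates$a))
  ccol <- ifelse(candidates$matrix == "A", idx(candidates$a), idx(candidates$b))
  D_free <- eng$derivs(B, E, free$row, free$col, free$matrix)
  D_cand <- eng$derivs(B, E, crow, ccol, candidates$matrix)
  SD_free <- lapply(D_free, function(d) iSig %*% d)
  SD_cand <- lapply(D_cand, function(d) iSig %*% d)
  q <- length(SD_free)
  Hff <- matrix(0, q, q)
  for (i in seq_len(q))
    for (j in i:q)
      Hff[i, j] <- Hff[j, i] <- 0.5 * sum(SD_free[[i]] * t(SD_free[[j]]))
  Hff_inv <- solve(Hff)
  mi <- numeric(nrow(candidates))
  ECB <- E %*% Cf %*% B
  BCB <- crossprod(B, Cf %*% B)
  for (k in seq_along(SD_cand)) {
    gk <- if (candidates$matrix[k] == "A") 2 * ECB[ccol[k], crow[k]]
    else if (crow[k] == ccol[k]) BCB[crow[k], ccol[k]]
    else 2 * BCB[crow[k], ccol[k]]
    hkk <- 0.5 * sum(SD_cand[[k]] * t(SD_cand[[k]]))
    hkf <- vapply(SD_free, function(s) 0.5 * sum(SD_cand[[k]] * t(s)),
                  numeric(1))
    denom <- hkk - as.numeric(t(hkf) %*% Hff_inv %*% hkf)
    ## score s = -(n-1)/2 g; information I = (n-1) h  =>  MI = s^2 / I_partial
    mi[k] <- if (denom > 1e-12) (fit$n - 1) * gk^2 / (4 * denom) else 0
  }
  sep <- ifelse(candidates$matrix == "S", " ~~ ", " -> ")
  out <- data.frame(label = paste0(candidates$a, sep, candidates$b),
                    a = candidates$a, b = candidates$b,
                    matrix = candidates$matrix, mi = mi)
  out[order(-out$mi), , drop = FALSE]
}

#' BIC-guided model respecification
#'
#' Greedy Lagrange-multiplier search: free the highest-MI candidate, refit,
#' keep the addition if and only if the BIC decreases, and stop at the
#' first rejected candidate (or when no candidates remain).
#'
#' @param spec base [sem_spec()].
#' @param data,sample_cov,n data or sample covariance as in [sem_fit()].
#' @param candidates candidate pool as in [modification_indices()];
#'   `NULL` proposes all omitted residual covariances.
#' @param max_add maximum number of additions.
#' @param ... passed to [sem_fit()].
#' @return list with `spec` (final specification), `fit` (final fit) and
#'   `log` (data frame: `step`, `label`, `mi`, `chisq`, `bic`, `kept`).
#' @export
sem_respecify <- function(spec, data = NULL, sample_cov = NULL, n = NULL,
                          candidates = NULL, max_add = 10, ...) {
  fit <- sem_fit(spec, data = data, sample_cov = sample_cov, n = n, ...)
  log <- data.frame(step = integer(), label = character(), mi = numeric(),
                    chisq = numeric(), bic = numeric(), kept = logical())
  if (!is.null(candidates) && !nrow(candidates))
    return(list(spec = spec, fit = fit, log = log))
  for (step in seq_len(max_add)) {
    mi <- tryCatch(modification_indices(fit, candidates),
                   error = function(e) NULL)
    if (is.null(mi) || !nrow(mi)) break
    top <- mi[1, ]
    cov2 <- rbind(spec$covariances %||%
                    data.frame(a = character(), b = character(),
                               value = numeric()),
                  data.frame(a = top$a, b = top$b, value = NA_real_))
    spec2 <- sem_spec(spec$latents, spec$observed, spec$paths, cov2,
                      latent_scaling = spec$latent_scaling)
    fit2 <- tryCatch(sem_fit(spec2, data = data, sample_cov = sample_cov,
                             n = n, ...),
                     error = function(e) NULL)
    kept <- !is.null(fit2) && fit2$fit_indices$bic < fit$fit_indices$bic
    log[nrow(log) + 1L, ] <- list(step, top$label, top$mi,
                                  if (is.null(fit2)) NA_real_ else fit2$chisq,
                                  if (is.null(fit2)) NA_real_ else fit2$fit_indices$bic,
                                  kept)
    if (!kept) break
    spec <- spec2; fit <- fit2
    if (!is.null(candidates))
      candidates <- candidates[!(candidates$a == top$a & candidates$b == top$b), ,
                               drop = FALSE]
  }
  list(spec = spec, fit = fit, log = log)
}
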