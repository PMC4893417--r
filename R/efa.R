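#' Bartlett test of sphericity
#'
#' Tests whether a correlation matrix differs from the identity,
#' chi-square = -(n - 1 - (2p + 5)/6) * ln det(R) with p(p-1)/2 degrees of
#' freedom.  A significant result indicates correlations beyond chance,
#' i.e. data amenable to factor analysis.
#'
#' @param R correlation matrix.
#' @param n sample size.
#' @return list with `chisq`, `df`, `p_value`, class `"bartlett_sphericity"`.
#' @examples
#' bartlett_sphericity(diag(5), n = 100)$chisq   # 0
#' @export
bartlett_sphericity <- function(R, n) {
  p <- ncol(R)
  ld <- determinant(R, logarithm = TRUE)
  if (ld$sign <= 0 || !is.finite(ld$modulus))
    stop2("correlation matrix is not positive-definite")
  chisq <- -(n - 1 - (2 * p + 5) / 6) * as.numeric(ld$modulus)
  df <- p * (p - 1) / 2
  structure(list(chisq = chisq, df = df,
                 p_value = stats::pchisq(chisq, df, lower.tail = FALSE)),
            class = "bartlett_sphericity")
}

#' @export
print.bartlett_sphericity <- function(x, ...) {
  cat(sprintf("Bartlett test of sphericity: chi^2 = %.1f, df = %d, p %s\n",
              x$chisq, x$df,
              if (x$p_value < 0.001) "< 0.001" else sprintf("= %.3f", x$p_value)))
  invisible(x)
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Ratio of summed squared correlations to summed squared correlations plus
#' summed squared partial (anti-image) correlations, over all off-diagonal
#' pairs.  Values near 1 indicate compact correlation patterns suited to
#' factor analysis; with only two variables the measure is 0.5 by
#' construction.
#'
#' @param R correlation matrix.
#' @return list with `overall` KMO and per-variable `msa`, class `"kmo"`.
#' @export
kmo <- function(R) {
  Ri <- tryCatch(solve(R), error = function(e)
    stop2("correlation matrix is singular"))
  d <- 1 / sqrt(diag(Ri))
  A <- -Ri * outer(d, d)          # anti-image (partial) correlations
  diag(A) <- 0
  R0 <- R; diag(R0) <- 0
  overall <- sum(R0^2) / (sum(R0^2) + sum(A^2))
  msa <- colSums(R0^2) / (colSums(R0^2) + colSums(A^2))
  structure(list(overall = overall, msa = msa), class = "kmo")
}

#' @export
print.kmo <- function(x, ...) {
  cat(sprintf("Kaiser-Meyer-Olkin measure of sampling adequacy: %.3f\n",
              x$overall))
  invisible(x)
}

#' Extract common factors
#'
#' Principal-axis factoring (default) with iterated communality estimates
#' started at the squared multiple correlations, or maximum likelihood
#' extraction via [stats::factanal()].  Eigenvalues are those of the
#' reduced correlation matrix at the converged communalities.
#'
#' @param R correlation matrix.
#' @param n_factors number of factors to extract.
#' @param method `"paf"` or `"ml"`.
#' @param max_iter,tol communality iteration controls (PAF).
#' @return an `efa_solution`: list with `loadings` (p x k, unrotated),
#'   `eigenvalues`, `communalities`, `method`, `rotation = "none"`.
#' @examples
#' R <- tcrossprod(c(.8, .7, .6)); diag(R) <- 1
#' round(efa_extract(R, 1)$loadings, 3)
#' @export
efa_extract <- function(R, n_factors, method = c("paf", "ml"),
                        max_iter = 5000, tol = 1e-5) {
  method <- match.arg(method)
  p <- ncol(R)
  vn <- colnames(R) %||% paste0("V", seq_len(p))
  if (n_factors < 1 || n_factors >= p)
    stop2("'n_factors' must be between 1 and p - 1")
  if (method == "ml") {
    fa <- stats::factanal(covmat = R, factors = n_factors, rotation = "none")
    L <- unclass(fa$loadings)
    ev <- eigen(`diag<-`(R, rowSums(L^2)), symmetric = TRUE,
                only.values = TRUE)$values
    sol <- list(loadings = L, eigenvalues = ev,
                communalities = rowSums(L^2), method = "ml",
                rotation = "none")
  } else {
    h <- 1 - 1 / diag(solve(R))           # SMC start
    L <- NULL; converged <- FALSE
    damp <- 0
    for (it in seq_len(max_iter)) {
      Rr <- R; diag(Rr) <- h
      e <- eigen(Rr, symmetric = TRUE)
      L <- e$vectors[, seq_len(n_factors), drop = FALSE] %*%
        diag(sqrt(pmax(e$values[seq_len(n_factors)], 0)), n_factors)
      ## cap at [0, 1]: unbounded communality iteration can drift above 1
      ## (ultra-Heywood) and oscillate on nearly collinear variable blocks
      hn <- pmin(pmax(rowSums(L^2), 0), 1)
      ## after a burn-in, average the update: the plain fixed-point map can
      ## settle into a period-2 cycle near degenerate eigenvalues, which
      ## the half-step removes without moving the fixed point
      hn <- (1 - damp) * hn + damp * h
      if (it == 50L) damp <- 0.5
      change <- max(abs(hn - h))
      h <- hn
      if (change < tol) { converged <- TRUE; break }
    }
    if (!converged)
      stop2(sprintf("communality iteration did not converge in %d iterations (last change %.2e)",
                    max_iter, change))
    sol <- list(loadings = L, eigenvalues = e$values,
                communalities = h, method = "paf", rotation = "none")
  }
  dimnames(sol$loadings) <- list(vn, paste0("F", seq_len(n_factors)))
  names(sol$communalities) <- vn
  class(sol) <- "efa_solution"
  sol
}

#' Varimax rotation
#'
#' Kaiser-normalized varimax rotation of a loading matrix (via
#' [stats::varimax()]), with the sign of each factor fixed so that its
#' largest-magnitude loading is positive.  Being orthogonal, the rotation
#' preserves communalities exactly.
#'
#' @param loadings p x k loading matrix or an `efa_solution`.
#' @return rotated loadings (same form as the input).
#' @export
efa_varimax <- function(loadings) {
  sol <- NULL
  if (inherits(loadings, "efa_solution")) { sol <- loadings; loadings <- sol$loadings }
  L <- if (ncol(loadings) > 1L)
    unclass(stats::varimax(loadings, normalize = TRUE, eps = 1e-10)$loadings)
  else loadings
  for (j in seq_len(ncol(L)))
    if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  dimnames(L) <- dimnames(loadings)
  if (is.null(sol)) return(L)
  sol$loadings <- L
  sol$rotation <- "varimax"
  sol
}

#' Number of factors by the latent-root criterion
#'
#' Counts the eigenvalues of the (unreduced) correlation matrix greater
#' than one.  With strongly correlated constructs this criterion is known
#' to undercount; [efa_refine()] accepts an explicit `n_factors` override.
#'
#' @param R correlation matrix.
#' @return integer count.
#' @export
kaiser_count <- function(R) {
  sum(eigen(R, symmetric = TRUE, only.values = TRUE)$values > 1)
}

#' Proportion of variance explained by each factor
#'
#' Per-factor sum of squared loadings divided by the total number of
#' variables, and their sum.
#'
#' @param x loading matrix or `efa_solution`.
#' @param p_total divisor: number of variables over which proportions are
#'   expressed (defaults to the number of rows of the loading matrix).
#' @return list with `proportions` (per factor) and `total`.
#' @examples
#' variance_explained(aki_efa_loadings())
#' @export
variance_explained <- function(x, p_total = NULL) {
  L <- if (inherits(x, "efa_solution")) x$loadings else x
  p_total <- p_total %||% nrow(L)
  prop <- colSums(L^2) / p_total
  list(proportions = prop, total = sum(prop))
}

#' Exploratory factor analysis of an indicator matrix
#'
#' Convenience wrapper: correlation matrix, adequacy diagnostics,
#' extraction and varimax rotation in one call.
#'
#' @param x indicator matrix / data frame (a `patient_id` column is
#'   ignored) or a correlation matrix (with `n` supplied).
#' @param n_factors number of factors; `NULL` uses [kaiser_count()].
#' @param n sample size (required when `x` is a correlation matrix).
#' @param method extraction method, see [efa_extract()].
#' @param rotate apply varimax rotation?
#' @return an `efa_solution` with `adequacy` (Bartlett + KMO) attached.
#' @export
efa <- function(x, n_factors = NULL, n = NULL, method = "paf", rotate = TRUE) {
  if (is.matrix(x) && isSymmetric(unname(x)) && all(abs(diag(x) - 1) < 1e-12)) {
    R <- x
    if (is.null(n)) stop2("supply 'n' when passing a correlation matrix")
  } else {
    d <- as.data.frame(x)
    d$patient_id <- NULL
    R <- stats::cor(as.matrix(d))
    n <- nrow(d)
  }
  k <- n_factors %||% max(1L, kaiser_count(R))
  sol <- efa_extract(R, k, method = method)
  if (rotate) sol <- efa_varimax(sol)
  sol$adequacy <- list(bartlett = bartlett_sphericity(R, n), kmo = kmo(R))
  sol$n <- n
  sol
}

#' @export
print.efa_solution <- function(x, digits = 3, cutoff = 0.2, ...) {
  cat(sprintf("Factor solution: %d factors, %s extraction, %s rotation\n",
              ncol(x$loadings), x$method, x$rotation))
  L <- round(x$loadings, digits)
  Lc <- format(L)
  Lc[abs(L) < cutoff] <- ""
  print(cbind(as.data.frame(Lc),
              communality = round(x$communalities, digits)))
  ve <- variance_explained(x)
  cat(sprintf("Variance explained: %s (total %.3f)\n",
              paste(sprintf("%.3f", ve$proportions), collapse = ", "),
              ve$total))
  if (!is.null(x$adequacy)) { print(x$adequacy$bartlett); print(x$adequacy$kmo) }
  invisible(x)
}

#' Write a factor solution as CSV
#'
#' Loadings table (one row per variable, one column per factor) with
#' communalities, followed by eigenvalue and proportion rows.
#'
#' @param sol an `efa_solution`.
#' @param path file path.
#' @export
write_factor_solution_csv <- function(sol, path) {
  L <- sol$loadings
  ve <- variance_explained(sol)
  tab <- rbind(cbind(as.data.frame(L), communality = sol$communalities),
               eigenvalue = c(sol$eigenvalues[seq_len(ncol(L))], NA),
               proportion = c(ve$proportions, ve$total))
  utils::write.csv(tab, path, row.names = TRUE)
  invisible(path)
}
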