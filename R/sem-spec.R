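#' Specify a covariance-structure model with latent variables
#'
#' Defines a structural equation model in RAM form: an asymmetric matrix
#' `A` of directed coefficients (loadings and structural paths), a
#' symmetric matrix `S` of variances and covariances of exogenous terms and
#' residuals, and a selection of observed variables `F`.  The model-implied
#' covariance is `F (I - A)^-1 S (I - A)^-T F^T`.
#'
#' Free parameters are: every path with `value = NA`; the residual variance
#' of every observed variable; the residual variance of every endogenous
#' latent; and every covariance with `value = NA`.  Latent scaling fixes
#' each exogenous latent variance at 1 (`"unit_variance"`, the default) or
#' fixes the first loading of every latent at 1 (`"marker"`); either way
#' the reported standardized solution rescales all coefficients to
#' unit-variance variables.
#'
#' @param latents character vector of latent variable names (may be empty
#'   for observed-variable path models).
#' @param observed character vector of observed variable names.
#' @param paths data frame `from`, `to`, `value` (`NA` = free; a number
#'   fixes the coefficient).
#' @param covariances optional data frame `a`, `b`, `value` of two-headed
#'   arcs (between residuals of the named variables, or between exogenous
#'   variables).
#' @param latent_scaling `"unit_variance"` or `"marker"`.
#' @return a `sem_spec` object; notable fields: `parameters` (the free
#'   parameter table with labels), `npar`, `df_model` (degrees of freedom
#'   `p(p+1)/2 - npar`).
#' @examples
#' spec <- sem_spec(latents = "F1", observed = c("x1", "x2", "x3"),
#'                  paths = data.frame(from = "F1", to = c("x1", "x2", "x3"),
#'                                     value = NA))
#' spec$npar      # 3 loadings + 3 residual variances
#' @export
sem_spec <- function(latents, observed, paths, covariances = NULL,
                     latent_scaling = c("unit_variance", "marker")) {
  latent_scaling <- match.arg(latent_scaling)
  stopifnot(is.data.frame(paths), all(c("from", "to") %in% names(paths)))
  if (is.null(paths$value)) paths$value <- NA_real_
  all_vars <- c(observed, latents)
  if (anyDuplicated(all_vars))
    stop2("duplicate variable names across observed and latents")
  bad <- setdiff(unique(c(paths$from, paths$to)), all_vars)
  if (length(bad)) stop2("unknown variables in paths: ", paste(bad, collapse = ", "))
  if (anyDuplicated(paths[c("from", "to")]))
    stop2("duplicate directed edges in 'paths'")
  ## acyclicity among latents (validated via topological sort)
  lp <- paths[paths$from %in% latents & paths$to %in% latents, , drop = FALSE]
  if (length(latents)) topological_order(latents, lp$from, lp$to)
  ## reachability: every observed variable measured by some edge
  unreached <- setdiff(observed, paths$to)
  exo_obs <- unreached       # treated as exogenous observed, free variance
  endo_lat <- intersect(latents, paths$to)
  exo_lat <- setdiff(latents, endo_lat)

  m <- length(all_vars); p <- length(observed)
  idx <- function(v) match(v, all_vars)

  par <- list(); add <- function(label, matrix, row, col, free, value, start) {
    par[[length(par) + 1L]] <<- data.frame(label = label, matrix = matrix,
                                           row = row, col = col, free = free,
                                           value = value, start = start)
  }
  marker_fixed <- character(0)
  if (latent_scaling == "marker")
    for (l in latents) {
      first <- paths$to[paths$from == l & paths$to %in% observed][1]
      if (!is.na(first)) marker_fixed <- c(marker_fixed, paste(l, first))
    }
  for (i in seq_len(nrow(paths))) {
    lab <- paste0(paths$from[i], " -> ", paths$to[i])
    fixed_marker <- paste(paths$from[i], paths$to[i]) %in% marker_fixed
    free <- is.na(paths$value[i]) && !fixed_marker
    val <- if (fixed_marker) 1 else paths$value[i]
    add(lab, "A", idx(paths$to[i]), idx(paths$from[i]), free,
        ifelse(free, NA, val), 0.5)
  }
  ## variances
  for (v in observed)
    add(paste0(v, " ~~ ", v), "S", idx(v), idx(v), TRUE, NA, 0.5)
  ## latent scale: without a fixed scale per latent the likelihood is flat
  ## along a rescaling ridge (loadings down, paths/variance up).  Unit
  ## scaling fixes exogenous latent variances and endogenous latent
  ## *residual* variances at 1; marker scaling frees them (the fixed
  ## first loading carries the scale instead).
  for (l in exo_lat) {
    fixed <- latent_scaling == "unit_variance"
    add(paste0(l, " ~~ ", l), "S", idx(l), idx(l), !fixed,
        ifelse(fixed, 1, NA), 0.5)
  }
  for (l in endo_lat) {
    fixed <- latent_scaling == "unit_variance"
    add(paste0(l, " ~~ ", l), "S", idx(l), idx(l), !fixed,
        ifelse(fixed, 1, NA), 0.5)
  }
  ## covariances between exogenous latents are free by default
  if (length(exo_lat) > 1L)
    for (i in seq_len(length(exo_lat) - 1L))
      for (j in seq(i + 1L, length(exo_lat)))
        add(paste0(exo_lat[i], " ~~ ", exo_lat[j]), "S",
            idx(exo_lat[i]), idx(exo_lat[j]), TRUE, NA, 0)
  if (!is.null(covariances) && nrow(covariances)) {
    if (is.null(covariances$value)) covariances$value <- NA_real_
    for (i in seq_len(nrow(covariances))) {
      a <- covariances$a[i]; b <- covariances$b[i]
      if (!all(c(a, b) %in% all_vars))
        stop2("unknown variables in covariances: ", a, ", ", b)
      add(paste0(a, " ~~ ", b), "S", idx(a), idx(b),
          is.na(covariances$value[i]), covariances$value[i], 0)
    }
  }
  parameters <- do.call(rbind, par)
  if (anyDuplicated(parameters[c("matrix", "row", "col")]))
    stop2("duplicate parameters in the specification")
  npar <- sum(parameters$free)
  structure(list(latents = latents, observed = observed,
                 all_vars = all_vars, paths = paths,
                 covariances = covariances, latent_scaling = latent_scaling,
                 parameters = parameters, npar = npar, p = p, m = m,
                 df_model = p * (p + 1) / 2 - npar,
                 exo_obs = exo_obs),
            class = "sem_spec")
}

#' @export
print.sem_spec <- function(x, ...) {
  cat(sprintf("SEM specification: %d observed, %d latent, %d free parameters, df = %d\n",
              x$p, length(x$latents), x$npar, x$df_model))
  invisible(x)
}

#' RAM matrices of a model at a parameter point
#'
#' @param spec a [sem_spec()].
#' @param theta numeric vector of free parameter values (in the order of
#'   `spec$parameters[spec$parameters$free, ]`); `NULL` uses start values.
#' @return list with matrices `A`, `S`, `F`.
#' @export
ram_matrices <- function(spec, theta = NULL) {
  pm <- spec$parameters
  theta <- theta %||% pm$start[pm$free]
  if (length(theta) != spec$npar)
    stop2(sprintf("theta must have length %d", spec$npar))
  m <- spec$m
  A <- matrix(0, m, m, dimnames = list(spec$all_vars, spec$all_vars))
  S <- matrix(0, m, m, dimnames = list(spec$all_vars, spec$all_vars))
  vals <- pm$value
  vals[pm$free] <- theta
  isA <- pm$matrix == "A"
  A[cbind(pm$row[isA], pm$col[isA])] <- vals[isA]
  isS <- pm$matrix == "S"
  S[cbind(pm$row[isS], pm$col[isS])] <- vals[isS]
  S[cbind(pm$col[isS], pm$row[isS])] <- vals[isS]
  Fm <- diag(m)[seq_len(spec$p), , drop = FALSE]
  dimnames(Fm) <- list(spec$observed, spec$all_vars)
  list(A = A, S = S, F = Fm)
}

#' Model-implied covariance matrix
#'
#' `F (I - A)^-1 S (I - A)^-T F^T` at a given parameter point.
#'
#' @inheritParams ram_matrices
#' @return p x p implied covariance matrix of the observed variables.
#' @examples
#' spec <- sem_spec("F1", c("x1", "x2"),
#'                  data.frame(from = "F1", to = c("x1", "x2"), value = NA))
#' # loadings .8, .7; residuals 1 - lambda^2
#' implied_covariance(spec, c(.8, .7, 1 - .64, 1 - .49))
#' @export
implied_covariance <- function(spec, theta = NULL) {
  ram <- ram_matrices(spec, theta)
  B <- tryCatch(solve(diag(spec$m) - ram$A), error = function(e)
    stop2("(I - A) is singular at this parameter point"))
  E <- B %*% ram$S %*% t(B)
  sigma <- E[seq_len(spec$p), seq_len(spec$p), drop = FALSE]
  dimnames(sigma) <- list(spec$observed, spec$observed)
  sigma
}

#' Serialise a model specification as JSON
#'
#' @param spec a [sem_spec()].
#' @param path file path.
#' @export
write_sem_spec_json <- function(spec, path) {
  jsonlite::write_json(list(latents = spec$latents, observed = spec$observed,
                            paths = spec$paths,
                            covariances = spec$covariances,
                            latent_scaling = spec$latent_scaling),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Export the model graph in DOT format
#'
#' Latents as ellipses, observed variables as boxes, directed paths as
#' arrows and covariance arcs as dashed double-headed edges; edge labels
#' carry coefficients when a fitted object is supplied.
#'
#' @param x a `sem_spec` or `sem_fit`.
#' @param path file path; `NULL` returns the DOT text.
#' @return the DOT source, invisibly when written to a file.
#' @export
write_sem_dot <- function(x, path = NULL) {
  spec <- if (inherits(x, "sem_fit")) x$spec else x
  est <- if (inherits(x, "sem_fit")) x$standardized else NULL
  lab <- function(from, to) {
    if (is.null(est)) return(NA_character_)
    i <- which((est$from == from & est$to == to) |
                 (est$from == to & est$to == from))
    if (length(i)) sprintf("%.3f", est$std[i[1]]) else NA_character_
  }
  edge_attr <- function(from, to, extra = character(0)) {
    l <- lab(from, to)
    attrs <- c(extra, if (!is.na(l)) sprintf("label=\"%s\"", l))
    if (length(attrs)) sprintf(" [%s]", paste(attrs, collapse = ", ")) else ""
  }
  lines <- c("digraph sem {", "  rankdir=LR;",
             sprintf("  \"%s\" [shape=ellipse];", spec$latents),
             sprintf("  \"%s\" [shape=box];", spec$observed))
  for (i in seq_len(nrow(spec$paths)))
    lines <- c(lines, sprintf("  \"%s\" -> \"%s\"%s;", spec$paths$from[i],
                              spec$paths$to[i],
                              edge_attr(spec$paths$from[i], spec$paths$to[i])))
  if (!is.null(spec$covariances))
    for (i in seq_len(nrow(spec$covariances)))
      lines <- c(lines, sprintf(
        "  \"%s\" -> \"%s\"%s;",
        spec$covariances$a[i], spec$covariances$b[i],
        edge_attr(spec$covariances$a[i], spec$covariances$b[i],
                  c("dir=both", "style=dashed"))))
  lines <- c(lines, "}")
  txt <- paste(lines, collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
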