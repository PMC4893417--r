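#' Statistic extractors for bootstrap inference
#'
#' Helpers building named statistic functions of a fitted model, for use
#' with [sem_bootstrap()]: a standardized direct path (or loading), a
#' Wright total effect between two variables of the fitted graph, or a
#' difference of two total effects.
#'
#' @param from,to variable names in the fitted model.
#' @param from2,to2 second pair for a difference of totals.
#' @param ... passed to [total_effect()] (e.g. `exclude_nodes`).
#' @return a function mapping a `sem_fit` to a single number.
#' @examples
#' st <- stat_path("CPB", "AKI")
#' @export
stat_path <- function(from, to) {
  force(from); force(to)
  function(fit) {
    s <- fit$standardized
    i <- which(s$matrix == "A" & s$from == from & s$to == to)
    if (!length(i)) stop2("no such path in the model: ", from, " -> ", to)
    s$std[i[1]]
  }
}

#' @rdname stat_path
#' @export
stat_total_effect <- function(from, to, ...) {
  force(from); force(to)
  dots <- list(...)
  function(fit) {
    g <- as_path_graph(fit)
    do.call(total_effect, c(list(g, from, to), dots))$total
  }
}

#' @rdname stat_path
#' @export
stat_effect_difference <- function(from, to, from2, to2, ...) {
  f1 <- stat_total_effect(from, to, ...)
  f2 <- stat_total_effect(from2, to2, ...)
  function(fit) f1(fit) - f2(fit)
}

#' Standardized path graph of a fitted model
#'
#' Directed edges for every free or fixed loading/structural path and
#' covariance arcs (as residual correlations), valued at the standardized
#' solution -- the input for Wright trace enumeration on fitted models.
#'
#' @param fit a [sem_fit()].
#' @return a [path_graph()].
#' @export
as_path_graph <- function(fit) {
  s <- fit$standardized
  dir <- s[s$matrix == "A", , drop = FALSE]
  cov <- s[s$matrix == "S" & s$from != s$to, , drop = FALSE]
  path_graph(data.frame(
    from = c(dir$from, cov$from),
    to = c(dir$to, cov$to),
    type = c(rep("directed", nrow(dir)), rep("covariance", nrow(cov))),
    value = c(dir$std, cov$std)))
}

#' Nonparametric bootstrap of a structural equation model
#'
#' Case-resampling bootstrap: draws `B` with-replacement resamples of
#' patients, refits the model on each, evaluates every requested statistic,
#' and returns percentile confidence intervals (linear-interpolation
#' quantiles of the stored per-resample values).  Non-convergent resamples
#' are redrawn up to `max_retries` times and then counted as failed; more
#' than 20\% failures aborts with an error (unstable model).
#'
#' @param data indicator data (rows = patients).
#' @param spec a [sem_spec()].
#' @param statistics named list of functions of a `sem_fit` (see
#'   [stat_path()] and friends).
#' @param B number of resamples (default 200).
#' @param seed integer seed; the same seed reproduces the intervals
#'   bit-identically.
#' @param level confidence level (default 0.95).
#' @param max_retries redraw attempts per failed resample.
#' @param ... passed to [sem_fit()].
#' @return a `sem_boot`: data frame `results` (`statistic`, `estimate`,
#'   `lower`, `upper`), matrix `resamples` (B x statistics, the audit
#'   trail), `n_failed`, `B`, `level`, `seed`.
#' @examples
#' cfg <- cohort_config(n_patients = 150, seed = 9)
#' ind <- simulate_indicators(simulate_latents(cfg), cfg,
#'                            mortality = "propensity")
#' bt <- sem_bootstrap(ind, aki_model_spec(),
#'                     list(cpb_aki = stat_path("CPB", "AKI")),
#'                     B = 30, seed = 1)
#' bt$results
#' @export
sem_bootstrap <- function(data, spec, statistics, B = 200, seed = NULL,
                          level = 0.95, max_retries = 5, ...) {
  if (B < 2) stop2("'B' must be at least 2")
  if (level <= 0 || level >= 1) stop2("'level' must be in (0, 1)")
  if (is.null(names(statistics)) || any(!nzchar(names(statistics))))
    stop2("'statistics' must be a named list")
  d <- as.data.frame(data)
  d$patient_id <- NULL
  n <- nrow(d)
  if (!is.null(seed)) set.seed(seed)
  full <- sem_fit(spec, d, ...)
  point <- vapply(statistics, function(f) f(full), numeric(1))
  vals <- matrix(NA_real_, B, length(statistics),
                 dimnames = list(NULL, names(statistics)))
  n_failed <- 0L
  for (b in seq_len(B)) {
    ok <- FALSE
    for (try in seq_len(max_retries + 1L)) {
      idx <- sample.int(n, n, replace = TRUE)
      ## Heywood warnings do not invalidate a resample (warn-only policy)
      fit_b <- tryCatch(suppressWarnings(sem_fit(spec, d[idx, , drop = FALSE],
                                                 ...)),
                        error = function(e) NULL)
      if (!is.null(fit_b)) {
        vals[b, ] <- vapply(statistics, function(f) f(fit_b), numeric(1))
        ok <- TRUE
        break
      }
    }
    if (!ok) n_failed <- n_failed + 1L
  }
  if (n_failed > 0.2 * B)
    stop2(sprintf("bootstrap unstable: %d of %d resamples failed to converge",
                  n_failed, B))
  alpha <- (1 - level) / 2
  qs <- apply(vals, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              na.rm = TRUE, type = 7)
  results <- data.frame(statistic = names(statistics), estimate = point,
                        lower = qs[1, ], upper = qs[2, ],
                        row.names = NULL)
  structure(list(results = results, resamples = vals, n_failed = n_failed,
                 B = B, level = level, seed = seed),
            class = "sem_boot")
}

#' @export
print.sem_boot <- function(x, digits = 3, ...) {
  cat(sprintf("Percentile bootstrap, B = %d (%d failed), %.0f%% CIs\n",
              x$B, x$n_failed, 100 * x$level))
  print(cbind(x$results["statistic"], round(x$results[-1], digits)),
        row.names = FALSE)
  invisible(x)
}

#' Significance report
#'
#' Merges the z tests of the fitted model with bootstrap intervals: a
#' statistic is flagged significant when its percentile CI excludes zero
#' (a degenerate zero-width interval at zero is not significant).
#'
#' @param fit a `sem_fit`.
#' @param boot a `sem_boot`.
#' @return data frame `statistic`, `estimate`, `lower`, `upper`,
#'   `significant`, and `z`/`p_value` where the statistic matches a free
#'   parameter label.
#' @export
significance_report <- function(fit, boot) {
  r <- boot$results
  r$significant <- (r$lower > 0 & r$upper > 0) | (r$lower < 0 & r$upper < 0)
  m <- match(r$statistic, fit$estimates$label)
  r$z <- fit$estimates$z[m]
  r$p_value <- fit$estimates$p_value[m]
  r
}

#' Export bootstrap results
#'
#' CSV of the interval table plus a JSON audit trail with the
#' per-resample statistic values and the seed.
#'
#' @param boot a `sem_boot`.
#' @param csv_path,json_path file paths (`NULL` skips either output).
#' @export
write_bootstrap_results <- function(boot, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(boot$results, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(B = boot$B, level = boot$level,
                              seed = boot$seed, n_failed = boot$n_failed,
                              results = boot$results,
                              resamples = as.data.frame(boot$resamples)),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(boot)
}
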