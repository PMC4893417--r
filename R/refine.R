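#' Iterative EFA variable refinement
#'
#' Reduces an indicator set to a stable, simple-structure factor solution
#' by iterating: extract (varimax-rotated principal-axis factors), drop the
#' worst offending variable, collapse families of interchangeable metrics
#' to their best-loading surrogate, and repeat until stable.
#'
#' The drop rules per iteration, in order of precedence:
#' \itemize{
#'   \item \emph{low loading}: no loading reaches `loading_threshold`
#'     (0.400, the significance bar for a sample of 200) on any factor;
#'     among violators the variable with the smallest maximum loading goes.
#'   \item \emph{cross-loading}: loadings of at least `cross_threshold` on
#'     two or more factors; the variable with the largest secondary loading
#'     goes.
#'   \item \emph{low communality}: communality below `comm_threshold`
#'     (0.50) \emph{and} no clean simple structure (a significant loading
#'     on exactly one factor).  A variable that loads cleanly on a single
#'     factor is never dropped for communality alone: the criterion targets
#'     variables poorly represented by the solution overall, and weak but
#'     clean indicators (an oliguria burden, a binary mortality) are
#'     legitimate construct markers.
#' }
#' After each drop, families of metrics that express the same phenomenon
#' (see [aki_metric_families()]) are collapsed: only the member with the
#' highest maximum absolute loading is kept as surrogate (lexicographic
#' order breaks exact ties).
#'
#' The number of factors is re-assessed each iteration by the latent-root
#' criterion unless `n_factors` fixes it, and is reduced whenever a factor
#' holds fewer than two significant loadings (the scree-style reduction).
#'
#' @param x indicator matrix / data frame; a `patient_id` column is ignored.
#' @param families named list of character vectors of interchangeable
#'   variables.
#' @param loading_threshold significance bar for loadings (default 0.400).
#' @param comm_threshold communality bar (default 0.50).
#' @param cross_threshold secondary-loading bar defining a cross-loading
#'   (default 0.400).
#' @param n_factors fixed number of factors; `NULL` re-assesses by the
#'   latent-root criterion each iteration.
#' @param method extraction method, see [efa_extract()].
#' @param max_iter safety cap on refinement iterations.
#' @return an `efa_refinement`: list with the final `solution`
#'   (an `efa_solution`), `retained` variable names, `assignment` (factor
#'   index of the dominant loading per retained variable) and `trace`
#'   (data frame of every action: `iteration`, `variable`, `action`,
#'   `value`).
#' @examples
#' cfg <- cohort_config(n_patients = 400, seed = 11)
#' ind <- simulate_indicators(simulate_latents(cfg), cfg)
#' ref <- efa_refine(ind, n_factors = 4)
#' ref$trace
#' @export
efa_refine <- function(x, families = list(),
                       loading_threshold = 0.400,
                       comm_threshold = 0.50,
                       cross_threshold = 0.400,
                       n_factors = NULL, method = "paf",
                       max_iter = 50) {
  d <- as.data.frame(x)
  d$patient_id <- NULL
  d <- d[vapply(d, is.numeric, logical(1))]
  vars <- names(d)
  n <- nrow(d)
  trace <- data.frame(iteration = integer(), variable = character(),
                      action = character(), value = numeric())
  log_action <- function(it, var, action, value) {
    trace[nrow(trace) + 1L, ] <<- list(it, var, action, value)
  }
  sol <- NULL
  k_cap <- Inf       # scree reductions persist across iterations
  for (it in seq_len(max_iter)) {
    if (length(vars) < 3L)
      stop2("refinement exhausted the variable set (fewer than 3 variables remain)")
    R <- stats::cor(as.matrix(d[vars]))
    k <- min(n_factors %||% max(1L, kaiser_count(R)), k_cap)
    if (length(vars) < k + 1L)
      stop2(sprintf("fewer than k + 1 = %d variables remain for %d factors",
                    k + 1L, k))
    repeat {                       # scree-style reduction
      sol <- efa_varimax(efa_extract(R, k, method = method))
      nsig <- colSums(abs(sol$loadings) >= loading_threshold)
      if (k > 1L && any(nsig < 2L)) k <- k - 1L else break
    }
    k_cap <- k
    L <- sol$loadings
    amax <- apply(abs(L), 1, max)
    nsig_var <- rowSums(abs(L) >= loading_threshold)
    second <- apply(abs(L), 1, function(z)
      if (length(z) > 1L) sort(z, decreasing = TRUE)[2L] else 0)
    comm <- sol$communalities

    low_load <- which(amax < loading_threshold)
    if (length(low_load)) {
      v <- vars[low_load[which.min(amax[low_load])]]
      log_action(it, v, "dropped-low-loading", amax[match(v, vars)])
      vars <- setdiff(vars, v)
      next
    }
    cross <- which(rowSums(abs(L) >= cross_threshold) >= 2L)
    if (length(cross)) {
      v <- vars[cross[which.max(second[cross])]]
      log_action(it, v, "dropped-cross-loading", second[match(v, vars)])
      vars <- setdiff(vars, v)
      next
    }
    low_comm <- which(comm < comm_threshold & nsig_var != 1L)
    if (length(low_comm)) {
      v <- vars[low_comm[which.min(comm[low_comm])]]
      log_action(it, v, "dropped-low-communality", comm[match(v, vars)])
      vars <- setdiff(vars, v)
      next
    }
    ## family surrogate selection (one family per iteration)
    collapsed <- FALSE
    for (fam in names(families)) {
      members <- intersect(families[[fam]], vars)
      if (length(members) > 1L) {
        strength <- amax[match(members, vars)]
        best <- members[order(-strength, members)][1L]
        for (m in setdiff(members, best))
          log_action(it, m, "dropped-family-duplicate", amax[match(m, vars)])
        log_action(it, best, "surrogate-selected", amax[match(best, vars)])
        vars <- setdiff(vars, setdiff(members, best))
        collapsed <- TRUE
        break
      }
    }
    if (collapsed) next
    break                          # stable
  }
  assignment <- apply(abs(sol$loadings), 1, which.max)
  names(assignment) <- vars
  sol$adequacy <- list(bartlett = bartlett_sphericity(stats::cor(as.matrix(d[vars])), n),
                       kmo = kmo(stats::cor(as.matrix(d[vars]))))
  sol$n <- n
  structure(list(solution = sol, retained = vars, assignment = assignment,
                 trace = trace, n_factors = ncol(sol$loadings)),
            class = "efa_refinement")
}

#' @export
print.efa_refinement <- function(x, ...) {
  cat(sprintf("EFA refinement: %d variables retained in %d factors; %d actions\n",
              length(x$retained), x$n_factors, nrow(x$trace)))
  if (nrow(x$trace)) print(x$trace)
  print(x$solution)
  invisible(x)
}

#' Serialise a refinement trace as JSON
#'
#' @param refinement an `efa_refinement`.
#' @param path file path.
#' @export
write_refinement_json <- function(refinement, path) {
  jsonlite::write_json(list(retained = refinement$retained,
                            n_factors = refinement$n_factors,
                            assignment = as.list(refinement$assignment),
                            trace = refinement$trace),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
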