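`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

#' @keywords internal
assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop2(sprintf("'%s' must be a single finite number", name))
  invisible(x)
}

## Draw n samples from N(0, Sigma) via Cholesky.  Sigma must be PD.
rmvnorm_chol <- function(n, sigma) {
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch))
    stop2("covariance matrix is not positive-definite")
  matrix(stats::rnorm(n * ncol(sigma)), n, ncol(sigma)) %*% ch
}

## topological order of a DAG given an edge list (from, to); error on cycles
topological_order <- function(nodes, from, to) {
  order <- character(0)
  remaining <- nodes
  edges <- data.frame(from = from, to = to, stringsAsFactors = FALSE)
  while (length(remaining)) {
    has_parent <- remaining %in% edges$to[edges$from %in% remaining]
    roots <- remaining[!has_parent]
    if (!length(roots))
      stop2("cycle detected in structural graph among: ",
            paste(remaining, collapse = ", "))
    order <- c(order, sort(roots))
    remaining <- setdiff(remaining, roots)
  }
  order
}

## align columns of loading matrix L to reference ref (permutation + sign),
## greedy by absolute column correlation; returns the aligned L
align_loadings <- function(L, ref) {
  k <- ncol(ref)
  used <- integer(0)
  out <- matrix(0, nrow(ref), k, dimnames = dimnames(ref))
  for (j in seq_len(k)) {
    cors <- vapply(seq_len(ncol(L)), function(i) sum(L[, i] * ref[, j]),
                   numeric(1))
    acors <- abs(cors)
    acors[used] <- -Inf
    best <- which.max(acors)
    used <- c(used, best)
    out[, j] <- L[, best] * sign(cors[best] + (cors[best] == 0))
  }
  out
}
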