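test_that("trace products follow the multiplication rule", {
  g <- path_graph(data.frame(from = c("X", "M"), to = c("M", "Y"),
                             type = "directed", value = c(0.5, 0.4)))
  tr <- enumerate_traces(g, "X", "Y")
  expect_length(tr, 1)
  expect_equal(tr[[1]]$product, 0.2)
  ## disconnected pair: no traces, zero total
  g2 <- path_graph(data.frame(from = c("X", "Z"), to = c("M", "Y"),
                              type = "directed", value = c(0.5, 0.4)))
  expect_length(enumerate_traces(g2, "X", "Y"), 0)
  expect_equal(total_effect(g2, "X", "Y")$total, 0)
  expect_error(enumerate_traces(g, "X", "X"), "differ")
  expect_error(enumerate_traces(g, "X", "Q"), "unknown")
})

test_that("the fitted AKI graph yields exactly the published traces", {
  g <- aki_path_graph()
  tr <- enumerate_traces(g, "CPB", "AKI")
  expect_length(tr, 3)
  prods <- sort(vapply(tr, `[[`, numeric(1), "product"))
  expect_equal(sort(c(0.596, 0.451 * 0.347, 0.997 * 0.137 * 0.508)), prods,
               tolerance = 1e-12)
  ## strict Wright rules exclude the residual-arc bridge
  expect_length(enumerate_traces(g, "CPB", "AKI", strict = TRUE), 2)
  expect_length(enumerate_traces(g, "AKI", "ungal"), 3)
  expect_length(enumerate_traces(g, "AKI", "Outcome"), 2)
})

test_that("total effects equal model-implied correlations (Wright identity)", {
  ## random recursive standardized models: DAG among observed variables
  ## plus a covariance arc between the two exogenous roots; the sum over
  ## canonical traces must equal the implied correlation from the RAM
  ## engine to near machine precision
  for (s in 1:8) {
    set.seed(130 + s)
    nodes <- c("e1", "e2", "m1", "m2", "y")
    edges <- data.frame(from = c("e1", "e2", "e1", "m1", "m2", "e2"),
                        to = c("m1", "m1", "m2", "y", "y", "y"),
                        value = round(runif(6, -0.35, 0.35), 3))
    arc <- round(runif(1, -0.4, 0.4), 3)
    ## residual variances completing unit variance per node
    spec <- sem_spec(latents = character(0), observed = nodes,
                     paths = data.frame(from = edges$from, to = edges$to,
                                        value = edges$value),
                     covariances = data.frame(a = "e1", b = "e2",
                                              value = arc))
    ## free parameters: the 5 variances; solve for unit total variances
    unit_var_theta <- function(spec) {
      th <- rep(1, 5)
      for (it in 1:50) {
        Sig <- implied_covariance(spec, th)
        th <- pmax(th - (diag(Sig) - 1), 0.05)
        if (max(abs(diag(Sig) - 1)) < 1e-12) break
      }
      th
    }
    th <- unit_var_theta(spec)
    Sig <- implied_covariance(spec, th)
    expect_lt(max(abs(diag(Sig) - 1)), 1e-10)
    g <- path_graph(rbind(
      data.frame(from = edges$from, to = edges$to, type = "directed",
                 value = edges$value),
      data.frame(from = "e1", to = "e2", type = "covariance", value = arc)))
    for (pair in list(c("e1", "y"), c("e2", "y"), c("e1", "m1"),
                      c("m1", "y"))) {
      te <- total_effect(g, pair[1], pair[2], strict = TRUE)
      expect_equal(te$total, Sig[pair[1], pair[2]], tolerance = 1e-8,
                   label = paste(pair, collapse = "->"))
    }
  }
})

test_that("trace enumeration is exhaustive on small graphs", {
  ## independent permutation-based oracle: check every ordered subset of
  ## intermediate nodes as a candidate trail
  g <- aki_path_graph()
  oracle_count <- function(graph, from, to, strict) {
    e <- graph$edges
    nodes <- setdiff(graph$nodes, c(from, to))
    find_edges <- function(a, b) {
      which((e$from == a & e$to == b) | (e$from == b & e$to == a))
    }
    perms <- function(v) {
      if (length(v) <= 1) return(list(v))
      out <- list()
      for (i in seq_along(v))
        for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
      out
    }
    count <- 0
    for (k in 0:3) {
      mids <- if (k == 0) list(character(0)) else {
        combs <- utils::combn(nodes, k, simplify = FALSE)
        do.call(c, lapply(combs, perms))
      }
      for (mid in mids) {
        seqn <- c(from, mid, to)
        ok <- TRUE; moves <- character(0); arcs <- 0
        for (j in seq_len(length(seqn) - 1)) {
          cand <- find_edges(seqn[j], seqn[j + 1])
          if (!length(cand)) { ok <- FALSE; break }
          i <- cand[1]
          mv <- if (e$type[i] == "covariance") "A"
          else if (e$from[i] == seqn[j]) "F" else "B"
          if (mv == "A") arcs <- arcs + 1
          moves <- c(moves, mv)
        }
        if (ok && arcs <= 1 &&
            akisem:::trace_admissible(moves, strict)) count <- count + 1
      }
    }
    count
  }
  expect_length(enumerate_traces(g, "CPB", "AKI"),
                oracle_count(g, "CPB", "AKI", FALSE))
  expect_length(enumerate_traces(g, "LCOS", "AKI", strict = TRUE),
                oracle_count(g, "LCOS", "AKI", TRUE))
})

test_that("worked compound effects reproduce the published arithmetic", {
  we <- aki_worked_effects()
  expect_equal(we$total[we$effect == "CPB -> AKI"],
               0.596 + 0.451 * 0.347 + 0.997 * 0.137 * 0.508,
               tolerance = 1e-12)
  expect_equal(we$total[we$effect == "age -> AKI"], -0.661 * 0.347,
               tolerance = 1e-12)
  ## difference of totals and its antisymmetry
  g <- aki_path_graph()
  a <- total_effect(g, "CPB", "AKI")
  b <- total_effect(g, "LCOS", "AKI")
  expect_equal(effect_difference(a, b), a$total - b$total)
  expect_equal(effect_difference(a, b), -effect_difference(b, a))
  expect_equal(effect_difference(a, a), 0)
  expect_equal(shared_variance_pct(0), 0)
})
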