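# The continuous stochastic block model: likelihood, optimizer, selection.

test_that("edge probability is the bilinear form and stays in [0, 1]", {
  B <- rbind(c(0, 0, 0), c(0, 0.4, 0), c(0, 0, 0.4))
  expect_equal(edge_probability(c(0, 0.5, 0.5), c(0, 0.5, 0.5), B), 0.2)
  B2 <- rbind(c(0, 0, 0), c(0, 0.7, 0.01), c(0, 0.01, 0.3))
  expect_equal(edge_probability(c(0, 1, 0), c(0, 0, 1), B2), 0.01)
  expect_equal(edge_probability(c(1, 0, 0), c(1, 0, 0), B2), 0)
  expect_error(edge_probability(c(1, 0), c(0, 1, 0), B2), "dimension")
  # convexity bound on random valid inputs
  set.seed(1)
  for (i in 1:50) {
    u <- as.numeric(matenet:::rdirichlet_(2, rep(1, 3)))
    p <- edge_probability(u[c(1, 3, 5)] / sum(u[c(1, 3, 5)]),
                          u[c(2, 4, 6)] / sum(u[c(2, 4, 6)]), B2)
    expect_gte(p, 0); expect_lte(p, 1)
  }
})

test_that("log-likelihood matches hand-computed pair sums", {
  B <- rbind(c(0, 0), c(0, 0.5))
  U <- rbind(c(0, 1), c(0, 1))
  g <- igraph::graph_from_edgelist(rbind(c(1, 2)), directed = FALSE)
  expect_equal(csbm_loglik(g, U, B), log(0.5), tolerance = 1e-10)
  # 3 nodes, one edge, all pure connected-EHN: three pairs each at pi = 0.5
  U3 <- rbind(c(0, 1), c(0, 1), c(0, 1))
  g3 <- igraph::make_empty_graph(3, directed = FALSE) |>
    igraph::add_edges(c(1, 2))
  expect_equal(csbm_loglik(g3, U3, B), 3 * log(0.5), tolerance = 1e-10)
  # empty network fully on EHN0: perfect fit up to clipping
  g0 <- igraph::make_empty_graph(4, directed = FALSE)
  U0 <- cbind(rep(1, 4), 0)
  expect_gt(csbm_loglik(g0, U0, B), -4 * 4 * 1e-9)
})

test_that("saturated limits are attained: complete and empty graphs", {
  g <- igraph::make_full_graph(4)
  igraph::V(g)$name <- paste0("n", 1:4)
  f <- csbm(g, Q = 2, n_restarts = 3, seed = 1)
  expect_gte(f$logL, -0.01)
  g0 <- igraph::make_empty_graph(6, directed = FALSE)
  igraph::V(g0)$name <- paste0("n", 1:6)
  f0 <- csbm(g0, Q = 2, n_restarts = 3, seed = 1)
  expect_gte(f0$logL, -0.01)
})

test_that("fit invariants: simplex rows, symmetric B, zero EHN0, AIC formula", {
  p <- planted_csbm(3, n1 = 25, n2 = 25, n_int = 5)
  f <- csbm(p$A, Q = 3, n_restarts = 3, seed = 2, trace = TRUE)
  expect_simplex_rows(f$U)
  expect_equal(f$B, t(f$B), tolerance = 1e-12)
  expect_true(all(f$B[1, ] == 0) && all(f$B[, 1] == 0))
  expect_true(all(f$B >= 0 & f$B <= 1))
  k <- f$n * 2 + 3
  expect_equal(f$aic, -2 * f$logL + 2 * k)
  expect_equal(AIC(logLik(f)), f$aic)
  # monotone ascent of accepted iterates
  expect_true(all(diff(f$trace) >= -1e-8))
})

test_that("fitted likelihood beats a Monte-Carlo oracle on small graphs", {
  # brute-force oracle: best of many random valid (U, B) draws
  oracle <- function(X, Q, n_draws = 2000) {
    best <- -Inf
    for (i in seq_len(n_draws)) {
      U <- matenet:::rdirichlet_(nrow(X), rep(1, Q))
      B <- matrix(0, Q, Q)
      for (q in 2:Q) for (l in q:Q)
        B[q, l] <- B[l, q] <- runif(1)
      best <- max(best, matenet:::loglik_(X, U, B))
    }
    best
  }
  set.seed(5)
  for (i in 1:5) {
    A <- matrix(0L, 6, 6)
    ut <- upper.tri(A)
    A[ut] <- rbinom(sum(ut), 1, 0.4)
    A <- A + t(A)
    for (Q in 2:3) {
      f <- csbm(A, Q = Q, n_restarts = 4, seed = 10 + i)
      expect_gte(f$logL, oracle(A, Q) - 1e-6)
    }
  }
})

test_that("relabelling nodes leaves logL and AIC unchanged", {
  p <- planted_csbm(7, n1 = 20, n2 = 20, n_int = 0)
  f1 <- csbm(p$A, Q = 3, n_restarts = 3, seed = 3)
  set.seed(8)
  perm <- sample(nrow(p$A))
  A2 <- p$A[perm, perm]
  f2 <- csbm(A2, Q = 3, n_restarts = 3, seed = 3)
  expect_equal(f1$logL, f2$logL, tolerance = 0.02 * abs(f1$logL))
  expect_equal(f1$aic, f2$aic, tolerance = 0.02 * f1$aic)
})

test_that("low-degree nodes load on the unconnected EHN", {
  # heterogeneous-degree graph from the model itself: memberships with
  # varying EHN0 mass
  set.seed(9)
  n <- 80
  u1 <- runif(n, 0.05, 1)
  U <- cbind(1 - u1, u1)
  B <- rbind(c(0, 0), c(0, 0.4))
  P <- U %*% B %*% t(U)
  A <- matrix(0L, n, n)
  ut <- upper.tri(A)
  A[ut] <- rbinom(sum(ut), 1, P[ut])
  A <- A + t(A)
  f <- csbm(A, Q = 2, n_restarts = 3, seed = 10)
  rho <- stats::cor(igraph::degree(igraph::graph_from_adjacency_matrix(
    A, mode = "undirected")), f$U[, 1], method = "spearman")
  expect_lt(rho, 0)
})

test_that("two disjoint cliques are recovered exactly with Q = 3", {
  gc <- igraph::disjoint_union(igraph::make_full_graph(10),
                               igraph::make_full_graph(10))
  igraph::V(gc)$name <- paste0("n", 1:20)
  f <- csbm(gc, Q = 3, n_restarts = 10, seed = 4)
  cl <- classify_memberships(f)
  expect_equal(sum(cl$label == "intermediate"), 0)
  expect_equal(length(unique(cl$label[1:10])), 1)
  expect_equal(length(unique(cl$label[11:20])), 1)
  expect_false(cl$label[1] == cl$label[11])
})

test_that("model scan ranks by AIC and honours a manual override", {
  gc <- igraph::make_full_graph(10)
  igraph::V(gc)$name <- paste0("n", 1:10)
  sc <- csbm_scan(gc, 2, 3, n_restarts = 2, seed = 6)
  expect_equal(sc$ranking, sc$table$Q[order(sc$table$aic)])
  # a single clique needs no second connected EHN; the penalty decides
  expect_lte(sc$table$aic[sc$table$Q == 2], sc$table$aic[sc$table$Q == 3])
  expect_equal(sc$selected_Q, sc$ranking[1])
  sc3 <- csbm_scan(gc, 2, 3, select = 3, n_restarts = 2, seed = 6)
  expect_equal(sc3$selected_Q, 3)
  expect_true(sc3$override)
  expect_equal(sc3$ranking, sc$ranking)
  expect_error(csbm_scan(gc, 2, 3, select = 7, n_restarts = 2), "one of")
  expect_error(csbm_scan(gc, 5, 3), "Q_min")
})

test_that("degenerate inputs are rejected or warned about", {
  g <- igraph::make_full_graph(3)
  expect_error(csbm(g, Q = 1), "at least 2")
  expect_warning(csbm(g, Q = 5, n_restarts = 1, max_iter = 50, seed = 1),
                 "over-parameterised")
  expect_error(csbm(igraph::make_empty_graph(1, directed = FALSE), Q = 2),
               "at least 2 nodes")
})

test_that("model methods are coherent with the fit", {
  p <- planted_csbm(11, n1 = 15, n2 = 15, n_int = 0)
  g <- igraph::graph_from_adjacency_matrix(p$A, mode = "undirected")
  f <- csbm(g, Q = 3, n_restarts = 3, seed = 12)
  P <- fitted(f)
  expect_equal(P, t(P))
  expect_true(all(P[upper.tri(P)] >= 0 & P[upper.tri(P)] <= 1))
  pr <- predict(f, pairs = cbind("n1", "n2"))
  expect_equal(unname(pr), P["n1", "n2"])
  r <- residuals(f)
  X <- matenet:::as_adjacency_(g)
  expect_equal(r["n1", "n2"], X["n1", "n2"] - P["n1", "n2"],
               tolerance = 1e-6)
  sims <- simulate(f, nsim = 2, seed = 13)
  expect_length(sims, 2)
  expect_setequal(igraph::V(sims[[1]])$name, f$nodes)
  co <- coef(f)
  expect_named(co, c("U", "B"))
  expect_output(print(f), "Continuous stochastic block model")
  expect_output(print(summary(f)), "dominant EHN")
})
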