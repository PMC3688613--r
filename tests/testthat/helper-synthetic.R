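# Shared fixtures, all generated in code.

# Small two-species stand with strong differentiation, handy defaults for
# fast tests.
small_stand <- function(n_A = 30, n_B = 20, seed = 1, ...) {
  generate_stand(n_A = n_A, n_B = n_B, seed = seed, ...)
}

# Bernoulli network drawn from known C-SBM parameters (the planted model):
# n1/n2 nodes mixing EHN0 with one species EHN each, n_int interior nodes.
planted_csbm <- function(seed, n1 = 90, n2 = 100, n_int = 10,
                         B11 = 0.25, B22 = 0.25, B12 = 0.01) {
  set.seed(seed)
  n <- n1 + n2 + n_int
  U <- matrix(0, n, 3)
  u1 <- runif(n1, 0.2, 1)
  u2 <- runif(n2, 0.2, 1)
  U[seq_len(n1), 2] <- u1
  U[seq_len(n1), 1] <- 1 - u1
  U[n1 + seq_len(n2), 3] <- u2
  U[n1 + seq_len(n2), 1] <- 1 - u2
  if (n_int > 0) {
    D <- matrix(rgamma(3 * n_int, 1), n_int, 3)
    U[n1 + n2 + seq_len(n_int), ] <- D / rowSums(D)
  }
  B <- rbind(c(0, 0, 0), c(0, B11, B12), c(0, B12, B22))
  P <- U %*% B %*% t(U)
  A <- matrix(0L, n, n)
  ut <- upper.tri(A)
  A[ut] <- rbinom(sum(ut), 1L, P[ut])
  A <- A + t(A)
  dimnames(A) <- list(paste0("n", seq_len(n)), paste0("n", seq_len(n)))
  list(A = A, U = U, B = B,
       truth = rep(c("S1", "S2", "int"), c(n1, n2, n_int)))
}

# Align a Q = 3 fit to known planted parameters through the model's
# invariances: species-EHN permutation chosen by label agreement on pure
# nodes, then a per-column least-squares scale (pi = U B U' is invariant to
# scaling a species column of U against B). Returns aligned labels, B and
# the scales.
align_to_truth <- function(fit, planted, epsilon = 0.05) {
  pure <- planted$truth != "int"
  lab1 <- classify_memberships(fit, epsilon)$label
  U2 <- fit$U[, c(1, 3, 2)]
  lab2 <- ifelse(U2[, 3] <= epsilon & U2[, 2] > U2[, 3], "S1",
                 ifelse(U2[, 2] <= epsilon & U2[, 3] > U2[, 2], "S2",
                        "intermediate"))
  if (mean(lab2[pure] == planted$truth[pure]) >
      mean(lab1[pure] == planted$truth[pure])) {
    U <- U2
    B <- fit$B[c(1, 3, 2), c(1, 3, 2)]
    lab <- lab2
  } else {
    U <- fit$U
    B <- fit$B
    lab <- lab1
  }
  s <- vapply(2:3, function(q)
    sum(U[, q] * planted$U[, q]) / sum(U[, q]^2), numeric(1))
  B_aligned <- B
  B_aligned[2:3, 2:3] <- B[2:3, 2:3] / outer(s, s)
  list(labels = lab, B = B_aligned, scales = s, U = U)
}

expect_simplex_rows <- function(U, tol = 1e-8) {
  expect_true(all(U >= -tol))
  expect_true(all(abs(rowSums(U) - 1) < tol))
}
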