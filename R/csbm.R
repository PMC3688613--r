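# Continuous (mixed-membership) stochastic block model with extremal
# hypothetical nodes (EHNs). Every node i carries a membership vector u_i on
# the Q-simplex; the probability of an edge between i and j is the bilinear
# form pi_ij = u_i' B u_j, where B is the symmetric EHN-EHN connectivity
# matrix. EHN 1 (written EHN0) is structurally unconnected: its row and
# column of B are fixed at zero, which lets the model absorb degree
# heterogeneity. Edges are independent Bernoulli(pi_ij).

PI_CLIP <- 1e-9

# adjacency matrix (dense, 0/1, zero diagonal) from an igraph or a matrix
as_adjacency_ <- function(network) {
  if (inherits(network, "igraph")) {
    X <- as.matrix(igraph::as_adjacency_matrix(network, type = "both"))
    X[X > 1] <- 1
  } else {
    X <- as.matrix(network)
  }
  diag(X) <- 0
  X
}

#' Edge probability under the continuous stochastic block model
#'
#' `pi_ij = u_i' B u_j`, a convex combination of entries of `B`, hence always
#' in `[0, 1]` for valid inputs.
#'
#' @param u_i,u_j membership vectors on the simplex (length Q).
#' @param B symmetric Q-by-Q EHN connectivity matrix with entries in
#'   `[0, 1]` and first row/column zero.
#' @return the edge probability, a scalar in `[0, 1]`.
#' @examples
#' B <- rbind(c(0, 0, 0), c(0, 0.4, 0), c(0, 0, 0.4))
#' edge_probability(c(0, 0.5, 0.5), c(0, 0.5, 0.5), B)  # 0.2
#' @export
edge_probability <- function(u_i, u_j, B) {
  if (length(u_i) != nrow(B) || length(u_j) != ncol(B))
    stop("dimension mismatch between memberships and B")
  as.numeric(u_i %*% B %*% u_j)
}

#' Bernoulli log-likelihood of a network under given C-SBM parameters
#'
#' Sum over unordered node pairs of
#' `X_ij log(pi_ij) + (1 - X_ij) log(1 - pi_ij)`, with `pi` clipped to
#' `[1e-9, 1 - 1e-9]`.
#'
#' @param network an [igraph::graph] (or adjacency matrix); row order of `U`
#'   must match the node order.
#' @param U n-by-Q membership matrix, rows on the simplex.
#' @param B symmetric EHN connectivity matrix (see [edge_probability()]).
#' @return the log-likelihood (scalar).
#' @export
csbm_loglik <- function(network, U, B) {
  X <- as_adjacency_(network)
  loglik_(X, U, B)
}

loglik_ <- function(X, U, B) {
  P <- U %*% B %*% t(U)
  P <- pmin(pmax(P, PI_CLIP), 1 - PI_CLIP)
  M <- X * log(P) + (1 - X) * log(1 - P)
  diag(M) <- 0
  0.5 * sum(M)
}

# gradient pieces shared by the U- and B-steps
grad_w_ <- function(X, U, B) {
  P <- U %*% B %*% t(U)
  P <- pmin(pmax(P, PI_CLIP), 1 - PI_CLIP)
  W <- X / P - (1 - X) / (1 - P)
  diag(W) <- 0
  W
}

# one backtracking projected-gradient ascent step on all rows of U
step_U_ <- function(X, U, B, ll, step) {
  G <- grad_w_(X, U, B) %*% U %*% B
  step <- step * 2
  repeat {
    U2 <- project_simplex_rows(U + step * G)
    ll2 <- loglik_(X, U2, B)
    if (ll2 >= ll) return(list(U = U2, ll = ll2, step = step))
    step <- step / 2
    if (step < 1e-14) return(list(U = U, ll = ll, step = 1e-10))
  }
}

# one backtracking projected-gradient step on B (box [0,1], symmetric,
# zero first row/column)
step_B_ <- function(X, U, B, ll, step) {
  G <- t(U) %*% grad_w_(X, U, B) %*% U
  diag(G) <- 0.5 * diag(G)
  G[1, ] <- 0; G[, 1] <- 0
  step <- step * 2
  repeat {
    B2 <- B + step * G
    B2 <- (B2 + t(B2)) / 2
    B2 <- pmin(pmax(B2, 0), 1)
    B2[1, ] <- 0; B2[, 1] <- 0
    ll2 <- loglik_(X, U, B2)
    if (ll2 >= ll) return(list(B = B2, ll = ll2, step = step))
    step <- step / 2
    if (step < 1e-14) return(list(B = B, ll = ll, step = 1e-10))
  }
}

# spectral-cluster initialisation (first restart); random otherwise
init_params_ <- function(X, Q, type = c("spectral", "random")) {
  type <- match.arg(type)
  n <- nrow(X)
  deg <- rowSums(X)
  U <- matrix(0, n, Q)
  B <- matrix(0, Q, Q)
  if (type == "spectral" && Q >= 2) {
    cl <- tryCatch({
      ev <- eigen(X, symmetric = TRUE)
      emb <- ev$vectors[, seq_len(Q - 1L), drop = FALSE]
      if (Q == 2L) rep(1L, n)
      else stats::kmeans(emb, centers = Q - 1L, nstart = 5)$cluster
    }, error = function(e) sample.int(Q - 1L, n, replace = TRUE))
    own <- 0.2 + 0.7 * deg / max(deg, 1)
    U[cbind(seq_len(n), cl + 1L)] <- own
    U[, 1] <- 1 - own
    U <- project_simplex_rows(U + matrix(stats::runif(n * Q, 0, 0.02), n, Q))
    for (q in 2:Q) for (l in 2:Q) {
      iq <- cl == (q - 1L); il <- cl == (l - 1L)
      m <- if (q == l) sum(X[iq, il]) / max(1, sum(iq) * (sum(iq) - 1))
           else sum(X[iq, il]) / max(1, sum(iq) * sum(il))
      B[q, l] <- min(0.9, max(0.02, 2 * m))
    }
    B <- (B + t(B)) / 2
  } else {
    U <- rdirichlet_(n, rep(0.5, Q))
    for (q in 2:Q) for (l in q:Q)
      B[q, l] <- B[l, q] <- if (q == l) stats::runif(1, 0.3, 0.9)
                            else stats::runif(1, 0, 0.2)
  }
  B[1, ] <- 0; B[, 1] <- 0
  list(U = U, B = B)
}

# scale species columns of U up to the feasibility boundary (and B down
# accordingly), so each EHN is extremal w.r.t. the data: coordinate ascent on
# sum(log s_q) subject to row sums <= 1; pi = U B U' is exactly invariant
anchor_extremal_ <- function(U, B) {
  Q <- ncol(U)
  if (Q < 2) return(list(U = U, B = B))
  sp <- 2:Q
  active <- sp[apply(U[, sp, drop = FALSE], 2, max) > 1e-6]
  s <- rep(1, Q)
  if (length(active) > 0) {
    for (iter in 1:50) {
      s_old <- s
      for (q in active) {
        others <- setdiff(active, q)
        rest <- if (length(others))
          as.numeric(U[, others, drop = FALSE] %*% s[others])
        else rep(0, nrow(U))
        rows <- U[, q] > 1e-9
        if (!any(rows)) next
        s[q] <- max(1, min((1 - rest[rows]) / U[rows, q]))
      }
      if (max(abs(s - s_old)) < 1e-12) break
    }
  }
  U2 <- U %*% diag(s, Q)
  U2[, 1] <- pmax(0, 1 - rowSums(U2[, sp, drop = FALSE]))
  B2 <- B / outer(s, s)
  B2[1, ] <- 0; B2[, 1] <- 0
  list(U = U2, B = pmin(B2, 1))
}

# order EHN columns: EHN0 first (structural), then species EHNs by
# descending within-EHN connectivity; ties by first-node membership mass
order_ehns_ <- function(U, B) {
  Q <- ncol(U)
  if (Q < 3) return(list(U = U, B = B))
  sp <- 2:Q
  o <- sp[order(-diag(B)[sp], -U[1, sp])]
  perm <- c(1L, o)
  list(U = U[, perm, drop = FALSE], B = B[perm, perm, drop = FALSE])
}

fit_one_ <- function(X, Q, max_iter, tol, init_type) {
  p <- init_params_(X, Q, init_type)
  U <- p$U; B <- p$B
  ll <- loglik_(X, U, B)
  su <- sb <- 0.1
  path <- numeric(0)
  converged <- FALSE
  it <- 0L
  n_small <- 0L
  # an alternating scheme can make a near-zero gain on one iteration while
  # still far from a stationary point; require the relative gain to stay
  # below tol on several consecutive iterations before declaring convergence
  while (it < max_iter) {
    it <- it + 1L
    ll_prev <- ll
    rb <- step_B_(X, U, B, ll, sb); B <- rb$B; ll <- rb$ll; sb <- rb$step
    ru <- step_U_(X, U, B, ll, su); U <- ru$U; ll <- ru$ll; su <- ru$step
    path <- c(path, ll)
    n_small <- if (abs(ll - ll_prev) <= tol * (abs(ll_prev) + 1e-12))
      n_small + 1L else 0L
    if (n_small >= 5L) {
      converged <- TRUE
      break
    }
  }
  list(U = U, B = B, logL = ll, converged = converged, iterations = it,
       trace = path)
}

#' Fit the continuous stochastic block model to a network
#'
#' Maximum-likelihood fit of the mixed-membership (grade of membership)
#' stochastic block model with `Q` extremal hypothetical nodes, the first of
#' which (EHN0) is structurally unconnected. Inference alternates a
#' projected-gradient ascent step on the membership matrix `U` (each row
#' projected back onto the simplex) with one on the connectivity matrix `B`
#' (projected onto `[0,1]`, symmetry and the zero EHN0 row enforced
#' exactly), both with backtracking line search, so the log-likelihood of
#' accepted iterates never decreases. The best of `n_restarts` starts (one
#' spectral-clustering start, the rest random) is returned.
#'
#' Because EHN0 absorbs arbitrary slack, the representation is only
#' identified up to rescaling species columns of `U` against `B`; the
#' returned fit uses the extremal convention in which species memberships
#' are scaled up to the simplex feasibility boundary (see the package
#' vignette), which leaves the likelihood untouched.
#'
#' @param network an undirected [igraph::graph] (or a 0/1 adjacency matrix).
#' @param Q number of EHNs including EHN0 (`Q >= 2`).
#' @param n_restarts independent starts (default 10).
#' @param max_iter maximum outer iterations per start.
#' @param tol relative log-likelihood convergence tolerance.
#' @param seed integer seed controlling all restarts.
#' @param trace keep the per-iteration log-likelihood path of the best start.
#' @return an object of class `"csbm"`: list with `Q`, `U` (n-by-Q, rownames
#'   = node ids), `B`, `logL`, `aic`, `df`, `n`, `converged`, `iterations`,
#'   `n_restarts_used`, `best_restart`, `network`, and optionally `trace`.
#'   `aic = -2 logL + 2 k` with `k = n (Q - 1) + (Q - 1) Q / 2`.
#' @seealso [csbm_scan()] for AIC model selection over `Q`,
#'   [classify_memberships()] for the species rule, and the `print`,
#'   `summary`, `coef`, `logLik`, `predict`, `fitted`, `residuals`,
#'   `simulate` and `plot` methods.
#' @examples
#' g <- igraph::sample_gnp(20, 0.3)
#' igraph::V(g)$name <- paste0("n", 1:20)
#' fit <- csbm(g, Q = 2, n_restarts = 2, seed = 1)
#' fit
#' @export
csbm <- function(network, Q = 3, n_restarts = 10, max_iter = 2000,
                 tol = 1e-6, seed = NULL, trace = FALSE) {
  if (Q < 2) stop("Q must be at least 2 (EHN0 plus one connected EHN)")
  X <- as_adjacency_(network)
  n <- nrow(X)
  if (n < 2) stop("network must have at least 2 nodes")
  if (Q > n) warning("Q exceeds the number of nodes; fit is over-parameterised")
  ids <- rownames(X) %||%
    (if (inherits(network, "igraph") &&
         !is.null(igraph::V(network)$name)) igraph::V(network)$name
     else as.character(seq_len(n)))
  best <- NULL
  best_r <- NA_integer_
  for (r in seq_len(n_restarts)) {
    f <- with_seed_(derive_seed(seed, r),
                    fit_one_(X, Q, max_iter, tol,
                             if (r == 1L) "spectral" else "random"))
    if (is.null(best) || f$logL > best$logL) { best <- f; best_r <- r }
  }
  a <- anchor_extremal_(best$U, best$B)
  a <- order_ehns_(a$U, a$B)
  U <- a$U; B <- a$B
  rownames(U) <- ids
  dimnames(B) <- rep(list(c("EHN0", paste0("EHN", seq_len(Q - 1)))), 2)
  colnames(U) <- rownames(B)
  k <- n * (Q - 1) + (Q - 1) * Q / 2
  out <- list(Q = Q, U = U, B = B, logL = best$logL,
              aic = -2 * best$logL + 2 * k, df = k, n = n,
              n_edges = sum(X) / 2, converged = best$converged,
              iterations = best$iterations, n_restarts_used = n_restarts,
              best_restart = best_r, seed = seed,
              network = if (inherits(network, "igraph")) network else NULL,
              nodes = ids, call = match.call())
  if (trace) out$trace <- best$trace
  class(out) <- "csbm"
  out
}

#' Fit C-SBMs over a range of Q and rank them by AIC
#'
#' Fits [csbm()] for each `Q` in `Q_min:Q_max` and ranks the models by AIC
#' (`-2 logL + 2 k`, `k = n (Q - 1) + (Q - 1) Q / 2`). The AIC-best model is
#' selected unless `select` overrides it — on real data the AIC-best model
#' can reflect sampling-design structure rather than biology, so a manual
#' override is first-class.
#'
#' @inheritParams csbm
#' @param Q_min,Q_max scan range (`2 <= Q_min <= Q_max`).
#' @param select optional manual override of the selected `Q`.
#' @param ... passed to [csbm()] (`n_restarts`, `max_iter`, `tol`, `seed`).
#' @return object of class `"csbm_scan"`: list with `fits` (named by Q),
#'   `table` (Q, logL, df, aic, converged), `ranking` (Q values, best
#'   first), `selected_Q`, `override`.
#' @export
csbm_scan <- function(network, Q_min = 2, Q_max = 5, select = NULL, ...) {
  if (!(2 <= Q_min && Q_min <= Q_max)) stop("need 2 <= Q_min <= Q_max")
  Qs <- Q_min:Q_max
  fits <- lapply(Qs, function(q) csbm(network, Q = q, ...))
  names(fits) <- Qs
  tab <- data.frame(Q = Qs,
                    logL = vapply(fits, `[[`, numeric(1), "logL"),
                    df = vapply(fits, `[[`, numeric(1), "df"),
                    aic = vapply(fits, `[[`, numeric(1), "aic"),
                    converged = vapply(fits, `[[`, logical(1), "converged"))
  ranking <- Qs[order(tab$aic)]
  if (!is.null(select) && !select %in% Qs)
    stop("select must be one of the scanned Q values")
  structure(list(fits = fits, table = tab, ranking = ranking,
                 selected_Q = if (is.null(select)) ranking[1] else select,
                 override = !is.null(select)),
            class = "csbm_scan")
}

#' @export
print.csbm_scan <- function(x, ...) {
  cat("C-SBM model scan\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("AIC ranking (best first): %s\n",
              paste(x$ranking, collapse = " > ")))
  cat(sprintf("Selected Q = %d%s\n", x$selected_Q,
              if (x$override) " (manual override)" else " (AIC best)"))
  invisible(x)
}

#' Extract the selected fit from a model scan
#' @param scan a [csbm_scan()] object.
#' @return the selected `"csbm"` fit.
#' @export
selected_fit <- function(scan) {
  stopifnot(inherits(scan, "csbm_scan"))
  scan$fits[[as.character(scan$selected_Q)]]
}
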